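miR-1261, miR-1268, miR-1280, miR-1304, miR-1308, miR-1908, miR-198, miR-513a-5p, miR-513b, miR-548h, miR-580
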