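miR-1206, miR-548a-5p, miR-548f, miR-576-5p, miR-600, miR-639, miR-640, miR-641, miR-647, miR-662, miR-886-3p, miR-887, miR-628-3p, miR-888
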