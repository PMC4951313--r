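test_that("alignment identity matches hand-checkable cases", {
  expect_equal(align_identity("UGAGG", "UGAGG"), 1)
  expect_equal(align_identity("AAAA", "UUUU"), 0)
  expect_equal(align_identity("UGAGGUA", "UGAGCUA"), 6 / 7)
  # T and case are normalized to the RNA alphabet
  expect_equal(align_identity("ugagg", "UGAGG"), 1)
  expect_equal(align_identity("TGAGG", "UGAGG"), 1)
  expect_lt(align_identity("UGAGG", "UGAG"), 1) # 1.0 iff identical
  expect_error(align_identity("UGAXG", "UGAGG"), "alphabet")
  expect_error(align_identity("", "UGAGG"), "nonempty")
})

test_that("alignment identity agrees with exhaustive enumeration", {
  set.seed(515)
  for (i in 1:40) {
    a <- random_rna_str(sample(3:7, 1))
    b <- random_rna_str(sample(3:7, 1))
    oracle <- brute_align(a, b)
    got <- align_identity(a, b)
    expect_lt(min(abs(oracle$identities - got)), 1e-9,
              label = paste("identity of", a, "vs", b))
    # symmetry
    expect_equal(align_identity(b, a), got, tolerance = 1e-12)
  }
})

test_that("best cross-species hit is the all-pairs maximum", {
  set.seed(99)
  h <- mirna_catalog(sprintf("hsa-miR-%d", 1:8), random_rna_str_v(8), "hsa")
  m <- mirna_catalog(sprintf("mmu-miR-%d", 1:10), random_rna_str_v(10),
                     "mmu")
  for (id in h$ids) {
    hit <- best_cross_species_hit(id, h, m)
    idents <- vapply(m$ids, function(mm)
      align_identity(h$seq[[id]], m$seq[[mm]]), numeric(1))
    expect_equal(hit$identity, max(idents), tolerance = 1e-12)
    best_ids <- sort(m$ids[abs(idents - max(idents)) < 1e-12])
    expect_equal(hit$hit, best_ids[1]) # lexicographic tie-break
  }
  # identical sequence present: identity exactly 1
  m2 <- mirna_catalog(c("mmu-miR-z", m$ids), c(h$seq[[1]], m$seq), "mmu")
  expect_equal(best_cross_species_hit(h$ids[1], h, m2)$identity, 1)
  # empty mouse catalog: sentinel no-hit at identity 0
  m0 <- mirna_catalog(character(0), character(0), "mmu")
  expect_equal(best_cross_species_hit(h$ids[1], h, m0),
               list(hit = NA_character_, identity = 0, status = "no_hit"))
  # candidate absent from the human catalog: unresolved, not fatal
  expect_equal(best_cross_species_hit("hsa-miR-none", h, m)$status,
               "unresolved")
})

test_that("species-specificity filter handles the edge catalogs", {
  set.seed(77)
  seqs <- random_rna_str_v(6)
  h <- mirna_catalog(sprintf("hsa-miR-%d", 1:6), seqs, "hsa")
  m_same <- mirna_catalog(sprintf("mmu-miR-%d", 1:6), seqs, "mmu")
  cand <- structure(list(direction = "up", members = h$ids,
                         provenance = stats::setNames(
                           rep(list("c|h"), 6), h$ids),
                         cutoff = 2), class = "candidate_set")
  # mouse catalog identical to human: nothing retained
  flt <- filter_species_specific(cand, h, m_same, 0.8)
  expect_length(flt$retained$members, 0)
  expect_true(all(flt$report$decision == "excluded"))
  # fully disjoint synthetic catalogs: everything retained
  cats <- simulate_catalogs(0, 6, 6, seed = 8)
  cand2 <- structure(list(direction = "up", members = cats$human$ids,
                          provenance = stats::setNames(
                            rep(list("c|h"), 6), cats$human$ids),
                          cutoff = 2), class = "candidate_set")
  flt2 <- filter_species_specific(cand2, cats$human, cats$mouse, 0.8)
  expect_setequal(flt2$retained$members, cats$human$ids)
  expect_equal(flt2$retained$provenance, cand2$provenance[flt2$retained$members])
  # unresolved candidates are reported and excluded from retained
  cand3 <- cand2
  cand3$members <- c(cand3$members, "hsa-miR-ghost")
  flt3 <- filter_species_specific(cand3, cats$human, cats$mouse, 0.8)
  expect_equal(sum(flt3$report$decision == "unresolved"), 1)
  expect_false("hsa-miR-ghost" %in% flt3$retained$members)
  # conservation: decisions partition the input
  expect_setequal(flt3$report$candidate, cand3$members)
  expect_error(filter_species_specific(cand2, cats$human, cats$mouse, 0),
               "identity_threshold")
})

test_that("raising the identity threshold never shrinks the retained set", {
  cats <- simulate_catalogs(4, 4, 4, seed = 23, n_near_identical = 2)
  cand <- structure(list(direction = "up", members = cats$human$ids,
                         provenance = stats::setNames(
                           rep(list("c|h"), length(cats$human$ids)),
                           cats$human$ids),
                         cutoff = 2), class = "candidate_set")
  prev <- character(0)
  for (th in c(0.3, 0.5, 0.8, 0.95, 1)) {
    kept <- filter_species_specific(cand, cats$human, cats$mouse,
                                    th)$retained$members
    expect_true(all(prev %in% kept))
    prev <- kept
  }
})

test_that("printed candidate lists parse to the published partition", {
  up <- parse_candidate_list(system.file("extdata",
                                         "human_specific_up.txt",
                                         package = "miRtraverse"))
  down <- parse_candidate_list(system.file("extdata",
                                           "human_specific_down.txt",
                                           package = "miRtraverse"))
  expect_length(up, 11)
  expect_length(down, 14)
  expect_length(union(up, down), 25)
  expect_true(all(startsWith(c(up, down), "hsa-miR-")))
  expect_true("hsa-miR-548h" %in% up)
  expect_true("hsa-miR-1206" %in% down)
})

test_that("candidate list parsing validates tokens and duplicates", {
  expect_equal(parse_candidate_list("miR-21, mmu-miR-22"),
               c("hsa-miR-21", "mmu-miR-22"))
  expect_equal(parse_candidate_list(character(0)), character(0))
  expect_equal(parse_candidate_list(""), character(0))
  expect_error(parse_candidate_list("miR-21, banana"), "banana")
  expect_error(parse_candidate_list("miR-21 miR-21"), "duplicate")
})

test_that("top-marker flagging applies the strict fold bar to up sets", {
  cfg <- small_config(noise_cv = 0, seed = 61,
                      top_fold_range = c(12, 12))
  sim <- simulate_mirnome(cfg)
  scr <- mirnome_screen(sim$matrix, sim$manifest)
  expect_setequal(scr$top_markers, sim$truth$top_markers)
  expect_length(scr$top_markers, 2)
  # min_fold 1 flags every up candidate
  all_flagged <- flag_top_markers(scr$traverse$up, scr$ranks$up,
                                  min_fold = 1)
  expect_setequal(all_flagged, scr$traverse$up$members)
  # impossible bar flags nothing
  expect_length(flag_top_markers(scr$traverse$up, scr$ranks$up,
                                 min_fold = 1e6), 0)
  expect_error(flag_top_markers(scr$traverse$down, scr$ranks$down),
               "upregulated")
})

test_that("catalog FASTA round-trip keeps ids and normalized sequences", {
  cats <- simulate_catalogs(3, 2, 2, seed = 5)
  p <- withr::local_tempfile(fileext = ".fa")
  write_mirna_catalog(cats$human, p)
  back <- read_mirna_catalog(p, species = "hsa")
  expect_equal(back$seq, cats$human$seq)
  # miRBase-style headers with annotations parse by first token
  writeLines(c(">hsa-miR-21-5p MIMAT0000076 Homo sapiens miR-21-5p",
               "UAGCUUAUCAGACUGAUGUUGA",
               ">mmu-miR-21a-5p MIMAT0000530 Mus musculus miR-21a-5p",
               "uagcuuaucagacugauguuga"), p)
  hsa <- read_mirna_catalog(p, species = "hsa")
  expect_equal(hsa$ids, "hsa-miR-21-5p")
  mmu <- read_mirna_catalog(p, species = "mmu")
  expect_equal(unname(mmu$seq), "UAGCUUAUCAGACUGAUGUUGA")
  writeLines(c(">NOT_A_SPECIES-miR-1", "ACGUACGUACGUACGUACGU"), p)
  expect_error(read_mirna_catalog(p), "species prefix")
})
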