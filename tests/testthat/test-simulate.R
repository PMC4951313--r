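test_that("sim_config enforces the study-design invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_mirna_probes = 0), "positive")
  expect_error(sim_config(n_up_planted = 500, n_down_planted = 500),
               "exceed")
  expect_error(sim_config(up_fold_range = c(1.5, 4)), "above 2")
  expect_error(sim_config(down_fold_range = c(0.1, 0.6)), "0.5")
  expect_error(sim_config(n_top_markers = 40), "n_up_planted")
  expect_error(sim_config(noise_cv = -1), "nonnegative")
})

test_that("default simulation plants the published candidate counts", {
  sim <- simulate_mirnome(sim_config(seed = 2))
  expect_length(sim$truth$planted_up, 34)
  expect_length(sim$truth$planted_down, 46)
  expect_length(sim$truth$top_markers, 3)
  expect_true(all(sim$truth$top_markers %in% names(sim$truth$planted_up)))
  expect_length(intersect(names(sim$truth$planted_up),
                          names(sim$truth$planted_down)), 0)
  # platform scale: 852 miRNA probes + 144 controls
  expect_equal(dim(sim$matrix), c(852L + 144L, 8L))
  expect_equal(sum(sim$matrix$probe_class == "mirna"), 852)
  expect_equal(sum(sim$matrix$probe_class != "mirna"), 144)
})

test_that("identical seed and config give byte-identical output", {
  a <- simulate_mirnome(sim_config(seed = 17))
  b <- simulate_mirnome(sim_config(seed = 17))
  expect_identical(a, b)
  c <- simulate_mirnome(sim_config(seed = 18))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("noiseless planted folds survive preprocessing exactly", {
  sim <- simulate_mirnome(small_config(noise_cv = 0, seed = 9))
  pp <- preprocess(sim$matrix, sim$manifest)
  man <- sim$manifest
  ctl <- man$sample_id[man$group == "nmx"][1]
  for (cs in man$sample_id[man$group == "hr"]) {
    fc <- fold_change(pp, ctl, cs)
    got <- fc$ratio[match(names(sim$truth$planted_up), fc$mirna)]
    expect_equal(got, unname(sim$truth$planted_up), tolerance = 1e-10)
    got_d <- fc$ratio[match(names(sim$truth$planted_down), fc$mirna)]
    expect_equal(got_d, unname(sim$truth$planted_down), tolerance = 1e-10)
  }
})

test_that("catalog homology classes behave as constructed", {
  # disjoint construction: every human entry species-specific
  cat0 <- simulate_catalogs(0, 5, 5, seed = 3)
  expect_true(all(cat0$truth$species_specific))
  expect_length(cat0$human$ids, 5)
  expect_length(cat0$mouse$ids, 5)
  # identical construction: none species-specific
  cat1 <- simulate_catalogs(5, 0, 0, seed = 3)
  expect_false(any(cat1$truth$species_specific))
  expect_equal(unname(cat1$human$seq),
               unname(cat1$mouse$seq))
  expect_error(simulate_catalogs(0, 0, 0), "nonzero")
})

test_that("catalog truth table matches the downstream homology filter", {
  cats <- simulate_catalogs(3, 2, 1, seed = 21, n_near_identical = 2)
  cats_again <- simulate_catalogs(3, 2, 1, seed = 21, n_near_identical = 2)
  expect_identical(cats, cats_again)
  cand <- structure(list(direction = "up", members = cats$human$ids,
                         provenance = setNames(vector("list",
                                                      length(cats$human$ids)),
                                               cats$human$ids),
                         cutoff = 2), class = "candidate_set")
  flt <- filter_species_specific(cand, cats$human, cats$mouse, 0.8)
  expect_setequal(flt$retained$members,
                  cats$truth$id[cats$truth$species_specific])
  near <- cats$truth$id[cats$truth$class == "near_identical"]
  near_rows <- flt$report[match(near, flt$report$candidate), ]
  expect_true(all(near_rows$decision == "excluded"))
  expect_true(all(near_rows$identity >= 0.8 & near_rows$identity < 1))
})

test_that("qPCR generator recovers folds through delta-delta-Ct exactly", {
  q <- simulate_qpcr(c(`hsa-miR-x` = 4, `hsa-miR-y` = 1), ct_noise_sd = 0,
                     seed = 4)
  folds <- qpcr_fold_change(q$ct, q$manifest)
  hr <- folds[folds$group == "hr", ]
  expect_equal(unique(hr$ddct[hr$mirna == "hsa-miR-x"]), -2,
               tolerance = 1e-12)
  expect_equal(hr$fold[hr$mirna == "hsa-miR-x"], rep(4, 3),
               tolerance = 1e-12)
  expect_equal(hr$fold[hr$mirna == "hsa-miR-y"], rep(1, 3),
               tolerance = 1e-12)
  expect_error(simulate_qpcr(c(a = -2)), "positive")
  expect_error(simulate_qpcr(c(a = 2), n_replicates = 0), "replicates")
})

test_that("positivity counts follow the planted proportions", {
  p0 <- simulate_positivity(c(g = 0), n_fields = 10, seed = 1)
  expect_true(all(p0$positive == 0))
  p1 <- simulate_positivity(c(g = 1), n_fields = 10, seed = 1)
  expect_true(all(p1$positive == p1$total))
  expect_error(simulate_positivity(c(g = 1.2)), "\\[0, 1\\]")
  # binomial sampling: mean positivity near 30% across seeds
  means <- vapply(1:40, function(s) {
    tab <- simulate_positivity(c(g = 0.3), n_fields = 63, seed = s)
    mean(100 * tab$positive / tab$total)
  }, numeric(1))
  expect_true(mean(abs(means - 30) <= 3) >= 0.95)
})

test_that("target map plants common genes exactly and is reproducible", {
  groups <- list(up = c("m1", "m2", "m3", "m4", "m5"), down = c("m6", "m7"))
  map <- simulate_target_map(groups, planted_common = list(GENE1 = groups$up),
                             n_background_targets = 30, seed = 6)
  expect_identical(map, simulate_target_map(
    groups, planted_common = list(GENE1 = groups$up),
    n_background_targets = 30, seed = 6))
  tab <- common_targets(map, groups$up, min_support = 2)
  expect_equal(tab$gene[1], "GENE1")
  expect_equal(tab$count[1], 5L)
  # background is 1-regular: without planting, no gene exceeds support 1
  map_bg <- simulate_target_map(groups, n_background_targets = 30, seed = 6)
  tab_bg <- common_targets(map_bg, unlist(groups), min_support = 2)
  expect_true(all(!startsWith(tab_bg$gene, "BG")))
  expect_error(simulate_target_map(groups,
                                   planted_common = list(G = "absent")),
               "not in any group")
})
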