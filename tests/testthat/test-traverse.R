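pos_matrix <- function(vals) expression_matrix(vals)

test_that("fold_change is the elementwise case/control ratio", {
  v <- matrix(c(2, 10, 8, 5), ncol = 2,
              dimnames = list(c("hsa-miR-a", "hsa-miR-b"), c("c1", "h1")))
  x <- pos_matrix(v)
  fc <- fold_change(x, "c1", "h1")
  expect_equal(fc$ratio, c(4, 0.5))
  # identity comparison
  expect_equal(fold_change(x, "c1", "c1")$ratio, c(1, 1))
  # anti-symmetry
  rev <- fold_change(x, "h1", "c1")
  expect_equal(rev$ratio, 1 / fc$ratio)
  expect_error(fold_change(x, "c1", "nope"), "unknown sample")
})

test_that("threshold sets honor the inclusive 2-fold criterion", {
  fc <- data.frame(mirna = c("A", "B", "C", "D"),
                   ratio = c(4, 1.5, 0.4, 2))
  s <- threshold_sets(fc, cutoff = 2)
  expect_setequal(s$up, c("A", "D")) # boundary 2.0 is included
  expect_equal(s$down, "C")
  strict <- threshold_sets(fc, cutoff = 2, strict = TRUE)
  expect_equal(strict$up, "A")
  # degenerate cutoff 1: ratio exactly 1 goes to neither set
  fc1 <- data.frame(mirna = c("A", "B", "C"), ratio = c(1, 2, 0.5))
  s1 <- threshold_sets(fc1, cutoff = 1)
  expect_false("A" %in% c(s1$up, s1$down))
  expect_setequal(c(s1$up, s1$down), c("B", "C"))
  expect_error(threshold_sets(fc, cutoff = 0.5), ">= 1")
})

test_that("per-control consensus is plain intersection", {
  expect_equal(per_control_consensus(list(c("A", "B"), c("B", "C"), "B")),
               "B")
  expect_equal(per_control_consensus(list(c("A", "B"))), c("A", "B"))
  expect_equal(per_control_consensus(list(character(0), c("A"))),
               character(0))
  expect_error(per_control_consensus(list()), "at least one")
})

test_that("traverse consensus matches brute-force enumeration", {
  set.seed(424)
  for (i in 1:25) {
    n_m <- sample(3:20, 1)
    n_c <- sample(1:3, 1)
    n_h <- sample(1:3, 1)
    ids <- sprintf("hsa-miR-t%02d", seq_len(n_m))
    samples <- c(sprintf("nmx_%d", seq_len(n_c)),
                 sprintf("hr_%d", seq_len(n_h)))
    v <- matrix(2^runif(n_m * length(samples), -4, 4), nrow = n_m,
                dimnames = list(ids, samples))
    man <- sample_manifest(samples, rep(c("nmx", "hr"), c(n_c, n_h)))
    res <- traverse_consensus(pos_matrix(v), man, cutoff = 2)
    oracle <- brute_traverse(v, man, cutoff = 2)
    expect_equal(res$up$members, oracle$up)
    expect_equal(res$down$members, oracle$down)
  }
})

test_that("single comparison consensus equals its thresholded sets", {
  v <- matrix(c(3, 9, 10, 2), ncol = 2,
              dimnames = list(c("hsa-miR-a", "hsa-miR-b"),
                              c("nmx_1", "hr_1")))
  man <- sample_manifest(colnames(v), c("nmx", "hr"))
  res <- traverse_consensus(pos_matrix(v), man, cutoff = 2)
  s <- threshold_sets(fold_change(pos_matrix(v), "nmx_1", "hr_1"), 2)
  expect_setequal(res$up$members, s$up)
  expect_setequal(res$down$members, s$down)
  expect_error(traverse_consensus(pos_matrix(v), man[1, , drop = FALSE]),
               "manifest|missing-group")
})

test_that("candidate sets are invariant under sample order shuffles", {
  sim <- simulate_mirnome(small_config(seed = 44))
  pp <- preprocess(sim$matrix, sim$manifest)
  res <- traverse_consensus(pp, sim$manifest)
  set.seed(7)
  perm <- sample(colnames(pp$values))
  pp2 <- expression_matrix(pp$values[, perm], pp$probe_class)
  res2 <- traverse_consensus(pp2, sim$manifest[sample(nrow(sim$manifest)), ])
  expect_identical(res$up$members, res2$up$members)
  expect_identical(res$down$members, res2$down$members)
})

test_that("the report narrows monotonically through intersection stages", {
  sim <- simulate_mirnome(sim_config(seed = 45))
  pp <- preprocess(sim$matrix, sim$manifest)
  res <- traverse_consensus(pp, sim$manifest)
  rep <- res$report
  fin <- rep[rep$stage == "final", ]
  for (ctl in unique(rep$control[rep$stage == "per_control"])) {
    pc <- rep[rep$stage == "per_control" & rep$control == ctl, ]
    pw <- rep[rep$stage == "pairwise" & rep$control == ctl, ]
    expect_true(all(pc$n_up <= pw$n_up))
    expect_true(all(pc$n_down <= pw$n_down))
    expect_true(fin$n_up <= pc$n_up)
    expect_true(fin$n_down <= pc$n_down)
  }
  expect_equal(fin$n_up, length(res$up$members))
  # provenance covers every comparison for every final member
  expect_true(all(lengths(res$up$provenance) == length(res$tables)))
})

test_that("raising the cutoff never grows a candidate set", {
  sim <- simulate_mirnome(small_config(seed = 46))
  pp <- preprocess(sim$matrix, sim$manifest)
  prev_up <- NULL
  for (cut in c(1.5, 2, 3, 5)) {
    res <- traverse_consensus(pp, sim$manifest, cutoff = cut)
    if (!is.null(prev_up)) {
      expect_true(all(res$up$members %in% prev_up))
      expect_true(all(res$down$members %in% prev_dn))
    }
    prev_up <- res$up$members
    prev_dn <- res$down$members
  }
})

test_that("conservative fold ranking uses the worst comparison and id ties", {
  tabs <- list(
    a = data.frame(mirna = c("hsa-miR-x", "hsa-miR-y"), ratio = c(4, 6)),
    b = data.frame(mirna = c("hsa-miR-x", "hsa-miR-y"), ratio = c(6, 4)))
  cs <- structure(list(direction = "up", members = c("hsa-miR-x",
                                                     "hsa-miR-y"),
                       provenance = list(), cutoff = 2),
                  class = "candidate_set")
  rk <- rank_by_min_fold(cs, tabs)
  expect_equal(rk$conservative_fold, c(4, 4))
  expect_equal(rk$mirna, c("hsa-miR-x", "hsa-miR-y")) # lexicographic tie
  # down direction keeps the least-suppressed (max) ratio
  csd <- structure(list(direction = "down", members = "hsa-miR-x",
                        provenance = list(), cutoff = 2),
                   class = "candidate_set")
  tabs_d <- list(a = data.frame(mirna = "hsa-miR-x", ratio = 0.1),
                 b = data.frame(mirna = "hsa-miR-x", ratio = 0.3))
  expect_equal(rank_by_min_fold(csd, tabs_d)$conservative_fold, 0.3)
  # missing candidate is a consistency error
  bad <- list(a = data.frame(mirna = "hsa-miR-z", ratio = 2))
  expect_error(rank_by_min_fold(cs, bad), "consistency error")
})
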