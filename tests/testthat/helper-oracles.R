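# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by exhaustive enumeration, never through the package's
# own code paths (or the libraries standing behind them).

# Enumerate every global alignment of two short strings and return the
# optimal score plus the set of identity fractions achieved by
# score-optimal alignments.
brute_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  res <- list()
  rec <- function(i, j, score, matches, len) {
    if (i > length(av) && j > length(bv)) {
      res[[length(res) + 1]] <<- c(score, matches, len)
      return(invisible(NULL))
    }
    if (i <= length(av) && j <= length(bv)) {
      hit <- av[i] == bv[j]
      rec(i + 1, j + 1, score + if (hit) match else mismatch,
          matches + hit, len + 1)
    }
    if (i <= length(av)) rec(i + 1, j, score + gap, matches, len + 1)
    if (j <= length(bv)) rec(i, j + 1, score + gap, matches, len + 1)
  }
  rec(1L, 1L, 0, 0L, 0L)
  m <- do.call(rbind, res)
  best <- max(m[, 1])
  list(score = best,
       identities = unique(m[m[, 1] == best, 2] / m[m[, 1] == best, 3]))
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_rna_str_v <- function(n, len_range = 20:24) {
  vapply(seq_len(n), function(i) random_rna_str(sample(len_range, 1)),
         character(1))
}

# Independent traverse enumeration: plain nested loops over every
# control-case pair, no set machinery shared with the implementation.
brute_traverse <- function(values, manifest, cutoff) {
  controls <- sort(manifest$sample_id[manifest$group == "nmx"])
  cases <- sort(manifest$sample_id[manifest$group == "hr"])
  up <- character(0)
  down <- character(0)
  for (m in rownames(values)) {
    ok_up <- TRUE
    ok_dn <- TRUE
    for (ctl in controls) {
      for (cs in cases) {
        r <- values[m, cs] / values[m, ctl]
        if (!(r >= cutoff)) ok_up <- FALSE
        if (!(r <= 1 / cutoff)) ok_dn <- FALSE
      }
    }
    if (ok_up) up <- c(up, m)
    if (ok_dn) down <- c(down, m)
  }
  list(up = sort(up), down = sort(down))
}

# Independent common-target counting by direct looping.
brute_common_targets <- function(map, mirnas, min_support, min_evidence) {
  lev <- c(predicted = 1, highly_predicted = 2, experimental = 3)
  keep <- map$mirna %in% mirnas & lev[map$evidence] >= lev[min_evidence]
  sub <- map[keep, , drop = FALSE]
  genes <- unique(toupper(sub$gene))
  counts <- stats::setNames(integer(0), character(0))
  for (g in genes) {
    supp <- unique(sub$mirna[toupper(sub$gene) == g])
    if (length(supp) >= min_support) counts[g] <- length(supp)
  }
  counts[order(-counts, names(counts))]
}

# Tiny positive expression matrix with explicit values for unit tests.
tiny_matrix <- function(values, classes = NULL) {
  expression_matrix(values, classes)
}

# A reduced study configuration used where the full platform scale is not
# the point of the test.
small_config <- function(...) {
  sim_config(n_mirna_probes = 60, n_control_probes = 24, n_up_planted = 6,
             n_down_planted = 6, n_top_markers = 2, ...)
}
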