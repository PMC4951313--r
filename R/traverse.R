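#' Per-miRNA fold change between one control and one case sample
#'
#' @param x Preprocessed [expression_matrix()] (strictly positive values).
#' @param control,case Sample ids present in `x`.
#' @return data.frame with columns `mirna` and `ratio` (case / control),
#'   with attributes `control` and `case`.
#' @export
fold_change <- function(x, control, case) {
  s <- colnames(x$values)
  miss <- setdiff(c(control, case), s)
  if (length(miss))
    stop("unknown sample id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(x$values[, c(control, case)] <= 0))
    stop("fold changes need strictly positive values; preprocess first",
         call. = FALSE)
  fc <- data.frame(mirna = rownames(x$values),
                   ratio = x$values[, case] / x$values[, control],
                   stringsAsFactors = FALSE, row.names = NULL)
  attr(fc, "control") <- control
  attr(fc, "case") <- case
  fc
}

#' Threshold a fold-change table into up / down sets
#'
#' Upregulated: ratio at or above `cutoff` (strictly above with
#' `strict = TRUE`); downregulated: ratio at or below `1 / cutoff`. Ratios
#' exactly 1 belong to neither set (this only matters for the degenerate
#' `cutoff = 1`).
#'
#' @param fc A [fold_change()] table.
#' @param cutoff Fold-change cutoff, at least 1 (default 2).
#' @param strict Use strict inequalities (default FALSE, i.e. ">= 2 fold").
#' @return List with character vectors `up` and `down`.
#' @export
threshold_sets <- function(fc, cutoff = 2, strict = FALSE) {
  if (cutoff < 1) stop("cutoff must be >= 1", call. = FALSE)
  r <- fc$ratio
  up <- if (strict) r > cutoff else r >= cutoff
  down <- if (strict) r < 1 / cutoff else r <= 1 / cutoff
  up <- up & r != 1
  down <- down & r != 1
  list(up = fc$mirna[up], down = fc$mirna[down])
}

#' Intersect per-case candidate sets for one control
#'
#' @param sets List of miRNA id vectors, one per case sample.
#' @return The intersection (ids consistent across all cases).
#' @export
per_control_consensus <- function(sets) {
  if (length(sets) == 0)
    stop("per_control_consensus needs at least one set", call. = FALSE)
  Reduce(intersect, sets)
}

new_candidate_set <- function(direction, members, provenance, cutoff) {
  structure(list(direction = direction, members = members,
                 provenance = provenance, cutoff = cutoff),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set (", x$direction, "regulated): ", length(x$members),
      " miRNAs at cutoff ", x$cutoff, "\n", sep = "")
  if (length(x$members))
    cat(" ", paste(utils::head(x$members, 8), collapse = ", "),
        if (length(x$members) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Traverse consensus analysis over all control-by-case comparisons
#'
#' Runs the traverse analysis: every NM-X control is compared with every
#' high-risk case; each comparison is thresholded into up / down sets; the
#' sets are intersected across cases for each control, and the per-control
#' consensus sets are intersected across controls to give the final
#' candidate sets. A stage-wise report records raw (any-direction) and
#' thresholded counts for every comparison, per-control consensus and the
#' final consensus, mirroring the successive narrowing of the published
#' box diagram.
#'
#' @param x Preprocessed [expression_matrix()].
#' @param manifest A [sample_manifest()]; needs at least one `nmx` and one
#'   `hr` sample present in `x`.
#' @param cutoff Fold-change cutoff (default 2).
#' @param strict Strict inequalities at the cutoff (default FALSE).
#' @return An object of class `traverse_result`: list with `up` and `down`
#'   [candidate sets][per_control_consensus], `report` (stage-wise count
#'   data.frame), and `tables` (named list of fold-change tables, one per
#'   comparison, named `"control|case"`).
#' @export
traverse_consensus <- function(x, manifest, cutoff = 2, strict = FALSE) {
  controls <- manifest_samples(x, manifest, "nmx")
  cases <- manifest_samples(x, manifest, "hr")
  if (length(controls) == 0 || length(cases) == 0)
    stop("missing-group error: need at least one nmx and one hr sample",
         call. = FALSE)
  controls <- sort(controls)
  cases <- sort(cases)

  tables <- list()
  pair_sets <- list()
  pair_raw <- list()
  report <- list()
  for (ctl in controls) {
    for (cs in cases) {
      key <- paste(ctl, cs, sep = "|")
      fc <- fold_change(x, ctl, cs)
      tables[[key]] <- fc
      pair_sets[[key]] <- threshold_sets(fc, cutoff, strict)
      pair_raw[[key]] <- list(up = fc$mirna[fc$ratio > 1],
                              down = fc$mirna[fc$ratio < 1])
      report[[length(report) + 1]] <- data.frame(
        stage = "pairwise", control = ctl, case = cs,
        n_up_raw = length(pair_raw[[key]]$up),
        n_up = length(pair_sets[[key]]$up),
        n_down_raw = length(pair_raw[[key]]$down),
        n_down = length(pair_sets[[key]]$down),
        stringsAsFactors = FALSE)
    }
  }

  ctl_cons <- list()
  for (ctl in controls) {
    keys <- paste(ctl, cases, sep = "|")
    ctl_cons[[ctl]] <- list(
      up = per_control_consensus(lapply(pair_sets[keys], `[[`, "up")),
      down = per_control_consensus(lapply(pair_sets[keys], `[[`, "down")),
      up_raw = per_control_consensus(lapply(pair_raw[keys], `[[`, "up")),
      down_raw = per_control_consensus(lapply(pair_raw[keys], `[[`, "down")))
    report[[length(report) + 1]] <- data.frame(
      stage = "per_control", control = ctl, case = NA_character_,
      n_up_raw = length(ctl_cons[[ctl]]$up_raw),
      n_up = length(ctl_cons[[ctl]]$up),
      n_down_raw = length(ctl_cons[[ctl]]$down_raw),
      n_down = length(ctl_cons[[ctl]]$down),
      stringsAsFactors = FALSE)
  }

  final_up <- sort(per_control_consensus(lapply(ctl_cons, `[[`, "up")))
  final_down <- sort(per_control_consensus(lapply(ctl_cons, `[[`, "down")))
  final_up_raw <- per_control_consensus(lapply(ctl_cons, `[[`, "up_raw"))
  final_down_raw <- per_control_consensus(lapply(ctl_cons, `[[`, "down_raw"))
  report[[length(report) + 1]] <- data.frame(
    stage = "final", control = NA_character_, case = NA_character_,
    n_up_raw = length(final_up_raw), n_up = length(final_up),
    n_down_raw = length(final_down_raw), n_down = length(final_down),
    stringsAsFactors = FALSE)
  report <- do.call(rbind, report)

  # monotone filtration sanity check: counts never grow along intersections
  for (ctl in controls) {
    pc <- report[report$stage == "per_control" & report$control == ctl, ]
    pw <- report[report$stage == "pairwise" & report$control == ctl, ]
    stopifnot(all(pc$n_up <= pw$n_up), all(pc$n_down <= pw$n_down))
    stopifnot(length(final_up) <= pc$n_up, length(final_down) <= pc$n_down)
  }

  comparisons <- names(tables)
  provenance_for <- function(members)
    stats::setNames(rep(list(comparisons), length(members)), members)
  structure(list(
    up = new_candidate_set("up", final_up, provenance_for(final_up), cutoff),
    down = new_candidate_set("down", final_down, provenance_for(final_down),
                             cutoff),
    report = report, tables = tables), class = "traverse_result")
}

#' @export
print.traverse_result <- function(x, ...) {
  fin <- x$report[x$report$stage == "final", ]
  cat("traverse_result: ", length(x$tables), " comparisons, cutoff ",
      x$up$cutoff, "\n", sep = "")
  cat("  final consensus: ", fin$n_up, " up, ", fin$n_down, " down\n",
      sep = "")
  invisible(x)
}

#' Rank candidates by conservative (worst-case) fold change
#'
#' The conservative fold of an upregulated candidate is its minimum ratio
#' over all comparisons it survived; for a downregulated candidate it is the
#' maximum (least suppressed) ratio. Ordering is by decreasing effect size,
#' ties broken lexicographically by miRNA id.
#'
#' @param cands A candidate set from [traverse_consensus()].
#' @param tables The fold-change tables of the run (`$tables` of a
#'   `traverse_result`).
#' @return data.frame with columns `mirna` and `conservative_fold`, ordered
#'   by decreasing effect size.
#' @export
rank_by_min_fold <- function(cands, tables) {
  if (length(cands$members) == 0)
    return(data.frame(mirna = character(0), conservative_fold = numeric(0)))
  ratios <- vapply(tables, function(fc) {
    idx <- match(cands$members, fc$mirna)
    if (anyNA(idx))
      stop("consistency error: candidate(s) missing from a fold table: ",
           paste(cands$members[is.na(idx)], collapse = ", "), call. = FALSE)
    fc$ratio[idx]
  }, numeric(length(cands$members)))
  ratios <- matrix(ratios, nrow = length(cands$members))
  cons <- if (cands$direction == "up") apply(ratios, 1, min)
          else apply(ratios, 1, max)
  ord <- if (cands$direction == "up") order(-cons, cands$members)
         else order(cons, cands$members)
  data.frame(mirna = cands$members[ord], conservative_fold = cons[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write candidate sets with conservative folds to TSV
#'
#' One row per candidate: `mirna`, `direction`, `conservative_fold`,
#' `n_comparisons`.
#'
#' @param result A `traverse_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(result, path) {
  rows <- lapply(list(result$up, result$down), function(cs) {
    rk <- rank_by_min_fold(cs, result$tables)
    if (nrow(rk) == 0) return(NULL)
    data.frame(mirna = rk$mirna, direction = cs$direction,
               conservative_fold = rk$conservative_fold,
               n_comparisons = lengths(cs$provenance[rk$mirna]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mirna = character(0), direction = character(0),
                      conservative_fold = numeric(0),
                      n_comparisons = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
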