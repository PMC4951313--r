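#' Screen a serum miRnome array for prognostic biomarker candidates
#'
#' The central fitting-style entry point: preprocesses the raw array
#' (background subtraction, control normalization, sham baseline
#' correction), runs the traverse fold-change consensus between NM-X
#' controls and high-risk cases, ranks candidates by conservative fold,
#' flags top markers above the high-fold bar, and - when two-species mature
#' catalogs are supplied - applies the zero-homology filter to retain
#' human-specific candidates.
#'
#' @param x Raw [expression_matrix()].
#' @param manifest A [sample_manifest()].
#' @param human,mouse Optional [mirna_catalog()] objects enabling the
#'   homology filter.
#' @param cutoff Traverse fold-change cutoff (default 2).
#' @param identity_threshold Homology identity threshold (default 0.80).
#' @param top_fold Top-marker fold bar (default 10); flagging is applied to
#'   the full upregulated consensus set, before the homology filter.
#' @param normalize,sham_correct,background_subtract,epsilon Passed to
#'   [preprocess()].
#' @param strict Strict threshold inequalities (default FALSE).
#' @return An object of class `mirnome_screen` with components `matrix`
#'   (preprocessed), `traverse` (the `traverse_result`), `ranks` (named
#'   list of conservative-fold tables), `top_markers`, `homology` (NULL or
#'   per-direction filter results), `params` and `call`. Methods:
#'   [print.mirnome_screen()], [summary.mirnome_screen()],
#'   [coef.mirnome_screen()], [plot.mirnome_screen()].
#' @examples
#' sim <- simulate_mirnome(sim_config(n_mirna_probes = 60, n_up_planted = 5,
#'                                    n_down_planted = 5, n_top_markers = 1,
#'                                    noise_cv = 0, seed = 3))
#' scr <- mirnome_screen(sim$matrix, sim$manifest)
#' scr
#' @export
mirnome_screen <- function(x, manifest, human = NULL, mouse = NULL,
                           cutoff = 2, identity_threshold = 0.8,
                           top_fold = 10, normalize = "spike_in",
                           sham_correct = TRUE, background_subtract = TRUE,
                           epsilon = 1, strict = FALSE) {
  pp <- preprocess(x, manifest, normalize = normalize,
                   sham_correct = sham_correct,
                   background_subtract = background_subtract,
                   epsilon = epsilon)
  tr <- traverse_consensus(pp, manifest, cutoff = cutoff, strict = strict)
  ranks <- list(up = rank_by_min_fold(tr$up, tr$tables),
                down = rank_by_min_fold(tr$down, tr$tables))
  top <- flag_top_markers(tr$up, ranks$up, min_fold = top_fold)
  hom <- NULL
  if (!is.null(human) && !is.null(mouse)) {
    hom <- list(up = filter_species_specific(tr$up, human, mouse,
                                             identity_threshold),
                down = filter_species_specific(tr$down, human, mouse,
                                               identity_threshold))
  }
  structure(list(matrix = pp, traverse = tr, ranks = ranks,
                 top_markers = top, homology = hom,
                 params = list(cutoff = cutoff,
                               identity_threshold = identity_threshold,
                               top_fold = top_fold, normalize = normalize,
                               sham_correct = sham_correct,
                               epsilon = epsilon, strict = strict),
                 call = match.call()),
            class = "mirnome_screen")
}

#' @export
print.mirnome_screen <- function(x, ...) {
  cat("mirnome_screen of", nrow(x$matrix$values), "miRNAs over",
      length(x$traverse$tables), "control-case comparisons\n")
  cat("  consensus candidates: ", length(x$traverse$up$members), " up, ",
      length(x$traverse$down$members), " down (cutoff ", x$params$cutoff,
      "-fold)\n", sep = "")
  if (!is.null(x$homology))
    cat("  species-specific:     ",
        length(x$homology$up$retained$members), " up, ",
        length(x$homology$down$retained$members),
        " down (identity < ", x$params$identity_threshold, ")\n", sep = "")
  cat("  top markers (> ", x$params$top_fold, "-fold): ",
      if (length(x$top_markers)) paste(x$top_markers, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' @rdname print.mirnome_screen
#' @param object A `mirnome_screen`.
#' @method summary mirnome_screen
#' @export
summary.mirnome_screen <- function(object, ...) {
  cat("Traverse report:\n")
  print(object$traverse$report, row.names = FALSE)
  cat("\nTop of the ranked candidate tables:\n")
  print(utils::head(object$ranks$up), row.names = FALSE)
  print(utils::head(object$ranks$down), row.names = FALSE)
  if (!is.null(object$homology)) {
    cat("\nHomology decisions (up):\n")
    print(utils::head(object$homology$up$report, 12), row.names = FALSE)
  }
  invisible(object)
}

#' Conservative log2 fold changes of the consensus candidates
#'
#' @param object A `mirnome_screen`.
#' @param ... Unused.
#' @return Named numeric vector of conservative log2 folds (positive for
#'   upregulated, negative for downregulated candidates).
#' @method coef mirnome_screen
#' @export
coef.mirnome_screen <- function(object, ...) {
  up <- object$ranks$up
  dn <- object$ranks$down
  stats::setNames(c(log2(up$conservative_fold), log2(dn$conservative_fold)),
                  c(up$mirna, dn$mirna))
}

#' Plot conservative fold changes of a screen
#'
#' Base-graphics dot chart of conservative log2 fold changes, upregulated
#' candidates in red and downregulated in blue, with the cutoff and
#' top-marker bars drawn.
#'
#' @param x A `mirnome_screen`.
#' @param ... Passed to [graphics::plot()].
#' @method plot mirnome_screen
#' @export
plot.mirnome_screen <- function(x, ...) {
  lfc <- sort(coef(x))
  col <- ifelse(lfc > 0, "firebrick", "steelblue")
  graphics::plot(seq_along(lfc), lfc, pch = 19, col = col,
                 xlab = "candidate rank", ylab = "conservative log2 fold",
                 main = "Traverse consensus candidates", ...)
  graphics::abline(h = c(-1, 1) * log2(x$params$cutoff), lty = 2)
  graphics::abline(h = log2(x$params$top_fold), lty = 3)
  invisible(x)
}
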