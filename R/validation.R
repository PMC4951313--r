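#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Technical replicates are averaged per (miRNA, sample); delta-Ct is the
#' target Ct minus the reference (U6) Ct of the same sample; delta-delta-Ct
#' subtracts the mean control-group delta-Ct of the miRNA; the fold change
#' is `2^-ddCt` (exact amplification doubling assumed). By construction the
#' geometric mean fold over the control group is 1.
#'
#' @param ct Long-format Ct table: data.frame with columns `mirna`,
#'   `sample`, `ct` (optionally `replicate`).
#' @param manifest Sample manifest (`sample_id`, `group`).
#' @param control_group Group label anchoring the fold scale (default
#'   `"nmx"`).
#' @param reference Reference assay id (default `"U6"`).
#' @return data.frame with columns `mirna`, `sample`, `group`, `delta_ct`,
#'   `ddct`, `fold`.
#' @export
qpcr_fold_change <- function(ct, manifest, control_group = "nmx",
                             reference = "U6") {
  stopifnot(all(c("mirna", "sample", "ct") %in% names(ct)))
  if (any(!is.finite(ct$ct)))
    stop("Ct values must be finite", call. = FALSE)
  if (any(ct$ct < 5 | ct$ct > 40))
    warning("Ct value(s) outside the typical 5-40 cycle range")

  # mean over technical replicates
  agg <- stats::aggregate(ct ~ mirna + sample, data = ct, FUN = mean)
  ref <- agg[agg$mirna == reference, ]
  targets <- agg[agg$mirna != reference, ]
  samples <- unique(targets$sample)
  no_ref <- setdiff(samples, ref$sample)
  if (length(no_ref))
    stop("missing-reference error: no ", reference, " Ct for sample(s) ",
         paste(no_ref, collapse = ", "), call. = FALSE)

  grp <- manifest$group[match(targets$sample, manifest$sample_id)]
  if (anyNA(grp))
    stop("sample(s) missing from manifest: ",
         paste(unique(targets$sample[is.na(grp)]), collapse = ", "),
         call. = FALSE)
  ctrl_samples <- manifest$sample_id[manifest$group == control_group]
  if (!any(targets$sample %in% ctrl_samples))
    stop("control group '", control_group, "' has no samples in the table",
         call. = FALSE)

  dct <- targets$ct - ref$ct[match(targets$sample, ref$sample)]
  ctrl_mean <- tapply(dct[targets$sample %in% ctrl_samples],
                      targets$mirna[targets$sample %in% ctrl_samples],
                      mean)
  miss <- setdiff(unique(targets$mirna), names(ctrl_mean))
  if (length(miss))
    stop("no control-group Ct for miRNA(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ddct <- dct - ctrl_mean[targets$mirna]
  data.frame(mirna = targets$mirna, sample = targets$sample, group = grp,
             delta_ct = dct, ddct = as.numeric(ddct),
             fold = 2^(-as.numeric(ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate array and qPCR fold changes across a shared miRNA panel
#'
#' Fold changes are compared on the log2 scale (ratios are multiplicative);
#' set `log2_scale = FALSE` to correlate raw folds.
#'
#' @param array_folds,qpcr_folds Named positive numeric vectors of per-miRNA
#'   fold changes; at least 3 shared ids required.
#' @param method Correlation method (default `"pearson"`).
#' @param log2_scale Correlate log2 folds (default TRUE).
#' @return List with `r`, `p` and `n` (number of shared miRNAs).
#' @export
correlate_platforms <- function(array_folds, qpcr_folds,
                                method = "pearson", log2_scale = TRUE) {
  shared <- intersect(names(array_folds), names(qpcr_folds))
  if (length(shared) < 3)
    stop("insufficient-data error: fewer than 3 shared miRNAs",
         call. = FALSE)
  a <- array_folds[shared]
  q <- qpcr_folds[shared]
  if (log2_scale) {
    a <- log2(a)
    q <- log2(q)
  }
  ct <- stats::cor.test(a, q, method = method)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Percent positivity per imaged field
#'
#' The published statistic `A / B * 100`, where A is the marker-positive
#' (Alexa Fluor) cell count and B the total (DAPI) cell count of the field.
#'
#' @param table data.frame with columns `positive` and `total` (and
#'   typically `field`, `group`).
#' @return The input with a `percent` column appended (values in
#'   `[0, 100]`).
#' @export
percent_positivity <- function(table) {
  stopifnot(all(c("positive", "total") %in% names(table)))
  if (any(table$total < 1))
    stop("total cell count must be >= 1 in every field", call. = FALSE)
  if (any(table$positive < 0))
    stop("positive cell counts must be nonnegative", call. = FALSE)
  if (any(table$positive > table$total))
    stop("integrity error: positive count exceeds total count",
         call. = FALSE)
  table$percent <- 100 * table$positive / table$total
  table
}

#' Group comparison by ANOVA with Tukey's post-hoc correction
#'
#' One-factor or two-factor ANOVA over group labels with Tukey HSD adjusted
#' pairwise comparisons for the primary grouping factor. The omnibus
#' statistic reported is the F test of the primary factor.
#'
#' @param values Numeric measurements.
#' @param groups Primary group labels (at least 2 groups, each with at
#'   least 2 values).
#' @param factor2 Optional second factor (e.g. miRNA identity for a qPCR
#'   panel), giving a two-factor ANOVA.
#' @return An object of class `group_comparison`: list with `groups`
#'   (per-group n, mean, sd), `anova` (F, df, p of the primary factor),
#'   `tukey` (data.frame: `pair`, `diff`, `lwr`, `upr`, `p_adj`) and
#'   `n_factors`.
#' @export
group_compare <- function(values, groups, factor2 = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    stop("insufficient-data error: need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("insufficient-data error: every group needs >= 2 values",
         call. = FALSE)
  df <- data.frame(value = values, group = groups)
  if (is.null(factor2)) {
    fit <- stats::aov(value ~ group, data = df)
    n_factors <- 1L
  } else {
    df$factor2 <- factor(factor2)
    fit <- stats::aov(value ~ group * factor2, data = df)
    n_factors <- 2L
  }
  tab <- summary(fit)[[1]]
  row <- grep("^group\\s*$", rownames(tab))
  anova <- data.frame(term = "group",
                      df = tab[row, "Df"],
                      F = tab[row, "F value"],
                      p = tab[row, "Pr(>F)"],
                      row.names = NULL)
  tk <- stats::TukeyHSD(fit, which = "group")$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE, row.names = NULL)
  per_group <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd)),
    stringsAsFactors = FALSE)
  structure(list(groups = per_group, anova = anova, tukey = tukey,
                 n_factors = n_factors), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$n_factors, "-factor ANOVA, omnibus F(", x$anova$df, ") = ",
      signif(x$anova$F, 4), ", p = ", format.pval(x$anova$p, digits = 3),
      "\n", sep = "")
  print(x$groups, row.names = FALSE)
  cat("Tukey HSD:\n")
  print(x$tukey, row.names = FALSE)
  invisible(x)
}
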