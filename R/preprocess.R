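#' Subtract blank (background) intensity per sample
#'
#' For each sample, the mean intensity of the blank probes is subtracted
#' from every probe, and results are floored at `epsilon` so downstream
#' ratios stay defined. Blank probes are retained in the output and flagged
#' as consumed (attribute `consumed_controls`).
#'
#' @param x An [expression_matrix()] containing at least one blank probe.
#' @param epsilon Intensity floor (default 1).
#' @return The background-subtracted [expression_matrix()].
#' @export
subtract_background <- function(x, epsilon = 1) {
  blanks <- names(x$probe_class)[x$probe_class == "blank"]
  if (length(blanks) == 0)
    stop("missing-control error: no blank probes to estimate background",
         call. = FALSE)
  bg <- colMeans(x$values[blanks, , drop = FALSE])
  v <- sweep(x$values, 2, bg, `-`)
  v[v < epsilon] <- epsilon
  out <- expression_matrix(v, x$probe_class)
  attr(out, "consumed_controls") <- union(attr(x, "consumed_controls"),
                                          "blank")
  out
}

#' Normalize samples to a control probe class
#'
#' Divides each sample by its mean control-class intensity (spike-in or U6)
#' and rescales by the across-sample grand mean of that class, so that after
#' normalization the per-sample control mean is constant across samples.
#'
#' @param x An [expression_matrix()].
#' @param mode `"spike_in"` or `"u6"`.
#' @return The normalized [expression_matrix()].
#' @export
normalize_controls <- function(x, mode = c("spike_in", "u6")) {
  mode <- match.arg(mode)
  ctl <- names(x$probe_class)[x$probe_class == mode]
  if (length(ctl) == 0)
    stop("missing-control error: no ", mode, " probes present",
         call. = FALSE)
  ctl_mean <- colMeans(x$values[ctl, , drop = FALSE])
  if (any(ctl_mean <= 0))
    stop("degenerate-control error: nonpositive ", mode,
         " mean in sample(s) ",
         paste(colnames(x$values)[ctl_mean <= 0], collapse = ", "),
         call. = FALSE)
  v <- sweep(x$values, 2, ctl_mean, `/`) * mean(ctl_mean)
  out <- expression_matrix(v, x$probe_class)
  attr(out, "consumed_controls") <- union(attr(x, "consumed_controls"), mode)
  out
}

#' Subtract the sham (tumor-free) baseline per probe
#'
#' Removes the host mouse serum background: for every probe, the mean
#' intensity over the sham samples is subtracted from each non-sham sample,
#' floored at `epsilon`. Sham samples are dropped from the output.
#'
#' @param x An [expression_matrix()].
#' @param manifest A [sample_manifest()] covering the matrix samples.
#' @param epsilon Intensity floor (default 1).
#' @return The baseline-corrected [expression_matrix()] without sham
#'   samples.
#' @export
subtract_sham_baseline <- function(x, manifest, epsilon = 1) {
  sham <- manifest_samples(x, manifest, "sham")
  if (length(sham) == 0)
    stop("missing-baseline error: no sham samples in matrix", call. = FALSE)
  keep <- setdiff(colnames(x$values), sham)
  if (length(keep) == 0)
    stop("no non-sham samples left after baseline correction",
         call. = FALSE)
  base <- rowMeans(x$values[, sham, drop = FALSE])
  v <- x$values[, keep, drop = FALSE] - base
  v[v < epsilon] <- epsilon
  out <- expression_matrix(v, x$probe_class)
  attr(out, "consumed_controls") <- attr(x, "consumed_controls")
  out
}

#' Full array preprocessing: background, normalization, sham baseline
#'
#' Composes the preprocessing stages in the order background subtraction,
#' control normalization (spike-in by default, optionally U6 or both, in
#' the order given), then sham baseline correction, and finally restricts
#' the matrix to miRNA-class probes and xenograft (nmx / hr) samples.
#'
#' @param x Raw [expression_matrix()].
#' @param manifest A [sample_manifest()].
#' @param normalize Character vector of control classes to normalize to, in
#'   order (default `"spike_in"`); use `character(0)` to skip normalization.
#' @param sham_correct Subtract the sham baseline (default TRUE).
#' @param background_subtract Subtract the blank background (default TRUE).
#' @param epsilon Intensity floor (default 1).
#' @return Preprocessed [expression_matrix()] of miRNA probes over nmx and
#'   hr samples, strictly positive.
#' @export
preprocess <- function(x, manifest, normalize = "spike_in",
                       sham_correct = TRUE, background_subtract = TRUE,
                       epsilon = 1) {
  check_manifest(x, manifest)
  if (background_subtract) x <- subtract_background(x, epsilon)
  for (mode in normalize) x <- normalize_controls(x, mode)
  if (sham_correct) x <- subtract_sham_baseline(x, manifest, epsilon)
  mirna <- names(x$probe_class)[x$probe_class == "mirna"]
  keep <- intersect(colnames(x$values),
                    manifest$sample_id[manifest$group %in% c("nmx", "hr")])
  em_subset(x, probes = mirna, samples = keep)
}
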