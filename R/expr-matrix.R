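#' Probe-by-sample intensity matrix with probe-class annotations
#'
#' The array data model used throughout the package: a numeric grid of
#' nonnegative intensities (probes in rows, samples in columns) together with
#' a per-probe class label. The four probe classes are `"mirna"` (measurement
#' features), `"blank"` (background features), `"spike_in"` (exogenous
#' normalization controls) and `"u6"` (the endogenous U6 control).
#'
#' @param values Numeric matrix with probe ids as row names and sample ids as
#'   column names. Values must be finite and nonnegative.
#' @param probe_class Character vector of probe classes, either named by probe
#'   id or in row order; one of `"mirna"`, `"blank"`, `"spike_in"`, `"u6"`.
#'   If `NULL`, classes are inferred from id prefixes (`"BLANK_"`, `"SPIKE_"`,
#'   `"U6"`; everything else is `"mirna"`).
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `probe_class` (named character vector).
#' @examples
#' m <- matrix(c(100, 40, 10, 120, 40, 12), nrow = 3,
#'             dimnames = list(c("hsa-miR-1", "BLANK_1", "U6_1"),
#'                             c("s1", "s2")))
#' expression_matrix(m)
#' @export
expression_matrix <- function(values, probe_class = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry probe row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in matrix", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all intensities must be finite", call. = FALSE)
  if (any(values < 0))
    stop("intensities must be nonnegative", call. = FALSE)

  if (is.null(probe_class)) {
    probe_class <- infer_probe_class(rownames(values))
  } else {
    probe_class <- as.character(probe_class)
    if (!is.null(names(probe_class))) {
      missing <- setdiff(rownames(values), names(probe_class))
      if (length(missing))
        stop("probe_class missing for: ", paste(missing, collapse = ", "),
             call. = FALSE)
      probe_class <- probe_class[rownames(values)]
    } else {
      if (length(probe_class) != nrow(values))
        stop("probe_class length does not match probe count", call. = FALSE)
      names(probe_class) <- rownames(values)
    }
  }
  bad <- setdiff(unique(probe_class), PROBE_CLASSES)
  if (length(bad))
    stop("unknown probe class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(values = values, probe_class = probe_class),
            class = "expr_matrix")
}

PROBE_CLASSES <- c("mirna", "blank", "spike_in", "u6")

#' Infer probe classes from identifier prefixes
#'
#' `"BLANK_"` marks blanks, `"SPIKE_"` spike-in controls, and ids starting
#' with `"U6"` the endogenous U6 control; anything else is a miRNA probe.
#'
#' @param ids Character vector of probe identifiers.
#' @return Named character vector of classes.
#' @export
infer_probe_class <- function(ids) {
  cls <- rep("mirna", length(ids))
  cls[startsWith(ids, "BLANK_")] <- "blank"
  cls[startsWith(ids, "SPIKE_")] <- "spike_in"
  cls[startsWith(ids, "U6")] <- "u6"
  names(cls) <- ids
  cls
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(factor(x$probe_class, levels = PROBE_CLASSES))
  cat("expr_matrix: ", nrow(x$values), " probes x ", ncol(x$values),
      " samples\n", sep = "")
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  samples:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Subset an expr_matrix by probe and/or sample ids, keeping annotations.
em_subset <- function(x, probes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(probes)) {
    miss <- setdiff(probes, rownames(v))
    if (length(miss))
      stop("unknown probe id(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    v <- v[probes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    miss <- setdiff(samples, colnames(v))
    if (length(miss))
      stop("unknown sample id(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, x$probe_class[rownames(v)])
}

#' Read an expression matrix from TSV
#'
#' Expects the dialect written by [write_expression_matrix()]: first column
#' `probe_id`, remaining columns one per sample, header row of sample ids.
#' Probe classes come from an optional annotation TSV (`probe_id`, `class`);
#' without one they are inferred from id prefixes. Where both are available
#' the annotation file wins.
#'
#' @param path Path to the matrix TSV.
#' @param annotation Optional path to a probe-class annotation TSV.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, annotation = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  cls <- infer_probe_class(rownames(m))
  if (!is.null(annotation)) {
    ann <- utils::read.delim(annotation, stringsAsFactors = FALSE)
    if (!all(c("probe_id", "class") %in% names(ann)))
      stop("annotation TSV needs columns probe_id, class", call. = FALSE)
    cls[match(ann$probe_id, names(cls), nomatch = 0)] <-
      ann$class[ann$probe_id %in% names(cls)]
  }
  expression_matrix(m, cls)
}

#' Write an expression matrix (and optionally its annotations) to TSV
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV path.
#' @param annotation Optional path for the probe-class annotation TSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, annotation = NULL) {
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    ann <- data.frame(probe_id = names(x$probe_class),
                      class = unname(x$probe_class))
    utils::write.table(ann, annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct and validate a sample manifest
#'
#' @param sample_id Character vector of sample ids.
#' @param group Character vector of group labels, one of `"sham"`, `"nmx"`
#'   (non-metastatic xenograft control) or `"hr"` (high-risk case).
#' @param replicate Integer replicate index within group.
#' @return A `data.frame` with columns `sample_id`, `group`, `replicate`.
#' @export
sample_manifest <- function(sample_id, group, replicate = NULL) {
  group <- as.character(group)
  bad <- setdiff(unique(group), GROUPS)
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in manifest", call. = FALSE)
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  data.frame(sample_id = as.character(sample_id), group = group,
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}

GROUPS <- c("sham", "nmx", "hr")

#' Read / write a sample manifest TSV (`sample_id`, `group`, `replicate`)
#'
#' @param path TSV path.
#' @return For the reader, a validated manifest `data.frame`.
#' @export
read_sample_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_manifest(df$sample_id, df$group, df$replicate)
}

#' @rdname read_sample_manifest
#' @param manifest A manifest `data.frame`.
#' @export
write_sample_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Check that manifest covers the matrix samples exactly once.
check_manifest <- function(x, manifest) {
  s <- colnames(x$values)
  if (anyDuplicated(manifest$sample_id))
    stop("duplicate sample ids in manifest", call. = FALSE)
  miss <- setdiff(s, manifest$sample_id)
  if (length(miss))
    stop("samples absent from manifest: ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

manifest_samples <- function(x, manifest, group) {
  check_manifest(x, manifest)
  intersect(colnames(x$values),
            manifest$sample_id[manifest$group == group])
}
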