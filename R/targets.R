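#' Evidence levels for miRNA-target associations, weakest to strongest
#' @export
EVIDENCE_LEVELS <- c("predicted", "highly_predicted", "experimental")

evidence_rank <- function(x) {
  r <- match(x, EVIDENCE_LEVELS)
  if (anyNA(r))
    stop("unknown evidence level(s): ",
         paste(unique(x[is.na(r)]), collapse = ", "), call. = FALSE)
  r
}

#' Read / write a miRNA-target map TSV (`mirna`, `gene`, `evidence`)
#'
#' @param path TSV path.
#' @return For the reader, a validated target-map data.frame with
#'   upper-cased gene symbols and no duplicate (miRNA, gene) pairs.
#' @export
read_target_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_target_map(df)
}

#' @rdname read_target_map
#' @param map A target-map data.frame.
#' @export
write_target_map <- function(map, path) {
  utils::write.table(validate_target_map(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_target_map <- function(map) {
  stopifnot(all(c("mirna", "gene", "evidence") %in% names(map)))
  map$gene <- toupper(map$gene)
  evidence_rank(map$evidence)
  key <- paste(map$mirna, map$gene, sep = "\r")
  if (anyDuplicated(key)) {
    # keep the strongest evidence for a duplicated association
    map <- map[order(key, -evidence_rank(map$evidence)), ]
    map <- map[!duplicated(paste(map$mirna, map$gene, sep = "\r")), ]
    rownames(map) <- NULL
  }
  map
}

#' Common gene targets of a miRNA set
#'
#' Ranks genes by how many miRNAs of the set are annotated to target them,
#' counting only associations at or above `min_evidence` and keeping genes
#' supported by at least `min_support` miRNAs. Ordering is by decreasing
#' support count, then lexicographic gene symbol.
#'
#' @param map Target map (`mirna`, `gene`, `evidence`).
#' @param mirnas Nonempty character vector of miRNA ids.
#' @param min_support Minimum supporting miRNAs per gene (default 2,
#'   "commonly regulated by multiple candidates").
#' @param min_evidence Weakest evidence level counted (default
#'   `"predicted"`, i.e. all).
#' @return data.frame with columns `gene`, `count`, `best_evidence`,
#'   `mirnas` (semicolon-joined supporting set).
#' @export
common_targets <- function(map, mirnas, min_support = 2,
                           min_evidence = "predicted") {
  if (length(mirnas) == 0)
    stop("usage error: empty miRNA set", call. = FALSE)
  if (min_support < 1)
    stop("min_support must be >= 1", call. = FALSE)
  map <- validate_target_map(map)
  keep <- map$mirna %in% mirnas &
    evidence_rank(map$evidence) >= evidence_rank(min_evidence)
  sub <- map[keep, , drop = FALSE]
  empty <- data.frame(gene = character(0), count = integer(0),
                      best_evidence = character(0), mirnas = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sub) == 0) return(empty)
  by_gene <- split(sub, sub$gene)
  out <- data.frame(
    gene = names(by_gene),
    count = vapply(by_gene, function(d) length(unique(d$mirna)),
                   integer(1)),
    best_evidence = vapply(by_gene, function(d)
      EVIDENCE_LEVELS[max(evidence_rank(d$evidence))], character(1)),
    mirnas = vapply(by_gene, function(d)
      paste(sort(unique(d$mirna)), collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$count >= min_support, , drop = FALSE]
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Crisscross common-target mining across candidate groups
#'
#' Applies [common_targets()] independently to each of the (typically four:
#' up/down x homologous/non-homologous) candidate groups and summarizes
#' genes recurring in at least two groups' tables.
#'
#' @param map Target map.
#' @param groups Named list of pairwise-disjoint miRNA id vectors.
#' @param min_support,min_evidence Passed to [common_targets()].
#' @return List with `tables` (one consensus table per group, `group`
#'   column added) and `summary` (data.frame of genes appearing in >= 2
#'   groups).
#' @export
crisscross <- function(map, groups, min_support = 2,
                       min_evidence = "predicted") {
  ids <- unlist(groups)
  if (anyDuplicated(ids))
    stop("integrity error: candidate groups overlap (",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), ")",
         call. = FALSE)
  tables <- lapply(names(groups), function(g) {
    if (length(groups[[g]]) == 0) {
      tab <- common_targets(map, "__none__", min_support, min_evidence)
    } else {
      tab <- common_targets(map, groups[[g]], min_support, min_evidence)
    }
    if (nrow(tab)) tab <- cbind(group = g, tab)
    else tab <- cbind(group = character(0), tab)
    tab
  })
  names(tables) <- names(groups)
  gene_groups <- lapply(tables, `[[`, "gene")
  counts <- table(unlist(gene_groups))
  recur <- sort(names(counts)[counts >= 2])
  summary <- data.frame(
    gene = recur,
    n_groups = as.integer(counts[recur]),
    groups = vapply(recur, function(g)
      paste(names(tables)[vapply(gene_groups, function(v) g %in% v,
                                 logical(1))], collapse = ";"),
      character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(tables = tables, summary = summary)
}

#' Write crisscross consensus tables to TSV
#'
#' @param cc Result of [crisscross()].
#' @param path Output TSV path (stacked tables, `group` column first).
#' @return `path`, invisibly.
#' @export
write_consensus_tables <- function(cc, path) {
  out <- do.call(rbind, cc$tables)
  if (is.null(out) || nrow(out) == 0)
    out <- data.frame(group = character(0), gene = character(0),
                      count = integer(0), best_evidence = character(0),
                      mirnas = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
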