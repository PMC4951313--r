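#' Species-tagged catalog of mature miRNA sequences
#'
#' Sequences are upper-cased and normalized to the RNA alphabet (T becomes
#' U); lengths must fall in the mature-miRNA range 16-30 nt.
#'
#' @param ids Character vector of unique miRNA ids.
#' @param sequences Character vector of mature sequences over A, C, G, U/T.
#' @param species Species prefix label, e.g. `"hsa"` or `"mmu"`.
#' @return An object of class `mirna_catalog`: list with `species`, `ids`
#'   and `seq` (named character vector).
#' @export
mirna_catalog <- function(ids, sequences, species) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate miRNA ids within a catalog", call. = FALSE)
  if (length(ids) != length(sequences))
    stop("ids and sequences differ in length", call. = FALSE)
  seqs <- normalize_rna(sequences)
  len <- nchar(seqs)
  if (length(len) && any(len < 16 | len > 30))
    stop("mature sequences must be 16-30 nt long", call. = FALSE)
  names(seqs) <- ids
  structure(list(species = species, ids = ids, seq = seqs),
            class = "mirna_catalog")
}

normalize_rna <- function(x) {
  x <- chartr("acgut", "ACGUU", x)
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop("invalid alphabet in sequence(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  x
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat("mirna_catalog (", x$species, "): ", length(x$ids), " mature sequences\n",
      sep = "")
  invisible(x)
}

#' Read a mature miRNA catalog from FASTA
#'
#' Accepts the miRBase `mature.fa` header dialect (`>hsa-miR-21-5p MIMAT...
#' description`): the id is the first header token and the species prefix is
#' its leading hyphen-delimited field. When `species` is given, only entries
#' with that prefix are kept; headers whose prefix is not a plausible species
#' code are rejected with the offending header echoed.
#'
#' @param path FASTA path (RNA or DNA alphabet; T is normalized to U).
#' @param species Optional species prefix to select (e.g. `"hsa"`).
#' @return A [mirna_catalog()].
#' @export
read_mirna_catalog <- function(path, species = NULL) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1)
  prefix <- sub("-.*$", "", ids)
  bad <- !grepl("^[a-z]{3,4}$", prefix)
  if (any(bad))
    stop("unrecognized species prefix in header(s): ",
         paste(utils::head(headers[bad], 3), collapse = "; "),
         call. = FALSE)
  if (!is.null(species)) {
    keep <- prefix == species
    if (!any(keep))
      stop("no entries with species prefix '", species, "' in ", path,
           call. = FALSE)
    set <- set[keep]
    ids <- ids[keep]
  } else {
    species <- prefix[1]
  }
  mirna_catalog(ids, as.character(set), species = species)
}

#' Write a catalog as FASTA (`>{id}` headers, RNA alphabet)
#'
#' @param catalog A [mirna_catalog()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_mirna_catalog <- function(catalog, path) {
  set <- Biostrings::RNAStringSet(catalog$seq)
  names(set) <- catalog$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Global alignment identity between two mature sequences
#'
#' Needleman-Wunsch global alignment under unit match score with
#' configurable mismatch and gap costs; identity is the number of matched
#' positions divided by the alignment length (gap columns included). The
#' measure is symmetric, lies in `[0, 1]`, and equals 1 exactly when the
#' sequences are identical.
#'
#' @param a,b Sequences over A, C, G, U/T (case-insensitive).
#' @param match Match score (default 1).
#' @param mismatch Mismatch score (default -1).
#' @param gap Per-position gap score (default -1; must be nonpositive).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' align_identity("UGAGGUA", "UGAGCUA") # 6/7
#' @export
align_identity <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  a <- normalize_rna(a)
  b <- normalize_rna(b)
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("sequences must be nonempty", call. = FALSE)
  identity_vs_set(a, b, match = match, mismatch = mismatch, gap = gap)
}

# Vectorized identity of one sequence against a set (both in RNA alphabet).
identity_vs_set <- function(seq, set, match = 1, mismatch = -1, gap = -1) {
  if (gap > 0) stop("gap score must be nonpositive", call. = FALSE)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = TRUE)
  pat <- Biostrings::DNAStringSet(chartr("U", "T", set))
  subj <- Biostrings::DNAString(chartr("U", "T", seq))
  aln <- Biostrings::pairwiseAlignment(pat, subj,
                                       substitutionMatrix = sm,
                                       gapOpening = 0,
                                       gapExtension = abs(gap),
                                       type = "global")
  # alignment length (gap columns included): every base sits either in a
  # base-base column or opposite a gap, so ncol = la + lb - matches - mismatches
  width <- nchar(set) + nchar(seq) - Biostrings::nmatch(aln) -
    Biostrings::nmismatch(aln)
  unname(Biostrings::nmatch(aln) / width)
}

#' Best cross-species hit for a candidate miRNA
#'
#' Scans the mouse catalog for the entry maximizing alignment identity with
#' the candidate's human mature sequence; ties are broken by lexicographic
#' mouse id. A candidate absent from the human catalog is reported as
#' unresolved rather than an error; an empty mouse catalog yields a no-hit
#' sentinel with identity 0.
#'
#' @param id Candidate miRNA id.
#' @param human,mouse [mirna_catalog()] objects.
#' @param ... Scoring parameters passed to [align_identity()].
#' @return List with `hit`, `identity` and `status` (`"ok"`, `"no_hit"` or
#'   `"unresolved"`).
#' @export
best_cross_species_hit <- function(id, human, mouse, ...) {
  if (!id %in% human$ids)
    return(list(hit = NA_character_, identity = NA_real_,
                status = "unresolved"))
  if (length(mouse$ids) == 0)
    return(list(hit = NA_character_, identity = 0, status = "no_hit"))
  ident <- identity_vs_set(human$seq[[id]], mouse$seq, ...)
  ord <- order(-ident, mouse$ids)
  list(hit = mouse$ids[ord[1]], identity = ident[ord[1]], status = "ok")
}

#' Retain species-specific ("zero homology") candidates
#'
#' Operationalizes the zero-homology criterion: a candidate is retained
#' when its best cross-species alignment identity is strictly below
#' `identity_threshold`. Candidates whose sequence is absent from the human
#' catalog are flagged unresolved and excluded from the retained set;
#' direction and provenance of retained candidates are preserved.
#'
#' @param cands A candidate set (from [traverse_consensus()]).
#' @param human,mouse [mirna_catalog()] objects.
#' @param identity_threshold Identity threshold in `(0, 1]` (default 0.80).
#' @param ... Scoring parameters passed to [align_identity()].
#' @return List with `retained` (a candidate set) and `report`
#'   (data.frame: `candidate`, `best_hit`, `identity`, `decision`).
#' @export
filter_species_specific <- function(cands, human, mouse,
                                    identity_threshold = 0.8, ...) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  hits <- lapply(cands$members, best_cross_species_hit,
                 human = human, mouse = mouse, ...)
  identity <- vapply(hits, `[[`, numeric(1), "identity")
  status <- vapply(hits, `[[`, character(1), "status")
  decision <- ifelse(status == "unresolved", "unresolved",
                     ifelse(identity < identity_threshold,
                            "retained", "excluded"))
  report <- data.frame(candidate = cands$members,
                       best_hit = vapply(hits, `[[`, character(1), "hit"),
                       identity = identity, decision = decision,
                       stringsAsFactors = FALSE)
  kept <- cands$members[decision == "retained"]
  retained <- new_candidate_set(cands$direction, kept,
                                cands$provenance[kept], cands$cutoff)
  list(retained = retained, report = report)
}

#' Parse a printed candidate list into normalized miRNA ids
#'
#' Accepts a file path or character input of comma/whitespace-separated
#' `miR-...` tokens (the format in which candidate enumerations are
#' printed). Ids without a species prefix are normalized with `hsa-`;
#' order is preserved; duplicates and malformed tokens are errors.
#'
#' @param x Path to a text file, or a character vector of tokens/text.
#' @return Character vector of normalized miRNA ids.
#' @export
parse_candidate_list <- function(x) {
  if (length(x) == 1 && !grepl("[,[:space:]]", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  tokens <- unlist(strsplit(x, "[,;[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) return(character(0))
  ok <- grepl("^([a-z]{3,4}-)?(miR|let)-[0-9A-Za-z]+([-.][0-9A-Za-z]+)*$",
              tokens)
  if (any(!ok))
    stop("malformed miRNA token(s): ",
         paste(tokens[!ok], collapse = ", "), call. = FALSE)
  ids <- ifelse(grepl("^[a-z]{3,4}-", tokens), tokens,
                paste0("hsa-", tokens))
  if (anyDuplicated(ids))
    stop("duplicate miRNA id(s) in list: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  ids
}

#' Flag top markers among upregulated candidates
#'
#' Returns the upregulated candidates whose conservative fold change is
#' strictly above `min_fold` (default 10, the published top-marker bar),
#' in order of decreasing fold.
#'
#' @param cands An up-direction candidate set.
#' @param ranked The [rank_by_min_fold()] table for `cands`.
#' @param min_fold Fold bar (default 10).
#' @return Character vector of flagged miRNA ids, descending by fold.
#' @export
flag_top_markers <- function(cands, ranked, min_fold = 10) {
  if (cands$direction != "up")
    stop("top markers are defined for upregulated candidates only",
         call. = FALSE)
  miss <- setdiff(cands$members, ranked$mirna)
  if (length(miss))
    stop("conservative folds missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  ranked$mirna[ranked$conservative_fold > min_fold]
}
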