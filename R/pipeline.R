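#' Configuration for a full pipeline run
#'
#' Collects every tunable of the discovery pipeline with its documented
#' default: the traverse cutoff (2-fold), homology identity threshold
#' (0.80), top-marker fold bar (10), target-consensus support (2), the
#' preprocessing options, and either input file paths or a simulation
#' configuration. All randomness of a simulated run flows from `seed` via
#' fixed per-stage offsets, so stages are independently reproducible.
#'
#' @param out_dir Artifact directory (created if absent).
#' @param seed Integer master seed.
#' @param simulate Generate inputs with the synthetic-data module (default
#'   TRUE). When FALSE, `paths$matrix` and `paths$manifest` are required.
#' @param sim A [sim_config()] used when `simulate = TRUE`; its seed is
#'   overridden by the derived stage seed.
#' @param paths Named list of input paths (`matrix`, `annotation`,
#'   `manifest`, `human_fa`, `mouse_fa`, `ct`, `ct_manifest`, `targets`,
#'   `positivity`); any subset may be given for a partial run.
#' @param cutoff,identity_threshold,top_fold,min_support,min_evidence
#'   Stage parameters (defaults 2, 0.80, 10, 2, `"predicted"`).
#' @param normalize,sham_correct,epsilon Preprocessing options.
#' @param n_mouse_only Mouse-only catalog entries in a simulated run (50).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, simulate = TRUE,
                            sim = sim_config(), paths = list(),
                            cutoff = 2, identity_threshold = 0.8,
                            top_fold = 10, min_support = 2,
                            min_evidence = "predicted",
                            normalize = "spike_in", sham_correct = TRUE,
                            epsilon = 1, n_mouse_only = 50) {
  if (missing(out_dir)) stop("out_dir is required", call. = FALSE)
  if (cutoff < 1) stop("cutoff must be >= 1", call. = FALSE)
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must lie in (0, 1]", call. = FALSE)
  if (top_fold < 1) stop("top_fold must be >= 1", call. = FALSE)
  if (min_support < 1) stop("min_support must be >= 1", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  evidence_rank(min_evidence)
  if (!simulate) {
    need <- c("matrix", "manifest")
    have <- names(paths)[vapply(paths, function(p)
      is.character(p) && file.exists(p), logical(1))]
    miss <- setdiff(need, have)
    if (length(miss))
      stop("simulation disabled and input path(s) missing or absent: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, sim = sim, paths = paths,
                 cutoff = cutoff, identity_threshold = identity_threshold,
                 top_fold = top_fold, min_support = min_support,
                 min_evidence = min_evidence, normalize = normalize,
                 sham_correct = sham_correct, epsilon = epsilon,
                 n_mouse_only = n_mouse_only),
            class = "pipeline_config")
}

stage_seed <- function(seed, k) as.integer((seed + 17 * k) %% 2147483647L)

#' Run the full biomarker discovery pipeline
#'
#' Executes every stage against simulated or file inputs and writes a fixed
#' artifact layout under `config$out_dir`: the generated or echoed inputs
#' (`inputs/`), the preprocessed matrix, traverse report and candidate
#' table, homology reports and top markers, qPCR validation (folds plus
#' cross-platform correlation), crisscross consensus tables, positivity
#' statistics, and `run_manifest.json` (config echo, input checksums,
#' per-stage counts and wall-clock). The run manifest is written on both
#' success and failure.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `mirnome_run`: list with `screen` (the
#'   [mirnome_screen()] object), `qpcr`, `targets`, `positivity`, `truth`
#'   (simulated ground truth or NULL), `artifacts` (named paths) and
#'   `manifest` (the run manifest list). Returned invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "inputs"), showWarnings = FALSE)
  art <- function(...) file.path(config$out_dir, ...)

  run_manifest <- list(
    tool = paste0("miRtraverse ",
                  as.character(utils::packageVersion("miRtraverse"))),
    status = "failed",
    config = config[!(names(config) %in% "sim")],
    stage_counts = list(), timings = list(), checksums = list())
  write_manifest <- function() {
    jsonlite::write_json(run_manifest, art("run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }
  on.exit(write_manifest())

  timer <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    run_manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  log_stage <- function(...) message("[miRtraverse] ", ...)

  truth <- NULL
  catalog_truth <- NULL
  # ---- inputs: simulate or load -------------------------------------------
  if (config$simulate) {
    log_stage("simulating miRnome array (seed ", config$seed, ")")
    sim_cfg <- config$sim
    sim_cfg$seed <- stage_seed(config$seed, 0)
    sim <- timer("simulate_array", simulate_mirnome(sim_cfg))
    x <- sim$matrix
    manifest <- sim$manifest
    truth <- sim$truth
    write_expression_matrix(x, art("inputs", "matrix.tsv"),
                            annotation = art("inputs", "probe_classes.tsv"))
    write_sample_manifest(manifest, art("inputs", "manifest.tsv"))

    log_stage("simulating two-species mature catalogs")
    ids <- names(truth$species_specific)
    cats <- timer("simulate_catalogs", simulate_catalogs(
      n_shared = 0, n_human_only = 0,
      n_mouse_only = config$n_mouse_only,
      seed = stage_seed(config$seed, 1),
      identity_threshold = config$identity_threshold,
      shared_ids = ids[!truth$species_specific],
      human_only_ids = ids[truth$species_specific]))
    catalog_truth <- cats$truth
    human <- cats$human
    mouse <- cats$mouse
    write_mirna_catalog(human, art("inputs", "human_mature.fa"))
    write_mirna_catalog(mouse, art("inputs", "mouse_mature.fa"))
  } else {
    log_stage("loading inputs")
    x <- read_expression_matrix(config$paths$matrix,
                                annotation = config$paths$annotation)
    manifest <- read_sample_manifest(config$paths$manifest)
    human <- if (!is.null(config$paths$human_fa))
      read_mirna_catalog(config$paths$human_fa) else NULL
    mouse <- if (!is.null(config$paths$mouse_fa))
      read_mirna_catalog(config$paths$mouse_fa) else NULL
    for (p in config$paths)
      if (is.character(p) && file.exists(p))
        run_manifest$checksums[[basename(p)]] <- unname(tools::md5sum(p))
  }

  # ---- screen: preprocess + traverse + homology ---------------------------
  log_stage("preprocess + traverse consensus (cutoff ", config$cutoff, ")")
  screen <- timer("screen", mirnome_screen(
    x, manifest, human = human, mouse = mouse,
    cutoff = config$cutoff,
    identity_threshold = config$identity_threshold,
    top_fold = config$top_fold, normalize = config$normalize,
    sham_correct = config$sham_correct, epsilon = config$epsilon))

  write_expression_matrix(screen$matrix, art("preprocessed_matrix.tsv"))
  utils::write.table(screen$traverse$report, art("traverse_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates(screen$traverse, art("candidates.tsv"))
  if (!is.null(screen$homology)) {
    utils::write.table(screen$homology$up$report,
                       art("homology_up.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(screen$homology$down$report,
                       art("homology_down.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeLines(screen$top_markers, art("top_markers.txt"))
  run_manifest$stage_counts$candidates_up <-
    length(screen$traverse$up$members)
  run_manifest$stage_counts$candidates_down <-
    length(screen$traverse$down$members)
  run_manifest$stage_counts$top_markers <- length(screen$top_markers)
  if (!is.null(screen$homology)) {
    run_manifest$stage_counts$retained_up <-
      length(screen$homology$up$retained$members)
    run_manifest$stage_counts$retained_down <-
      length(screen$homology$down$retained$members)
  }

  # ---- qPCR validation ----------------------------------------------------
  qpcr <- NULL
  array_folds <- geometric_array_folds(screen)
  if (config$simulate) {
    log_stage("simulating qPCR validation panel")
    panel <- qpcr_panel(screen, truth)
    qsim <- simulate_qpcr(panel, n_replicates = 3, ct_noise_sd = 0.1,
                          seed = stage_seed(config$seed, 2))
    ct <- qsim$ct
    ct_manifest <- qsim$manifest
  } else if (!is.null(config$paths$ct)) {
    ct <- utils::read.delim(config$paths$ct, stringsAsFactors = FALSE)
    ct_manifest <- if (!is.null(config$paths$ct_manifest))
      read_sample_manifest(config$paths$ct_manifest) else manifest
  } else ct <- NULL
  if (!is.null(ct)) {
    folds <- timer("qpcr", qpcr_fold_change(ct, ct_manifest))
    case_folds <- folds[folds$group == "hr", ]
    mean_folds <- tapply(log2(case_folds$fold), case_folds$mirna, mean)
    qpcr_folds <- stats::setNames(2^as.numeric(mean_folds),
                                  names(mean_folds))
    corr <- tryCatch(correlate_platforms(array_folds, qpcr_folds),
                     error = function(e) NULL)
    qpcr <- list(folds = folds, mean_folds = qpcr_folds,
                 correlation = corr)
    utils::write.table(folds, art("qpcr_folds.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(corr))
      utils::write.table(as.data.frame(corr), art("qpcr_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    run_manifest$stage_counts$qpcr_mirnas <-
      length(unique(folds$mirna))
  }

  # ---- crisscross target consensus ----------------------------------------
  targets <- NULL
  groups <- candidate_groups(screen)
  if (config$simulate && length(unlist(groups))) {
    log_stage("simulating target map + crisscross mining")
    map <- simulate_target_map(
      groups, planted_common = plant_common_genes(groups),
      n_background_targets = 200, seed = stage_seed(config$seed, 3))
    write_target_map(map, art("inputs", "target_map.tsv"))
  } else if (!is.null(config$paths$targets)) {
    map <- read_target_map(config$paths$targets)
  } else map <- NULL
  if (!is.null(map) && length(unlist(groups))) {
    targets <- timer("targets", crisscross(map, groups,
                                           min_support = config$min_support,
                                           min_evidence = config$min_evidence))
    write_consensus_tables(targets, art("consensus_tables.tsv"))
    run_manifest$stage_counts$consensus_genes <-
      sum(vapply(targets$tables, nrow, integer(1)))
  }

  # ---- positivity quantification ------------------------------------------
  positivity <- NULL
  if (config$simulate) {
    log_stage("simulating positivity counts")
    pos <- simulate_positivity(c(control = 0.12, inhibited = 0.35),
                               seed = stage_seed(config$seed, 4))
  } else if (!is.null(config$paths$positivity)) {
    pos <- utils::read.delim(config$paths$positivity,
                             stringsAsFactors = FALSE)
  } else pos <- NULL
  if (!is.null(pos)) {
    pct <- percent_positivity(pos)
    cmp <- timer("positivity", group_compare(pct$percent, pct$group))
    positivity <- list(table = pct, comparison = cmp)
    utils::write.table(pct, art("positivity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    run_manifest$stage_counts$positivity_fields <- nrow(pct)
  }

  if (config$simulate)
    for (f in list.files(art("inputs"), full.names = TRUE))
      run_manifest$checksums[[basename(f)]] <- unname(tools::md5sum(f))
  run_manifest$status <- "ok"

  out <- structure(list(screen = screen, qpcr = qpcr, targets = targets,
                        positivity = positivity, truth = truth,
                        catalog_truth = catalog_truth,
                        artifacts = list(
                          dir = config$out_dir,
                          candidates = art("candidates.tsv"),
                          report = art("traverse_report.tsv"),
                          run_manifest = art("run_manifest.json")),
                        manifest = run_manifest),
                   class = "mirnome_run")
  out
}

#' @export
print.mirnome_run <- function(x, ...) {
  cat("mirnome_run (", x$manifest$status, ") -> ", x$artifacts$dir, "\n",
      sep = "")
  print(x$screen)
  if (!is.null(x$qpcr$correlation))
    cat("  qPCR validation: r = ", round(x$qpcr$correlation$r, 3),
        " over ", x$qpcr$correlation$n, " miRNAs\n", sep = "")
  invisible(x)
}

# Geometric mean of HR/NM-X ratios per candidate across all comparisons.
geometric_array_folds <- function(screen) {
  tabs <- screen$traverse$tables
  ids <- tabs[[1]]$mirna
  lr <- rowMeans(vapply(tabs, function(fc)
    log2(fc$ratio[match(ids, fc$mirna)]), numeric(length(ids))))
  stats::setNames(2^lr, ids)
}

# A validation panel resembling the published 5-assay design: candidates
# spanning both directions plus an unchanged miRNA, with array-measured
# folds as the simulated qPCR truth.
qpcr_panel <- function(screen, truth) {
  af <- geometric_array_folds(screen)
  up <- utils::head(screen$ranks$up$mirna, 2)
  dn <- utils::head(screen$ranks$down$mirna, 2)
  null_ids <- setdiff(names(af), c(names(truth$planted_up),
                                   names(truth$planted_down)))
  panel <- c(up, dn, utils::head(null_ids, 1))
  af[panel]
}

# Four crisscross groups: direction x homology decision.
candidate_groups <- function(screen) {
  if (is.null(screen$homology)) {
    return(list(up = screen$traverse$up$members,
                down = screen$traverse$down$members))
  }
  rep_up <- screen$homology$up$report
  rep_dn <- screen$homology$down$report
  list(up_nonhom = rep_up$candidate[rep_up$decision == "retained"],
       up_hom = rep_up$candidate[rep_up$decision == "excluded"],
       down_nonhom = rep_dn$candidate[rep_dn$decision == "retained"],
       down_hom = rep_dn$candidate[rep_dn$decision == "excluded"])
}

# Plant up to three common genes per nonempty group for the simulated map.
plant_common_genes <- function(groups) {
  planted <- list()
  for (g in names(groups)) {
    m <- groups[[g]]
    if (length(m) < 2) next
    for (k in seq_len(min(3, length(m) %/% 2))) {
      gene <- sprintf("COMMON_%s_%d", toupper(g), k)
      planted[[gene]] <- utils::head(m, min(5, length(m)))
    }
  }
  planted
}
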