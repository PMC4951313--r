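#' Simulation configuration for the synthetic miRnome array
#'
#' Defines the study conditions emulated by [simulate_mirnome()]: the array
#' platform scale (852 miRNA probes compared between groups, 144 experimental
#' control probes), the animal design (3 sham, 2 non-metastatic xenograft
#' controls, 3 high-risk cases) and the planted differential signal (34
#' upregulated and 46 downregulated miRNAs, of which 3 upregulated markers
#' exceed 10-fold).
#'
#' Intensities are built additively from a shared mouse-serum background
#' component (present in every animal), a tumor component (xenograft-bearing
#' animals only) and planted fold effects on the tumor component of high-risk
#' animals, then scaled by a per-sample factor that spike-in normalization
#' must undo, and perturbed by multiplicative lognormal noise with
#' coefficient of variation `noise_cv`.
#'
#' @param n_mirna_probes Number of miRNA probes (default 852).
#' @param n_control_probes Number of experimental control probes (default
#'   144), split internally into blank, spike-in and U6 features.
#' @param n_sham,n_nmx,n_hr Animals per group (defaults 3, 2, 3).
#' @param n_up_planted,n_down_planted Planted differential miRNAs (34 / 46).
#' @param up_fold_range Fold interval for planted upregulation below the
#'   top-marker threshold, default `c(2.5, 16)`; draws are truncated below 10
#'   so that the planted top-marker set is exactly the >=10-fold set.
#' @param down_fold_range Fold interval for planted downregulation, default
#'   `c(1/16, 0.4)`.
#' @param n_top_markers Planted upregulated miRNAs with fold drawn from
#'   `top_fold_range` (default 3).
#' @param top_fold_range Fold interval for top markers, default `c(10, 16)`;
#'   must lie at or above 10.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   measurement noise (default 0.2; 0 gives a noiseless array).
#' @param baseline_mean,baseline_sd log2-scale mean and sd of the per-probe
#'   tumor-component intensity (defaults 9 and 1).
#' @param background_mean,background_sd log2-scale center and residual sd of
#'   the per-probe mouse background component (defaults 6 and 0.5). The
#'   background shares the probe's abundance effect with the tumor
#'   component (conserved miRNAs circulate abundantly in both species), so
#'   the background-to-signal ratio is centered at
#'   `2^(background_mean - baseline_mean)` with log2 spread
#'   `background_sd`.
#' @param blank_level Additive background floor, also the blank-probe level
#'   (default 32).
#' @param sample_scale_sdlog Log-sd of the per-sample scale factor (0.15).
#' @param p_species_specific Probability that a miRNA is human-specific
#'   (no mouse homolog), default 0.30.
#' @param seed Integer seed; identical seed and config give identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mirna_probes = 852, n_control_probes = 144,
                       n_sham = 3, n_nmx = 2, n_hr = 3,
                       n_up_planted = 34, n_down_planted = 46,
                       up_fold_range = c(2.5, 16),
                       down_fold_range = c(1 / 16, 0.4),
                       n_top_markers = 3, top_fold_range = c(10, 16),
                       noise_cv = 0.2,
                       baseline_mean = 9, baseline_sd = 1,
                       background_mean = 6, background_sd = 0.5,
                       blank_level = 32, sample_scale_sdlog = 0.15,
                       p_species_specific = 0.30, seed = 1) {
  cfg <- list(n_mirna_probes = n_mirna_probes,
              n_control_probes = n_control_probes,
              n_sham = n_sham, n_nmx = n_nmx, n_hr = n_hr,
              n_up_planted = n_up_planted, n_down_planted = n_down_planted,
              up_fold_range = up_fold_range,
              down_fold_range = down_fold_range,
              n_top_markers = n_top_markers,
              top_fold_range = top_fold_range,
              noise_cv = noise_cv,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              background_mean = background_mean,
              background_sd = background_sd,
              blank_level = blank_level,
              sample_scale_sdlog = sample_scale_sdlog,
              p_species_specific = p_species_specific,
              seed = as.integer(seed))
  counts <- c(n_mirna_probes, n_control_probes, n_sham, n_nmx, n_hr)
  if (any(counts <= 0))
    stop("all probe and sample counts must be positive", call. = FALSE)
  if (n_up_planted < 0 || n_down_planted < 0 || n_top_markers < 0)
    stop("planted counts must be nonnegative", call. = FALSE)
  if (n_up_planted + n_down_planted > n_mirna_probes)
    stop("planted miRNAs exceed the number of miRNA probes", call. = FALSE)
  if (n_top_markers > n_up_planted)
    stop("n_top_markers must not exceed n_up_planted", call. = FALSE)
  if (up_fold_range[1] <= 2 || up_fold_range[2] < up_fold_range[1])
    stop("up_fold_range must lie above 2 so planted effects clear the cutoff",
         call. = FALSE)
  if (down_fold_range[2] >= 0.5 || down_fold_range[1] > down_fold_range[2] ||
      down_fold_range[1] <= 0)
    stop("down_fold_range must lie in (0, 0.5)", call. = FALSE)
  if (n_top_markers > 0 && top_fold_range[1] < 10)
    stop("top_fold_range must start at or above 10", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be nonnegative", call. = FALSE)
  if (p_species_specific < 0 || p_species_specific > 1)
    stop("p_species_specific must be in [0, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# Split the experimental control probes into blank / spike-in / U6 features
# in roughly the 48:90:6 proportion used for a 144-control platform.
split_controls <- function(n_control) {
  n_u6 <- max(1L, round(n_control * 6 / 144))
  n_blank <- max(1L, round(n_control * 48 / 144))
  n_spike <- n_control - n_u6 - n_blank
  if (n_spike < 1)
    stop("n_control_probes too small to host blank, spike-in and U6 features",
         call. = FALSE)
  c(blank = n_blank, spike_in = n_spike, u6 = n_u6)
}

lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a whole-miRnome serum array with planted ground truth
#'
#' Generates raw probe intensities for sham, non-metastatic xenograft (NM-X)
#' and high-risk (HR) animals. Sham animals carry only the mouse background
#' component; NM-X animals add a tumor component; HR animals carry the
#' planted fold effects on top of the tumor component, so that after
#' background subtraction, spike-in normalization and sham baseline
#' correction, the HR / NM-X ratio of a planted miRNA equals its planted
#' fold exactly in the noiseless limit.
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{raw [expression_matrix()] (miRNA + control probes,
#'       all samples)}
#'     \item{manifest}{[sample_manifest()] covering all samples}
#'     \item{truth}{planted ground truth: `planted_up` and `planted_down`
#'       (named fold vectors), `top_markers` (ids with fold >= 10), and
#'       `species_specific` (named logical over all miRNA ids)}
#'   }
#' @examples
#' sim <- simulate_mirnome(sim_config(n_mirna_probes = 50, n_up_planted = 4,
#'                                    n_down_planted = 4, n_top_markers = 1,
#'                                    seed = 7))
#' sim$matrix
#' @export
simulate_mirnome <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  ids <- sprintf("hsa-miR-sim-%04d", seq_len(config$n_mirna_probes))
  ctl <- split_controls(config$n_control_probes)
  blank_ids <- sprintf("BLANK_%03d", seq_len(ctl[["blank"]]))
  spike_ids <- sprintf("SPIKE_%03d", seq_len(ctl[["spike_in"]]))
  u6_ids <- sprintf("U6_%02d", seq_len(ctl[["u6"]]))

  samples <- c(sprintf("sham_%d", seq_len(config$n_sham)),
               sprintf("nmx_%d", seq_len(config$n_nmx)),
               sprintf("hr_%d", seq_len(config$n_hr)))
  groups <- rep(c("sham", "nmx", "hr"),
                c(config$n_sham, config$n_nmx, config$n_hr))
  manifest <- sample_manifest(samples, groups)

  # planted identities and folds
  planted <- sample(ids, config$n_up_planted + config$n_down_planted)
  up_ids <- planted[seq_len(config$n_up_planted)]
  down_ids <- setdiff(planted, up_ids)
  up_folds <- numeric(config$n_up_planted)
  names(up_folds) <- up_ids
  n_top <- config$n_top_markers
  if (n_top > 0)
    up_folds[seq_len(n_top)] <- stats::runif(n_top, config$top_fold_range[1],
                                             config$top_fold_range[2])
  if (config$n_up_planted > n_top) {
    lo <- config$up_fold_range[1]
    hi <- min(config$up_fold_range[2], 10 * (1 - 1e-9))
    up_folds[-seq_len(n_top)] <-
      stats::runif(config$n_up_planted - n_top, lo, hi)
  }
  down_folds <- stats::runif(config$n_down_planted,
                             config$down_fold_range[1],
                             config$down_fold_range[2])
  names(down_folds) <- down_ids

  fold <- rep(1, config$n_mirna_probes)
  names(fold) <- ids
  fold[up_ids] <- up_folds
  fold[down_ids] <- down_folds

  species_specific <- stats::runif(config$n_mirna_probes) <
    config$p_species_specific
  names(species_specific) <- ids

  # probe-level components; the mouse background shares the per-probe
  # abundance effect of the tumor component (conserved miRNAs are abundant
  # in both species' serum), with a residual species-specific spread
  abundance <- stats::rnorm(config$n_mirna_probes, 0, config$baseline_sd)
  tumor <- 2^(config$baseline_mean + abundance)
  background <- 2^(config$background_mean + abundance +
                     stats::rnorm(config$n_mirna_probes, 0,
                                  config$background_sd))
  spike_level <- 2^stats::runif(length(spike_ids), 7, 11)
  u6_level <- 2^stats::runif(length(u6_ids), 9.5, 10.5)
  scale <- stats::rlnorm(length(samples), 0, config$sample_scale_sdlog)
  names(scale) <- samples

  all_ids <- c(ids, blank_ids, spike_ids, u6_ids)
  mu <- matrix(0, nrow = length(all_ids), ncol = length(samples),
               dimnames = list(all_ids, samples))
  has_tumor <- groups != "sham"
  is_hr <- groups == "hr"
  for (j in seq_along(samples)) {
    f_j <- if (is_hr[j]) fold else rep(1, length(fold))
    t_j <- if (has_tumor[j]) tumor * f_j else 0
    mu[ids, j] <- config$blank_level + background + t_j
    mu[blank_ids, j] <- config$blank_level
    mu[spike_ids, j] <- spike_level
    mu[u6_ids, j] <- u6_level
  }
  mu <- sweep(mu, 2, scale, `*`)
  noise <- matrix(lognoise(length(mu), config$noise_cv), nrow = nrow(mu))
  values <- mu * noise

  truth <- list(planted_up = up_folds, planted_down = down_folds,
                top_markers = names(up_folds)[up_folds >= 10],
                species_specific = species_specific)
  list(matrix = expression_matrix(values), manifest = manifest,
       truth = truth)
}

random_rna <- function(n, len_range = c(20L, 24L)) {
  vapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate two-species mature miRNA catalogs with controlled homology
#'
#' Builds a human and a mouse catalog containing three homology classes:
#' shared entries (identical mature sequence in both species, identity 1),
#' optional near-identical entries (one substitution in the mouse copy,
#' identity above the filter threshold), and human-only entries guaranteed by
#' rejection sampling to have best mouse identity below `identity_threshold`.
#'
#' @param n_shared Entries identical between the species.
#' @param n_human_only Human-specific entries (no mouse homolog above the
#'   threshold).
#' @param n_mouse_only Mouse entries without any human counterpart.
#' @param seed Integer seed.
#' @param n_near_identical Shared-family entries whose mouse copy carries a
#'   single substitution (default 0); these count as homologous.
#' @param identity_threshold Identity bound used to certify human-only
#'   entries (default 0.80, matching the homology filter default).
#' @param shared_ids,human_only_ids Optional explicit human ids (with or
#'   without the `hsa-` prefix) overriding `n_shared` / `n_human_only`;
#'   used to build catalogs consistent with an array ground truth.
#' @return A list with `human` and `mouse` [mirna_catalog()] objects and
#'   `truth`, a data.frame (`id`, `class`, `species_specific`) over the
#'   human entries.
#' @export
simulate_catalogs <- function(n_shared, n_human_only, n_mouse_only,
                              seed = 1, n_near_identical = 0,
                              identity_threshold = 0.8,
                              shared_ids = NULL, human_only_ids = NULL) {
  if (!is.null(shared_ids)) n_shared <- length(shared_ids)
  if (!is.null(human_only_ids)) n_human_only <- length(human_only_ids)
  if (any(c(n_shared, n_human_only, n_mouse_only, n_near_identical) < 0))
    stop("catalog class counts must be nonnegative", call. = FALSE)
  if (n_shared + n_human_only + n_mouse_only + n_near_identical == 0)
    stop("at least one catalog class must be nonzero", call. = FALSE)
  set.seed(seed)

  strip_prefix <- function(x) sub("^[a-z]{3,4}-", "", x)
  shared_names <- if (is.null(shared_ids))
    sprintf("miR-s%03d", seq_len(n_shared)) else strip_prefix(shared_ids)
  near_names <- sprintf("miR-n%03d", seq_len(n_near_identical))
  human_names <- if (is.null(human_only_ids))
    sprintf("miR-h%03d", seq_len(n_human_only)) else
      strip_prefix(human_only_ids)
  mouse_names <- sprintf("miR-m%03d", seq_len(n_mouse_only))

  shared_seq <- random_rna(n_shared)
  near_seq <- random_rna(n_near_identical)
  mouse_only_seq <- random_rna(n_mouse_only)

  mutate1 <- function(s) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), 1)
    v[i] <- sample(setdiff(c("A", "C", "G", "U"), v[i]), 1)
    paste(v, collapse = "")
  }
  near_mouse_seq <- vapply(near_seq, mutate1, character(1), USE.NAMES = FALSE)

  mouse_seqs <- c(shared_seq, near_mouse_seq, mouse_only_seq)
  mouse_ids <- paste0("mmu-", c(shared_names, near_names, mouse_names))

  # human-only entries: reject any draw with a mouse hit at or above the
  # filter threshold, so species-specificity holds by construction
  human_only_seq <- character(n_human_only)
  for (i in seq_len(n_human_only)) {
    repeat {
      s <- random_rna(1)
      if (length(mouse_seqs) == 0 ||
          max(identity_vs_set(s, mouse_seqs)) < identity_threshold) {
        human_only_seq[i] <- s
        break
      }
    }
  }

  human <- mirna_catalog(paste0("hsa-", c(shared_names, near_names,
                                          human_names)),
                         c(shared_seq, near_seq, human_only_seq),
                         species = "hsa")
  mouse <- mirna_catalog(mouse_ids, mouse_seqs, species = "mmu")
  truth <- data.frame(
    id = human$ids,
    class = rep(c("shared", "near_identical", "human_only"),
                c(n_shared, n_near_identical, n_human_only)),
    species_specific = rep(c(FALSE, FALSE, TRUE),
                           c(n_shared, n_near_identical, n_human_only)),
    stringsAsFactors = FALSE)
  list(human = human, mouse = mouse, truth = truth)
}

#' Simulate a qPCR cycle-threshold table with known fold changes
#'
#' Ct values are constructed so that U6-referenced delta-delta-Ct
#' quantification recovers `true_folds` exactly when `ct_noise_sd = 0`:
#' the case-group target Ct is shifted by `-log2(fold)` relative to the
#' control group, a per-sample offset (shared by target and U6 wells) models
#' input-amount variation, and well noise is Gaussian on the cycle scale.
#'
#' @param true_folds Named positive numeric vector, miRNA id -> fold change
#'   of the case group relative to the control group.
#' @param n_replicates Technical replicates per well (default 3).
#' @param ct_noise_sd Gaussian well noise, in cycles (default 0).
#' @param seed Integer seed.
#' @param n_case,n_control Biological samples per group (defaults 3 and 2).
#' @param reference Reference assay id (default `"U6"`).
#' @param u6_ct,base_ct Reference Ct and central target Ct (18 and 25).
#' @return List with `ct` (long data.frame: `mirna`, `sample`, `replicate`,
#'   `ct`) and `manifest` (`sample_id`, `group`, `replicate`).
#' @export
simulate_qpcr <- function(true_folds, n_replicates = 3, ct_noise_sd = 0,
                          seed = 1, n_case = 3, n_control = 2,
                          reference = "U6", u6_ct = 18, base_ct = 25) {
  if (any(true_folds <= 0))
    stop("fold changes must be strictly positive", call. = FALSE)
  if (is.null(names(true_folds)) || anyDuplicated(names(true_folds)))
    stop("true_folds must be uniquely named by miRNA id", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (ct_noise_sd < 0) stop("ct_noise_sd must be nonnegative", call. = FALSE)
  set.seed(seed)

  samples <- c(sprintf("nmx_%d", seq_len(n_control)),
               sprintf("hr_%d", seq_len(n_case)))
  groups <- rep(c("nmx", "hr"), c(n_control, n_case))
  offset <- stats::rnorm(length(samples), 0, 0.3)
  names(offset) <- samples
  base <- base_ct + stats::runif(length(true_folds), -2, 2)
  names(base) <- names(true_folds)

  rows <- expand.grid(mirna = c(names(true_folds), reference),
                      sample = samples,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  is_ref <- rows$mirna == reference
  grp <- groups[match(rows$sample, samples)]
  ct <- ifelse(is_ref, u6_ct,
               base[rows$mirna] -
                 ifelse(grp == "hr", log2(true_folds[rows$mirna]), 0))
  ct <- ct + offset[rows$sample]
  if (ct_noise_sd > 0) ct <- ct + stats::rnorm(length(ct), 0, ct_noise_sd)
  rows$ct <- as.numeric(ct)
  list(ct = rows,
       manifest = sample_manifest(samples, groups))
}

#' Simulate per-field positive / total cell counts
#'
#' Emulates high-content immunofluorescence quantification: for each group,
#' `n_fields` imaged fields with a total (DAPI) cell count drawn uniformly
#' from `cells_per_field` and a binomial marker-positive count at the
#' group's true positivity fraction.
#'
#' @param group_proportions Named numeric vector of true positive fractions
#'   in `[0, 1]`, one per group.
#' @param n_fields Fields per group (default 63).
#' @param cells_per_field Integer range of total cells per field
#'   (default `c(80, 200)`).
#' @param seed Integer seed.
#' @return data.frame with columns `field`, `group`, `positive`, `total`.
#' @export
simulate_positivity <- function(group_proportions, n_fields = 63,
                                cells_per_field = c(80, 200), seed = 1) {
  if (any(group_proportions < 0 | group_proportions > 1))
    stop("group proportions must lie in [0, 1]", call. = FALSE)
  if (is.null(names(group_proportions)))
    stop("group_proportions must be named by group", call. = FALSE)
  set.seed(seed)
  out <- lapply(names(group_proportions), function(g) {
    total <- sample(seq(cells_per_field[1], cells_per_field[2]), n_fields,
                    replace = TRUE)
    data.frame(field = sprintf("%s_f%03d", g, seq_len(n_fields)),
               group = g,
               positive = stats::rbinom(n_fields, total,
                                        group_proportions[[g]]),
               total = total, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a miRNA-to-gene target map with planted common targets
#'
#' Planted genes are associated with exactly the stated miRNA subset (so
#' their consensus support count is known); background genes are 1-regular,
#' each associated with a single random miRNA.
#'
#' @param mirna_groups Named list of miRNA id vectors (the candidate groups).
#' @param planted_common Named list, gene symbol -> character vector of
#'   miRNAs (drawn from the groups) that target it.
#' @param n_background_targets Number of singleton background genes.
#' @param seed Integer seed.
#' @return data.frame with columns `mirna`, `gene`, `evidence`.
#' @export
simulate_target_map <- function(mirna_groups, planted_common = list(),
                                n_background_targets = 50, seed = 1) {
  all_mirnas <- unique(unlist(mirna_groups))
  if (length(all_mirnas) == 0)
    stop("mirna_groups must contain at least one miRNA", call. = FALSE)
  stray <- setdiff(unlist(planted_common), all_mirnas)
  if (length(stray))
    stop("planted miRNA(s) not in any group: ",
         paste(stray, collapse = ", "), call. = FALSE)
  set.seed(seed)
  planted <- lapply(names(planted_common), function(g) {
    m <- planted_common[[g]]
    data.frame(mirna = m, gene = toupper(g),
               evidence = sample(EVIDENCE_LEVELS, length(m), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  bg <- if (n_background_targets > 0)
    data.frame(mirna = sample(all_mirnas, n_background_targets,
                              replace = TRUE),
               gene = sprintf("BG%04d", seq_len(n_background_targets)),
               evidence = sample(EVIDENCE_LEVELS, n_background_targets,
                                 replace = TRUE),
               stringsAsFactors = FALSE)
  else NULL
  out <- do.call(rbind, c(planted, list(bg)))
  rownames(out) <- NULL
  out
}
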