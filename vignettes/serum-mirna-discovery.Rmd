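---
title: "Serum miRNA biomarker discovery by traverse fold-change consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum miRNA biomarker discovery by traverse fold-change consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRtraverse)
```

## The problem and the procedure

Neuroblastoma presents in two clinically distinct forms: a favorable disease
that often regresses, and a high-risk metastatic disease (HR-NB) with very
poor survival. A minimally invasive way to detect the switch from favorable
to high-risk disease is to profile miRNAs circulating in serum.
`miRtraverse` implements the discovery analysis for this setting: serum
miRnome microarray profiles from xenograft mouse models are screened for
miRNAs whose serum levels consistently separate high-risk cases from
favorable-disease controls, and the resulting candidates are filtered for
human specificity and validated across platforms.

The pipeline has five analytic stages:

1. **Array preprocessing.** Per sample, the mean intensity of blank
   (background) probes is subtracted from every feature; samples are then
   normalized to a control probe class (spike-in controls by default, U6
   optionally), dividing each sample by its mean control intensity and
   rescaling by the grand mean so control features become flat across
   samples. Finally, the per-probe mean over sham (tumor-free) animals is
   subtracted from the xenograft samples, removing host mouse serum
   background.
2. **Traverse consensus.** Every favorable-disease control (NM-X) is
   compared with every high-risk case: per comparison, the per-miRNA case
   over control ratio is thresholded at 2-fold, inclusively
   (`ratio >= 2` up, `ratio <= 1/2` down). The up (down) sets are
   intersected across cases within each control, and then across controls.
   A miRNA is a candidate only if it clears the cutoff in **every**
   control-by-case comparison; this intersection-of-all design is what
   removes inter-animal variation without any distributional model.
3. **Homology filtering.** Because mouse serum contributes its own
   circulating miRNAs, candidates are screened against the mouse mature
   catalog. "Zero homology" is operationalized as best global-alignment
   identity strictly below a threshold (default 0.80): retained candidates
   are human-specific prognostic marker candidates. Upregulated candidates
   whose *conservative* fold (their minimum ratio over all comparisons)
   exceeds 10 are flagged as top markers.
4. **qPCR validation.** Cycle thresholds are quantified by the
   delta-delta-Ct method against the U6 reference
   (fold = $2^{-\Delta\Delta C_t}$, exact doubling assumed), and the
   per-miRNA fold changes are correlated with the array folds on the log2
   scale.
5. **Downstream statistics.** Crisscross target mining ranks genes by how
   many candidate miRNAs of a group target them; imaging readouts are
   summarized as percent positivity ($100 \cdot A/B$ per field) and group
   differences are tested by ANOVA with Tukey's post-hoc correction.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 2 | fold-change bar per comparison (inclusive; a `strict` flag switches to strict inequalities) |
| `epsilon` | 1 intensity unit | floor applied after each subtraction so ratios stay defined |
| `normalize` | `"spike_in"` | control class(es) used for between-sample normalization |
| `identity_threshold` | 0.80 | alignment identity above which a candidate counts as mouse-homologous |
| `top_fold` | 10 | conservative-fold bar for top markers (strict `>`) |
| `min_support` | 2 | miRNAs per gene required in the target consensus |
| `min_evidence` | `"predicted"` | weakest association evidence counted |

Choices worth explaining:

* **Inclusive thresholding.** The procedure's criterion is "at least
  2-fold"; ratios exactly at the boundary are kept. Under the degenerate
  `cutoff = 1`, ratios exactly 1 belong to neither direction.
* **Mean, not median.** Control normalization and sham correction use
  means; the choice is configurable in spirit but means are what a small
  (n = 2-3 per group) design supports.
* **No variance model, no multiple-testing correction.** The screen is
  fold-change-only by design; its stringency comes from requiring survival
  in all six comparisons, not from p-values. This is a methodological
  property of the procedure, stated prominently rather than hidden.
* **Top markers are flagged before the homology filter**, on the full
  upregulated consensus set. A mouse-homologous miRNA can therefore be a
  top marker while not being a human-specific candidate; the two labels
  answer different questions (effect size vs. species provenance).
* **Homology metric.** No alignment metric is prescribed by the original
  search procedure, so the package uses Needleman-Wunsch global alignment
  identity (matches over alignment columns, unit match, mismatch -1, gap
  -1 by default) with the threshold exposed and logged. Identity 1.0 holds
  exactly when sequences are identical.

## What the synthetic data emulates

The generator reproduces the study's structure so that every stage is
testable without external data:

* **Platform scale:** 852 miRNA probes compared between groups plus 144
  experimental control probes (blank / spike-in / U6, split 48:90:6).
* **Design:** 3 sham, 2 NM-X controls, 3 HR-NB cases.
* **Planted signal:** 34 upregulated (folds 2.5-16) and 46 downregulated
  (folds 1/16-0.4) miRNAs, 3 of the upregulated above 10-fold. Planted
  folds avoid (0.5, 2) so the 2-fold criterion is unambiguous at low
  noise; boundary behavior is tested separately.
* **Signal construction:** intensities are built additively: sham animals
  carry only the mouse serum background; xenograft animals add a tumor
  component; high-risk animals multiply the tumor component by the planted
  folds. Each sample is scaled by a lognormal factor (log-sd 0.15) that
  spike-in normalization must undo, and measurements carry multiplicative
  lognormal noise (`noise_cv`, default 0.2). In the noiseless limit the
  preprocessing chain recovers planted folds exactly - a property the
  tests assert to 1e-10.
* **Background structure:** the mouse background on a probe shares the
  probe's abundance effect with the tumor component (ratio centered at
  1/8, residual log2 sd 0.5). This reflects that the mouse serum signal on
  a human probe is dominated by conserved miRNAs whose abundance tracks
  the miRNA's overall abundance; an independently drawn background would
  instead create a heavy tail of probes whose host background swamps the
  tumor signal, which is not how conserved serum miRNAs behave.
* **Catalogs:** mature sequences 20-24 nt over A/C/G/U. Shared entries are
  identical across species; optional near-identical entries carry one
  substitution; human-only entries are rejection-sampled until their best
  mouse identity is below the filter threshold, so species-specificity
  holds by construction.
* **qPCR:** case-group target Ct values are shifted by $-\log_2(\mathrm{fold})$;
  per-sample offsets hit target and U6 wells alike (and cancel in
  delta-Ct); well noise is Gaussian in cycles.

The generator does **not** emulate probe-level cross-hybridization, batch
or array-position effects, qPCR efficiency deviations from doubling, or
image-level variation (positivity starts from counts). Passing tests
therefore demonstrate correctness of the analysis logic under the stated
noise model, not robustness to platform artifacts absent from that model.

The number of sham animals is not part of the published design; the
default of 3 is an assumption recorded in the configuration.

## Numerical choices and degenerate inputs

* Subtraction can produce nonpositive intensities; values are floored at
  `epsilon` (default 1) so fold changes stay finite and positive. No
  further pseudo-count is added.
* Candidate ordering is deterministic: by conservative effect size, ties
  broken lexicographically by miRNA id. Best-hit ties in the homology
  search also break lexicographically.
* Missing controls (no blanks, no spike-ins, nonpositive control means, no
  sham samples, no U6 well for a sample) are hard errors with named error
  classes in the message, not silent fallbacks.
* Ct values outside 5-40 cycles warn but do not stop the analysis.
* All generators are deterministic given their seed; the pipeline derives
  fixed per-stage seeds from the master seed so stages are independently
  reproducible.

## Design of the package

The package is organized in the classic R modelling idiom: one central
function, `mirnome_screen()`, takes the data and the screen parameters and
returns a classed S3 object with `print`, `summary`, `coef` (conservative
log2 folds) and `plot` methods; internals are base R. The screen is a
set-valued discovery procedure rather than a fitted statistical model, so
`predict` and `residuals` have no meaningful definition and are not
provided; simulation lives in the explicit generator functions
(`simulate_mirnome()` and friends) whose outputs are inputs, not model
draws. `run_pipeline()` composes all stages, writes a fixed artifact
layout (candidate tables, stage reports, run manifest with checksums and
timings) and is the reproducibility entry point; users drive it from R,
and each stage is equally usable as a standalone function on TSV/FASTA
inputs.

## Problem sizes used by the tests

The unit suite exercises small matrices (up to 20 miRNAs, 6 samples)
against brute-force enumerations, plus the full 852-probe platform for
recovery and reporting checks; recovery under noise is averaged over 20
simulation seeds, cross-platform correlation over 100, and ANOVA
calibration over 2000 null draws - sizes chosen so the suite gives stable
Monte-Carlo estimates while remaining quick to run routinely.

## Known limitations

* The screen's all-comparisons intersection is conservative by design:
  with measurement noise, mildly changed miRNAs near the cutoff (folds
  between about 2 and 3, or 1/3 and 1/2) are frequently lost in at least
  one of the six comparisons. Precision stays near 1; recall is the cost.
* With 2-3 animals per group there is no basis for per-miRNA variance
  estimation; the procedure deliberately trades statistical modelling for
  replication-by-intersection, and the package does not add inference the
  design cannot support.
* The homology decision depends on the identity threshold; 0.80 is a
  defensible default for 20-24 nt sequences but is exposed precisely
  because no canonical value exists.
* Target maps are inputs. The package ranks support counts within the map
  it is given and knows nothing about the completeness or bias of the
  annotation source.
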