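#' Planted ground truth for a synthetic trial
#'
#' Defines the gene classes, planted treatment effects and variance
#' components that the synthetic generators encode and that recovery tests
#' check against. Classes: `ifng_activity` and `nk_activity` (rejection
#' activity genes, correlated with the early-rejection archetype score and
#' distinguished by cell expression), `endothelial` (correlated with the
#' fully-developed-rejection score and endothelium-expressed), `injury_up` /
#' `injury_down` (parenchymal injury response genes following linear
#' per-week trajectories with arm-specific slopes) and `null`.
#'
#' @param planted_sets Named list of character gene vectors, one per class.
#' @param ddfc Named list: per class, list with `b_w24` and `b_w52`, the
#'   planted log2 difference-in-differences (active-arm change minus
#'   placebo-arm change) at week 24 and week 52 relative to baseline. The
#'   reported delta-delta contrast carries an additional /2 scaling, so a
#'   planted value of -1 appears as -0.5 in contrast tables.
#' @param slopes Named list with per-week log2 slopes for `placebo` and
#'   `felzartamab`, applied to `injury_up` genes (sign-flipped for
#'   `injury_down`).
#' @param patient_sd,resid_sd Gaussian SDs (log2 units) of the per-gene
#'   patient random intercept and residual noise.
#' @param seed Integer recorded with the truth object.
#' @return A `trial_truth` object.
#' @export
trial_truth <- function(planted_sets, ddfc, slopes,
                        patient_sd = 0.5, resid_sd = 0.3, seed = NA_integer_) {
  stopifnot(is.list(planted_sets), is.list(ddfc), is.list(slopes))
  genes <- unlist(planted_sets, use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop_ddfx("a planted gene appears in more than one class",
              "ddfx_config_error")
  }
  if (!all(c("placebo", "felzartamab") %in% names(slopes))) {
    stop_ddfx("slopes must name placebo and felzartamab", "ddfx_config_error")
  }
  eff <- unlist(ddfc, use.names = FALSE)
  if (length(eff) > 0 && any(!is.finite(unlist(eff)))) {
    stop_ddfx("planted effects must be finite", "ddfx_config_error")
  }
  structure(
    list(planted_sets = planted_sets, ddfc = ddfc, slopes = slopes,
         patient_sd = patient_sd, resid_sd = resid_sd, seed = seed),
    class = "trial_truth"
  )
}

#' Default planted truth
#'
#' The default conditions plant a strong suppression of rejection-activity
#' genes at week 24 (log2 difference-in-differences -1.0) with partial
#' rebound by week 52, a milder endothelial effect, and injury trajectories
#' that fall under treatment (-0.01 log2/week) and rise under placebo
#' (+0.005 log2/week).
#'
#' @param n_genes Total gene universe size (>= 200).
#' @param n_per_class Named integer vector of planted class sizes.
#' @return A `trial_truth`.
#' @export
default_trial_truth <- function(n_genes = 2000,
                                n_per_class = c(ifng_activity = 20,
                                                nk_activity = 20,
                                                endothelial = 20,
                                                injury_up = 30,
                                                injury_down = 30)) {
  if (n_genes < sum(n_per_class) + 50) {
    stop_ddfx("n_genes too small for the planted classes", "ddfx_invalid_argument")
  }
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  idx <- 0
  planted <- lapply(n_per_class, function(k) {
    out <- gene_ids[idx + seq_len(k)]
    idx <<- idx + k
    out
  })
  planted$null <- gene_ids[(idx + 1):n_genes]
  ddfc <- list(
    ifng_activity = list(b_w24 = -1.0, b_w52 = -0.3),
    nk_activity   = list(b_w24 = -1.0, b_w52 = -0.3),
    endothelial   = list(b_w24 = -0.5, b_w52 = -0.4)
  )
  trial_truth(planted_sets = planted, ddfc = ddfc,
              slopes = list(placebo = 0.005, felzartamab = -0.01))
}

truth_universe <- function(truth) {
  sort(unlist(truth$planted_sets, use.names = FALSE))
}

truth_class_of <- function(truth) {
  cls <- rep(names(truth$planted_sets), lengths(truth$planted_sets))
  setNames(cls, unlist(truth$planted_sets, use.names = FALSE))
}

#' Generator configuration for the reference cohort
#'
#' @param rho_hi Minimum population Spearman correlation between a planted
#'   activity gene and its latent archetype score.
#' @param rho_margin Planted correlations target `rho_hi + rho_margin`.
#' @param base_mean,base_sd Per-gene baseline log2 level distribution.
#' @param gene_cor Optional shared-factor variance fraction inducing
#'   correlation among genes (0 = independent given the latent scores).
#' @return A list of validated parameters.
#' @export
cohort_params <- function(rho_hi = 0.7, rho_margin = 0.1,
                          base_mean = 7, base_sd = 1.5, gene_cor = 0) {
  if (rho_hi < 0 || rho_hi + rho_margin >= 1) {
    stop_ddfx("need 0 <= rho_hi and rho_hi + rho_margin < 1", "ddfx_config_error")
  }
  if (gene_cor < 0 || gene_cor >= 1) {
    stop_ddfx("gene_cor must be in [0, 1)", "ddfx_config_error")
  }
  list(rho_hi = rho_hi, rho_margin = rho_margin, base_mean = base_mean,
       base_sd = base_sd, gene_cor = gene_cor)
}

# Gaussian loading that yields a target Spearman correlation: for bivariate
# normal data Spearman rho_s = (6/pi) asin(rho_p / 2), inverted here.
loading_for_spearman <- function(rho_s) {
  rho_p <- 2 * sin(pi * rho_s / 6)
  rho_p / sqrt(1 - rho_p^2)
}

#' Simulate a reference cohort with archetype scores
#'
#' Emulates a large cross-sectional biopsy cohort carrying per-sample
#' early-rejection (`eabmr_score`) and fully-developed-rejection
#' (`fabmr_score`) archetype scores in \[0,1\]. Activity-class genes load on
#' the early score, endothelial-class genes on the fully-developed score,
#' all other genes on neither.
#'
#' @param n_samples Number of cohort samples (>= 20).
#' @param n_genes Gene universe size (>= 200); ignored when `truth` is given.
#' @param params See [cohort_params()].
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param truth Optional [trial_truth()] fixing gene ids and classes.
#' @return A `ref_cohort`: list with `expr` (genes x samples log2 matrix),
#'   `eabmr_score`, `fabmr_score`, and the class map used.
#' @export
generate_reference_cohort <- function(n_samples, n_genes = 2000,
                                      params = cohort_params(), seed = 1,
                                      truth = NULL) {
  if (n_samples < 20 || (is.null(truth) && n_genes < 200)) {
    stop_ddfx("need n_samples >= 20 and n_genes >= 200", "ddfx_invalid_argument")
  }
  if (is.null(truth)) truth <- default_trial_truth(n_genes)
  gene_ids <- truth_universe(truth)
  class_of <- truth_class_of(truth)[gene_ids]
  n_genes <- length(gene_ids)

  set.seed(seed)
  z_e <- rnorm(n_samples)
  z_f <- rnorm(n_samples)
  shared <- rnorm(n_samples)

  lam <- loading_for_spearman(min(params$rho_hi + params$rho_margin, 0.99))
  lam_e <- ifelse(class_of %in% c("ifng_activity", "nk_activity"), lam, 0)
  lam_f <- ifelse(class_of == "endothelial", lam, 0)

  base <- rnorm(n_genes, params$base_mean, params$base_sd)
  resid_sd <- sqrt(1 - params$gene_cor)
  expr <- base +
    outer(lam_e, z_e) + outer(lam_f, z_f) +
    sqrt(params$gene_cor) * matrix(rep(shared, each = n_genes),
                                   nrow = n_genes) +
    matrix(rnorm(n_genes * n_samples, sd = resid_sd), nrow = n_genes)
  dimnames(expr) <- list(gene_ids, sprintf("REF%05d", seq_len(n_samples)))

  structure(
    list(expr = expr,
         eabmr_score = setNames(stats::pnorm(z_e), colnames(expr)),
         fabmr_score = setNames(stats::pnorm(z_f), colnames(expr)),
         class_of = class_of, params = params, seed = seed),
    class = "ref_cohort"
  )
}

#' Cell-profile generator configuration
#'
#' @param margin_log2 Log2 margin by which planted classes clear their
#'   derivation filters (> 0).
#' @param base_mean,base_sd Distribution of the per-gene baseline level
#'   shared across cell types (expression levels of a gene are highly
#'   correlated between cell types; large fold differences are the
#'   exception, not the rule).
#' @param dev_sd SD of the condition-specific deviation around the shared
#'   baseline (controls how often an unselective gene shows a large
#'   between-cell-type fold difference by chance).
#' @param jitter Uniform jitter width added above each enforced margin.
#' @return Parameter list.
#' @export
profile_params <- function(margin_log2 = 1, base_mean = 7, base_sd = 1.5,
                           dev_sd = 0.5, jitter = 0.5) {
  if (margin_log2 <= 0) stop_ddfx("margin_log2 must be > 0", "ddfx_config_error")
  list(margin_log2 = margin_log2, base_mean = base_mean, base_sd = base_sd,
       dev_sd = dev_sd, jitter = jitter)
}

#' Simulate NK-cell and endothelial (HUVEC) expression profiles
#'
#' Produces one log2 summary value per gene for NK cells, unstimulated
#' HUVECs and IFN-gamma-stimulated HUVECs, constructed so that each planted
#' class clears its cell-selectivity filter by at least `margin_log2`:
#' IFN-gamma-inducible genes exceed both NK and unstimulated HUVEC levels by
#' > log2(5); NK-expressed genes sit below the panel floor in both HUVEC
#' conditions and at the panel ceiling in NK cells; endothelial genes exceed
#' NK levels by > log2(4) in unstimulated HUVECs.
#'
#' @param truth A [trial_truth()] providing the class membership.
#' @param params See [profile_params()].
#' @param seed Integer seed.
#' @return A `cell_profiles` tibble: gene_id, nk, huvec_unstim, huvec_ifng.
#' @export
generate_cell_profiles <- function(truth, params = profile_params(), seed = 1) {
  stopifnot(inherits(truth, "trial_truth"))
  gene_ids <- truth_universe(truth)
  class_of <- truth_class_of(truth)[gene_ids]
  n <- length(gene_ids)

  set.seed(seed)
  common <- rnorm(n, params$base_mean, params$base_sd)
  nk <- common + rnorm(n, 0, params$dev_sd)
  hu0 <- common + rnorm(n, 0, params$dev_sd)
  hui <- common + rnorm(n, 0, params$dev_sd)

  m <- params$margin_log2
  jit <- function(k) runif(k, 0, params$jitter)

  i <- which(class_of == "ifng_activity")
  hui[i] <- pmax(nk[i], hu0[i]) + log2(5) + m + jit(length(i))

  i <- which(class_of == "nk_activity")
  # pinned above/below the panel extremes so the median and top-k filters
  # select exactly this class regardless of the baseline draw
  nk[i] <- max(nk) + m + jit(length(i))
  hu0[i] <- min(hu0) - m - jit(length(i))
  hui[i] <- min(hui) - m - jit(length(i))

  i <- which(class_of == "endothelial")
  hu0[i] <- nk[i] + log2(4) + m + jit(length(i))

  structure(
    tibble::tibble(gene_id = gene_ids, nk = nk, huvec_unstim = hu0,
                   huvec_ifng = hui),
    class = c("cell_profiles", "tbl_df", "tbl", "data.frame"),
    seed = seed
  )
}

#' Trial design parameters
#'
#' @param n_per_arm Patients per arm (>= 2); the default 10 gives the
#'   60-biopsy design (2 arms x 10 patients x 3 visits).
#' @param medulla_frac Fraction of genes given a nonzero %cortex slope.
#' @param cortex_slope_sd SD of the per-percent log2 cortex slope for
#'   medulla-sensitive genes.
#' @return Parameter list.
#' @export
trial_design <- function(n_per_arm = 10, medulla_frac = 0.1,
                         cortex_slope_sd = 0.01) {
  if (n_per_arm < 2) stop_ddfx("n_per_arm must be >= 2", "ddfx_invalid_argument")
  list(n_per_arm = n_per_arm, medulla_frac = medulla_frac,
       cortex_slope_sd = cortex_slope_sd)
}

# planted arm x visit offset for one class (placebo reference coding: the
# planted ddfc is the felzartamab-minus-placebo difference in changes)
class_effect <- function(truth, cls, arm, visit) {
  eff <- truth$ddfc[[cls]]
  if (is.null(eff) || arm != "felzartamab" || visit == "baseline") return(0)
  if (visit == "week24") eff$b_w24 else eff$b_w52
}

#' Simulate one randomized two-arm trial with repeated biopsies
#'
#' Per-gene model: log2 value = gene baseline + patient random intercept +
#' planted arm-by-visit class effect + %cortex slope x (cortex - 70) +
#' Gaussian noise. Injury-class genes additionally follow linear per-week
#' trends with arm-specific slopes from `truth$slopes`.
#'
#' @param design See [trial_design()].
#' @param truth A [trial_truth()].
#' @param seed Integer seed.
#' @return A `trial_data`: list with `expr` (genes x samples), `meta`
#'   (sample metadata tibble) and the `truth` used.
#' @export
generate_trial <- function(design = trial_design(), truth = default_trial_truth(),
                           seed = 1) {
  stopifnot(inherits(truth, "trial_truth"))
  gene_ids <- truth_universe(truth)
  class_of <- truth_class_of(truth)[gene_ids]
  n_genes <- length(gene_ids)
  n_pat <- 2L * design$n_per_arm

  patient_id <- sprintf("P%02d", seq_len(n_pat))
  arm <- rep(ARM_LEVELS, each = design$n_per_arm)
  meta <- tidyr::expand_grid(
    patient_id = patient_id,
    visit = factor(VISIT_LEVELS, levels = VISIT_LEVELS)
  )
  meta$arm <- factor(rep(arm, each = length(VISIT_LEVELS)), levels = ARM_LEVELS)
  meta$sample_id <- paste(meta$patient_id, meta$visit, sep = "_")

  set.seed(seed)
  meta$pct_cortex <- runif(nrow(meta), 40, 100)
  meta <- meta[, c("sample_id", "patient_id", "arm", "visit", "pct_cortex")]

  base <- rnorm(n_genes, 7, 1.5)
  pat_int <- matrix(rnorm(n_genes * n_pat, sd = truth$patient_sd),
                    nrow = n_genes, dimnames = list(gene_ids, patient_id))
  slope <- numeric(n_genes)
  n_med <- round(design$medulla_frac * n_genes)
  if (n_med > 0) {
    med_idx <- sample.int(n_genes, n_med)
    slope[med_idx] <- rnorm(n_med, sd = design$cortex_slope_sd)
  }

  injury_dir <- ifelse(class_of == "injury_up", 1,
                       ifelse(class_of == "injury_down", -1, 0))

  expr <- matrix(0, n_genes, nrow(meta),
                 dimnames = list(gene_ids, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    a <- as.character(meta$arm[s])
    v <- as.character(meta$visit[s])
    wk <- VISIT_WEEKS[[v]]
    eff <- vapply(names(truth$planted_sets), function(cl)
      class_effect(truth, cl, a, v), numeric(1))
    expr[, s] <- base +
      pat_int[, meta$patient_id[s]] +
      eff[class_of] +
      injury_dir * truth$slopes[[a]] * wk +
      slope * (meta$pct_cortex[s] - 70) +
      rnorm(n_genes, sd = truth$resid_sd)
  }

  structure(list(expr = expr, meta = normalize_meta(meta), truth = truth,
                 design = design, seed = seed),
            class = "trial_data")
}

# synthetic AKI marker table mirroring a single-nucleus cell-state catalog:
# injury classes map to 'New' (injury-induced) cell states, a few null genes
# provide non-'New' rows that the ontology builder must drop
synth_marker_table <- function(truth) {
  up <- truth$planted_sets$injury_up %||% character()
  dn <- truth$planted_sets$injury_down %||% character()
  nul <- head(truth$planted_sets$null %||% character(), 10)
  dplyr::bind_rows(
    tibble::tibble(gene = up,
                   cell_state = rep(c("PT_injured", "TAL_injured"),
                                    length.out = length(up)),
                   state_class = "New"),
    tibble::tibble(gene = dn, cell_state = "PT_failed_repair",
                   state_class = "New"),
    tibble::tibble(gene = nul, cell_state = "PT_healthy",
                   state_class = "other")
  )
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Generates a trial, cell profiles and marker table from `truth` and writes
#' expression TSV, metadata TSV, a GMT library of the planted sets, the cell
#' profile TSV, the AKI marker TSV and the truth JSON. All files round-trip
#' losslessly through the package readers.
#'
#' @param dir Output directory (created if needed).
#' @param truth A [trial_truth()].
#' @param design See [trial_design()].
#' @param seed Integer seed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixture_bundle <- function(dir, truth = default_trial_truth(),
                                 design = trial_design(), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_ddfx("cannot create output directory", "ddfx_io_error")
  truth$seed <- seed
  trial <- generate_trial(design, truth, seed = seed)
  profiles <- generate_cell_profiles(truth, seed = seed + 1L)
  markers <- synth_marker_table(truth)
  lib <- geneset_library(purrr::imap(
    truth$planted_sets[setdiff(names(truth$planted_sets), "null")],
    function(genes, nm) geneset(nm, genes, provenance = "planted synthetic class")
  ))

  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    meta = file.path(dir, "sample_meta.tsv"),
    gmt = file.path(dir, "planted_sets.gmt"),
    profiles = file.path(dir, "cell_profiles.tsv"),
    markers = file.path(dir, "aki_markers.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(trial$expr, paths[["expression"]])
  write_sample_meta(trial$meta, paths[["meta"]])
  write_gmt(lib, paths[["gmt"]])
  readr::write_tsv(profiles, paths[["profiles"]], progress = FALSE)
  readr::write_tsv(markers, paths[["markers"]], progress = FALSE)
  write_truth_json(truth, paths[["truth"]])
  invisible(paths)
}
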