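#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, original
#' order restored.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Numeric vector of adjusted values (q-values).
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_ddfx("p-values must be finite and in [0,1]", "ddfx_invalid_argument")
  }
  p.adjust(p, method = "BH")
}

#' Omnibus PERMANOVA on a block of molecular scores
#'
#' Permutational multivariate ANOVA on Euclidean distances between biopsies
#' in score space, testing for any group effect across a category of
#' scores. The pseudo-F partitions among/within sums of squares; on a
#' single score with two groups it equals the classical one-way ANOVA F.
#' p = (1 + #\{permuted F >= observed F\}) / (1 + n_perm).
#'
#' @param scores Data frame or matrix of score columns (rows = biopsies).
#' @param group Group labels, one per row.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional blocking factor (e.g. patient) restricting
#'   permutations within blocks; default free permutation.
#' @return A `permanova_fit`: list with `pseudo_f`, `p`, `n_perm`, `seed`,
#'   and the underlying vegan table.
#' @export
omnibus_permanova <- function(scores, group, n_perm = 1e5, seed = 1,
                              strata = NULL) {
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    stop_ddfx("scores must be finite", "ddfx_invalid_argument")
  }
  group <- factor(group)
  if (nlevels(group) < 2) {
    stop_ddfx("need at least 2 groups", "ddfx_invalid_argument")
  }
  if (n_perm < 99) stop_ddfx("n_perm must be >= 99", "ddfx_config_error")
  if (all(apply(m, 2, function(x) diff(range(x)) == 0))) {
    stop_ddfx("score matrix is constant", "ddfx_degenerate_input")
  }
  set.seed(seed)
  perm <- if (is.null(strata)) {
    n_perm
  } else {
    permute::how(blocks = factor(strata), nperm = n_perm)
  }
  res <- vegan::adonis2(m ~ group, permutations = perm, method = "euclidean")
  structure(
    list(pseudo_f = res$F[1], p = res$`Pr(>F)`[1], n_perm = n_perm,
         seed = seed, table = as.data.frame(res)),
    class = "permanova_fit"
  )
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean): pseudo-F = %.4g, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$p, x$n_perm))
  invisible(x)
}

#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::tibble(statistic = x$pseudo_f, p.value = x$p, n_perm = x$n_perm)
}

# all mixed-model summaries in this package use Satterthwaite denominator df;
# sets the emmeans option and returns a restorer closure
with_satterthwaite_df <- function() {
  old <- emmeans::emm_options(lmer.df = "satterthwaite")
  function() do.call(emmeans::emm_options, old)
}

# unweighted cell-mean decomposition of a one- or two-factor layout;
# returns per-observation fitted components
cell_components <- function(data, response, factors) {
  y <- data[[response]]
  if (any(!is.finite(y))) {
    stop_ddfx("response must be finite", "ddfx_invalid_argument")
  }
  fs <- lapply(factors, function(f) factor(data[[f]]))
  if (length(fs) == 1) {
    cm <- tapply(y, fs[[1]], mean)
    if (anyNA(cm)) stop_ddfx("empty factor cell", "ddfx_invalid_argument")
    grand <- mean(cm)
    cell <- as.vector(cm[as.character(fs[[1]])])
    list(cell = cell, a = cell, b = NULL, grand = grand, ab = NULL)
  } else {
    cm <- tapply(y, fs, mean)
    if (anyNA(cm)) stop_ddfx("empty factorial cell", "ddfx_invalid_argument")
    a_marg <- rowMeans(cm)
    b_marg <- colMeans(cm)
    grand <- mean(cm)
    ia <- as.character(fs[[1]]); ib <- as.character(fs[[2]])
    cell <- as.vector(cm[cbind(ia, ib)])
    list(cell = cell, a = as.vector(a_marg[ia]), b = as.vector(b_marg[ib]),
         grand = grand)
  }
}

#' Aligned-rank transform of a response for one effect
#'
#' Alignment strips from every observation the estimated (unweighted
#' cell-mean) contributions of all effects other than the target effect,
#' then assigns average ranks. One aligned-ranked column is produced per
#' effect of interest; the factorial model refit on that column tests only
#' the target effect.
#'
#' @param data Data frame with the response and factor columns.
#' @param response Response column name.
#' @param factors Character vector of one or two factor column names.
#' @param effect Target effect: a factor name, or `"A:B"` for the
#'   interaction of two factors.
#' @return `data` with added columns `aligned` and `aligned_rank`.
#' @export
art_transform <- function(data, response, factors,
                          effect = paste(factors, collapse = ":")) {
  stopifnot(length(factors) %in% 1:2)
  comp <- cell_components(data, response, factors)
  y <- data[[response]]
  resid <- y - comp$cell
  eff <- if (length(factors) == 1) {
    comp$a - comp$grand
  } else if (effect == factors[1]) {
    comp$a - comp$grand
  } else if (effect == factors[2]) {
    comp$b - comp$grand
  } else if (effect %in% paste(factors, collapse = ":")) {
    comp$cell - comp$a - comp$b + comp$grand
  } else {
    stop_ddfx(sprintf("unknown effect '%s'", effect), "ddfx_invalid_argument")
  }
  out <- tibble::as_tibble(data)
  out$aligned <- resid + eff
  out$aligned_rank <- rank(out$aligned, ties.method = "average")
  out
}

#' Aligned-rank-transform ANOVA with a patient random intercept
#'
#' Nonparametric factorial ANOVA for the repeated-measures two-arm design:
#' for each effect (treatment arm, follow-up visit, their interaction) the
#' response is aligned and ranked for that effect, then refit by REML with
#' the full factorial fixed part and a per-patient random intercept;
#' F-tests use Satterthwaite denominator degrees of freedom. The treatment
#' effect is the arm-by-visit interaction. A sanity check that non-target
#' effects are near zero on each aligned column is stored in
#' `$alignment_check`.
#'
#' @param data Data frame (e.g. a score table).
#' @param response Response column name.
#' @param arm,visit,patient Column names of the two factors and the
#'   repeated-measures unit.
#' @param effects Effects to test (default all three); restricting to the
#'   interaction alone skips two REML fits.
#' @return An `art_anova` object: `$effects` tibble (effect, f, df_num,
#'   df_den, p), `$data`, column names, and per-effect fits.
#' @export
art_anova <- function(data, response, arm = "arm", visit = "visit",
                      patient = "patient_id",
                      effects = c(arm, visit, paste(arm, visit, sep = ":"))) {
  y <- data[[response]]
  if (is.null(y)) stop_ddfx("response column not found", "ddfx_invalid_argument")
  if (diff(range(y)) == 0) {
    stop_ddfx("response is constant; ART-ANOVA undefined", "ddfx_degenerate_input")
  }
  factors <- c(arm, visit)
  fits <- list()
  rows <- list()
  checks <- list()
  for (eff in effects) {
    aligned <- art_transform(data, response, factors, effect = eff)
    fml <- as.formula(sprintf("aligned_rank ~ %s * %s + (1 | %s)",
                              arm, visit, patient))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(fml, data = aligned, REML = TRUE))),
      error = function(e) stop_ddfx(
        paste0("REML fit failed for effect ", eff, ": ", conditionMessage(e)),
        "ddfx_fit_error")
    )
    an <- suppressMessages(anova(fit, type = 3))
    rows[[eff]] <- tibble::tibble(
      effect = eff,
      f = an[eff, "F value"],
      df_num = an[eff, "NumDF"],
      df_den = an[eff, "DenDF"],
      p = an[eff, "Pr(>F)"]
    )
    checks[[eff]] <- max(an[setdiff(rownames(an), eff), "F value"], 0)
    fits[[eff]] <- fit
  }
  structure(
    list(effects = dplyr::bind_rows(rows),
         data = tibble::as_tibble(data), response = response,
         arm = arm, visit = visit, patient = patient,
         fits = fits, alignment_check = unlist(checks)),
    class = "art_anova"
  )
}

#' @export
print.art_anova <- function(x, ...) {
  cat(sprintf("ART-ANOVA of %s\n", x$response))
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' @method tidy art_anova
#' @export
tidy.art_anova <- function(x, ...) {
  dplyr::rename(x$effects, statistic = "f", p.value = "p")
}

#' @method glance art_anova
#' @export
glance.art_anova <- function(x, ...) {
  int <- x$effects[x$effects$effect == paste(x$arm, x$visit, sep = ":"), ]
  tibble::tibble(interaction_f = int$f, interaction_p = int$p,
                 alignment_max_off_f = max(x$alignment_check))
}

#' Pairwise and window contrasts within the treatment-by-visit interaction
#'
#' Aligned-rank contrasts (ART-C): the two factors are concatenated into a
#' single six-level cell factor, the response aligned and ranked for it,
#' refit with a patient random intercept, and all C(6,2) = 15 pairwise cell
#' contrasts computed on that scale with BH-FDR across the family. The
#' three difference-in-differences windows (baseline to week 24, week 24 to
#' week 52, baseline to week 52) — the treatment effects — are returned as
#' additional rows flagged `primary`, FDR-corrected within the three
#' windows.
#'
#' @param fit An [art_anova()] object.
#' @return Tibble: contrast, type (`pairwise` or `dd_window`), primary,
#'   estimate, se, df, p, fdr.
#' @export
interaction_contrasts <- function(fit) {
  if (!inherits(fit, "art_anova")) {
    stop_ddfx("interaction_contrasts() needs a fitted art_anova object",
              "ddfx_state_error")
  }
  restore <- with_satterthwaite_df()
  on.exit(restore(), add = TRUE)
  data <- fit$data
  data$.cell <- interaction(data[[fit$arm]], data[[fit$visit]], sep = ".",
                            lex.order = TRUE)
  # align for the concatenated cell factor, then rank
  aligned <- art_transform(data, fit$response, ".cell")
  fml <- as.formula(sprintf("aligned_rank ~ .cell + (1 | %s)", fit$patient))
  cfit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = aligned, REML = TRUE)))
  emm <- emmeans::emmeans(cfit, ".cell")

  pw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "none"))
  pairwise <- tibble::tibble(
    contrast = as.character(pw$contrast), type = "pairwise", primary = FALSE,
    estimate = pw$estimate, se = pw$SE, df = pw$df, p = pw$p.value
  )
  pairwise$fdr <- bh_fdr(pairwise$p)

  cells <- levels(data$.cell)
  arms <- sort(unique(as.character(data[[fit$arm]])))
  wins <- list(b_w24 = c("baseline", "week24"),
               w24_w52 = c("week24", "week52"),
               b_w52 = c("baseline", "week52"))
  cw <- function(arm, visit) as.numeric(cells == paste(arm, visit, sep = "."))
  dd_methods <- purrr::map(wins, function(v) {
    (cw("felzartamab", v[2]) - cw("felzartamab", v[1])) -
      (cw("placebo", v[2]) - cw("placebo", v[1]))
  })
  dd <- as.data.frame(emmeans::contrast(emm, method = dd_methods,
                                        adjust = "none"))
  windows <- tibble::tibble(
    contrast = as.character(dd$contrast), type = "dd_window", primary = TRUE,
    estimate = dd$estimate, se = dd$SE, df = dd$df, p = dd$p.value
  )
  windows$fdr <- bh_fdr(windows$p)

  dplyr::bind_rows(pairwise, windows)
}

#' Mixed-effects trajectory slopes for a molecular score
#'
#' REML fit of score ~ arm x weeks with per-patient random intercept and
#' slope, giving per-arm fitted slopes (score units per week) with 95%
#' confidence intervals, the arm-by-time interaction test (Satterthwaite),
#' and predicted trajectories with confidence bands. Singular random-slope
#' fits fall back to a random intercept (and, degenerately, to ordinary
#' least squares), recorded in `$downgraded`.
#'
#' @param scores Score table (long per-biopsy tibble).
#' @param score Score column name.
#' @param weeks Named vector mapping visit levels to weeks.
#' @return A `slope_fit`: `$slopes` (arm, slope, se, df, lower, upper),
#'   `$interaction_p`, `$trajectories` (arm, week, fit, lower, upper),
#'   `$downgraded`, `$fit`.
#' @export
fit_mixed_slopes <- function(scores, score, weeks = VISIT_WEEKS) {
  d <- tibble::as_tibble(scores)
  if (is.null(d[[score]])) {
    stop_ddfx("score column not found", "ddfx_invalid_argument")
  }
  d$week <- unname(weeks[as.character(d$visit)])
  d$.y <- d[[score]]
  if (min(table(d$patient_id)) < 2) {
    stop_ddfx("every patient needs >= 2 time points", "ddfx_invalid_argument")
  }
  restore <- with_satterthwaite_df()
  on.exit(restore(), add = TRUE)
  fit_candidate <- function(kind) {
    if (kind == "ols") return(stats::lm(.y ~ arm * week, data = d))
    fml <- if (kind == "random_slope") {
      .y ~ arm * week + (week | patient_id)
    } else {
      .y ~ arm * week + (1 | patient_id)
    }
    f <- suppressWarnings(suppressMessages(
      lmerTest::lmer(fml, data = d, REML = TRUE)))
    if (kind == "random_slope" && lme4::isSingular(f, tol = 1e-4)) {
      stop("singular random-slope fit")
    }
    f
  }
  # degenerate (e.g. noise-free) data can defeat the REML fits entirely;
  # fall back random slope -> random intercept -> OLS
  candidates <- c(random_slope = "none", random_intercept = "random_intercept",
                  ols = "ols")
  fit <- NULL; tr <- NULL; gdf <- NULL; downgraded <- "ols"
  for (kind in names(candidates)) {
    res <- tryCatch({
      f <- fit_candidate(kind)
      tr0 <- as.data.frame(emmeans::emtrends(f, "arm", var = "week"))
      grid <- emmeans::emmeans(f, ~ arm * week,
                               at = list(week = seq(0, max(d$week), by = 4)))
      list(fit = f, tr = tr0, gdf = as.data.frame(grid))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      fit <- res$fit; tr <- res$tr; gdf <- res$gdf
      downgraded <- candidates[[kind]]
      break
    }
  }
  if (is.null(fit)) {
    stop_ddfx("all trajectory model fits failed", "ddfx_fit_error")
  }

  slopes <- tibble::tibble(
    arm = as.character(tr$arm), slope = tr$week.trend, se = tr$SE,
    df = tr$df, lower = tr$lower.CL, upper = tr$upper.CL
  )

  interaction_p <- if (inherits(fit, "lmerModLmerTest")) {
    an <- suppressMessages(anova(fit, type = 3))
    an["arm:week", "Pr(>F)"]
  } else {
    an <- anova(fit)
    an["arm:week", "Pr(>F)"]
  }
  trajectories <- tibble::tibble(
    arm = as.character(gdf$arm), week = gdf$week, fit = gdf$emmean,
    lower = gdf$lower.CL, upper = gdf$upper.CL
  )

  vc <- if (inherits(fit, "lmerMod") || inherits(fit, "lmerModLmerTest")) {
    as.data.frame(lme4::VarCorr(fit))$vcov
  } else {
    numeric(0)
  }

  structure(
    list(score = score, slopes = slopes, interaction_p = interaction_p,
         trajectories = trajectories, downgraded = downgraded,
         variance_components = vc, fit = fit),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects slopes for %s (interaction p = %.4g%s)\n",
              x$score, x$interaction_p,
              if (x$downgraded != "none") paste0(", downgraded: ", x$downgraded) else ""))
  print(as.data.frame(x$slopes), row.names = FALSE)
  invisible(x)
}

#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  dplyr::mutate(x$slopes, term = paste0("slope_", .data$arm),
                .before = 1)
}

#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble::tibble(score = x$score, interaction_p = x$interaction_p,
                 downgraded = x$downgraded)
}

#' @method autoplot slope_fit
#' @export
autoplot.slope_fit <- function(object, ...) {
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$week, y = .data$fit,
                               colour = .data$arm, fill = .data$arm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Week", y = object$score,
                  title = sprintf("Fitted %s trajectories (interaction p = %.3g)",
                                  object$score, object$interaction_p)) +
    ggplot2::theme_minimal()
}
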