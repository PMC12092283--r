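test_that("bh_fdr equals the brute-force step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), bh_brute(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "ddfx_invalid_argument")
})

test_that("univariate PERMANOVA pseudo-F equals the classical one-way ANOVA F", {
  set.seed(7)
  y <- rnorm(24) + rep(c(0, 1), each = 12)
  g <- rep(c("a", "b"), each = 12)
  pm <- omnibus_permanova(matrix(y, ncol = 1), g, n_perm = 199, seed = 1)
  f_aov <- summary(aov(y ~ g))[[1]]["g", "F value"]
  expect_equal(pm$pseudo_f, f_aov, tolerance = 1e-10)
  expect_gte(pm$p, 1 / (199 + 1))

  # identical group multisets -> zero among-group variance, p = 1
  same <- rbind(diag(3), diag(3))
  pm0 <- omnibus_permanova(same, rep(c("a", "b"), each = 3),
                           n_perm = 199, seed = 1)
  expect_equal(pm0$pseudo_f, 0, tolerance = 1e-12)
  expect_equal(pm0$p, 1)

  expect_error(omnibus_permanova(matrix(1, 10, 2), rep(c("a", "b"), 5),
                                 n_perm = 199),
               class = "ddfx_degenerate_input")
  # seeded determinism of the permutation p-value
  set.seed(99)
  pm1 <- omnibus_permanova(matrix(y, ncol = 1), g, n_perm = 199, seed = 5)
  pm2 <- omnibus_permanova(matrix(y, ncol = 1), g, n_perm = 199, seed = 5)
  expect_identical(pm1$p, pm2$p)
})

test_that("alignment matches a brute-force effect decomposition", {
  # single factor: aligned values are residuals from the grand mean,
  # ranks equal raw-data ranks
  d1 <- tibble::tibble(g = rep(c("a", "b"), each = 4), y = c(1, 3, 2, 5, 9, 7, 8, 4))
  a1 <- art_transform(d1, "y", "g", effect = "g")
  expect_equal(a1$aligned, d1$y - mean(tapply(d1$y, d1$g, mean)))
  expect_equal(a1$aligned_rank, rank(d1$y))

  # constant response: all aligned 0, all ranks tied at (n+1)/2
  d0 <- tibble::tibble(g = rep(c("a", "b"), 3), y = rep(2, 6))
  a0 <- art_transform(d0, "y", "g", effect = "g")
  expect_equal(a0$aligned, rep(0, 6))
  expect_equal(a0$aligned_rank, rep(3.5, 6))

  # 2x2 balanced toy vs independent brute-force alignment oracle
  d <- tidyr::expand_grid(A = c("a1", "a2"), B = c("b1", "b2"),
                          rep = 1:3)
  set.seed(5)
  d$y <- rnorm(nrow(d)) + 2 * (d$A == "a2") + 1 * (d$B == "b2") +
    1.5 * (d$A == "a2" & d$B == "b2")
  cm <- tapply(d$y, list(d$A, d$B), mean)
  A_hat <- rowMeans(cm); B_hat <- colMeans(cm); grand <- mean(cm)
  cell <- cm[cbind(d$A, d$B)]
  oracle_int <- (d$y - cell) + (cell - A_hat[d$A] - B_hat[d$B] + grand)
  got <- art_transform(d, "y", c("A", "B"), effect = "A:B")
  expect_equal(got$aligned, unname(oracle_int))
  oracle_a <- (d$y - cell) + (A_hat[d$A] - grand)
  expect_equal(art_transform(d, "y", c("A", "B"), effect = "A")$aligned,
               unname(oracle_a))
})

test_that("ART-ANOVA statistics are affine-invariant and reject degenerate input", {
  # the rank step makes the test invariant to location/scale changes of the
  # response (alignment is linear, ranking ignores positive scaling)
  d <- null_score_data(1)
  d$y <- d$y + 2 * (d$arm == "felzartamab") * (d$visit != "baseline")
  f1 <- art_anova(d, "y")
  d2 <- d
  d2$y <- 3.7 * d$y - 12
  f2 <- art_anova(d2, "y")
  expect_equal(f1$effects$f, f2$effects$f, tolerance = 1e-8)
  expect_equal(f1$effects$p, f2$effects$p, tolerance = 1e-8)
  expect_named(f1$fits, c("arm", "visit", "arm:visit"))

  dc <- d
  dc$y <- 1
  expect_error(art_anova(dc, "y"), class = "ddfx_degenerate_input")
})

test_that("ART-ANOVA detects the planted interaction with high power", {
  # scores from the generator's default planted suppression (-1.0 log2 on
  # the activity class at week 24)
  truth <- small_truth()
  rej <- vapply(1:40, function(s) {
    trial <- generate_trial(trial_design(10), truth, seed = 2000 + s)
    lib <- geneset_library(list(geneset("act", truth$planted_sets$ifng_activity)))
    sc <- assemble_score_table(trial$expr, lib, trial$meta)
    fit <- art_anova(sc, "act", effects = "arm:visit")
    fit$effects$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("interaction contrasts: 15 cell pairs, BH property, symmetric-effect doubling", {
  d <- null_score_data(3)
  fit <- art_anova(d, "y")
  ctr <- interaction_contrasts(fit)
  expect_equal(sum(ctr$type == "pairwise"), choose(6, 2))
  expect_true(all(ctr$fdr >= ctr$p - 1e-12))
  expect_equal(sum(ctr$primary), 3)

  # opposite-sign follow-up shifts in the two arms: the window contrast is
  # about twice the single-arm change on the aligned-rank scale
  d2 <- null_score_data(4, patient_sd = 0)
  shift <- 3 * (d2$visit != "baseline")
  d2$y <- d2$y + ifelse(d2$arm == "felzartamab", -shift, shift)
  ctr2 <- interaction_contrasts(art_anova(d2, "y"))
  dd <- ctr2$estimate[ctr2$type == "dd_window" & ctr2$contrast == "b_w24"]
  single <- ctr2$estimate[ctr2$type == "pairwise" &
                            grepl("felzartamab.baseline - felzartamab.week24",
                                  ctr2$contrast)]
  expect_equal(abs(dd), 2 * abs(single), tolerance = 0.15)

  expect_error(interaction_contrasts(list()), class = "ddfx_state_error")
})

test_that("mixed-effects slopes recover noise-free trajectories exactly", {
  d <- null_score_data(5, patient_sd = 0)
  week <- c(baseline = 0, week24 = 24, week52 = 52)[as.character(d$visit)]
  pat <- as.integer(factor(d$patient_id)) / 10
  d$y <- pat + ifelse(d$arm == "felzartamab", -0.01, 0.01) * week
  sf <- fit_mixed_slopes(d, "y")
  expect_equal(sf$slopes$slope[sf$slopes$arm == "felzartamab"], -0.01,
               tolerance = 1e-8)
  expect_equal(sf$slopes$slope[sf$slopes$arm == "placebo"], 0.01,
               tolerance = 1e-8)
  expect_true(all(sf$variance_components >= 0))
  expect_true(all(sf$slopes$lower <= sf$slopes$slope &
                    sf$slopes$slope <= sf$slopes$upper))
  expect_true(all(c("arm", "week", "fit", "lower", "upper") %in%
                    names(sf$trajectories)))
})

test_that("null interaction p-values are roughly uniform (smoke calibration)", {
  # the full 1000-simulation calibration lives with the acceptance checks;
  # this smaller run guards the sampling path itself
  p <- vapply(1:150, function(s) {
    fit <- art_anova(null_score_data(s + 1000), "y", effects = "arm:visit")
    fit$effects$p
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.11)
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.001)
})
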