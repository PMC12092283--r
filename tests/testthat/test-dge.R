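test_that("IQR filter keeps the most variable genes with documented tie-breaks", {
  # hand-computed IQRs: type-7 quantiles over 5 samples
  expr <- rbind(
    g1 = c(1, 1.25, 1.5, 1.75, 2),   # IQR 0.5
    g2 = c(0, 1, 2, 3, 4),           # IQR 2.0
    g3 = c(1, 1.5, 2, 2.5, 3)        # IQR 1.0
  )
  colnames(expr) <- paste0("S", 1:5)
  kept <- iqr_filter(expr, 2)
  expect_equal(rownames(kept), c("g2", "g3"))

  expect_equal(iqr_filter(expr, 3), expr)          # keep = n is the identity
  expect_equal(iqr_filter(expr, 0.99), expr)       # fraction rounding to n likewise

  const <- rbind(flat = rep(2, 5), vary = c(0, 1, 2, 3, 4))
  colnames(const) <- paste0("S", 1:5)
  expect_equal(rownames(iqr_filter(const, 1)), "vary")
  expect_error(iqr_filter(expr, 0), class = "ddfx_invalid_argument")
  expect_error(iqr_filter(expr, 10), class = "ddfx_invalid_argument")
})

test_that("baseline imbalance flags fire on planted shifts and stay quiet otherwise", {
  trial <- fixture_trial()
  # identical baseline multisets across arms -> zero flags
  expr <- trial$expr
  meta <- trial$meta
  base_p <- meta$sample_id[meta$visit == "baseline" & meta$arm == "placebo"]
  base_f <- meta$sample_id[meta$visit == "baseline" & meta$arm == "felzartamab"]
  expr_eq <- expr
  expr_eq[, base_f] <- expr[, base_p]
  flags <- baseline_imbalance_flags(expr_eq, meta)
  expect_false(any(flags$baseline_imbalance))

  # planted +3 log2 arm shift at baseline is flagged
  expr_shift <- expr
  expr_shift["G00001", base_f] <- expr_shift["G00001", base_f] + 3
  flags2 <- baseline_imbalance_flags(expr_shift, meta)
  expect_true(flags2$baseline_imbalance[flags2$gene_id == "G00001"])

  # null flag rate near alpha
  truth0 <- small_truth()
  truth0$ddfc <- list()
  truth0$slopes <- list(placebo = 0, felzartamab = 0)
  rates <- vapply(1:8, function(s) {
    t0 <- generate_trial(trial_design(10), truth0, seed = 300 + s)
    mean(baseline_imbalance_flags(t0$expr, t0$meta)$baseline_imbalance)
  }, numeric(1))
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})

test_that("per-gene OLS recovers exact cell means and has residual df 53", {
  trial <- fixture_trial()
  fit <- fit_gene_models(trial$expr, trial$meta)
  expect_equal(fit$df, 60 - 7)

  # noise-free construction: known cell means + cortex slope recovered exactly
  meta <- trial$meta
  cells <- interaction(meta$arm, meta$visit, sep = ".", lex.order = TRUE)
  cm <- setNames(seq(1, 3.5, by = 0.5), levels(cells))
  cortex_c <- meta$pct_cortex - mean(meta$pct_cortex)
  y <- cm[as.character(cells)] + 0.02 * cortex_c
  expr0 <- rbind(exact = y, flat = rep(5, 60))
  colnames(expr0) <- meta$sample_id
  fit0 <- fit_gene_models(expr0, meta)
  expect_equal(unname(fit0$coefficients["exact", levels(cells)]),
               unname(cm), tolerance = 1e-10)
  expect_equal(unname(fit0$coefficients["exact", "cortex_c"]), 0.02,
               tolerance = 1e-10)
  expect_equal(unname(fit0$sigma2["exact"]), 0, tolerance = 1e-16)

  # permuting sample order leaves the fit unchanged
  perm <- sample(ncol(trial$expr))
  fit_p <- fit_gene_models(trial$expr[, perm], trial$meta)
  expect_equal(fit_p$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(fit_p$sigma2, fit$sigma2, tolerance = 1e-10)
})

test_that("delta-delta contrasts follow the printed halved arithmetic and telescope", {
  trial <- fixture_trial()
  fit <- fit_gene_models(trial$expr, trial$meta)
  b <- fit$coefficients
  # direct arithmetic oracle for one gene
  g <- "G00001"
  oracle <- (b[g, "felzartamab.week24"] - b[g, "felzartamab.baseline"]) / 2 -
    (b[g, "placebo.week24"] - b[g, "placebo.baseline"]) / 2
  expect_equal(unname(delta_delta_contrasts(fit, "b_w24")[g]), unname(oracle),
               tolerance = 1e-12)
  # unscaled variant is exactly twice the reported value
  expect_equal(delta_delta_contrasts(fit, "b_w24", scale = FALSE),
               2 * delta_delta_contrasts(fit, "b_w24"), tolerance = 1e-12)
  # window telescoping identity per gene
  expect_equal(delta_delta_contrasts(fit, "b_w52"),
               delta_delta_contrasts(fit, "b_w24") +
                 delta_delta_contrasts(fit, "w24_w52"),
               tolerance = 1e-12)
})

test_that("empirical-Bayes prior recovery and the moderated-t shrinkage formula", {
  # known scaled-inverse-chi-square truth d0=4, s0^2=0.05
  d <- 53
  set.seed(10)
  est <- replicate(40, {
    s2_true <- 4 * 0.05 / rchisq(500, df = 4)
    s2 <- s2_true * rchisq(500, df = d) / d
    fake <- structure(list(sigma2 = s2, df = d), class = "gene_fit")
    unlist(estimate_ebayes_hyper(fake))
  })
  expect_lt(abs(median(est["d0", ]) - 4) / 4, 0.25)
  expect_lt(abs(median(est["s0_2", ]) - 0.05) / 0.05, 0.25)

  # homoscedastic truth (d0 = Inf): estimated prior df is large
  set.seed(11)
  big <- mean(replicate(30, {
    s2 <- 0.1 * rchisq(500, df = d) / d
    fake <- structure(list(sigma2 = s2, df = d), class = "gene_fit")
    estimate_ebayes_hyper(fake)$d0 > 50
  }))
  expect_gte(big, 0.9)

  # duplicated gene rows leave the hyperparameters unchanged
  set.seed(12)
  s2 <- 0.05 * rchisq(200, df = d) / d
  f1 <- structure(list(sigma2 = s2, df = d), class = "gene_fit")
  f2 <- structure(list(sigma2 = rep(s2, 2), df = d), class = "gene_fit")
  expect_equal(estimate_ebayes_hyper(f1), estimate_ebayes_hyper(f2))
})

test_that("moderated t matches the hand shrinkage formula and its limits", {
  trial <- fixture_trial()
  expr <- trial$expr[1:50, ]
  fit <- fit_gene_models(expr, trial$meta)
  cvec <- ddfx:::dd_contrast_vector(fit, "b_w24")
  v <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)

  hyper <- list(d0 = 4, s0_2 = 0.05)
  tab <- moderated_tests(fit, hyper, "b_w24")
  g <- fit$gene_ids[7]
  s2_post <- (4 * 0.05 + fit$df * fit$sigma2[g]) / (4 + fit$df)
  dd <- unname(delta_delta_contrasts(fit, "b_w24")[g])
  expect_equal(tab$t[tab$gene_id == g], unname(dd / sqrt(s2_post * v)),
               tolerance = 1e-12)
  expect_equal(tab$df_total[1], 4 + fit$df)

  # d0 = 0: ordinary t
  tab0 <- moderated_tests(fit, list(d0 = 0, s0_2 = 1), "b_w24")
  ord_t <- delta_delta_contrasts(fit, "b_w24") / sqrt(fit$sigma2 * v)
  expect_equal(tab0$t, unname(ord_t), tolerance = 1e-12)

  # d0 = Inf: all variances at the prior, normal reference
  tabI <- moderated_tests(fit, list(d0 = Inf, s0_2 = 0.09), "b_w24")
  expect_equal(tabI$t, unname(delta_delta_contrasts(fit, "b_w24")) / sqrt(0.09 * v),
               tolerance = 1e-12)
  expect_true(all(is.infinite(tabI$df_total)))
  # shrinkage monotonicity: posterior variance between s^2 and s0^2
  s2_post_all <- (4 * 0.05 + fit$df * fit$sigma2) / (4 + fit$df)
  expect_true(all(
    (s2_post_all - fit$sigma2) * (s2_post_all - 0.05) <= 1e-12))
})

test_that("full moderated pipeline agrees with an independent limma fit", {
  trial <- fixture_trial()
  expr <- trial$expr
  meta <- trial$meta
  fit <- fit_gene_models(expr, meta)
  hyper <- estimate_ebayes_hyper(fit)
  tab <- moderated_tests(fit, hyper, "b_w24")

  cells <- interaction(meta$arm, meta$visit, sep = ".", lex.order = TRUE)
  design <- cbind(model.matrix(~ 0 + cells),
                  cortex_c = meta$pct_cortex - mean(meta$pct_cortex))
  colnames(design) <- c(levels(cells), "cortex_c")
  lfit <- limma::lmFit(expr, design)
  cmat <- matrix(ddfx:::dd_contrast_vector(fit, "b_w24"), ncol = 1,
                 dimnames = list(colnames(design), "dd"))
  cfit <- limma::eBayes(limma::contrasts.fit(lfit, cmat))
  expect_equal(tab$ddlogfc, unname(cfit$coefficients[, "dd"]), tolerance = 1e-8)
  expect_equal(tab$t, unname(cfit$t[, "dd"]), tolerance = 1e-6)
  expect_equal(tab$p, unname(cfit$p.value[, "dd"]), tolerance = 1e-6)
})

test_that("gene ranking honors flags, direction and table bounds", {
  trial <- fixture_trial()
  fit <- fit_gene_models(trial$expr, trial$meta)
  hyper <- estimate_ebayes_hyper(fit)
  flags <- baseline_imbalance_flags(trial$expr, trial$meta)
  tab <- moderated_tests(fit, hyper, "b_w24", flags = flags)

  expect_setequal(tab$rank, seq_len(nrow(tab)))  # rank is a permutation
  expect_true(all(tab$fdr >= tab$p - 1e-12))

  top <- rank_genes(tab, 20)
  expect_false(any(top$baseline_imbalance))
  expect_equal(top$p, sort(top$p))
  # planted activity suppression dominates the top of the list
  activity <- unlist(trial$truth$planted_sets[c("ifng_activity", "nk_activity")])
  expect_gte(mean(top$gene_id %in% activity), 0.8)
  # k beyond the table returns everything
  expect_equal(nrow(rank_genes(tab, 1e6, exclude_flagged = FALSE)), nrow(tab))
  down <- rank_genes(tab, 10, direction = "down")
  expect_true(all(down$ddlogfc < 0))
})

test_that("moderated p-values are calibrated under the null generator", {
  truth0 <- small_truth()
  truth0$ddfc <- list()
  truth0$slopes <- list(placebo = 0, felzartamab = 0)
  # iid-noise null: p-values approximately uniform
  truth0$patient_sd <- 0
  ps <- unlist(lapply(1:3, function(s) {
    t0 <- generate_trial(trial_design(10), truth0, seed = 400 + s)
    f <- fit_gene_models(t0$expr, t0$meta)
    moderated_tests(f, estimate_ebayes_hyper(f), "b_w24")$p
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)

  # with patient random intercepts the per-gene fixed-effect test is
  # conservative: intercepts cancel in the within-patient contrast but
  # inflate the residual variance estimate
  truth0$patient_sd <- 0.5
  t1 <- generate_trial(trial_design(10), truth0, seed = 410)
  f1 <- fit_gene_models(t1$expr, t1$meta)
  p1 <- moderated_tests(f1, estimate_ebayes_hyper(f1), "b_w24")$p
  expect_lte(mean(p1 < 0.05), 0.07)
})
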