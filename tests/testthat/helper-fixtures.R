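# shared fixtures, all generated in code under fixed seeds

# compact planted truth for fast trials
small_truth <- function(n_genes = 300) {
  default_trial_truth(n_genes,
                      n_per_class = c(ifng_activity = 10, nk_activity = 10,
                                      endothelial = 10, injury_up = 15,
                                      injury_down = 15))
}

# a moderately sized cohort for derivation recovery checks
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- default_trial_truth(800)
      cache <<- list(
        truth = truth,
        ref = generate_reference_cohort(400, truth = truth, seed = 101),
        profiles = generate_cell_profiles(truth, seed = 102)
      )
    }
    cache
  }
})

# one default trial, cached
fixture_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_trial(trial_design(10), small_truth(), seed = 103)
    }
    cache
  }
})

# score-level null data for calibration: patient intercept + iid noise
null_score_data <- function(seed, n_per_arm = 10, patient_sd = 0.5) {
  set.seed(seed)
  d <- tidyr::expand_grid(
    patient_id = sprintf("P%02d", seq_len(2 * n_per_arm)),
    visit = factor(c("baseline", "week24", "week52"),
                   levels = c("baseline", "week24", "week52"))
  )
  d$arm <- factor(rep(c("placebo", "felzartamab"), each = 3 * n_per_arm),
                  levels = c("placebo", "felzartamab"))
  pat <- stats::rnorm(2 * n_per_arm, 0, patient_sd)
  d$y <- pat[as.integer(factor(d$patient_id))] + stats::rnorm(nrow(d))
  d
}

# brute-force Benjamini-Hochberg by the step-up definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric upper tail by enumerating all draws
hyper_brute <- function(k, K, N, n) {
  draws <- combn(N, n)
  in_set <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

# independent running-sum oracle for the weighted KS enrichment score
gsea_es_brute <- function(stat, set_genes, weight) {
  ord <- order(-stat, names(stat))
  s <- stat[ord]
  hit <- names(s) %in% set_genes
  w <- abs(s)^weight
  run <- 0
  best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / sum(!hit)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
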