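#' Filter genes by interquartile range
#'
#' Keeps the most variable genes by across-sample IQR (linear-interpolation
#' quantiles), ties broken by gene id; used to restrict genome-wide testing
#' to informative genes.
#'
#' @param expr Log2 genes x samples matrix.
#' @param keep Number of genes to keep (integer > 1) or a fraction in
#'   (0, 1\] of the gene space.
#' @return The filtered matrix, genes in original row order.
#' @export
iqr_filter <- function(expr, keep) {
  check_expression_matrix(expr)
  n <- nrow(expr)
  if (!is.numeric(keep) || length(keep) != 1 || keep <= 0) {
    stop_ddfx("keep must be a positive count or fraction", "ddfx_invalid_argument")
  }
  k <- if (keep < 1) max(1L, round(keep * n)) else as.integer(keep)
  if (k > n) stop_ddfx("keep exceeds the number of genes", "ddfx_invalid_argument")
  iqr <- apply(expr, 1, function(x) {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  })
  ord <- order(-iqr, rownames(expr))
  sel <- sort(ord[seq_len(k)])
  expr[sel, , drop = FALSE]
}

# vectorized two-sample Welch t-test across gene rows
welch_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  p[se2 == 0] <- 1  # no variance and no difference
  tibble::tibble(statistic = t, df = df, p = p)
}

#' Flag genes imbalanced between arms at baseline
#'
#' Per-gene Welch two-sample t-test comparing baseline expression between
#' arms; genes with p < `alpha` are flagged. Flags annotate interpretation
#' (flagged genes are excluded from reported gene lists) but never remove
#' genes from model fitting.
#'
#' @param expr Log2 genes x samples matrix.
#' @param meta Sample metadata.
#' @param alpha Flagging threshold (default 0.05).
#' @return Tibble: gene_id, baseline_p, baseline_imbalance (logical).
#' @export
baseline_imbalance_flags <- function(expr, meta, alpha = 0.05) {
  check_expression_matrix(expr)
  meta <- normalize_meta(check_sample_meta(meta, colnames(expr)))
  base <- meta[meta$visit == "baseline", ]
  ids <- split(base$sample_id, base$arm)
  if (any(lengths(ids) < 2)) {
    stop_ddfx("both arms need >= 2 baseline samples", "ddfx_invalid_argument")
  }
  res <- welch_rows(expr[, ids$felzartamab, drop = FALSE],
                    expr[, ids$placebo, drop = FALSE])
  tibble::tibble(gene_id = rownames(expr), baseline_p = res$p,
                 baseline_imbalance = res$p < alpha)
}

#' Per-gene linear model with cell-means coding and a %cortex covariate
#'
#' Ordinary least squares for every gene: the six arm-by-visit cell means
#' plus a slope for centered %cortex (cortical fraction of the biopsy, a
#' tissue-composition nuisance). Centering makes the cell-mean coefficients
#' interpretable at the average cortex fraction. Residual df = n - 7 on the
#' complete two-arm three-visit design.
#'
#' @param expr Log2 genes x samples matrix.
#' @param meta Sample metadata.
#' @return A `gene_fit`: coefficient matrix (genes x 7), residual
#'   variances `sigma2`, residual df `df`, the design matrix and
#'   `(X'X)^{-1}` needed for contrast variances.
#' @export
fit_gene_models <- function(expr, meta) {
  check_expression_matrix(expr)
  meta <- normalize_meta(check_sample_meta(meta, colnames(expr)))
  meta <- meta[match(colnames(expr), meta$sample_id), ]
  cell <- interaction(meta$arm, meta$visit, sep = ".", lex.order = TRUE)
  cortex_c <- meta$pct_cortex - mean(meta$pct_cortex)
  X <- model.matrix(~ 0 + cell)
  colnames(X) <- levels(cell)
  X <- cbind(X, cortex_c = cortex_c)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop_ddfx(paste0("design matrix is rank deficient; confounded column(s): ",
                     paste(bad, collapse = ", ")),
              "ddfx_invalid_argument")
  }
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  coefs <- t(qr.coef(qx, t(expr)))          # genes x 7
  fitted <- coefs %*% t(X)
  resid <- expr - fitted
  df <- ncol(expr) - qx$rank
  sigma2 <- rowSums(resid^2) / df
  structure(
    list(coefficients = coefs, sigma2 = sigma2, df = df,
         design = X, xtx_inv = xtx_inv, cells = levels(cell),
         gene_ids = rownames(expr)),
    class = "gene_fit"
  )
}

#' @export
print.gene_fit <- function(x, ...) {
  cat(sprintf("<gene_fit> %d genes, %d parameters, residual df = %d\n",
              length(x$gene_ids), ncol(x$coefficients), x$df))
  invisible(x)
}

dd_contrast_vector <- function(fit, window = c("b_w24", "w24_w52", "b_w52"),
                               scale = TRUE) {
  window <- match.arg(window)
  wins <- list(b_w24 = c("baseline", "week24"),
               w24_w52 = c("week24", "week52"),
               b_w52 = c("baseline", "week52"))
  v <- wins[[window]]
  cvec <- setNames(numeric(ncol(fit$coefficients)), colnames(fit$coefficients))
  cvec[paste("felzartamab", v[2], sep = ".")] <- 1
  cvec[paste("felzartamab", v[1], sep = ".")] <- -1
  cvec[paste("placebo", v[2], sep = ".")] <- -1
  cvec[paste("placebo", v[1], sep = ".")] <- 1
  if (scale) cvec / 2 else cvec
}

#' Difference-in-differences (delta-delta) log fold-change contrast
#'
#' The interactive treatment effect for a time window: the change in the
#' active arm minus the change in the placebo arm, halved — e.g. for the
#' baseline-to-week-24 window, (Felz_w24 - Felz_baseline)/2 -
#' (Placebo_w24 - Placebo_baseline)/2. Positive values mean a larger
#' increase under active treatment. `scale = FALSE` returns the plain
#' (unhalved) difference in differences.
#'
#' @param fit A [fit_gene_models()] result.
#' @param window `"b_w24"`, `"w24_w52"` or `"b_w52"`.
#' @param scale Apply the conventional /2 scaling (default TRUE).
#' @return Named numeric vector of per-gene log2 delta-delta fold changes.
#' @export
delta_delta_contrasts <- function(fit, window = c("b_w24", "w24_w52", "b_w52"),
                                  scale = TRUE) {
  stopifnot(inherits(fit, "gene_fit"))
  cvec <- dd_contrast_vector(fit, window, scale = scale)
  drop(fit$coefficients %*% cvec)
}

#' Empirical-Bayes variance prior
#'
#' Moment-matching estimate of the prior degrees of freedom d0 and prior
#' variance s0^2 of the scaled-inverse-chi-square distribution assumed for
#' per-gene residual variances (trigamma inversion on log s^2, as in the
#' moderated-t literature). d0 = Inf when the spread of log s^2 does not
#' exceed its sampling component.
#'
#' @param fit A [fit_gene_models()] result.
#' @return List with `d0` and `s0_2`.
#' @export
estimate_ebayes_hyper <- function(fit) {
  stopifnot(inherits(fit, "gene_fit"))
  s2 <- fit$sigma2
  if (sum(s2 > 0) < 10) {
    stop_ddfx("need >= 10 genes with positive residual variance",
              "ddfx_degenerate_input")
  }
  fd <- limma::fitFDist(s2, df1 = fit$df)
  list(d0 = fd$df2, s0_2 = fd$scale)
}

#' Moderated t-tests for a delta-delta contrast
#'
#' Posterior residual variance s~^2 = (d0 s0^2 + d s^2) / (d0 + d);
#' moderated t = ddlogFC / (s~ sqrt(v)) with v the contrast's unscaled
#' variance c'(X'X)^{-1}c; two-sided p on d0 + d df; BH-FDR; genes ranked
#' by ascending uncorrected p (ties by gene id), the reporting basis for
#' top-gene lists.
#'
#' @param fit A [fit_gene_models()] result.
#' @param hyper Prior from [estimate_ebayes_hyper()] (list d0, s0_2).
#' @param window Contrast window, see [delta_delta_contrasts()].
#' @param flags Optional [baseline_imbalance_flags()] tibble.
#' @param scale Apply the /2 contrast scaling (default TRUE).
#' @return A `contrast_table` tibble: gene_id, ddlogfc, t, df_total, p,
#'   fdr, rank, baseline_imbalance.
#' @export
moderated_tests <- function(fit, hyper, window = c("b_w24", "w24_w52", "b_w52"),
                            flags = NULL, scale = TRUE) {
  stopifnot(inherits(fit, "gene_fit"))
  window <- match.arg(window)
  d0 <- hyper$d0; s0_2 <- hyper$s0_2
  if (is.null(d0) || is.null(s0_2) || d0 < 0 || s0_2 <= 0) {
    stop_ddfx("invalid empirical-Bayes prior", "ddfx_invalid_argument")
  }
  cvec <- dd_contrast_vector(fit, window, scale = scale)
  v <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  if (v <= 0) stop_ddfx("non-positive contrast variance", "ddfx_internal_error")
  dd <- unname(drop(fit$coefficients %*% cvec))
  d <- fit$df
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(fit$sigma2)) else {
    (d0 * s0_2 + d * fit$sigma2) / (d0 + d)
  }
  tstat <- unname(dd / sqrt(s2_post * v))
  df_total <- d0 + d
  p <- 2 * pt(-abs(tstat), df = df_total)
  out <- tibble::tibble(
    gene_id = fit$gene_ids, ddlogfc = dd, t = tstat,
    df_total = df_total, p = p, fdr = bh_fdr(p)
  )
  out$rank <- order(order(out$p, out$gene_id))  # 1 = smallest p
  if (!is.null(flags)) {
    out <- dplyr::left_join(out, flags[, c("gene_id", "baseline_imbalance")],
                            by = "gene_id")
  } else {
    out$baseline_imbalance <- FALSE
  }
  attr(out, "window") <- window
  attr(out, "scale") <- scale
  class(out) <- c("contrast_table", class(out))
  out
}

#' Top-ranked genes from a contrast table
#'
#' @param table A [moderated_tests()] result.
#' @param k Number of genes to list.
#' @param direction `"both"`, `"up"` or `"down"` (sign of ddlogfc).
#' @param exclude_flagged Drop baseline-imbalanced genes (default TRUE).
#' @return Tibble of the top genes by ascending uncorrected p.
#' @export
rank_genes <- function(table, k = 20, direction = c("both", "up", "down"),
                       exclude_flagged = TRUE) {
  direction <- match.arg(direction)
  out <- table
  if (exclude_flagged) out <- out[!out$baseline_imbalance, , drop = FALSE]
  if (direction == "up") out <- out[out$ddlogfc > 0, , drop = FALSE]
  if (direction == "down") out <- out[out$ddlogfc < 0, , drop = FALSE]
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  head(tibble::as_tibble(out), k)
}

#' Gene-set-level delta-delta percent effect
#'
#' Averages the delta-delta log2 fold change over the member genes of a set
#' and expresses it as a percent change, (2^mean - 1) x 100.
#'
#' @param table A [moderated_tests()] result.
#' @param set A [geneset()] or character vector of gene ids.
#' @return List with `mean_ddlogfc` and `pct_effect`.
#' @export
set_ddfc_pct <- function(table, set) {
  genes <- if (inherits(set, "geneset")) set$genes else as.character(set)
  rows <- table[table$gene_id %in% genes, , drop = FALSE]
  if (nrow(rows) == 0) {
    stop_ddfx("no set gene present in the contrast table", "ddfx_invalid_argument")
  }
  m <- mean(rows$ddlogfc)
  list(mean_ddlogfc = m, pct_effect = (2^m - 1) * 100, n_genes = nrow(rows))
}

#' Volcano-style plot of a delta-delta contrast table
#'
#' @param table A [moderated_tests()] result.
#' @param label_top Number of top genes to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(table, label_top = 10) {
  top <- rank_genes(table, k = label_top)
  ggplot2::ggplot(table, ggplot2::aes(x = -log10(.data$p), y = .data$ddlogfc)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$baseline_imbalance),
                        alpha = 0.5, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "orange")) +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$gene_id),
                       size = 2.5, vjust = -0.5) +
    ggplot2::labs(x = "-log10 p", y = "delta-delta log2 FC",
                  title = paste("Treatment effect,", attr(table, "window"))) +
    ggplot2::theme_minimal()
}
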