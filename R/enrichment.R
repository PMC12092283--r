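#' Over-representation analysis (hypergeometric)
#'
#' One-sided hypergeometric upper-tail test of each library term against a
#' selected gene list (e.g. genes with delta-delta p < 0.05), with BH-FDR
#' across terms within the library. Library sets are intersected with the
#' universe before testing.
#'
#' @param selected Character vector of selected genes (subset of universe).
#' @param universe Character vector of all tested genes.
#' @param library A [geneset_library()].
#' @param direction Label recorded with the result (`"both"`, `"up"`,
#'   `"down"`); selection by sign is the caller's responsibility (see
#'   [enrich_contrast()]).
#' @return Tibble: term, library size columns (k, K, n, N), p, fdr,
#'   direction, overlap genes.
#' @export
ora_hypergeometric <- function(selected, universe, library, direction = "both") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    stop_ddfx("empty universe", "ddfx_invalid_argument")
  }
  selected <- unique(as.character(selected))
  if (!all(selected %in% universe)) {
    stop_ddfx("selected genes must be a subset of the universe",
              "ddfx_invalid_argument")
  }
  if (length(selected) == 0) {
    rlang::warn("empty selection; returning zero enrichment rows")
    return(tibble::tibble(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = numeric(),
                          fdr = numeric(), direction = character(),
                          genes = list()))
  }
  N <- length(universe); n <- length(selected)
  rows <- purrr::map(library$sets, function(s) {
    set_genes <- intersect(s$genes, universe)
    K <- length(set_genes)
    overlap <- intersect(selected, set_genes)
    k <- length(overlap)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term = s$name, k = k, K = K, n = n, N = N, p = p,
                   genes = list(sort(overlap)))
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p)
  out$direction <- direction
  out[, c("term", "k", "K", "n", "N", "p", "fdr", "direction", "genes")]
}

#' Enrichment of a delta-delta contrast table
#'
#' Convenience wrapper: selects genes at `p_cutoff` from a
#' [moderated_tests()] table (flagged genes excluded), partitions them by
#' delta-delta sign, and runs [ora_hypergeometric()] for up, down and both.
#'
#' @param table A contrast table.
#' @param library A [geneset_library()].
#' @param p_cutoff Selection threshold on uncorrected p (default 0.05).
#' @return Tibble of enrichment rows across the three directions.
#' @export
enrich_contrast <- function(table, library, p_cutoff = 0.05) {
  tab <- table[!table$baseline_imbalance, , drop = FALSE]
  universe <- tab$gene_id
  sel <- tab[tab$p < p_cutoff, , drop = FALSE]
  pick <- function(rows, dir) {
    if (nrow(rows) == 0) return(NULL)
    suppressWarnings(ora_hypergeometric(rows$gene_id, universe, library, dir))
  }
  dplyr::bind_rows(
    pick(sel, "both"),
    pick(sel[sel$ddlogfc > 0, ], "up"),
    pick(sel[sel$ddlogfc < 0, ], "down")
  )
}

# weighted KS running sum for one set on a ranked statistic
gsea_running_sum <- function(stat_sorted, in_set, weight) {
  w <- abs(stat_sorted)^weight
  w_hit <- sum(w[in_set])
  n_miss <- sum(!in_set)
  step <- numeric(length(stat_sorted))
  step[!in_set] <- -1 / n_miss
  step[in_set] <- if (w_hit > 0) w[in_set] / w_hit else 1 / sum(in_set)
  cumsum(step)
}

#' Rank-based gene-set enrichment (weighted Kolmogorov-Smirnov)
#'
#' Running-sum enrichment score on genes ranked by a signed statistic
#' (e.g. the moderated t): member genes add |stat|^weight (normalized),
#' non-members subtract 1/(N-K); the enrichment score (ES) is the running
#' sum's extremum. Significance uses a gene-permutation null: random sets
#' of the same size, NES = ES / mean(|null ES| of the same sign), p from
#' the same-sign permutation tail with +1 smoothing. Leading edge: member
#' genes at or before the extremum (after it for negative ES).
#'
#' @param stat Named numeric vector of finite per-gene signed statistics.
#' @param library A [geneset_library()].
#' @param n_perm Permutations (>= 99).
#' @param seed Integer seed.
#' @param weight Exponent on |stat| (0 = classical unweighted KS; default 1).
#' @param min_size Minimum set overlap with the ranking (default 5).
#' @return Tibble: term, size, es, nes, p, fdr, leading_edge (list).
#' @export
gsea_rank <- function(stat, library, n_perm = 1000, seed = 1, weight = 1,
                      min_size = 5) {
  if (any(!is.finite(stat))) {
    stop_ddfx("statistics must be finite", "ddfx_invalid_argument")
  }
  if (n_perm < 99) stop_ddfx("n_perm must be >= 99", "ddfx_config_error")
  ord <- order(-stat, names(stat))
  stat_sorted <- stat[ord]
  genes_sorted <- names(stat_sorted)
  N <- length(stat_sorted)

  set.seed(seed)
  rows <- purrr::map(library$sets, function(s) {
    members <- intersect(s$genes, genes_sorted)
    K <- length(members)
    if (K < min_size || K >= N) return(NULL)
    in_set <- genes_sorted %in% members
    rs <- gsea_running_sum(stat_sorted, in_set, weight)
    i_ext <- which.max(abs(rs))
    es <- unname(rs[i_ext])
    leading <- if (es >= 0) {
      genes_sorted[seq_len(i_ext)][in_set[seq_len(i_ext)]]
    } else {
      genes_sorted[i_ext:N][in_set[i_ext:N]]
    }
    null_es <- vapply(seq_len(n_perm), function(i) {
      perm_in <- logical(N)
      perm_in[sample.int(N, K)] <- TRUE
      rs_p <- gsea_running_sum(stat_sorted, perm_in, weight)
      rs_p[which.max(abs(rs_p))]
    }, numeric(1))
    same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
    tibble::tibble(term = s$name, size = K, es = es, nes = nes, p = p,
                   leading_edge = list(leading))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$fdr <- bh_fdr(out$p) else out$fdr <- numeric(0)
  out[, c("term", "size", "es", "nes", "p", "fdr", "leading_edge")]
}

#' Summarize enrichment results by gene representation
#'
#' Ranks genes by the number of enriched terms (FDR below `fdr_cutoff`)
#' whose overlap or leading edge contains them; ties broken by the gene's
#' best (smallest) term FDR, then lexicographically. This is the mechanical
#' "top genes by representation across all enrichment terms" ranking used
#' to label volcano plots.
#'
#' @param results Rows from [ora_hypergeometric()] / [enrich_contrast()] /
#'   [gsea_rank()] (needs term, fdr and a gene-list column `genes` or
#'   `leading_edge`).
#' @param top_gene_budget Number of genes to report.
#' @param fdr_cutoff Term enrichment threshold (default 0.05).
#' @return Tibble: gene_id, n_terms, best_fdr.
#' @export
summarize_enrichment <- function(results, top_gene_budget = 10,
                                 fdr_cutoff = 0.05) {
  if (nrow(results) == 0) {
    stop_ddfx("no enrichment results to summarize", "ddfx_invalid_argument")
  }
  gene_col <- if ("genes" %in% names(results)) "genes" else "leading_edge"
  hits <- results[results$fdr < fdr_cutoff, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(gene_id = character(), n_terms = integer(),
                          best_fdr = numeric()))
  }
  long <- tidyr::unnest(
    tibble::tibble(term = hits$term, fdr = hits$fdr, gene_id = hits[[gene_col]]),
    "gene_id")
  out <- long |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_terms = dplyr::n_distinct(.data$term),
                     best_fdr = min(.data$fdr), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_terms), .data$best_fdr, .data$gene_id)
  head(out, top_gene_budget)
}
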