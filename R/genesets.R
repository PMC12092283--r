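#' Gene sets and gene-set libraries
#'
#' A `geneset` is an ordered, duplicate-free gene list with a free-text
#' provenance string recording the derivation rule and parameters. A
#' `geneset_library` is a named collection of gene sets with an optional
#' gene universe.
#'
#' @param name Set name.
#' @param genes Character vector of gene ids (duplicates dropped, order kept).
#' @param provenance Free-text derivation record.
#' @return A `geneset`.
#' @export
geneset <- function(name, genes, provenance = "") {
  genes <- as.character(genes)
  genes <- genes[!duplicated(genes)]
  structure(list(name = name, genes = genes, provenance = provenance),
            class = "geneset")
}

#' @rdname geneset
#' @param sets List of `geneset` objects.
#' @param universe Optional character vector of all assayed genes.
#' @export
geneset_library <- function(sets, universe = NULL) {
  stopifnot(all(vapply(sets, inherits, logical(1), "geneset")))
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets))) {
    stop_ddfx("gene-set names must be unique", "ddfx_invalid_argument")
  }
  structure(list(sets = sets, universe = universe), class = "geneset_library")
}

#' @export
print.geneset <- function(x, ...) {
  cat(sprintf("<geneset> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
print.geneset_library <- function(x, ...) {
  cat(sprintf("<geneset_library> %d sets\n", length(x$sets)))
  for (s in x$sets) cat(sprintf("  %s (%d)\n", s$name, length(s$genes)))
  invisible(x)
}

#' @export
length.geneset_library <- function(x) length(x$sets)

#' Per-gene Spearman correlation against an archetype score
#'
#' Ranks every gene of a reference cohort by its Spearman correlation
#' (average-rank tie handling) with the chosen per-sample archetype score.
#'
#' @param ref A `ref_cohort` (see [generate_reference_cohort()]), or any
#'   list with `expr` and `eabmr_score` / `fabmr_score`.
#' @param which `"eabmr"` (early rejection) or `"fabmr"` (fully developed).
#' @return Tibble (gene_id, rho) sorted by descending rho, ties broken by
#'   gene id.
#' @export
spearman_vs_score <- function(ref, which = c("eabmr", "fabmr")) {
  which <- match.arg(which)
  expr <- ref$expr
  check_expression_matrix(expr)
  score <- if (which == "eabmr") ref$eabmr_score else ref$fabmr_score
  score <- as.numeric(score)
  if (ncol(expr) < 3) {
    stop_ddfx("need at least 3 samples for correlation", "ddfx_invalid_argument")
  }
  if (length(score) != ncol(expr) || any(!is.finite(score))) {
    stop_ddfx("score vector must be finite and match the samples",
              "ddfx_invalid_argument")
  }
  if (sd(score) == 0) {
    stop_ddfx("archetype score is constant", "ddfx_degenerate_input")
  }
  rho <- suppressWarnings(
    as.numeric(cor(t(expr), score, method = "spearman"))
  )
  rho[is.na(rho)] <- 0  # constant gene rows carry no rank information
  out <- tibble::tibble(gene_id = rownames(expr), rho = rho)
  dplyr::arrange(out, dplyr::desc(.data$rho), .data$gene_id)
}

top_pool <- function(ref, which, n_top = 100, rho_min = NULL) {
  tab <- spearman_vs_score(ref, which)
  pool <- head(tab, n_top)
  if (!is.null(rho_min)) pool <- pool[pool$rho > rho_min, , drop = FALSE]
  pool
}

profiles_for <- function(profiles, genes) {
  stopifnot(is.data.frame(profiles))
  missing <- setdiff(genes, profiles$gene_id)
  if (length(missing) > 0) {
    stop_ddfx(paste0("cell profiles missing gene(s): ",
                     paste(head(missing, 10), collapse = ", "),
                     if (length(missing) > 10) " ..."),
              "ddfx_invalid_argument")
  }
  profiles[match(genes, profiles$gene_id), , drop = FALSE]
}

#' Rejection-activity gene set (top 20 by early-rejection correlation)
#'
#' The 20 genes most correlated (Spearman) with the early-rejection
#' archetype score in the reference cohort.
#'
#' @param ref A `ref_cohort`.
#' @return A `geneset` of exactly 20 genes.
#' @export
derive_activity_set <- function(ref) {
  if (nrow(ref$expr) < 20) {
    stop_ddfx("need at least 20 genes", "ddfx_invalid_argument")
  }
  pool <- top_pool(ref, "eabmr", n_top = 20)
  geneset("abmr_activity", pool$gene_id,
          provenance = "top 20 genes by Spearman correlation with the early-rejection archetype score")
}

#' IFN-gamma-inducible rejection-activity gene set
#'
#' Candidates are the top 100 genes by Spearman correlation with the
#' early-rejection score, restricted to rho > 0.2; candidates are then
#' filtered on the cell profile panel. Default mode `"ifng_inducible"`
#' keeps genes whose IFN-gamma-stimulated endothelial (HUVEC) expression
#' exceeds both their NK-cell and unstimulated-HUVEC expression fivefold
#' (log2 differences >= log2 5, boundary inclusive). Mode `"huvec_over_nk"`
#' is the alternate reading of the rule: both HUVEC conditions fivefold
#' above NK cells.
#'
#' @param ref A `ref_cohort`.
#' @param profiles A `cell_profiles` tibble.
#' @param mode Filter interpretation, see Details.
#' @return A `geneset` (possibly empty, with a warning).
#' @export
derive_ifng_set <- function(ref, profiles,
                            mode = c("ifng_inducible", "huvec_over_nk")) {
  mode <- match.arg(mode)
  pool <- top_pool(ref, "eabmr", n_top = 100, rho_min = 0.2)
  if (nrow(pool) == 0) {
    rlang::warn("no gene passes the rho > 0.2 filter; returning an empty set")
    return(geneset("ifng_inducible", character(),
                   provenance = "empty: no candidate passed rho > 0.2"))
  }
  prof <- profiles_for(profiles, pool$gene_id)
  keep <- if (mode == "ifng_inducible") {
    prof$huvec_ifng - prof$nk >= log2(5) &
      prof$huvec_ifng - prof$huvec_unstim >= log2(5)
  } else {
    prof$huvec_unstim - prof$nk >= log2(5) &
      prof$huvec_ifng - prof$nk >= log2(5)
  }
  if (!any(keep)) rlang::warn("no candidate passed the fivefold cell filter")
  geneset("ifng_inducible", pool$gene_id[keep],
          provenance = sprintf(
            "top 100 by early-rejection Spearman, rho > 0.2, fivefold cell filter (mode=%s)",
            mode))
}

#' NK-cell-expressed rejection-activity gene set
#'
#' Candidates are the top 100 genes by Spearman correlation with the
#' early-rejection score. Genes with endothelial (HUVEC) expression above
#' the panel 50th percentile are removed — by default a gene is dropped if
#' EITHER the unstimulated or the IFN-gamma-stimulated HUVEC value exceeds
#' its panel median (`exclude = "either"`); `exclude = "both"` drops only
#' genes above both medians. The top 20 survivors by NK-cell expression are
#' retained.
#'
#' @param ref A `ref_cohort`.
#' @param profiles A `cell_profiles` tibble.
#' @param exclude Median-exclusion rule, see Details.
#' @return A `geneset` of at most 20 genes.
#' @export
derive_nk_set <- function(ref, profiles, exclude = c("either", "both")) {
  exclude <- match.arg(exclude)
  pool <- top_pool(ref, "eabmr", n_top = 100)
  prof <- profiles_for(profiles, pool$gene_id)
  # panel medians over the full gene universe, linear-interpolation quantile
  med_unstim <- quantile(profiles$huvec_unstim, 0.5, type = 7, names = FALSE)
  med_ifng <- quantile(profiles$huvec_ifng, 0.5, type = 7, names = FALSE)
  drop <- if (exclude == "either") {
    prof$huvec_unstim > med_unstim | prof$huvec_ifng > med_ifng
  } else {
    prof$huvec_unstim > med_unstim & prof$huvec_ifng > med_ifng
  }
  surv <- pool$gene_id[!drop]
  if (length(surv) == 0) {
    rlang::warn("all candidates exceed the HUVEC medians; returning an empty set")
    return(geneset("nk_expressed", character(),
                   provenance = "empty: all candidates HUVEC-expressed"))
  }
  nk_expr <- profiles_for(profiles, surv)$nk
  ord <- order(-nk_expr, surv)
  genes <- surv[ord][seq_len(min(20, length(surv)))]
  geneset("nk_expressed", genes,
          provenance = sprintf(
            "top 100 by early-rejection Spearman, HUVEC median exclusion (%s), top 20 by NK expression",
            exclude))
}

#' Rejection-associated endothelial gene set
#'
#' Candidates are the top 100 genes by Spearman correlation with the
#' fully-developed-rejection score; genes with fourfold greater expression
#' in unstimulated HUVECs than in NK cells (log2 difference >= log2 4,
#' boundary inclusive) are retained.
#'
#' @param ref A `ref_cohort`.
#' @param profiles A `cell_profiles` tibble.
#' @return A `geneset`.
#' @export
derive_endothelial_set <- function(ref, profiles) {
  pool <- top_pool(ref, "fabmr", n_top = 100)
  prof <- profiles_for(profiles, pool$gene_id)
  keep <- prof$huvec_unstim - prof$nk >= log2(4)
  if (!any(keep)) rlang::warn("no candidate passed the fourfold filter")
  geneset("endothelial", pool$gene_id[keep],
          provenance = "top 100 by fully-developed-rejection Spearman, fourfold unstimulated-HUVEC/NK filter")
}

#' Build the injury ontology from an AKI marker-gene table
#'
#' Retains only `New` (injury-induced) cell states; emits one gene set per
#' retained cell state plus a single collated union set
#' (`aki_injury_all`) for enrichment.
#'
#' @param markers Tibble with columns gene, cell_state, state_class.
#' @return A `geneset_library`.
#' @export
build_injury_ontology <- function(markers) {
  stopifnot(is.data.frame(markers))
  if (nrow(markers) == 0) {
    stop_ddfx("marker table is empty", "ddfx_invalid_argument")
  }
  new_rows <- markers[markers$state_class == "New", , drop = FALSE]
  if (nrow(new_rows) == 0) {
    rlang::warn("no 'New' cell states in the marker table; empty ontology")
    return(geneset_library(list()))
  }
  states <- sort(unique(new_rows$cell_state))
  sets <- lapply(states, function(st) {
    geneset(st, sort(unique(new_rows$gene[new_rows$cell_state == st])),
            provenance = "AKI marker genes of an injury-induced ('New') cell state")
  })
  union_set <- geneset("aki_injury_all", sort(unique(new_rows$gene)),
                       provenance = "collated markers of all 'New' cell states")
  geneset_library(c(sets, list(union_set)))
}
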