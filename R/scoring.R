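#' Per-biopsy gene-set score
#'
#' Pathogenesis-based-transcript-style score: the arithmetic mean, over the
#' member genes present in the matrix, of the per-gene log2 difference from
#' a control reference (equivalently the log of the geometric mean fold
#' change versus control). With `control = NULL` each gene is centered at
#' its cohort mean, so scores are relative to the cohort average biopsy.
#'
#' @param expr Log2 genes x samples matrix.
#' @param set A [geneset()].
#' @param control Optional named numeric vector of per-gene control mean
#'   log2 expression.
#' @return Named numeric vector, one score per sample.
#' @export
score_geneset <- function(expr, set, control = NULL) {
  check_expression_matrix(expr)
  stopifnot(inherits(set, "geneset"))
  present <- intersect(set$genes, rownames(expr))
  absent <- setdiff(set$genes, rownames(expr))
  if (length(present) == 0) {
    stop_ddfx(sprintf("no gene of set '%s' is present in the matrix", set$name),
              "ddfx_invalid_argument")
  }
  if (length(absent) > 0) {
    rlang::warn(sprintf("set '%s': %d gene(s) absent from the matrix: %s",
                        set$name, length(absent),
                        paste(head(absent, 5), collapse = ", ")))
  }
  sub <- expr[present, , drop = FALSE]
  ctrl <- if (is.null(control)) {
    rowMeans(sub)
  } else {
    miss <- setdiff(present, names(control))
    if (length(miss) > 0) {
      stop_ddfx("control reference missing genes present in the set",
                "ddfx_invalid_argument")
    }
    control[present]
  }
  colMeans(sub - ctrl)
}

#' Assemble the molecular score table
#'
#' Scores every set of a library on the expression matrix and joins the
#' sample metadata; one row per biopsy, one column per score, columns in
#' library order.
#'
#' @param expr Log2 genes x samples matrix.
#' @param library A [geneset_library()].
#' @param meta Sample metadata tibble (sample_id, patient_id, arm, visit,
#'   pct_cortex).
#' @param control Optional per-gene control means (see [score_geneset()]).
#' @return A tibble: metadata columns followed by one column per score.
#' @export
assemble_score_table <- function(expr, library, meta, control = NULL) {
  stopifnot(inherits(library, "geneset_library"))
  if (length(library$sets) == 0) {
    stop_ddfx("gene-set library is empty", "ddfx_invalid_argument")
  }
  check_sample_meta(meta, colnames(expr))
  meta <- normalize_meta(meta)
  scores <- purrr::map(library$sets, ~ score_geneset(expr, .x, control))
  out <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  for (nm in names(scores)) out[[nm]] <- unname(scores[[nm]])
  # canonical row order: by patient then visit
  dplyr::arrange(out, .data$patient_id, .data$visit)
}

#' Names of the score columns of a score table
#' @param scores A score table from [assemble_score_table()].
#' @return Character vector of score column names.
#' @export
score_columns <- function(scores) {
  setdiff(names(scores), c("sample_id", "patient_id", "arm", "visit",
                           "pct_cortex"))
}
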