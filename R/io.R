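#' Read a log2 expression matrix from TSV
#'
#' Expects genes as rows, the first column named `gene_id`, and one column
#' per sample.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix (genes x samples) with gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene_id") {
    stop_ddfx("expression TSV must have `gene_id` as its first column",
              "ddfx_io_error")
  }
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df$gene_id
  check_expression_matrix(expr)
}

#' Write a log2 expression matrix to TSV
#'
#' @param expr Numeric genes x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  check_expression_matrix(expr)
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Columns: sample_id, patient_id, arm, visit, pct_cortex.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with canonical arm/visit factor levels.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_sample_meta(meta)
  normalize_meta(meta)
}

#' Write sample metadata to TSV
#' @param meta Sample metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  check_sample_meta(meta)
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path Path to a .gmt file.
#' @return A `geneset_library`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop_ddfx("malformed GMT line (need name, description, >=1 gene)",
                "ddfx_io_error")
    }
    geneset(name = parts[1], genes = parts[-(1:2)], provenance = parts[2])
  })
  geneset_library(sets)
}

#' Write a gene-set library to GMT
#' @param library A `geneset_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "geneset_library"))
  lines <- vapply(library$sets, function(s) {
    desc <- if (nzchar(s$provenance)) gsub("[\t\n]", " ", s$provenance) else "na"
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an AKI marker-gene table
#'
#' Columns: gene, cell_state, state_class (`New` marks injury-induced
#' cell states; anything else is ignored by the injury ontology).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_marker_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene", "cell_state", "state_class")
  if (!all(needed %in% names(df))) {
    stop_ddfx("marker table needs columns gene, cell_state, state_class",
              "ddfx_io_error")
  }
  if (anyDuplicated(df[, c("gene", "cell_state")])) {
    stop_ddfx("duplicate (gene, cell_state) rows in marker table",
              "ddfx_io_error")
  }
  tibble::as_tibble(df)
}

#' Read / write planted ground truth as JSON
#' @param path JSON path.
#' @return A `trial_truth` object.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trial_truth(
    planted_sets = lapply(x$planted_sets, as.character),
    ddfc = lapply(x$ddfc, as.list),
    slopes = x$slopes,
    patient_sd = x$patient_sd,
    resid_sd = x$resid_sd,
    seed = x$seed
  )
}

#' @rdname read_truth_json
#' @param truth A `trial_truth` object.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "trial_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Report-only checks of matrix/metadata alignment, duplicate ids, missing
#' visits and GMT syntax. Never raises; returns a tibble of findings with
#' severity `"error"` or `"warning"` (zero rows when everything is clean).
#'
#' @param expr Expression matrix, or path to one.
#' @param meta Sample metadata tibble, or path.
#' @param gmt Optional GMT path.
#' @return A tibble with columns `severity`, `check`, `message`.
#' @export
validate_inputs <- function(expr, meta, gmt = NULL) {
  issues <- list()
  note <- function(severity, check, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, check = check, message = message)
  }
  expr <- tryCatch({
    if (is.character(expr)) read_expression_tsv(expr) else check_expression_matrix(expr)
  }, error = function(e) { note("error", "expression", conditionMessage(e)); NULL })
  meta <- tryCatch({
    if (is.character(meta)) read_sample_meta(meta) else normalize_meta(check_sample_meta(meta))
  }, error = function(e) { note("error", "metadata", conditionMessage(e)); NULL })
  if (!is.null(expr) && !is.null(meta)) {
    only_expr <- setdiff(colnames(expr), meta$sample_id)
    only_meta <- setdiff(meta$sample_id, colnames(expr))
    for (s in only_expr) note("error", "alignment",
                              paste0("sample ", s, " in expression but not metadata"))
    for (s in only_meta) note("error", "alignment",
                              paste0("sample ", s, " in metadata but not expression"))
  }
  if (!is.null(meta)) {
    visit_counts <- table(meta$patient_id)
    short <- names(visit_counts)[visit_counts != length(VISIT_LEVELS)]
    for (p in short) note("warning", "visits",
                          paste0("patient ", p, " has ", visit_counts[[p]],
                                 " visits (design expects ", length(VISIT_LEVELS), ")"))
    arms_per_patient <- tapply(as.character(meta$arm), meta$patient_id,
                               function(a) length(unique(a)))
    for (p in names(arms_per_patient)[arms_per_patient > 1]) {
      note("error", "arms", paste0("patient ", p, " appears in more than one arm"))
    }
    bad_cortex <- meta$sample_id[meta$pct_cortex < 0 | meta$pct_cortex > 100]
    for (s in bad_cortex) note("error", "pct_cortex",
                               paste0("sample ", s, " has pct_cortex outside [0,100]"))
  }
  if (!is.null(gmt)) {
    tryCatch(read_gmt(gmt),
             error = function(e) note("error", "gmt", conditionMessage(e)))
  }
  if (length(issues) == 0) {
    tibble::tibble(severity = character(), check = character(), message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
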