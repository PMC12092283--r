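#' Default pipeline configuration
#'
#' Returns the configuration list understood by [run_pipeline()]. With
#' `simulate` enabled the pipeline is self-contained: it generates a
#' reference cohort, cell profiles and a trial with planted effects, then
#' derives gene sets, scores biopsies, runs score-level inference, the
#' genome-wide delta-delta analysis and enrichment. Users with real data
#' disable `simulate` and point `paths` at their expression TSV, metadata
#' TSV, GMT library, cell-profile TSV and marker table.
#'
#' @param outdir Output directory.
#' @param seed Master integer seed.
#' @param stages Stages to run, in dependency order.
#' @return Config list.
#' @export
default_config <- function(outdir = tempfile("ddfx_run_"), seed = 1,
                           stages = c("simulate", "derive_sets", "score",
                                      "score_stats", "dge", "enrich")) {
  list(
    outdir = outdir,
    seed = seed,
    stages = stages,
    simulate = list(n_genes = 2000, n_per_arm = 10, ref_samples = 400),
    paths = list(expression = NULL, meta = NULL, gmt = NULL,
                 profiles = NULL, markers = NULL),
    score_stats = list(n_perm = 10000),
    dge = list(iqr_keep = 1000, scale = TRUE, baseline_alpha = 0.05),
    enrich = list(p_cutoff = 0.05, mode = "ora", n_perm = 1000)
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  cfg <- utils::modifyList(base, config)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  cfg
}

pipeline_order <- c("simulate", "derive_sets", "score", "score_stats",
                    "dge", "enrich")
stage_deps <- list(
  simulate = character(),
  derive_sets = character(),   # needs reference inputs (simulated or paths)
  score = "derive_sets",
  score_stats = "score",
  dge = character(),
  enrich = "dge"
)

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order, writing per-stage TSV /
#' GMT / JSON artifacts under `outdir` plus a manifest JSON with parameter
#' values, seeds, package version and md5 hashes of every output. Given
#' the same configuration the outputs are bit-identical. A failing stage
#' leaves earlier outputs in place and writes a `FAILED` marker naming the
#' stage before re-raising the error.
#'
#' @param config A config list (see [default_config()]) or path to a YAML
#'   file of the same shape.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- read_config(config)
  stages <- intersect(pipeline_order, cfg$stages)
  for (st in stages) {
    miss <- setdiff(stage_deps[[st]], stages)
    if (length(miss) > 0) {
      stop_ddfx(sprintf("stage '%s' requires disabled stage(s): %s",
                        st, paste(miss, collapse = ", ")),
                "ddfx_dependency_error")
    }
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  outputs <- character()
  emit <- function(name, path) outputs[[name]] <<- path

  run_stage <- function(st) {
    switch(st,
      simulate = stage_simulate(cfg, state, emit),
      derive_sets = stage_derive_sets(cfg, state, emit),
      score = stage_score(cfg, state, emit),
      score_stats = stage_score_stats(cfg, state, emit),
      dge = stage_dge(cfg, state, emit),
      enrich = stage_enrich(cfg, state, emit)
    )
  }

  for (st in stages) {
    tryCatch(run_stage(st), error = function(e) {
      writeLines(paste("stage", st, "failed:", conditionMessage(e)),
                 file.path(cfg$outdir, "FAILED"))
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", st,
                           conditionMessage(e)),
                   class = "ddfx_stage_error", parent = e)
    })
  }

  manifest <- list(
    package = "ddfx",
    version = as.character(utils::packageVersion("ddfx")),
    seed = cfg$seed,
    stages = as.list(stages),
    parameters = cfg[c("simulate", "score_stats", "dge", "enrich")],
    outputs = as.list(unname(outputs)),
    hashes = as.list(unname(tools::md5sum(unlist(outputs))))
  )
  names(manifest$hashes) <- basename(unlist(outputs))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}


# stage results carry REML-solver noise in the last few ulps; rounding to 10
# significant digits makes repeated runs byte-identical on disk
write_result_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 10)
  readr::write_tsv(df, path, progress = FALSE)
  path
}

stage_simulate <- function(cfg, state, emit) {
  sm <- cfg$simulate
  truth <- default_trial_truth(sm$n_genes)
  truth$seed <- cfg$seed
  state$truth <- truth
  state$ref <- generate_reference_cohort(sm$ref_samples, sm$n_genes,
                                         seed = cfg$seed, truth = truth)
  state$profiles <- generate_cell_profiles(truth, seed = cfg$seed + 1L)
  trial <- generate_trial(trial_design(sm$n_per_arm), truth, seed = cfg$seed + 2L)
  state$expression <- trial$expr
  state$meta <- trial$meta
  state$markers <- synth_marker_table(truth)
  ddir <- file.path(cfg$outdir, "data")
  dir.create(ddir, showWarnings = FALSE)
  emit("expression", write_expression_tsv(state$expression, file.path(ddir, "expression.tsv")))
  emit("meta", write_sample_meta(state$meta, file.path(ddir, "sample_meta.tsv")))
  readr::write_tsv(state$profiles, file.path(ddir, "cell_profiles.tsv"),
                   progress = FALSE)
  emit("profiles", file.path(ddir, "cell_profiles.tsv"))
  readr::write_tsv(state$markers, file.path(ddir, "aki_markers.tsv"),
                   progress = FALSE)
  emit("markers", file.path(ddir, "aki_markers.tsv"))
  emit("truth", write_truth_json(truth, file.path(ddir, "truth.json")))
}

require_input <- function(state, cfg, what, loader) {
  if (!is.null(state[[what]])) return(state[[what]])
  path <- cfg$paths[[what]]
  if (is.null(path)) {
    stop_ddfx(sprintf("input '%s' unavailable: enable the simulate stage or set paths$%s",
                      what, what), "ddfx_dependency_error")
  }
  state[[what]] <- loader(path)
  state[[what]]
}

stage_derive_sets <- function(cfg, state, emit) {
  if (is.null(state$ref)) {
    stop_ddfx("derive_sets needs a reference cohort (simulate stage)",
              "ddfx_dependency_error")
  }
  profiles <- require_input(state, cfg, "profiles",
                            function(p) readr::read_tsv(p, show_col_types = FALSE))
  markers <- require_input(state, cfg, "markers", read_marker_table)
  sets <- list(
    derive_activity_set(state$ref),
    derive_ifng_set(state$ref, profiles),
    derive_nk_set(state$ref, profiles),
    derive_endothelial_set(state$ref, profiles)
  )
  injury <- build_injury_ontology(markers)
  state$library <- geneset_library(c(sets, injury$sets))
  emit("genesets", write_gmt(state$library,
                             file.path(cfg$outdir, "derived_sets.gmt")))
}

stage_score <- function(cfg, state, emit) {
  expr <- require_input(state, cfg, "expression", read_expression_tsv)
  lib <- state$library
  meta <- require_input(state, cfg, "meta", read_sample_meta)
  state$scores <- suppressWarnings(assemble_score_table(expr, lib, meta))
  p <- file.path(cfg$outdir, "score_table.tsv")
  write_result_tsv(state$scores, p)
  emit("scores", p)
}

stage_score_stats <- function(cfg, state, emit) {
  scores <- state$scores
  cols <- score_columns(scores)
  art_rows <- purrr::map(cols, function(sc) {
    fit <- art_anova(scores, sc)
    eff <- tidy(fit)
    eff$score <- sc
    ctr <- interaction_contrasts(fit)
    ctr$score <- sc
    list(effects = eff, contrasts = ctr)
  })
  effects <- dplyr::bind_rows(purrr::map(art_rows, "effects"))
  # FDR across scores within each effect family
  effects <- effects |>
    dplyr::group_by(.data$effect) |>
    dplyr::mutate(fdr = bh_fdr(.data$p.value)) |>
    dplyr::ungroup()
  contrasts <- dplyr::bind_rows(purrr::map(art_rows, "contrasts"))
  slopes <- dplyr::bind_rows(purrr::map(cols, function(sc) {
    sf <- fit_mixed_slopes(scores, sc)
    out <- sf$slopes
    out$score <- sc
    out$interaction_p <- sf$interaction_p
    out$downgraded <- sf$downgraded
    out
  }))
  perm <- omnibus_permanova(scores[, cols, drop = FALSE],
                            interaction(scores$arm, scores$visit),
                            n_perm = cfg$score_stats$n_perm, seed = cfg$seed)
  state$score_stats <- list(effects = effects, contrasts = contrasts,
                            slopes = slopes, permanova = perm)
  p1 <- file.path(cfg$outdir, "art_effects.tsv")
  write_result_tsv(effects, p1); emit("art_effects", p1)
  p2 <- file.path(cfg$outdir, "art_contrasts.tsv")
  write_result_tsv(contrasts, p2); emit("art_contrasts", p2)
  p3 <- file.path(cfg$outdir, "score_slopes.tsv")
  write_result_tsv(slopes, p3); emit("slopes", p3)
  p4 <- file.path(cfg$outdir, "permanova.tsv")
  write_result_tsv(tidy(perm), p4); emit("permanova", p4)
}

stage_dge <- function(cfg, state, emit) {
  expr <- require_input(state, cfg, "expression", read_expression_tsv)
  meta <- require_input(state, cfg, "meta", read_sample_meta)
  filtered <- iqr_filter(expr, cfg$dge$iqr_keep)
  flags <- baseline_imbalance_flags(filtered, meta,
                                    alpha = cfg$dge$baseline_alpha)
  fit <- fit_gene_models(filtered, meta)
  hyper <- estimate_ebayes_hyper(fit)
  tabs <- purrr::map(c(b_w24 = "b_w24", w24_w52 = "w24_w52", b_w52 = "b_w52"),
                     function(w) moderated_tests(fit, hyper, w, flags = flags,
                                                 scale = cfg$dge$scale))
  state$dge <- list(fit = fit, hyper = hyper, flags = flags, tables = tabs)
  for (w in names(tabs)) {
    p <- file.path(cfg$outdir, sprintf("ddfc_%s.tsv", w))
    write_result_tsv(tabs[[w]], p)
    emit(paste0("ddfc_", w), p)
  }
}

stage_enrich <- function(cfg, state, emit) {
  if (is.null(state$dge)) {
    stop_ddfx("enrich requires the dge stage", "ddfx_dependency_error")
  }
  if (is.null(state$library)) {
    state$library <- require_input(state, cfg, "gmt", read_gmt)
  }
  res <- purrr::imap(state$dge$tables, function(tab, w) {
    er <- if (cfg$enrich$mode == "gsea") {
      stat <- setNames(tab$t, tab$gene_id)
      gsea_rank(stat, state$library, n_perm = cfg$enrich$n_perm,
                seed = cfg$seed)
    } else {
      enrich_contrast(tab, state$library, p_cutoff = cfg$enrich$p_cutoff)
    }
    if (nrow(er) > 0) er$window <- w
    er
  })
  out <- dplyr::bind_rows(res)
  gene_col <- if ("genes" %in% names(out)) "genes" else "leading_edge"
  flat <- out
  flat[[gene_col]] <- purrr::map_chr(out[[gene_col]] %||% list(),
                                     paste, collapse = ";")
  p <- file.path(cfg$outdir, "enrichment.tsv")
  write_result_tsv(flat, p)
  emit("enrichment", p)
  state$enrichment <- out
}
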