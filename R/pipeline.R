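# Orchestration: run the synthetic end-to-end demonstration with a single
# global seed fanned out into per-stage child seeds, writing stage outputs
# and a provenance log.

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds derive from it via
#'   [child_seed()].
#' @param stages subset of `c("imaging", "states", "landscape", "tracks",
#'   "survival")`.
#' @param out_dir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c("imaging", "states", "landscape",
                                       "tracks", "survival"),
                            out_dir = tempfile("routescape_run_")) {
  known <- c("imaging", "states", "landscape", "tracks", "survival")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(seed = as.integer(seed), stages = stages,
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_stage_csv <- function(x, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("routescape")),
                  error = function(e) "dev")
  writeLines(sprintf("# routescape %s | seed %d | %s", ver, seed,
                     basename(path)), con)
  utils::write.csv(x, con, row.names = FALSE)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the requested stages on synthetic data generated under the
#' configured seed and writes per-stage CSV outputs (each with a header
#' comment carrying version and seed) plus a run log. Deterministic:
#' rerunning with the same config reproduces the outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of per-stage summary results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("routescape run, global seed %d\n", config$seed),
      file = log_path)
  results <- list()

  if ("imaging" %in% config$stages) {
    sd <- child_seed(config$seed, "imaging")
    g <- gen_multiplex_image(image_scenario(seed = sd))
    img <- correct_channels(g$image)
    masks <- segment_base(img, k = 5, seed = sd + 1L)
    L <- label_compartments(masks, img, band_mask = g$truth$band_mask)
    sc <- compartment_scores(img, L)
    areas <- compartment_areas(L)
    write_stage_csv(as.data.frame(sc$scores),
                    file.path(config$out_dir, "imaging_scores.csv"), sd)
    write_stage_csv(data.frame(class = names(areas), fraction = areas),
                    file.path(config$out_dir, "imaging_areas.csv"), sd)
    logf("imaging: %d classes, %d px", length(L$schema), length(L$labels))
    results$imaging <- list(scores = sc, areas = areas, labeling = L,
                            truth = g$truth)
  }

  if ("states" %in% config$stages) {
    sd <- child_seed(config$seed, "states")
    g <- gen_state_counts(state_population_spec(seed = sd))
    qp <- g$qc_params
    fl <- qc_filter(g$counts, g$cell_meta, g$gene_meta, qp$min_genes,
                    qp$min_cells, qp$max_genes, qp$max_mito)
    expr <- normalize_counts(fl$counts)
    gm <- fl$gene_meta
    scores <- vapply(c("MES", "AC", "OPC", "NPC"), function(st)
      score_signature(expr, gm$gene[gm$class == st], seed = sd),
      numeric(ncol(expr)))
    emb <- neftel_embedding(scores)
    assoc <- state_route_association(emb$quadrant, fl$cell_meta$route)
    out <- data.frame(cell = fl$cell_meta$cell, emb,
                      route = fl$cell_meta$route)
    write_stage_csv(out, file.path(config$out_dir, "state_embedding.csv"),
                    sd)
    logf("states: %d cells kept, chi2=%.1f (df %d)",
         ncol(fl$counts), assoc$chi2, assoc$df)
    results$states <- list(embedding = emb, association = assoc,
                           qc_report = fl$report,
                           cell_meta = fl$cell_meta)
  }

  if ("landscape" %in% config$stages) {
    sd <- child_seed(config$seed, "landscape")
    g <- gen_regulatory_tables(landscape_spec(seed = sd))
    L <- merge_landscape(g$tables)
    hc <- cluster_modules(L)
    asg <- cut_metamodules(hc, k = length(unique(g$truth$assignment)))
    sigs <- metamodule_signatures(asg, L$gene_sets)
    anova_route <- regulator_anova(L, "route")
    write_stage_csv(anova_route,
                    file.path(config$out_dir, "landscape_anova_route.csv"),
                    sd)
    write_stage_csv(data.frame(module = names(asg), metamodule = asg),
                    file.path(config$out_dir, "landscape_metamodules.csv"),
                    sd)
    logf("landscape: %d modules into %d metamodules",
         length(asg), length(unique(asg)))
    results$landscape <- list(landscape = L, assignment = asg,
                              signatures = sigs, anova = anova_route,
                              truth = g$truth)
  }

  if ("tracks" %in% config$stages) {
    sd <- child_seed(config$seed, "tracks")
    g <- gen_tracks_movie(motion_spec(seed = sd))
    ts <- link_tracks(g$detections, dt = 0.25, pixel_size = 2)
    sp <- track_speeds(ts)
    va <- vessel_association(ts, g$vessel_mask)
    write_stage_csv(ts$tracks, file.path(config$out_dir, "tracks.csv"), sd)
    write_stage_csv(sp, file.path(config$out_dir, "track_speeds.csv"), sd)
    logf("tracks: %d tracks, %.2f vessel-associated",
         length(unique(ts$tracks$id)), va$proportion)
    results$tracks <- list(track_set = ts, speeds = sp, association = va,
                           truth = g$truth)
  }

  if ("survival" %in% config$stages) {
    sd <- child_seed(config$seed, "survival")
    g <- gen_survival_tma(survival_spec(seed = sd))
    kl <- km_logrank(g$survival)
    fr <- tma_fractions(g$nuclei, c(marker1 = g$threshold))
    d <- merge(fr, g$survival, by = "patient")
    cx <- cox_marker(d)
    write_stage_csv(fr, file.path(config$out_dir, "tma_fractions.csv"), sd)
    write_stage_csv(data.frame(stat = c("logrank_chi2", "logrank_df",
                                        "logrank_p", "cox_HR", "cox_lo",
                                        "cox_hi", "cox_p"),
                               value = c(kl$chi2, kl$df, kl$p, cx$HR,
                                         cx$ci[1], cx$ci[2], cx$p)),
                    file.path(config$out_dir, "survival_stats.csv"), sd)
    logf("survival: logrank chi2=%.2f, cox HR=%.3f", kl$chi2, cx$HR)
    results$survival <- list(logrank = kl, cox = cx, fractions = fr,
                             truth = g$truth)
  }

  invisible(results)
}
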