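#!/usr/bin/env Rscript
# Generate the five synthetic study scenarios under one global seed and
# write their observable inputs under results/sim/. Downstream scripts
# (02-06) regenerate the same scenarios from the seed, so this script's
# outputs are for inspection, not a dependency.

suppressMessages(library(routescape))
seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

img <- gen_multiplex_image(image_scenario(seed = child_seed(seed, "imaging")))
cat("imaging scenario:", dim(img$image$pixels)[1], "x",
    dim(img$image$pixels)[2], "px,",
    sum(img$truth$T), "tumor px,", sum(img$truth$V), "vessel px\n")
write.csv(data.frame(class = img$truth$schema,
                     planted_fraction = as.numeric(
                       tabulate(img$truth$labels,
                                length(img$truth$schema)) /
                         length(img$truth$labels)),
                     analytic_budget =
                       img$truth$area_budget[img$truth$schema]),
          file.path(out, "imaging_truth_areas.csv"), row.names = FALSE)

sc <- gen_state_counts(state_population_spec(seed = child_seed(seed,
                                                               "states")))
cat("state scenario:", nrow(sc$counts), "genes x", ncol(sc$counts),
    "cells;", sum(sc$cell_meta$qc_class != "ok"), "planted QC violators\n")
write.csv(sc$cell_meta, file.path(out, "states_cell_meta.csv"),
          row.names = FALSE)

land <- gen_regulatory_tables(landscape_spec(seed = child_seed(seed,
                                                               "landscape")))
cat("landscape scenario:", length(land$tables), "samples,",
    sum(vapply(land$tables, function(t) ncol(t$coefficients), 0)),
    "modules,", length(land$truth$drivers), "planted metamodules\n")

trk <- gen_tracks_movie(motion_spec(seed = child_seed(seed, "tracks")))
cat("tracking scenario:", length(trk$frames), "frames,",
    length(unique(trk$truth$tracks$id)), "cells,",
    round(100 * mean(trk$truth$vessel)), "% vessel-bound\n")
write.csv(trk$truth$tracks, file.path(out, "tracks_truth.csv"),
          row.names = FALSE)

surv <- gen_survival_tma(survival_spec(seed = child_seed(seed, "survival")))
cat("survival scenario:", nrow(surv$survival), "subjects,",
    nrow(surv$nuclei), "nuclei across cores\n")
write.csv(surv$survival, file.path(out, "survival_table.csv"),
          row.names = FALSE)
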