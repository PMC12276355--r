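# Synthetic per-sample regulator x gene-module coefficient tables with a
# planted metamodule block structure, overlapping module gene sets, and
# per-factor regulator selectivity effects.

#' Landscape specification
#'
#' @param n_samples number of samples (each contributes one table).
#' @param n_regulators regulators (rows) per table.
#' @param modules_per_sample gene modules (columns) per sample.
#' @param n_metamodules planted metamodule count (each spans >= 4 modules).
#' @param selectivity_effects named list of effect sizes (coefficient
#'   units) for `condition`, `patient` and `route` selective regulators.
#' @param driver_strength coefficient elevation of a metamodule's driver
#'   regulators in its member modules.
#' @param genes_per_module genes per module gene set (>= 10).
#' @param pool_size metamodule gene pool size modules draw from.
#' @param noise_sd coefficient noise.
#' @param seed integer seed.
#' @export
landscape_spec <- function(n_samples = 6L, n_regulators = 40L,
                           modules_per_sample = 20L, n_metamodules = 3L,
                           selectivity_effects = list(condition = 0,
                                                      patient = 0,
                                                      route = 2),
                           driver_strength = 3, genes_per_module = 30L,
                           pool_size = 60L, noise_sd = 0.5, seed = 1L) {
  total <- n_samples * modules_per_sample
  if (n_metamodules > total)
    stop("n_metamodules exceeds the total number of modules")
  if (4 * n_metamodules > total)
    stop("each planted metamodule must span at least 4 modules")
  if (4 * n_metamodules + 6 > n_regulators)
    stop("not enough regulators for drivers plus selective regulators")
  if (genes_per_module < 10)
    stop("module gene sets need at least 10 genes")
  structure(list(n_samples = as.integer(n_samples),
                 n_regulators = as.integer(n_regulators),
                 modules_per_sample = as.integer(modules_per_sample),
                 n_metamodules = as.integer(n_metamodules),
                 selectivity_effects = selectivity_effects,
                 driver_strength = driver_strength,
                 genes_per_module = as.integer(genes_per_module),
                 pool_size = as.integer(pool_size),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Generate per-sample regulatory tables with planted metamodules
#'
#' @param spec a [landscape_spec()].
#' @return list with `tables` (one `regulatory_table` per sample:
#'   `coefficients`, `gene_sets`, `annotations`) and `truth` (module to
#'   metamodule assignment, driver sets, selective regulators, gene
#'   pools).
#' @export
gen_regulatory_tables <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_samples; nm <- spec$modules_per_sample
    nr <- spec$n_regulators; k <- spec$n_metamodules
    regs <- sprintf("R%02d", seq_len(nr))
    routes <- rep(c("perivascular", "diffuse", "leptomeningeal"),
                  length.out = ns)
    samples <- data.frame(sample = sprintf("S%d", seq_len(ns)),
                          patient = sprintf("P%d", seq_len(ns)),
                          condition = rep(c("in vitro", "in vivo"),
                                          length.out = ns),
                          route = routes)

    drivers <- lapply(seq_len(k), function(m) regs[((m - 1) * 4 + 1):(m * 4)])
    nxt <- 4 * k
    sel_regs <- list(condition = regs[nxt + 1:2],
                     patient = regs[nxt + 3:4],
                     route = regs[nxt + 5:6])
    sel_level <- list(condition = "in vivo", patient = samples$patient[1],
                      route = "perivascular")

    total <- ns * nm
    repeat {
      mm <- sample.int(k, total, replace = TRUE)
      if (all(tabulate(mm, k) >= 4)) break
    }

    pools <- lapply(seq_len(k), function(m)
      sprintf("MM%d_g%03d", m, seq_len(spec$pool_size)))

    module_id <- as.vector(t(outer(samples$sample, sprintf("M%02d",
                                                           seq_len(nm)),
                                   paste, sep = "_")))
    ann <- data.frame(module = module_id,
                      sample = rep(samples$sample, each = nm),
                      patient = rep(samples$patient, each = nm),
                      condition = rep(samples$condition, each = nm),
                      route = rep(samples$route, each = nm),
                      metamodule = mm)

    tables <- lapply(seq_len(ns), function(s) {
      cols <- which(ann$sample == samples$sample[s])
      C <- matrix(stats::rnorm(nr * length(cols), 0, spec$noise_sd),
                  nr, length(cols), dimnames = list(regs, ann$module[cols]))
      for (j in seq_along(cols)) {
        m <- mm[cols[j]]
        C[drivers[[m]], j] <- C[drivers[[m]], j] + spec$driver_strength
      }
      for (f in names(sel_regs)) {
        eff <- spec$selectivity_effects[[f]] %||% 0
        if (eff != 0 && ann[[f]][cols[1]] == sel_level[[f]])
          C[sel_regs[[f]], ] <- C[sel_regs[[f]], ] + eff
      }
      gsets <- lapply(cols, function(j) {
        pool <- pools[[mm[j]]]
        sample(pool, min(spec$genes_per_module, length(pool)))
      })
      names(gsets) <- ann$module[cols]
      structure(list(coefficients = C, gene_sets = gsets,
                     annotations = ann[cols, , drop = FALSE]),
                class = "regulatory_table")
    })
    names(tables) <- samples$sample
    list(tables = tables,
         truth = list(assignment = stats::setNames(mm, module_id),
                      drivers = drivers, selective = sel_regs,
                      selective_level = sel_level, pools = pools,
                      samples = samples))
  })
}
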