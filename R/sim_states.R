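# Synthetic single-cell counts with planted 4-state structure, QC-failure
# cells, cycling cells and route-biased sample assignment. Counts are
# negative binomial around state-specific means; each planted QC violator
# breaks exactly one filter rule so removal counts can be checked against
# brute-force recounts.

#' State population specification
#'
#' @param n_cells_per_state named integer vector over MES, AC, OPC, NPC.
#' @param n_genes total gene count.
#' @param signature_size genes per state signature (disjoint sets).
#' @param mito_fraction_outliers proportion of cells planted as
#'   high-mitochondrial outliers (> 30% mito counts).
#' @param doublet_rate proportion of cells planted as doublets (sum of two
#'   cells' profiles, exceeding the kit-specific detected-gene ceiling).
#' @param low_quality_rate proportion of cells planted below the
#'   500-detected-genes floor.
#' @param cycling_fraction proportion of cells with boosted S or G2M
#'   programs.
#' @param rare_gene_count extra genes expressed in fewer than 10 cells
#'   (removed by the prevalence rule).
#' @param fold_change expression fold change of a state's signature genes
#'   in cells of that state.
#' @param route_bias probability that a MES/OPC cell is assigned to a
#'   perivascular-route sample (AC/NPC mirror to the diffuse route).
#' @param seed integer seed.
#' @export
state_population_spec <- function(n_cells_per_state = c(MES = 250, AC = 250,
                                                        OPC = 250, NPC = 250),
                                  n_genes = 2000L, signature_size = 50L,
                                  mito_fraction_outliers = 0.02,
                                  doublet_rate = 0.02,
                                  low_quality_rate = 0.02,
                                  cycling_fraction = 0.2,
                                  rare_gene_count = 10L,
                                  fold_change = 4,
                                  route_bias = 0.75,
                                  seed = 1L) {
  states <- c("MES", "AC", "OPC", "NPC")
  if (!all(states %in% names(n_cells_per_state)))
    stop("n_cells_per_state must name MES, AC, OPC, NPC")
  props <- c(mito_fraction_outliers, doublet_rate, low_quality_rate,
             cycling_fraction)
  if (any(props < 0 | props > 1)) stop("proportions must be in [0, 1]")
  if (signature_size * 4 > n_genes)
    stop("four disjoint signatures do not fit in n_genes")
  structure(list(n_cells_per_state = n_cells_per_state[states],
                 n_genes = as.integer(n_genes),
                 signature_size = as.integer(signature_size),
                 mito_fraction_outliers = mito_fraction_outliers,
                 doublet_rate = doublet_rate,
                 low_quality_rate = low_quality_rate,
                 cycling_fraction = cycling_fraction,
                 rare_gene_count = as.integer(rare_gene_count),
                 fold_change = fold_change, route_bias = route_bias,
                 seed = as.integer(seed)),
            class = "state_population_spec")
}

#' Generate synthetic single-cell counts with ground truth
#'
#' @param spec a [state_population_spec()].
#' @param count_noise draw negative-binomial counts (default); `FALSE`
#'   returns the noise-free expected means (real-valued), used for
#'   noise-free recovery checks.
#' @return list with `counts` (genes x cells), `cell_meta` (true state,
#'   sample, route, kit, qc_class, cycling), `gene_meta` (class and
#'   mito/ribo/hemoglobin flags) and `qc_params` (the filter thresholds the
#'   planted violators are calibrated against).
#' @export
gen_state_counts <- function(spec, count_noise = TRUE) {
  stopifnot(inherits(spec, "state_population_spec"))
  states <- c("MES", "AC", "OPC", "NPC")
  n_state <- spec$n_cells_per_state
  n_cells <- sum(n_state)
  ng <- spec$n_genes; s <- spec$signature_size

  gene_class <- rep("background", ng)
  idx <- 1L
  take <- function(n) { r <- idx:(idx + n - 1L); idx <<- idx + n; r }
  sig_idx <- lapply(states, function(st) take(s))
  names(sig_idx) <- states
  for (st in states) gene_class[sig_idx[[st]]] <- st
  n_cc <- min(40L, max(0L, (ng - idx + 1L) %/% 8L))
  s_idx <- take(n_cc); g2m_idx <- take(n_cc)
  gene_class[s_idx] <- "S"; gene_class[g2m_idx] <- "G2M"
  n_mito <- min(50L, max(0L, (ng - idx + 1L) %/% 6L))
  mito_idx <- take(n_mito); gene_class[mito_idx] <- "mito"
  n_ribo <- min(100L, max(0L, (ng - idx + 1L) %/% 4L))
  ribo_idx <- take(n_ribo); gene_class[ribo_idx] <- "ribo"
  n_hb <- min(5L, max(0L, ng - idx + 1L))
  hb_idx <- if (n_hb > 0) take(n_hb) else integer(0)
  gene_class[hb_idx] <- "hb"
  rare_idx <- if (spec$rare_gene_count > 0 && idx <= ng)
    take(min(spec$rare_gene_count, ng - idx + 1L)) else integer(0)
  gene_class[rare_idx] <- "rare"

  gene_names <- sprintf("g%04d", seq_len(ng))
  gene_names[mito_idx] <- sprintf("MT-%02d", seq_along(mito_idx))
  gene_names[ribo_idx] <- sprintf("RPL%03d", seq_along(ribo_idx))
  gene_names[hb_idx] <- sprintf("HBB%d", seq_along(hb_idx))
  gene_meta <- data.frame(gene = gene_names, class = gene_class,
                          mito = gene_class == "mito",
                          ribo = gene_class == "ribo",
                          hb = gene_class == "hb")

  qc_params <- list(min_genes = 500L, min_cells = 10L,
                    max_genes = c(v2 = 1250L, v3 = 1350L), max_mito = 0.30)

  if (n_cells == 0) {
    return(list(counts = matrix(0L, ng, 0,
                                dimnames = list(gene_names, NULL)),
                cell_meta = data.frame(cell = character(0),
                                       state = character(0),
                                       sample = character(0),
                                       route = character(0),
                                       kit = character(0),
                                       qc_class = character(0),
                                       cycling = character(0)),
                gene_meta = gene_meta, qc_params = qc_params))
  }

  with_seed(spec$seed, {
    # floor keeps every real gene comfortably above the 10-cell
    # prevalence rule, so only the planted rare genes trip it
    base_mu <- pmax(stats::rlnorm(ng, meanlog = -0.7, sdlog = 1.2), 0.06)
    base_mu[mito_idx] <- base_mu[mito_idx] * 3
    base_mu[ribo_idx] <- base_mu[ribo_idx] * 5
    base_mu[rare_idx] <- 0

    state <- rep(states, n_state)
    cell_f <- stats::rlnorm(n_cells, 0, 0.2)

    # route-biased sample assignment: 6 samples over three invasion routes
    samples <- data.frame(
      sample = paste0("S", 1:6),
      route = c("perivascular", "perivascular", "diffuse", "diffuse",
                "leptomeningeal", "leptomeningeal"),
      condition = rep(c("in vitro", "in vivo"), 3),
      kit = c("v2", "v3", "v2", "v3", "v2", "v3"))
    pb <- spec$route_bias
    rest <- (1 - pb)
    route_p <- rbind(MES = c(pb, rest * 0.6, rest * 0.4),
                     OPC = c(pb, rest * 0.6, rest * 0.4),
                     AC = c(rest * 0.6, pb, rest * 0.4),
                     NPC = c(rest * 0.6, pb, rest * 0.4))
    route <- vapply(state, function(st)
      sample(c("perivascular", "diffuse", "leptomeningeal"), 1,
             prob = route_p[st, ]), "")
    sample_id <- vapply(route, function(r) {
      cand <- samples$sample[samples$route == r]
      cand[sample.int(length(cand), 1)]
    }, "")
    kit <- samples$kit[match(sample_id, samples$sample)]

    cycling <- rep("none", n_cells)
    n_cyc <- round(spec$cycling_fraction * n_cells)
    if (n_cyc > 0) {
      cyc_cells <- sample.int(n_cells, n_cyc)
      cycling[cyc_cells] <- sample(c("S", "G2M"), n_cyc, replace = TRUE)
    }

    qc_class <- rep("ok", n_cells)
    pool <- seq_len(n_cells)
    pick <- function(rate) {
      n <- round(rate * n_cells)
      sel <- if (n > 0) sample(pool, min(n, length(pool))) else integer(0)
      pool <<- setdiff(pool, sel)
      sel
    }
    mito_cells <- pick(spec$mito_fraction_outliers)
    doublet_cells <- pick(spec$doublet_rate)
    low_cells <- pick(spec$low_quality_rate)
    qc_class[mito_cells] <- "mito"
    qc_class[doublet_cells] <- "doublet"
    qc_class[low_cells] <- "low_genes"

    mu <- matrix(base_mu, ng, n_cells)
    for (st in states) {
      cols <- which(state == st)
      mu[sig_idx[[st]], cols] <- mu[sig_idx[[st]], cols] * spec$fold_change
    }
    mu[s_idx, cycling == "S"] <- mu[s_idx, cycling == "S"] * 3
    mu[g2m_idx, cycling == "G2M"] <- mu[g2m_idx, cycling == "G2M"] * 3
    mu <- sweep(mu, 2, cell_f, `*`)

    # planted violators, each breaking exactly one rule
    mu[mito_idx, mito_cells] <- mu[mito_idx, mito_cells] * 25
    if (length(doublet_cells)) {
      ok_pool <- which(qc_class == "ok")
      partners <- ok_pool[sample.int(length(ok_pool),
                                     length(doublet_cells),
                                     replace = TRUE)]
      mu[, doublet_cells] <- 3 * (mu[, doublet_cells] + mu[, partners])
    }
    mu[, low_cells] <- mu[, low_cells] * 0.12

    if (count_noise) {
      counts <- matrix(stats::rnbinom(ng * n_cells, size = 2, mu = mu),
                       ng, n_cells)
    } else {
      counts <- mu
    }
    if (length(rare_idx)) {
      ok_cells <- which(qc_class == "ok")
      for (g in rare_idx) {
        k <- sample(3:9, 1)
        cells <- sample(ok_cells, min(k, length(ok_cells)))
        counts[g, cells] <- sample(1:3, length(cells), replace = TRUE)
      }
    }
    dimnames(counts) <- list(gene_names,
                             sprintf("c%05d", seq_len(n_cells)))
    cell_meta <- data.frame(cell = colnames(counts), state = state,
                            sample = sample_id, route = route,
                            condition = samples$condition[
                              match(sample_id, samples$sample)],
                            kit = kit, qc_class = qc_class,
                            cycling = cycling)
    list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
         qc_params = qc_params)
  })
}
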