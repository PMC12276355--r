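# Single-cell module: QC filtering, normalisation, signature scoring,
# cell-cycle regression, graph clustering, the 4-state quadrant embedding,
# state-route association and differential expression.

#' Quality-control filtering of a counts matrix
#'
#' Applies, in order: (1) removal of cells expressing fewer than
#' `min_genes` genes; (2) removal of genes expressed in fewer than
#' `min_cells` cells; (3) kit-specific doublet ceilings on the
#' detected-gene count (nFeature > ceiling for the cell's kit version);
#' (4) removal of cells with a mitochondrial count fraction above
#' `max_mito`; (5) removal of flagged ribosomal/mitochondrial/hemoglobin
#' genes. Each rule is applied to the matrix left by the previous one.
#'
#' @param counts genes x cells nonnegative matrix with dimnames.
#' @param cell_meta data.frame with a `kit` column (one row per cell).
#' @param gene_meta data.frame with logical `mito`, `ribo`, `hb` columns.
#' @param min_genes detected-genes floor per cell (default 500).
#' @param min_cells prevalence floor per gene (default 10 cells).
#' @param max_genes named ceiling per kit version, e.g.
#'   `c(v2 = 5100, v3 = 7200)`.
#' @param max_mito maximal mitochondrial count fraction (default 0.30).
#' @return list with `counts`, `cell_meta`, `gene_meta` (filtered) and a
#'   `report` of per-rule removal counts.
#' @export
qc_filter <- function(counts, cell_meta, gene_meta,
                      min_genes = 500L, min_cells = 10L,
                      max_genes = c(v2 = 5100L, v3 = 7200L),
                      max_mito = 0.30) {
  stopifnot(ncol(counts) == nrow(cell_meta), nrow(counts) == nrow(gene_meta))
  if (is.null(cell_meta$kit) || anyNA(cell_meta$kit))
    stop("kit version annotation is required for every cell")
  if (!all(cell_meta$kit %in% names(max_genes)))
    stop("unknown kit version: ",
         paste(setdiff(cell_meta$kit, names(max_genes)), collapse = ", "))

  # (1) gene floor
  det <- colSums(counts > 0)
  keep_c <- det >= min_genes
  n_floor <- sum(!keep_c)
  counts <- counts[, keep_c, drop = FALSE]
  cell_meta <- cell_meta[keep_c, , drop = FALSE]

  # (2) gene prevalence
  prev <- rowSums(counts > 0)
  keep_g <- prev >= min_cells
  n_prev <- sum(!keep_g)
  counts <- counts[keep_g, , drop = FALSE]
  gene_meta <- gene_meta[keep_g, , drop = FALSE]

  # (3) kit-specific doublet ceiling
  det <- colSums(counts > 0)
  ceil <- max_genes[cell_meta$kit]
  keep_c <- det <= ceil
  n_doublet <- sum(!keep_c)
  counts <- counts[, keep_c, drop = FALSE]
  cell_meta <- cell_meta[keep_c, , drop = FALSE]

  # (4) mitochondrial fraction
  tot <- colSums(counts)
  mito <- colSums(counts[gene_meta$mito, , drop = FALSE])
  frac <- ifelse(tot > 0, mito / tot, 0)
  keep_c <- frac <= max_mito
  n_mito <- sum(!keep_c)
  counts <- counts[, keep_c, drop = FALSE]
  cell_meta <- cell_meta[keep_c, , drop = FALSE]

  # (5) flagged gene families
  flag <- gene_meta$mito | gene_meta$ribo | gene_meta$hb
  n_flag <- sum(flag)
  counts <- counts[!flag, , drop = FALSE]
  gene_meta <- gene_meta[!flag, , drop = FALSE]

  list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta,
       report = c(cells_low_genes = n_floor, genes_low_prevalence = n_prev,
                  cells_doublet = n_doublet, cells_high_mito = n_mito,
                  genes_flagged = n_flag))
}

#' Library-size normalisation (counts per 10k, log1p)
#'
#' @param counts genes x cells matrix.
#' @param scale library-size target (default 1e4).
#' @return log-normalised matrix.
#' @export
normalize_counts <- function(counts, scale = 1e4) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log1p(sweep(counts, 2, lib, `/`) * scale)
}

#' Expression-bin-controlled signature score per cell
#'
#' Score of a gene set per cell: mean expression of the signature genes
#' minus the mean of a control set, where `nctrl` control genes are drawn
#' (with replacement if needed) for each signature gene from its
#' average-expression bin (`nbin` bins). Missing signature genes are
#' dropped with a warning. Deterministic given `seed`.
#'
#' @param expr normalised genes x cells matrix with rownames.
#' @param genes character vector of signature genes.
#' @param nbin number of average-expression bins (default 24).
#' @param nctrl control genes drawn per signature gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return numeric score per cell.
#' @export
score_signature <- function(expr, genes, nbin = 24L, nctrl = 100L,
                            seed = 1L) {
  present <- intersect(genes, rownames(expr))
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " signature genes absent from the matrix; dropped")
  if (!length(present)) stop("no signature genes present in the matrix")
  avg <- rowMeans(expr)
  nbin <- min(nbin, length(unique(avg)))
  bins <- if (nbin < 2) rep(1L, nrow(expr)) else
    cut(rank(avg, ties.method = "first"), breaks = nbin, labels = FALSE)
  names(bins) <- rownames(expr)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- names(bins)[bins == bins[g]]
      pool[sample.int(length(pool), nctrl, replace = TRUE)]
    }))
  })
  colMeans(expr[present, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
}

#' Regress the cell-cycle score difference out of every gene
#'
#' Computes S and G2M scores with [score_signature()] and removes from
#' every gene its linear dependence on (S - G2M). If the difference is
#' (numerically) constant the regression is skipped.
#'
#' @param expr normalised genes x cells matrix.
#' @param s_genes,g2m_genes phase signature gene sets.
#' @inheritParams score_signature
#' @return matrix of the same shape; attribute `"cc_difference"` holds the
#'   per-cell regressor.
#' @export
cc_regress <- function(expr, s_genes, g2m_genes, nbin = 24L, nctrl = 100L,
                       seed = 1L) {
  s <- score_signature(expr, s_genes, nbin, nctrl, seed)
  g2m <- score_signature(expr, g2m_genes, nbin, nctrl, seed + 1L)
  d <- s - g2m
  if (stats::sd(d) < 1e-12) {
    attr(expr, "cc_difference") <- d
    return(expr)
  }
  dc <- d - mean(d)
  beta <- as.numeric(expr %*% dc) / sum(dc^2)
  out <- expr - outer(beta, dc)
  attr(out, "cc_difference") <- d
  out
}

#' Graph-based clustering of cells (PCA, kNN graph, Louvain)
#'
#' @param expr normalised genes x cells matrix.
#' @param resolution Louvain resolution parameter.
#' @param n_pcs number of principal components (capped by data size).
#' @param k_nn neighbours per cell in the kNN graph.
#' @param seed RNG seed.
#' @return integer cluster label per cell.
#' @export
cluster_cells <- function(expr, resolution = 0.3, n_pcs = 20L, k_nn = 20L,
                          seed = 1L) {
  n <- ncol(expr)
  if (n == 1) return(1L)
  g <- cell_knn_graph(expr, n_pcs, k_nn)
  comm <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  as.integer(igraph::membership(comm))
}

#' kNN graph over cells in PCA space (internal to clustering, exposed for
#' resolution sweeps on a fixed graph)
#' @inheritParams cluster_cells
#' @export
cell_knn_graph <- function(expr, n_pcs = 20L, k_nn = 20L) {
  n <- ncol(expr)
  X <- t(expr)
  X <- scale(X, center = TRUE, scale = FALSE)
  n_pcs <- min(n_pcs, n - 1L, nrow(expr))
  pc <- stats::prcomp(X, rank. = n_pcs, center = FALSE)$x
  k <- min(k_nn, n - 1L)
  d2 <- as.matrix(stats::dist(pc))^2
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d2[i, ])[2:(k + 1L)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Four-state ("butterfly") embedding of per-cell state scores
#'
#' Given per-cell scores for the MES-, AC-, OPC- and NPC-like states, the
#' vertical coordinate is D = max(SC_OPC, SC_NPC) - max(SC_AC, SC_MES);
#' for D > 0 the horizontal coordinate separates NPC from OPC,
#' x = sign(SC_NPC - SC_OPC) * log2(|SC_NPC - SC_OPC| + 1), otherwise it
#' separates MES from AC, x = sign(SC_MES - SC_AC) *
#' log2(|SC_MES - SC_AC| + 1). Quadrants: upper-right NPC, upper-left OPC,
#' lower-right MES, lower-left AC. Exact ties resolve to the lower-left
#' and are flagged. Cells with missing scores are dropped with a warning.
#'
#' @param scores cells x 4 matrix/data.frame with columns MES, AC, OPC,
#'   NPC.
#' @return data.frame with scores, x, y, assigned `state` (argmax score),
#'   `quadrant` and a `tie` flag.
#' @export
neftel_embedding <- function(scores) {
  scores <- as.data.frame(scores)
  stopifnot(all(c("MES", "AC", "OPC", "NPC") %in% colnames(scores)))
  keep <- stats::complete.cases(scores[, c("MES", "AC", "OPC", "NPC")])
  if (any(!keep)) {
    warning(sum(!keep), " cells dropped for missing scores")
    scores <- scores[keep, , drop = FALSE]
  }
  D <- pmax(scores$OPC, scores$NPC) - pmax(scores$AC, scores$MES)
  up <- D > 0
  dx <- ifelse(up, scores$NPC - scores$OPC, scores$MES - scores$AC)
  x <- sign(dx) * log2(abs(dx) + 1)
  y <- D
  quadrant <- ifelse(y > 0, ifelse(x > 0, "NPC", "OPC"),
                     ifelse(x > 0, "MES", "AC"))
  tie <- (D == 0 & dx == 0) | (up & scores$NPC == scores$OPC) |
    (!up & scores$MES == scores$AC)
  sc <- as.matrix(scores[, c("MES", "AC", "OPC", "NPC")])
  state <- colnames(sc)[max.col(sc, ties.method = "first")]
  data.frame(scores, x = x, y = y, state = state, quadrant = quadrant,
             tie = tie)
}

#' Association between cell state and invasion route
#'
#' Pearson's chi-squared test of independence on the state x route
#' contingency table (no continuity correction), with the standardized
#' residuals used for mosaic-plot shading.
#'
#' @param states,routes factors/character vectors per cell.
#' @return list: `table`, `chi2`, `df`, `p`, `stdres`, `expected`.
#' @export
state_route_association <- function(states, routes) {
  tab <- table(states, routes)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("need at least 2 states and 2 routes")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, stdres = ct$stdres, expected = ct$expected)
}

#' Differential gene expression between two groups of cells
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalised expression,
#' log2 fold change of group mean normalised expression (pseudocount 1),
#' Benjamini-Hochberg adjustment, and MA coordinates (log2 total raw gene
#' count vs log2FC).
#'
#' @param counts genes x cells raw counts.
#' @param groups factor with two levels per cell; fold changes are level 1
#'   over level 2.
#' @return data.frame: gene, log2FC, p, padj, mean_count (log2 total);
#'   attribute `"groups"` records the level order.
#' @export
dge <- function(counts, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups")
  expr <- normalize_counts(counts)
  norm <- expm1(expr)
  a <- groups == levels(groups)[1]
  res <- t(vapply(seq_len(nrow(counts)), function(g) {
    x <- expr[g, a]; y <- expr[g, !a]
    p <- if (stats::sd(c(x, y)) == 0) 1 else
      suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    lfc <- log2((mean(norm[g, a]) + 1) / (mean(norm[g, !a]) + 1))
    c(lfc, p)
  }, numeric(2)))
  data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             log2FC = res[, 1], p = res[, 2], padj = bh_adjust(res[, 2]),
             mean_count = log2(rowSums(counts) + 1)) -> out
  attr(out, "groups") <- levels(groups)
  out
}

#' Shortlist route-associated regulators from a DGE table
#'
#' Intersects a regulator list with DGE rows passing adjusted p < `padj_max`
#' and |log2FC| > `lfc_min`; the direction labels which group the regulator
#' is elevated in.
#'
#' @param dge_table output of [dge()].
#' @param regulators character vector of regulator gene names.
#' @param padj_max,lfc_min selection thresholds (defaults 0.01 and 0.5).
#' @return data.frame subset of the DGE table with a `direction` column.
#' @export
select_route_regulators <- function(dge_table, regulators,
                                    padj_max = 0.01, lfc_min = 0.5) {
  groups <- attr(dge_table, "groups") %||% c("group1", "group2")
  sel <- dge_table$gene %in% regulators &
    !is.na(dge_table$padj) & dge_table$padj < padj_max &
    abs(dge_table$log2FC) > lfc_min
  out <- dge_table[sel, , drop = FALSE]
  out$direction <- ifelse(out$log2FC > 0, groups[1], groups[2])
  out
}
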