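# Regulatory-landscape meta-analysis: merging per-sample regulator x
# module tables, module clustering into metamodules, signature
# construction, Jaccard overlap with external signatures, and ANOVA-based
# regulator selectivity.

#' Merge per-sample regulatory tables into a common z-transformed landscape
#'
#' Takes the union of regulators over samples (absent entries 0),
#' concatenates module columns (prefixed by sample, so duplicated module
#' ids stay distinct), and z-transforms each regulator row to mean 0 and
#' population standard deviation 1 across all modules (constant rows are
#' left at 0).
#'
#' @param tables list of `regulatory_table` objects.
#' @return a `landscape` list: `coefficients` (regulators x modules,
#'   z-transformed), `annotations`, `gene_sets`.
#' @export
merge_landscape <- function(tables) {
  stopifnot(length(tables) >= 1)
  regs <- sort(unique(unlist(lapply(tables, function(t)
    rownames(t$coefficients)))))
  mats <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    C <- t$coefficients
    prefix <- t$annotations$sample[1] %||% paste0("S", i)
    cn <- colnames(C)
    if (!all(startsWith(cn, paste0(prefix, "_"))))
      cn <- paste(prefix, cn, sep = "_")
    M <- matrix(0, length(regs), ncol(C), dimnames = list(regs, cn))
    M[rownames(C), ] <- C
    M
  })
  coef <- do.call(cbind, mats)
  if (anyDuplicated(colnames(coef)))
    colnames(coef) <- make.unique(colnames(coef))
  mu <- rowMeans(coef)
  sd_pop <- sqrt(rowMeans((coef - mu)^2))
  z <- (coef - mu) / ifelse(sd_pop > 0, sd_pop, 1)
  z[sd_pop == 0, ] <- 0
  ann <- do.call(rbind, lapply(tables, function(t) t$annotations))
  rownames(ann) <- NULL
  ann$module_col <- colnames(coef)
  gsets <- do.call(c, lapply(tables, function(t) t$gene_sets))
  names(gsets) <- colnames(coef)
  structure(list(coefficients = z, annotations = ann, gene_sets = gsets),
            class = "landscape")
}

#' Hierarchical clustering of landscape modules
#'
#' Complete-linkage agglomeration of the module columns under Euclidean
#' distance (the hclust defaults); deterministic.
#'
#' @param merged a `landscape` from [merge_landscape()].
#' @return an `hclust` dendrogram over module columns.
#' @export
cluster_modules <- function(merged) {
  stopifnot(inherits(merged, "landscape"))
  stats::hclust(stats::dist(t(merged$coefficients)), method = "complete")
}

#' Cut the module dendrogram into metamodules
#'
#' @param dendrogram an `hclust` from [cluster_modules()].
#' @param height cut height (a data-specific choice, deliberately not
#'   hard-coded); exactly one of `height`/`k` must be given.
#' @param k alternatively, a target number of metamodules.
#' @return named integer module-to-metamodule assignment.
#' @export
cut_metamodules <- function(dendrogram, height = NULL, k = NULL) {
  if (is.null(height) == is.null(k))
    stop("give exactly one of height or k")
  if (!is.null(height)) stats::cutree(dendrogram, h = height)
  else stats::cutree(dendrogram, k = k)
}

#' Metamodule gene signatures by member-module support
#'
#' A gene enters a metamodule's signature iff it occurs in at least
#' `min_support` of the member modules' gene sets.
#'
#' @param assignment named module-to-metamodule assignment.
#' @param gene_sets named list of module gene sets.
#' @param min_support minimal number of member modules (default 4).
#' @return list of metamodules: `id`, `modules`, `signature`,
#'   `min_support`.
#' @export
metamodule_signatures <- function(assignment, gene_sets, min_support = 4L) {
  stopifnot(!is.null(names(assignment)))
  lapply(sort(unique(assignment)), function(m) {
    mods <- names(assignment)[assignment == m]
    counts <- table(unlist(lapply(gene_sets[mods], unique)))
    list(id = m, modules = mods,
         signature = sort(names(counts)[counts >= min_support]),
         min_support = min_support)
  })
}

#' Jaccard overlap between two families of gene sets
#'
#' J(A, B) = |A intersect B| / |A union B| for every pair.
#'
#' @param sets_a,sets_b named lists of character gene sets.
#' @return matrix |sets_a| x |sets_b| of Jaccard indices.
#' @export
jaccard_overlap <- function(sets_a, sets_b) {
  out <- matrix(0, length(sets_a), length(sets_b),
                dimnames = list(names(sets_a), names(sets_b)))
  for (i in seq_along(sets_a)) for (j in seq_along(sets_b)) {
    a <- unique(sets_a[[i]]); b <- unique(sets_b[[j]])
    u <- length(union(a, b))
    out[i, j] <- if (u == 0) 0 else length(intersect(a, b)) / u
  }
  out
}

#' Fit invasion-route gene signatures from expression data
#'
#' One-vs-rest differential expression per route; a route's signature is
#' the top `n_genes` genes by log2 fold change among those with adjusted
#' p below `padj_max` and positive fold change. Routes represented by
#' fewer than 2 samples are omitted with a warning.
#'
#' @param counts genes x cells raw counts.
#' @param routes route label per cell.
#' @param samples optional sample id per cell (for the 2-sample check).
#' @param n_genes signature size (default 50).
#' @param padj_max significance threshold (default 0.01).
#' @return named list of gene sets, one per (retained) route.
#' @export
fit_route_signatures <- function(counts, routes, samples = NULL,
                                 n_genes = 50L, padj_max = 0.01) {
  routes <- as.character(routes)
  out <- list()
  for (r in unique(routes)) {
    if (!is.null(samples) && length(unique(samples[routes == r])) < 2) {
      warning("route ", r, " has fewer than 2 samples; signature omitted")
      next
    }
    grp <- factor(ifelse(routes == r, r, "rest"), levels = c(r, "rest"))
    tab <- dge(counts, grp)
    tab <- tab[!is.na(tab$padj) & tab$padj < padj_max & tab$log2FC > 0, ,
               drop = FALSE]
    tab <- tab[order(-tab$log2FC), , drop = FALSE]
    out[[r]] <- utils::head(tab$gene, n_genes)
  }
  out
}

#' Regulator selectivity by one-way ANOVA
#'
#' For each regulator, a classical one-way ANOVA of its per-module
#' (z-transformed) coefficients across the levels of a module annotation
#' factor (growth condition, patient, or invasion route). Two-sided,
#' unadjusted. Regulators with no between- or within-variance are
#' reported as missing.
#'
#' @param merged a `landscape`.
#' @param factor_name one of the annotation columns, e.g. `"route"`.
#' @return data.frame: regulator, F, p, ordered as in the landscape.
#' @export
regulator_anova <- function(merged, factor_name) {
  stopifnot(inherits(merged, "landscape"))
  f <- merged$annotations[[factor_name]]
  if (is.null(f)) stop("unknown annotation factor: ", factor_name)
  f <- factor(f)
  if (nlevels(f) < 2) stop("factor needs at least 2 levels")
  X <- merged$coefficients
  n <- ncol(X); k <- nlevels(f)
  idx <- split(seq_len(n), f)
  nj <- lengths(idx)
  gm <- rowMeans(X)
  means <- vapply(idx, function(j) rowMeans(X[, j, drop = FALSE]),
                  numeric(nrow(X)))
  ssb <- as.numeric((means - gm)^2 %*% nj)
  sst <- rowSums((X - gm)^2)
  ssw <- sst - ssb
  Fs <- (ssb / (k - 1)) / (ssw / (n - k))
  Fs[sst < 1e-24] <- NA
  p <- stats::pf(Fs, k - 1, n - k, lower.tail = FALSE)
  data.frame(regulator = rownames(X), F = Fs, p = p)
}
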