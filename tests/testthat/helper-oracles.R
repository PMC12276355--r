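# Independent oracles used across the suite: slow, literal
# implementations kept deliberately separate from the package internals.

# per-pixel brute-force compartment score
oracle_scores <- function(pixels, dapi_idx, labels, n_classes, eps,
                          channels) {
  out <- matrix(NA_real_, length(channels), n_classes)
  counts <- integer(n_classes)
  for (j in seq_len(n_classes)) {
    counts[j] <- sum(labels == j)
  }
  for (ci in seq_along(channels)) {
    for (j in seq_len(n_classes)) {
      if (counts[j] == 0) next
      acc <- 0
      for (y in seq_len(nrow(labels))) for (x in seq_len(ncol(labels))) {
        if (labels[y, x] == j) {
          acc <- acc + pixels[y, x, channels[ci]] /
            max(pixels[y, x, dapi_idx], eps)
        }
      }
      out[ci, j] <- acc / counts[j]
    }
  }
  list(scores = out, counts = counts)
}

# textbook Pearson chi-square with standardized residuals
oracle_chisq <- function(tab) {
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - E)^2 / E)
  rp <- rowSums(tab) / n
  cp <- colSums(tab) / n
  stdres <- (tab - E) / sqrt(E * outer(1 - rp, 1 - cp))
  list(chi2 = chi2, df = (nrow(tab) - 1) * (ncol(tab) - 1),
       stdres = stdres)
}

# two-group logrank chi-square from the aggregated risk-set table
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  times <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in times) {
    at <- time >= t
    n1 <- sum(at & group == 1); n2 <- sum(at & group == 2)
    nt <- n1 + n2
    d1 <- sum(time == t & event == 1 & group == 1)
    d2 <- sum(time == t & event == 1 & group == 2)
    d <- d1 + d2
    if (nt == 0 || d == 0) next
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / nt
    if (nt > 1) V <- V + d * (n1 / nt) * (1 - n1 / nt) * (nt - d) / (nt - 1)
  }
  (O1 - E1)^2 / V
}

# brute-force minimal assignment by permutation enumeration
oracle_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- Inf
  for (p in perms(seq_len(m))) {
    val <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    best <- min(best, val)
  }
  best
}

# sequential QC recount, literal loops
oracle_qc_report <- function(counts, kit, mito_flag, ribo_flag, hb_flag,
                             min_genes, min_cells, max_genes, max_mito) {
  det <- apply(counts, 2, function(v) sum(v > 0))
  low <- det < min_genes
  counts <- counts[, !low, drop = FALSE]; kit <- kit[!low]
  prev <- apply(counts, 1, function(v) sum(v > 0))
  lowg <- prev < min_cells
  counts <- counts[!lowg, , drop = FALSE]
  mito_flag <- mito_flag[!lowg]; ribo_flag <- ribo_flag[!lowg]
  hb_flag <- hb_flag[!lowg]
  det <- apply(counts, 2, function(v) sum(v > 0))
  dbl <- det > max_genes[kit]
  counts <- counts[, !dbl, drop = FALSE]; kit <- kit[!dbl]
  frac <- apply(counts, 2, function(v) sum(v[mito_flag]) / max(sum(v), 1))
  hi <- frac > max_mito
  counts <- counts[, !hi, drop = FALSE]
  flag <- mito_flag | ribo_flag | hb_flag
  c(cells_low_genes = sum(low), genes_low_prevalence = sum(lowg),
    cells_doublet = sum(dbl), cells_high_mito = sum(hi),
    genes_flagged = sum(flag))
}

# minimal multiplex_image constructor for toy tests
toy_image <- function(pixels, roles = c(DAPI = 1L, AF = 2L, tumor = 3L,
                                        vessel = 4L)) {
  structure(list(pixels = pixels, channel_roles = roles, pixel_size = 1),
            class = "multiplex_image")
}

toy_labeling <- function(labels, schema) {
  structure(list(labels = labels, schema = schema,
                 masks = list(T = labels != length(schema),
                              V = matrix(FALSE, nrow(labels), ncol(labels))),
                 params = list()),
            class = "labeling_matrix")
}

f1_by_class <- function(est, truth, k) {
  vapply(seq_len(k), function(i) {
    tp <- sum(est == i & truth == i)
    fp <- sum(est == i & truth != i)
    fn <- sum(est != i & truth == i)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
}
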