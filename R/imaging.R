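# Spatial-proteomics computation on multiplex immunofluorescence scans:
# channel correction, tumor/vessel base segmentation, compartment labeling,
# cellularity-corrected protein scoring, compartment areas and group-wise
# differential protein tests.

channel_idx <- function(img, role) {
  i <- img$channel_roles[[role]]
  if (is.null(i)) stop("missing channel role: ", role)
  i
}

#' Remove shared variation between channels by ridge regression
#'
#' Each channel is replaced by its residual after an L2-regularised
#' regression (no intercept) on the other channels, with pixels as
#' observations. The penalty is 0 for the DAPI and AF channels and
#' `penalty` for the rest. Residuals are clipped at zero. With
#' `penalty = 0` this is the ordinary least-squares residual; as
#' `penalty` grows the channel converges back to its raw values.
#' All-constant (degenerate) channels are flagged and returned unchanged.
#'
#' The penalty acts on the per-pixel-normalised Gram matrix, so its scale
#' is intensity-squared units and independent of image size: a penalty
#' comparable to the mean squared channel intensity substantially shrinks
#' the correction.
#'
#' @param img a `multiplex_image`.
#' @param penalty nonnegative ridge penalty for non-DAPI/AF channels.
#' @return the corrected `multiplex_image`; attribute `"degenerate"` lists
#'   any channels left untouched.
#' @export
correct_channels <- function(img, penalty = 1e4) {
  stopifnot(inherits(img, "multiplex_image"), penalty >= 0)
  dm <- dim(img$pixels)
  if (dm[3] < 2) stop("need at least 2 channels")
  X <- matrix(img$pixels, prod(dm[1:2]), dm[3])
  free <- img$channel_roles[c("DAPI", "AF")]
  out <- X
  degenerate <- integer(0)
  n_px <- nrow(X)
  G <- crossprod(X) / n_px     # per-pixel channel Gram, pixels as observations
  for (i in seq_len(dm[3])) {
    if (stats::var(X[, i]) < 1e-12) {
      degenerate <- c(degenerate, i)
      next
    }
    lam <- if (i %in% free) 0 else penalty
    Zi <- setdiff(seq_len(dm[3]), i)
    A <- G[Zi, Zi] + diag(lam, length(Zi))
    beta <- tryCatch(solve(A, G[Zi, i]), error = function(e) NULL)
    if (is.null(beta)) {       # singular design: fall back to a tiny ridge
      beta <- solve(G[Zi, Zi] + diag(1e-8 * mean(diag(G)), length(Zi)),
                    G[Zi, i])
    }
    out[, i] <- pmax(X[, i] - X[, Zi, drop = FALSE] %*% beta, 0)
  }
  res <- img
  res$pixels <- array(out, dm)
  attr(res, "degenerate") <- degenerate
  res
}

#' Tumor and vessel masks by k-means on the four common channels
#'
#' Clusters the (DAPI, AF, tumor, vessel) pixel vectors with k-means
#' (k-means++-style multiple restarts) and identifies the vascular mask V
#' as the cluster whose centroid is maximal in the vessel channel and the
#' tumor mask T as the union of clusters whose centroid in the tumor
#' channel reaches at least half of the maximal tumor centroid. A channel
#' that is zero everywhere yields an empty mask rather than an error.
#'
#' @param img corrected `multiplex_image`.
#' @param k number of clusters (default 5).
#' @param seed RNG seed for the restarts.
#' @return list with logical masks `T` and `V`, the `centers` matrix and
#'   the integer `cluster` matrix.
#' @export
segment_base <- function(img, k = 5L, seed = 1L) {
  stopifnot(inherits(img, "multiplex_image"))
  if (k < 2) stop("k must be >= 2")
  dm <- dim(img$pixels)
  idx <- vapply(c("DAPI", "AF", "tumor", "vessel"),
                function(r) channel_idx(img, r), 1L)
  X <- matrix(img$pixels, prod(dm[1:2]), dm[3])[, idx]
  colnames(X) <- c("DAPI", "AF", "tumor", "vessel")
  km <- with_seed(seed, stats::kmeans(X, centers = k, nstart = 10,
                                      iter.max = 100))
  cen <- km$centers
  v_cl <- which.max(cen[, "vessel"])
  t_max <- max(cen[, "tumor"])
  t_cl <- setdiff(which(cen[, "tumor"] >= 0.5 * t_max), v_cl)
  v_empty <- max(cen[, "vessel"]) <= 1e-9
  t_empty <- t_max <= 1e-9
  if (!v_empty && !t_empty && which.max(cen[, "tumor"]) == v_cl)
    stop("tumor and vessel centroids coincide")
  cl <- matrix(km$cluster, dm[1], dm[2])
  Tm <- if (t_empty) matrix(FALSE, dm[1], dm[2]) else
    matrix(km$cluster %in% t_cl, dm[1], dm[2])
  Vm <- if (v_empty) matrix(FALSE, dm[1], dm[2]) else cl == v_cl
  list(T = Tm, V = Vm, centers = cen, cluster = cl)
}

# Per-component area, eccentricity and moment-based roundness.
component_stats <- function(comp) {
  ids <- sort(unique(comp[comp > 0]))
  if (!length(ids)) return(NULL)
  px <- which(comp > 0, arr.ind = TRUE)
  cid <- comp[comp > 0]
  o <- order(cid); px <- px[o, , drop = FALSE]; cid <- cid[o]
  res <- lapply(split(seq_along(cid), cid), function(ii) {
    y <- px[ii, 1]; x <- px[ii, 2]; n <- length(ii)
    my <- mean(y); mx <- mean(x)
    # second central moments (+1/12 grid correction keeps 1-px-wide shapes
    # from collapsing to zero variance)
    syy <- mean((y - my)^2) + 1 / 12
    sxx <- mean((x - mx)^2) + 1 / 12
    sxy <- mean((y - my) * (x - mx))
    tr <- syy + sxx; dt <- syy * sxx - sxy^2
    l1 <- tr / 2 + sqrt(max(tr^2 / 4 - dt, 0))
    l2 <- tr / 2 - sqrt(max(tr^2 / 4 - dt, 0))
    ecc <- if (l1 <= 0) 0 else sqrt(max(1 - l2 / l1, 0))
    roundness <- n / (pi * 4 * l1)   # = area / (pi * (major/2)^2)
    c(area = n, ecc = ecc, roundness = min(roundness, 1), cy = my, cx = mx)
  })
  stats <- do.call(rbind, res)
  rownames(stats) <- names(res)
  stats
}

#' Assign every pixel to a spatial compartment
#'
#' Combines the tumor/vessel masks into the compartment labeling: density
#' stratification of the tumor mask by a uniform box filter, perivascular
#' tumor within `d_pv` of the vessel mask, circle-shaped aggregates and
#' elongated diffuse cells by morphological component filters, an optional
#' corpus-callosum band (9-class schema; merged into the elongated class
#' when absent, giving the 8-class schema), and parenchyma elsewhere.
#' Precedence for overlapping claims: vessel > perivascular > aggregates >
#' high/medium density > elongated > low density > parenchyma (elongated
#' cells are by construction detected inside low-density tumor, which they
#' refine).
#'
#' @param masks list with logical masks `T` and `V` (from [segment_base()]).
#' @param img the `multiplex_image` (used for shape only).
#' @param params list of labeling parameters: `w` box-filter window (31),
#'   `density_thresholds` c(lo, hi) on the cell fraction (0.45, 0.80), or
#'   `density_quantiles` to derive them from the within-T density
#'   distribution, `d_pv` perivascular distance (10), `c_min` aggregate
#'   roundness (0.8), `agg_area` c(100, 2000), `e_min` eccentricity (0.9),
#'   `min_area_el` minimal elongated component area (20).
#' @param band_mask optional logical matrix marking the anatomical
#'   corpus-callosum band.
#' @return a `labeling_matrix`: integer `labels`, the `schema`, the input
#'   `masks`, and the resolved `params`.
#' @export
label_compartments <- function(masks, img, params = list(),
                               band_mask = NULL) {
  p <- utils::modifyList(list(
    w = 31L, density_thresholds = c(0.45, 0.80), density_quantiles = NULL,
    d_pv = 10, c_min = 0.8, agg_area = c(100, 2000), e_min = 0.9,
    min_area_el = 20
  ), params)
  Tm <- masks$T; Vm <- masks$V
  h <- nrow(Tm); w <- ncol(Tm)
  if (p$w > min(h, w)) stop("box filter window larger than image")
  schema <- compartment_schema(include_cc = !is.null(band_mask))
  lab <- matrix(match("parenchyma", schema), h, w)

  dens <- box_filter(Tm * 1, p$w)
  thr <- p$density_thresholds
  if (!is.null(p$density_quantiles) && any(Tm))
    thr <- stats::quantile(dens[Tm], p$density_quantiles, names = FALSE)
  lab[Tm & dens >= thr[2]] <- match("tumor_high", schema)
  lab[Tm & dens >= thr[1] & dens < thr[2]] <- match("tumor_med", schema)
  lab[Tm & dens < thr[1]] <- match("tumor_low", schema)

  if (any(Tm)) {
    comp <- EBImage::bwlabel(Tm * 1)
    comp <- matrix(as.integer(comp), h, w)
    st <- component_stats(comp)
    if (!is.null(st)) {
      mean_dens <- vapply(split(dens[comp > 0], comp[comp > 0]), mean, 0)
      mean_dens <- mean_dens[rownames(st)]
      elong_ids <- as.integer(rownames(st))[
        st[, "area"] >= p$min_area_el & st[, "ecc"] >= p$e_min &
          mean_dens < thr[1]]
      if (length(elong_ids))
        lab[comp %in% elong_ids] <- match("elongated", schema)
      if (!is.null(band_mask)) {
        in_band <- as.integer(rownames(st))[
          band_mask[cbind(pmin(pmax(round(st[, "cy"]), 1), h),
                          pmin(pmax(round(st[, "cx"]), 1), w))]]
        cc_ids <- intersect(elong_ids, in_band)
        if (length(cc_ids))
          lab[comp %in% cc_ids] <- match("cc_diffuse", schema)
      }
      agg_ids <- as.integer(rownames(st))[
        st[, "area"] >= p$agg_area[1] & st[, "area"] <= p$agg_area[2] &
          st[, "roundness"] >= p$c_min]
      if (length(agg_ids))
        lab[comp %in% agg_ids] <- match("aggregates", schema)
    }
  }
  if (any(Vm)) {
    dv <- dist_to(Vm)
    lab[Tm & dv <= p$d_pv] <- match("perivascular", schema)
    lab[Vm] <- match("vessel", schema)
  }
  structure(list(labels = lab, schema = schema, masks = masks, params = p),
            class = "labeling_matrix")
}

#' Cellularity-corrected mean protein intensity per compartment
#'
#' For protein i and compartment j the score is the mean over the pixels
#' S_j of class j of z_i(x, y) / z_DAPI(x, y), the per-pixel intensity
#' ratio against the DAPI channel. z_DAPI is floored at `eps` to guard
#' empty-DAPI pixels. Compartments with no pixels score NA.
#'
#' @param img a `multiplex_image`.
#' @param L a `labeling_matrix` congruent with `img`.
#' @param eps positive DAPI floor (default 1 intensity unit).
#' @param channels channels to score (default all).
#' @return a `score_matrix`: `scores` (proteins x classes), `pixel_counts`.
#' @export
compartment_scores <- function(img, L, eps = 1,
                               channels = seq_len(dim(img$pixels)[3])) {
  stopifnot(inherits(img, "multiplex_image"), inherits(L, "labeling_matrix"))
  if (eps <= 0) stop("eps must be > 0")
  dm <- dim(img$pixels)
  if (!all(dim(L$labels) == dm[1:2])) stop("labeling and image shapes differ")
  dapi <- pmax(img$pixels[, , channel_idx(img, "DAPI")], eps)
  lab <- factor(L$labels, levels = seq_along(L$schema), labels = L$schema)
  counts <- as.integer(table(lab))
  scores <- t(vapply(channels, function(i) {
    ratio <- img$pixels[, , i] / dapi
    m <- tapply(as.numeric(ratio), lab, mean)
    as.numeric(m)
  }, numeric(length(L$schema))))
  ch_names <- names(img$channel_roles)[match(channels, img$channel_roles)]
  ch_names[is.na(ch_names)] <- paste0("ch", channels[is.na(ch_names)])
  dimnames(scores) <- list(ch_names, L$schema)
  structure(list(scores = scores, pixel_counts = stats::setNames(
    counts, L$schema)), class = "score_matrix")
}

#' Relative area of each compartment
#'
#' @param L a `labeling_matrix`.
#' @return named vector of per-class pixel fractions summing to one.
#' @export
compartment_areas <- function(L) {
  stopifnot(inherits(L, "labeling_matrix"))
  tab <- tabulate(L$labels, nbins = length(L$schema))
  stats::setNames(tab / sum(tab), L$schema)
}

#' Differential protein expression between invasion-route groups
#'
#' Per (protein, compartment), a two-sided Welch (heteroscedastic) t-test
#' of the per-slide scores between the two route groups, with no
#' multiplicity adjustment. Mean difference is group level 1 minus level 2.
#'
#' @param scores list of `score_matrix` objects, one per slide.
#' @param groups factor (2 levels) of route labels, one per slide.
#' @return data.frame: protein, class, mean_diff, t, p, neg_log10_p.
#' @export
spatial_de <- function(scores, groups) {
  stopifnot(length(scores) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly 2 groups")
  if (any(table(groups) < 2))
    warning("a group has fewer than 2 slides; p-values will be missing")
  mats <- lapply(scores, function(s) s$scores)
  proteins <- rownames(mats[[1]]); classes <- colnames(mats[[1]])
  grid <- expand.grid(protein = proteins, class = classes,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(r) {
    v <- vapply(mats, function(m) m[grid$protein[r], grid$class[r]], 0)
    a <- v[groups == levels(groups)[1]]; b <- v[groups == levels(groups)[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0))
      return(c(mean(a) - mean(b), NA_real_, NA_real_))
    tt <- stats::t.test(a, b, var.equal = FALSE)
    c(mean(a) - mean(b), unname(tt$statistic), tt$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(grid, mean_diff = res[, 1], t = res[, 2], p = res[, 3],
             neg_log10_p = -log10(res[, 3]))
}

#' Per-compartment area change between knockout and control xenografts
#'
#' Mean difference of per-class relative areas across mouse replicates,
#' with a two-sided 90% t confidence interval (Welch degrees of freedom).
#'
#' @param areas_ko,areas_ctrl matrices replicates x classes of relative
#'   areas (same class columns).
#' @param conf confidence level (default 0.90).
#' @return data.frame: class, diff, lo, hi, p.
#' @export
score_ko_shift <- function(areas_ko, areas_ctrl, conf = 0.90) {
  areas_ko <- as.matrix(areas_ko); areas_ctrl <- as.matrix(areas_ctrl)
  if (nrow(areas_ko) < 2 || nrow(areas_ctrl) < 2)
    stop("need at least 2 replicates per arm for a confidence interval")
  classes <- colnames(areas_ko)
  res <- lapply(classes, function(cl) {
    a <- areas_ko[, cl]; b <- areas_ctrl[, cl]
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(data.frame(class = cl, diff = mean(a) - mean(b),
                        lo = mean(a) - mean(b), hi = mean(a) - mean(b),
                        p = NA_real_))
    tt <- stats::t.test(a, b, conf.level = conf, var.equal = FALSE)
    data.frame(class = cl, diff = mean(a) - mean(b),
               lo = tt$conf.int[1], hi = tt$conf.int[2], p = tt$p.value)
  })
  do.call(rbind, res)
}
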