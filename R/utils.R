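#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific child seed from a global seed
#'
#' Each pipeline stage receives its own reproducible stream so that rerunning
#' one stage does not perturb the others. Child seeds stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
child_seed <- function(seed, stage) {
  offsets <- c(
    imaging = 101L, states = 211L, landscape = 307L,
    tracks = 401L, survival = 503L, pipeline = 601L,
    analysis = 701L
  )
  off <- unname(offsets[stage])
  if (is.na(off)) off <- sum(utf8ToInt(stage)) %% 997L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483587)
}

#' Uniform box filter (mean over a w-by-w window)
#'
#' Local mean of a matrix over a square window, computed with integral
#' images. Windows are clipped at the image border and normalised by the
#' number of in-bounds pixels, so the result at the edge is the mean over
#' the visible part of the window.
#'
#' @param x numeric matrix.
#' @param w odd window side in pixels.
#' @return matrix of local means, same dimensions as `x`.
#' @export
box_filter <- function(x, w) {
  stopifnot(is.matrix(x), w >= 1, w %% 2 == 1)
  if (w > min(dim(x))) stop("box filter window larger than image")
  h <- nrow(x); wd <- ncol(x); r <- (w - 1L) / 2L
  # integral image with a leading zero row/col
  cs <- apply(x, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = h)
  cs <- apply(cs, 1L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = wd)
  S <- matrix(0, h + 1L, wd + 1L)
  S[-1L, -1L] <- t(cs)
  i1 <- pmax(seq_len(h) - r, 1L); i2 <- pmin(seq_len(h) + r, h)
  j1 <- pmax(seq_len(wd) - r, 1L); j2 <- pmin(seq_len(wd) + r, wd)
  # window sums via the four-corner rule, vectorised over the grid
  sums <- S[i2 + 1L, j2 + 1L, drop = FALSE] - S[i1, j2 + 1L, drop = FALSE] -
    S[i2 + 1L, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  cnt <- outer(i2 - i1 + 1L, j2 - j1 + 1L)
  sums / cnt
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a disc mask of given radius centred at (cy, cx) into a logical matrix
#' @noRd
stamp_disc <- function(mask, cy, cx, r) {
  h <- nrow(mask); w <- ncol(mask)
  y <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  x <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(y) || !length(x)) return(mask)
  d2 <- outer((y - cy)^2, (x - cx)^2, `+`)
  mask[y, x] <- mask[y, x] | (d2 <= r^2)
  mask
}

#' Draw a filled rotated ellipse into a logical matrix
#' @noRd
stamp_ellipse <- function(mask, cy, cx, a, b, theta) {
  h <- nrow(mask); w <- ncol(mask); r <- max(a, b)
  y <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  x <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(y) || !length(x)) return(mask)
  dy <- outer(y - cy, rep(1, length(x)))
  dx <- outer(rep(1, length(y)), x - cx)
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  mask[y, x] <- mask[y, x] | ((u / a)^2 + (v / b)^2 <= 1)
  mask
}

#' Benjamini-Hochberg adjusted p-values via stats::p.adjust
#' @noRd
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
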