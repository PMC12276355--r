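# Channel correction, base segmentation, compartment labeling, scoring
# and the group-wise protein tests.

small_scene <- function(seed = 2, noise = 0)
  gen_multiplex_image(image_scenario(height = 160, width = 160,
                                     bulk_radius = 45, vessel_count = 1,
                                     noise_sd = noise, seed = seed))

test_that("a duplicated channel is fully absorbed at penalty zero", {
  set.seed(1)
  px <- array(runif(40 * 40 * 8, 0, 50), c(40, 40, 8))
  px[, , 5] <- px[, , 3]
  img <- toy_image(px, c(DAPI = 1L, AF = 2L, tumor = 3L, vessel = 4L))
  out <- correct_channels(img, penalty = 0)
  expect_lt(max(abs(out$pixels[, , 5])), 1e-8)
})

test_that("a channel with disjoint support is returned unchanged", {
  px <- array(0, c(20, 20, 8))
  px[1:10, , -5] <- array(runif(10 * 20 * 7, 1, 30), c(10, 20, 7))
  px[11:20, , 5] <- matrix(runif(10 * 20, 1, 30), 10, 20)
  img <- toy_image(px)
  out <- correct_channels(img, penalty = 0)
  expect_equal(out$pixels[, , 5], px[, , 5], tolerance = 1e-10)
})

test_that("penalty zero equals the no-intercept OLS residual, clipped", {
  set.seed(3)
  px <- array(rexp(30 * 30 * 8, 1 / 20), c(30, 30, 8))
  img <- toy_image(px)
  out <- correct_channels(img, penalty = 0)
  X <- matrix(px, 900, 8)
  for (ch in c(5, 7)) {
    beta <- stats::coef(stats::lm.fit(X[, -ch], X[, ch]))
    ref <- pmax(X[, ch] - X[, -ch] %*% beta, 0)
    expect_equal(as.numeric(out$pixels[, , ch]), as.numeric(ref),
                 tolerance = 1e-8)
  }
})

test_that("a huge penalty converges to the raw channel", {
  set.seed(4)
  px <- array(rexp(20 * 20 * 8, 1 / 20), c(20, 20, 8))
  img <- toy_image(px)
  out <- correct_channels(img, penalty = 1e12)
  for (ch in setdiff(1:8, c(1, 2)))   # DAPI/AF stay OLS-corrected
    expect_equal(out$pixels[, , ch], px[, , ch], tolerance = 1e-4)
})

test_that("an all-constant channel is flagged and left untouched", {
  set.seed(5)
  px <- array(runif(20 * 20 * 8), c(20, 20, 8))
  px[, , 6] <- 7
  img <- toy_image(px)
  out <- correct_channels(img, penalty = 1)
  expect_equal(attr(out, "degenerate"), 6L)
  expect_equal(out$pixels[, , 6], px[, , 6])
})

test_that("corrected markers recover ground-truth signals (r >= 0.95)", {
  g <- small_scene(seed = 11, noise = 2)
  out <- correct_channels(g$image, penalty = 0)
  for (ch in 5:7) {
    r <- stats::cor(as.numeric(out$pixels[, , ch]),
                    as.numeric(g$truth$signals[, , ch]))
    expect_gte(r, 0.95)
  }
})

test_that("segment_base returns k centroids and recovers masks", {
  g <- small_scene(seed = 12)
  img <- correct_channels(g$image)
  m <- segment_base(img, k = 5, seed = 1)
  expect_equal(nrow(m$centers), 5)
  expect_gte(mean(m$T == g$truth$T), 0.99)
  expect_gte(mean(m$V == g$truth$V), 0.99)
  expect_error(segment_base(img, k = 1), "k must be")
})

test_that("an image with a silent vessel channel yields an empty V mask", {
  g <- small_scene(seed = 13)
  px <- g$image$pixels
  px[, , 4] <- 0
  img <- toy_image(px, g$image$channel_roles)
  m <- segment_base(img, k = 5, seed = 1)
  expect_false(any(m$V))
})

test_that("label_compartments recovers all planted classes (F1 >= 0.9)", {
  g <- gen_multiplex_image(image_scenario(height = 256, width = 256,
                                          bulk_radius = 60, seed = 14))
  img <- correct_channels(g$image)
  m <- segment_base(img, k = 5, seed = 1)
  L <- label_compartments(m, img, band_mask = g$truth$band_mask)
  expect_equal(length(L$schema), 9)
  f1 <- f1_by_class(L$labels, g$truth$labels, 9)
  expect_true(all(f1 >= 0.9, na.rm = TRUE))
  # without a band mask the schema collapses to 8 classes
  L8 <- label_compartments(m, img)
  expect_equal(length(L8$schema), 8)
  expect_false("cc_diffuse" %in% L8$schema)
})

test_that("an all-background image is labeled parenchyma everywhere", {
  masks <- list(T = matrix(FALSE, 64, 64), V = matrix(FALSE, 64, 64))
  img <- toy_image(array(1, c(64, 64, 8)))
  L <- label_compartments(masks, img)
  expect_true(all(L$labels == match("parenchyma", L$schema)))
  expect_error(label_compartments(masks, img, params = list(w = 101)),
               "window")
})

test_that("compartment scores equal the formula on toy input", {
  # constant protein and DAPI: score is exactly v / d
  px <- array(0, c(3, 3, 8))
  px[, , 1] <- 4; px[, , 5] <- 10
  img <- toy_image(px)
  lab <- matrix(c(1, 1, 2, 1, 1, 2, 2, 2, 2), 3, 3)
  L <- toy_labeling(lab, c("a", "b"))
  sc <- compartment_scores(img, L, eps = 1)
  expect_equal(unname(sc$scores[5, ]), c(10 / 4, 10 / 4))
  # integer toy image, one class of 4 pixels, hand-computed mean of ratios
  px[, , 1] <- matrix(c(2, 4, 8, 1, 2, 4, 8, 1, 2), 3, 3)
  px[, , 5] <- matrix(c(6, 8, 16, 3, 10, 2, 24, 5, 18), 3, 3)
  img <- toy_image(px)
  sc <- compartment_scores(img, L, eps = 1)
  hand <- mean(c(6 / 2, 8 / 4, 3 / 1, 10 / 2))   # the four class-1 pixels
  expect_equal(unname(sc$scores[5, 1]), hand, tolerance = 1e-12)
  expect_equal(unname(sc$pixel_counts), c(4L, 5L))
})

test_that("empty classes score NA with pixel count zero", {
  px <- array(1, c(2, 2, 8))
  L <- toy_labeling(matrix(1, 2, 2), c("a", "b"))
  sc <- compartment_scores(toy_image(px), L)
  expect_true(all(is.na(sc$scores[, "b"])))
  expect_equal(unname(sc$pixel_counts["b"]), 0L)
  expect_error(compartment_scores(toy_image(px), L, eps = 0), "eps")
})

test_that("compartment scores match the brute-force per-pixel loop", {
  set.seed(20)
  for (rep in 1:10) {
    h <- sample(4:12, 1); w <- sample(4:12, 1)
    px <- array(runif(h * w * 8, 0, 20), c(h, w, 8))
    k <- sample(2:4, 1)
    lab <- matrix(sample(seq_len(k), h * w, replace = TRUE), h, w)
    L <- toy_labeling(lab, letters[seq_len(k)])
    sc <- compartment_scores(toy_image(px), L, eps = 1)
    or <- oracle_scores(px, 1, lab, k, 1, 1:8)
    expect_equal(unname(sc$scores), or$scores, tolerance = 1e-12)
  }
})

test_that("compartment areas sum to one and honor single-class labelings", {
  L <- toy_labeling(matrix(2, 5, 5), c("a", "b"))
  a <- compartment_areas(L)
  expect_equal(unname(a), c(0, 1))
  set.seed(21)
  L2 <- toy_labeling(matrix(sample(1:3, 36, TRUE), 6, 6), c("a", "b", "c"))
  expect_equal(sum(compartment_areas(L2)), 1)
})

test_that("spatial_de computes Welch t-tests per protein and class", {
  mk_score <- function(vals) {
    m <- matrix(vals, 1, 1, dimnames = list("p1", "c1"))
    structure(list(scores = m, pixel_counts = c(c1 = 10L)),
              class = "score_matrix")
  }
  set.seed(22)
  a <- c(1, 1, 1) + rnorm(3, 0, 1e-6)
  b <- c(2, 2, 2) + rnorm(3, 0, 1e-6)
  res <- spatial_de(lapply(c(a, b), mk_score),
                    rep(c("perivascular", "diffuse"), each = 3))
  # difference is factor level 1 (diffuse) minus level 2 (perivascular)
  expect_equal(res$mean_diff, 1, tolerance = 1e-4)
  expect_lt(res$p, 1e-4)
  # hand-worked 3 vs 3 Welch statistic
  x <- c(1.1, 2.3, 3.0); y <- c(4.0, 5.5, 4.7)
  res2 <- spatial_de(lapply(c(x, y), mk_score), rep(c("g1", "g2"), each = 3))
  sx <- var(x) / 3; sy <- var(y) / 3
  t_hand <- (mean(y) - mean(x)) / sqrt(sx + sy)   # g1 = diffuse-first level
  expect_equal(abs(res2$t), abs(t_hand), tolerance = 1e-12)
  expect_warning(
    spatial_de(lapply(c(1, 2, 3), mk_score), c("g1", "g2", "g2")),
    "fewer than 2")
})

test_that("null spatial_de p-values are roughly uniform", {
  set.seed(23)
  mk <- function(vals) structure(
    list(scores = matrix(vals, 1, 1, dimnames = list("p", "c"))),
    class = "score_matrix")
  ps <- replicate(200, {
    v <- rnorm(8)
    spatial_de(lapply(v, mk), rep(c("a", "b"), each = 4))$p
  })
  expect_gt(mean(ps > 0.5), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("score_ko_shift intervals behave on identical and shifted input", {
  areas <- matrix(rep(c(0.2, 0.8), each = 4), 4, 2,
                  dimnames = list(NULL, c("a", "b")))
  res <- score_ko_shift(areas, areas)
  expect_equal(res$diff, c(0, 0))
  expect_true(all(res$lo <= 0 & res$hi >= 0))
  expect_error(score_ko_shift(areas[1, , drop = FALSE], areas),
               "replicates")
  set.seed(24)
  cover <- replicate(400, {
    ko <- matrix(rnorm(4, 0.5, 0.05), 4, 1, dimnames = list(NULL, "a"))
    ct <- matrix(rnorm(4, 0.3, 0.05), 4, 1, dimnames = list(NULL, "a"))
    r <- score_ko_shift(ko, ct)
    r$lo <= 0.2 && r$hi >= 0.2
  })
  expect_gte(mean(cover), 0.85)
})
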