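# Landscape merging, module clustering, metamodule signatures, Jaccard
# overlap, route signatures and ANOVA selectivity.

mk_table <- function(C, sample_id = "S1", gene_sets = NULL) {
  ann <- data.frame(module = colnames(C), sample = sample_id,
                    patient = paste0("P_", sample_id),
                    condition = "in vitro", route = "diffuse")
  structure(list(coefficients = C,
                 gene_sets = gene_sets %||%
                   stats::setNames(replicate(ncol(C),
                                             letters[1:10],
                                             simplify = FALSE),
                                   colnames(C)),
                 annotations = ann),
            class = "regulatory_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("row z-transform matches the hand-computed population z-score", {
  C <- matrix(c(1, 2, 3), 1, 3,
              dimnames = list("R1", c("S1_M1", "S1_M2", "S1_M3")))
  L <- merge_landscape(list(mk_table(C)))
  expect_equal(unname(L$coefficients[1, ]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
})

test_that("regulators absent from a sample merge in as zeros", {
  C1 <- matrix(1:4, 2, 2, dimnames = list(c("R1", "R2"),
                                          c("S1_M1", "S1_M2")))
  C2 <- matrix(5:8, 2, 2, dimnames = list(c("R1", "R3"),
                                          c("S2_M1", "S2_M2")))
  L <- merge_landscape(list(mk_table(C1, "S1"), mk_table(C2, "S2")))
  expect_equal(rownames(L$coefficients), c("R1", "R2", "R3"))
  # raw zeros for R3 in S1's columns surface as equal z-values
  z <- L$coefficients
  expect_equal(z["R3", "S1_M1"], z["R3", "S1_M2"])
  # constant rows are left at zero
  Cc <- matrix(2, 1, 3, dimnames = list("R1", paste0("S1_M", 1:3)))
  Lc <- merge_landscape(list(mk_table(Cc)))
  expect_true(all(Lc$coefficients == 0))
})

test_that("complete-linkage merge order matches brute force on 4 columns", {
  C <- matrix(c(0, 0, 0.1, 0, 5, 0, 5.1, 0.2), 2, 4,
              dimnames = list(c("R1", "R2"), paste0("S1_M", 1:4)))
  # cluster on raw distances: build the landscape without z by using a
  # two-row matrix whose z-transform preserves the block structure
  L <- merge_landscape(list(mk_table(C)))
  hc <- cluster_modules(L)
  expect_true(all(diff(hc$height) >= -1e-12))
  D <- as.matrix(dist(t(L$coefficients)))
  # first merge joins the closest pair
  first <- sort(-hc$merge[1, ])
  pair <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  expect_setequal(first, sort(unname(pair)))
  # identical columns merge first at height zero
  C2 <- matrix(c(1, 2, 1, 2, 5, 9), 2, 3,
               dimnames = list(c("R1", "R2"), paste0("S1_M", 1:3)))
  hc2 <- cluster_modules(merge_landscape(list(mk_table(C2))))
  expect_equal(hc2$height[1], 0)
  expect_setequal(-hc2$merge[1, ], c(1, 2))
})

test_that("complete-linkage heights equal the brute-force cluster maxima", {
  set.seed(50)
  C <- matrix(rnorm(5 * 7), 5, 7,
              dimnames = list(paste0("R", 1:5), paste0("S1_M", 1:7)))
  L <- merge_landscape(list(mk_table(C)))
  hc <- cluster_modules(L)
  D <- as.matrix(dist(t(L$coefficients)))
  for (k in c(2, 3)) {
    cl <- cutree(hc, k = k)
    # the merge height leaving k clusters is the max within-cluster
    # pairwise distance after the next merge
    cl_next <- cutree(hc, k = k - 1)
    h <- hc$height[length(hc$height) - k + 2]
    maxd <- max(vapply(unique(cl_next), function(g) {
      idx <- which(cl_next == g)
      if (length(idx) < 2) 0 else max(D[idx, idx])
    }, 0))
    expect_equal(h, maxd, tolerance = 1e-10)
  }
})

test_that("dendrogram cuts behave at the extremes and recover blocks", {
  g <- gen_regulatory_tables(landscape_spec(n_metamodules = 2,
                                            selectivity_effects =
                                              list(condition = 0,
                                                   patient = 0, route = 0),
                                            noise_sd = 0, seed = 51))
  L <- merge_landscape(g$tables)
  hc <- cluster_modules(L)
  expect_error(cut_metamodules(hc), "exactly one")
  all_own <- cut_metamodules(hc, height = -1e-9)
  expect_equal(length(unique(all_own)), ncol(L$coefficients))
  one <- cut_metamodules(hc, height = max(hc$height) + 1)
  expect_equal(length(unique(one)), 1)
  # noiseless 2-block landscape: cutting between the two top merges
  # recovers the planted partition exactly
  h_cut <- mean(utils::tail(hc$height, 2))
  asg <- cut_metamodules(hc, height = h_cut)
  truth <- g$truth$assignment[names(asg)]
  expect_equal(mclust::adjustedRandIndex(asg, truth), 1)
})

test_that("metamodule signatures follow the >= 4-module support rule", {
  # gene present in 3 of 10 member modules: excluded; 4 of 4: included
  sets <- c(lapply(1:10, function(i)
    c(if (i <= 3) "rare3", paste0("g", i), "common")),
    list(m11 = c("x", "common")))
  names(sets) <- paste0("m", 1:11)
  asg <- stats::setNames(c(rep(1, 10), 2), names(sets))
  sig <- metamodule_signatures(asg, sets, min_support = 4)
  expect_false("rare3" %in% sig[[1]]$signature)
  expect_true("common" %in% sig[[1]]$signature)
  sets4 <- stats::setNames(replicate(4, c("a", "b"), simplify = FALSE),
                           paste0("k", 1:4))
  sig4 <- metamodule_signatures(stats::setNames(rep(1, 4), names(sets4)),
                                sets4)
  expect_setequal(sig4[[1]]$signature, c("a", "b"))
})

test_that("signatures equal an exhaustive counting oracle on random sets", {
  set.seed(52)
  for (rep in 1:10) {
    nm <- sample(3:6, 1)
    genes <- paste0("g", 1:20)
    sets <- stats::setNames(replicate(nm, sample(genes, sample(5:15, 1)),
                                      simplify = FALSE),
                            paste0("m", 1:nm))
    asg <- stats::setNames(rep(1, nm), names(sets))
    supp <- sample(2:4, 1)
    sig <- metamodule_signatures(asg, sets, min_support = supp)
    oracle <- sort(Filter(function(g)
      sum(vapply(sets, function(s) g %in% s, TRUE)) >= supp, genes))
    expect_equal(sig[[1]]$signature, oracle)
  }
})

test_that("jaccard_overlap equals set arithmetic, bounded and symmetric", {
  A <- list(a = c("x", "y", "z", "w"))
  B <- list(b = c("x", "y", "p", "q", "r", "s"))
  expect_equal(jaccard_overlap(A, A)[1, 1], 1)
  expect_equal(jaccard_overlap(A, list(b = c("p", "q")))[1, 1], 0)
  expect_equal(jaccard_overlap(A, B)[1, 1], 2 / 8)
  set.seed(53)
  pool <- paste0("g", 1:100)
  As <- lapply(1:4, function(i) sample(pool, sample(1:40, 1)))
  Bs <- lapply(1:3, function(i) sample(pool, sample(1:40, 1)))
  J <- jaccard_overlap(As, Bs)
  expect_true(all(J >= 0 & J <= 1))
  brute <- outer(seq_along(As), seq_along(Bs), Vectorize(function(i, j)
    length(intersect(As[[i]], Bs[[j]])) / length(union(As[[i]], Bs[[j]]))))
  expect_equal(unname(J), brute)
  expect_equal(unname(jaccard_overlap(Bs, As)), t(unname(J)))
})

test_that("route signatures recover planted route-specific genes", {
  set.seed(54)
  ng <- 60; nc <- 150
  counts <- matrix(rnbinom(ng * nc, mu = 15, size = 5), ng, nc,
                   dimnames = list(paste0("g", 1:ng), NULL))
  routes <- sample(c("pv", "diff", "lepto"), nc, replace = TRUE)
  samples <- paste0(routes, "_", rep(1:2, length.out = nc))
  planted <- list(pv = paste0("g", 1:3), diff = paste0("g", 4:6),
                  lepto = paste0("g", 7:9))
  for (r in names(planted))
    counts[planted[[r]], routes == r] <-
      rnbinom(3 * sum(routes == r), mu = 120, size = 5)
  sig <- fit_route_signatures(counts, routes, samples, n_genes = 3)
  for (r in names(planted)) expect_setequal(sig[[r]], planted[[r]])
  # identical expression: empty signatures
  counts0 <- matrix(rep(rnbinom(ng, mu = 10, size = 5), nc), ng, nc,
                    dimnames = list(paste0("g", 1:ng), NULL))
  sig0 <- fit_route_signatures(counts0, routes, samples)
  expect_true(all(lengths(sig0) == 0))
  # single-sample route is omitted with a warning
  expect_warning(
    fit_route_signatures(counts, routes,
                         ifelse(routes == "pv", "only_one", samples)),
    "fewer than 2")
  sig1 <- fit_route_signatures(counts, routes, samples, n_genes = 1)
  expect_true(all(lengths(sig1) == 1))
})

test_that("regulator ANOVA equals the closed-form one-way F", {
  C <- matrix(c(1, 2, 3, 2, 3, 4, 6, 7, 8), 1, 9,
              dimnames = list("R1", paste0("S1_M", 1:9)))
  L <- structure(list(
    coefficients = C,
    annotations = data.frame(module = colnames(C),
                             route = rep(c("a", "b", "c"), each = 3)),
    gene_sets = list()), class = "landscape")
  res <- regulator_anova(L, "route")
  fit <- stats::aov(as.numeric(C) ~ rep(c("a", "b", "c"), each = 3))
  sm <- summary(fit)[[1]]
  expect_equal(res$F, sm[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, sm[["Pr(>F)"]][1], tolerance = 1e-10)
  # constant regulator: missing; near-duplicate groups: huge F
  C2 <- rbind(C, R2 = rep(1, 9),
              R3 = rep(c(0, 1, 0), each = 3) + rnorm(9, 0, 1e-6))
  L$coefficients <- C2
  res2 <- regulator_anova(L, "route")
  expect_true(is.na(res2$F[2]))
  expect_gt(res2$F[3], 1e6)
  expect_error(regulator_anova(L, "nope"), "unknown")
})

test_that("moderate-noise metamodule recovery reaches ARI >= 0.9", {
  g <- gen_regulatory_tables(landscape_spec(n_metamodules = 3,
                                            noise_sd = 0.8, seed = 55))
  L <- merge_landscape(g$tables)
  asg <- cut_metamodules(cluster_modules(L), k = 3)
  expect_gte(mclust::adjustedRandIndex(asg, g$truth$assignment[names(asg)]),
             0.9)
})
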