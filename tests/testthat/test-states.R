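# QC filtering, signature scoring, cell-cycle regression, clustering, the
# 4-state embedding, state-route association and differential expression.

test_that("qc_filter removal counts equal brute-force recounts", {
  set.seed(30)
  for (rep in 1:6) {
    ng <- sample(60:120, 1); nc <- sample(40:90, 1)
    counts <- matrix(rpois(ng * nc, 2), ng, nc,
                     dimnames = list(paste0("g", 1:ng), paste0("c", 1:nc)))
    cm <- data.frame(kit = sample(c("v2", "v3"), nc, replace = TRUE))
    gm <- data.frame(mito = seq_len(ng) <= 5,
                     ribo = seq_len(ng) %in% 6:10,
                     hb = seq_len(ng) %in% 11:12)
    # plant violators
    counts[, 1] <- 0; counts[1:3, 1] <- 1              # low genes
    counts[, 2] <- 5                                   # doublet-ish
    counts[1:5, 3] <- 500                              # high mito
    counts[15, ] <- 0; counts[15, 1:4] <- 1            # low prevalence
    args <- list(min_genes = 10, min_cells = 5,
                 max_genes = c(v2 = ng - 10, v3 = ng - 5), max_mito = 0.3)
    res <- qc_filter(counts, cm, gm, args$min_genes, args$min_cells,
                     args$max_genes, args$max_mito)
    or <- oracle_qc_report(counts, cm$kit, gm$mito, gm$ribo, gm$hb,
                           args$min_genes, args$min_cells, args$max_genes,
                           args$max_mito)
    expect_equal(res$report, or)
  }
})

test_that("planted violator counts are recovered exactly", {
  g <- gen_state_counts(state_population_spec(seed = 31))
  qp <- g$qc_params
  res <- qc_filter(g$counts, g$cell_meta, g$gene_meta, qp$min_genes,
                   qp$min_cells, qp$max_genes, qp$max_mito)
  planted <- table(g$cell_meta$qc_class)
  expect_equal(unname(res$report["cells_low_genes"]),
               unname(planted["low_genes"]))
  expect_equal(unname(res$report["cells_doublet"]),
               unname(planted["doublet"]))
  expect_equal(unname(res$report["cells_high_mito"]),
               unname(planted["mito"]))
  expect_equal(unname(res$report["genes_low_prevalence"]),
               sum(g$gene_meta$class == "rare"))
  expect_true(all(res$cell_meta$qc_class == "ok"))
})

test_that("a cell expressing 499 genes is removed by the gene floor", {
  ng <- 600
  counts <- matrix(1L, ng, 3,
                   dimnames = list(paste0("g", 1:ng), paste0("c", 1:3)))
  counts[500:ng, 2] <- 0L          # cell 2 detects 499 genes
  cm <- data.frame(kit = rep("v3", 3))
  gm <- data.frame(mito = rep(FALSE, ng), ribo = FALSE, hb = FALSE)
  res <- qc_filter(counts, cm, gm, min_genes = 500, min_cells = 1,
                   max_genes = c(v3 = ng), max_mito = 0.3)
  expect_equal(unname(res$report["cells_low_genes"]), 1L)
  expect_equal(colnames(res$counts), c("c1", "c3"))
})

test_that("an all-pass matrix comes through qc_filter unchanged", {
  set.seed(32)
  counts <- matrix(rpois(50 * 20, 5) + 1L, 50, 20,
                   dimnames = list(paste0("g", 1:50), paste0("c", 1:20)))
  cm <- data.frame(kit = rep("v2", 20))
  gm <- data.frame(mito = rep(FALSE, 50), ribo = FALSE, hb = FALSE)
  res <- qc_filter(counts, cm, gm, min_genes = 10, min_cells = 2,
                   max_genes = c(v2 = 100), max_mito = 0.3)
  expect_identical(res$counts, counts)
  expect_true(all(res$report == 0))
  expect_error(qc_filter(counts, data.frame(kit = rep(NA, 20)), gm),
               "kit")
})

test_that("score_signature is centred, deterministic and shift-recovering", {
  set.seed(33)
  expr <- matrix(rnorm(200 * 50, 2), 200, 50,
                 dimnames = list(paste0("g", 1:200), NULL))
  all_genes <- rownames(expr)
  s <- score_signature(expr, all_genes, seed = 1)
  expect_lt(max(abs(s)), 0.3)                        # ~0 for the full set
  expect_identical(score_signature(expr, all_genes[1:30], seed = 7),
                   score_signature(expr, all_genes[1:30], seed = 7))
  # signature genes upshifted by delta over expression-matched controls
  delta <- 1.5
  expr2 <- expr
  expr2[1:30, ] <- expr2[1:30, ] + delta
  s2 <- score_signature(expr2, all_genes[1:30], nbin = 1, seed = 2)
  expect_equal(mean(s2), delta * (1 - 30 / 200), tolerance = 0.1)
  expect_warning(score_signature(expr, c(all_genes[1], "absent")),
                 "absent")
})

test_that("cc_regress removes cycle-correlated variation only", {
  set.seed(34)
  ng <- 150; nc <- 80
  expr <- matrix(rnorm(ng * nc), ng, nc,
                 dimnames = list(paste0("g", 1:ng), NULL))
  s_genes <- paste0("g", 1:20); g2m_genes <- paste0("g", 21:40)
  expr[1:20, ] <- expr[1:20, ] + rep(rnorm(nc, 0, 2), each = 20)
  out <- cc_regress(expr, s_genes, g2m_genes, seed = 3)
  d <- attr(out, "cc_difference")
  # a gene built as 2 * (S - G2M) + noise keeps only the noise variance
  target <- 2 * d + rnorm(nc, 0, 0.1)
  expr2 <- rbind(expr, target = target)
  out2 <- cc_regress(expr2, s_genes, g2m_genes, seed = 3)
  expect_lt(var(out2["target", ]), 0.05)
  # genes uncorrelated with the difference stay put (up to tolerance)
  unrel <- paste0("g", 100:150)
  expect_equal(out[unrel, ], expr[unrel, ], tolerance = 0.2)
  # constant difference: regression skipped
  const <- matrix(1, 50, 10, dimnames = list(paste0("g", 1:50), NULL))
  out3 <- cc_regress(const, paste0("g", 1:5), paste0("g", 6:10))
  expect_equal(unname(out3[, ]), unname(const), tolerance = 1e-12)
})

test_that("cluster_cells separates blobs and is monotone in resolution", {
  set.seed(35)
  blob <- function(mu, n) matrix(rnorm(40 * n, mu, 0.3), 40, n)
  expr <- cbind(blob(0, 40), blob(6, 40))
  rownames(expr) <- paste0("g", 1:40)
  cl <- cluster_cells(expr, resolution = 0.3, seed = 1)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:40])), 1)
  g <- cell_knn_graph(expr)
  ks <- vapply(c(0.1, 0.5, 1, 2), function(r)
    length(unique(igraph::membership(
      routescape:::with_seed(1, igraph::cluster_louvain(g, resolution = r))))),
    0)
  expect_true(all(diff(ks) >= 0))
  expect_equal(cluster_cells(expr[, 1, drop = FALSE]), 1L)
})

test_that("the quadrant embedding follows the published formulas", {
  sc <- data.frame(MES = 1, AC = 0, OPC = 0, NPC = 0)
  e <- neftel_embedding(sc)
  expect_equal(e$y, -1)
  expect_equal(e$x, 1)
  expect_equal(e$quadrant, "MES")
  # all-equal scores tie to the lower-left and are flagged
  e2 <- neftel_embedding(data.frame(MES = 0.5, AC = 0.5, OPC = 0.5,
                                    NPC = 0.5))
  expect_equal(e2$x, 0); expect_equal(e2$y, 0)
  expect_equal(e2$quadrant, "AC")
  expect_true(e2$tie)
  # invariance under adding a constant to all four scores of a cell
  set.seed(36)
  sc3 <- as.data.frame(matrix(rnorm(40), 10, 4))
  colnames(sc3) <- c("MES", "AC", "OPC", "NPC")
  e3 <- neftel_embedding(sc3)
  e4 <- neftel_embedding(sc3 + 5)
  expect_equal(e3$x, e4$x); expect_equal(e3$y, e4$y)
  expect_equal(e3$quadrant, e4$quadrant)
  sc3$MES[1] <- NA
  expect_warning(e5 <- neftel_embedding(sc3), "dropped")
  expect_equal(nrow(e5), 9)
})

test_that("pure-state synthetic cells land in their planted quadrant", {
  g <- gen_state_counts(state_population_spec(
    mito_fraction_outliers = 0, doublet_rate = 0, low_quality_rate = 0,
    seed = 37), count_noise = FALSE)
  expr <- normalize_counts(g$counts)
  gm <- g$gene_meta
  sc <- vapply(c("MES", "AC", "OPC", "NPC"), function(st)
    score_signature(expr, gm$gene[gm$class == st], seed = 5),
    numeric(ncol(expr)))
  emb <- neftel_embedding(sc)
  expect_gte(mean(emb$quadrant == g$cell_meta$state), 0.95)
})

test_that("state-route association matches the textbook chi-square", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  res <- state_route_association(rep(c("a", "b"), c(10, 10)),
                                 rep(c("x", "y", "x", "y"), c(10, 0, 0, 10)))
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)
  # oracle equivalence on random small tables
  set.seed(38)
  for (rep in 1:10) {
    r <- sample(2:5, 1); c <- sample(2:5, 1)
    tab <- matrix(sample(1:20, r * c, replace = TRUE), r, c)
    states <- rep(rep(paste0("s", 1:r), c), tab)
    routes <- rep(paste0("r", rep(1:c, each = r)), tab)
    res <- suppressWarnings(state_route_association(states, routes))
    or <- oracle_chisq(unclass(res$table))
    expect_equal(res$chi2, or$chi2, tolerance = 1e-10)
    expect_equal(res$df, or$df)
    expect_equal(unname(unclass(res$stdres)), unname(or$stdres),
                 tolerance = 1e-10)
  }
})

test_that("a 4-state by 3-route table has 6 degrees of freedom", {
  set.seed(39)
  res <- state_route_association(sample(c("MES", "AC", "OPC", "NPC"), 300,
                                        replace = TRUE),
                                 sample(c("pv", "diff", "lepto"), 300,
                                        replace = TRUE))
  expect_equal(res$df, 6)
})

test_that("dge recovers planted fold changes and adjusts with BH", {
  set.seed(40)
  ng <- 80; nc <- 120
  counts <- matrix(rnbinom(ng * nc, mu = 20, size = 5), ng, nc,
                   dimnames = list(paste0("g", 1:ng), NULL))
  grp <- factor(rep(c("A", "B"), each = nc / 2), levels = c("A", "B"))
  counts[1, grp == "A"] <- rnbinom(nc / 2, mu = 80, size = 5)
  res <- dge(counts, grp)
  expect_equal(res$log2FC[1], 2, tolerance = 0.35)
  expect_lt(res$padj[1], 0.01)
  expect_lt(max(abs(res$log2FC[-1])), 0.5)
  # identical groups: no signal
  counts2 <- matrix(rep(rnbinom(ng, mu = 10, size = 5), nc), ng, nc)
  rownames(counts2) <- paste0("g", 1:ng)
  res2 <- dge(counts2, grp)
  expect_true(all(abs(res2$log2FC) < 1e-12))
  expect_true(all(res2$padj > 0.9))
  # BH step-up formula on a hand example
  expect_equal(routescape:::bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
})

test_that("route-regulator shortlisting applies both thresholds", {
  tab <- data.frame(gene = c("r1", "r2", "r3", "g1"),
                    log2FC = c(1, 0.4, -0.8, 2),
                    p = c(1e-6, 1e-6, 1e-4, 1e-8),
                    padj = c(1e-5, 1e-5, 1e-3, 1e-7))
  attr(tab, "groups") <- c("perivascular", "diffuse")
  res <- select_route_regulators(tab, c("r1", "r2", "r3"))
  expect_equal(res$gene, c("r1", "r3"))
  expect_equal(res$direction, c("perivascular", "diffuse"))
  expect_equal(nrow(select_route_regulators(tab, character(0))), 0)
  # below the fold-change threshold: excluded regardless of p
  expect_false("r2" %in% res$gene)
})
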