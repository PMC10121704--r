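test_that("log-normalization equals its elementwise definition", {
  m <- toy_matrix(15, 8, seed = 1)
  m[, 1] <- 0L
  m[1, 1] <- 1L
  norm <- lognormalize(m)
  expect_equal(dim(norm), dim(m))
  tot <- colSums(m)
  for (j in seq_len(ncol(m)))                      # loop oracle
    expect_equal(unname(as.numeric(norm[, j])),
                 log1p(10000 * m[, j] / tot[j]), ignore_attr = TRUE)
  expect_true(all(as.matrix(norm)[m == 0] == 0))
  ## count 10 in a cell of total 10000 gives log(11)
  big <- matrix(c(10, 9990), 2, 1, dimnames = list(c("a", "b"), "c1"))
  expect_equal(as.numeric(lognormalize(big)["a", 1]), log(11))
  zero <- m; zero[, 2] <- 0L
  expect_error(lognormalize(zero), "zero-total")
})

test_that("PCA separates planted populations and orders variance", {
  sim <- simulate_counts(toy_count_config(n_cells = 150, seed = 21,
                                          doublet_rate = 0,
                                          ambient_fraction = 0))
  norm <- lognormalize(sim$counts)
  excl <- sim$annotation$gene[!is.na(sim$annotation$chromosome)]
  emb <- pca_embed(norm, n_pcs = 8, exclude_genes = excl)
  expect_true(all(diff(emb$sdev) <= 1e-8))
  expect_true(all(diff(apply(emb$embedding, 2, var)) <= 1e-8))
  ## PC1 separates at least two of the planted types (positive silhouette)
  ty <- sim$truth$subpop
  pc1 <- emb$embedding[, 1]
  ms <- tapply(pc1, ty, mean)
  spread <- tapply(pc1, ty, sd)
  expect_gt(max(dist(ms)), 2 * min(spread))
})

test_that("clustering recovers planted types and ignores cell order", {
  skip_if_not_installed("mclust")
  sim <- simulate_counts(toy_count_config(n_cells = 300, seed = 22))
  norm <- lognormalize(sim$counts)
  excl <- sim$annotation$gene[!is.na(sim$annotation$chromosome) |
                                sim$annotation$is_mito |
                                sim$annotation$is_ribo]
  emb <- pca_embed(norm, n_pcs = 10, exclude_genes = excl)
  cl <- cluster_cells(emb$embedding, resolution = 0.5, seed = 1)
  singlet <- !sim$truth$is_doublet
  ari <- mclust::adjustedRandIndex(cl$labels[singlet],
                                   sim$truth$subpop[singlet])
  expect_gte(ari, 0.9)

  ## permutation of cell order gives the same partition up to renaming
  perm <- sample(nrow(emb$embedding))
  cl2 <- cluster_cells(emb$embedding[perm, ], resolution = 0.5, seed = 1)
  ari_perm <- mclust::adjustedRandIndex(cl2$labels[names(cl$labels)],
                                        cl$labels)
  expect_gte(ari_perm, 0.99)
})

test_that("marker detection finds planted markers, Wilcoxon matches the exact null", {
  sim <- simulate_counts(toy_count_config(n_cells = 240, seed = 23,
                                          doublet_rate = 0,
                                          ambient_fraction = 0))
  norm <- lognormalize(sim$counts)
  clusters <- factor(sim$truth$subpop)
  names(clusters) <- rownames(sim$truth)
  mk <- find_markers_all(norm, clusters)
  astro_mk <- mk$gene[mk$cluster == "astrocyte"]
  expect_true(all(c("Aqp4", "Aldh1l1", "Gjb6") %in% astro_mk))
  expect_true(all(mk$pct_in >= 0.10))
  expect_true(all(mk$log2FC > 0.25))

  ## exact 70-permutation oracle for the 4-vs-4 rank-sum p-value
  x <- c(1.3, 2.1, 0.4, 3.3)
  y <- c(4.9, 5.2, 6.0, 4.1)
  p_pkg <- suppressWarnings(wilcox.test(x, y)$p.value)
  combs <- combn(8, 4)
  vals <- c(x, y)
  w_obs <- sum(rank(vals)[1:4])
  w_null <- apply(combs, 2, function(idx) sum(rank(vals)[idx]))
  mu <- 4 * 9 / 2
  p_exact <- mean(abs(w_null - mu) >= abs(w_obs - mu))
  expect_equal(p_pkg, p_exact, tolerance = 1e-12)
})

test_that("differential expression: identity contrast is null, Welch t matches closed form", {
  sim <- simulate_counts(toy_count_config(n_cells = 100, seed = 24))
  norm <- lognormalize(sim$counts)
  cells <- colnames(norm)[1:40]
  de <- differential_expression(norm, cells, cells)
  expect_true(all(de$log2FC == 0))
  expect_false(any(de$significant))

  ## closed-form Welch on {1,2,3} vs {4,5,6}: t = -3/sqrt(2/3)
  xa <- matrix(c(1, 2, 3), 1)
  xb <- matrix(c(4, 5, 6), 1)
  res <- gliakit:::welch_rows(xa, xb)
  expect_equal(res$stat, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(abs(-3 / sqrt(2 / 3)), df = 4,
                             lower.tail = FALSE), tolerance = 1e-12)

  ## zero variance in both groups reported as p = 1, not NaN
  flat <- matrix(5, 4, 12,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:12)))
  flat[1, 1:6] <- 9
  dn <- differential_expression(flat, paste0("c", 1:6), paste0("c", 7:12),
                                min_cells = 1)
  expect_equal(dn$p[dn$gene == "g2"], 1)
  expect_true(dn$zero_variance[dn$gene == "g2"])
})

test_that("planted log2-effect genes are recovered with no false flags", {
  planted <- sprintf("Gene%04d", 1:30)
  cfg <- sim_count_config(
    n_cells_per_sample = 200, n_genes = 600, doublet_rate = 0,
    ambient_fraction = 0,
    condition_effects = list(list(genes = planted, log2fc = 2)),
    samples = data.frame(sample = c("C", "S"), condition = c("CTRL", "SOD1"),
                         age = "4M", sex = "female"),
    seed = 25)
  sim <- simulate_counts(cfg)
  norm <- lognormalize(sim$counts)
  a <- rownames(sim$truth)[sim$truth$condition == "SOD1"]
  b <- rownames(sim$truth)[sim$truth$condition == "CTRL"]
  de <- differential_expression(norm, a, b)
  expect_true(all(de$significant[de$gene %in% planted]))
  expect_equal(sum(de$significant & !(de$gene %in% planted)), 0)
})

test_that("pseudobulk sums conserve counts and match a loop oracle", {
  sim <- simulate_counts(toy_count_config(n_cells = 60, seed = 26))
  sim$counts$cell_meta$sex <- sim$truth$sex
  pb1 <- pseudobulk(sim$counts, keys = "condition")
  expect_equal(unname(as.numeric(pb1$matrix[, 1])),
               unname(Matrix::rowSums(sim$counts$counts)))

  pb <- pseudobulk(sim$counts, keys = c("condition", "age", "sex"))
  expect_equal(sum(pb$matrix), sum(sim$counts$counts))
  expect_lte(ncol(pb$matrix), 16)
  ## loop-and-add oracle
  meta <- sim$counts$cell_meta
  key <- paste(meta$condition, meta$age, meta$sex, sep = "_")
  for (g in colnames(pb$matrix)) {
    members <- rownames(meta)[key == g]
    expect_equal(unname(as.numeric(pb$matrix[, g])),
                 unname(Matrix::rowSums(sim$counts$counts[, members,
                                                          drop = FALSE])))
  }
  expect_error(pseudobulk(sim$counts, keys = "missing_key"), "missing")
})

test_that("pseudobulk PCA exposes planted sample shifts through loadings", {
  stress <- sprintf("Stress%02d", 1:15)
  cfg <- sim_count_config(
    n_cells_per_sample = 60, n_genes = 400,
    condition_effects = list(list(genes = stress, log2fc = 2.5, ages = "4M")),
    seed = 27)
  sim <- simulate_counts(cfg)
  sim$counts$cell_meta$sex <- sim$truth$sex
  pb <- pseudobulk(sim$counts, keys = c("condition", "age", "sex"))
  pp <- pseudobulk_pca(pb)
  shifted <- pb$groups$condition == "SOD1" & pb$groups$age == "4M"
  sep <- apply(pp$scores, 2, function(s)
    abs(mean(s[shifted]) - mean(s[!shifted])) / (sd(s[!shifted]) + 1e-9))
  pc <- which.max(sep)
  expect_gt(sep[pc], 3)
  top <- names(sort(abs(pp$loadings[, pc]), decreasing = TRUE))[1:20]
  expect_gte(sum(stress %in% top), 12)

  ## identical columns have no variance: all scores 0
  flat <- matrix(rep(c(5, 3, 8), 4), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  pz <- pseudobulk_pca(flat)
  expect_lt(max(abs(pz$scores)), 1e-10)
  expect_error(pseudobulk_pca(flat[, 1:2]), "at least 3")
})

test_that("cluster annotation enforces the 80% expressing rule", {
  set.seed(5)
  norm <- matrix(0, 4, 200,
                 dimnames = list(c("Aqp4", "Aldh1l1", "Cx3cr1", "P2ry12"),
                                 paste0("c", 1:200)))
  cl <- factor(rep(c(1, 2), each = 100))
  names(cl) <- colnames(norm)
  ## cluster 1: astro markers in 95% of cells; cluster 2: 79% only
  norm[1:2, 1:95] <- 1
  norm[1:2, 101:179] <- 1
  ann <- annotate_clusters(norm, cl,
                           list(astrocyte = c("Aqp4", "Aldh1l1")))
  expect_equal(ann$label[ann$cluster == "1"], "astrocyte")
  expect_equal(ann$label[ann$cluster == "2"], "ambiguous")

  ## two matching marker sets are reported, never silently resolved
  norm[3:4, 1:95] <- 1
  ann2 <- annotate_clusters(norm, cl,
                            list(astrocyte = c("Aqp4", "Aldh1l1"),
                                 microglia = c("Cx3cr1", "P2ry12")))
  expect_equal(ann2$label[ann2$cluster == "1"], "ambiguous")
  expect_equal(ann2$matches[ann2$cluster == "1"], "astrocyte;microglia")
  expect_error(annotate_clusters(norm, cl, list(x = "NotAGene")), "absent")
})

test_that("subpopulation proportions sum to one and recover counts", {
  sim <- simulate_counts(toy_count_config(n_cells = 120, seed = 28))
  cl <- factor(sim$truth$subpop)
  names(cl) <- rownames(sim$truth)
  one <- subpopulation_proportions(factor(setNames(rep(1, 10),
                                                   rownames(sim$truth)[1:10])),
                                   sim$counts$cell_meta)
  expect_true(all(one$fraction == 1))

  tab <- subpopulation_proportions(cl, sim$counts$cell_meta,
                                   by = c("condition", "age"))
  sums <- tapply(tab$fraction, paste(tab$condition, tab$age), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  ## fractions times stratum sizes give back integer cell counts
  strat_n <- tapply(tab$n_cells, paste(tab$condition, tab$age), sum)
  recovered <- tab$fraction * strat_n[paste(tab$condition, tab$age)]
  expect_equal(as.numeric(recovered), tab$n_cells)
})
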