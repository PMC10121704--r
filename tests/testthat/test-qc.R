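test_that("droplet filter keeps barcodes at or above the UMI threshold", {
  m <- matrix(0L, 5, 3, dimnames = list(paste0("g", 1:5), c("a", "b", "c")))
  m[1, 1] <- 99L; m[2, 2] <- 100L; m[3, 3] <- 5000L
  out <- filter_droplets(m, min_umi = 100)
  expect_equal(colnames(out), c("b", "c"))        # 100 kept (>=), 99 dropped
  expect_equal(rownames(out), rownames(m))

  expect_equal(colnames(filter_droplets(m, min_umi = 0)), colnames(m))
  expect_error(filter_droplets(m, min_umi = 1e6), "below the UMI threshold")

  rmat <- toy_matrix(30, 25, seed = 9, lambda = 4)
  kept <- colnames(filter_droplets(rmat, min_umi = 120))
  oracle <- colnames(rmat)[vapply(seq_len(ncol(rmat)),
                                  function(j) sum(rmat[, j]) >= 120,
                                  logical(1))]
  expect_equal(kept, oracle)
})

test_that("cell metrics match hand and loop recomputation", {
  genes <- c("mt-Nd1", "Aqp4", "Plp1", "Xist", "Ddx3y", "Uty")
  m <- matrix(0L, 6, 2, dimnames = list(genes, c("c1", "c2")))
  m[, 1] <- c(5L, 30L, 15L, 0L, 0L, 0L)   # 3 genes, 50 UMIs, 10% mito
  m[, 2] <- c(0L, 1L, 0L, 2L, 0L, 0L)     # Xist 2, no Y
  ann <- gene_annotation(genes, chromosome = c("MT", "1", "1", "X", "Y", "Y"))
  met <- compute_cell_metrics(m, ann)
  expect_equal(met["c1", "nFeature_RNA"], 3)
  expect_equal(met["c1", "nCount_RNA"], 50)
  expect_equal(met["c1", "percent_mt"], 10)
  expect_equal(met["c2", "xist_count"], 2)
  expect_equal(met["c2", "nFeature_Y"], 0)

  sim <- simulate_counts(toy_count_config(n_cells = 80, seed = 2))
  met <- compute_cell_metrics(sim$counts, sim$annotation)
  mat <- as.matrix(sim$counts$counts)
  ann <- sim$annotation[rownames(mat), ]
  for (j in seq_len(ncol(mat))) {          # naive per-cell loop oracle
    v <- mat[, j]
    expect_equal(met$nFeature_RNA[j], sum(v > 0))
    expect_equal(met$nCount_RNA[j], sum(v))
    expect_equal(met$percent_mt[j], 100 * sum(v[ann$is_mito]) / sum(v))
    expect_equal(met$nCount_Y[j],
                 sum(v[!is.na(ann$chromosome) & ann$chromosome == "Y"]))
  }
})

test_that("sex rules are applied verbatim and totally", {
  mk <- function(xist, nfy, ncy)
    data.frame(xist_count = xist, nFeature_Y = nfy, nCount_Y = ncy,
               row.names = sprintf("c%d", seq_along(xist)))
  expect_equal(as.character(assign_sex(mk(0, 2, 7))), "male")
  expect_equal(as.character(assign_sex(mk(3, 1, 1))), "female")
  expect_equal(as.character(assign_sex(mk(0, 0, 0))), "undefined")
  expect_equal(as.character(assign_sex(mk(2, 2, 5))), "undefined")
  ## total on a grid; the printed rules are mutually exclusive
  grid <- expand.grid(xist = 0:3, nfy = 0:3, ncy = 0:5)
  lab <- assign_sex(data.frame(xist_count = grid$xist, nFeature_Y = grid$nfy,
                               nCount_Y = grid$ncy,
                               row.names = sprintf("g%d", seq_len(nrow(grid)))))
  expect_false(anyNA(lab))
  male_rule <- grid$xist < 1 & grid$nfy > 0
  female_rule <- grid$xist > 0 & grid$nfy < 2 & grid$ncy < 2
  expect_false(any(male_rule & female_rule))
  expect_equal(as.character(lab),
               ifelse(male_rule, "male",
                      ifelse(female_rule, "female", "undefined")))
})

test_that("QC gates use strict inequalities and equal the brute-force mask", {
  met <- data.frame(
    nFeature_RNA = c(1500, 1000, 1001, 800, 700),
    nCount_RNA = c(5000, 5000, 2000, 10000, 5000),
    percent_mt = c(3, 3, 3, 4, 8),
    row.names = paste0("c", 1:5))
  astro <- apply_celltype_qc(met, "astrocyte")
  expect_true(astro[["c1"]])
  expect_false(astro[["c2"]])   # nFeature exactly 1000: strict >
  expect_false(astro[["c3"]])   # nCount exactly 2000: strict >
  micro <- apply_celltype_qc(met, "microglia")
  expect_false(micro[["c4"]])   # nCount exactly 10000: strict <
  expect_false(micro[["c5"]])   # percent_mt exactly... 8 >= 5

  set.seed(7)
  rmet <- data.frame(nFeature_RNA = sample(400:2000, 300, TRUE),
                     nCount_RNA = sample(500:60000, 300, TRUE),
                     percent_mt = runif(300, 0, 12),
                     row.names = paste0("r", 1:300))
  for (ty in names(celltype_qc_thresholds())) {
    th <- celltype_qc_thresholds()[[ty]]
    oracle <- vapply(seq_len(nrow(rmet)), function(i)
      rmet$nFeature_RNA[i] > th$min_features &&
        rmet$nCount_RNA[i] > th$min_counts &&
        rmet$nCount_RNA[i] < th$max_counts &&
        rmet$percent_mt[i] < th$max_percent_mt, logical(1))
    expect_equal(unname(apply_celltype_qc(rmet, ty)), oracle)
  }
})

test_that("relaxing any QC threshold never drops a kept cell", {
  set.seed(8)
  met <- data.frame(nFeature_RNA = sample(400:2000, 200, TRUE),
                    nCount_RNA = sample(500:60000, 200, TRUE),
                    percent_mt = runif(200, 0, 12),
                    row.names = paste0("r", 1:200))
  base <- celltype_qc_thresholds()$astrocyte
  kept <- apply_celltype_qc(met, "astrocyte")
  relaxed_list <- list(
    modifyList(base, list(min_features = base$min_features - 200)),
    modifyList(base, list(min_counts = base$min_counts - 500)),
    modifyList(base, list(max_counts = base$max_counts + 5000)),
    modifyList(base, list(max_percent_mt = base$max_percent_mt + 2)))
  for (th in relaxed_list)
    expect_true(all(kept <= apply_celltype_qc(met, "x", thresholds = th)))
})

test_that("module scores behave like signature minus matched controls", {
  ## hand-computable toy: 2 genes x 3 cells, one bin, controls = both genes
  norm <- matrix(c(1, 0, 2, 1, 0, 3), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  sc <- module_score(norm, "gA", n_bins = 1, n_ctrl = 50, seed = 1)
  ## controls drawn from {gA, gB}; with many draws control mean ~ colMeans
  expected <- norm["gA", ] - colMeans(norm)
  expect_lt(max(abs(sc - expected)), 0.25)

  ## a set scored against a universe of identical statistics centers near 0
  set.seed(3)
  big <- matrix(rpois(100 * 60, 3), 100, 60,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("c%02d", 1:60)))
  nb <- lognormalize(big)
  null_sc <- module_score(nb, sample(rownames(nb), 20), n_bins = 4,
                          n_ctrl = 100, seed = 2)
  expect_lt(abs(mean(null_sc)), 0.1)

  ## planted high-expression cells score higher
  hot <- big
  hot[1:10, 1:20] <- hot[1:10, 1:20] + 20L
  sc2 <- module_score(lognormalize(hot), rownames(hot)[1:10], seed = 4)
  expect_gt(mean(sc2[1:20]), mean(sc2[21:60]))

  ## invariance to gene order and to duplicated cells
  perm <- sample(nrow(big))
  sc_perm <- module_score(nb[perm, ], sample(rownames(nb)[1:20]),
                          n_bins = 4, n_ctrl = 100, seed = 2)
  sc_orig <- module_score(nb, rownames(nb)[1:20], n_bins = 4, n_ctrl = 100,
                          seed = 2)
  expect_equal(sort(names(sc_perm)), sort(names(sc_orig)))
  expect_error(module_score(nb, c("absent1", "absent2")), "no signature gene")
})

test_that("cell-cycle phase is the positive argmax with S tie-break", {
  s <- c(a = 0.5, b = -0.2, c = 0.3, d = 0.3)
  g <- c(a = 0.1, b = -0.1, c = 0.6, d = 0.3)
  ph <- assign_cell_cycle(s, g)
  expect_equal(as.character(ph), c("S", "G1", "G2M", "S"))
  expect_error(assign_cell_cycle(s[1:3], g), "same cells")
})
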