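# shared fixtures, built in code at test time

canonical_glia_markers <- function() {
  list(astrocyte = c("Aqp4", "Aldh1l1", "Gjb6"),
       microglia = c("Cx3cr1", "P2ry12", "Tmem119"),
       oligodendrocyte = c("Plp1", "Mbp", "Mog"))
}

# one-sample mixed-sex config small enough for unit tests
toy_count_config <- function(n_cells = 200, n_genes = 300, seed = 1L, ...) {
  sim_count_config(
    n_cells_per_sample = n_cells, n_genes = n_genes,
    samples = data.frame(sample = "s1", condition = "CTRL", age = "4M",
                         sex = "mixed"),
    seed = seed, ...)
}

# QC gates rescaled to a toy gene universe (a few hundred genes)
toy_qc_thresholds <- function() {
  list(astrocyte = list(min_features = 100, min_counts = 1000,
                        max_counts = 60000, max_percent_mt = 8),
       microglia = list(min_features = 100, min_counts = 1000,
                        max_counts = 60000, max_percent_mt = 5),
       oligodendrocyte = list(min_features = 100, min_counts = 1000,
                              max_counts = 60000, max_percent_mt = 5))
}

# tiny deterministic count matrix with dimnames
toy_matrix <- function(n_genes = 20, n_cells = 10, seed = 42, lambda = 3) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("c%02d", seq_len(n_cells))))
  m
}

# independent brute-force running-sum recomputation of the enrichment score
brute_force_es <- function(ranked, gene_set, p = 1) {
  N <- length(ranked)
  hits <- names(ranked) %in% gene_set
  k <- sum(hits)
  w <- abs(ranked[hits])^p
  w <- if (sum(w) == 0) rep(1 / k, k) else w / sum(w)
  run <- numeric(N)
  cur <- 0
  wi <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      wi <- wi + 1
      cur <- cur + w[wi]
    } else cur <- cur - 1 / (N - k)
    run[i] <- cur
  }
  hi <- max(run)
  lo <- min(run)
  if (hi >= -lo) hi else lo
}

# dense sampling oracle for circle/polyline crossings: count sign changes of
# (distance - r) along finely sampled branch paths
sampled_crossings <- function(branches, center, r, step = 0.005) {
  total <- 0L
  for (pts in branches) {
    dd <- numeric(0)
    for (s in seq_len(nrow(pts) - 1)) {
      p0 <- pts[s, ]
      p1 <- pts[s + 1, ]
      len <- sqrt(sum((p1 - p0)^2))
      ts <- seq(0, 1, length.out = max(2, ceiling(len / step)))
      if (s > 1) ts <- ts[-1]
      dd <- c(dd, sqrt((p0[1] + ts * (p1[1] - p0[1]) - center[1])^2 +
                         (p0[2] + ts * (p1[2] - p0[2]) - center[2])^2))
    }
    sgn <- sign(dd - r)
    sgn <- sgn[sgn != 0]
    total <- total + sum(diff(sgn) != 0)
  }
  total
}
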