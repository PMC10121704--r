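#' Log-normalize UMI counts
#'
#' Per-cell depth normalization: `log(1 + scale_factor * count / total)`,
#' natural log. Zeros stay zero, so sparsity is preserved.
#'
#' @param m a [count_matrix()] or gene x cell matrix; no zero-total cells.
#' @param scale_factor target depth (default 10000).
#' @return sparse gene x cell matrix of log-normalized values.
#' @export
lognormalize <- function(m, scale_factor = 10000) {
  mat <- as_counts(m)
  total <- Matrix::colSums(mat)
  stop_if_not(all(total > 0), "zero-total cells must be removed first")
  norm <- mat %*% Matrix::Diagonal(x = scale_factor / total)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(mat)
  as(norm, "CsparseMatrix")
}

## per-gene variance of a sparse matrix, computed from the nonzeros
sparse_row_var <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  sq <- Matrix::rowSums(m^2)
  (sq - n * mu^2) / (n - 1)
}

#' PCA embedding of cells
#'
#' Selects the `n_hvg` most variable genes from the log-normalized matrix,
#' centres and unit-scales each (values capped at `scale_cap`), and runs PCA
#' by SVD. Variance explained is non-increasing across components.
#'
#' @param norm log-normalized gene x cell matrix.
#' @param n_pcs number of components (the emulated study used 17 for the full
#'   dataset, 16 for astrocyte/microglia subtypes).
#' @param n_hvg number of highly variable genes (default 2000, capped at the
#'   gene count).
#' @param scale_cap cap applied to scaled values (default 10).
#' @param exclude_genes genes removed before HVG selection (e.g. confounders
#'   before subtype clustering).
#' @return list with `embedding` (cells x n_pcs), `sdev`, `loadings`
#'   (genes x n_pcs), `hvg`.
#' @export
pca_embed <- function(norm, n_pcs = 17, n_hvg = 2000, scale_cap = 10,
                      exclude_genes = NULL) {
  if (!is.null(exclude_genes))
    norm <- norm[setdiff(rownames(norm), exclude_genes), , drop = FALSE]
  stop_if_not(n_pcs < min(dim(norm)), "n_pcs must be < min(genes, cells)")
  v <- sparse_row_var(norm)
  hvg <- names(sort(v, decreasing = TRUE))[seq_len(min(n_hvg, sum(v > 0)))]
  x <- as.matrix(norm[hvg, , drop = FALSE])
  x <- t(scale(t(x)))            # per-gene center / unit variance
  x[x > scale_cap] <- scale_cap
  x[x < -scale_cap] <- -scale_cap
  pc <- prcomp(t(x), center = FALSE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(emb) <- colnames(norm)
  list(embedding = emb, sdev = pc$sdev[seq_len(n_pcs)],
       loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE], hvg = hvg)
}

#' Graph-based clustering of cells
#'
#' Builds a k-nearest-neighbour graph in PC space (Euclidean), reweights edges
#' by shared-neighbour Jaccard similarity, and partitions it by Louvain
#' modularity optimization at the given resolution. Results are deterministic
#' under a fixed seed; labels are contiguous integers ordered by decreasing
#' cluster size.
#'
#' @param embedding cells x PCs matrix (see [pca_embed()]).
#' @param k_neighbors neighbourhood size (default 20).
#' @param resolution modularity resolution (0.5 for the full dataset, 0.2 for
#'   subtype analyses in the emulated study).
#' @param seed integer seed.
#' @return list with `labels` (named factor), `k_neighbors`, `resolution`,
#'   `n_pcs`.
#' @export
cluster_cells <- function(embedding, k_neighbors = 20, resolution = 0.5,
                          seed = 1L) {
  n <- nrow(embedding)
  stop_if_not(n >= k_neighbors + 1, "need at least k_neighbors + 1 cells")
  d <- as.matrix(stats::dist(embedding))
  knn <- t(apply(d, 1, function(row) order(row)[2:(k_neighbors + 1)]))
  ## SNN Jaccard weights over the union of directed kNN edges
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                              j = as.vector(t(knn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  pairs <- Matrix::which(shared > 0, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  sh <- shared[pairs]
  jac <- sh / (2 * k_neighbors - sh)
  keep <- jac >= 1 / 15          # prune weak links, standard SNN practice
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
               weight = jac[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)[as.character(seq_len(n))]
  ## relabel contiguously by decreasing size
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes), names(sizes))
  labels <- factor(relab[as.character(memb)])
  names(labels) <- rownames(embedding)
  list(labels = labels, k_neighbors = k_neighbors,
       resolution = resolution, n_pcs = ncol(embedding))
}

#' Annotate clusters from canonical markers
#'
#' A cluster receives a type label iff at least `min_expressing` of its cells
#' have nonzero expression of the type's markers. By default every listed
#' marker must individually clear the threshold (`rule = "each"`); with
#' `rule = "any"` one qualifying marker suffices. Clusters matching no type,
#' or more than one, are reported as `"ambiguous"` rather than silently
#' resolved.
#'
#' @param norm log-normalized gene x cell matrix.
#' @param clusters factor of cluster labels per cell.
#' @param canonical_markers named list: type -> marker genes.
#' @param min_expressing expressing-cell fraction required (default 0.80,
#'   compared with `>=`).
#' @param rule `"each"` or `"any"`.
#' @return data.frame per cluster: `cluster`, `label`, `matches`
#'   (semicolon-joined candidate types).
#' @export
annotate_clusters <- function(norm, clusters, canonical_markers,
                              min_expressing = 0.80, rule = c("each", "any")) {
  rule <- match.arg(rule)
  stop_if_not(length(canonical_markers) > 0, "marker map is empty")
  missing <- setdiff(unlist(canonical_markers), rownames(norm))
  stop_if_not(length(missing) == 0, "marker gene(s) absent: %s",
              paste(missing, collapse = ", "))
  out <- lapply(levels(clusters), function(cl) {
    cells <- which(clusters == cl)
    frac <- vapply(canonical_markers, function(genes) {
      f <- Matrix::rowMeans(norm[genes, cells, drop = FALSE] > 0)
      if (rule == "each") min(f) else max(f)
    }, numeric(1))
    hits <- names(frac)[frac >= min_expressing]
    data.frame(cluster = cl,
               label = if (length(hits) == 1) hits else "ambiguous",
               matches = paste(hits, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Subpopulation proportions per stratum
#'
#' Fractions of cells per cluster within each stratum (by default the
#' condition); fractions within a stratum sum to 1.
#'
#' @param clusters factor of cluster labels per cell (named by barcode).
#' @param cell_meta data.frame keyed by barcode.
#' @param by metadata columns defining the strata (default `"condition"`).
#' @return data.frame with stratum columns, `cluster`, `n_cells`, `fraction`.
#' @export
subpopulation_proportions <- function(clusters, cell_meta,
                                      by = "condition") {
  stop_if_not(all(names(clusters) %in% rownames(cell_meta)),
              "metadata missing for some cells")
  meta <- cell_meta[names(clusters), by, drop = FALSE]
  stratum <- interaction(meta, drop = TRUE, sep = "/")
  tab <- as.data.frame(table(stratum = stratum, cluster = clusters),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n_cells"
  tot <- tapply(tab$n_cells, tab$stratum, sum)
  tab$fraction <- tab$n_cells / as.numeric(tot[tab$stratum])
  strata_cols <- do.call(rbind, strsplit(as.character(tab$stratum), "/",
                                         fixed = TRUE))
  colnames(strata_cols) <- by
  cbind(as.data.frame(strata_cols, stringsAsFactors = FALSE),
        tab[, c("cluster", "n_cells", "fraction")])
}
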