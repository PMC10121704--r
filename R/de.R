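## fold change on log-normalized values: back-transform to the normalized
## scale, pseudocount of 1 on each group mean
log2_fold_change <- function(norm, cells_a, cells_b) {
  ma <- Matrix::rowMeans(norm[, cells_a, drop = FALSE])
  mb <- Matrix::rowMeans(norm[, cells_b, drop = FALSE])
  ## rowMeans of expm1 via the nonzeros
  ea <- Matrix::rowSums(expm1(norm[, cells_a, drop = FALSE])) / length(cells_a)
  eb <- Matrix::rowSums(expm1(norm[, cells_b, drop = FALSE])) / length(cells_b)
  log2((ea + 1) / (eb + 1))
}

pct_expressing <- function(norm, cells) {
  Matrix::rowMeans(norm[, cells, drop = FALSE] > 0)
}

## vectorized Welch t-test per gene; returns data.frame(stat, p)
welch_rows <- function(x_a, x_b) {
  na <- ncol(x_a); nb <- ncol(x_b)
  ma <- rowMeans(x_a); mb <- rowMeans(x_b)
  va <- rowSums((x_a - ma)^2) / (na - 1)
  vb <- rowSums((x_b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  zerovar <- se2 == 0
  stat[zerovar] <- 0
  p[zerovar] <- 1                      # undefined statistic reported as 1
  data.frame(stat = stat, p = p, zero_variance = zerovar)
}

#' Differential expression between two cell groups
#'
#' Per-gene Welch t-test (default) or Wilcoxon rank-sum on log-normalized
#' values. A gene is flagged significant when adjusted p < `alpha` and
#' |log2FC| > `lfc_threshold`; the flag is stored, rows are never dropped.
#' Genes detected in fewer than `min_cells` cells of the two groups combined
#' are not tested. Fold change is computed on back-transformed normalized
#' means with a pseudocount of 1.
#'
#' @param norm log-normalized gene x cell matrix.
#' @param cells_a,cells_b barcodes (or indices) of the two groups, >= 3 each.
#' @param test `"t"` (Welch) or `"wilcoxon"`.
#' @param min_cells detection floor over the union (default 3).
#' @param p_adjust `"bonferroni"` (default) or `"BH"`, over tested genes.
#' @param alpha,lfc_threshold significance flag thresholds (0.05 and 1).
#' @return data.frame per tested gene: `gene`, `log2FC`, `p`, `p_adj`,
#'   `pct_in`, `pct_out`, `significant`, `zero_variance`, ordered by p.
#' @export
differential_expression <- function(norm, cells_a, cells_b,
                                    test = c("t", "wilcoxon"),
                                    min_cells = 3,
                                    p_adjust = c("bonferroni", "BH"),
                                    alpha = 0.05, lfc_threshold = 1) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  stop_if_not(length(cells_a) >= 3 && length(cells_b) >= 3,
              "each group needs at least 3 cells")
  detected <- Matrix::rowSums(norm[, c(cells_a, cells_b), drop = FALSE] > 0)
  tested <- which(detected >= min_cells)
  stop_if_not(length(tested) > 0, "no gene passes the detection floor")
  sub <- norm[tested, , drop = FALSE]
  lfc <- log2_fold_change(sub, cells_a, cells_b)
  if (test == "t") {
    res <- welch_rows(as.matrix(sub[, cells_a, drop = FALSE]),
                      as.matrix(sub[, cells_b, drop = FALSE]))
  } else {
    xa <- as.matrix(sub[, cells_a, drop = FALSE])
    xb <- as.matrix(sub[, cells_b, drop = FALSE])
    p <- vapply(seq_len(nrow(sub)), function(i) {
      if (all(xa[i, ] == xa[i, 1]) && all(xb[i, ] == xb[i, 1]) &&
          xa[i, 1] == xb[i, 1]) return(1)
      suppressWarnings(wilcox.test(xa[i, ], xb[i, ])$p.value)
    }, numeric(1))
    res <- data.frame(stat = NA_real_, p = p,
                      zero_variance = FALSE)
  }
  out <- data.frame(
    gene = rownames(sub),
    log2FC = lfc,
    p = res$p,
    p_adj = p.adjust(res$p, method = ifelse(p_adjust == "BH", "BH",
                                            "bonferroni")),
    pct_in = pct_expressing(sub, cells_a),
    pct_out = pct_expressing(sub, cells_b),
    zero_variance = res$zero_variance,
    stringsAsFactors = FALSE
  )
  out$significant <- out$p_adj < alpha & abs(out$log2FC) > lfc_threshold
  out[order(out$p, out$gene), ]
}

#' One-vs-rest marker detection for every cluster
#'
#' Wilcoxon rank-sum per gene, cluster versus all other cells. Only genes
#' expressed in at least `min_pct` of the cluster's cells and with
#' log2FC > `min_log2fc` are tested and reported (the pre-filter is how the
#' emulated toolkit keeps the test count manageable). Adjusted p-values are
#' computed over the tested genes per cluster.
#'
#' @param norm log-normalized gene x cell matrix.
#' @param clusters factor per cell (named by barcode), >= 2 levels; clusters
#'   of fewer than 3 cells are an error.
#' @param min_pct minimum expressing fraction inside the cluster (default 0.10).
#' @param min_log2fc minimum log2 fold change (default 0.25, strict `>`).
#' @param p_adjust `"bonferroni"` or `"BH"`.
#' @return data.frame: `cluster`, `gene`, `log2FC`, `p`, `p_adj`, `pct_in`,
#'   `pct_out`.
#' @export
find_markers_all <- function(norm, clusters, min_pct = 0.10,
                             min_log2fc = 0.25,
                             p_adjust = c("bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stop_if_not(nlevels(droplevels(clusters)) >= 2, "need at least 2 clusters")
  stop_if_not(min(table(clusters)) >= 3, "cluster of size < 3")
  cells <- names(clusters) %||% colnames(norm)
  res <- lapply(levels(clusters), function(cl) {
    in_cells <- cells[clusters == cl]
    out_cells <- cells[clusters != cl]
    pct_in <- pct_expressing(norm, in_cells)
    lfc <- log2_fold_change(norm, in_cells, out_cells)
    cand <- which(pct_in >= min_pct & lfc > min_log2fc)
    if (!length(cand)) return(NULL)
    xa <- as.matrix(norm[cand, in_cells, drop = FALSE])
    xb <- as.matrix(norm[cand, out_cells, drop = FALSE])
    p <- vapply(seq_along(cand), function(i)
      suppressWarnings(wilcox.test(xa[i, ], xb[i, ])$p.value), numeric(1))
    data.frame(cluster = cl, gene = rownames(norm)[cand],
               log2FC = lfc[cand], p = p,
               p_adj = p.adjust(p, method = ifelse(p_adjust == "BH", "BH",
                                                   "bonferroni")),
               pct_in = pct_in[cand],
               pct_out = pct_expressing(norm, out_cells)[cand],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$cluster, out$p, out$gene), ]
}

#' Pseudobulk aggregation
#'
#' Sums raw gene counts over cells sharing the grouping key (default
#' condition x age x sex). Column sums equal the total counts of the member
#' cells; empty groups are absent.
#'
#' @param m a [count_matrix()] (metadata must carry every key) or a matrix
#'   plus `cell_meta`.
#' @param keys metadata columns defining the groups.
#' @param cell_meta metadata data.frame when `m` is a bare matrix.
#' @return list with `matrix` (gene x group sums), `groups` (data.frame of key
#'   values and cell counts per group).
#' @export
pseudobulk <- function(m, keys = c("condition", "age", "sex"),
                       cell_meta = NULL) {
  if (inherits(m, "glia_counts")) {
    cell_meta <- m$cell_meta
    mat <- m$counts
  } else mat <- as_counts(m)
  stop_if_not(all(keys %in% names(cell_meta)),
              "missing metadata key(s): %s",
              paste(setdiff(keys, names(cell_meta)), collapse = ", "))
  meta <- cell_meta[colnames(mat), keys, drop = FALSE]
  stop_if_not(!anyNA(meta), "cells with missing key values")
  grp <- interaction(meta, drop = TRUE, sep = "_", lex.order = TRUE)
  ind <- Matrix::sparseMatrix(i = seq_len(ncol(mat)), j = as.integer(grp),
                              x = 1, dims = c(ncol(mat), nlevels(grp)))
  pb <- mat %*% ind
  colnames(pb) <- levels(grp)
  groups <- unique(cbind(meta, group = as.character(grp)))
  groups <- groups[match(levels(grp), groups$group), , drop = FALSE]
  groups$n_cells <- as.integer(table(grp)[groups$group])
  rownames(groups) <- NULL
  list(matrix = as(pb, "CsparseMatrix"), groups = groups)
}

#' PCA of pseudobulk samples
#'
#' Columns are depth-normalized (counts per `scale_factor`), log1p
#' transformed, genes centred, and decomposed by SVD. Scores and per-gene
#' loadings are both returned so genes driving an outlying sample (e.g. a
#' stress-response module) can be read off the loadings.
#'
#' @param pb output of [pseudobulk()] or a gene x sample matrix (>= 3 columns).
#' @param n_pcs number of components (default all).
#' @param scale_factor depth target (default 1e6).
#' @return list with `scores` (samples x PCs), `loadings` (genes x PCs),
#'   `sdev`.
#' @export
pseudobulk_pca <- function(pb, n_pcs = NULL, scale_factor = 1e6) {
  mat <- if (is.list(pb) && !is.null(pb$matrix)) pb$matrix else pb
  mat <- as.matrix(mat)
  stop_if_not(ncol(mat) >= 3, "pseudobulk PCA needs at least 3 samples")
  depth <- colSums(mat)
  x <- log1p(t(t(mat) / depth * scale_factor))
  x <- x - rowMeans(x)
  n_pcs <- n_pcs %||% (ncol(mat) - 1)
  sv <- svd(t(x), nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  rownames(scores) <- colnames(mat)
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  loadings <- sv$v
  rownames(loadings) <- rownames(mat)
  colnames(loadings) <- colnames(scores)
  list(scores = scores, loadings = loadings,
       sdev = sv$d[seq_len(n_pcs)] / sqrt(max(1, ncol(mat) - 1)))
}
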