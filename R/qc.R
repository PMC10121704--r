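#' Remove droplets below a UMI total
#'
#' The droplet pre-filter retains barcodes with at least `min_umi` total UMIs
#' (a barcode at exactly the threshold is kept). Column order and the gene set
#' are unchanged.
#'
#' @param raw a [count_matrix()] or gene x cell matrix.
#' @param min_umi minimum UMI total per droplet (default 100).
#' @return filtered object of the same class as the input.
#' @export
filter_droplets <- function(raw, min_umi = 100) {
  m <- as_counts(raw)
  stop_if_not(ncol(m) >= 1, "input has no barcodes")
  keep <- Matrix::colSums(m) >= min_umi
  if (!any(keep))
    stop("all droplets fall below the UMI threshold", call. = FALSE)
  if (inherits(raw, "glia_counts")) subset_cells(raw, cells = which(keep))
  else m[, keep, drop = FALSE]
}

#' Per-cell QC metrics
#'
#' Computes genes detected (nFeature_RNA), UMI totals (nCount_RNA), the
#' mitochondrial count percentage, Xist UMIs, and the number and total UMIs
#' of detected Y-chromosome genes — the quantities the sex classifier and the
#' cell-type gates operate on.
#'
#' @param m a [count_matrix()] or gene x cell matrix.
#' @param ann a [gene_annotation()] covering all genes (chromosome `"Y"` marks
#'   Y genes; `"Xist"` or the gene named in `xist_gene` supplies Xist counts).
#' @param xist_gene gene id carrying Xist counts.
#' @return data.frame keyed by barcode with columns `nFeature_RNA`,
#'   `nCount_RNA`, `percent_mt`, `xist_count`, `nFeature_Y`, `nCount_Y` and a
#'   logical `zero_total` flag.
#' @export
compute_cell_metrics <- function(m, ann, xist_gene = "Xist") {
  mat <- as_counts(m)
  stop_if_not(all(rownames(mat) %in% rownames(ann)),
              "annotation must cover every gene in the matrix")
  ann <- ann[rownames(mat), , drop = FALSE]
  total <- Matrix::colSums(mat)
  mito <- which(ann$is_mito)
  mito_counts <- if (length(mito)) Matrix::colSums(mat[mito, , drop = FALSE]) else 0
  ygenes <- which(!is.na(ann$chromosome) & ann$chromosome == "Y")
  ymat <- mat[ygenes, , drop = FALSE]
  xist <- if (xist_gene %in% rownames(mat)) mat[xist_gene, ] else
    rep(0, ncol(mat))
  data.frame(
    nFeature_RNA = Matrix::colSums(mat > 0),
    nCount_RNA = total,
    percent_mt = ifelse(total > 0, 100 * mito_counts / total, 0),
    xist_count = as.numeric(xist),
    nFeature_Y = Matrix::colSums(ymat > 0),
    nCount_Y = Matrix::colSums(ymat),
    zero_total = total == 0,
    row.names = colnames(mat)
  )
}

#' Assign sex to cells from Xist and Y-gene expression
#'
#' A cell is called male iff it has no Xist UMIs and at least one detected
#' Y-encoded gene; female iff it has Xist UMIs, fewer than two detected Y
#' genes and fewer than two Y UMIs. Cells matching neither rule (or both,
#' which the printed rules make impossible) are `"undefined"` and are meant
#' to be excluded downstream. Raw UMI counts are used, before normalization.
#'
#' @param metrics output of [compute_cell_metrics()].
#' @return factor per cell with levels male/female/undefined, named by barcode.
#' @export
assign_sex <- function(metrics) {
  stop_if_not(all(c("xist_count", "nFeature_Y", "nCount_Y") %in% names(metrics)),
              "metrics must carry xist_count, nFeature_Y, nCount_Y")
  male <- metrics$xist_count < 1 & metrics$nFeature_Y > 0
  female <- metrics$xist_count > 0 & metrics$nFeature_Y < 2 & metrics$nCount_Y < 2
  out <- rep("undefined", nrow(metrics))
  out[male] <- "male"
  out[female] <- "female"
  factor(setNames(out, rownames(metrics)),
         levels = c("male", "female", "undefined"))
}

#' Default per-cell-type QC gates
#'
#' Strict inequalities exactly as applied in the emulated study:
#' astrocytes nFeature > 1000, 2000 < nCount < 10000, percent_mt < 8;
#' microglia nFeature > 700, 1000 < nCount < 10000, percent_mt < 5;
#' oligodendrocytes nFeature > 1300, 2500 < nCount < 50000, percent_mt < 5.
#' @return named list of threshold lists.
#' @export
celltype_qc_thresholds <- function() {
  list(
    astrocyte = list(min_features = 1000, min_counts = 2000,
                     max_counts = 10000, max_percent_mt = 8),
    microglia = list(min_features = 700, min_counts = 1000,
                     max_counts = 10000, max_percent_mt = 5),
    oligodendrocyte = list(min_features = 1300, min_counts = 2500,
                           max_counts = 50000, max_percent_mt = 5)
  )
}

#' Apply a cell-type QC gate
#'
#' All comparisons are strict, so a cell sitting exactly on a threshold is
#' dropped. Relaxing any threshold can only keep more cells (the gate is
#' monotone).
#'
#' @param metrics output of [compute_cell_metrics()].
#' @param cell_type one of `"astrocyte"`, `"microglia"`, `"oligodendrocyte"`,
#'   or any name when `thresholds` is supplied.
#' @param thresholds optional list with `min_features`, `min_counts`,
#'   `max_counts`, `max_percent_mt` overriding the built-in gates.
#' @return logical keep mask named by barcode.
#' @export
apply_celltype_qc <- function(metrics, cell_type, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- celltype_qc_thresholds()[[cell_type]]
    stop_if_not(!is.null(thresholds),
                "unknown cell type '%s' and no custom thresholds", cell_type)
  }
  keep <- metrics$nFeature_RNA > thresholds$min_features &
    metrics$nCount_RNA > thresholds$min_counts &
    metrics$nCount_RNA < thresholds$max_counts &
    metrics$percent_mt < thresholds$max_percent_mt
  setNames(keep, rownames(metrics))
}

#' Gene-signature module score
#'
#' For each cell, the mean log-normalized expression of the signature genes
#' minus the mean expression of a pooled control set: genes are binned into
#' `n_bins` equal-frequency bins by their average expression across cells, and
#' each signature gene contributes `n_ctrl` control genes sampled (with
#' replacement) from its bin. Scores are therefore centred near zero for a
#' signature with no coherent signal.
#'
#' @param norm log-normalized gene x cell matrix (see [lognormalize()]).
#' @param gene_set character vector of signature genes; genes absent from the
#'   matrix are dropped (an error if none remain).
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl control genes sampled per signature gene (default 100).
#' @param seed integer seed for the control draw.
#' @return numeric score per cell, named by barcode, with attributes
#'   `genes_used` and `n_ctrl`/`n_bins`.
#' @export
module_score <- function(norm, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (inherits(norm, "glia_counts")) norm <- norm$counts
  present <- intersect(gene_set, rownames(norm))
  stop_if_not(length(present) >= 1,
              "no signature gene present in the matrix")
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, length(avg))
  ## equal-frequency bins of average expression; ties broken by gene name so
  ## the binning (and hence the score) is invariant to gene order
  rk <- integer(length(avg))
  rk[order(avg, names(avg))] <- seq_along(avg)
  br <- if (n_bins == 1) rep(1L, length(avg))
        else cut(rk, breaks = n_bins, labels = FALSE)
  names(br) <- names(avg)
  ctrl <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- names(br)[br == br[[g]]]
      sample(pool, n_ctrl, replace = TRUE)
    }))
  })
  sig_mean <- Matrix::colMeans(norm[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(norm[ctrl, , drop = FALSE])
  score <- sig_mean - ctrl_mean
  attr(score, "genes_used") <- present
  attr(score, "n_bins") <- n_bins
  attr(score, "n_ctrl") <- n_ctrl
  score
}

#' Assign cell-cycle phase from S and G2M module scores
#'
#' Phase is the higher-scoring program when that score is positive, else G1.
#' Exact S = G2M > 0 ties resolve to S (a declared, deterministic rule).
#'
#' @param scores_S,scores_G2M per-cell module scores on the same cells.
#' @return factor per cell with levels G1/S/G2M.
#' @export
assign_cell_cycle <- function(scores_S, scores_G2M) {
  stop_if_not(length(scores_S) == length(scores_G2M) &&
                all(names(scores_S) == names(scores_G2M)),
              "S and G2M scores must cover the same cells")
  phase <- ifelse(pmax(scores_S, scores_G2M) <= 0, "G1",
                  ifelse(scores_S >= scores_G2M, "S", "G2M"))
  factor(setNames(phase, names(scores_S)), levels = c("G1", "S", "G2M"))
}
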