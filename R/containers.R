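#' UMI count matrix with per-cell metadata
#'
#' Lightweight container pairing a sparse gene x cell UMI matrix with a
#' per-cell metadata table (sample, condition, age, sex, and any labels added
#' downstream). All gliakit single-cell functions accept either this container
#' or a bare matrix with gene rownames and barcode colnames.
#'
#' @param counts non-negative integer matrix, genes in rows, cells in columns;
#'   rownames are gene ids, colnames are cell barcodes.
#' @param cell_meta data.frame with one row per cell, rownames matching the
#'   barcodes (or a `barcode` column). May be `NULL`.
#' @return an object of class `glia_counts` with elements `counts` (dgCMatrix)
#'   and `cell_meta` (data.frame keyed by barcode).
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' gc <- count_matrix(m, data.frame(sample = rep("s1", 4), row.names = colnames(m)))
#' gc
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  m <- as_counts(counts)
  stop_if_not(all(m@x >= 0), "counts must be non-negative")
  stop_if_not(all(m@x == round(m@x)), "counts must be integral")
  stop_if_not(!anyDuplicated(colnames(m)), "cell barcodes must be unique")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = colnames(m))
  } else {
    if ("barcode" %in% names(cell_meta) && is.null(rownames(cell_meta)))
      rownames(cell_meta) <- cell_meta$barcode
    stop_if_not(all(colnames(m) %in% rownames(cell_meta)),
                "cell_meta must cover every barcode")
    cell_meta <- cell_meta[colnames(m), , drop = FALSE]
  }
  structure(list(counts = m, cell_meta = cell_meta), class = "glia_counts")
}

#' @exportS3Method base::print
print.glia_counts <- function(x, ...) {
  cat(sprintf("<glia_counts> %d genes x %d cells; meta: %s\n",
              nrow(x$counts), ncol(x$counts),
              if (ncol(x$cell_meta)) paste(names(x$cell_meta), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
dim.glia_counts <- function(x) dim(x$counts)

#' Subset a glia_counts object by genes and/or cells
#' @param x a `glia_counts` object.
#' @param genes,cells index vectors (names, integers or logicals); `NULL` keeps all.
#' @return a `glia_counts` object.
#' @export
subset_cells <- function(x, genes = NULL, cells = NULL) {
  stopifnot(inherits(x, "glia_counts"))
  m <- x$counts
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  count_matrix(m, x$cell_meta[colnames(m), , drop = FALSE])
}

#' Build a gene annotation table
#'
#' Flags mitochondrial genes (prefix `mt-`), ribosomal genes (prefix
#' `Rps`/`Rpl`), records the chromosome when known, and marks the confounder
#' genes excluded before subtype clustering (Sod1, Gm8566, Cmss1, Cdk8, Xist,
#' Gm42418, Gm424181, Malat1 by default).
#'
#' @param gene_ids character vector of gene names.
#' @param chromosome optional character vector (same length); `"Y"` entries
#'   drive the Y-gene metrics used for sex assignment.
#' @param excluded_confounders genes flagged for exclusion before subtype
#'   clustering (not before differential expression).
#' @return data.frame with columns `gene`, `chromosome`, `is_mito`, `is_ribo`,
#'   `is_excluded_confounder`, rownames = gene.
#' @export
gene_annotation <- function(gene_ids,
                            chromosome = NULL,
                            excluded_confounders = c("Sod1", "Gm8566", "Cmss1",
                                                     "Cdk8", "Xist", "Gm42418",
                                                     "Gm424181", "Malat1")) {
  stop_if_not(!anyDuplicated(gene_ids), "gene ids must be unique")
  chromosome <- chromosome %||% rep(NA_character_, length(gene_ids))
  stop_if_not(length(chromosome) == length(gene_ids),
              "chromosome must match gene_ids length")
  data.frame(
    gene = gene_ids,
    chromosome = chromosome,
    is_mito = startsWith(gene_ids, "mt-"),
    is_ribo = startsWith(gene_ids, "Rps") | startsWith(gene_ids, "Rpl"),
    is_excluded_confounder = gene_ids %in% excluded_confounders,
    row.names = gene_ids,
    stringsAsFactors = FALSE
  )
}

#' Image stack container
#'
#' A 3-D fluorescence stack with physical pixel geometry. Frames are stored as
#' an array indexed `[y, x, z]`; coordinates are physical micrometres with the
#' origin at the image corner and y pointing down.
#'
#' @param data numeric array `[y, x, z]` (a matrix is treated as one frame).
#' @param pixel_size_um pixel edge length in micrometres, `(dy, dx)` or one
#'   number for square pixels.
#' @param z_step_um spacing between frames in micrometres.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_um, z_step_um = 1) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stop_if_not(length(dim(data)) == 3, "data must be a [y, x, z] array")
  stop_if_not(all(data >= 0), "intensities must be non-negative")
  if (length(pixel_size_um) == 1) pixel_size_um <- rep(pixel_size_um, 2)
  stop_if_not(all(pixel_size_um > 0) && z_step_um > 0, "pixel sizes must be > 0")
  structure(list(data = data,
                 pixel_size_um = as.numeric(pixel_size_um),
                 z_step_um = as.numeric(z_step_um)),
            class = "image_stack")
}

#' @exportS3Method base::print
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d frames; pixel %.3g x %.3g um, z-step %.3g um\n",
              d[1], d[2], d[3], x$pixel_size_um[1], x$pixel_size_um[2], x$z_step_um))
  invisible(x)
}

n_frames <- function(stack) dim(stack$data)[3]
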