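#' Read a Matrix-Market count matrix with gene/barcode sidecars
#'
#' Reads the 10x-style triplet layout: `matrix.mtx`, `genes.tsv` (one gene id
#' per line, first column used), `barcodes.tsv`. An optional `cell_meta.csv`
#' keyed by barcode is attached when present.
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return a [count_matrix()] object.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  barcodes <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  dimnames(m) <- list(genes, barcodes)
  meta_path <- file.path(dir, "cell_meta.csv")
  meta <- if (file.exists(meta_path))
    read.csv(meta_path, row.names = 1, stringsAsFactors = FALSE) else NULL
  count_matrix(m, meta)
}

#' Write a count matrix in Matrix-Market triplet layout
#' @param x a `glia_counts` object or matrix with dimnames.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- as_counts(x)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  if (inherits(x, "glia_counts") && ncol(x$cell_meta))
    write.csv(x$cell_meta, file.path(dir, "cell_meta.csv"))
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member genes.
#' @param path GMT file path.
#' @return named list of character vectors; the description lines are kept in
#'   the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names <- vapply(parts, `[`, "", 1L)
  stop_if_not(!anyDuplicated(names), "duplicate gene-set names in %s", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  stop_if_not(all(lengths(sets) > 0), "empty gene set in %s", path)
  names(sets) <- names
  attr(sets, "description") <- setNames(vapply(parts, `[`, "", 2L), names)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "gliakit") {
  stop_if_not(length(names(sets)) == length(sets) && all(nzchar(names(sets))),
              "sets must be named")
  description <- rep_len(description, length(sets))
  writeLines(mapply(function(nm, d, genes)
    paste(c(nm, d, genes), collapse = "\t"),
    names(sets), description, sets), path)
  invisible(path)
}

#' Read a multi-page TIFF stack with its geometry sidecar
#'
#' Geometry comes from `<path>.json` (keys `pixel_size_um`, `z_step_um`)
#' written by [write_stack()].
#' @param path TIFF file path.
#' @return an [image_stack()].
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  sidecar <- paste0(path, ".json")
  stop_if_not(file.exists(sidecar), "missing sidecar metadata %s", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scale <- meta$intensity_scale %||% 1
  image_stack(arr * scale, meta$pixel_size_um, meta$z_step_um %||% 1)
}

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored as 16-bit; the scale needed to recover the original
#' values is recorded in the sidecar so read/write round-trips.
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$data)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(i) stack$data[, , i] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                            z_step_um = stack$z_step_um,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
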