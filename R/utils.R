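## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so simulators and permutation tests are
#' reproducible without disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## coerce to a column-sparse counts matrix with dimnames
as_counts <- function(x) {
  if (inherits(x, "glia_counts")) x <- x$counts
  m <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  stop_if_not(!is.null(rownames(m)) && !is.null(colnames(m)),
              "count matrix must carry gene rownames and barcode colnames")
  m
}
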