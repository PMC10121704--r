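## shared 256-bin histogram machinery for the automatic thresholds
## x: numeric vector/array, or list(counts, mids) for a precomputed histogram
as_histogram <- function(x, n_bins = 256) {
  if (is.list(x) && all(c("counts", "mids") %in% names(x)))
    return(list(counts = as.numeric(x$counts), mids = as.numeric(x$mids)))
  v <- as.numeric(x)
  rng <- range(v)
  stop_if_not(diff(rng) > 0, "constant image: no threshold exists")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  list(counts = counts, mids = (edges[-1] + edges[-(n_bins + 1)]) / 2)
}

#' Yen automatic threshold
#'
#' Histogram-based threshold maximizing Yen's maximum-correlation criterion
#' over all cut points of a 256-bin histogram:
#' `crit(t) = 2 log(P1 (1 - P1)) - log(sum_{i<=t} p_i^2 * sum_{i>t} p_i^2)`.
#' Pixels strictly above the returned level are foreground. Deterministic; the
#' first maximizing cut wins exact ties.
#'
#' @param x numeric image (any shape), an [image_stack()], or a precomputed
#'   histogram as `list(counts, mids)`.
#' @param n_bins histogram bins (default 256).
#' @return the threshold level (a bin center), with the criterion values in
#'   attribute `"criterion"`.
#' @export
yen_threshold <- function(x, n_bins = 256) {
  if (inherits(x, "image_stack")) x <- x$data
  h <- as_histogram(x, n_bins)
  pmf <- h$counts / sum(h$counts)
  P1 <- cumsum(pmf)
  P1sq <- cumsum(pmf^2)
  P2sq <- sum(pmf^2) - P1sq
  nb <- length(pmf)
  t <- seq_len(nb - 1)              # cut after bin t
  crit <- rep(-Inf, nb - 1)
  ok <- P1[t] > 0 & P1[t] < 1 & P1sq[t] > 0 & P2sq[t] > 0
  crit[ok] <- 2 * log(P1[t][ok] * (1 - P1[t][ok])) -
    log(P1sq[t][ok] * P2sq[t][ok])
  stop_if_not(any(is.finite(crit)), "degenerate histogram")
  best <- which.max(crit)
  structure(h$mids[best], criterion = crit)
}

#' Otsu automatic threshold
#'
#' Maximizes the between-class variance over all cut points of a 256-bin
#' histogram; the default per-frame mask threshold for the fiber volume
#' fraction. Pixels strictly above the level are foreground.
#'
#' @inheritParams yen_threshold
#' @return the threshold level (a bin center).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  if (inherits(x, "image_stack")) x <- x$data
  h <- as_histogram(x, n_bins)
  pmf <- h$counts / sum(h$counts)
  w1 <- cumsum(pmf)
  mu <- cumsum(pmf * h$mids)
  mu_t <- mu[length(mu)]
  nb <- length(pmf)
  t <- seq_len(nb - 1)
  w <- w1[t]
  between <- rep(-Inf, nb - 1)
  ok <- w > 0 & w < 1
  between[ok] <- (mu_t * w[ok] - mu[t][ok])^2 / (w[ok] * (1 - w[ok]))
  h$mids[which.max(between)]
}

auto_threshold <- function(x, method = c("otsu", "yen"), n_bins = 256) {
  method <- match.arg(method)
  if (method == "otsu") otsu_threshold(x, n_bins) else yen_threshold(x, n_bins)
}
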