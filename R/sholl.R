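#' Sholl profile of a binary mask
#'
#' Counts process crossings of concentric sampling circles around the soma.
#' Each circle is sampled at arc steps of at most half a pixel; an
#' intersection is a maximal contiguous run of foreground samples along the
#' circle, with the run closed across the angular seam. Background gaps
#' narrower than one pixel of arc are closed before counting (the raster
#' cannot represent an inter-process gap below the pixel size; such holes are
#' staircase aliasing), and samples landing exactly on a pixel edge read
#' foreground if either neighbouring pixel is foreground. A circle lying
#' fully inside foreground counts as one intersection. Radii whose circle
#' leaves the image bounds are reported as missing, not zero.
#'
#' @param mask binary 2-D matrix (`[y, x]`), e.g. a thresholded maximum
#'   projection.
#' @param soma_center_um `(x, y)` center in micrometres (origin at the image
#'   corner, y down); `NULL` uses the centroid of the largest foreground
#'   component.
#' @param pixel_size_um pixel edge in micrometres.
#' @param r_start,r_step Sholl geometry (defaults 5 and 5 um).
#' @param r_max largest radius (default: grows until the circle exits the
#'   image).
#' @return data.frame with `radius_um` and `intersections` (NA beyond image
#'   bounds); the center used is stored in attribute `"soma_center_um"`.
#' @export
sholl_profile <- function(mask, soma_center_um = NULL, pixel_size_um,
                          r_start = 5, r_step = 5, r_max = NULL) {
  stop_if_not(is.matrix(mask), "mask must be a 2-D matrix")
  stop_if_not(r_start > 0 && r_step > 0, "radii must be positive")
  mode(mask) <- "logical"
  px <- pixel_size_um
  ny <- nrow(mask); nx <- ncol(mask)
  if (is.null(soma_center_um)) {
    stop_if_not(any(mask), "empty mask and no soma center supplied")
    lab <- EBImage::imageData(EBImage::bwlabel(mask))
    big <- which.max(tabulate(lab[lab > 0]))
    rc <- arrayInd(which(lab == big), dim(lab))
    soma_center_um <- c((mean(rc[, 2]) - 0.5) * px, (mean(rc[, 1]) - 0.5) * px)
  }
  cx <- soma_center_um[1]; cy <- soma_center_um[2]
  stop_if_not(cx >= 0 && cx <= nx * px && cy >= 0 && cy <= ny * px,
              "soma center outside the image")
  ## largest radius fully inside the field
  r_inside <- min(cx, cy, nx * px - cx, ny * px - cy)
  if (is.null(r_max)) r_max <- floor(r_inside / r_step) * r_step
  radii <- seq(r_start, max(r_start, r_max), by = r_step)
  counts <- vapply(radii, function(r) {
    if (r > r_inside) return(NA_integer_)
    n_steps <- max(8L, ceiling(2 * pi * (r / px) / 0.5))
    ang <- seq(0, 2 * pi, length.out = n_steps + 1)[-(n_steps + 1)]
    xs <- cx + r * cos(ang); ys <- cy + r * sin(ang)
    ## pixels are closed regions: a sample landing exactly on a pixel edge
    ## (to sub-nanometre precision) belongs to both neighbours and reads
    ## foreground if either is foreground
    eps <- 1e-6
    j1 <- pmin(pmax(ceiling((xs - eps) / px), 1L), nx)
    j2 <- pmin(pmax(ceiling((xs + eps) / px), 1L), nx)
    i1 <- pmin(pmax(ceiling((ys - eps) / px), 1L), ny)
    i2 <- pmin(pmax(ceiling((ys + eps) / px), 1L), ny)
    fg <- mask[cbind(i1, j1)] | mask[cbind(i1, j2)] |
      mask[cbind(i2, j1)] | mask[cbind(i2, j2)]
    if (all(fg)) return(1L)
    if (!any(fg)) return(0L)
    ## close background gaps narrower than one pixel of arc (<= 2 samples at
    ## 0.5-px steps): the raster cannot carry an inter-process gap below the
    ## pixel size, so such holes are staircase aliasing, not separations
    rl <- rle(fg)
    fr <- which(!rl$values)
    if (all(rl$lengths[fr] <= 2L)) return(1L)  # only sub-pixel holes remain
    ## rotate the circular sequence to start inside the longest gap, then
    ## close the small gaps and count foreground runs linearly
    longest <- fr[which.max(rl$lengths[fr])]
    start <- if (longest == 1L) 1L
             else sum(rl$lengths[seq_len(longest - 1L)]) + 1L
    fg <- c(fg[start:length(fg)], fg[seq_len(start - 1L)])
    rl <- rle(fg)
    gap <- !rl$values & rl$lengths <= 2L
    gap[1L] <- FALSE
    rl$values[gap] <- TRUE
    rl <- rle(inverse.rle(rl))
    sum(rl$values)
  }, integer(1))
  out <- data.frame(radius_um = radii, intersections = counts)
  attr(out, "soma_center_um") <- soma_center_um
  out
}

#' Sholl analysis of an image stack
#'
#' The full procedure used for microglial morphology: maximum-intensity
#' projection, automatic thresholding to a binary mask, then [sholl_profile()]
#' starting 5 um from the soma with 5 um steps.
#'
#' @param stack an [image_stack()].
#' @param soma_center_um `(x, y)` um, or `NULL` to use the largest-component
#'   centroid.
#' @param method `"yen"` (default) or `"otsu"` projection threshold.
#' @param min_component_px connected components smaller than this are removed
#'   from the mask before counting; sub-resolution specks are noise, not
#'   processes (default 9 px, a 1.5 x 1.5 um blob at 0.5 um pixels; 0
#'   disables).
#' @inheritParams sholl_profile
#' @return as [sholl_profile()], with the threshold in attribute
#'   `"threshold"`.
#' @export
sholl_from_stack <- function(stack, soma_center_um = NULL,
                             method = c("yen", "otsu"),
                             r_start = 5, r_step = 5, r_max = NULL,
                             min_component_px = 9) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "image_stack"))
  proj <- max_projection(stack)
  thr <- auto_threshold(proj, method)
  mask <- proj > thr
  if (min_component_px > 0 && any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(mask))
    small <- which(tabulate(lab[lab > 0]) < min_component_px)
    mask[lab %in% small] <- FALSE
  }
  out <- sholl_profile(mask, soma_center_um,
                       pixel_size_um = mean(stack$pixel_size_um),
                       r_start = r_start, r_step = r_step, r_max = r_max)
  attr(out, "threshold") <- thr
  out
}
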