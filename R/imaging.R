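quant_result <- function(kind, value, per_unit = NULL, threshold = NA_real_,
                         flag = character()) {
  structure(list(kind = kind, value = value, per_unit = per_unit,
                 threshold = threshold, flag = flag),
            class = "quant_result")
}

#' @exportS3Method base::print
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result:%s> value = %.6g%s%s\n", x$kind, x$value,
              if (!is.na(x$threshold))
                sprintf(" (threshold %.4g)", x$threshold) else "",
              if (length(x$flag)) paste0(" [", paste(x$flag, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Maximum-intensity projection
#' @param stack an [image_stack()] or `[y, x, z]` array.
#' @return 2-D matrix, per-pixel maximum over z.
#' @export
max_projection <- function(stack) {
  arr <- if (inherits(stack, "image_stack")) stack$data else stack
  if (is.matrix(arr)) return(arr)
  d <- dim(arr)
  out <- arr[, , 1]
  for (k in seq_len(d[3])[-1]) out <- pmax(out, arr[, , k])
  out
}

#' Integrated density limited to the Yen threshold
#'
#' Computes the Yen threshold on the stack's intensity histogram and sums the
#' intensities of all suprathreshold voxels (the area x mean-of-suprathreshold
#' reading of "integrated density limited to threshold"). For per-animal
#' numbers, average the values of the animal's images with
#' [aggregate_quant()].
#'
#' @param stack an [image_stack()].
#' @return a `quant_result` with `kind = "integrated_density"`, the threshold
#'   used, and flag `"nothing_above_threshold"` when the value is 0.
#' @export
integrated_density_limited <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  thr <- yen_threshold(stack$data)
  above <- stack$data > thr
  val <- sum(stack$data[above])
  quant_result("integrated_density", val, threshold = as.numeric(thr),
               flag = if (!any(above)) "nothing_above_threshold" else character())
}

#' Average quantification values across images
#' @param results list of `quant_result` objects of one kind.
#' @return a `quant_result` whose value is the mean and whose `per_unit` holds
#'   the per-image values.
#' @export
aggregate_quant <- function(results) {
  kinds <- unique(vapply(results, `[[`, "", "kind"))
  stop_if_not(length(kinds) == 1, "mixed quantification kinds")
  vals <- vapply(results, `[[`, 0, "value")
  quant_result(kinds, mean(vals), per_unit = vals)
}

#' Substack of the brightest frames
#'
#' Ranks frames by mean intensity, keeps the top `n`, and preserves the
#' original z order; exact ties go to the lower z index. Fewer than `n`
#' frames returns all of them with a warning.
#'
#' @param stack an [image_stack()].
#' @param n frames to keep (default 20).
#' @return an [image_stack()]; selected indices in attribute `"frames"`.
#' @export
brightest_substack <- function(stack, n = 20) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_frames(stack)
  if (nz < n) {
    warning(sprintf("stack has %d < %d frames; keeping all", nz, n))
    n <- nz
  }
  means <- apply(stack$data, 3, mean)
  sel <- sort(order(-means, seq_len(nz))[seq_len(n)])
  out <- image_stack(stack$data[, , sel, drop = FALSE],
                     stack$pixel_size_um, stack$z_step_um)
  attr(out, "frames") <- sel
  out
}

#' Fiber volume fraction from the brightest substack
#'
#' Extracts the `n_frames` brightest frames, thresholds each frame
#' independently (Otsu by default, Yen selectable), measures the covered
#' fraction per frame, and reports the mean as the volume fraction. Frames
#' with no dynamic range are counted as fraction 0 and flagged.
#'
#' @param stack an [image_stack()].
#' @param n_frames substack size (default 20).
#' @param method `"otsu"` or `"yen"` per-frame threshold.
#' @return a `quant_result` with `kind = "volume_fraction"`, per-frame
#'   fractions in `per_unit`, and the per-frame thresholds in attribute
#'   `"thresholds"`.
#' @export
fiber_volume_fraction <- function(stack, n_frames = 20,
                                  method = c("otsu", "yen")) {
  method <- match.arg(method)
  sub <- brightest_substack(stack, n_frames)
  nz <- n_frames(sub)
  fractions <- numeric(nz)
  thresholds <- rep(NA_real_, nz)
  flags <- character()
  for (k in seq_len(nz)) {
    frame <- sub$data[, , k]
    if (diff(range(frame)) < sqrt(.Machine$double.eps)) {
      ## no dynamic range: a uniformly dark frame is blank, a uniformly
      ## bright one fully covered
      if (max(frame) == 0) {
        fractions[k] <- 0
        flags <- union(flags, "blank_frame")
      } else {
        fractions[k] <- 1
        flags <- union(flags, "saturated_frame")
      }
      next
    }
    thresholds[k] <- auto_threshold(frame, method)
    fractions[k] <- mean(frame > thresholds[k])
  }
  out <- quant_result("volume_fraction", mean(fractions),
                      per_unit = fractions, flag = flags)
  attr(out, "thresholds") <- thresholds
  attr(out, "frames") <- attr(sub, "frames")
  out
}

#' Count marker-positive nuclei and co-localization ratios
#'
#' Segments nuclei from the max-projected DAPI channel (Gaussian smoothing,
#' Otsu threshold, connected components filtered by area around the expected
#' nucleus size), then calls a nucleus positive for a marker when the mean
#' marker intensity inside its mask exceeds the marker's automatic threshold.
#' Reports per-marker percentages of DAPI+ nuclei and any requested
#' conditional ratios (e.g. CC3+ among APC+ cells).
#'
#' @param dapi DAPI channel, an [image_stack()].
#' @param markers named list of marker [image_stack()]s, co-registered with
#'   the DAPI channel (same geometry).
#' @param ratio_pairs list of `c(numerator_marker, denominator_marker)`
#'   conditional ratios.
#' @param nucleus_diameter_um expected nucleus diameter (default 10);
#'   components outside 0.25-4x the nominal disk area are discarded.
#' @param smooth_sigma_um Gaussian sigma for the DAPI projection (default a
#'   tenth of the nucleus diameter).
#' @param method `"otsu"` or `"yen"` marker threshold.
#' @return list with `n_nuclei`, `positivity` (data.frame: nucleus id,
#'   centroid, logical per marker), `percent` (named, marker+ / DAPI+ x 100),
#'   `ratios` (named `num|den` fractions), and `quant` (list of
#'   `quant_result`s for the ratios).
#' @export
count_positive_cells <- function(dapi, markers, ratio_pairs = list(),
                                 nucleus_diameter_um = 10,
                                 smooth_sigma_um = nucleus_diameter_um / 10,
                                 method = c("otsu", "yen")) {
  method <- match.arg(method)
  stopifnot(inherits(dapi, "image_stack"))
  for (m in markers) {
    stopifnot(inherits(m, "image_stack"))
    stop_if_not(all(dim(m$data)[1:2] == dim(dapi$data)[1:2]),
                "marker channel geometry differs from DAPI")
  }
  px <- mean(dapi$pixel_size_um)
  proj <- max_projection(dapi)
  sigma_px <- max(smooth_sigma_um / px, 0.5)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(proj),
                                          sigma = sigma_px))
  thr <- auto_threshold(sm, method)
  lab <- EBImage::imageData(EBImage::bwlabel(sm > thr))
  areas <- tabulate(lab[lab > 0])
  nominal <- pi * (nucleus_diameter_um / 2 / px)^2
  keep_ids <- which(areas >= 0.25 * nominal & areas <= 4 * nominal)
  stop_if_not(length(keep_ids) > 0, "no nuclei detected")
  marker_proj <- lapply(markers, max_projection)
  marker_thr <- lapply(marker_proj, function(mp) {
    if (diff(range(mp)) < sqrt(.Machine$double.eps)) Inf
    else auto_threshold(mp, method)
  })
  pos <- data.frame(nucleus = seq_along(keep_ids))
  cx <- numeric(length(keep_ids)); cy <- numeric(length(keep_ids))
  idx_list <- lapply(keep_ids, function(id) which(lab == id))
  rowcol <- lapply(idx_list, function(ii) arrayInd(ii, dim(lab)))
  pos$x_um <- vapply(rowcol, function(rc) mean(rc[, 2] - 0.5) * px, 0)
  pos$y_um <- vapply(rowcol, function(rc) mean(rc[, 1] - 0.5) * px, 0)
  for (mn in names(markers)) {
    mp <- marker_proj[[mn]]
    pos[[mn]] <- vapply(idx_list, function(ii)
      mean(mp[ii]) > marker_thr[[mn]], logical(1))
  }
  n <- length(keep_ids)
  percent <- vapply(names(markers), function(mn) 100 * mean(pos[[mn]]),
                    numeric(1))
  ratios <- list(); quants <- list()
  for (pr in ratio_pairs) {
    den <- sum(pos[[pr[2]]])
    val <- if (den > 0) sum(pos[[pr[1]]] & pos[[pr[2]]]) / den else NA_real_
    key <- paste(pr[1], pr[2], sep = "|")
    ratios[[key]] <- val
    quants[[key]] <- quant_result("count_ratio", val,
                                  flag = if (den == 0) "empty_denominator"
                                  else character())
  }
  list(n_nuclei = n, positivity = pos, percent = percent,
       ratios = unlist(ratios), quant = quants, threshold = thr)
}
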