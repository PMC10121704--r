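#' Configuration for the microscopy-stack simulators
#'
#' Field geometry mirrors the emulated confocal acquisitions: 212 x 212 um
#' fields, 30 um deep, square pixels. Noise is additive Gaussian on a flat
#' background; no optical PSF is modeled (ground truths are analytic).
#'
#' @param field_size_um `(x, y, z)` physical extents in micrometres.
#' @param pixel_size_um pixel edge in micrometres (square pixels).
#' @param n_frames number of z frames.
#' @param noise_sd additive Gaussian noise sd (intensity units, signal ~ 1).
#' @param background_level flat background intensity.
#' @param seed integer seed.
#' @return a `sim_image_config` list.
#' @export
sim_image_config <- function(field_size_um = c(212, 212, 30),
                             pixel_size_um = 0.5,
                             n_frames = 30L,
                             noise_sd = 0.02,
                             background_level = 0.05,
                             seed = 1L) {
  stop_if_not(pixel_size_um > 0, "pixel_size_um must be > 0")
  stop_if_not(n_frames >= 1, "n_frames must be >= 1")
  stop_if_not(noise_sd >= 0 && background_level >= 0,
              "noise and background must be non-negative")
  npx <- field_size_um[1:2] / pixel_size_um
  stop_if_not(max(abs(npx - round(npx))) < 1e-6,
              "field extent must be an integer number of pixels")
  structure(list(field_size_um = field_size_um,
                 pixel_size_um = pixel_size_um,
                 n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, background_level = background_level,
                 seed = as.integer(seed)),
            class = "sim_image_config")
}

## pixel-center coordinate grids (um), origin at corner, y down
grid_um <- function(nx, ny, px) {
  list(x = (seq_len(nx) - 0.5) * px, y = (seq_len(ny) - 0.5) * px)
}

## stamp a filled disk onto a [y, x] matrix; center (x, y) in um
stamp_disk <- function(mask, cx, cy, radius, px) {
  ny <- nrow(mask); nx <- ncol(mask)
  j0 <- max(1L, floor((cx - radius) / px)); j1 <- min(nx, ceiling((cx + radius) / px) + 1)
  i0 <- max(1L, floor((cy - radius) / px)); i1 <- min(ny, ceiling((cy + radius) / px) + 1)
  if (j0 > j1 || i0 > i1) return(mask)
  jj <- j0:j1; ii <- i0:i1
  xs <- (jj - 0.5) * px; ys <- (ii - 0.5) * px
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  mask[ii, jj][d2 <= radius^2] <- TRUE
  mask
}

## rasterize a constant-width polyline as a union of capsules (round caps):
## a pixel is foreground iff its center lies within width/2 of a segment
stamp_polyline <- function(mask, pts, width, px) {
  r <- width / 2
  ny <- nrow(mask); nx <- ncol(mask)
  for (s in seq_len(nrow(pts) - 1)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1, ]
    j0 <- max(1L, floor((min(p0[1], p1[1]) - r) / px))
    j1 <- min(nx, ceiling((max(p0[1], p1[1]) + r) / px) + 1)
    i0 <- max(1L, floor((min(p0[2], p1[2]) - r) / px))
    i1 <- min(ny, ceiling((max(p0[2], p1[2]) + r) / px) + 1)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    gx <- matrix((jj - 0.5) * px, length(ii), length(jj), byrow = TRUE)
    gy <- matrix((ii - 0.5) * px, length(ii), length(jj))
    d <- p1 - p0
    len2 <- sum(d * d)
    t <- if (len2 == 0) 0 else
      pmin(pmax(((gx - p0[1]) * d[1] + (gy - p0[2]) * d[2]) / len2, 0), 1)
    dist2 <- (gx - (p0[1] + t * d[1]))^2 + (gy - (p0[2] + t * d[2]))^2
    mask[ii, jj] <- mask[ii, jj] | (dist2 <= r^2)
  }
  mask
}

#' Analytic circle-crossing count for a set of polyline branches
#'
#' Counts intersection points of each sampling circle with the branch
#' centerlines by solving the segment/circle quadratic per segment. Roots are
#' counted on `[0, 1)` per segment (the final vertex of each branch is
#' included on its last segment) so shared vertices are not double counted.
#'
#' @param branches list of n x 2 matrices of `(x, y)` um vertices.
#' @param center `(x, y)` um circle center.
#' @param radii numeric radii (um).
#' @return integer vector of crossing counts per radius.
#' @export
circle_crossings <- function(branches, center, radii) {
  vapply(radii, function(r) {
    total <- 0L
    for (pts in branches) {
      nseg <- nrow(pts) - 1
      for (s in seq_len(nseg)) {
        d <- pts[s + 1, ] - pts[s, ]
        f <- pts[s, ] - center
        a <- sum(d * d); b <- 2 * sum(f * d); cc <- sum(f * f) - r^2
        if (a == 0) next
        disc <- b^2 - 4 * a * cc
        if (disc <= 0) next   # tangency not counted as a crossing
        sq <- sqrt(disc)
        for (t in c((-b - sq) / (2 * a), (-b + sq) / (2 * a))) {
          last <- s == nseg
          if (t >= 0 && (t < 1 || (last && t <= 1))) total <- total + 1L
        }
      }
    }
    total
  }, integer(1))
}

#' Simulate a microglia-like branching tree stack with analytic Sholl truth
#'
#' Renders a bright soma disk plus constant-width polyline branches onto a
#' noisy background, replicated over z with per-frame amplitude jitter. The
#' returned ground-truth profile is the analytic count of circle crossings of
#' the branch centerlines (the soma disk is not a branch).
#'
#' @param config a [sim_image_config()].
#' @param tree_spec list with `soma_center_um` (x, y), `soma_radius_um`,
#'   `branches` (list of n x 2 um polylines starting at the soma) and
#'   `branch_width_um`.
#' @param r_start,r_step,r_max Sholl geometry for the truth profile (um).
#' @return list with `stack` (an [image_stack()]), `profile` (data.frame
#'   radius_um / crossings), `soma_center_um`, and `mask` (the noiseless
#'   binary render).
#' @export
simulate_microglia_stack <- function(config, tree_spec,
                                     r_start = 5, r_step = 5, r_max = NULL) {
  stopifnot(inherits(config, "sim_image_config"))
  px <- config$pixel_size_um
  stop_if_not(tree_spec$branch_width_um >= px,
              "pixel size larger than branch width")
  nx <- round(config$field_size_um[1] / px)
  ny <- round(config$field_size_um[2] / px)
  for (pts in tree_spec$branches)
    stop_if_not(all(pts[, 1] >= 0 & pts[, 1] <= config$field_size_um[1] &
                      pts[, 2] >= 0 & pts[, 2] <= config$field_size_um[2]),
                "branch exits the field")
  with_seed(config$seed, {
    mask <- matrix(FALSE, ny, nx)
    ctr <- tree_spec$soma_center_um
    mask <- stamp_disk(mask, ctr[1], ctr[2], tree_spec$soma_radius_um, px)
    for (pts in tree_spec$branches)
      mask <- stamp_polyline(mask, pts, tree_spec$branch_width_um, px)
    if (is.null(r_max)) {
      reach <- max(vapply(tree_spec$branches, function(pts)
        max(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)), 0))
      r_max <- max(r_start, floor(reach / r_step) * r_step)
    }
    radii <- seq(r_start, r_max, by = r_step)
    profile <- data.frame(radius_um = radii,
                          crossings = circle_crossings(tree_spec$branches,
                                                       ctr, radii))
    arr <- array(0, c(ny, nx, config$n_frames))
    for (k in seq_len(config$n_frames)) {
      amp <- runif(1, 0.8, 1)
      frame <- config$background_level + amp * mask
      if (config$noise_sd > 0)
        frame <- frame + rnorm(length(frame), 0, config$noise_sd)
      arr[, , k] <- pmax(frame, 0)
    }
    list(stack = image_stack(arr, px,
                             config$field_size_um[3] / config$n_frames),
         profile = profile, soma_center_um = ctr, mask = mask)
  })
}

#' Random radial tree specification for the microglia simulator
#'
#' Draws `n_branches` polyline arms radiating from the soma with jittered but
#' monotonically increasing radial distance (so each arm crosses each circle
#' at most once) and a minimum angular separation that keeps rasterized arms
#' from merging near the soma.
#'
#' @param n_branches number of arms.
#' @param soma_center_um `(x, y)` um.
#' @param soma_radius_um soma radius (um).
#' @param length_range_um min/max arm length.
#' @param branch_width_um arm width.
#' @param min_sep_deg minimum angular separation between arms.
#' @param seed integer seed.
#' @return a `tree_spec` list for [simulate_microglia_stack()].
#' @export
random_tree_spec <- function(n_branches = 8,
                             soma_center_um = c(106, 106),
                             soma_radius_um = 4,
                             length_range_um = c(25, 45),
                             branch_width_um = 1.5,
                             min_sep_deg = 360 / n_branches * 0.8,
                             seed = 1L) {
  with_seed(seed, {
    ## jittered equal spacing guarantees the minimum separation exactly
    spacing <- 360 / n_branches
    jit <- max(0, (spacing - min_sep_deg) / 2)
    ang <- (seq(0, 360 - spacing, by = spacing) + runif(1, 0, 360) +
              runif(n_branches, -jit, jit)) * pi / 180
    branches <- lapply(ang, function(a) {
      len <- runif(1, length_range_um[1], length_range_um[2])
      ## land arm tips midway between 5-um sampling radii so the rounded
      ## raster cap (width/2 past the tip) cannot add a spurious crossing
      len <- floor(len / 5) * 5 + 2.5
      rr <- seq(soma_radius_um * 0.5, len, length.out = 6)
      aa <- a + cumsum(c(0, runif(5, -0.08, 0.08)))
      cbind(x = soma_center_um[1] + rr * cos(aa),
            y = soma_center_um[2] + rr * sin(aa))
    })
    list(soma_center_um = soma_center_um, soma_radius_um = soma_radius_um,
         branches = branches, branch_width_um = branch_width_um)
  })
}

#' Simulate a myelinated-fiber stack with recorded per-frame area fractions
#'
#' Each frame receives randomly oriented constant-width fiber segments until
#' the covered area fraction reaches `target_fraction` (within 0.5 percentage
#' points); the realized per-frame fraction is recorded as truth. Frame
#' amplitudes vary so brightest-substack selection is exercised.
#'
#' @param config a [sim_image_config()].
#' @param target_fraction desired covered fraction per frame, in (0, 1).
#' @param fiber_width_um fiber width.
#' @return list with `stack`, `truth` (data.frame frame / fraction), and
#'   `masks` (list of noiseless binary frames).
#' @export
simulate_fiber_stack <- function(config, target_fraction,
                                 fiber_width_um = 1.5) {
  stopifnot(inherits(config, "sim_image_config"))
  stop_if_not(target_fraction >= 0 && target_fraction < 1,
              "target_fraction must be in [0, 1)")
  px <- config$pixel_size_um
  nx <- round(config$field_size_um[1] / px)
  ny <- round(config$field_size_um[2] / px)
  fx <- config$field_size_um[1]; fy <- config$field_size_um[2]
  with_seed(config$seed, {
    masks <- vector("list", config$n_frames)
    arr <- array(0, c(ny, nx, config$n_frames))
    frac <- numeric(config$n_frames)
    for (k in seq_len(config$n_frames)) {
      mask <- matrix(FALSE, ny, nx)
      if (target_fraction > 0) {
        guard <- 0L
        repeat {
          cur <- mean(mask)
          if (cur >= target_fraction - 0.005) break
          guard <- guard + 1L
          if (guard > 20000L)
            stop("target fraction unreachable with this fiber width/field")
          ## long strokes far from target, short ones for the final approach
          len <- if (target_fraction - cur > 0.01) runif(1, 30, 60)
                 else runif(1, 4, 10)
          x0 <- runif(1, 0, fx); y0 <- runif(1, 0, fy)
          a <- runif(1, 0, pi)
          x1 <- min(max(x0 + len * cos(a), 0), fx)
          y1 <- min(max(y0 + len * sin(a), 0), fy)
          mask <- stamp_polyline(mask, rbind(c(x0, y0), c(x1, y1)),
                                 fiber_width_um, px)
        }
      }
      frac[k] <- mean(mask)
      masks[[k]] <- mask
      amp <- runif(1, 0.6, 1)
      frame <- config$background_level + amp * mask
      if (config$noise_sd > 0)
        frame <- frame + rnorm(length(frame), 0, config$noise_sd)
      arr[, , k] <- pmax(frame, 0)
    }
    list(stack = image_stack(arr, px,
                             config$field_size_um[3] / config$n_frames),
         truth = data.frame(frame = seq_len(config$n_frames), fraction = frac),
         masks = masks)
  })
}

#' Simulate a DAPI field with marker channels and per-nucleus truth
#'
#' Places non-overlapping disk nuclei (rejection sampling with a minimum
#' centre distance), renders a DAPI channel, and one channel per marker bright
#' over its designated nuclei. Marker positivity is assigned exactly:
#' `round(fraction * n)` nuclei per marker; a coexpression map draws one
#' marker's positives from another's (e.g. CC3 within APC).
#'
#' @param config a [sim_image_config()].
#' @param n_nuclei number of nuclei.
#' @param marker_positive_fraction named fractions in `[0, 1]` per marker.
#' @param coexpression named list: marker -> parent marker whose positives it
#'   must be drawn from.
#' @param nucleus_radius_um nucleus radius.
#' @return list with `channels` (named list of [image_stack()], including
#'   `DAPI`) and `truth` (data.frame: nucleus, x_um, y_um, one logical column
#'   per marker).
#' @export
simulate_nuclei_field <- function(config, n_nuclei,
                                  marker_positive_fraction,
                                  coexpression = list(),
                                  nucleus_radius_um = 4) {
  stopifnot(inherits(config, "sim_image_config"))
  stop_if_not(all(unlist(marker_positive_fraction) >= 0 &
                    unlist(marker_positive_fraction) <= 1),
              "marker fractions must be in [0, 1]")
  px <- config$pixel_size_um
  nx <- round(config$field_size_um[1] / px)
  ny <- round(config$field_size_um[2] / px)
  fx <- config$field_size_um[1]; fy <- config$field_size_um[2]
  r <- nucleus_radius_um
  min_dist <- 2 * r + 2           # 2 um clearance so segmentation separates
  with_seed(config$seed, {
    centers <- matrix(NA_real_, n_nuclei, 2)
    placed <- 0L; attempts <- 0L
    while (placed < n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > 2000L * n_nuclei)
        stop("nucleus packing failed: field too crowded")
      cx <- runif(1, r + 1, fx - r - 1); cy <- runif(1, r + 1, fy - r - 1)
      if (placed > 0) {
        d2 <- (centers[seq_len(placed), 1] - cx)^2 +
          (centers[seq_len(placed), 2] - cy)^2
        if (min(d2) < min_dist^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(cx, cy)
    }
    markers <- names(marker_positive_fraction)
    truth <- data.frame(nucleus = seq_len(n_nuclei),
                        x_um = centers[, 1], y_um = centers[, 2])
    pos <- list()
    for (m in markers) {
      k <- round(marker_positive_fraction[[m]] * n_nuclei)
      pool <- if (!is.null(coexpression[[m]])) which(pos[[coexpression[[m]]]])
              else seq_len(n_nuclei)
      stop_if_not(k <= length(pool),
                  "coexpression pool smaller than requested positives for %s", m)
      sel <- if (k > 0) sample(pool, k) else integer()
      pos[[m]] <- seq_len(n_nuclei) %in% sel
      truth[[m]] <- pos[[m]]
    }
    render <- function(which_nuclei) {
      mask <- matrix(FALSE, ny, nx)
      for (i in which_nuclei)
        mask <- stamp_disk(mask, centers[i, 1], centers[i, 2], r, px)
      arr <- array(0, c(ny, nx, config$n_frames))
      for (k in seq_len(config$n_frames)) {
        frame <- config$background_level + 1.0 * mask
        if (config$noise_sd > 0)
          frame <- frame + rnorm(length(frame), 0, config$noise_sd)
        arr[, , k] <- pmax(frame, 0)
      }
      image_stack(arr, px, config$field_size_um[3] / config$n_frames)
    }
    channels <- c(list(DAPI = render(seq_len(n_nuclei))),
                  setNames(lapply(markers, function(m) render(which(pos[[m]]))),
                           markers))
    list(channels = channels, truth = truth)
  })
}
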