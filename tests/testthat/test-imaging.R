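# independent naive evaluation of Yen's criterion for one cut point
yen_criterion_naive <- function(pmf, t) {
  p1 <- sum(pmf[1:t])
  p1sq <- sum(pmf[1:t]^2)
  p2sq <- sum(pmf[-(1:t)]^2)
  if (p1 <= 0 || p1 >= 1 || p1sq <= 0 || p2sq <= 0) return(-Inf)
  2 * log(p1 * (1 - p1)) - log(p1sq * p2sq)
}

test_that("Yen threshold equals exhaustive criterion maximization", {
  ## two-delta histogram: threshold strictly between the modes
  img <- c(rep(10, 500), rep(200, 500))
  thr <- yen_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)

  set.seed(41)
  for (i in 1:100) {                     # exhaustive-search oracle
    counts <- rpois(256, lambda = runif(1, 0.5, 50)) +
      if (runif(1) < 0.5) c(rep(0, 200), rpois(56, 30)) else 0
    if (sum(counts) == 0 || sum(counts > 0) < 2) next
    h <- list(counts = counts, mids = seq(0.5, 255.5, by = 1))
    thr <- as.numeric(yen_threshold(h))
    pmf <- counts / sum(counts)
    crits <- vapply(1:255, function(t) yen_criterion_naive(pmf, t),
                    numeric(1))
    expect_equal(thr, h$mids[which.max(crits)])
  }
})

test_that("Yen threshold shifts with the image intensities", {
  set.seed(42)
  img <- c(rnorm(2000, 40, 6), rnorm(800, 150, 15))
  t0 <- yen_threshold(img)
  t1 <- yen_threshold(img + 25)
  binw <- diff(range(img)) / 256
  expect_lt(abs((t1 - t0) - 25), binw + 1e-9)
  expect_error(yen_threshold(rep(3, 100)), "constant image")
})

test_that("integrated density sums suprathreshold voxels only", {
  arr <- array(0, c(8, 8, 4))
  arr[cbind(sample(1:8, 10, TRUE), sample(1:8, 10, TRUE),
            sample(1:4, 10, TRUE))] <- 100
  n_bright <- sum(arr == 100)
  st <- image_stack(arr, 0.5, 1)
  q <- integrated_density_limited(st)
  expect_equal(q$value, 100 * n_bright)      # zero background + bright voxels
  expect_lt(q$threshold, 100)

  q2 <- integrated_density_limited(image_stack(arr * 2, 0.5, 1))
  expect_equal(q2$value, 2 * q$value)        # linearity under doubling

  set.seed(43)
  rnd <- image_stack(array(runif(8 * 8 * 4, 0, 255), c(8, 8, 4)), 0.5, 1)
  qr <- integrated_density_limited(rnd)
  expect_equal(qr$value, sum(rnd$data[rnd$data > qr$threshold]))  # voxel loop
})

test_that("max projection is the per-pixel maximum", {
  one <- image_stack(matrix(1:9, 3), 1)
  expect_equal(max_projection(one), matrix(1:9, 3))
  a <- matrix(0, 3, 3); a[1, 1] <- 5
  b <- matrix(0, 3, 3); b[3, 3] <- 7
  expect_equal(max_projection(array(c(a, b), c(3, 3, 2))), pmax(a, b))
  set.seed(44)
  arr <- array(runif(5 * 4 * 6), c(5, 4, 6))
  mp <- max_projection(arr)
  for (i in 1:5) for (j in 1:4)
    expect_equal(mp[i, j], max(arr[i, j, ]))
})

test_that("Sholl profiles count crossings of sampled circles", {
  ## straight 2-px line through the center: 2 at every radius
  mask <- matrix(FALSE, 200, 200)
  mask[100:101, ] <- TRUE
  sp <- sholl_profile(mask, c(50, 50), pixel_size_um = 0.5, r_max = 40)
  expect_equal(sp$intersections, rep(2L, 8))

  empty <- matrix(FALSE, 100, 100)
  sp0 <- sholl_profile(empty, c(25, 25), pixel_size_um = 0.5, r_max = 20)
  expect_true(all(sp0$intersections == 0))

  ## radii whose circle exits the field are missing, not zero
  spna <- sholl_profile(mask, c(10, 50), pixel_size_um = 0.5, r_max = 40)
  expect_true(anyNA(spna$intersections))
  expect_error(sholl_profile(mask, c(500, 500), pixel_size_um = 0.5),
               "outside")
})

test_that("Sholl on synthetic trees equals the analytic ground truth", {
  for (sd in 1:3) {
    ts <- random_tree_spec(seed = sd)
    ms <- simulate_microglia_stack(sim_image_config(noise_sd = 0, seed = sd),
                                   ts)
    ## noiseless mask route: exact at every radius
    sp <- sholl_profile(ms$mask, ts$soma_center_um, pixel_size_um = 0.5,
                        r_max = max(ms$profile$radius_um))
    expect_equal(sp$intersections, ms$profile$crossings)
    ## full stack route (projection + threshold): exact at default noise too
    msn <- simulate_microglia_stack(sim_image_config(seed = sd), ts)
    spn <- sholl_from_stack(msn$stack, ts$soma_center_um,
                            r_max = max(msn$profile$radius_um))
    expect_equal(spn$intersections, msn$profile$crossings)
  }
})

test_that("brightest-substack selection ranks frames by mean", {
  set.seed(45)
  arr <- array(0, c(4, 4, 30))
  for (k in 1:30) arr[, , k] <- k        # strictly increasing means
  st <- image_stack(arr, 0.5, 1)
  sel <- brightest_substack(st, 20)
  expect_equal(attr(sel, "frames"), 11:30)

  flat <- image_stack(array(1, c(4, 4, 30)), 0.5, 1)
  expect_equal(attr(brightest_substack(flat, 20), "frames"), 1:20)

  rnd <- image_stack(array(runif(4 * 4 * 30), c(4, 4, 30)), 0.5, 1)
  sel_r <- attr(brightest_substack(rnd, 20), "frames")
  means <- apply(rnd$data, 3, mean)
  expect_equal(sel_r, sort(order(means, decreasing = TRUE)[1:20]))

  expect_warning(brightest_substack(image_stack(arr[, , 1:5], 0.5, 1), 20),
                 "keeping all")
})

test_that("fiber volume fraction recovers the planted coverage", {
  cfg <- sim_image_config(field_size_um = c(64, 64, 25), n_frames = 25,
                          seed = 46)
  fs <- simulate_fiber_stack(cfg, 0.25)
  vf <- fiber_volume_fraction(fs$stack, n_frames = 20)
  truth <- mean(fs$truth$fraction[attr(vf, "frames")])
  expect_lt(abs(vf$value - truth), 0.02)
  expect_equal(vf$value, mean(vf$per_unit))   # internal consistency

  full <- image_stack(array(1, c(8, 8, 20)), 0.5, 1)
  expect_equal(fiber_volume_fraction(full, 20)$value, 1)
  blank <- image_stack(array(0, c(8, 8, 20)), 0.5, 1)
  qb <- fiber_volume_fraction(blank, 20)
  expect_equal(qb$value, 0)
  expect_true("blank_frame" %in% qb$flag)
})

test_that("co-localization counts equal the planted truth on clean fields", {
  cfg <- sim_image_config(field_size_um = c(150, 150, 4), n_frames = 2,
                          noise_sd = 0, seed = 47)
  nf <- simulate_nuclei_field(cfg, 100, list(APC = 0.3, CC3 = 0.1),
                              coexpression = list(CC3 = "APC"),
                              nucleus_radius_um = 4)
  cc <- count_positive_cells(nf$channels$DAPI, nf$channels[c("APC", "CC3")],
                             ratio_pairs = list(c("CC3", "APC")),
                             nucleus_diameter_um = 8)
  expect_equal(cc$n_nuclei, 100)
  expect_equal(unname(cc$percent["APC"]), 30)
  expect_equal(unname(cc$ratios["CC3|APC"]), 1 / 3)

  ## no marker signal anywhere: zero positives
  zero <- image_stack(array(0, dim(nf$channels$DAPI$data)), 0.5,
                      nf$channels$DAPI$z_step_um)
  cz <- count_positive_cells(nf$channels$DAPI, list(M = zero),
                             nucleus_diameter_um = 8)
  expect_equal(unname(cz$percent["M"]), 0)

  bad <- image_stack(array(0, c(10, 10, 2)), 0.5, 1)
  expect_error(count_positive_cells(nf$channels$DAPI, list(M = bad)),
               "geometry")
})
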