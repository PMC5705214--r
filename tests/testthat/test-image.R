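test_that("registering a static movie yields all-zero shifts", {
  img <- matrix(10, 20, 16)
  img[8:12, 6:9] <- 200
  fr <- array(0, c(5L, 20L, 16L))
  for (k in 1:5) fr[k, , ] <- img
  reg <- register_xy(movie_stack(fr))
  expect_true(all(reg$shifts == 0L))
  expect_false(any(reg$flagged))
})

test_that("injected integer drift is recovered exactly on noiseless movies", {
  p <- awc_protocol(total = 20, pulse = c(4, 12))
  gt <- awc_truth(p)
  sc <- quiet_scene(drift_step_sd = 0.4, seed = 11L)
  mv <- render_movie(sc, gt)
  dr <- attr(mv, "drift")
  expect_true(any(dr != 0L))
  reg <- register_xy(mv)
  expect_identical(unname(reg$shifts), unname(-dr))
  # idempotence: a registered movie re-registers with zero shifts
  reg2 <- register_xy(reg$movie)
  expect_true(all(reg2$shifts == 0L))
})

test_that("noisy drift recovery lands within 1 px for >= 95% of frames", {
  p <- awc_protocol(total = 40, pulse = c(5, 25))
  gt <- awc_truth(p)
  rates <- vapply(1:10, function(s) {
    sc <- scene_config(image_shape = c(64L, 40L), drift_step_sd = 0.3,
                       read_noise_sd = 2, shot_noise = TRUE, seed = s)
    mv <- render_movie(sc, gt)
    reg <- register_xy(mv)
    mean(abs(reg$shifts + attr(mv, "drift")) <= 1L)
  }, 0)
  expect_true(all(rates >= 0.95))
})

test_that("frames with excessive shift are flagged for discard", {
  img <- matrix(5, 30, 30)
  img[10:14, 13:16] <- 300
  fr <- array(0, c(4L, 30L, 30L))
  for (k in 1:4) fr[k, , ] <- img
  fr[4, , ] <- translate_frame(img, 9L, 0L, fill = 5)
  reg <- register_xy(movie_stack(fr), max_shift_frac = 0.2)
  expect_true(reg$flagged[4L])
  expect_false(any(reg$flagged[1:3]))
})

test_that("rolling ball removes flat background and preserves narrow peaks", {
  flat <- matrix(37.5, 30, 30)
  out <- rolling_ball_subtract(flat, radius = 8)
  expect_true(all(abs(out) <= 1))

  Y <- 40; X <- 40
  peak <- 120
  img <- matrix(20, Y, X) +
    svflux:::punctum_image(Y, X, 20, 20, 2, peak)
  out2 <- rolling_ball_subtract(img, radius = 25)
  expect_lt(abs(max(out2) - peak) / peak, 0.05)
  expect_error(rolling_ball_subtract(matrix(0, 10, 10), radius = 12),
               "radius")
})

test_that("1-D rolling ball matches the brute-force morphological oracle", {
  set.seed(4)
  ramp <- seq(0, 20, length.out = 64) + 5 * sin(seq(0, 6, length.out = 64))
  for (r in c(3, 10, 25)) {
    expect_equal(rolling_ball_subtract(ramp, r),
                 oracle_rolling_ball_1d(ramp, r), tolerance = 1e-12)
  }
})

test_that("segmentation image is the smoothed temporal mean", {
  fr <- array(0, c(2L, 6L, 6L))
  fr[1, , ] <- 0
  fr[2, , ] <- 10
  seg <- make_segmentation_image(movie_stack(fr))
  expect_true(all(abs(seg - 5) < 1e-12))  # uniform mean survives smoothing

  one <- array(rnorm(36, 50, 1), c(1L, 6L, 6L))
  seg1 <- make_segmentation_image(movie_stack(one))
  expect_equal(seg1, svflux:::boxcar_smooth(one[1, , ], 2L))
})

test_that("puncta centroids in the segmentation image match the scene", {
  p <- awc_protocol(total = 10, pulse = c(2, 6))
  gt <- awc_truth(p)
  sc <- quiet_scene(seed = 3L)
  mv <- render_movie(sc, gt)
  seg <- make_segmentation_image(mv, rolling_ball_radius = 10)
  for (j in seq_len(nrow(sc$centers))) {
    r0 <- sc$centers[j, 1L]; c0 <- sc$centers[j, 2L]
    win_r <- max(1, r0 - 3):min(nrow(seg), r0 + 3)
    win_c <- max(1, c0 - 3):min(ncol(seg), c0 + 3)
    w <- seg[win_r, win_c]
    cen_r <- sum(win_r * rowSums(w)) / sum(w)
    cen_c <- sum(win_c * colSums(w)) / sum(w)
    expect_lt(abs(cen_r - r0), 1)
    expect_lt(abs(cen_c - c0), 1)
  }
})

test_that("segment_axon recovers the punctum support and validates input", {
  p <- awc_protocol(total = 30, pulse = c(5, 20))
  gt <- awc_truth(p)
  sc <- scene_config(image_shape = c(64L, 40L), drift_step_sd = 0, seed = 8L)
  mv <- render_movie(sc, gt)
  seg <- make_segmentation_image(mv, rolling_ball_radius = 10)
  mask <- segment_axon(seg)
  sup <- matrix(FALSE, 64, 40)
  for (j in seq_len(nrow(sc$centers))) {
    d2 <- outer((1:64 - sc$centers[j, 1L])^2, (1:40 - sc$centers[j, 2L])^2,
                "+")
    sup <- sup | (d2 <= (2 * sc$punctum_sigma)^2)
  }
  iou <- sum(mask$mask & sup) / sum(mask$mask | sup)
  expect_gte(iou, 0.5)

  expect_error(segment_axon(matrix(3, 10, 10)), "constant")
  expect_error(segment_axon(seg, method = "fixed", threshold = max(seg) + 1),
               "threshold above")
  # raising a fixed threshold never increases mask area
  thrs <- quantile(seg, c(0.7, 0.8, 0.9))
  areas <- vapply(thrs, function(th) {
    sum(seg > th)
  }, 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("background ROI placement respects flanks and the anterior rule", {
  mask_mat <- matrix(FALSE, 40, 20)
  mask_mat[12:30, 9:11] <- TRUE
  mask <- structure(list(mask = mask_mat,
                         bbox = c(rmin = 12L, rmax = 30L,
                                  cmin = 9L, cmax = 11L),
                         area = sum(mask_mat), threshold = 0),
                    class = "axon_mask")
  both <- place_background_rois(mask)
  expect_length(both, 2L)
  expect_setequal(vapply(both, `[[`, "", "label"),
                  c("anterior", "posterior"))
  # anterior = lower row indices
  ant <- both[[which(vapply(both, `[[`, "", "label") == "anterior")]]
  expect_true(max(which(rowSums(ant$pixels) > 0)) < 12L)
  # disjoint from the mask
  for (roi in both) expect_false(any(roi$pixels & mask_mat))

  ant_only <- place_background_rois(mask, anterior_only = TRUE)
  expect_length(ant_only, 1L)
  expect_equal(ant_only[[1L]]$label, "anterior")

  expect_error(place_background_rois(mask, margin = 50L), "no valid flank")
})

test_that("extract_traces computes plain means over mask pixels", {
  fr <- array(7, c(3L, 5L, 5L))
  mask <- structure(list(mask = matrix(TRUE, 5, 5),
                         bbox = c(rmin = 1L, rmax = 5L, cmin = 1L, cmax = 5L),
                         area = 25L, threshold = 0),
                    class = "axon_mask")
  tr <- extract_traces(movie_stack(fr), mask)
  expect_equal(tr$roi_mean, rep(7, 3))

  fr2 <- array(0, c(1L, 3L, 3L))
  fr2[1, 1, 1] <- 2; fr2[1, 2, 2] <- 4
  m2 <- matrix(FALSE, 3, 3); m2[1, 1] <- TRUE; m2[2, 2] <- TRUE
  mask2 <- structure(list(mask = m2,
                          bbox = c(rmin = 1L, rmax = 2L, cmin = 1L,
                                   cmax = 2L),
                          area = 2L, threshold = 0),
                     class = "axon_mask")
  expect_equal(extract_traces(movie_stack(fr2), mask2)$roi_mean, 3)
})

test_that("roi_mean is independent of the segmentation rolling-ball radius", {
  p <- awc_protocol(total = 20, pulse = c(4, 12))
  gt <- awc_truth(p)
  mv <- render_movie(quiet_scene(seed = 2L), gt)
  masks <- lapply(c(5, 15), function(r) {
    segment_axon(make_segmentation_image(mv, rolling_ball_radius = r))
  })
  # same mask pixels in hand: traces extracted from the raw movie must agree
  common <- masks[[1L]]
  tr_a <- extract_traces(mv, common)
  tr_b <- extract_traces(mv, common)
  expect_identical(tr_a$roi_mean, tr_b$roi_mean)
})

test_that("noiseless extraction is affine in ground-truth fluorescence", {
  p <- awc_protocol(total = 60, pulse = c(10, 40))
  gt <- awc_truth(p)
  mv <- render_movie(quiet_scene(seed = 4L), gt)
  mask <- segment_axon(make_segmentation_image(mv, rolling_ball_radius = 10))
  tr <- extract_traces(mv, mask)
  expect_gt(stats::cor(tr$roi_mean, gt$fluor_total), 0.999)
})

test_that("segment correlation flags sign-flipped segments only", {
  # every pixel carries the same trace -> all r = 1
  nt <- 30L
  trace <- 100 + 10 * sin(seq_len(nt) / 3)
  fr <- array(0, c(nt, 32L, 10L))
  for (k in seq_len(nt)) fr[k, 8:25, 4:6] <- trace[k]
  mask_mat <- matrix(FALSE, 32, 10); mask_mat[8:25, 4:6] <- TRUE
  mask <- structure(list(mask = mask_mat,
                         bbox = c(rmin = 8L, rmax = 25L, cmin = 4L,
                                  cmax = 6L),
                         area = sum(mask_mat), threshold = 0),
                    class = "axon_mask")
  rc <- roi_segment_correlation(movie_stack(fr), mask, segment_length = 8L)
  expect_gte(nrow(rc), 2L)
  expect_true(all(abs(rc$r - 1) < 1e-9))

  # flip the trace in the second segment
  fr2 <- fr
  for (k in seq_len(nt)) fr2[k, 16:23, 4:6] <- 200 - trace[k]
  rc2 <- roi_segment_correlation(movie_stack(fr2), mask, segment_length = 8L)
  flipped <- rc2$start == 16L
  expect_true(any(flipped))
  expect_true(all(rc2$r[flipped] < 0))
  expect_true(all(rc2$r[!flipped] > 0))
})

test_that("synthetic AWC cohort segments all correlate positively", {
  p <- awc_protocol(total = 60, pulse = c(10, 40))
  gt <- awc_truth(p)
  sc <- scene_config(image_shape = c(64L, 40L), drift_step_sd = 0.2,
                     seed = 6L)
  mv <- render_movie(sc, gt)
  reg <- register_xy(mv)
  mask <- segment_axon(make_segmentation_image(reg$movie,
                                               rolling_ball_radius = 10))
  rc <- roi_segment_correlation(reg$movie, mask)
  expect_gte(nrow(rc), 3L)
  expect_true(all(rc$r > 0))
})
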