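#' Movie stack container
#'
#' A time-lapse movie: a `T x Y x X` array of non-negative intensities
#' (counts) with a frame interval and nominal camera bit depth.
#'
#' @param frames numeric array `T x Y x X`.
#' @param frame_interval seconds per frame.
#' @param bit_depth camera bit depth (default 14).
#' @return object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_interval = 0.2, bit_depth = 14L) {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, dim(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L,
            dim(frames)[1L] >= 1L, frame_interval > 0)
  if (any(frames < 0)) stop("movie intensities must be >= 0")
  structure(list(frames = frames, frame_interval = frame_interval,
                 bit_depth = as.integer(bit_depth)),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d frames of %dx%d px, %.3f s/frame, %d-bit\n",
              d[1L], d[2L], d[3L], x$frame_interval, x$bit_depth))
  invisible(x)
}

#' Synthetic imaging scene configuration
#'
#' Describes how ground-truth fluorescence is rendered into a movie: a row of
#' Gaussian puncta along the axon axis on an autofluorescent background with
#' optional linear bleaching, frame-to-frame integer random-walk drift,
#' Poisson shot noise and Gaussian read noise, clipped to the camera range.
#'
#' Punctum centers are placed deterministically, evenly spaced along the
#' central line of the chosen axis over the `axon_span` fraction of the
#' image, leaving headroom for drift and for background strips clear of the
#' axon's fluorescence tails.
#'
#' @param image_shape `c(Y, X)` image size in pixels.
#' @param n_puncta number of synaptic puncta.
#' @param punctum_sigma Gaussian sigma of each punctum, pixels.
#' @param punctum_amplitudes relative punctum weights (recycled/normalized);
#'   default equal.
#' @param axon_axis `"vertical"` (along rows) or `"horizontal"`.
#' @param axon_span fraction of the long axis covered by puncta,
#'   `c(lo, hi)`.
#' @param background_level autofluorescent background, counts.
#' @param bleach_slope fractional change of background per second (<= 0;
#'   e.g. -0.01/120 is a 1% drop per 2 min).
#' @param drift_step_sd SD of the per-frame drift step, pixels; steps are
#'   rounded to integers so registration can recover them exactly.
#' @param axon_line_frac amplitude of the diffuse axonal ridge connecting the
#'   puncta, as a fraction of the mean punctum peak (default 0.15; reporter
#'   between synaptic puncta is dim but continuous).
#' @param read_noise_sd additive Gaussian read noise SD, counts.
#' @param shot_noise apply Poisson shot noise (default `TRUE`).
#' @param max_intensity saturation level, counts (14-bit default 16383).
#' @param seed integer seed for drift and noise.
#' @return object of class `scene_config` (punctum centers in `$centers`,
#'   one `(row, col)` per punctum, 1-based).
#' @export
scene_config <- function(image_shape = c(64L, 32L),
                         n_puncta = 6L,
                         punctum_sigma = 1.5,
                         punctum_amplitudes = NULL,
                         axon_axis = c("vertical", "horizontal"),
                         axon_span = c(0.25, 0.75),
                         background_level = 100,
                         bleach_slope = 0,
                         drift_step_sd = 0,
                         axon_line_frac = 0.15,
                         read_noise_sd = 2,
                         shot_noise = TRUE,
                         max_intensity = 16383,
                         seed = 1L) {
  axon_axis <- match.arg(axon_axis)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            n_puncta >= 1L, punctum_sigma > 0, background_level > 0,
            axon_line_frac >= 0,
            bleach_slope <= 0, drift_step_sd >= 0, read_noise_sd >= 0,
            max_intensity > 0)
  if (is.null(punctum_amplitudes)) punctum_amplitudes <- rep(1, n_puncta)
  w <- rep_len(as.numeric(punctum_amplitudes), n_puncta)
  if (any(w <= 0)) stop("punctum amplitudes must be > 0")
  stopifnot(length(axon_span) == 2L, axon_span[1L] < axon_span[2L],
            axon_span[1L] > 0, axon_span[2L] < 1)
  Y <- as.integer(image_shape[1L]); X <- as.integer(image_shape[2L])
  along <- if (axon_axis == "vertical") Y else X
  across <- if (axon_axis == "vertical") X else Y
  pos <- round(seq(axon_span[1L] * along, axon_span[2L] * along,
                   length.out = n_puncta))
  mid <- round((across + 1) / 2)
  centers <- if (axon_axis == "vertical") {
    cbind(row = pos, col = rep(mid, n_puncta))
  } else {
    cbind(row = rep(mid, n_puncta), col = pos)
  }
  if (any(centers[, 1L] < 1 | centers[, 1L] > Y |
          centers[, 2L] < 1 | centers[, 2L] > X)) {
    stop("punctum centers fall outside the image")
  }
  structure(list(image_shape = c(Y, X), n_puncta = as.integer(n_puncta),
                 punctum_sigma = punctum_sigma,
                 punctum_weights = w / sum(w), centers = centers,
                 axon_axis = axon_axis, background_level = background_level,
                 axon_line_frac = axon_line_frac,
                 bleach_slope = bleach_slope, drift_step_sd = drift_step_sd,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 max_intensity = max_intensity, seed = as.integer(seed)),
            class = "scene_config")
}

# separable 2-D Gaussian with peak `amp` at (r0, c0)
punctum_image <- function(Y, X, r0, c0, sigma, amp) {
  gy <- exp(-((seq_len(Y) - r0)^2) / (2 * sigma^2))
  gx <- exp(-((seq_len(X) - c0)^2) / (2 * sigma^2))
  amp * (gy %o% gx)
}

# dim Gaussian ridge along the axon axis spanning the punctum extent
axon_ridge_image <- function(scene, d_row, d_col, amp) {
  Y <- scene$image_shape[1L]; X <- scene$image_shape[2L]
  sigma <- scene$punctum_sigma
  if (scene$axon_axis == "vertical") {
    lo <- min(scene$centers[, 1L]) + d_row
    hi <- max(scene$centers[, 1L]) + d_row
    mid <- scene$centers[1L, 2L] + d_col
    along <- seq_len(Y)
    prof <- ifelse(along < lo, exp(-((along - lo)^2) / (2 * sigma^2)),
                   ifelse(along > hi, exp(-((along - hi)^2) / (2 * sigma^2)),
                          1))
    across <- exp(-((seq_len(X) - mid)^2) / (2 * sigma^2))
    amp * (prof %o% across)
  } else {
    lo <- min(scene$centers[, 2L]) + d_col
    hi <- max(scene$centers[, 2L]) + d_col
    mid <- scene$centers[1L, 1L] + d_row
    along <- seq_len(X)
    prof <- ifelse(along < lo, exp(-((along - lo)^2) / (2 * sigma^2)),
                   ifelse(along > hi, exp(-((along - hi)^2) / (2 * sigma^2)),
                          1))
    across <- exp(-((seq_len(Y) - mid)^2) / (2 * sigma^2))
    amp * (across %o% prof)
  }
}

#' Render a ground-truth trace into a synthetic movie
#'
#' Each frame is `background_level * (1 + bleach_slope * t)` plus Gaussian
#' puncta whose summed peak amplitude equals `fluor_total(t)`, translated by a
#' cumulative integer random-walk drift, then Poisson shot noise and additive
#' read noise, clipped to `[0, max_intensity]`.
#'
#' @param scene a [scene_config()].
#' @param truth a `ground_truth` from [simulate_sv_fluorescence()].
#' @return a [movie_stack()] with attribute `"drift"` (a `T x 2` integer
#'   matrix of cumulative `(d_row, d_col)` offsets, first row `(0, 0)`).
#' @export
render_movie <- function(scene, truth) {
  stopifnot(inherits(scene, "scene_config"), inherits(truth, "ground_truth"))
  nt <- length(truth$time)
  if (nt < 1L) stop("ground truth has no frames")
  Y <- scene$image_shape[1L]; X <- scene$image_shape[2L]

  # room left for drift before any punctum center leaves the field of view
  room <- c(-(min(scene$centers[, 1L]) - 1L), Y - max(scene$centers[, 1L]),
            -(min(scene$centers[, 2L]) - 1L), X - max(scene$centers[, 2L]))
  if (room[1L] > 0L || room[2L] < 0L || room[3L] > 0L || room[4L] < 0L) {
    stop("puncta start outside the field of view")
  }
  if (room[1L] > room[2L] || room[3L] > room[4L]) {
    stop("puncta leave the field of view under worst-case drift")
  }
  set.seed(scene$seed)
  steps <- matrix(0L, nt, 2L)
  if (scene$drift_step_sd > 0 && nt > 1L) {
    steps[-1L, ] <- matrix(
      as.integer(round(stats::rnorm(2L * (nt - 1L), 0, scene$drift_step_sd))),
      nt - 1L, 2L)
  }
  # cumulative integer random walk, reflected at the bounds so puncta stay
  # in view for every seed (the recorded trajectory is the walk as applied)
  drift <- matrix(0L, nt, 2L)
  for (ax in 1:2) {
    lo <- room[2L * ax - 1L]; hi <- room[2L * ax]
    pos <- 0L
    for (k in seq_len(nt)) {
      pos <- pos + steps[k, ax]
      if (pos < lo) pos <- lo
      if (pos > hi) pos <- hi
      drift[k, ax] <- pos
    }
  }
  colnames(drift) <- c("d_row", "d_col")

  rows <- outer(drift[, 1L], scene$centers[, 1L], "+")
  cols <- outer(drift[, 2L], scene$centers[, 2L], "+")

  frames <- array(0, dim = c(nt, Y, X))
  for (k in seq_len(nt)) {
    img <- matrix(scene$background_level *
                    (1 + scene$bleach_slope * truth$time[k]), Y, X)
    amps <- scene$punctum_weights * truth$fluor_total[k]
    for (j in seq_len(scene$n_puncta)) {
      img <- img + punctum_image(Y, X, rows[k, j], cols[k, j],
                                 scene$punctum_sigma, amps[j])
    }
    if (scene$axon_line_frac > 0) {
      img <- img + axon_ridge_image(scene, drift[k, 1L], drift[k, 2L],
                                    scene$axon_line_frac * mean(amps))
    }
    if (scene$shot_noise) {
      img <- matrix(stats::rpois(Y * X, pmax(img, 0)), Y, X)
    }
    if (scene$read_noise_sd > 0) {
      img <- img + stats::rnorm(Y * X, 0, scene$read_noise_sd)
    }
    frames[k, , ] <- pmin(pmax(img, 0), scene$max_intensity)
  }

  out <- movie_stack(frames, truth$protocol$frame_interval, 14L)
  attr(out, "drift") <- drift
  out
}

#' Generate a multi-group cohort of synthetic trials
#'
#' Builds reproducible trials for several groups (e.g. wild-type-like vs
#' perturbed), scaling exocytosis and/or retrieval rates per group. Each trial
#' gets its own seed derived from the master seed so trials are independent
#' and individually reproducible. A group may set `k_exo_scale = 0` to
#' emulate abolished release (as with tetanus-toxin cleavage of the release
#' machinery).
#'
#' @param groups list of group descriptors, each a list with `name`,
#'   `n_trials`, and optional `k_exo_scale` (default 1, may be 0) and
#'   `k_ret_scale` (default 1, must be > 0).
#' @param protocol a [stimulus_protocol()] shared by all trials.
#' @param ca a [calcium_params()].
#' @param sv an [sv_cycle_params()] (per-group rates scaled from this).
#' @param output `"traces"` (fast; measured fluorescence = fluor_total plus
#'   Gaussian noise of SD `trace_noise_sd`) or `"movies"` (full rendering via
#'   [render_movie()] using `scene`).
#' @param scene a [scene_config()], required for `output = "movies"`.
#' @param trace_noise_sd measurement noise for `output = "traces"`, counts
#'   (default 150, about 1% of the default baseline fluorescence — typical
#'   single-trial dF/F noise).
#' @param seed master integer seed.
#' @return list with `trials` (each: `group`, `trial`, `seed`, `protocol`,
#'   `truth`, and `recording` data.frame or `movie`) and `manifest`
#'   (one row per trial with the latent kinetic parameters).
#' @export
make_cohort <- function(groups, protocol, ca = calcium_params(),
                        sv = sv_cycle_params(),
                        output = c("traces", "movies"), scene = NULL,
                        trace_noise_sd = 150, seed = 1L) {
  output <- match.arg(output)
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (output == "movies" && is.null(scene)) {
    stop("`scene` is required for output = 'movies'")
  }
  total <- sum(vapply(groups, function(g) as.integer(g$n_trials), 1L))
  if (total < 1L) stop("zero trials requested")

  trials <- vector("list", total)
  rows <- vector("list", total)
  idx <- 0L
  for (g in groups) {
    stopifnot(!is.null(g$name), !is.null(g$n_trials))
    kes <- if (is.null(g$k_exo_scale)) 1 else g$k_exo_scale
    krs <- if (is.null(g$k_ret_scale)) 1 else g$k_ret_scale
    if (kes < 0) stop("k_exo_scale must be >= 0")
    if (krs <= 0) stop("k_ret_scale must be > 0")
    sv_g <- sv
    sv_g$k_exo_basal <- sv$k_exo_basal * kes
    sv_g$k_exo_ca_gain <- sv$k_exo_ca_gain * kes
    sv_g$k_ret_basal <- sv$k_ret_basal * krs
    sv_g$k_ret_fast <- sv$k_ret_fast * krs
    for (i in seq_len(as.integer(g$n_trials))) {
      idx <- idx + 1L
      trial_seed <- as.integer((as.numeric(seed) + 104729 * idx) %% 2147483647)
      ca_tr <- simulate_calcium(protocol, ca, seed = trial_seed)
      truth <- simulate_sv_fluorescence(protocol, sv_g, ca_tr,
                                        ca_baseline = ca$baseline)
      tr <- list(group = g$name, trial = i, seed = trial_seed,
                 protocol = protocol, truth = truth)
      if (output == "movies") {
        sc <- scene
        sc$seed <- trial_seed
        tr$movie <- render_movie(sc, truth)
      } else {
        set.seed(trial_seed)
        tr$recording <- data.frame(
          time_s = truth$time,
          fluor = truth$fluor_total +
            stats::rnorm(length(truth$time), 0, trace_noise_sd))
      }
      trials[[idx]] <- tr
      rows[[idx]] <- data.frame(
        group = g$name, trial = i, seed = trial_seed,
        k_exo_basal = sv_g$k_exo_basal, k_exo_ca_gain = sv_g$k_exo_ca_gain,
        k_ret_basal = sv_g$k_ret_basal, k_ret_fast = sv_g$k_ret_fast,
        pool_size = sv_g$pool_size, fluor_scale = sv_g$fluor_scale,
        dark_offset = sv_g$dark_offset)
    }
  }
  list(trials = trials, manifest = do.call(rbind, rows))
}
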