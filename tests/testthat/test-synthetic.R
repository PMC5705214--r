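test_that("stimulus protocols validate their pulse structure", {
  p <- stimulus_protocol(list(c(10, 70)), "awc_like", total_duration = 100)
  expect_equal(n_frames(p), 500L)
  expect_equal(frame_times(p)[1:3], c(0, 0.2, 0.4))

  expect_error(stimulus_protocol(list(c(10, 5)), "awc_like", 100),
               "t_on < t_off")
  expect_error(stimulus_protocol(list(c(10, 60), c(50, 80)), "awc_like", 100),
               "non-overlapping")
  expect_error(stimulus_protocol(list(c(10, 120)), "awc_like", 100),
               "within")
  expect_error(stimulus_protocol(list(), "awc_like", total_duration = 0),
               "positive")
})

test_that("calcium without stimulus is flat at baseline", {
  p <- stimulus_protocol(list(), "awc_like", total_duration = 30)
  ca <- simulate_calcium(p)
  expect_equal(ca, rep(calcium_params()$baseline, n_frames(p)))
})

test_that("off-type calcium overshoot peaks ~1 s after pulse end", {
  p <- awc_protocol(total = 120, pulse = c(10, 70))
  ca <- simulate_calcium(p)
  tt <- frame_times(p)
  in_pulse <- tt >= 11 & tt < 70
  expect_true(all(ca[in_pulse] < calcium_params()$baseline))
  post <- tt > 70 & tt < 85
  t_peak <- tt[post][which.max(ca[post])] - 70
  expect_gte(t_peak, 0.4)
  expect_lte(t_peak, 1.6)
  expect_gt(max(ca[post]), calcium_params()$baseline)
})

test_that("overshoot amplitude is monotone in stimulus duration", {
  params <- calcium_params()
  amps <- vapply(c(10, 20, 60, 180), function(d) {
    p <- stimulus_protocol(list(c(5, 5 + d)), "awc_like",
                           total_duration = d + 30)
    ca <- simulate_calcium(p, params)
    max(ca) - params$baseline
  }, 0)
  expect_true(all(diff(amps) >= -1e-9))
  # configured gain map evaluated directly
  g10 <- svflux:::eval_overshoot_gain(params, 10)
  g60 <- svflux:::eval_overshoot_gain(params, 60)
  expect_lte(g10, g60)
})

test_that("on-type calcium rises during the pulse and returns to baseline", {
  p <- ash_protocol()
  ca <- simulate_calcium(p)
  tt <- frame_times(p)
  expect_gt(max(ca[tt > 12 & tt < 40]), 1.5)
  expect_lt(max(abs(ca[tt > 60] - 1)), 0.05)
})

test_that("constant-rate surface pool reaches the closed-form steady state", {
  p <- stimulus_protocol(list(), "awc_like", total_duration = 400)
  sv <- sv_cycle_params()
  gt <- simulate_sv_fluorescence(p, sv, rep(1, n_frames(p)), s0 = 1)
  s_star <- sv$k_exo_basal * sv$pool_size / sv$k_ret_basal
  expect_lt(abs(utils::tail(gt$surface_pool, 1) - s_star) / s_star, 0.01)
})

test_that("shutting off exocytosis yields a clean 1/k_ret exponential decay", {
  p <- stimulus_protocol(list(), "awc_like", total_duration = 60)
  sv <- sv_cycle_params(k_exo_basal = 1e-12, k_exo_ca_gain = 0)
  gt <- simulate_sv_fluorescence(p, sv, rep(1, n_frames(p)), s0 = 18)
  fit <- fit_decay(gt$surface_pool, gt$time, 1L)
  expect_lt(abs(fit$tau - 1 / sv$k_ret_basal) / (1 / sv$k_ret_basal), 0.01)
})

test_that("AWC-like fluorescence falls during odor and recovers fast-then-slow", {
  p <- awc_protocol()
  gt <- awc_truth(p)
  tt <- gt$time
  during <- gt$fluor_total[tt >= 11 & tt < 70]
  expect_true(all(diff(during) < 1e-9))
  # fast initial rise just after removal, slower later
  rate_early <- mean(diff(gt$fluor_total[tt >= 70.2 & tt <= 72]))
  rate_late <- mean(diff(gt$fluor_total[tt >= 85 & tt <= 95]))
  expect_gt(rate_early, 0)
  expect_gt(rate_early, 3 * abs(rate_late))
})

test_that("surface pool stays within conservation bounds", {
  p <- dual_pulse_protocol()
  sv <- sv_cycle_params()
  ca <- simulate_calcium(p)
  gt <- simulate_sv_fluorescence(p, sv, ca)
  k_exo_max <- sv$k_exo_basal + sv$k_exo_ca_gain * max(ca - 1, 0)
  expect_true(all(gt$surface_pool >= 0))
  expect_true(all(gt$surface_pool <=
                    k_exo_max * sv$pool_size / sv$k_ret_basal + 1e-9))
})

test_that("retrieval acceleration reverts exactly after the hold window", {
  p <- awc_protocol(total = 160, pulse = c(10, 70))
  sv <- sv_cycle_params()
  ca <- simulate_calcium(p)
  gt <- simulate_sv_fluorescence(p, sv, ca)
  tt <- gt$time
  supra <- tt[ca > sv$accel_ca_threshold]
  last_supra <- max(supra)
  after <- tt > last_supra + sv$accel_window
  expect_true(length(supra) > 0)
  expect_true(all(gt$k_ret[after] == sv$k_ret_basal))
  # and fast retrieval while the window is live
  live <- tt >= last_supra & tt <= last_supra + sv$accel_window
  expect_true(all(gt$k_ret[live] == sv$k_ret_fast))
})

test_that("sv_cycle_params rejects invalid rates and windows", {
  expect_error(sv_cycle_params(k_ret_basal = 0))
  expect_error(sv_cycle_params(k_ret_fast = 1 / 30), "k_ret_fast")
  expect_error(sv_cycle_params(accel_window = 80), "70")
  expect_error(
    simulate_sv_fluorescence(awc_protocol(), sv_cycle_params(), rep(1, 3)),
    "length")
})

test_that("rendered movies are deterministic and proportional to truth", {
  p <- awc_protocol(total = 30, pulse = c(5, 20))
  gt <- awc_truth(p)
  sc <- quiet_scene(seed = 5L)
  m1 <- render_movie(sc, gt)
  m2 <- render_movie(sc, gt)
  expect_identical(m1$frames, m2$frames)

  # noiseless: signal (above background) scales exactly with fluor_total
  sig <- apply(m1$frames, 1L, function(f) sum(f - sc$background_level))
  ratio <- sig / sig[1L]
  expected <- gt$fluor_total / gt$fluor_total[1L]
  expect_true(all(abs(ratio - expected) < 1e-3))
})

test_that("a punctum-free region bleaches at the configured linear slope", {
  p <- stimulus_protocol(list(), "awc_like", total_duration = 120)
  gt <- awc_truth(p)
  sc <- scene_config(image_shape = c(64L, 40L), drift_step_sd = 0,
                     bleach_slope = -0.01 / 120, read_noise_sd = 0,
                     shot_noise = TRUE, seed = 2L)
  mv <- render_movie(sc, gt)
  corner <- apply(mv$frames[, 1:6, 1:6], 1L, mean)
  fit <- stats::lm.fit(cbind(1, gt$time), corner)
  slope_frac <- fit$coefficients[2L] / sc$background_level
  expect_lt(abs(slope_frac - sc$bleach_slope),
            3 * sqrt(sc$background_level / 36 / length(corner)) /
              stats::sd(gt$time) / sc$background_level)
})

test_that("render_movie rejects puncta that cannot stay in view", {
  p <- awc_protocol(total = 5, pulse = c(1, 3))
  gt <- awc_truth(p)
  sc <- quiet_scene()
  sc$centers[1L, 1L] <- 0L  # force an out-of-bounds punctum
  expect_error(render_movie(sc, gt), "field of view")
})

test_that("cohorts are reproducible and sized as requested", {
  p <- awc_protocol()
  groups <- list(list(name = "wt", n_trials = 3L),
                 list(name = "mut", n_trials = 3L, k_exo_scale = 0.5))
  c1 <- make_cohort(groups, p, seed = 7L)
  c2 <- make_cohort(groups, p, seed = 7L)
  expect_equal(nrow(c1$manifest), 6L)
  expect_identical(c1$trials[[4L]]$recording, c2$trials[[4L]]$recording)
  expect_error(make_cohort(list(list(name = "none", n_trials = 0L)), p),
               "zero trials")
})

test_that("abolished exocytosis (TeTx-like) responses sit at the noise floor", {
  p <- awc_protocol()
  sv <- sv_cycle_params()
  coh <- make_cohort(list(list(name = "tetx", n_trials = 12L,
                               k_exo_scale = 0)), p, sv = sv, seed = 5L)
  peaks <- vapply(coh$trials, function(tr) {
    corr <- compute_dff(tr$recording$fluor, tr$recording$time_s, p)
    abs(peak_response(corr$dff, corr$time, 70, window = 30,
                      direction = "up")$peak)
  }, 0)
  # independent null: the same statistic on pure measurement noise around
  # the abolished baseline (dark offset only)
  tt <- frame_times(p)
  null_peaks <- vapply(1:12, function(s) {
    set.seed(s + 900)
    f <- sv$dark_offset + rnorm(length(tt), 0, 150)
    corr <- compute_dff(f, tt, p)
    abs(peak_response(corr$dff, corr$time, 70, window = 30,
                      direction = "up")$peak)
  }, 0)
  expect_lt(mean(peaks), 2 * mean(null_peaks))

  # and far below a wild-type response
  wt <- make_cohort(list(list(name = "wt", n_trials = 6L)), p, sv = sv,
                    seed = 5L)
  wt_peaks <- vapply(wt$trials, function(tr) {
    corr <- compute_dff(tr$recording$fluor, tr$recording$time_s, p)
    abs(peak_response(corr$dff, corr$time, 70, window = 30,
                      direction = "up")$peak)
  }, 0)
  expect_lt(mean(peaks), 0.25 * mean(wt_peaks))
})

test_that("halving exocytosis halves the absolute fluorescence response", {
  p <- awc_protocol()
  groups <- list(list(name = "wt", n_trials = 20L),
                 list(name = "half", n_trials = 20L, k_exo_scale = 0.5))
  coh <- make_cohort(groups, p, trace_noise_sd = 50, seed = 3L)
  drop_counts <- function(tr) {
    f <- tr$recording$fluor
    tt <- tr$recording$time_s
    base <- mean(f[tt < 10])
    base - min(f[tt >= 10 & tt <= 70])  # absolute drop during stimulus
  }
  drops <- vapply(coh$trials, drop_counts, 0)
  grp <- vapply(coh$trials, `[[`, "", "group")
  ratio <- mean(drops[grp == "half"]) / mean(drops[grp == "wt"])
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
})
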