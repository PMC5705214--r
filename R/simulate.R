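#' Calcium dynamics parameters
#'
#' Parameters of the phenomenological calcium model driving the synaptic
#' vesicle cycle simulator. OFF-type (AWC-like) neurons sit at `baseline`,
#' drop to `suppressed_level` during the stimulus, and show a transient
#' overshoot above baseline after stimulus removal whose amplitude grows with
#' stimulus duration. ON-type (ASH-like) neurons rise during the stimulus and
#' relax back afterwards.
#'
#' @param baseline resting calcium, arbitrary units (a.u.).
#' @param suppressed_level calcium during the stimulus for OFF-type neurons;
#'   must be below `baseline`.
#' @param overshoot_gain monotone map from stimulus duration (s) to
#'   overshoot/response amplitude (a.u.): a two-column `data.frame`
#'   (`duration`, `amplitude`) interpolated linearly and clamped at the ends.
#' @param overshoot_rise_time time to overshoot peak after stimulus removal,
#'   seconds (default 1 s).
#' @param overshoot_decay_tau decay time constant of the overshoot, seconds.
#' @param transition_tau first-order relaxation time constant for stimulus
#'   on/off transitions, seconds.
#' @return object of class `calcium_params`.
#' @export
calcium_params <- function(baseline = 1,
                           suppressed_level = 0.2,
                           overshoot_gain = default_overshoot_gain(),
                           overshoot_rise_time = 1,
                           overshoot_decay_tau = 10,
                           transition_tau = 0.5) {
  stopifnot(is.numeric(baseline), baseline > 0,
            is.numeric(suppressed_level), suppressed_level < baseline,
            suppressed_level >= 0,
            overshoot_rise_time > 0, overshoot_decay_tau > 0,
            transition_tau > 0)
  g <- as.data.frame(overshoot_gain)
  if (!all(c("duration", "amplitude") %in% names(g))) {
    stop("`overshoot_gain` needs columns `duration` and `amplitude`")
  }
  g <- g[order(g$duration), , drop = FALSE]
  if (is.unsorted(g$amplitude)) {
    stop("`overshoot_gain` must be monotone non-decreasing in duration")
  }
  structure(list(baseline = baseline, suppressed_level = suppressed_level,
                 overshoot_gain = g,
                 overshoot_rise_time = overshoot_rise_time,
                 overshoot_decay_tau = overshoot_decay_tau,
                 transition_tau = transition_tau),
            class = "calcium_params")
}

#' @rdname calcium_params
#' @export
default_overshoot_gain <- function() {
  data.frame(duration = c(0, 10, 20, 60, 180),
             amplitude = c(0.5, 0.8, 1.2, 2.0, 2.5))
}

# evaluate the monotone duration -> amplitude map (clamped linear interpolation)
eval_overshoot_gain <- function(params, duration) {
  g <- params$overshoot_gain
  if (nrow(g) == 1L) return(rep(g$amplitude, length(duration)))
  stats::approx(g$duration, g$amplitude, xout = duration, rule = 2)$y
}

# overshoot kernel: rises to its peak within ~rise_time, decays with tau_d.
# Normalized so its maximum is 1.
overshoot_kernel <- function(t, rise_time, tau_d) {
  tau_r <- rise_time / 5
  h <- (1 - exp(-pmax(t, 0) / tau_r)) * exp(-pmax(t, 0) / tau_d)
  tpk <- tau_r * log(1 + tau_d / tau_r)
  hmax <- (1 - exp(-tpk / tau_r)) * exp(-tpk / tau_d)
  ifelse(t >= 0, h / hmax, 0)
}

#' Simulate a calcium trace for a stimulus protocol
#'
#' OFF-type (AWC-like): calcium relaxes to `suppressed_level` during each
#' pulse and back to `baseline` afterwards, plus an additive post-pulse
#' overshoot whose amplitude is the configured monotone function of pulse
#' duration and which peaks about `overshoot_rise_time` seconds after pulse
#' end. ON-type (ASH-like): calcium rises toward
#' `baseline + overshoot_gain(duration)` during each pulse and relaxes back to
#' baseline with `overshoot_decay_tau` after the pulse ends.
#'
#' The trace is deterministic unless `noise_sd > 0`.
#'
#' @param protocol a [stimulus_protocol()].
#' @param params a [calcium_params()].
#' @param seed integer seed used when `noise_sd > 0`.
#' @param noise_sd SD of additive Gaussian noise (a.u.), default 0.
#' @return numeric calcium trace (a.u.), one value per frame.
#' @export
simulate_calcium <- function(protocol, params = calcium_params(),
                             seed = 1L, noise_sd = 0) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(params, "calcium_params"))
  nt <- n_frames(protocol)
  if (nt < 1L) stop("protocol has zero duration")
  tt <- frame_times(protocol)
  dt <- protocol$frame_interval
  off_type <- protocol$neuron_class == "awc_like"
  pl <- protocol$pulses

  # first-order relaxation toward a piecewise-constant target
  ca <- numeric(nt)
  ca[1L] <- params$baseline
  in_pulse <- frames_in_pulse(protocol)
  amp_of <- function(i) eval_overshoot_gain(params, pl$t_off[i] - pl$t_on[i])
  for (k in seq_len(nt - 1L)) {
    if (in_pulse[k + 1L]) {
      target <- if (off_type) params$suppressed_level else {
        i <- which(pl$t_on <= tt[k + 1L] & tt[k + 1L] < pl$t_off)[1L]
        params$baseline + amp_of(i)
      }
      tau <- params$transition_tau
    } else {
      # both classes relax back to baseline quickly once the stimulus state
      # changes; the slow component of OFF-type recovery is the additive
      # overshoot below, and lingering ON-type effects on retrieval are
      # carried by the acceleration hold window, not by slow calcium decay
      target <- params$baseline
      tau <- params$transition_tau
    }
    ca[k + 1L] <- target + (ca[k] - target) * exp(-dt / tau)
  }

  if (off_type && nrow(pl) > 0L) {
    for (i in seq_len(nrow(pl))) {
      amp <- amp_of(i)
      h <- amp * overshoot_kernel(tt - pl$t_off[i],
                                  params$overshoot_rise_time,
                                  params$overshoot_decay_tau)
      if (i < nrow(pl)) {
        # the next odor application re-suppresses calcium: quench the
        # remaining overshoot with the fast transition time constant
        t_next <- pl$t_on[i + 1L]
        after <- tt >= t_next
        h_at <- amp * overshoot_kernel(t_next - pl$t_off[i],
                                       params$overshoot_rise_time,
                                       params$overshoot_decay_tau)
        h[after] <- h_at * exp(-(tt[after] - t_next) / params$transition_tau)
      }
      ca <- ca + h
    }
  }

  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    ca <- ca + stats::rnorm(nt, 0, noise_sd)
  }
  ca
}

#' Synaptic vesicle cycle parameters
#'
#' Rates of the two-pool exo/endocytosis model. Vesicles fuse (exocytose) at
#' rate `k_exo(t) * V` moving reporter to the bright surface pool `S`, and are
#' retrieved (endocytosis + reacidification, which re-quenches the reporter)
#' at rate `k_ret(t) * S`. Exocytosis is calcium-coupled piecewise linearly
#' about the calcium baseline; retrieval switches from `k_ret_basal` to
#' `k_ret_fast` for `accel_window` seconds after calcium exceeds
#' `accel_ca_threshold` (activity-dependent acceleration of retrieval, which
#' must outlast activity by less than 70 s).
#'
#' Defaults place the basal retrieval time constant at 18 s and the
#' accelerated one at 8 s, the tonic/elevated-calcium values measured for
#' AWC-like and ASH-like neurons.
#'
#' @param pool_size V, vesicle-equivalents available for release.
#' @param k_exo_basal basal exocytosis rate constant, 1/s.
#' @param k_exo_ca_gain increase in exocytosis rate per a.u. of calcium above
#'   baseline, (1/s)/a.u.
#' @param k_ret_basal basal retrieval rate, 1/s (default 1/18).
#' @param k_ret_fast accelerated retrieval rate, 1/s (default 1/8); must be
#'   `>= k_ret_basal` (equality disables the acceleration).
#' @param accel_window duration of the accelerated-retrieval state after the
#'   last supra-threshold calcium sample, seconds; must be < 70.
#' @param accel_ca_threshold calcium level (a.u.) that engages acceleration.
#' @param fluor_scale fluorescence counts per surface vesicle-equivalent.
#' @param dark_offset counts contributed by reporter in non-cycling neutral
#'   compartments (adds to total fluorescence but never changes).
#' @param finite_pool if `TRUE`, exocytosis draws down the pool
#'   (`flux = k_exo * max(V - S, 0)`); default `FALSE` (non-depleting pool).
#' @return object of class `sv_cycle_params`.
#' @export
sv_cycle_params <- function(pool_size = 100,
                            k_exo_basal = 0.01,
                            k_exo_ca_gain = 0.02,
                            k_ret_basal = 1 / 18,
                            k_ret_fast = 1 / 8,
                            accel_window = 60,
                            accel_ca_threshold = 1.5,
                            fluor_scale = 3000,
                            dark_offset = 500,
                            finite_pool = FALSE) {
  stopifnot(pool_size > 0,
            k_exo_basal >= 0, k_exo_ca_gain >= 0,
            k_ret_basal > 0, k_ret_fast > 0,
            fluor_scale > 0, dark_offset >= 0)
  if (k_ret_fast < k_ret_basal) stop("`k_ret_fast` must be >= `k_ret_basal`")
  if (!(accel_window > 0 && accel_window < 70)) {
    stop("`accel_window` must be in (0, 70) seconds")
  }
  structure(list(pool_size = pool_size, k_exo_basal = k_exo_basal,
                 k_exo_ca_gain = k_exo_ca_gain, k_ret_basal = k_ret_basal,
                 k_ret_fast = k_ret_fast, accel_window = accel_window,
                 accel_ca_threshold = accel_ca_threshold,
                 fluor_scale = fluor_scale, dark_offset = dark_offset,
                 finite_pool = finite_pool),
            class = "sv_cycle_params")
}

#' Simulate surface-pool and fluorescence dynamics
#'
#' Integrates the surface pool `dS/dt = k_exo(t) * V - k_ret(t) * S` with a
#' fixed-step explicit scheme at `substeps` sub-intervals per frame
#' (`substeps >= 5`). The exocytosis rate is coupled piecewise linearly to
#' calcium around `ca_baseline`: facilitation `k_exo_basal +
#' k_exo_ca_gain * (ca - ca_baseline)` above baseline, proportional
#' suppression `k_exo_basal * ca / ca_baseline` below it. Retrieval runs at
#' `k_ret_fast` until `accel_window` seconds have elapsed since the last
#' calcium sample above `accel_ca_threshold`, and at `k_ret_basal` otherwise.
#'
#' Total fluorescence is `fluor_scale * S + dark_offset`.
#'
#' @param protocol a [stimulus_protocol()].
#' @param sv an [sv_cycle_params()].
#' @param calcium calcium trace (a.u.), one value per frame
#'   (see [simulate_calcium()]).
#' @param ca_baseline calcium baseline used by the coupling (a.u.).
#' @param s0 initial surface pool; default is the basal steady state
#'   `k_exo_basal * V / k_ret_basal`.
#' @param substeps integration sub-steps per frame (minimum 5).
#' @param seed kept for interface symmetry; the integration is deterministic.
#' @return object of class `ground_truth` with fields `time`, `surface_pool`,
#'   `calcium`, `fluor_total`, `k_ret` (instantaneous retrieval rate at each
#'   frame), `params`, `protocol`.
#' @export
simulate_sv_fluorescence <- function(protocol, sv = sv_cycle_params(),
                                     calcium, ca_baseline = 1,
                                     s0 = NULL, substeps = 5L, seed = 1L) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            inherits(sv, "sv_cycle_params"))
  nt <- n_frames(protocol)
  if (length(calcium) != nt) {
    stop("`calcium` length must equal the protocol frame count (",
         nt, "), got ", length(calcium))
  }
  substeps <- max(5L, as.integer(substeps))
  dt <- protocol$frame_interval / substeps
  tt <- frame_times(protocol)

  k_exo_of <- function(ca) {
    if (ca >= ca_baseline) {
      sv$k_exo_basal + sv$k_exo_ca_gain * (ca - ca_baseline)
    } else {
      sv$k_exo_basal * max(ca, 0) / ca_baseline
    }
  }

  S <- numeric(nt)
  k_ret_tr <- numeric(nt)
  s <- if (is.null(s0)) sv$k_exo_basal * sv$pool_size / sv$k_ret_basal else s0
  accel_until <- -Inf
  for (k in seq_len(nt)) {
    if (calcium[k] > sv$accel_ca_threshold) {
      accel_until <- tt[k] + sv$accel_window
    }
    k_ret_now <- if (tt[k] <= accel_until) sv$k_ret_fast else sv$k_ret_basal
    S[k] <- s
    k_ret_tr[k] <- k_ret_now
    ke <- k_exo_of(calcium[k])
    for (j in seq_len(substeps)) {
      influx <- if (sv$finite_pool) {
        ke * max(sv$pool_size - s, 0)
      } else {
        ke * sv$pool_size
      }
      s <- s + dt * (influx - k_ret_now * s)
      if (s < 0) s <- 0
    }
  }

  structure(list(time = tt, surface_pool = S, calcium = calcium,
                 fluor_total = sv$fluor_scale * S + sv$dark_offset,
                 k_ret = k_ret_tr, params = sv, protocol = protocol),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d frames, surface pool %.2f-%.2f, fluor %.0f-%.0f counts\n",
    length(x$time), min(x$surface_pool), max(x$surface_pool),
    min(x$fluor_total), max(x$fluor_total)))
  invisible(x)
}
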