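# Shared fixtures and independent oracles, built in code at test time.

awc_protocol <- function(total = 110, pulse = c(10, 70)) {
  stimulus_protocol(list(pulse), "awc_like", total_duration = total)
}

ash_protocol <- function(total = 90, pulse = c(10, 40)) {
  stimulus_protocol(list(pulse), "ash_like", total_duration = total)
}

dual_pulse_protocol <- function() {
  stimulus_protocol(list(c(10, 70), c(80, 100)), "awc_like",
                    total_duration = 140)
}

# noiseless AWC ground truth shared by several image-pipeline tests
awc_truth <- function(protocol = awc_protocol(), sv = sv_cycle_params()) {
  ca <- simulate_calcium(protocol)
  simulate_sv_fluorescence(protocol, sv, ca)
}

quiet_scene <- function(...) {
  args <- utils::modifyList(
    list(image_shape = c(64L, 40L), drift_step_sd = 0, read_noise_sd = 0,
         shot_noise = FALSE, bleach_slope = 0),
    list(...))
  do.call(scene_config, args)
}

# --- independent oracles -------------------------------------------------

# brute-force grayscale opening of a 1-D profile by a circular (ball)
# structuring element: direct double loop over offsets, same Inf-padding
# boundary convention as the implementation under test
oracle_rolling_ball_1d <- function(v, radius) {
  n <- length(v)
  r <- as.integer(ceiling(radius))
  offs <- (-r:r)[abs(-r:r) <= radius]
  b <- sqrt(radius^2 - offs^2) - radius
  ero <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (q in seq_along(offs)) {
      j <- i + offs[q]
      if (j >= 1 && j <= n) vals <- c(vals, v[j] - b[q])
    }
    ero[i] <- min(vals)
  }
  open <- numeric(n)
  for (i in seq_len(n)) {
    vals <- c()
    for (q in seq_along(offs)) {
      j <- i + offs[q]
      if (j >= 1 && j <= n) vals <- c(vals, ero[j] + b[q])
    }
    open[i] <- max(vals)
  }
  pmax(v - open, 0)
}

# two-pass SEM: explicit mean, then explicit sum of squared deviations
oracle_sem <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1)) / sqrt(n)
}
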