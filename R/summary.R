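#' Classify a trial as a responder
#'
#' A trial responds when the magnitude of its baseline-referenced peak
#' response within the response window reaches `k_sd` times the SD of the
#' pre-stimulus baseline. (The criterion behind published "detectable
#' response" tallies is rarely stated; this k-sigma exceedance rule is this
#' package's operationalization.)
#'
#' @param dff dF/F trace, percent.
#' @param time time stamps, seconds.
#' @param protocol a [stimulus_protocol()] with at least one pulse.
#' @param k_sd threshold in baseline SDs (default 3).
#' @param window response window after the first stimulus onset, seconds;
#'   default runs to 20 s past the first stimulus offset.
#' @param baseline_span seconds of pre-stimulus baseline (>= 2 required).
#' @return logical.
#' @export
classify_responder <- function(dff, time, protocol, k_sd = 3,
                               window = NULL, baseline_span = 2) {
  if (nrow(protocol$pulses) == 0L) stop("protocol has no pulses")
  t_on <- protocol$pulses$t_on[1L]
  base_idx <- time >= t_on - baseline_span & time < t_on
  if (sum(base_idx) < 2L || t_on - baseline_span < min(time) - 1e-9) {
    stop("need at least ", baseline_span, " s of pre-stimulus baseline")
  }
  if (is.null(window)) {
    window <- protocol$pulses$t_off[1L] - t_on + 20
  }
  window <- min(window, max(time) - t_on)
  pk <- peak_response(dff, time, t_on, window, direction = "auto",
                      baseline_span = baseline_span)
  abs(pk$peak) >= k_sd * stats::sd(dff[base_idx])
}

#' Pooled responder percentage from non-responder tallies
#'
#' Given per-condition non-responder and trial counts, returns
#' `100 * (1 - sum(non_responders) / sum(trials))`.
#'
#' @param non_responders integer vector of non-responding trial counts.
#' @param trials integer vector of total trial counts (same length).
#' @return pooled responder percentage.
#' @export
responder_percentage <- function(non_responders, trials) {
  stopifnot(length(non_responders) == length(trials),
            all(non_responders >= 0), all(trials > 0),
            all(non_responders <= trials))
  100 * (1 - sum(non_responders) / sum(trials))
}

#' Aggregate trials into a cohort summary
#'
#' Pointwise mean and SEM (sample SD / sqrt(n)) across trials, plus the
#' trials-by-time heatmap matrix with rows in acquisition order.
#'
#' @param traces list of equal-length dF/F traces (acquisition order).
#' @param time optional shared time vector.
#' @param responders optional logical vector (one per trial) used to attach
#'   the responder fraction.
#' @return object of class `cohort_summary`: `mean`, `sem`, `heatmap`
#'   (`n_trials x T`), `n_trials`, `time`, `responder_fraction`.
#' @export
aggregate_trials <- function(traces, time = NULL, responders = NULL) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  lens <- vapply(traces, length, 1L)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])
    stop("trace length mismatch at trial(s): ", paste(bad, collapse = ", "))
  }
  m <- do.call(rbind, traces)
  n <- nrow(m)
  mu <- colMeans(m)
  sem <- if (n > 1L) apply(m, 2L, stats::sd) / sqrt(n) else rep(0, ncol(m))
  structure(list(mean = mu, sem = sem, heatmap = m, n_trials = n,
                 time = time,
                 responder_fraction = if (is.null(responders)) NA_real_
                                      else mean(responders)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d trials x %d frames; peak mean %.2f%%",
              x$n_trials, ncol(x$heatmap), max(abs(x$mean))))
  if (!is.na(x$responder_fraction)) {
    cat(sprintf("; responders %.0f%%", 100 * x$responder_fraction))
  }
  cat("\n")
  invisible(x)
}

# initial-20-s decay epoch for one pulse of a protocol
decay_epoch_for_pulse <- function(protocol, pulse_idx, fit_window = 20) {
  p <- protocol$pulses[pulse_idx, ]
  if (protocol$neuron_class == "awc_like") {
    # tonic release: fluorescence decays while the (inhibitory) stimulus is on
    c(p$t_on, min(p$t_on + fit_window, p$t_off))
  } else {
    # phasic release: decay follows stimulus removal
    c(p$t_off, p$t_off + fit_window)
  }
}

#' Dual-pulse retrieval-acceleration analysis
#'
#' For a protocol with two pulses (classically 60 s then 20 s, separated by a
#' short gap), fits a single-term exponential to the initial 20 s of each
#' pulse's decay epoch and reports both time constants and their ratio. A
#' second-pulse time constant markedly below the first indicates
#' activity-accelerated vesicle retrieval.
#'
#' @param dff dF/F trace, percent.
#' @param time time stamps, seconds.
#' @param protocol a [stimulus_protocol()] with at least two pulses.
#' @param fit_window seconds of decay fitted for each pulse (default 20).
#' @return list with `tau_p1`, `tau_p2`, `ratio` (tau_p2 / tau_p1), and the
#'   two `decay_fit` objects.
#' @export
dual_pulse_analysis <- function(dff, time, protocol, fit_window = 20) {
  if (nrow(protocol$pulses) < 2L) {
    stop("dual-pulse analysis needs a protocol with two pulses")
  }
  fit_one <- function(pulse_idx) {
    ep <- decay_epoch_for_pulse(protocol, pulse_idx, fit_window)
    idx <- time >= ep[1L] & time <= ep[2L]
    fit_decay(dff[idx], time[idx], n_terms = 1L)
  }
  f1 <- fit_one(1L)
  f2 <- fit_one(2L)
  if (!f1$converged || !f2$converged) {
    stop("decay fit failed quality control for pulse ",
         if (!f1$converged) "1" else "2")
  }
  list(tau_p1 = f1$tau, tau_p2 = f2$tau, ratio = f2$tau / f1$tau,
       fit_p1 = f1, fit_p2 = f2)
}

#' Chemotaxis index
#'
#' `(n_odor - n_control) / n_total`: +1 when all animals reach the odor
#' side, -1 when all reach the control side.
#'
#' @param n_odor animals on the odor side.
#' @param n_control animals on the control side.
#' @param n_total total counted animals (>= n_odor + n_control).
#' @return index in `[-1, 1]`.
#' @export
chemotaxis_index <- function(n_odor, n_control, n_total) {
  stopifnot(n_odor >= 0, n_control >= 0)
  if (n_total <= 0) stop("`n_total` must be > 0")
  if (n_odor + n_control > n_total) {
    stop("n_odor + n_control exceeds n_total")
  }
  (n_odor - n_control) / n_total
}
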