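#' Correction configuration
#'
#' Settings for background/bleach correction and dF/F referencing.
#'
#' The reference window is class-dependent: for AWC-like (OFF-type)
#' recordings F_o is the mean background-corrected signal over the 2 s ending
#' at the first stimulus offset (just before odor removal); for ASH-like
#' (ON-type) recordings it is the 2 s ending at the first stimulus onset
#' (just before the first stimulus). An explicit `c(t_start, t_end)` window
#' overrides both.
#'
#' @param bleach_drop_threshold fractional background drop per
#'   `bleach_span` seconds that counts as significant bleaching
#'   (default 0.005, i.e. 0.5%).
#' @param bleach_span reference span for the drop criterion, seconds
#'   (default 120, i.e. 2 min).
#' @param f_o_floor minimum acceptable F_o, counts; traces below it are
#'   flagged `low_F_o` and excluded from fitting (dF/F is unstable when its
#'   denominator is small). Default 10 (5x a typical 2-count read noise SD).
#' @param reference_window `NULL` for the class rule, or explicit
#'   `c(t_start, t_end)` seconds.
#' @param window_length reference window length, seconds (default 2).
#' @return object of class `correction_config`.
#' @export
correction_config <- function(bleach_drop_threshold = 0.005,
                              bleach_span = 120,
                              f_o_floor = 10,
                              reference_window = NULL,
                              window_length = 2) {
  stopifnot(bleach_drop_threshold > 0, bleach_span > 0, window_length > 0,
            f_o_floor >= 0)
  if (!is.null(reference_window)) {
    stopifnot(length(reference_window) == 2L,
              reference_window[2L] > reference_window[1L])
  }
  structure(list(bleach_drop_threshold = bleach_drop_threshold,
                 bleach_span = bleach_span, f_o_floor = f_o_floor,
                 reference_window = reference_window,
                 window_length = window_length),
            class = "correction_config")
}

#' Fit a linear bleach model to a background trace
#'
#' Ordinary least-squares line fit of background on time. Bleaching is
#' assumed approximately linear; it is flagged as significant when the
#' fractional *drop* over `bleach_span` seconds reaches
#' `bleach_drop_threshold` (default: a 0.5% drop in mean intensity over
#' 2 min). Increases never flag.
#'
#' @param bg background trace, counts.
#' @param time time stamps, seconds.
#' @param config a [correction_config()].
#' @return list with `slope` (counts/s), `intercept`, `frac_drop_per_span`
#'   (positive = declining), `flagged`.
#' @export
fit_background_bleach <- function(bg, time, config = correction_config()) {
  stopifnot(length(bg) == length(time))
  if (length(bg) < 10L) stop("need at least 10 frames to assess bleaching")
  if (stats::var(time) == 0) stop("time vector has zero variance")
  fit <- stats::lm.fit(cbind(1, time), bg)
  slope <- unname(fit$coefficients[2L])
  frac_drop <- -slope * config$bleach_span / mean(bg)
  list(slope = slope, intercept = unname(fit$coefficients[1L]),
       frac_drop_per_span = frac_drop,
       flagged = is.finite(frac_drop) &&
         frac_drop >= config$bleach_drop_threshold)
}

#' Correct background bleaching
#'
#' If (and only if) the trace is flagged by [fit_background_bleach()], the
#' fitted line — re-zeroed to its value at the first time point, so the
#' background level is preserved — is subtracted from the background signal.
#' Unflagged traces are returned unchanged.
#'
#' @inheritParams fit_background_bleach
#' @param fit optional precomputed result of [fit_background_bleach()].
#' @return list with `bg` (corrected trace) and `corrected` (logical).
#' @export
correct_bleach <- function(bg, time, config = correction_config(),
                           fit = NULL) {
  if (is.null(fit)) fit <- fit_background_bleach(bg, time, config)
  if (!fit$flagged) return(list(bg = bg, corrected = FALSE))
  line <- fit$intercept + fit$slope * time
  list(bg = bg - (line - line[1L]), corrected = TRUE)
}

#' Background-fluctuation correction
#'
#' The reporter baseline can be close to tissue autofluorescence, and part of
#' the ROI signal (reporter in non-cycling compartments) never changes, so
#' subtracting the full background would push F_o toward zero and make dF/F
#' unstable. Only the *fluctuations* of the background are therefore
#' removed: `BGDelta(t) = BG(t) - min_t BG(t)` and
#' `F(t) = F_roi(t) - BGDelta(t)`.
#'
#' When several background ROIs are provided their unweighted mean is used
#' (pass only the anterior ROI(s) for ASH-like recordings).
#'
#' @param f_roi axon ROI mean trace, counts.
#' @param bg background trace (vector) or one column per background ROI
#'   (matrix/data.frame), already bleach-corrected where flagged.
#' @return list with `F` (corrected trace) and `background`
#'   (class `background_series`: `bg`, `bg_min`, `bg_delta`).
#' @export
background_delta_correct <- function(f_roi, bg) {
  bgm <- as.matrix(bg)
  if (nrow(bgm) != length(f_roi)) stop("trace lengths differ")
  if (any(f_roi < 0) || any(bgm < 0)) {
    stop("negative intensities in input traces")
  }
  bg_mean <- rowMeans(bgm)
  bg_min <- min(bg_mean)
  bg_delta <- bg_mean - bg_min
  structure(list(F = f_roi - bg_delta,
                 background = structure(
                   list(bg = bg_mean, bg_min = bg_min, bg_delta = bg_delta),
                   class = "background_series")))
}

# resolve the class-appropriate reference window [t_start, t_end]
reference_window_for <- function(protocol, config) {
  if (!is.null(config$reference_window)) return(config$reference_window)
  if (nrow(protocol$pulses) == 0L) {
    stop("no pulses in protocol: supply an explicit reference_window")
  }
  anchor <- if (protocol$neuron_class == "awc_like") {
    protocol$pulses$t_off[1L]  # just before stimulus (odor) removal
  } else {
    protocol$pulses$t_on[1L]   # just before the first stimulus
  }
  c(anchor - config$window_length, anchor)
}

#' Compute dF/F
#'
#' `dff(t) = (F(t) - F_o) / F_o`, reported in percent. F_o is the mean of F
#' over the class-appropriate 2 s reference window (see
#' [correction_config()]). If `F_o` does not exceed `f_o_floor` the trace is
#' flagged `low_F_o`; its dF/F values are set to `NA` and it should be
#' excluded from fitting.
#'
#' @param F background-corrected fluorescence trace, counts.
#' @param time time stamps, seconds.
#' @param protocol a [stimulus_protocol()] (used for the reference window).
#' @param config a [correction_config()].
#' @param flags named logical flags carried over from earlier stages.
#' @return object of class `corrected_trace`: `time`, `F`, `F_o`, `dff`
#'   (percent), `flags`.
#' @export
compute_dff <- function(F, time, protocol, config = correction_config(),
                        flags = list()) {
  stopifnot(length(F) == length(time))
  win <- reference_window_for(protocol, config)
  if (win[1L] < min(time) - 1e-9 || win[2L] > max(time) + 1e-9) {
    stop(sprintf("reference window [%.2f, %.2f] s outside recording",
                 win[1L], win[2L]))
  }
  in_win <- time >= win[1L] - 1e-9 & time <= win[2L] + 1e-9
  if (!any(in_win)) stop("reference window contains no frames")
  F_o <- mean(F[in_win])
  low <- !(F_o > config$f_o_floor)
  dff <- if (low) rep(NA_real_, length(F)) else 100 * (F - F_o) / F_o
  flags$low_F_o <- low
  structure(list(time = time, F = F, F_o = F_o, dff = dff,
                 reference_window = win, flags = flags),
            class = "corrected_trace")
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf("<corrected_trace> %d frames, F_o = %.1f counts%s\n",
              length(x$time), x$F_o,
              if (isTRUE(x$flags$low_F_o)) " [low_F_o]" else ""))
  invisible(x)
}

#' Full trace correction: bleach, background fluctuations, dF/F
#'
#' Applies the fixed order of operations to a raw trace table: detect
#' bleaching on the (mean) background series, detrend the background only if
#' flagged, subtract background fluctuations (BGDelta), then normalize to
#' dF/F against the class-appropriate reference window.
#'
#' @param traces `data.frame` from [extract_traces()] (columns `time_s`,
#'   `roi_mean`, `bg_1`, ...), or any frame with those columns.
#' @param protocol a [stimulus_protocol()].
#' @param config a [correction_config()].
#' @param anterior_only use only background columns labelled `"anterior"`
#'   (requires the `bg_labels` attribute; the rule for ASH-like recordings).
#' @return a `corrected_trace` whose `flags` record `bleach_corrected` and
#'   `low_F_o`; the background series is attached as attribute
#'   `"background"`.
#' @export
correct_traces <- function(traces, protocol, config = correction_config(),
                           anterior_only = protocol$neuron_class == "ash_like") {
  stopifnot(is.data.frame(traces),
            all(c("time_s", "roi_mean") %in% names(traces)))
  bg_cols <- grep("^bg_", names(traces), value = TRUE)
  if (length(bg_cols) == 0L) stop("no background columns (bg_*) in traces")
  labels <- attr(traces, "bg_labels")
  if (anterior_only && !is.null(labels) && length(labels) == length(bg_cols)) {
    keep <- labels == "anterior"
    if (!any(keep)) stop("anterior-only requested but no anterior background ROI")
    bg_cols <- bg_cols[keep]
  }
  time <- traces$time_s
  bg <- rowMeans(as.matrix(traces[, bg_cols, drop = FALSE]))
  bl <- fit_background_bleach(bg, time, config)
  cb <- correct_bleach(bg, time, config, fit = bl)
  bdc <- background_delta_correct(traces$roi_mean, cb$bg)
  out <- compute_dff(bdc$F, time, protocol, config,
                     flags = list(bleach_corrected = cb$corrected))
  attr(out, "background") <- bdc$background
  attr(out, "bleach_fit") <- bl
  out
}
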