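#' Stimulus protocol
#'
#' Describes the stimulus timing of a recording: an ordered set of
#' non-overlapping pulses, the neuron class, the total recording duration and
#' the camera frame interval.
#'
#' Two neuron classes are supported. `"awc_like"` is an OFF-type chemosensory
#' neuron: tonically active, suppressed by the stimulus (odor), with a calcium
#' overshoot after stimulus removal. `"ash_like"` is an ON-type nociceptor:
#' activated by the stimulus, returning to baseline after removal.
#'
#' @param pulses two-column object (`t_on`, `t_off`, seconds) or a list of
#'   `c(t_on, t_off)` pairs; pulses must be strictly increasing and
#'   non-overlapping, with `0 <= t_on < t_off <= total_duration`. May be empty.
#' @param neuron_class `"awc_like"` (OFF-type) or `"ash_like"` (ON-type).
#' @param total_duration total recording duration, seconds.
#' @param frame_interval camera frame interval, seconds (default 0.2, i.e.
#'   5 frames per second).
#' @return an object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol(list(c(10, 70)), "awc_like", total_duration = 100)
#' n_frames(p)
#' @export
stimulus_protocol <- function(pulses = list(),
                              neuron_class = c("awc_like", "ash_like"),
                              total_duration,
                              frame_interval = 0.2) {
  neuron_class <- match.arg(neuron_class)
  if (!is.numeric(total_duration) || length(total_duration) != 1L ||
      !is.finite(total_duration) || total_duration <= 0) {
    stop("`total_duration` must be a single positive number (seconds)")
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be > 0")
  }
  pl <- normalize_pulses(pulses)
  if (nrow(pl) > 0L) {
    if (any(pl$t_on < 0) || any(pl$t_off > total_duration)) {
      stop("pulses must lie within [0, total_duration]")
    }
    if (any(pl$t_off <= pl$t_on)) stop("each pulse needs t_on < t_off")
    if (nrow(pl) > 1L && any(pl$t_on[-1L] < pl$t_off[-nrow(pl)])) {
      stop("pulses must be non-overlapping and strictly increasing")
    }
  }
  structure(
    list(pulses = pl, neuron_class = neuron_class,
         total_duration = total_duration, frame_interval = frame_interval),
    class = "stimulus_protocol")
}

normalize_pulses <- function(pulses) {
  if (is.null(pulses) || (is.list(pulses) && length(pulses) == 0L)) {
    return(data.frame(t_on = numeric(0), t_off = numeric(0)))
  }
  if (is.data.frame(pulses)) {
    stopifnot(all(c("t_on", "t_off") %in% names(pulses)))
    return(data.frame(t_on = as.numeric(pulses$t_on),
                      t_off = as.numeric(pulses$t_off)))
  }
  if (is.matrix(pulses)) {
    return(data.frame(t_on = pulses[, 1L], t_off = pulses[, 2L]))
  }
  if (is.list(pulses)) {
    m <- do.call(rbind, lapply(pulses, function(p) {
      if (length(p) != 2L) stop("each pulse must be c(t_on, t_off)")
      as.numeric(p)
    }))
    return(data.frame(t_on = m[, 1L], t_off = m[, 2L]))
  }
  if (is.numeric(pulses) && length(pulses) == 2L) {
    return(data.frame(t_on = pulses[1L], t_off = pulses[2L]))
  }
  stop("cannot interpret `pulses`")
}

#' Number of frames in a protocol
#' @param protocol a [stimulus_protocol()].
#' @return integer frame count.
#' @export
n_frames <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  max(1L, as.integer(round(protocol$total_duration / protocol$frame_interval)))
}

#' Frame time stamps of a protocol
#'
#' Frame i is stamped at the start of its exposure: `(i - 1) * frame_interval`.
#' @inheritParams n_frames
#' @return numeric vector of times in seconds, length [n_frames()].
#' @export
frame_times <- function(protocol) {
  (seq_len(n_frames(protocol)) - 1L) * protocol$frame_interval
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s, %.1f s at %.3f s/frame (%d frames)\n",
              x$neuron_class, x$total_duration, x$frame_interval, n_frames(x)))
  if (nrow(x$pulses) == 0L) {
    cat("  no pulses\n")
  } else {
    for (i in seq_len(nrow(x$pulses))) {
      cat(sprintf("  pulse %d: %.1f-%.1f s\n", i,
                  x$pulses$t_on[i], x$pulses$t_off[i]))
    }
  }
  invisible(x)
}

# TRUE for frames whose time stamp falls inside any pulse
frames_in_pulse <- function(protocol) {
  tt <- frame_times(protocol)
  inside <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(protocol$pulses))) {
    inside <- inside |
      (tt >= protocol$pulses$t_on[i] & tt < protocol$pulses$t_off[i])
  }
  inside
}
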