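#' AIC and small-sample-corrected AICc from a least-squares fit
#'
#' For a least-squares fit with residual sum of squares `SS`, `N` data points
#' and `K` fitted parameters: `AIC = N * ln(SS / N) + 2 * K` and
#' `AICc = AIC + 2 * K * (K + 1) / (N - K - 1)`.
#'
#' @param SS residual sum of squares (> 0).
#' @param N number of data points.
#' @param K number of fitted parameters.
#' @return list with `AIC` and `AICc`.
#' @export
compute_aicc <- function(SS, N, K) {
  stopifnot(is.numeric(SS), is.numeric(N), is.numeric(K))
  if (SS <= 0) stop("`SS` must be > 0")
  if (N <= K + 1) stop("AICc undefined: need N > K + 1")
  aic <- N * log(SS / N) + 2 * K
  list(AIC = aic, AICc = aic + 2 * K * (K + 1) / (N - K - 1))
}

#' Relative-likelihood probability from an AICc difference
#'
#' `AIC_P = exp(-Delta/2) / (1 + exp(-Delta/2))` — the probability that the
#' model whose AICc is lower by `Delta` is the better of the two. Evaluated
#' through the logistic CDF for numerical stability at large `|Delta|`.
#'
#' @param delta AICc difference (other model minus this model).
#' @return probability in (0, 1); `aic_probability(0)` is exactly 0.5.
#' @export
aic_probability <- function(delta) {
  stopifnot(all(is.finite(delta)))
  p <- stats::plogis(-delta / 2)
  # keep the open-interval contract even where the logistic saturates
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

# sum-of-exponentials model value: a_i, tau_i pairs plus constant C
exp_model <- function(par, t, n_terms) {
  a <- par[seq_len(n_terms)]
  tau <- par[n_terms + seq_len(n_terms)]
  C <- par[2L * n_terms + 1L]
  y <- rep(C, length(t))
  for (i in seq_len(n_terms)) y <- y + a[i] * exp(-t / tau[i])
  y
}

#' Fit a constrained multi-exponential decay
#'
#' Fits `y(t) = sum_i a_i * exp(-t / tau_i) + C` with all `a_i` and `tau_i`
#' constrained positive (`C` free), by bounded nonlinear least squares
#' (`L-BFGS-B`) from multiple starts on a log-spaced grid of time constants.
#' Time is re-zeroed to the segment start, so fits are invariant to the
#' absolute time origin.
#'
#' Quality control follows the practice of discarding traces that are too
#' noisy or show no decay: the fit is marked not converged when `r^2 < 0.2`
#' or when the fitted total amplitude is below 3x the residual SD.
#'
#' @param y decay segment (dF/F, percent or any amplitude unit).
#' @param t time stamps, seconds (same length as `y`).
#' @param n_terms number of exponential terms (1, 2 or 3).
#' @param n_starts number of multi-start tau grids (>= 5 recommended).
#' @return object of class `decay_fit`: `n_terms`, `a`, `tau`, `C`, `SS`,
#'   `N`, `K`, `AIC`, `AICc`, `r_squared`, `converged`, `fitted`.
#' @export
fit_decay <- function(y, t, n_terms = 1L, n_starts = 5L) {
  stopifnot(length(y) == length(t), n_terms %in% 1:3)
  keep <- is.finite(y) & is.finite(t)
  y <- y[keep]; t <- t[keep]
  N <- length(y)
  K <- 2L * n_terms + 1L
  if (N < 4L * K) stop("too few points: need at least 4 * K = ", 4L * K)
  t0 <- t - t[1L]
  span <- max(t0)

  obj <- function(par) {
    r <- y - exp_model(par, t0, n_terms)
    sum(r * r)
  }

  amp0 <- y[1L] - y[N]
  c0 <- y[N]
  scale_y <- max(stats::sd(y), abs(amp0), 1e-6)
  tau_grid <- exp(seq(log(max(diff(t0)[1L], span / 200)), log(3 * span),
                      length.out = max(5L, n_starts)))
  lower <- c(rep(1e-9, n_terms), rep(1e-6, n_terms), -Inf)
  upper <- c(rep(Inf, 2L * n_terms), Inf)

  best <- NULL
  for (s in seq_along(tau_grid)) {
    taus <- if (n_terms == 1L) tau_grid[s] else {
      # spread the terms around the grid point
      tau_grid[s] * (4^(seq_len(n_terms) - (n_terms + 1) / 2))
    }
    a0 <- rep(max(amp0, 0.1 * scale_y) / n_terms, n_terms)
    par0 <- c(a0, pmax(taus, 1e-3), c0)
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L,
                                  parscale = pmax(abs(par0), 1e-3))),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (!is.null(best)) {
    # polish from the best start; line-search hiccups near the optimum are
    # benign and cleared by a restart
    polish <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500L,
                                  parscale = pmax(abs(best$par), 1e-3))),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  if (is.null(best)) {
    return(structure(list(n_terms = n_terms, a = rep(NA_real_, n_terms),
                          tau = rep(NA_real_, n_terms), C = NA_real_,
                          SS = NA_real_, N = N, K = K, AIC = NA_real_,
                          AICc = NA_real_, r_squared = NA_real_,
                          converged = FALSE, fitted = NULL),
                     class = "decay_fit"))
  }
  par <- best$par
  a <- pmax(par[seq_len(n_terms)], 1e-9)
  tau <- pmax(par[n_terms + seq_len(n_terms)], 1e-9)
  ord <- order(tau)
  a <- a[ord]; tau <- tau[ord]
  C <- par[2L * n_terms + 1L]
  fitted <- exp_model(c(a, tau, C), t0, n_terms)
  SS <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - SS / ss_tot else 0
  resid_sd <- sqrt(SS / max(N - K, 1L))
  ic <- if (SS > 0 && N > K + 1) compute_aicc(SS, N, K) else
    list(AIC = -Inf, AICc = -Inf)
  # code 52 is L-BFGS-B's abnormal line-search termination, routinely hit at
  # a well-converged optimum; the r^2 and amplitude gates do the real QC
  converged <- best$convergence %in% c(0L, 52L) && r2 >= 0.2 &&
    sum(a) >= 3 * resid_sd
  structure(list(n_terms = n_terms, a = a, tau = tau, C = C,
                 SS = SS, N = N, K = K, AIC = ic$AIC, AICc = ic$AICc,
                 r_squared = r2, converged = converged, fitted = fitted),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d term(s), %s\n", x$n_terms,
              if (x$converged) "converged" else "NOT converged / excluded"))
  if (!all(is.na(x$tau))) {
    for (i in seq_len(x$n_terms)) {
      cat(sprintf("  a%d = %.4g, tau%d = %.4g s\n", i, x$a[i], i, x$tau[i]))
    }
    cat(sprintf("  C = %.4g, SS = %.4g, N = %d, K = %d, AICc = %.2f, r2 = %.3f\n",
                x$C, x$SS, x$N, x$K, x$AICc, x$r_squared))
  }
  invisible(x)
}

#' Select a decay model by AICc with a parsimony tie-break
#'
#' Fits 1..`max_terms` exponential terms and walks up in complexity: a more
#' complex model replaces the current choice only when the probability that
#' it is the better model (AIC_P from the AICc difference) exceeds
#' `complexity_threshold`. Otherwise the simpler model stands.
#'
#' @inheritParams fit_decay
#' @param max_terms maximum number of exponential terms to consider.
#' @param complexity_threshold AIC_P needed to accept added complexity
#'   (default 0.95).
#' @return list with `fit` (chosen `decay_fit`), `all_fits`, and
#'   `comparisons` (data.frame of pairwise `delta` and `aic_p`).
#' @export
select_decay_model <- function(y, t, max_terms = 3L,
                               complexity_threshold = 0.95, n_starts = 5L) {
  stopifnot(max_terms %in% 1:3)
  fits <- list(fit_decay(y, t, 1L, n_starts))
  if (!fits[[1L]]$converged) {
    stop("single-exponential fit failed quality control; trace excluded")
  }
  chosen <- 1L
  comparisons <- list()
  for (k in seq_len(max_terms)[-1L]) {
    fk <- tryCatch(fit_decay(y, t, k, n_starts), error = function(e) NULL)
    if (is.null(fk)) break
    fits[[k]] <- fk
    if (!fk$converged || !is.finite(fk$AICc)) next
    delta <- fk$AICc - fits[[chosen]]$AICc
    p <- aic_probability(delta)
    comparisons[[length(comparisons) + 1L]] <- data.frame(
      simpler = chosen, complex = k, delta = delta, aic_p = p)
    if (p > complexity_threshold) chosen <- k
  }
  list(fit = fits[[chosen]], all_fits = fits,
       comparisons = if (length(comparisons) > 0L) {
         do.call(rbind, comparisons)
       } else {
         data.frame(simpler = integer(0), complex = integer(0),
                    delta = numeric(0), aic_p = numeric(0))
       })
}

#' Smoothed time derivative of a dF/F trace
#'
#' Applies a centered running average of `smooth_frames` frames and takes the
#' first difference. Output units are change in dF/F (%) per 200 ms
#' regardless of the frame interval (i.e. per frame at 5 Hz). The first
#' output sample corresponds to the interval between the first two smoothed
#' frames; `smooth_frames - 1` edge samples and one differencing sample are
#' lost relative to the input.
#'
#' @param dff dF/F trace, percent.
#' @param smooth_frames running-average width in frames (default 3).
#' @param frame_interval seconds per frame (default 0.2).
#' @return numeric vector of derivative values with attribute `"time"`
#'   (midpoint times of each difference, seconds).
#' @export
time_derivative <- function(dff, smooth_frames = 3L, frame_interval = 0.2) {
  n <- length(dff)
  if (n <= smooth_frames + 1L) stop("trace too short for derivative")
  sm <- stats::filter(dff, rep(1 / smooth_frames, smooth_frames),
                      sides = 2L)
  sm <- as.numeric(sm)
  valid <- which(!is.na(sm))
  sm <- sm[valid]
  d <- diff(sm) * (0.2 / frame_interval)  # per 200 ms
  tt <- (valid[-1L] - 1.5) * frame_interval
  attr(d, "time") <- tt
  d
}

#' Peak response after an event
#'
#' Finds the extremum of `dff` relative to the pre-event baseline within
#' `[event_time, event_time + window]`. The search direction follows the
#' expected response sign (`"up"` for an ON-type stimulus onset or an
#' OFF-type stimulus removal, `"down"` for an OFF-type stimulus onset), or
#' `"auto"` to take the largest magnitude either way.
#'
#' @param dff dF/F trace, percent.
#' @param time time stamps, seconds.
#' @param event_time event (stimulus transition) time, seconds.
#' @param window search window length after the event, seconds.
#' @param direction `"auto"`, `"up"` or `"down"`.
#' @param baseline_span seconds of pre-event data averaged as baseline.
#' @return list with `peak` (% dF/F, signed, baseline-referenced), `latency`
#'   (s after event), `sign`.
#' @export
peak_response <- function(dff, time, event_time, window,
                          direction = c("auto", "up", "down"),
                          baseline_span = 2) {
  direction <- match.arg(direction)
  stopifnot(length(dff) == length(time), window > 0)
  in_win <- time >= event_time & time <= event_time + window
  if (!any(in_win)) stop("response window contains no frames")
  base_idx <- time >= event_time - baseline_span & time < event_time
  baseline <- if (any(base_idx)) mean(dff[base_idx]) else dff[1L]
  seg <- dff[in_win] - baseline
  tseg <- time[in_win]
  i <- switch(direction,
              up = which.max(seg),
              down = which.min(seg),
              auto = which.max(abs(seg)))
  list(peak = seg[i], latency = tseg[i] - event_time,
       sign = sign(seg[i]))
}
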