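#' Translate an image by an integer offset
#'
#' Content moves by `(dy, dx)`; pixels shifted in from outside the frame are
#' filled with `fill` (default: the frame median, a robust stand-in for local
#' background).
#'
#' @param m numeric matrix.
#' @param dy,dx integer row/column offsets.
#' @param fill fill value for exposed borders.
#' @return translated matrix of the same size.
#' @export
translate_frame <- function(m, dy, dx, fill = stats::median(m)) {
  Y <- nrow(m); X <- ncol(m)
  out <- matrix(fill, Y, X)
  sr <- max(1L, 1L + dy):min(Y, Y + dy)
  sc <- max(1L, 1L + dx):min(X, X + dx)
  if (dy <= -Y || dy >= Y || dx <= -X || dx >= X) return(out)
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

# integer (d_row, d_col) maximizing cross-correlation of `frame` vs `template`
cc_peak_shift <- function(frame, template) {
  Y <- nrow(frame); X <- ncol(frame)
  fa <- stats::fft(frame - mean(frame))
  fb <- stats::fft(template - mean(template))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  k <- which.max(cc) - 1L
  d_row <- k %% Y
  d_col <- k %/% Y
  if (d_row > Y / 2) d_row <- d_row - Y
  if (d_col > X / 2) d_col <- d_col - X
  c(d_row, d_col)
}

#' Register a movie for x-y drift
#'
#' Estimates one integer `(row, col)` shift per frame by cross-correlating
#' each frame against the time-averaged template, re-expresses shifts
#' relative to the first frame, and translates every frame back so the axon
#' occupies one fixed set of image coordinates for the whole recording.
#' Exposed borders are filled with the frame median.
#'
#' Frames whose shift magnitude exceeds `max_shift_frac` of the corresponding
#' image dimension are flagged for discard (the in-plane analogue of
#' discarding recordings with z-drift); they are still returned, translated,
#' so callers can drop them from traces.
#'
#' @param movie a [movie_stack()].
#' @param max_shift_frac maximum tolerated shift as a fraction of each image
#'   dimension (default 0.2).
#' @return list with `movie` (registered [movie_stack()]), `shifts`
#'   (`T x 2` integer matrix of applied frame displacements, relative to
#'   frame 1; the negated drift trajectory), `flagged` (logical, per frame),
#'   and `valid_box` (`rmin, rmax, cmin, cmax`: the rectangle of pixels that
#'   were never border-filled in any unflagged frame; quantification should
#'   stay inside it).
#' @export
register_xy <- function(movie, max_shift_frac = 0.2) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$frames)
  nt <- d[1L]; Y <- d[2L]; X <- d[3L]
  if (nt < 2L) stop("registration needs at least 2 frames")
  template <- apply(movie$frames, c(2L, 3L), mean)
  raw <- t(vapply(seq_len(nt), function(k) {
    as.integer(cc_peak_shift(movie$frames[k, , ], template))
  }, integer(2L)))
  rel <- sweep(raw, 2L, raw[1L, ])  # drift relative to frame 1
  storage.mode(rel) <- "integer"
  flagged <- abs(rel[, 1L]) > max_shift_frac * Y |
    abs(rel[, 2L]) > max_shift_frac * X
  reg <- movie$frames
  for (k in seq_len(nt)) {
    if (rel[k, 1L] != 0 || rel[k, 2L] != 0) {
      reg[k, , ] <- translate_frame(movie$frames[k, , ],
                                    -rel[k, 1L], -rel[k, 2L])
    }
  }
  shifts <- -rel
  colnames(shifts) <- c("d_row", "d_col")
  ok <- !flagged
  valid_box <- c(rmin = 1L + max(0L, max(shifts[ok, 1L])),
                 rmax = Y + min(0L, min(shifts[ok, 1L])),
                 cmin = 1L + max(0L, max(shifts[ok, 2L])),
                 cmax = X + min(0L, min(shifts[ok, 2L])))
  out_movie <- movie_stack(reg, movie$frame_interval, movie$bit_depth)
  attr(out_movie, "valid_box") <- valid_box
  list(movie = out_movie, shifts = shifts, flagged = flagged,
       valid_box = valid_box)
}

# ball structuring-element heights: apex 0 at the center, <= 0 at the rim
ball_offsets_2d <- function(radius) {
  r <- as.integer(ceiling(radius))
  ij <- expand.grid(i = -r:r, j = -r:r)
  keep <- ij$i^2 + ij$j^2 <= radius^2
  ij <- ij[keep, , drop = FALSE]
  ij$b <- sqrt(radius^2 - ij$i^2 - ij$j^2) - radius
  ij
}

rolling_ball_matrix <- function(m, radius) {
  Y <- nrow(m); X <- ncol(m)
  if (radius >= min(Y, X)) stop("rolling-ball radius must be < min(image dims)")
  off <- ball_offsets_2d(radius)
  r <- as.integer(ceiling(radius))
  pad <- matrix(Inf, Y + 2L * r, X + 2L * r)
  pad[(r + 1L):(r + Y), (r + 1L):(r + X)] <- m
  rows <- (r + 1L):(r + Y); cols <- (r + 1L):(r + X)
  ero <- matrix(Inf, Y, X)
  for (q in seq_len(nrow(off))) {
    ero <- pmin(ero, pad[rows + off$i[q], cols + off$j[q]] - off$b[q])
  }
  pad[] <- -Inf
  pad[(r + 1L):(r + Y), (r + 1L):(r + X)] <- ero
  bg <- matrix(-Inf, Y, X)
  for (q in seq_len(nrow(off))) {
    bg <- pmax(bg, pad[rows + off$i[q], cols + off$j[q]] + off$b[q])
  }
  pmax(m - bg, 0)
}

rolling_ball_vector <- function(v, radius) {
  n <- length(v)
  if (radius >= n) stop("rolling-ball radius must be < profile length")
  r <- as.integer(ceiling(radius))
  offs <- -r:r
  offs <- offs[abs(offs) <= radius]
  b <- sqrt(radius^2 - offs^2) - radius
  pad <- c(rep(Inf, r), v, rep(Inf, r))
  idx <- (r + 1L):(r + n)
  ero <- rep(Inf, n)
  for (q in seq_along(offs)) ero <- pmin(ero, pad[idx + offs[q]] - b[q])
  pad <- c(rep(-Inf, r), ero, rep(-Inf, r))
  bg <- rep(-Inf, n)
  for (q in seq_along(offs)) bg <- pmax(bg, pad[idx + offs[q]] + b[q])
  pmax(v - bg, 0)
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image by a
#' ball structuring element of the given radius (the classic rolling-ball
#' construction) and subtracts it, flooring the result at zero. Accepts a
#' numeric vector (1-D profile), a matrix (single image), or a
#' [movie_stack()] (applied per frame).
#'
#' @param x profile, image or movie.
#' @param radius ball radius, pixels (must be smaller than the image).
#' @return same shape as the input, background-subtracted.
#' @export
rolling_ball_subtract <- function(x, radius = 25) {
  if (radius < 1) stop("`radius` must be >= 1")
  if (inherits(x, "movie_stack")) {
    out <- x$frames
    for (k in seq_len(dim(out)[1L])) {
      out[k, , ] <- rolling_ball_matrix(out[k, , ], radius)
    }
    return(movie_stack(out, x$frame_interval, x$bit_depth))
  }
  if (is.matrix(x)) return(rolling_ball_matrix(x, radius))
  if (is.numeric(x)) return(rolling_ball_vector(x, radius))
  stop("`x` must be a movie_stack, matrix or numeric vector")
}

# w-pixel boxcar mean with edge clamping
boxcar_smooth <- function(m, w = 2L) {
  Y <- nrow(m); X <- ncol(m)
  out <- matrix(0, Y, X)
  offs <- seq_len(w) - 1L - (w - 1L) %/% 2L
  for (oi in offs) for (oj in offs) {
    ri <- pmin(pmax(seq_len(Y) + oi, 1L), Y)
    cj <- pmin(pmax(seq_len(X) + oj, 1L), X)
    out <- out + m[ri, cj]
  }
  out / (w * w)
}

#' Build the segmentation image
#'
#' Averages the movie over time, optionally removes smooth background with
#' the rolling ball, then applies a small spatial boxcar (default 2 px in x
#' and y). The result is used only to define masks; intensity quantification
#' always runs on the registered raw movie.
#'
#' @param movie a [movie_stack()] (registered).
#' @param rolling_ball_radius optional radius for background flattening of
#'   the temporal mean before smoothing (`NULL` to skip).
#' @param smooth_px boxcar width in pixels.
#' @return a 2-D numeric matrix.
#' @export
make_segmentation_image <- function(movie, rolling_ball_radius = NULL,
                                    smooth_px = 2L) {
  stopifnot(inherits(movie, "movie_stack"))
  img <- apply(movie$frames, c(2L, 3L), mean)
  if (!is.null(rolling_ball_radius)) {
    img <- rolling_ball_matrix(img, rolling_ball_radius)
  }
  boxcar_smooth(img, smooth_px)
}

# Otsu threshold on a 256-bin histogram
otsu_threshold <- function(img) {
  rng <- range(img)
  breaks <- seq(rng[1L], rng[2L], length.out = 257L)
  h <- tabulate(findInterval(img, breaks, all.inside = TRUE), nbins = 256L)
  p <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-257L]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256L]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# label 4-connected components of a logical matrix; returns integer matrix
label_components <- function(bw) {
  Y <- nrow(bw); X <- ncol(bw)
  lab <- matrix(0L, Y, X)
  cur <- 0L
  for (start in which(bw & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% Y + 1L
      cc <- (p - 1L) %/% Y + 1L
      for (nb in list(c(r - 1L, cc), c(r + 1L, cc),
                      c(r, cc - 1L), c(r, cc + 1L))) {
        if (nb[1L] >= 1L && nb[1L] <= Y && nb[2L] >= 1L && nb[2L] <= X) {
          q <- (nb[2L] - 1L) * Y + nb[1L]
          if (bw[q] && lab[q] == 0L) {
            lab[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Segment the axon from a segmentation image
#'
#' Thresholds the segmentation image (Otsu by default, or a fixed value) and
#' keeps the largest 4-connected component as the axon mask — the automated
#' analogue of outlining the axon by hand with the aid of intensity
#' thresholding.
#'
#' @param seg_image 2-D matrix from [make_segmentation_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value for `method = "fixed"`.
#' @param min_area minimum acceptable mask area, pixels.
#' @return object of class `axon_mask`: `mask` (logical matrix), `bbox`
#'   (`rmin, rmax, cmin, cmax`), `area`, `threshold`.
#' @export
segment_axon <- function(seg_image, method = c("otsu", "fixed"),
                         threshold = NULL, min_area = 4L) {
  method <- match.arg(method)
  stopifnot(is.matrix(seg_image))
  if (diff(range(seg_image)) == 0) stop("no axon found: constant image")
  # Otsu on sqrt intensities: the dim inter-punctum axon must land on the
  # foreground side, which raw-intensity Otsu misses when puncta are bright
  thr <- if (method == "otsu") otsu_threshold(sqrt(pmax(seg_image, 0)))^2 else {
    if (is.null(threshold)) stop("`threshold` required for method = 'fixed'")
    threshold
  }
  bw <- seg_image > thr
  if (!any(bw)) stop("no axon found: threshold above image maximum")
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes)
  mask <- lab == best
  if (sum(mask) < min_area) stop("no axon found: largest component below min_area")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  structure(list(mask = mask,
                 bbox = c(rmin = rows[1L], rmax = rows[2L],
                          cmin = cols[1L], cmax = cols[2L]),
                 area = sum(mask), threshold = thr),
            class = "axon_mask")
}

#' @export
print.axon_mask <- function(x, ...) {
  cat(sprintf("<axon_mask> %d px, bbox rows %d-%d cols %d-%d (thr %.2f)\n",
              x$area, x$bbox["rmin"], x$bbox["rmax"],
              x$bbox["cmin"], x$bbox["cmax"], x$threshold))
  invisible(x)
}

#' Place background ROIs flanking the axon
#'
#' Builds rectangular background strips beyond the axon bounding box at a
#' given margin. By row-index convention "anterior" is the lower-row-index
#' side of the image. With `anterior_only = TRUE` (the rule used for ASH-like
#' recordings, whose posterior neighborhood contains responsive structures)
#' only the anterior strip is kept.
#'
#' Strips that would leave the image are dropped; if none remain the call is
#' an error.
#'
#' @param mask an `axon_mask`.
#' @param anterior_only keep only the anterior strip.
#' @param margin gap between the axon bounding box and each strip, pixels
#'   (default 4, enough that fluorescence tails of the axon do not leak into
#'   the background measurement).
#' @param width strip thickness, pixels.
#' @param lateral_pad widen each strip beyond the bounding-box columns by
#'   this many pixels per side (clamped to the image), for better background
#'   statistics.
#' @return object of class `background_rois`: a list of ROIs, each with
#'   `pixels` (logical matrix) and `label` (`"anterior"`/`"posterior"`).
#' @export
place_background_rois <- function(mask, anterior_only = FALSE,
                                  margin = 4L, width = 3L,
                                  lateral_pad = 3L) {
  stopifnot(inherits(mask, "axon_mask"), margin >= 0L, width >= 1L)
  Y <- nrow(mask$mask); X <- ncol(mask$mask)
  bb <- mask$bbox
  cols <- max(1L, bb["cmin"] - lateral_pad):min(X, bb["cmax"] + lateral_pad)
  rois <- list()
  ant_rows <- (bb["rmin"] - margin - width):(bb["rmin"] - margin - 1L)
  if (all(ant_rows >= 1L)) {
    px <- matrix(FALSE, Y, X)
    px[ant_rows, cols] <- TRUE
    px[mask$mask] <- FALSE
    rois[[length(rois) + 1L]] <- list(pixels = px, label = "anterior")
  }
  if (!anterior_only) {
    post_rows <- (bb["rmax"] + margin + 1L):(bb["rmax"] + margin + width)
    if (all(post_rows <= Y)) {
      px <- matrix(FALSE, Y, X)
      px[post_rows, cols] <- TRUE
      px[mask$mask] <- FALSE
      rois[[length(rois) + 1L]] <- list(pixels = px, label = "posterior")
    }
  }
  if (anterior_only && (length(rois) == 0L ||
                        !any(vapply(rois, `[[`, "", "label") == "anterior"))) {
    stop("anterior-only requested but no anterior flank fits in the image")
  }
  if (length(rois) == 0L) {
    stop("no valid flank space for background ROIs")
  }
  structure(rois, class = "background_rois")
}

#' Extract ROI and background traces from a registered movie
#'
#' Computes the mean intensity over the axon mask and over each background
#' ROI at every frame, on the registered but otherwise unprocessed movie
#' (rolling-ball output is used for segmentation only, never for
#' quantification). Frames listed in `drop_frames` (e.g. flagged by
#' [register_xy()]) are removed from the output.
#'
#' @param movie registered [movie_stack()].
#' @param mask an `axon_mask`.
#' @param bgrois a `background_rois` (optional).
#' @param drop_frames integer indices of frames to drop.
#' @param valid_box optional `c(rmin, rmax, cmin, cmax)` rectangle (default:
#'   the `valid_box` attribute left by [register_xy()], else the full image);
#'   pixels outside it — border pixels synthesized during registration — are
#'   excluded from every ROI. Background ROIs left empty by the clipping are
#'   dropped.
#' @return a `data.frame` with columns `time_s`, `roi_mean`, and `bg_1`,
#'   `bg_2`, ... with attributes `bg_labels` and `dropped_frames`.
#' @export
extract_traces <- function(movie, mask, bgrois = NULL,
                           drop_frames = integer(0), valid_box = NULL) {
  stopifnot(inherits(movie, "movie_stack"), inherits(mask, "axon_mask"))
  d <- dim(movie$frames)
  nt <- d[1L]
  valid_box <- valid_box %||% attr(movie, "valid_box") %||%
    c(1L, d[2L], 1L, d[3L])
  inside <- matrix(FALSE, d[2L], d[3L])
  inside[valid_box[1L]:valid_box[2L], valid_box[3L]:valid_box[4L]] <- TRUE
  mean_over <- function(px) {
    vapply(seq_len(nt), function(k) mean(movie$frames[k, , ][px]), 0)
  }
  mask_px <- mask$mask & inside
  if (!any(mask_px)) stop("axon mask falls entirely outside the valid region")
  out <- data.frame(time_s = (seq_len(nt) - 1L) * movie$frame_interval,
                    roi_mean = mean_over(mask_px))
  labels <- character(0)
  if (!is.null(bgrois)) {
    stopifnot(inherits(bgrois, "background_rois"))
    for (i in seq_along(bgrois)) {
      px <- bgrois[[i]]$pixels & inside
      if (!any(px)) next
      out[[paste0("bg_", length(labels) + 1L)]] <- mean_over(px)
      labels <- c(labels, bgrois[[i]]$label)
    }
  }
  dropped <- intersect(as.integer(drop_frames), seq_len(nt))
  if (length(dropped) > 0L) out <- out[-dropped, , drop = FALSE]
  attr(out, "bg_labels") <- labels
  attr(out, "dropped_frames") <- dropped
  out
}

#' Per-segment correlation with the integrated axon trace
#'
#' Cuts the axon mask into consecutive segments (default 8 px) along its long
#' axis, extracts the mean trace of each segment, and correlates it (Pearson)
#' with the whole-axon mean trace. Used to validate treating the whole axon
#' as one integrated measurement: on well-behaved recordings every segment
#' should be positively correlated with the integrated trace.
#'
#' @param movie registered [movie_stack()].
#' @param mask an `axon_mask` spanning at least two segments.
#' @param segment_length segment length along the axon axis, pixels.
#' @return `data.frame` with one row per segment: `segment`, `start`, `end`
#'   (axis coordinates), `n_pixels`, `r`.
#' @export
roi_segment_correlation <- function(movie, mask, segment_length = 8L) {
  stopifnot(inherits(movie, "movie_stack"), inherits(mask, "axon_mask"),
            segment_length >= 1L)
  d <- dim(movie$frames)
  if (d[1L] < 3L) stop("need at least 3 frames for correlation")
  bb <- mask$bbox
  by_rows <- (bb["rmax"] - bb["rmin"]) >= (bb["cmax"] - bb["cmin"])
  lo <- if (by_rows) bb["rmin"] else bb["cmin"]
  hi <- if (by_rows) bb["rmax"] else bb["cmax"]
  starts <- seq(lo, hi, by = segment_length)
  if (length(starts) < 2L) {
    stop("mask must span at least 2 segments along the axon axis")
  }
  whole <- vapply(seq_len(d[1L]), function(k) {
    mean(movie$frames[k, , ][mask$mask])
  }, 0)
  rows <- lapply(seq_along(starts), function(s) {
    a <- starts[s]
    b <- min(a + segment_length - 1L, hi)
    px <- mask$mask
    if (by_rows) {
      px[setdiff(seq_len(nrow(px)), a:b), ] <- FALSE
    } else {
      px[, setdiff(seq_len(ncol(px)), a:b)] <- FALSE
    }
    if (!any(px)) return(NULL)
    seg_tr <- vapply(seq_len(d[1L]), function(k) {
      mean(movie$frames[k, , ][px])
    }, 0)
    data.frame(segment = s, start = a, end = b, n_pixels = sum(px),
               r = stats::cor(seg_tr, whole))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
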