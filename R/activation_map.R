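# Separable box smoothing of a T x P frame matrix arranged on an H x W
# grid; radius 0 is the identity. Edge windows are renormalized.
spatial_box_smooth <- function(M, H, W, radius) {
  if (radius < 1) return(M)
  k <- 2L * radius + 1L
  ones <- rep(1, k)
  smooth_dim <- function(A, n, along_rows) {
    # A: T x (H*W); smooth along the grid dimension of size n
    arr <- array(A, dim = c(nrow(A), H, W))
    if (along_rows) {
      for (w in seq_len(W)) {
        s <- t(apply(arr[, , w, drop = TRUE], 1L, function(r)
          as.numeric(stats::filter(r, ones, sides = 2))))
        cnt <- as.numeric(stats::filter(rep(1, n), ones, sides = 2))
        s <- sweep(s, 2L, cnt, "/")
        na <- is.na(s[1L, ])
        # renormalize edges: recompute with partial windows
        for (j in which(na)) {
          lo <- max(1L, j - radius); hi <- min(n, j + radius)
          s[, j] <- rowMeans(arr[, lo:hi, w, drop = FALSE])
        }
        arr[, , w] <- s
      }
    } else {
      for (h in seq_len(H)) {
        s <- t(apply(arr[, h, , drop = TRUE], 1L, function(r)
          as.numeric(stats::filter(r, ones, sides = 2))))
        cnt <- as.numeric(stats::filter(rep(1, n), ones, sides = 2))
        s <- sweep(s, 2L, cnt, "/")
        na <- is.na(s[1L, ])
        for (j in which(na)) {
          lo <- max(1L, j - radius); hi <- min(n, j + radius)
          s[, j] <- rowMeans(arr[, h, lo:hi, drop = FALSE])
        }
        arr[, h, ] <- s
      }
    }
    matrix(arr, nrow = nrow(A))
  }
  M <- smooth_dim(M, H, TRUE)
  if (W > 1) M <- smooth_dim(M, W, FALSE)
  M
}

#' Per-pixel activation map for one propagated beat
#'
#' Within the given time window, each pixel's activation time is the
#' sub-frame (parabolic-interpolated) time of its maximum temporal
#' derivative. Light spatial binning (default 5x5) is applied first, as is
#' standard in optical mapping, to tame per-pixel shot noise without
#' displacing a planar or gently curved wavefront. Pixels whose local
#' amplitude falls below a floor relative to the whole-field amplitude are
#' masked out of the quality mask.
#'
#' @param movie a [fluor_movie()].
#' @param window `c(t0, t1)` seconds; should bracket exactly one
#'   activation for most pixels (pick it from the global trace's beat
#'   list, e.g. via [recording_cv()]).
#' @param amp_floor_frac amplitude floor as a fraction of the global
#'   (whole-field) amplitude within the window (default 0.2).
#' @param spatial_radius box-smoothing radius in pixels (default 2 =
#'   5x5; 0 disables).
#' @param temporal_window Savitzky-Golay smoothing window, s (default
#'   0.03; 0 disables).
#' @return object of class `activation_map`: list with `act_time`
#'   (`H x W` matrix, seconds, `NA` where rejected), `quality` (logical
#'   `H x W`), `window`, `pixel_pitch`, `frame_rate`, `beat_frames`.
#' @export
compute_activation_map <- function(movie, window, amp_floor_frac = 0.2,
                                   spatial_radius = 2, temporal_window = 0.03) {
  stopifnot(inherits(movie, "fluor_movie"), length(window) == 2L,
            window[2] > window[1])
  d <- dim(movie$frames)
  fps <- movie$frame_rate
  i0 <- max(1L, 1L + floor(window[1] * fps))
  i1 <- min(d[1], 1L + ceiling(window[2] * fps))
  if (i1 - i0 < 3L) stop("window contains too few frames")
  M <- matrix(movie$frames[i0:i1, , ], nrow = i1 - i0 + 1L)
  H <- d[2]; W <- d[3]
  M <- spatial_box_smooth(M, H, W, spatial_radius)
  if (temporal_window > 0) {
    n <- round(temporal_window * fps)
    n <- max(5L, n + (1L - n %% 2L))
    if (n <= nrow(M)) {
      coef <- signal::sgolay(p = 3, n = n)[(n + 1L) / 2L, ]
      sm <- stats::filter(M, coef, sides = 2)
      keep <- !is.na(sm[, 1L])
      M[keep, ] <- sm[keep, ]
    }
  }
  D <- diff(M) * fps
  ipk <- max.col(t(D), ties.method = "first")
  off <- vapply(seq_len(ncol(D)), function(j)
    parabolic_offset(D[, j], ipk[j]), numeric(1))
  tw0 <- (i0 - 1) / fps
  act <- tw0 + (ipk - 0.5 + off) / fps
  amp <- apply(M, 2L, function(x) max(x) - min(x))
  gamp <- max(rowMeans(M)) - min(rowMeans(M))
  if (!(gamp > sqrt(.Machine$double.eps)))
    stop("no detectable activation anywhere in the window")
  pk <- D[cbind(ipk, seq_along(ipk))]
  qual <- amp >= amp_floor_frac * gamp & pk > 0
  if (!any(qual)) stop("no detectable activation anywhere in the window")
  act[!qual] <- NA_real_
  structure(list(act_time = matrix(act, H, W),
                 quality = matrix(qual, H, W),
                 window = c((i0 - 1) / fps, (i1 - 1) / fps),
                 pixel_pitch = movie$pixel_pitch,
                 frame_rate = fps),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> %dx%d px, window [%.3f, %.3f] s, %.1f%% quality\n",
    nrow(x$act_time), ncol(x$act_time), x$window[1], x$window[2],
    100 * mean(x$quality)))
  invisible(x)
}

#' Render an activation map to PNG
#'
#' @param map an [compute_activation_map()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_activation_png <- function(map, path) {
  grDevices::png(path, width = 480, height = 480)
  on.exit(grDevices::dev.off())
  z <- map$act_time - min(map$act_time, na.rm = TRUE)
  graphics::image(t(z)[, rev(seq_len(nrow(z))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = "activation time (s)")
  invisible(path)
}

#' Conduction velocity from an activation map
#'
#' Local plane fit of activation time over a sliding `k x k` neighborhood
#' (quality pixels only, least squares): the fitted spatial gradient `g`
#' (s/cm) gives the local wavefront speed `1/|g|`. Neighborhoods with a
#' near-zero gradient (below `grad_floor_frac` of the median gradient) or
#' a poor fit (R-squared below `r2_min`) are excluded. The headline
#' conduction velocity is the median of local speeds (robust to
#' wavefront-collision outliers); the mean is also reported.
#'
#' @param map an [compute_activation_map()] result.
#' @param k neighborhood size, odd (default 5).
#' @param min_quality minimum number of quality pixels (default 100).
#' @param min_fill minimum fraction of quality pixels per neighborhood
#'   (default 0.8).
#' @param grad_floor_frac gradient floor relative to the median gradient
#'   magnitude (default 0.01).
#' @param r2_min minimum plane-fit R-squared (default 0.9).
#' @return object of class `conduction_estimate`: `median_cv` and
#'   `mean_cv` (cm/s), `speed` (per-pixel field, cm/s, `NA` where
#'   excluded), `n_used`, `fraction_quality`, `global_activation` flag.
#'   When activation is simultaneous across the field (no finite speed),
#'   `global_activation` is `TRUE` and the velocities are `NA`.
#' @export
estimate_cv <- function(map, k = 5, min_quality = 100, min_fill = 0.8,
                        grad_floor_frac = 0.01, r2_min = 0.9) {
  stopifnot(inherits(map, "activation_map"), k %% 2 == 1, k >= 3)
  A <- map$act_time
  Q <- map$quality & !is.na(A)
  H <- nrow(A); W <- ncol(A)
  if (sum(Q) < min_quality)
    stop("too few quality pixels (", sum(Q), " < ", min_quality, ")")
  spread <- diff(range(A[Q]))
  if (spread < 0.5 / map$frame_rate) {
    out <- list(median_cv = NA_real_, mean_cv = NA_real_,
                speed = matrix(NA_real_, H, W), n_used = 0L,
                fraction_quality = mean(Q), global_activation = TRUE)
    class(out) <- "conduction_estimate"
    return(out)
  }
  r <- (k - 1L) / 2L
  pitch <- map$pixel_pitch
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  Xfull <- cbind(1, offs$dx * pitch, offs$dy * pitch)
  gx <- matrix(NA_real_, H, W); gy <- matrix(NA_real_, H, W)
  r2 <- matrix(NA_real_, H, W)
  for (i in (1L + r):(H - r)) {
    for (j in (1L + r):(W - r)) {
      block <- A[(i - r):(i + r), (j - r):(j + r)]
      y <- as.vector(block)
      ok <- !is.na(y)
      if (sum(ok) < max(6L, ceiling(min_fill * k * k))) next
      X <- Xfull[ok, , drop = FALSE]
      yv <- y[ok]
      cf <- tryCatch(qr.coef(qr(X), yv), error = function(e) NULL)
      if (is.null(cf) || anyNA(cf)) next
      res <- yv - X %*% cf
      tot <- sum((yv - mean(yv))^2)
      gx[i, j] <- cf[2L]; gy[i, j] <- cf[3L]
      r2[i, j] <- if (tot > 0) 1 - sum(res^2) / tot else 0
    }
  }
  gmag <- sqrt(gx^2 + gy^2)
  med_g <- stats::median(gmag, na.rm = TRUE)
  valid <- !is.na(gmag) & gmag > grad_floor_frac * med_g &
    !is.na(r2) & r2 >= r2_min
  speed <- matrix(NA_real_, H, W)
  speed[valid] <- 1 / gmag[valid]
  vs <- speed[valid]
  if (!length(vs)) {
    out <- list(median_cv = NA_real_, mean_cv = NA_real_, speed = speed,
                n_used = 0L, fraction_quality = mean(Q),
                global_activation = TRUE)
  } else {
    out <- list(median_cv = stats::median(vs), mean_cv = mean(vs),
                speed = speed, n_used = length(vs),
                fraction_quality = mean(Q), global_activation = FALSE)
  }
  class(out) <- "conduction_estimate"
  out
}

#' @export
print.conduction_estimate <- function(x, ...) {
  if (x$global_activation)
    cat("<conduction_estimate> global (simultaneous) activation; no finite CV\n")
  else
    cat(sprintf(
      "<conduction_estimate> median %.2f cm/s, mean %.2f cm/s (n=%d, %.0f%% quality)\n",
      x$median_cv, x$mean_cv, x$n_used, 100 * x$fraction_quality))
  invisible(x)
}

#' Conduction velocity of a recording
#'
#' Convenience wrapper: detects beats on the global trace, selects the
#' first fully-captured propagated beat (by default), builds its
#' activation map and estimates conduction velocity. Averaging over
#' several beats is available via `beats_to_use`.
#'
#' @param movie a [fluor_movie()].
#' @param beats optional beat table from [detect_beats()] on the global
#'   trace; detected automatically when `NULL`.
#' @param beats_to_use indices of beats to map (default 1 = first fully
#'   captured); estimates are averaged (median CV of each, then mean).
#' @param pre,post window margins around the beat onset, s.
#' @param guard margin subtracted before the next beat's onset so its
#'   upstroke (smeared by smoothing) cannot leak into the window, s.
#' @param ... passed to [compute_activation_map()] / [estimate_cv()]
#'   (arguments are routed by name).
#' @return a `conduction_estimate` (for several beats, the one from the
#'   first beat with `median_cv` replaced by the across-beat mean and
#'   attribute `"per_beat"` holding individual medians).
#' @export
recording_cv <- function(movie, beats = NULL, beats_to_use = 1L,
                         pre = 0.05, post = NULL, guard = 0.05, ...) {
  tr <- preprocess_trace(extract_trace(movie, "global"))
  if (is.null(beats)) beats <- detect_beats(tr)
  if (!nrow(beats)) stop("no beats detected in the global trace")
  dots <- list(...)
  map_args <- dots[names(dots) %in% names(formals(compute_activation_map))]
  cv_args <- dots[names(dots) %in% names(formals(estimate_cv))]
  dur <- movie_duration(movie)
  ests <- list()
  for (k in beats_to_use) {
    if (k > nrow(beats)) next
    t0 <- beats$onset[k] - pre
    t1 <- if (!is.null(post)) beats$onset[k] + post
          else if (k < nrow(beats)) beats$onset[k + 1L] - guard
          else min(dur, beats$onset[k] + 1)
    if (t0 < 0 || t1 > dur) next
    m <- do.call(compute_activation_map,
                 c(list(movie = movie, window = c(t0, t1)), map_args))
    ests[[length(ests) + 1L]] <- do.call(estimate_cv,
                                         c(list(map = m), cv_args))
  }
  if (!length(ests)) stop("no fully captured beat available for mapping")
  out <- ests[[1L]]
  meds <- vapply(ests, function(e) e$median_cv, numeric(1))
  out$median_cv <- mean(meds, na.rm = TRUE)
  attr(out, "per_beat") <- meds
  out
}
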