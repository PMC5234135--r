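#' Logan graphical analysis of a time-activity curve
#'
#' For reversible tracers the plot of normalised integrated tissue activity
#' Y(t) = int_0^t C(s) ds / C(t) against normalised integrated plasma
#' activity X(t) = int_0^t cp(s) ds / C(t) becomes linear after an
#' equilibration time t*, with asymptotic slope equal to VT. The plasma
#' integral is accumulated on the dense input-function grid; the tissue
#' integral uses trapezoids on frame mid-times anchored at (0, 0). Frames
#' with non-positive activity are excluded.
#'
#' @param tc a [tac()].
#' @param input_fn a [plasma_input()].
#' @param t_star start of the linear segment, minutes (default 30).
#' @return An object of class `logan_fit` with fields `vt` (slope, mL/cm^3),
#'   `intercept` (min), `t_star`, `n_points` and `max_rel_dev` (largest
#'   relative deviation of the used points from the fitted line).
#' @export
logan_vt <- function(tc, input_fn, t_star = 30) {
  stopifnot(inherits(tc, "tac"), inherits(input_fn, "plasma_input"))
  pts <- logan_points(tc$activity, tc$schedule, input_fn)
  fit <- logan_ols(pts, t_star)
  structure(c(fit, list(t_star = t_star)), class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("<logan_fit> VT=%.3f intercept=%.3g t*=%.1f min (%d points, max rel dev %.3g)\n",
              x$vt, x$intercept, x$t_star, x$n_points, x$max_rel_dev))
  invisible(x)
}

# Logan plot coordinates for every usable frame
logan_points <- function(activity, schedule, input_fn) {
  mids <- schedule$mid
  scan_end <- max(schedule$frame_end)
  n <- length(input_fn$time)
  cint <- c(0, cumsum((input_fn$cp[-1] + input_fn$cp[-n]) / 2 * diff(input_fn$time)))
  int_cp <- stats::approx(input_fn$time, cint, pmin(mids, max(input_fn$time)))$y
  tt <- c(0, mids)
  aa <- c(0, activity)
  int_c <- cumsum(c(0, (aa[-1] + aa[-length(aa)]) / 2 * diff(tt)))[-1]
  usable <- activity > 0
  list(mid = mids, x = int_cp / activity, y = int_c / activity,
       usable = usable, scan_end = scan_end)
}

logan_ols <- function(pts, t_star) {
  if (t_star >= pts$scan_end) {
    stop("t_star must lie within the scan", call. = FALSE)
  }
  sel <- pts$usable & pts$mid >= t_star
  if (sum(sel) < 3L) stop("fewer than 3 usable frames after t_star", call. = FALSE)
  x <- pts$x[sel]; y <- pts$y[sel]
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate Logan abscissa", call. = FALSE)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  yhat <- intercept + slope * x
  list(vt = slope, intercept = intercept, n_points = sum(sel),
       max_rel_dev = max(abs(y - yhat) / pmax(abs(y), .Machine$double.eps)))
}

#' Choose the Logan linearisation start time
#'
#' Returns the earliest frame mid-time from which every later Logan point
#' deviates from the terminal-segment regression line by at most `criterion`
#' (relative to the point's ordinate). The terminal segment is the last
#' max(3, n/4) usable points. If no start time satisfies the criterion the
#' scan midpoint is returned with a warning.
#'
#' @param tc a [tac()].
#' @param input_fn a [plasma_input()].
#' @param criterion maximum tolerated relative deviation, in (0, 0.5)
#'   (default 0.10).
#' @return t* in minutes.
#' @export
choose_t_star <- function(tc, input_fn, criterion = 0.10) {
  if (!is.numeric(criterion) || criterion <= 0 || criterion >= 0.5) {
    stop("criterion must lie in (0, 0.5)", call. = FALSE)
  }
  pts <- logan_points(tc$activity, tc$schedule, input_fn)
  ok <- which(pts$usable)
  if (length(ok) < 4L) stop("too few usable frames", call. = FALSE)
  tail_n <- max(3L, ceiling(length(ok) / 4))
  tail_ix <- ok[(length(ok) - tail_n + 1L):length(ok)]
  x <- pts$x[tail_ix]; y <- pts$y[tail_ix]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  dev <- abs(pts$y[ok] - (a + b * pts$x[ok])) /
    pmax(abs(pts$y[ok]), .Machine$double.eps)
  # earliest index from which all later deviations satisfy the criterion
  later_max <- rev(cummax(rev(dev)))
  good <- which(later_max <= criterion)
  if (!length(good)) {
    warning("no start time satisfies the linearity criterion; using scan midpoint")
    return(pts$scan_end / 2)
  }
  pts$mid[ok[good[1]]]
}

#' Parametric VT image
#'
#' @param values 3D array of VT (mL/cm^3), NaN outside the mask.
#' @param mask 3D logical array.
#' @param voxel_size voxel size, mm.
#' @return An object of class `parametric_image`.
#' @export
parametric_image <- function(values, mask, voxel_size = c(2, 2, 2)) {
  stopifnot(identical(dim(values), dim(mask)))
  structure(list(values = values, mask = mask, voxel_size = as.numeric(voxel_size)),
            class = "parametric_image")
}

#' Voxel-wise Logan parametric VT image
#'
#' Applies [logan_vt()] independently to every voxel inside the mask.
#' Optional Gaussian spatial pre-smoothing of the dynamic series (per frame)
#' tempers voxel-level noise; it is off by default, in which case the result
#' is exactly the voxel-wise ROI computation. Voxels whose fit fails are NaN.
#'
#' @param image a [dynamic_image()].
#' @param input_fn a [plasma_input()].
#' @param t_star Logan start time, minutes.
#' @param mask 3D logical array matching the image's spatial dimensions.
#' @param presmooth_fwhm_mm FWHM of optional spatial pre-smoothing (0 = off).
#' @return A [parametric_image()] of VT.
#' @export
parametric_logan <- function(image, input_fn, t_star = 30, mask,
                             presmooth_fwhm_mm = 0) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$voxels)
  if (!identical(dim(mask), d[1:3])) stop("mask shape mismatch", call. = FALSE)
  if (!any(mask)) stop("mask selects no voxels", call. = FALSE)
  vox <- image$voxels
  if (any(presmooth_fwhm_mm > 0)) {
    for (f in seq_len(d[4])) {
      vox[, , , f] <- gauss_smooth_3d(vox[, , , f], presmooth_fwhm_mm,
                                      image$voxel_size)
    }
  }
  m <- matrix(vox, nrow = prod(d[1:3]), ncol = d[4])
  idx <- which(as.vector(mask))
  out <- rep(NaN, prod(d[1:3]))
  n_ok <- 0L
  for (i in idx) {
    fit <- tryCatch({
      pts <- logan_points(m[i, ], image$schedule, input_fn)
      logan_ols(pts, t_star)
    }, error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$vt)) {
      out[i] <- fit$vt
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) warning("no voxel produced a valid Logan fit")
  parametric_image(array(out, dim = d[1:3]), mask, image$voxel_size)
}
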