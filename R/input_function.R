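#' Arterial blood curve
#'
#' Whole-blood radioactivity over time from either the continuous automatic
#' sampler (`source = "auto"`) or discrete manual samples
#' (`source = "manual"`).
#'
#' @param time sample times, minutes, strictly increasing.
#' @param activity whole-blood activity, kBq/mL.
#' @param source "auto" or "manual".
#' @return An object of class `blood_curve`.
#' @export
blood_curve <- function(time, activity, source = c("auto", "manual")) {
  source <- match.arg(source)
  time <- as.numeric(time); activity <- as.numeric(activity)
  if (length(time) != length(activity)) stop("time/activity length mismatch", call. = FALSE)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(activity))) stop("activity must be finite", call. = FALSE)
  structure(list(time = time, activity = activity, source = source),
            class = "blood_curve")
}

#' @export
print.blood_curve <- function(x, ...) {
  cat(sprintf("<blood_curve> %s, %d samples, %.2f-%.2f min\n",
              x$source, length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Dispersion model for the continuous blood sampler
#'
#' The sampling line smears the true blood curve by convolution with a
#' monoexponential kernel (1/tau) exp(-t/tau). The default time constant is
#' tau = 16 s. Deconvolution is iterative (projected Van Cittert additive
#' updates with a non-negativity constraint); an optional Gaussian smoothing
#' of the result (FWHM in seconds) is available for noisy curves and is off
#' by default because it blunts sharp transients.
#'
#' @param tau_s dispersion time constant, seconds (>= 0).
#' @param n_iter number of deconvolution iterations.
#' @param smooth_fwhm_s FWHM of optional post-smoothing, seconds (0 = none).
#' @return An object of class `dispersion_model`.
#' @export
dispersion_model <- function(tau_s = 16, n_iter = 200, smooth_fwhm_s = 0) {
  if (!is.numeric(tau_s) || tau_s < 0) stop("tau_s must be >= 0", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  structure(list(tau_s = tau_s, n_iter = as.integer(n_iter),
                 smooth_fwhm_s = smooth_fwhm_s),
            class = "dispersion_model")
}

# discrete causal monoexponential kernel on a uniform grid (dt, n in same unit
# as tau); normalised to unit sum so convolution preserves plateaus
exp_kernel <- function(n, dt, tau) {
  k <- exp(-seq(0, by = dt, length.out = n) / tau)
  k / sum(k)
}

causal_conv <- function(x, k) {
  n <- length(x)
  stats::convolve(x, rev(k), type = "open")[seq_len(n)]
}

gauss_smooth_1d <- function(x, dt, fwhm) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  hw <- max(1L, ceiling(4 * sigma / dt))
  g <- stats::dnorm(seq(-hw, hw) * dt, sd = sigma)
  g <- g / sum(g)
  n <- length(x)
  xp <- c(rep(x[1], hw), x, rep(x[n], hw))
  stats::convolve(xp, rev(g), type = "open")[hw + seq_len(n) + hw]
}

#' Forward dispersion: convolve a blood curve with the sampler kernel
#'
#' @param curve a [blood_curve()] on a uniform time grid.
#' @param tau_s dispersion time constant, seconds.
#' @return A [blood_curve()] of the dispersed (measured) signal.
#' @export
dispersion_convolve <- function(curve, tau_s) {
  stopifnot(inherits(curve, "blood_curve"))
  if (tau_s <= 0) return(curve)
  dt <- check_uniform(curve$time)
  k <- exp_kernel(length(curve$time), dt, tau_s / 60)
  blood_curve(curve$time, causal_conv(curve$activity, k), curve$source)
}

check_uniform <- function(time) {
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    stop("curve must be on a uniform time grid", call. = FALSE)
  }
  dt[1]
}

#' Correct a measured blood curve for sampler dispersion
#'
#' Recovers g such that g convolved with the monoexponential kernel
#' reproduces the measured curve. The default iterative scheme is projected
#' Van Cittert: g <- max(g + (m - K g), 0), which converges geometrically for
#' the monoexponential kernel. `method = "direct"` applies the analytic
#' inverse g = m + tau m' (central differences) and serves as an independent
#' cross-check.
#'
#' @param measured a [blood_curve()] on a uniform grid (resampled internally
#'   if not uniform).
#' @param model a [dispersion_model()].
#' @param method "vancittert" (iterative, default) or "direct".
#' @return A [blood_curve()] of the dispersion-corrected signal
#'   (non-negative).
#' @export
dispersion_correct <- function(measured, model = dispersion_model(),
                               method = c("vancittert", "direct")) {
  stopifnot(inherits(measured, "blood_curve"), inherits(model, "dispersion_model"))
  method <- match.arg(method)
  if (model$tau_s == 0) return(measured)
  t_min <- measured$time
  dt <- diff(t_min)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1]) {
    grid <- seq(min(t_min), max(t_min), by = stats::median(dt))
    act <- stats::approx(t_min, measured$activity, grid)$y
    t_min <- grid
  } else {
    act <- measured$activity
  }
  dtm <- t_min[2] - t_min[1]
  tau_min <- model$tau_s / 60
  if (method == "direct") {
    n <- length(act)
    dm <- c(act[2] - act[1],
            (act[-(1:2)] - act[seq_len(n - 2)]) / 2,
            act[n] - act[n - 1]) / dtm
    g <- pmax(act + tau_min * dm, 0)
  } else {
    k <- exp_kernel(length(act), dtm, tau_min)
    g <- act
    for (it in seq_len(model$n_iter)) {
      g <- pmax(g + (act - causal_conv(g, k)), 0)
    }
  }
  if (model$smooth_fwhm_s > 0) {
    g <- pmax(gauss_smooth_1d(g, dtm, model$smooth_fwhm_s / 60), 0)
  }
  blood_curve(t_min, g, measured$source)
}

#' Fit a bi-exponential blood-to-plasma ratio model
#'
#' r(t) = A1 exp(-lambda1 t) + A2 exp(-lambda2 t), fitted by bounded
#' least squares to observed whole-blood / plasma activity ratios. Constant
#' ratios are captured by the lambda -> 0 limit; the contract is the
#' predicted curve, not the (possibly degenerate) parameters.
#'
#' @param time observation times, minutes (>= 4 observations).
#' @param ratio observed blood-to-plasma ratios (> 0).
#' @return An object of class `b2p_model` with fields `A1`, `lambda1`, `A2`,
#'   `lambda2`.
#' @export
fit_blood_to_plasma <- function(time, ratio) {
  time <- as.numeric(time); ratio <- as.numeric(ratio)
  if (length(time) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (any(ratio <= 0)) stop("ratios must be positive", call. = FALSE)
  # crude mono-exponential init from a log-linear fit
  lf <- stats::lm(log(ratio) ~ time)
  A0 <- exp(stats::coef(lf)[1]); l0 <- max(-stats::coef(lf)[2], 0)
  start <- c(A1 = A0 / 2, l1 = l0 * 3 + 0.05, A2 = A0 / 2, l2 = l0 / 3)
  res_fn <- function(p) p[1] * exp(-p[2] * time) + p[3] * exp(-p[4] * time) - ratio
  fit <- minpack.lm::nls.lm(start, lower = c(0, 0, 0, 0),
                            upper = c(Inf, 20, Inf, 20), fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  structure(list(A1 = p[[1]], lambda1 = p[[2]], A2 = p[[3]], lambda2 = p[[4]]),
            class = "b2p_model")
}

#' Blood-to-plasma ratio model from known coefficients
#' @param A1,lambda1,A2,lambda2 bi-exponential coefficients (lambdas >= 0,
#'   1/min).
#' @return A `b2p_model`.
#' @export
b2p_model <- function(A1, lambda1, A2, lambda2) {
  if (lambda1 < 0 || lambda2 < 0) stop("lambdas must be >= 0", call. = FALSE)
  structure(list(A1 = A1, lambda1 = lambda1, A2 = A2, lambda2 = lambda2),
            class = "b2p_model")
}

#' @export
predict.b2p_model <- function(object, time, ...) {
  object$A1 * exp(-object$lambda1 * time) + object$A2 * exp(-object$lambda2 * time)
}

#' Fit a Hill model of the plasma parent fraction
#'
#' fp(t) = 1 - a t^b / (c + t^b): the fraction of plasma radioactivity still
#' attributable to unmetabolised parent radioligand, 1 at injection and
#' monotone non-increasing.
#'
#' @param time observation times, minutes (>= 4 observations).
#' @param parent_fraction observed parent fractions in \[0, 1\].
#' @return An object of class `hill_model` with fields `a` (in \[0,1\]),
#'   `b` (> 0) and `c` (> 0, units min^b).
#' @export
fit_hill_parent_fraction <- function(time, parent_fraction) {
  time <- as.numeric(time); pf <- as.numeric(parent_fraction)
  if (length(time) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (any(pf < 0 | pf > 1)) {
    stop("parent fractions must lie in [0, 1]", call. = FALSE)
  }
  a0 <- min(max(1 - min(pf), 0), 1)
  if (a0 < 1e-8) {
    return(structure(list(a = 0, b = 1, c = 1), class = "hill_model"))
  }
  # half-saturation guess: time at which half the eventual loss is reached
  target <- 1 - a0 / 2
  ix <- which(pf <= target)
  t_half <- if (length(ix)) max(time[min(ix)], 1e-3) else stats::median(time)
  start <- c(a = a0, b = 2, c = t_half^2)
  res_fn <- function(p) 1 - p[1] * time^p[2] / (p[3] + time^p[2]) - pf
  fit <- minpack.lm::nls.lm(start, lower = c(0, 1e-3, 1e-9),
                            upper = c(1, 10, Inf), fn = res_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  structure(list(a = p[[1]], b = p[[2]], c = p[[3]]), class = "hill_model")
}

#' Hill parent-fraction model from known coefficients
#' @param a amplitude in \[0,1\]; `b` Hill exponent > 0; `c` half-saturation
#'   constant > 0 (min^b).
#' @param b,c see `a`.
#' @return A `hill_model`.
#' @export
hill_model <- function(a, b, c) {
  if (a < 0 || a > 1 || b <= 0 || c <= 0) stop("invalid Hill parameters", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "hill_model")
}

#' @export
predict.hill_model <- function(object, time, ...) {
  tb <- pmax(time, 0)^object$b
  1 - object$a * tb / (object$c + tb)
}

#' Merge continuous-sampler and manual blood data onto a dense grid
#'
#' Combines the (dispersion-corrected) automatic sampler curve with the
#' timed manual samples: the auto curve is used up to its end (optionally
#' rescaled so its value at the first manual sample time inside its support
#' matches that sample, cross-calibrating sampler vs well counter), manual
#' samples carry the curve beyond, bridged by log-linear interpolation, and a
#' single exponential fitted to the last `tail_n` manual samples extrapolates
#' past the last sample.
#'
#' @param auto a [blood_curve()] (`source = "auto"`), already
#'   dispersion-corrected.
#' @param manual a [blood_curve()] (`source = "manual"`) or data.frame with
#'   columns `time` and `activity`.
#' @param grid output time grid, minutes (default 1-s spacing over 0-125
#'   min).
#' @param scale_to_manual rescale the auto curve to the first overlapping
#'   manual sample (default TRUE when an overlap exists).
#' @param tail_n number of terminal manual samples in the tail fit (>= 3).
#' @return A [blood_curve()] on `grid`.
#' @export
merge_blood_samples <- function(auto, manual = NULL,
                                grid = default_time_grid(),
                                scale_to_manual = TRUE, tail_n = 3) {
  stopifnot(inherits(auto, "blood_curve"))
  if (inherits(manual, "blood_curve")) {
    manual <- data.frame(time = manual$time, activity = manual$activity)
  }
  auto_end <- max(auto$time)
  m_t <- if (is.null(manual)) numeric(0) else as.numeric(manual$time)
  m_a <- if (is.null(manual)) numeric(0) else as.numeric(manual$activity)
  auto_act <- auto$activity
  inside <- which(m_t <= auto_end & m_t >= min(auto$time))
  if (scale_to_manual && length(inside)) {
    i0 <- inside[1]
    ref <- stats::approx(auto$time, auto_act, m_t[i0])$y
    if (is.finite(ref) && ref > 0) auto_act <- auto_act * (m_a[i0] / ref)
  }
  out <- numeric(length(grid))
  early <- grid <= auto_end
  out[early] <- stats::approx(auto$time, auto_act, grid[early], rule = 2)$y
  if (any(!early)) {
    later <- which(m_t > auto_end)
    if (!length(later)) {
      stop("no manual samples beyond the sampler window: cannot extrapolate tail",
           call. = FALSE)
    }
    # interpolation nodes: continuity point at auto end, then manual samples
    nt <- c(auto_end, m_t[later])
    na <- c(stats::approx(auto$time, auto_act, auto_end, rule = 2)$y, m_a[later])
    # exponential tail from the last tail_n manual samples
    k <- later[max(1L, length(later) - tail_n + 1L):length(later)]
    if (length(k) >= 2L && all(m_a[k] > 0)) {
      tf <- stats::lm(log(m_a[k]) ~ m_t[k])
      tail_A <- exp(stats::coef(tf)[[1]]); tail_l <- -stats::coef(tf)[[2]]
    } else {
      tail_A <- na[length(na)]; tail_l <- 0
    }
    mid <- !early & grid <= max(nt)
    if (any(mid)) {
      pos <- all(na > 0)
      out[mid] <- if (pos) {
        exp(stats::approx(nt, log(na), grid[mid])$y)
      } else {
        stats::approx(nt, na, grid[mid])$y
      }
    }
    late <- grid > max(nt)
    if (any(late)) out[late] <- tail_A * exp(-tail_l * grid[late])
  }
  blood_curve(grid, pmax(out, 0), "auto")
}

#' Default dense evaluation grid for input functions
#' @param end_min end of the grid, minutes.
#' @param dt_s grid spacing, seconds.
#' @return Numeric vector of times in minutes, starting at 0.
#' @export
default_time_grid <- function(end_min = 125, dt_s = 1) {
  seq(0, end_min, by = dt_s / 60)
}

#' Metabolite- and dispersion-corrected plasma input function
#'
#' @param time dense time grid, minutes, strictly increasing from 0.
#' @param cp parent (unmetabolised) plasma activity, kBq/mL.
#' @param whole_blood whole-blood activity on the same grid, kBq/mL.
#' @param components optional list of the fitted component models.
#' @return An object of class `plasma_input`.
#' @export
plasma_input <- function(time, cp, whole_blood, components = list()) {
  time <- as.numeric(time)
  if (time[1] != 0) stop("input-function grid must start at 0", call. = FALSE)
  if (any(diff(time) <= 0)) stop("grid must be strictly increasing", call. = FALSE)
  if (length(cp) != length(time) || length(whole_blood) != length(time)) {
    stop("cp/whole_blood must match the grid length", call. = FALSE)
  }
  if (any(cp < 0)) stop("cp must be non-negative", call. = FALSE)
  structure(list(time = time, cp = as.numeric(cp),
                 whole_blood = as.numeric(whole_blood),
                 components = components),
            class = "plasma_input")
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf("<plasma_input> %d points over %.1f min, peak cp %.3g kBq/mL\n",
              length(x$time), max(x$time), max(x$cp)))
  invisible(x)
}

#' Build the plasma input function from blood data and component models
#'
#' cp(t) = \[whole_blood(t) / r(t)\] * fp(t): the whole-blood curve is divided
#' by the blood-to-plasma ratio to obtain total plasma activity, then scaled
#' by the parent fraction to keep only unmetabolised radioligand. Negative
#' values are clipped at zero.
#'
#' @param blood merged, dispersion-corrected whole-blood [blood_curve()].
#' @param b2p a `b2p_model` (blood-to-plasma ratio).
#' @param fp a `hill_model` (parent fraction).
#' @param grid dense evaluation grid, minutes.
#' @return A [plasma_input()].
#' @export
build_plasma_input <- function(blood, b2p, fp, grid = default_time_grid()) {
  stopifnot(inherits(blood, "blood_curve"),
            inherits(b2p, "b2p_model"), inherits(fp, "hill_model"))
  wb <- stats::approx(blood$time, blood$activity, grid, rule = 2)$y
  r <- predict(b2p, grid)
  if (any(r <= 0)) {
    stop("blood-to-plasma ratio model is non-positive on the grid", call. = FALSE)
  }
  cp <- pmax(wb / r * predict(fp, grid), 0)
  plasma_input(grid, cp, wb,
               components = list(b2p = b2p, parent_fraction = fp))
}

#' Read blood sampling data
#'
#' Delimited file with columns `time_min`, `activity_kBq_ml`, `source`
#' (auto|manual) and, for manual rows, optional `plasma_activity_kBq_ml` and
#' `parent_fraction`.
#'
#' @param path file path.
#' @return List with `auto` ([blood_curve()]), `manual` (data.frame of the
#'   manual rows).
#' @export
read_blood_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "",
                          stringsAsFactors = FALSE)
  need <- c("time_min", "activity_kBq_ml", "source")
  if (!all(need %in% names(df))) {
    stop("blood table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  a <- df[df$source == "auto", ]
  m <- df[df$source == "manual", ]
  list(
    auto = blood_curve(a$time_min, a$activity_kBq_ml, "auto"),
    manual = data.frame(
      time = m$time_min, activity = m$activity_kBq_ml,
      plasma = if ("plasma_activity_kBq_ml" %in% names(m)) m$plasma_activity_kBq_ml else NA_real_,
      parent_fraction = if ("parent_fraction" %in% names(m)) m$parent_fraction else NA_real_
    )
  )
}

#' Write an input function to a delimited file
#' @param input a [plasma_input()].
#' @param path output path (`.tsv` selects tab separation).
#' @return `path`, invisibly.
#' @export
write_plasma_input <- function(input, path) {
  df <- data.frame(time_min = input$time, cp_kBq_ml = input$cp,
                   whole_blood_kBq_ml = input$whole_blood)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an input function written by [write_plasma_input()]
#' @param path file path.
#' @return A [plasma_input()].
#' @export
read_plasma_input <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  plasma_input(df$time_min, df$cp_kBq_ml, df$whole_blood_kBq_ml)
}
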