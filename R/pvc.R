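#' Tissue probability maps
#'
#' Gray matter, white matter and CSF probability volumes used by the
#' Mueller-Gartner correction.
#'
#' @param gm,wm,csf 3D arrays of probabilities in \[0, 1\], identical shape;
#'   their voxel-wise sum must not exceed 1.
#' @param voxel_size voxel size, mm.
#' @return An object of class `tissue_probability_maps`.
#' @export
tissue_probability_maps <- function(gm, wm, csf, voxel_size = c(2, 2, 2)) {
  if (!identical(dim(gm), dim(wm)) || !identical(dim(gm), dim(csf))) {
    stop("maps must share one shape", call. = FALSE)
  }
  for (m in list(gm, wm, csf)) {
    if (any(m < 0 | m > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(gm + wm + csf > 1 + 1e-6)) {
    stop("gm + wm + csf must not exceed 1", call. = FALSE)
  }
  structure(list(gm = gm, wm = wm, csf = csf, voxel_size = as.numeric(voxel_size)),
            class = "tissue_probability_maps")
}

#' Scanner point-spread function
#'
#' @param fwhm_mm full width at half maximum per axis, mm. The default
#'   (4.4, 4.4, 4.5) is the HRRT reconstructed resolution (4.4 mm in-plane,
#'   4.5 mm axial).
#' @return An object of class `point_spread_function`.
#' @export
point_spread_function <- function(fwhm_mm = c(4.4, 4.4, 4.5)) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(fwhm_mm <= 0)) stop("fwhm must be positive", call. = FALSE)
  structure(list(fwhm_mm = fwhm_mm), class = "point_spread_function")
}

# separable 3D Gaussian convolution with zero boundary (a true PSF model:
# signal spills out of the volume rather than being renormalised at edges)
gauss_smooth_3d <- function(arr, fwhm_mm, voxel_mm) {
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    sigma <- fwhm_mm[ax] / (2 * sqrt(2 * log(2)))
    if (sigma < 1e-6 * voxel_mm[ax]) next
    n <- d[ax]
    hw <- max(1L, ceiling(4 * sigma / voxel_mm[ax]))
    w <- stats::dnorm(seq(-hw, hw) * voxel_mm[ax], sd = sigma)
    w <- w / sum(w)
    K <- matrix(0, n, n)
    for (k in seq(-hw, hw)) {
      i <- seq_len(n)
      j <- i + k
      ok <- j >= 1 & j <= n
      K[cbind(i[ok], j[ok])] <- w[k + hw + 1]
    }
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    a <- aperm(out, perm)
    da <- dim(a)
    a <- K %*% matrix(a, nrow = da[1])
    dim(a) <- da
    out <- aperm(a, order(perm))
  }
  out
}

# 6-neighbour binary erosion
erode_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    src <- dst <- lapply(d, seq_len)
    n <- d[ax]
    if (by > 0) { dst[[ax]] <- (1 + by):n; src[[ax]] <- 1:(n - by) }
    else { dst[[ax]] <- 1:(n + by); src[[ax]] <- (1 - by):n }
    r[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(-1, 1)) out <- out & shift(mask, ax, by)
  out
}

#' Mueller-Gartner partial-volume correction of one PET frame
#'
#' Corrects gray-matter activity for resolution-induced spill-over:
#' GM_corrected = (frame - C_wm smooth(wm) - C_csf smooth(csf)) / smooth(gm),
#' evaluated where smooth(gm) exceeds `gm_threshold` and NaN elsewhere.
#' smooth() is Gaussian convolution with the scanner PSF. CSF activity is
#' assumed zero; the white-matter estimate is either supplied or taken as
#' the frame mean over voxels with wm probability > 0.95 after one-voxel
#' erosion (deep white matter, minimally contaminated by GM spill-in).
#'
#' @param frame 3D activity array, kBq/mL.
#' @param maps a [tissue_probability_maps()] of the same shape.
#' @param psf a [point_spread_function()].
#' @param wm_estimate "auto" or a numeric white-matter activity, kBq/mL.
#' @param csf_estimate CSF activity (default 0).
#' @param gm_threshold smooth(gm) validity threshold (default 0.3).
#' @return 3D array of corrected GM activity (NaN outside the valid mask),
#'   with the white-matter estimate attached as attribute `"c_wm"`.
#' @export
mueller_gartner <- function(frame, maps, psf = point_spread_function(),
                            wm_estimate = "auto", csf_estimate = 0,
                            gm_threshold = 0.3) {
  stopifnot(inherits(maps, "tissue_probability_maps"),
            inherits(psf, "point_spread_function"))
  if (!identical(dim(frame), dim(maps$gm))) {
    stop("frame and maps must share one shape", call. = FALSE)
  }
  if (identical(wm_estimate, "auto")) {
    core <- erode_mask(maps$wm > 0.95)
    if (!any(core)) {
      stop("no deep white-matter voxels (wm > 0.95 after erosion); ",
           "supply wm_estimate", call. = FALSE)
    }
    c_wm <- mean(frame[core])
  } else {
    c_wm <- as.numeric(wm_estimate)
  }
  sm <- function(x) gauss_smooth_3d(x, psf$fwhm_mm, maps$voxel_size)
  sgm <- sm(maps$gm)
  num <- frame - c_wm * sm(maps$wm)
  if (csf_estimate != 0) num <- num - csf_estimate * sm(maps$csf)
  out <- num / sgm
  out[sgm <= gm_threshold] <- NaN
  attr(out, "c_wm") <- c_wm
  out
}

#' Frame-by-frame Mueller-Gartner correction of a dynamic image
#'
#' The white-matter estimate is derived independently for each frame (white
#' matter has its own kinetics), unless a numeric vector of per-frame values
#' is supplied.
#'
#' @param image a [dynamic_image()].
#' @param maps a [tissue_probability_maps()].
#' @param psf a [point_spread_function()].
#' @param wm_estimate "auto" or numeric vector (length 1 or n frames).
#' @param ... passed to [mueller_gartner()].
#' @return A [dynamic_image()] of corrected GM activity (NaN outside the
#'   valid gray-matter mask).
#' @export
pvc_dynamic <- function(image, maps, psf = point_spread_function(),
                        wm_estimate = "auto", ...) {
  stopifnot(inherits(image, "dynamic_image"))
  d <- dim(image$voxels)
  if (!identical(d[1:3], dim(maps$gm))) stop("shape mismatch", call. = FALSE)
  out <- image$voxels
  for (f in seq_len(d[4])) {
    wmf <- if (identical(wm_estimate, "auto")) "auto"
           else rep_len(wm_estimate, d[4])[f]
    cf <- mueller_gartner(image$voxels[, , , f], maps, psf,
                          wm_estimate = wmf, ...)
    attr(cf, "c_wm") <- NULL
    out[, , , f] <- cf
  }
  dynamic_image(out, image$schedule, image$voxel_size)
}
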