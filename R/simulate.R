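#' Reference regional VT calibration table
#'
#' Regional [18F]-FEPPA VT group means and standard deviations (mL/cm^3)
#' for the four disease x TSPO-genotype cells of a 52-subject PD/HC cohort
#' (HC: 11 MAB, 11 HAB; PD: 14 MAB, 16 HAB), across ten cortical and
#' subcortical ROIs. HABs run roughly 30-45% above MABs in every region.
#' These values are the default calibration of the cohort generator.
#'
#' @return data.frame with columns `roi`, `disease`, `genotype`, `mean`,
#'   `sd`, `n`.
#' @export
feppa_reference_cells <- function() {
  rois <- c("frontal", "temporal", "cingulate", "occipital", "insula",
            "hippocampus", "cerebellum", "thalamus", "caudate", "putamen")
  # per ROI: HC-MAB mean/sd, HC-HAB mean/sd, PD-MAB mean/sd, PD-HAB mean/sd
  m <- rbind(
    frontal     = c(13.9, 2.8, 19.4, 2.8, 11.8, 0.2, 18.7, 1.6),
    temporal    = c(11.9, 2.9, 16.1, 1.8, 11.4, 1.2, 16.6, 1.2),
    cingulate   = c( 9.9, 1.6, 12.3, 1.5,  8.2, 0.0, 13.7, 1.1),
    occipital   = c(12.3, 2.7, 17.2, 2.4, 13.6, 3.0, 18.3, 1.4),
    insula      = c(10.6, 1.8, 14.0, 1.6,  9.8, 0.6, 15.7, 1.3),
    hippocampus = c( 8.7, 1.9, 10.4, 1.4,  8.6, 2.4, 12.4, 1.2),
    cerebellum  = c( 9.6, 2.2, 14.8, 1.6,  9.2, 0.7, 14.7, 1.3),
    thalamus    = c(12.8, 3.6, 16.8, 2.6, 13.5, 2.2, 19.9, 2.0),
    caudate     = c( 8.1, 1.8, 12.4, 1.6,  7.2, 0.3, 12.9, 1.0),
    putamen     = c( 8.0, 1.8, 13.5, 1.3,  7.8, 0.4, 12.4, 1.1)
  )
  ns <- c(hc_mab = 11L, hc_hab = 11L, pd_mab = 14L, pd_hab = 16L)
  cells <- data.frame(
    roi = rep(rois, each = 4),
    disease = rep(c("HC", "HC", "PD", "PD"), times = 10),
    genotype = rep(c("MAB", "HAB", "MAB", "HAB"), times = 10),
    mean = as.vector(t(m[, c(1, 3, 5, 7)])),
    sd = as.vector(t(m[, c(2, 4, 6, 8)])),
    n = rep(unname(ns[c("hc_mab", "hc_hab", "pd_mab", "pd_hab")]), times = 10)
  )
  cells
}

#' Default FEPPA-like plasma model components
#'
#' Blood-to-plasma ratio and parent-fraction models with coefficients giving
#' realistic FEPPA plasma behaviour: the blood-to-plasma ratio declines from
#' about 1.1 towards 0.8 over the scan, and the parent fraction falls to
#' roughly 12% by 120 min.
#'
#' @return list with elements `b2p` (a `b2p_model`) and `parent_fraction`
#'   (a `hill_model`).
#' @export
feppa_plasma_models <- function() {
  list(b2p = b2p_model(A1 = 0.30, lambda1 = 0.15, A2 = 0.82, lambda2 = 4e-4),
       parent_fraction = hill_model(a = 0.90, b = 2, c = 400))
}

#' Simulate a FEPPA-like arterial input function and its blood observations
#'
#' Constructs a ground-truth parent plasma curve (linear rise to a bolus
#' peak, tri-exponential washout), derives total plasma via the parent
#' fraction and whole blood via the blood-to-plasma ratio, then emulates the
#' measurement process: the continuous sampler sees the dispersion-convolved
#' blood curve over the first 22.5 min at 1 Hz, and timed manual samples
#' (default 2.5, 7, 12, 15, 30, 45, 60, 90, 120 min) provide whole-blood and
#' plasma activity plus parent-fraction measurements, all with seeded
#' multiplicative noise.
#'
#' @param peak_time bolus peak time, minutes (> 0).
#' @param peak_value parent plasma activity at the peak, kBq/mL.
#' @param washout list with `fractions` (summing to 1) and `rates` (1/min)
#'   of the tri-exponential washout.
#' @param b2p blood-to-plasma ratio model.
#' @param fp parent-fraction Hill model.
#' @param tau_s sampler dispersion time constant, seconds.
#' @param manual_times manual sampling schedule, minutes.
#' @param auto_end_min end of the continuous sampling window, minutes.
#' @param auto_noise,manual_noise multiplicative noise SD for sampler and
#'   manual measurements.
#' @param grid dense evaluation grid, minutes.
#' @param seed integer seed (NULL = do not touch the RNG state).
#' @return list with `truth` (a [plasma_input()] holding true cp and whole
#'   blood), `observations` (list: `auto` [blood_curve()], `manual`
#'   data.frame with `time`, `activity`, `plasma`, `parent_fraction`) and
#'   `models` (the generating component models and `tau_s`).
#' @export
simulate_input_function <- function(peak_time = 0.75, peak_value = 100,
                                    washout = list(fractions = c(0.55, 0.35, 0.10),
                                                   rates = c(4, 0.5, 0.02)),
                                    b2p = feppa_plasma_models()$b2p,
                                    fp = feppa_plasma_models()$parent_fraction,
                                    tau_s = 16,
                                    manual_times = c(2.5, 7, 12, 15, 30, 45, 60, 90, 120),
                                    auto_end_min = 22.5,
                                    auto_noise = 0.01, manual_noise = 0.02,
                                    grid = default_time_grid(), seed = NULL) {
  if (peak_time <= 0) stop("peak_time must be positive", call. = FALSE)
  if (any(washout$rates <= 0)) stop("washout rates must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fr <- washout$fractions / sum(washout$fractions)
  cp_at <- function(t) {
    rise <- pmin(t / peak_time, 1)
    tpost <- pmax(t - peak_time, 0)
    decay <- rowSums(vapply(seq_along(fr),
                            function(i) fr[i] * exp(-washout$rates[i] * tpost),
                            numeric(length(t))))
    peak_value * rise * decay
  }
  cp <- cp_at(grid)
  fp_g <- predict(fp, grid)
  plasma_total <- cp / pmax(fp_g, 1e-9)
  wb <- plasma_total * predict(b2p, grid)
  truth <- plasma_input(grid, cp, wb,
                        components = list(b2p = b2p, parent_fraction = fp))

  # continuous sampler: dispersed blood at 1 Hz over the sampling window
  auto_t <- grid[grid <= auto_end_min]
  wb_curve <- blood_curve(grid, wb, "auto")
  dispersed <- dispersion_convolve(wb_curve, tau_s)
  auto_a <- dispersed$activity[grid <= auto_end_min]
  if (auto_noise > 0) {
    auto_a <- pmax(auto_a * (1 + stats::rnorm(length(auto_a), 0, auto_noise)), 0)
  }
  mt <- manual_times
  noisy <- function(x, s) if (s > 0) pmax(x * (1 + stats::rnorm(length(x), 0, s)), 0) else x
  wb_m <- noisy(stats::approx(grid, wb, mt)$y, manual_noise)
  pl_m <- noisy(stats::approx(grid, plasma_total, mt)$y, manual_noise)
  pf_m <- pmin(pmax(noisy(predict(fp, mt), manual_noise), 0), 1)
  list(
    truth = truth,
    observations = list(
      auto = blood_curve(auto_t, auto_a, "auto"),
      manual = data.frame(time = mt, activity = wb_m, plasma = pl_m,
                          parent_fraction = pf_m)
    ),
    models = list(b2p = b2p, parent_fraction = fp, tau_s = tau_s)
  )
}

#' Draw 2-TCM micro-parameters realising a target VT exactly
#'
#' Samples (k2, k3/k4, k4) from plausibility priors and sets
#' K1 = VT k2 / (1 + k3/k4) so that [compute_vt()] returns the target
#' exactly. Draws violating the K1 bound are rejected and redrawn.
#'
#' @param target_vt target VT, mL/cm^3 (> 0).
#' @param k2_range,k3k4_range,k4_range uniform prior ranges for k2 (1/min),
#'   the k3/k4 ratio and k4 (1/min).
#' @param vb blood volume fraction stored in the result.
#' @param seed integer seed (NULL = do not touch the RNG state).
#' @return A [two_tissue_params()] with `compute_vt()` equal to `target_vt`.
#' @export
params_for_target_vt <- function(target_vt, k2_range = c(0.05, 0.3),
                                 k3k4_range = c(0.5, 4), k4_range = c(0.01, 0.06),
                                 vb = 0.05, seed = NULL) {
  if (target_vt <= 0) stop("target_vt must be positive", call. = FALSE)
  for (rg in list(k2_range, k3k4_range, k4_range)) {
    if (length(rg) != 2L || rg[2] < rg[1]) stop("invalid prior range", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  for (try in 1:200) {
    k2 <- stats::runif(1, k2_range[1], k2_range[2])
    ratio <- stats::runif(1, k3k4_range[1], k3k4_range[2])
    k4 <- stats::runif(1, k4_range[1], k4_range[2])
    K1 <- target_vt * k2 / (1 + ratio)
    if (K1 > 0 && K1 <= 2) {
      return(two_tissue_params(K1, k2, ratio * k4, k4, vb = vb))
    }
  }
  stop("could not realise target VT within the K1 bound; widen the priors",
       call. = FALSE)
}

#' Cohort simulation design
#'
#' Defines the generating conditions for a genotype-stratified PD/HC cohort:
#' cell sizes, the regional calibration table, the disease effect, the TAC
#' noise level and the targeted QC pass fraction. By default the disease
#' null holds exactly: the generating mean for each (ROI, genotype) is the
#' sample-size-weighted average of the calibrated HC and PD cell means (the
#' calibrated cells are one noisy realisation; the reference analysis found
#' no disease effect), with `disease_effect` (default 0) added to PD cells.
#' Set `disease_null = FALSE` to use the calibrated cell means verbatim.
#'
#' @param n_per_cell named integer vector `hc_mab`, `hc_hab`, `pd_mab`,
#'   `pd_hab` (defaults 11/11/14/16).
#' @param cells calibration data.frame as from [feppa_reference_cells()].
#' @param disease_null impose a true disease null (default TRUE).
#' @param disease_effect additive VT shift applied to PD cells, mL/cm^3.
#' @param noise_pct proportional TAC noise SD, percent (mode "fit").
#' @param qc_pass_target targeted fraction of fits passing %COV <= 20.
#' @param injected injected-amount distribution: named vector `hc_mean`,
#'   `hc_sd`, `pd_mean`, `pd_sd` (mCi).
#' @param seed default integer seed used by [simulate_cohort()].
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_cell = c(hc_mab = 11, hc_hab = 11,
                                         pd_mab = 14, pd_hab = 16),
                          cells = feppa_reference_cells(),
                          disease_null = TRUE, disease_effect = 0,
                          noise_pct = 5, qc_pass_target = 0.75,
                          injected = c(hc_mean = 4.79, hc_sd = 0.22,
                                       pd_mean = 5.04, pd_sd = 0.27),
                          seed = 1L) {
  if (any(n_per_cell < 0)) stop("cell sizes must be >= 0", call. = FALSE)
  if (any(cells$mean <= 0)) stop("calibration means must be positive", call. = FALSE)
  structure(list(n_per_cell = n_per_cell, cells = cells,
                 disease_null = isTRUE(disease_null),
                 disease_effect = disease_effect, noise_pct = noise_pct,
                 qc_pass_target = qc_pass_target, injected = injected,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# generating mean/SD per (roi, disease, genotype) under the design; under the
# disease null, HC and PD are identically distributed within genotype (means
# n-weighted, variances df-pooled), so the null holds in distribution and not
# merely in expectation
generating_means <- function(design) {
  cells <- design$cells
  out <- cells
  if (!design$disease_null) {
    out$gen_mean <- out$mean
    out$gen_sd <- out$sd
  } else {
    out$gen_mean <- NA_real_
    out$gen_sd <- NA_real_
    for (r in unique(cells$roi)) for (g in c("HAB", "MAB")) {
      ix <- cells$roi == r & cells$genotype == g
      w <- cells$n[ix]
      out$gen_mean[ix] <- sum(cells$mean[ix] * w) / sum(w)
      out$gen_sd[ix] <- sqrt(sum((w - 1) * cells$sd[ix]^2) / sum(w - 1))
    }
  }
  out$gen_mean[out$disease == "PD"] <- out$gen_mean[out$disease == "PD"] +
    design$disease_effect
  out
}

# vectorised positive-truncated normal (mean/sd recycled over n)
rtruncnorm_pos <- function(n, mean, sd, floor = 0.1) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- ifelse(sd > 0, stats::rnorm(n, mean, sd), mean)
  for (try in 1:100) {
    bad <- which(x <= floor & sd > 0)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
  }
  x[x <= floor] <- floor
  x
}

#' Simulate a genotype-stratified cohort of fitted VT values
#'
#' Two modes. `mode = "fast"` (default) draws each subject's fitted VT from
#' the design's generating cell distribution (truncated normal) and draws a
#' %COV for every (subject, ROI) from a lognormal model whose median is
#' calibrated so that the targeted fraction of estimates passes the
#' %COV <= 20 filter; the subject-level component dominates, so retention is
#' correlated across ROIs within subject, as in real data where scan quality
#' is a subject property. `mode = "fit"` realises every (subject, ROI)
#' through the full pipeline: micro-parameters via [params_for_target_vt()],
#' a simulated noisy TAC via [simulate_2tcm()] (proportional Gaussian noise,
#' frame-duration scaled), and an actual [fit_2tcm()]; it is exact but far
#' slower and intended for reduced problem sizes.
#'
#' @param design a [cohort_design()].
#' @param mode "fast" or "fit".
#' @param input_fn a [plasma_input()] (required for mode "fit"; defaults to
#'   the noise-free truth of [simulate_input_function()]).
#' @param schedule frame schedule for mode "fit".
#' @param cov_threshold %COV QC threshold.
#' @param seed integer seed (default from the design).
#' @return list with `table` (QC-filtered [cohort_table()]), `raw`
#'   (unfiltered table), and `truth` (list: `vt` data.frame of true VT,
#'   `params` list of generating micro-parameters for mode "fit",
#'   `design`).
#' @export
simulate_cohort <- function(design = cohort_design(), mode = c("fast", "fit"),
                            input_fn = NULL, schedule = feppa_frame_schedule(),
                            cov_threshold = 20, seed = design$seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "cohort_design"))
  if (!is.null(seed)) set.seed(seed)
  gm <- generating_means(design)
  n <- design$n_per_cell
  subj <- data.frame(
    subject_id = sprintf("S%03d", seq_len(sum(n))),
    disease = rep(c("HC", "HC", "PD", "PD"),
                  times = n[c("hc_mab", "hc_hab", "pd_mab", "pd_hab")]),
    genotype = rep(c("MAB", "HAB", "MAB", "HAB"),
                   times = n[c("hc_mab", "hc_hab", "pd_mab", "pd_hab")]),
    stringsAsFactors = FALSE
  )
  if (nrow(subj) == 0L) {
    empty <- cohort_table(data.frame(subject_id = character(0),
                                     disease = character(0),
                                     genotype = character(0),
                                     roi = character(0), vt = numeric(0)))
    return(list(table = empty, raw = empty,
                truth = list(vt = empty, params = list(), design = design)))
  }
  inj <- design$injected
  subj$injected_amount <- ifelse(
    subj$disease == "HC",
    stats::rnorm(nrow(subj), inj[["hc_mean"]], inj[["hc_sd"]]),
    stats::rnorm(nrow(subj), inj[["pd_mean"]], inj[["pd_sd"]]))
  rois <- unique(gm$roi)

  # %COV model: lognormal, subject-dominant; median calibrated to the target
  # pass fraction, with a mild ROI offset (smaller-VT regions are noisier)
  sd_subj <- 0.45; sd_res <- 0.15
  sd_tot <- sqrt(sd_subj^2 + sd_res^2)
  mu0 <- log(cov_threshold) - sd_tot * stats::qnorm(design$qc_pass_target)
  roi_mean_vt <- tapply(gm$gen_mean, gm$roi, mean)[rois]
  roi_off <- 0.25 * (log(mean(roi_mean_vt)) - log(roi_mean_vt))
  roi_off <- roi_off - mean(roi_off)
  z_subj <- stats::rnorm(nrow(subj))

  # long table: subjects x ROIs, generating moments looked up per row
  long <- subj[rep(seq_len(nrow(subj)), each = length(rois)), ]
  long$roi <- rep(rois, times = nrow(subj))
  key <- function(r, d, g) paste(r, d, g, sep = ".")
  gm_ix <- match(key(long$roi, long$disease, long$genotype),
                 key(gm$roi, gm$disease, gm$genotype))
  true_vt <- rtruncnorm_pos(nrow(long), gm$gen_mean[gm_ix], gm$gen_sd[gm_ix])

  params_list <- list()
  if (mode == "fast") {
    vt_hat <- true_vt
    pc <- exp(mu0 + roi_off[long$roi] +
                sd_subj * rep(z_subj, each = length(rois)) +
                sd_res * stats::rnorm(nrow(long)))
    conv <- rep(TRUE, nrow(long))
  } else {
    if (is.null(input_fn)) {
      input_fn <- simulate_input_function(seed = NULL,
                                          auto_noise = 0, manual_noise = 0)$truth
    }
    vt_hat <- pc <- numeric(nrow(long))
    conv <- logical(nrow(long))
    dur <- frame_durations(schedule)
    for (i in seq_len(nrow(long))) {
      pars <- params_for_target_vt(true_vt[i])
      act <- simulate_2tcm(pars, input_fn, schedule)$activity
      if (design$noise_pct > 0) {
        sdv <- design$noise_pct / 100 * act * sqrt(mean(dur) / dur)
        act <- act + stats::rnorm(length(act), 0, sdv)
      }
      fit <- fit_2tcm(tac(schedule, act, label = long$roi[i], noisy = TRUE),
                      input_fn)
      vt_hat[i] <- fit$vt; pc[i] <- fit$pct_cov; conv[i] <- fit$converged
      params_list[[paste(long$subject_id[i], long$roi[i], sep = ".")]] <- pars
    }
  }
  raw <- cohort_table(data.frame(
    subject_id = long$subject_id, disease = long$disease,
    genotype = long$genotype, roi = long$roi, vt = vt_hat, pct_cov = pc,
    injected_amount = long$injected_amount, converged = conv,
    row.names = NULL))
  filtered <- qc_filter(raw, threshold = cov_threshold)
  truth_vt <- data.frame(subject_id = long$subject_id, roi = long$roi,
                         true_vt = true_vt, row.names = NULL)
  list(table = filtered, raw = raw,
       truth = list(vt = truth_vt, params = params_list, design = design))
}

#' Simulate a two-tissue digital phantom
#'
#' A spherical white-matter core surrounded by a gray-matter shell, each
#' with its own 2-TCM kinetics, rendered to a 4D dynamic image, blurred with
#' the scanner PSF frame by frame, with optional proportional noise. The
#' returned probability maps are the exact binary geometry (they sum to 1 in
#' tissue and 0 in background).
#'
#' @param dims spatial dimensions in voxels (default 32^3).
#' @param voxel_size voxel size, mm.
#' @param wm_radius_mm,gm_outer_radius_mm radii of the white-matter core and
#'   the outer gray-matter shell surface, mm.
#' @param kinetics list with [two_tissue_params()] elements `gm` and `wm`.
#' @param input_fn a [plasma_input()].
#' @param schedule a [frame_schedule()].
#' @param psf a [point_spread_function()] (NULL = no blurring).
#' @param noise_pct proportional voxel noise SD, percent.
#' @param seed integer seed.
#' @return list with `image` ([dynamic_image()]), `maps`
#'   ([tissue_probability_maps()]), and `truth` (tissue [tac()]s, params and
#'   true VT per tissue).
#' @export
simulate_phantom <- function(dims = c(32, 32, 32), voxel_size = c(2, 2, 2),
                             wm_radius_mm = 14, gm_outer_radius_mm = 26,
                             kinetics = list(
                               gm = two_tissue_params(0.35, 0.07, 0.06, 0.04, vb = 0),
                               wm = two_tissue_params(0.10, 0.05, 0.03, 0.03, vb = 0)),
                             input_fn, schedule = feppa_frame_schedule(),
                             psf = point_spread_function(), noise_pct = 0,
                             seed = NULL) {
  stopifnot(inherits(input_fn, "plasma_input"))
  half_extent <- min(dims * voxel_size) / 2
  if (gm_outer_radius_mm >= half_extent) {
    stop("geometry exceeds the volume extent", call. = FALSE)
  }
  if (wm_radius_mm >= gm_outer_radius_mm) {
    stop("wm core must be smaller than the gm outer radius", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ctr <- (dims + 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - ctr[a]) * voxel_size[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  wm_mask <- r2 <= wm_radius_mm^2
  gm_mask <- r2 <= gm_outer_radius_mm^2 & !wm_mask
  gm_tac <- simulate_2tcm(kinetics$gm, input_fn, schedule, label = "gm")
  wm_tac <- simulate_2tcm(kinetics$wm, input_fn, schedule, label = "wm")
  nf <- n_frames(schedule)
  vox <- array(0, dim = c(dims, nf))
  for (f in seq_len(nf)) {
    fr <- gm_mask * gm_tac$activity[f] + wm_mask * wm_tac$activity[f]
    if (!is.null(psf)) fr <- gauss_smooth_3d(fr, psf$fwhm_mm, voxel_size)
    if (noise_pct > 0) {
      fr <- fr + stats::rnorm(length(fr), 0, noise_pct / 100 * max(abs(fr)))
    }
    vox[, , , f] <- fr
  }
  maps <- tissue_probability_maps(gm = gm_mask * 1, wm = wm_mask * 1,
                                  csf = array(0, dims), voxel_size = voxel_size)
  list(
    image = dynamic_image(vox, schedule, voxel_size),
    maps = maps,
    truth = list(gm_tac = gm_tac, wm_tac = wm_tac, kinetics = kinetics,
                 vt = c(gm = compute_vt(kinetics$gm), wm = compute_vt(kinetics$wm)))
  )
}
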