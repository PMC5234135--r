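#' Percentage difference between genotype group means
#'
#' 100 (mean_hab - mean_mab) / ((mean_hab + mean_mab) / 2): the difference
#' between high- and mixed-affinity-binder group means expressed as a
#' percentage of their average. Vectorised over pairs.
#'
#' @param mean_mab,mean_hab positive group mean VT values, mL/cm^3.
#' @return Percentage difference(s); positive when HAB exceeds MAB.
#' @export
percent_difference <- function(mean_mab, mean_hab) {
  if (any(mean_mab <= 0) || any(mean_hab <= 0)) {
    stop("group means must be positive", call. = FALSE)
  }
  100 * (mean_hab - mean_mab) / ((mean_hab + mean_mab) / 2)
}

# effects (sum-to-zero) coding, the convention under which Type III sums of
# squares reproduce SPSS output
ancova_lm <- function(df, covariate) {
  fml <- stats::as.formula(paste("vt ~", covariate, "+ disease * genotype"))
  stats::lm(fml, data = df,
            contrasts = list(disease = stats::contr.sum, genotype = stats::contr.sum))
}

#' Factorial ANCOVA of VT by disease and genotype
#'
#' Two-way fixed-effects analysis of covariance for one ROI: main effects of
#' disease (HC vs PD) and TSPO genotype (HAB vs MAB), their interaction, and
#' a continuous nuisance covariate (default injected amount), with Type III
#' sums of squares under effects coding.
#'
#' @param table a [cohort_table()].
#' @param roi ROI label to analyse.
#' @param covariate name of the nuisance covariate column.
#' @return data.frame with one row per effect (`covariate`, `disease`,
#'   `genotype`, `disease:genotype`): columns `effect`, `F`, `df1`, `df2`,
#'   `p`.
#' @export
two_way_ancova <- function(table, roi, covariate = "injected_amount") {
  df <- table[table$roi == roi & !is.na(table$vt), , drop = FALSE]
  if (!covariate %in% names(df)) {
    stop("covariate column '", covariate, "' not found", call. = FALSE)
  }
  df <- df[!is.na(df[[covariate]]), , drop = FALSE]
  cells <- table(df$disease, df$genotype)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)[1, ]
    stop(sprintf("cell %s-%s has fewer than 2 subjects in ROI '%s'",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]], roi),
         call. = FALSE)
  }
  mod <- ancova_lm(df, covariate)
  aov3 <- car::Anova(mod, type = 3)
  rows <- c(covariate, "disease", "genotype", "disease:genotype")
  df2 <- aov3["Residuals", "Df"]
  data.frame(
    effect = rows,
    F = aov3[rows, "F value"],
    df1 = aov3[rows, "Df"],
    df2 = df2,
    p = aov3[rows, "Pr(>F)"],
    row.names = NULL
  )
}

#' Levene test of equality of error variances (center = mean)
#'
#' Classic Levene W: a one-way ANOVA on the absolute deviations of each
#' observation from its group mean. A significant result (p < 0.05) flags
#' heteroscedastic groups; the downstream convention is then a stricter
#' per-ROI significance threshold of 0.01 for the factorial model.
#'
#' @param values numeric observations, or a list of per-group numeric
#'   vectors (then `group` is ignored).
#' @param group grouping factor aligned with `values`.
#' @return data.frame with `effect`, `statistic` (W), `df1`, `df2`, `p`.
#' @export
levene_test <- function(values, group = NULL) {
  if (is.list(values) && is.null(group)) {
    group <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) < 2L)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  dev <- abs(values - stats::ave(values, group))
  if (all(dev < .Machine$double.eps)) {
    stop("zero spread in every group: Levene W is undefined", call. = FALSE)
  }
  lt <- car::leveneTest(values, group, center = mean)
  data.frame(effect = "variance_homogeneity",
             statistic = lt[1, "F value"],
             df1 = lt[1, "Df"], df2 = lt[2, "Df"],
             p = lt[1, "Pr(>F)"], row.names = NULL)
}

#' Genotype t tests stratified by disease group
#'
#' Two-sided pooled-variance (Student) t tests comparing HAB vs MAB VT
#' within one disease stratum, per ROI. Welch's correction is available via
#' `var_equal = FALSE`.
#'
#' @param table a [cohort_table()].
#' @param within disease stratum, "HC" or "PD".
#' @param var_equal pooled variance (default TRUE).
#' @return data.frame with `roi`, `effect`, `statistic` (t, HAB minus MAB),
#'   `df`, `p`, `mean_hab`, `mean_mab`.
#' @export
stratified_t_tests <- function(table, within = c("HC", "PD"), var_equal = TRUE) {
  within <- match.arg(within)
  df <- table[table$disease == within & !is.na(table$vt), , drop = FALSE]
  rois <- unique(as.character(df$roi))
  if (!length(rois)) stop("no data in stratum ", within, call. = FALSE)
  out <- lapply(rois, function(r) {
    d <- df[df$roi == r, ]
    hab <- d$vt[d$genotype == "HAB"]
    mab <- d$vt[d$genotype == "MAB"]
    if (length(hab) < 2L || length(mab) < 2L) {
      stop("genotype group with fewer than 2 subjects in ROI '", r,
           "' (", within, ")", call. = FALSE)
    }
    tt <- stats::t.test(hab, mab, var.equal = var_equal)
    data.frame(roi = r, effect = paste0("genotype_", within),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, mean_hab = mean(hab), mean_mab = mean(mab))
  })
  do.call(rbind, out)
}

#' Correlations between clinical measures and VT
#'
#' Pearson correlations per (measure, ROI, genotype stratum), following the
#' convention that clinical severity measures are examined within each
#' genotype group of the patient sample.
#'
#' @param table a [cohort_table()] containing the clinical columns.
#' @param measures character vector of clinical column names (e.g. `ledd`,
#'   `updrs`, `duration`).
#' @param disease stratum holding the clinical measures (default "PD").
#' @return data.frame with `measure`, `roi`, `genotype`, `r`, `df`, `p`, `n`.
#' @export
clinical_correlations <- function(table, measures = c("ledd", "updrs", "duration"),
                                  disease = "PD") {
  df <- table[table$disease == disease & !is.na(table$vt), , drop = FALSE]
  measures <- intersect(measures, names(df))
  if (!length(measures)) stop("no clinical measure columns found", call. = FALSE)
  out <- list()
  for (m in measures) for (r in unique(as.character(df$roi))) {
    for (g in levels(droplevels(df$genotype))) {
      d <- df[df$roi == r & df$genotype == g & !is.na(df[[m]]), ]
      if (nrow(d) < 3L) {
        stop("fewer than 3 paired observations for ", m, " in ROI '", r,
             "' (", g, ")", call. = FALSE)
      }
      if (stats::sd(d$vt) == 0 || stats::sd(d[[m]]) == 0) {
        stop("zero variance in ", m, " or vt for ROI '", r, "' (", g, ")",
             call. = FALSE)
      }
      ct <- stats::cor.test(d$vt, d[[m]], method = "pearson")
      out[[length(out) + 1L]] <- data.frame(
        measure = m, roi = r, genotype = g,
        r = unname(ct$estimate), df = unname(ct$parameter),
        p = ct$p.value, n = nrow(d))
    }
  }
  do.call(rbind, out)
}

#' Per-region group summary with ANCOVA and percentage differences
#'
#' For every ROI: cell means and SDs per disease x genotype group, the
#' HAB-vs-MAB percentage difference within each disease group, the
#' Type III ANCOVA (disease, genotype, interaction, with nuisance
#' covariate), the Levene variance check across the four cells and the
#' per-ROI significance threshold it implies (`alpha_strict` when Levene
#' p < 0.05, else `alpha`). The means of the per-ROI percentage differences
#' are attached as attribute `"overall_pct_diff"`.
#'
#' @param table a QC-filtered [cohort_table()].
#' @param covariate nuisance covariate column name.
#' @param alpha nominal per-ROI significance level.
#' @param alpha_strict stricter level used when Levene flags
#'   heteroscedasticity.
#' @return data.frame, one row per ROI.
#' @export
region_summary <- function(table, covariate = "injected_amount",
                           alpha = 0.05, alpha_strict = 0.01) {
  rois <- unique(as.character(table$roi))
  rows <- lapply(rois, function(r) {
    d <- table[table$roi == r & !is.na(table$vt), ]
    cell <- function(dis, gen) d$vt[d$disease == dis & d$genotype == gen]
    cells <- list(hc_mab = cell("HC", "MAB"), hc_hab = cell("HC", "HAB"),
                  pd_mab = cell("PD", "MAB"), pd_hab = cell("PD", "HAB"))
    mn <- vapply(cells, function(x) if (length(x)) mean(x) else NA_real_, 0)
    sdv <- vapply(cells, function(x) if (length(x) > 1) stats::sd(x) else NA_real_, 0)
    ns <- vapply(cells, length, 0L)
    an <- two_way_ancova(table, r, covariate)
    lev <- tryCatch(levene_test(d$vt, interaction(d$disease, d$genotype)),
                    error = function(e) data.frame(p = NA_real_))
    a_used <- if (is.finite(lev$p[1]) && lev$p[1] < 0.05) alpha_strict else alpha
    data.frame(
      roi = r,
      mean_hc_mab = mn[["hc_mab"]], sd_hc_mab = sdv[["hc_mab"]], n_hc_mab = ns[["hc_mab"]],
      mean_hc_hab = mn[["hc_hab"]], sd_hc_hab = sdv[["hc_hab"]], n_hc_hab = ns[["hc_hab"]],
      mean_pd_mab = mn[["pd_mab"]], sd_pd_mab = sdv[["pd_mab"]], n_pd_mab = ns[["pd_mab"]],
      mean_pd_hab = mn[["pd_hab"]], sd_pd_hab = sdv[["pd_hab"]], n_pd_hab = ns[["pd_hab"]],
      pct_diff_hc = percent_difference(mn[["hc_mab"]], mn[["hc_hab"]]),
      pct_diff_pd = percent_difference(mn[["pd_mab"]], mn[["pd_hab"]]),
      disease_F = an$F[an$effect == "disease"],
      disease_p = an$p[an$effect == "disease"],
      genotype_F = an$F[an$effect == "genotype"],
      genotype_p = an$p[an$effect == "genotype"],
      interaction_F = an$F[an$effect == "disease:genotype"],
      interaction_p = an$p[an$effect == "disease:genotype"],
      df2 = an$df2[1],
      levene_p = lev$p[1],
      alpha_used = a_used
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "overall_pct_diff") <- c(HC = mean(out$pct_diff_hc),
                                     PD = mean(out$pct_diff_pd))
  out
}

#' Nonparametric and categorical demographic screens
#'
#' Thin delegation to the standard routines (no re-derivation):
#' Kolmogorov-Smirnov normality screen, Mann-Whitney U, Kruskal-Wallis and
#' chi-square tests as used for cohort demographics.
#'
#' @param values numeric observations (or counts matrix for `chisq`).
#' @param group grouping factor (unused for `ks`).
#' @param test which screen to run.
#' @return htest object from the corresponding stats routine.
#' @export
nonparametric_screen <- function(values, group = NULL,
                                 test = c("ks", "mannwhitney", "kruskal", "chisq")) {
  test <- match.arg(test)
  switch(test,
    ks = stats::ks.test(scale(values), "pnorm"),
    mannwhitney = stats::wilcox.test(values ~ factor(group)),
    kruskal = stats::kruskal.test(values, factor(group)),
    chisq = stats::chisq.test(values)
  )
}
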