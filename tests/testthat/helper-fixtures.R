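# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# noise-free ground-truth input function (dense 1-s grid, 125 min)
fixture_input <- function() {
  if (is.null(.fixtures$input)) {
    .fixtures$input <- simulate_input_function(seed = 42, auto_noise = 0,
                                               manual_noise = 0)$truth
  }
  .fixtures$input
}

fixture_schedule <- function() feppa_frame_schedule()

# the twenty reference cell means/SDs in wide per-ROI form
fixture_cells_wide <- function() {
  cells <- feppa_reference_cells()
  key <- paste(tolower(cells$disease), tolower(cells$genotype), sep = "_")
  out <- data.frame(roi = unique(cells$roi))
  for (k in unique(key)) {
    sub <- cells[key == k, ]
    out[[paste0("mean_", k)]] <- sub$mean[match(out$roi, sub$roi)]
    out[[paste0("sd_", k)]] <- sub$sd[match(out$roi, sub$roi)]
  }
  out
}

# build a cohort table with exact per-cell means (values mean + {-d, 0, +d})
# and a seeded covariate, for summary/ANCOVA fixtures
exact_mean_cohort <- function(n_per_cell = 3, spread = 0.5, seed = 11) {
  set.seed(seed)
  cells <- feppa_reference_cells()
  rows <- list()
  sid <- 0
  offs <- seq(-spread, spread, length.out = n_per_cell)
  offs <- offs - mean(offs)
  for (d in c("HC", "PD")) for (g in c("MAB", "HAB")) {
    ids <- sprintf("%s_%s_%02d", d, g, seq_len(n_per_cell))
    inj <- round(stats::rnorm(n_per_cell, if (d == "HC") 4.79 else 5.04, 0.25), 3)
    for (r in unique(cells$roi)) {
      m <- cells$mean[cells$roi == r & cells$disease == d & cells$genotype == g]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids, disease = d, genotype = g, roi = r,
        vt = m + offs, pct_cov = 5, injected_amount = inj)
    }
  }
  cohort_table(do.call(rbind, rows))
}

# independent Type III ANCOVA oracle: effects-coded regression, F from
# model-comparison RSS differences (each term dropped from the full model)
ancova_oracle <- function(df, covariate = "injected_amount") {
  d <- ifelse(df$disease == "HC", 1, -1)
  g <- ifelse(df$genotype == "HAB", 1, -1)
  x <- df[[covariate]]
  y <- df$vt
  X_full <- cbind(1, x, d, g, d * g)
  rss <- function(X) {
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(X_full)
  df_res <- nrow(X_full) - ncol(X_full)
  drop_F <- function(col) {
    r <- rss(X_full[, -col, drop = FALSE])
    ((r - rss_full) / 1) / (rss_full / df_res)
  }
  Fs <- c(drop_F(2), drop_F(3), drop_F(4), drop_F(5))
  data.frame(effect = c(covariate, "disease", "genotype", "disease:genotype"),
             F = Fs, df1 = 1, df2 = df_res,
             p = stats::pf(Fs, 1, df_res, lower.tail = FALSE))
}

# random unbalanced 2x2 + covariate fixture for the ANCOVA oracle tests
random_ancova_fixture <- function(seed) {
  set.seed(seed)
  ns <- sample(3:8, 4, replace = TRUE)
  rows <- list()
  cellz <- expand.grid(disease = c("HC", "PD"), genotype = c("MAB", "HAB"),
                       stringsAsFactors = FALSE)
  for (i in 1:4) {
    rows[[i]] <- data.frame(
      subject_id = sprintf("s%d_%02d", i, seq_len(ns[i])),
      disease = cellz$disease[i], genotype = cellz$genotype[i],
      roi = "frontal",
      vt = stats::rnorm(ns[i], mean = stats::runif(1, 8, 20), sd = stats::runif(1, 0.5, 3)),
      injected_amount = stats::rnorm(ns[i], 4.9, 0.25))
  }
  cohort_table(do.call(rbind, rows))
}
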