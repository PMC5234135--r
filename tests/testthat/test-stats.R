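test_that("percentage difference uses the mean-of-means denominator", {
  expect_equal(round(percent_difference(13.9, 19.4), 1), 33.0)
  expect_equal(round(percent_difference(8.0, 13.5), 1), 51.2)
  expect_equal(percent_difference(7.3, 7.3), 0)
  expect_error(percent_difference(0, 10), "positive")
})

test_that("percentage difference is antisymmetric and scale-invariant", {
  set.seed(301)
  a <- stats::runif(50, 1, 30)
  b <- stats::runif(50, 1, 30)
  expect_equal(percent_difference(a, b), -percent_difference(b, a))
  for (cc in c(0.1, 3, 1e4)) {
    expect_equal(percent_difference(cc * a, cc * b), percent_difference(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Type III ANCOVA matches the effects-coded regression oracle", {
  for (seed in 1:8) {
    tab <- random_ancova_fixture(seed)
    got <- two_way_ancova(tab, "frontal")
    want <- ancova_oracle(tab)
    m <- merge(got, want, by = "effect")
    expect_gt(nrow(m), 3.5)
    expect_equal(m$F.x, m$F.y, tolerance = 1e-8)
    expect_equal(m$p.x, m$p.y, tolerance = 1e-8)
    expect_equal(m$df2.x, m$df2.y)
  }
})

test_that("identical cells give vanishing F statistics", {
  vals <- c(10.2, 11.1, 9.8, 10.6)
  inj <- c(4.7, 4.9, 5.1, 5.0)
  rows <- list()
  i <- 0
  for (d in c("HC", "PD")) for (g in c("MAB", "HAB")) {
    i <- i + 1
    rows[[i]] <- data.frame(
      subject_id = sprintf("%s%s%d", d, g, 1:4), disease = d, genotype = g,
      roi = "frontal", vt = vals, injected_amount = inj)
  }
  tab <- cohort_table(do.call(rbind, rows))
  res <- two_way_ancova(tab, "frontal")
  expect_lt(max(res$F[res$effect != "injected_amount"]), 1e-20)
})

test_that("empty or underfilled cells are reported by name", {
  tab <- random_ancova_fixture(3)
  tab2 <- tab[!(tab$disease == "PD" & tab$genotype == "HAB"), ]
  class(tab2) <- class(tab)
  expect_error(two_way_ancova(tab2, "frontal"), "PD-HAB")
})

test_that("Levene (center = mean) equals the ANOVA-on-absolute-deviations oracle", {
  set.seed(302)
  for (i in 1:10) {
    g <- factor(rep(1:3, times = c(8, 11, 9)))
    y <- stats::rnorm(length(g), mean = 10, sd = rep(c(1, 2, 0.5), times = c(8, 11, 9)))
    got <- levene_test(y, g)
    dev <- abs(y - stats::ave(y, g))
    oracle <- stats::anova(stats::lm(dev ~ g))
    expect_equal(got$statistic, oracle[1, "F value"], tolerance = 1e-12)
    expect_equal(got$p, oracle[1, "Pr(>F)"], tolerance = 1e-12)
    expect_equal(c(got$df1, got$df2), oracle$Df)
  }
})

test_that("degenerate zero-spread groups make Levene error", {
  expect_error(levene_test(list(c(5, 5, 5), c(7, 7))), "undefined")
  expect_error(levene_test(list(c(5, 6, 5))), "2 groups")
  expect_error(levene_test(list(c(5, 6), c(7))), "2 observations")
})

test_that("Levene keeps its size under equal variances", {
  set.seed(303)
  hits <- 0L
  for (i in 1:100) {
    y <- stats::rnorm(40, 10, 2)
    g <- factor(rep(1:4, each = 10))
    if (levene_test(y, g)$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("pooled t matches the textbook formula on a 3+3 fixture", {
  hab <- c(14.1, 15.3, 16.2)
  mab <- c(10.4, 11.8, 10.9)
  tab <- cohort_table(data.frame(
    subject_id = sprintf("s%d", 1:6), disease = "HC",
    genotype = rep(c("HAB", "MAB"), each = 3), roi = "frontal",
    vt = c(hab, mab)))
  got <- stratified_t_tests(tab, "HC")
  sp2 <- (2 * stats::var(hab) + 2 * stats::var(mab)) / 4
  t_hand <- (mean(hab) - mean(mab)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$statistic, t_hand, tolerance = 1e-10)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * stats::pt(-abs(t_hand), 4), tolerance = 1e-10)
})

test_that("identical genotype groups give t = 0, p = 1", {
  v <- c(9.5, 10.5, 11.5)
  tab <- cohort_table(data.frame(
    subject_id = sprintf("s%d", 1:6), disease = "PD",
    genotype = rep(c("HAB", "MAB"), each = 3), roi = "putamen",
    vt = c(v, v)))
  got <- stratified_t_tests(tab, "PD")
  expect_equal(got$statistic, 0)
  expect_equal(got$p, 1)
  # singleton group errors
  tab2 <- tab[-1, ]; class(tab2) <- class(tab)
  expect_error(stratified_t_tests(tab2[tab2$subject_id != "s2", ], "PD"),
               "fewer than 2")
})

test_that("the calibrated PD stratum separates genotypes in every region", {
  all_sig <- vapply(1:7, function(s) {
    cs <- simulate_cohort(cohort_design(disease_null = FALSE, seed = 400 + s))
    res <- stratified_t_tests(cs$table, "PD")
    all(res$p < 0.05) && nrow(res) == 10
  }, TRUE)
  expect_gt(mean(all_sig), 0.5)
})

test_that("Pearson correlations match their definition and find y = x", {
  tab <- cohort_table(data.frame(
    subject_id = sprintf("s%d", 1:6), disease = "PD",
    genotype = "HAB", roi = "frontal",
    vt = c(8, 9, 10, 11, 12, 13), ledd = c(8, 9, 10, 11, 12, 13) * 30))
  got <- clinical_correlations(tab, measures = "ledd")
  expect_equal(got$r, 1, tolerance = 1e-12)
  set.seed(304)
  tab$ledd <- stats::rnorm(6, 400, 100)
  got2 <- clinical_correlations(tab, measures = "ledd")
  r_hand <- stats::cov(tab$vt, tab$ledd) / (stats::sd(tab$vt) * stats::sd(tab$ledd))
  expect_equal(got2$r, r_hand, tolerance = 1e-12)
  tab$ledd <- rep(100, 6)
  expect_error(clinical_correlations(tab, measures = "ledd"), "variance")
})

test_that("null clinical correlations have approximately uniform p values", {
  set.seed(305)
  ps <- vapply(1:60, function(i) {
    n <- 15
    tab <- cohort_table(data.frame(
      subject_id = sprintf("s%d", 1:n), disease = "PD", genotype = "HAB",
      roi = "frontal", vt = stats::rnorm(n, 12, 2),
      updrs = stats::rnorm(n, 24, 8)))
    clinical_correlations(tab, measures = "updrs")$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.15)
})

test_that("region summary reproduces the reference percentages from exact cell means", {
  tab <- exact_mean_cohort()
  summ <- region_summary(tab)
  wide <- fixture_cells_wide()
  m <- merge(summ, wide, by = "roi")
  expect_equal(round(m$pct_diff_hc, 1),
               round(percent_difference(m$mean_hc_mab.y, m$mean_hc_hab.y), 1))
  expect_equal(round(m$pct_diff_pd, 1),
               round(percent_difference(m$mean_pd_mab.y, m$mean_pd_hab.y), 1))
  expect_equal(m$mean_hc_mab.x, m$mean_hc_mab.y, tolerance = 1e-9)
  overall <- attr(summ, "overall_pct_diff")
  expect_equal(round(unname(overall["HC"]), 1), 32.6)
  expect_equal(round(unname(overall["PD"]), 1), 43.1)
})

test_that("region summary is invariant to row order and handles one ROI", {
  tab <- exact_mean_cohort()
  set.seed(306)
  shuffled <- tab[sample(nrow(tab)), ]
  class(shuffled) <- class(tab)
  s1 <- region_summary(tab)
  s2 <- region_summary(shuffled)
  s2 <- s2[match(s1$roi, s2$roi), ]
  rownames(s1) <- rownames(s2) <- NULL
  expect_equal(s1, s2, tolerance = 1e-12)
  one <- tab[tab$roi == "putamen", ]
  class(one) <- class(tab)
  expect_equal(nrow(region_summary(one)), 1L)
})

test_that("nonparametric screens delegate to the standard routines", {
  set.seed(307)
  x <- stats::rnorm(30)
  g <- rep(1:2, each = 15)
  expect_s3_class(nonparametric_screen(x, test = "ks"), "htest")
  mw <- nonparametric_screen(x, g, test = "mannwhitney")
  expect_identical(mw$statistic, stats::wilcox.test(x ~ factor(g))$statistic)
  kw <- nonparametric_screen(x, g, test = "kruskal")
  expect_identical(kw$statistic, stats::kruskal.test(x, factor(g))$statistic)
  tabm <- matrix(c(11, 11, 22, 8), 2)
  expect_equal(nonparametric_screen(tabm, test = "chisq")$p.value,
               stats::chisq.test(tabm)$p.value)
})
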