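# Association statistics: dichotomization, Wilcoxon, adjusted models,
# contingency tests and subgroup tables.

test_that("fibrosis dichotomization thresholds at grade 2", {
  expect_equal(as.character(dichotomize_fibrosis(0:4)),
               c("low", "low", "high", "high", "high"))
  grades <- rep(0:4, times = c(52, 83, 47, 17, 1))
  g <- dichotomize_fibrosis(grades)
  expect_equal(sum(g == "high"), 65L)
  expect_equal(sum(g == "low"), 135L)
  expect_error(dichotomize_fibrosis(c(1, 5)), "validation error")
})

test_that("grade distribution arithmetic matches the printed counts", {
  gt <- grade_distribution(c(52, 83, 47, 17, 1))
  expect_equal(attr(gt, "ge2_pct"), 32.50)
  expect_equal(gt$pct[gt$grade == 1], 41.50)
})

test_that("Wilcoxon: extreme separation, identity, and guards", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p.value, 0.1)    # 2 of the 20 rank assignments
  expect_equal(w$method, "exact")
  same <- wilcoxon_rank_sum(c(2, 2, 2, 2), c(2, 2, 2, 2))
  expect_equal(same$p.value, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("exact branch equals full enumeration for all m + n <= 10", {
  set.seed(derive_seed(5, "enum"))
  for (m in 1:5) for (n in m:(10 - m)) {
    x <- sample(seq(1, 1000), m)      # distinct integers: no ties
    y <- sample(setdiff(seq(1, 1000), x), n)
    mine <- wilcoxon_rank_sum(x, y)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p.value, enum_wilcoxon_p(x, y), tolerance = 1e-12)
    # independent route: R's exact Wilcoxon on the same data
    expect_equal(mine$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("group-label swap leaves the two-sided p unchanged", {
  set.seed(derive_seed(5, "swap"))
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    a <- wilcoxon_rank_sum(x, y); b <- wilcoxon_rank_sum(y, x)
    expect_equal(a$p.value, b$p.value, tolerance = 1e-12)
    # the rank sums are complementary
    N <- length(x) + length(y)
    expect_equal(a$statistic + b$statistic, N * (N + 1) / 2)
  }
})

test_that("Wilcoxon type-I error is calibrated at the 5% level", {
  set.seed(derive_seed(11, "type1"))
  reject <- vapply(seq_len(10000), function(i) {
    wilcoxon_rank_sum(rnorm(8), rnorm(8))$p.value <= 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.04)
  expect_lt(mean(reject), 0.06)
})

test_that("contingency tests choose chi-squared or Fisher correctly", {
  # stratified smoking counts: 92/43 ever/never among low, 33/32 among high
  records <- data.frame(
    smoking = c(rep("ever", 92), rep("never", 43),
                rep("ever", 33), rep("never", 32)),
    fibrosis_grade = c(rep(0, 135), rep(2, 65)))
  grp <- dichotomize_fibrosis(records)
  out <- covariate_tests(records, grp, covariates = "smoking")
  expect_equal(out$test, "chi-squared")
  expect_equal(out$statistic, 5.6538, tolerance = 1e-4)
  expect_equal(out$p_value, 0.01742, tolerance = 1e-3)

  # identical row proportions: statistic 0, p = 1
  rec2 <- data.frame(smoking = rep(c("ever", "never", "ever", "never"),
                                   times = c(40, 20, 20, 10)),
                     fibrosis_grade = rep(c(0, 0, 2, 2),
                                          times = c(40, 20, 20, 10)))
  out2 <- covariate_tests(rec2, dichotomize_fibrosis(rec2),
                          covariates = "smoking")
  expect_equal(out2$statistic, 0, tolerance = 1e-12)
  expect_equal(out2$p_value, 1)

  # sparse table: Fisher branch, cross-checked against hypergeometric
  # enumeration
  rec3 <- data.frame(smoking = rep(c("ever", "never", "ever", "never"),
                                   times = c(8, 1, 2, 7)),
                     fibrosis_grade = rep(c(0, 0, 2, 2),
                                          times = c(8, 1, 2, 7)))
  out3 <- covariate_tests(rec3, dichotomize_fibrosis(rec3),
                          covariates = "smoking")
  expect_equal(out3$test, "fisher")
  tab <- table(rec3$smoking, dichotomize_fibrosis(rec3) == "high")
  expect_equal(out3$p_value, enum_fisher_p(tab), tolerance = 1e-9)
})

test_that("covariate-free adjusted model reduces to the two-sample t-test", {
  set.seed(derive_seed(5, "ttest"))
  co <- simulate_cohort(cohort_config(seed = 5))
  grp <- dichotomize_fibrosis(co)
  cmp <- adjusted_comparison(co, grp, covariates = character(0))
  tt <- t.test(wb_ratio ~ grp, data = co, var.equal = TRUE)
  expect_equal(cmp$adjusted_p, tt$p.value, tolerance = 1e-12)
  # closed-form OLS slope for a binary predictor: the mean difference
  expect_equal(cmp$coefficient,
               mean(co$wb_ratio[grp == "high"]) -
                 mean(co$wb_ratio[grp == "low"]), tolerance = 1e-12)
})

test_that("null simulations give centred effects and uniform adjusted p", {
  R <- 1000L
  res <- vapply(seq_len(R), function(i) {
    co <- simulate_cohort(cohort_config(seed = derive_seed(13, paste0("n", i))))
    grp <- dichotomize_fibrosis(co)
    set.seed(derive_seed(13, paste0("y", i)))
    # response independent of group but confounded with covariates
    co$wb_ratio <- 2 + 0.02 * (co$age - 55) +
      0.2 * (co$smoking == "ever") + rnorm(nrow(co), 0, 0.4)
    cmp <- adjusted_comparison(co, grp)
    c(cmp$coefficient, cmp$adjusted_p)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ])) , 3 * sd(res[1, ]) / sqrt(R))
  expect_gt(suppressWarnings(stats::ks.test(res[2, ], "punif"))$p.value, 0.01)
})

test_that("an injected group effect is recovered within 2 SE", {
  R <- 1000L
  delta <- 0.3
  ok <- vapply(seq_len(R), function(i) {
    co <- simulate_cohort(cohort_config(seed = derive_seed(13, paste0("e", i))))
    grp <- dichotomize_fibrosis(co)
    set.seed(derive_seed(13, paste0("z", i)))
    co$wb_ratio <- 2 + 0.02 * (co$age - 55) +
      0.2 * (co$smoking == "ever") + delta * (grp == "high") +
      rnorm(nrow(co), 0, 0.4)
    cmp <- adjusted_comparison(co, grp)
    abs(cmp$coefficient - delta) <= 2 * cmp$se
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("singular designs fail naming the collinear columns", {
  co <- simulate_cohort(cohort_config(seed = 5))
  co$chemo_copy <- co$chemo
  grp <- dichotomize_fibrosis(co)
  expect_error(adjusted_comparison(co, grp,
                                   covariates = c("chemo", "chemo_copy")),
               "singular design")
})

test_that("a single-level subgroup reproduces the main comparison exactly", {
  co <- simulate_cohort(cohort_config(seed = 5))
  grp <- dichotomize_fibrosis(co)
  main <- adjusted_comparison(co, grp)
  sub <- subgroup_analysis(co, grp, subgroups = list(
    all = list(levels = function(r) rep("all", nrow(r)),
               drop = NA_character_)))
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$crude_p, main$crude_p, tolerance = 1e-12)
  expect_equal(sub$adjusted_p, main$adjusted_p, tolerance = 1e-12)
  expect_equal(sub$median_low, main$strata$median[1], tolerance = 1e-12)
})

test_that("subgroup tables localize an effect present only in smokers", {
  co <- simulate_cohort(cohort_config(n_patients = 600L, seed = 5))
  grp <- dichotomize_fibrosis(co)
  set.seed(derive_seed(5, "smoke_eff"))
  co$wb_ratio <- 2 + 0.5 * (grp == "high") * (co$smoking == "ever") +
    rnorm(nrow(co), 0, 0.4)
  sub <- subgroup_analysis(co, grp)
  smoker <- sub[sub$variable == "smoking" & sub$level == "ever", ]
  nonsmoker <- sub[sub$variable == "smoking" & sub$level == "never", ]
  expect_lt(smoker$crude_p, 0.05)
  expect_lt(smoker$crude_p, nonsmoker$crude_p)
  # schema mirrors the published subgroup layout
  expect_true(all(c("variable", "level", "median_low", "q25_low", "q75_low",
                    "median_high", "q25_high", "q75_high", "crude_p",
                    "adjusted_p") %in% names(sub)))
})

test_that("sparse subgroup levels keep medians but suppress p-values", {
  co <- simulate_cohort(cohort_config(seed = 5))
  grp <- dichotomize_fibrosis(co)
  co$rare <- c(rep("tiny", 6), rep("rest", nrow(co) - 6))
  sub <- subgroup_analysis(co, grp, subgroups = list(
    rare = list(levels = function(r) r$rare, drop = NA_character_)))
  tiny <- sub[sub$level == "tiny", ]
  expect_equal(tiny$flag, "sparse_stratum")
  expect_true(is.na(tiny$crude_p))
  expect_false(is.na(tiny$median_low) && is.na(tiny$median_high))
})
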