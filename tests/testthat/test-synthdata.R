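# Synthetic-data module: cohorts, fluorescence fields, kinetics.

test_that("cohort generator is reproducible and validates its config", {
  a <- simulate_cohort(cohort_config(seed = 5))
  b <- simulate_cohort(cohort_config(seed = 5))
  expect_identical(a, b)
  expect_equal(nrow(a), 200L)

  expect_error(cohort_config(n_patients = 0), "configuration error")
  expect_error(cohort_config(grade_probs = c(0.5, 0.5, 0.1, 0, 0)),
               "configuration error")
  expect_error(cohort_config(ratio_model = list(
    lt2 = list(median = 2, log_sd = 0.2, bounds = c(2.5, 3)),
    ge2 = list(median = 2.5, log_sd = 0.2, bounds = c(1, 4)))),
    "configuration error")
})

test_that("degenerate grade distribution puts everyone in the low stratum", {
  co <- simulate_cohort(cohort_config(grade_probs = c(1, 0, 0, 0, 0),
                                      seed = 5))
  expect_true(all(co$fibrosis_grade == 0))
  expect_true(all(dichotomize_fibrosis(co) == "low"))
})

test_that("ratio draws respect their truncation bounds and follow-up its range", {
  co <- simulate_cohort(cohort_config(seed = 5))
  g <- dichotomize_fibrosis(co)
  expect_true(all(co$wb_ratio[g == "low"] >= 1.09 &
                  co$wb_ratio[g == "low"] <= 3.57))
  expect_true(all(co$wb_ratio[g == "high"] >= 1.25 &
                  co$wb_ratio[g == "high"] <= 3.76))
  expect_true(all(co$if_ratio > 0))
  expect_true(all(co$followup_years >= 2.0 & co$followup_years <= 6.8))
})

test_that("grade >= 2 fraction matches its binomial expectation over replicates", {
  # Monte-Carlo oracle: the >= grade 2 indicator is Bernoulli(0.325), so
  # the mean fraction over R cohorts of size n has SE sqrt(p(1-p)/(n R)).
  R <- 1000L; n <- 200L; p <- 0.325
  fracs <- vapply(seq_len(R), function(i) {
    mean(simulate_cohort(cohort_config(seed = derive_seed(5, paste0("rep", i))))
         $fibrosis_grade >= 2)
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (n * R))
  expect_lt(abs(mean(fracs) - p), 3 * se)
})

test_that("stratum ratio medians converge to the calibrated targets", {
  # truncated-median calibration: one large draw hits the target median,
  # and the mean of per-cohort stratum medians converges to 2.04 / 2.51
  set.seed(derive_seed(5, "cal0"))
  expect_lt(abs(median(rlnorm_trunc(2e5, 2.51, 0.22, c(1.25, 3.76))) - 2.51),
            0.01)
  meds <- vapply(1:40, function(s) {
    co <- simulate_cohort(cohort_config(seed = derive_seed(5, paste0("cal", s))))
    g <- dichotomize_fibrosis(co)
    as.numeric(tapply(co$wb_ratio, g, median))
  }, numeric(2))
  expect_lt(abs(mean(meds[1, ]) - 2.04), 0.03)
  expect_lt(abs(mean(meds[2, ]) - 2.51), 0.03)
})

test_that("field generator honours forced cell counts and stays inside the frame", {
  cfg <- field_config(n_cells = c(10L, 10L), seed = 5)
  f <- simulate_field(cfg)
  expect_equal(length(unique(f$labels[f$labels > 0])), 10L)
  # nuclei pairwise disjoint by construction of the label mask; check the
  # frame margin using the ground-truth geometry
  outer_r <- pmax(f$truth$a, f$truth$b)
  expect_true(all(f$truth$row - outer_r >= cfg$margin))
  expect_true(all(f$truth$row + outer_r <= cfg$size[1] - cfg$margin))
  expect_true(all(f$truth$col + outer_r <= cfg$size[2] - cfg$margin))
})

test_that("field generator is bit-reproducible and rejects impossible packings", {
  cfg <- field_config(seed = 9)
  expect_identical(simulate_field(cfg), simulate_field(cfg))
  expect_error(
    simulate_field(field_config(size = c(64L, 64L), n_cells = c(30L, 30L),
                                seed = 5)),
    "generation error")
})

test_that("noiseless single cell shows exactly the two constructed plateaus", {
  f <- two_plateau_field(ratio = 2, cyto = 100)
  vals <- sort(unique(as.vector(f$p65)))
  expect_identical(vals, c(0, 100, 200))
  expect_true(all(f$p65[f$labels == 1] == 200))
})

test_that("ground-truth masks recover the generated per-cell ratios", {
  # self-consistency oracle: median-intensity ratio over the true nucleus
  # and true annulus, pooled over three default noisy fields
  errs <- unlist(lapply(1:3, function(i) {
    f <- simulate_field(field_config(seed = derive_seed(5, paste0("f", i))))
    gt <- f$truth; w <- f$config$annulus_width
    vapply(seq_len(nrow(gt)), function(k) {
      nuc <- which(f$labels == k)
      ring <- setdiff(p65trans:::ellipse_pixels(
        gt$row[k], gt$col[k], gt$a[k] + w, gt$b[k] + w, gt$theta[k],
        nrow(f$p65), ncol(f$p65)), nuc)
      abs(median(f$p65[nuc]) / median(f$p65[ring]) / gt$true_ratio[k] - 1)
    }, numeric(1))
  }))
  expect_gte(mean(errs < 0.10), 0.95)
})

test_that("activation curve has the stated closed form and shape", {
  expect_equal(p65_response(0), 1)
  expect_equal(p65_response(1, peak_time = 1, peak_ratio = 2.3), 2.3)
  tt <- seq(0, 12, by = 0.01)
  r <- p65_response(tt, peak_time = 1, peak_ratio = 2.3)
  expect_equal(tt[which.max(r)], 1)          # unique max at tau
  expect_true(all(diff(r[tt < 1]) > 0))      # increasing before the peak
  expect_true(all(diff(r[tt > 1]) < 0))      # decreasing after it
})

test_that("time-course tables are reproducible and validate the grid", {
  cfg <- kinetics_config(seed = 5)
  expect_identical(simulate_timecourse(cfg), simulate_timecourse(cfg))
  expect_error(kinetics_config(grid = numeric()), "configuration error")
  tc <- simulate_timecourse(cfg, sample_ids = c("A", "B"))
  expect_setequal(unique(tc$sample_id), c("A", "B"))
  expect_true(all(tc$gray_value >= 0))
})
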