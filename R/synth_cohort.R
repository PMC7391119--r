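# Synthetic patient cohorts calibrated to the head-and-neck radiotherapy
# study the pipeline emulates: RTOG/EORTC late-fibrosis grades, Table-2
# style covariates with stratum-specific prevalences, truncated log-normal
# biomarker ratios, and follow-up times.

# Default stratum-wise covariate prevalences (proportions among patients
# with late fibrosis grade < 2 vs >= 2).
default_covariate_model <- function() {
  list(
    age_ge65 = c(lt2 = 0.2593, ge2 = 0.2000),
    sex_male = c(lt2 = 0.7778, ge2 = 0.8154),
    smoking  = c(lt2 = 0.6815, ge2 = 0.5077),
    alcohol  = c(lt2 = 0.7852, ge2 = 0.6462),
    chemo    = c(lt2 = 0.2370, ge2 = 0.2462),
    surgery  = c(lt2 = 0.5185, ge2 = 0.4923),
    site = rbind(
      lt2 = c(oral_cavity = 0.1704, oropharynx = 0.1111, hypopharynx = 0.1111,
              larynx = 0.3111, nasopharynx = 0.2815, unknown = 0.0148),
      ge2 = c(oral_cavity = 0.1231, oropharynx = 0.0462, hypopharynx = 0.2000,
              larynx = 0.4308, nasopharynx = 0.2000, unknown = 0.0000)
    ),
    stage_group = rbind(
      lt2 = c(`I-II` = 0.4296, `III-IVa-b` = 0.5481, unknown = 0.0222),
      ge2 = c(`I-II` = 0.4154, `III-IVa-b` = 0.5692, unknown = 0.0154)
    ),
    rt_technique = rbind(
      lt2 = c(`3D-CRT` = 0.3037, IMRT = 0.5704, unknown = 0.1259),
      ge2 = c(`3D-CRT` = 0.3077, IMRT = 0.5538, unknown = 0.1385)
    )
  )
}

#' Configuration for the synthetic patient cohort
#'
#' Defaults reproduce the published cohort: n = 200, grade distribution
#' (26, 41.5, 23.5, 8.5, 0.5)%, Western-blot activation-ratio medians
#' 2.04 (grade < 2) and 2.51 (grade >= 2) truncated to the printed ranges,
#' immunofluorescence N:C ratio medians 0.80 and 0.92 likewise, and median
#' follow-up 3.2 years on [2.0, 6.8]. Ratio distributions are log-normal
#' truncated to the printed range, with the log-mean calibrated so the
#' truncated distribution's median equals the configured one (see
#' [rlnorm_trunc()]).
#'
#' @param n_patients cohort size.
#' @param grade_probs probability vector over fibrosis grades 0-4; must
#'   sum to 1 within 1e-12.
#' @param ratio_model,if_ratio_model per-stratum (`lt2`, `ge2`) lists with
#'   elements `median`, `log_sd`, `bounds` (length-2 truncation range) for
#'   the Western-blot and image-based ratios respectively.
#' @param covariate_model stratum-wise covariate prevalences; see
#'   `p65trans:::default_covariate_model()` for the shape.
#' @param followup_model list with `median`, `min`, `max` (years) and
#'   `log_sd` of the shifted log-normal.
#' @param seed integer seed (mandatory: the generator is fully
#'   reproducible).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 200L,
                          grade_probs = c(0.26, 0.415, 0.235, 0.085, 0.005),
                          ratio_model = list(
                            lt2 = list(median = 2.04, log_sd = 0.22,
                                       bounds = c(1.09, 3.57)),
                            ge2 = list(median = 2.51, log_sd = 0.22,
                                       bounds = c(1.25, 3.76))),
                          if_ratio_model = list(
                            lt2 = list(median = 0.80, log_sd = 0.30,
                                       bounds = c(0.35, 1.38)),
                            ge2 = list(median = 0.92, log_sd = 0.30,
                                       bounds = c(0.36, 1.91))),
                          covariate_model = default_covariate_model(),
                          followup_model = list(median = 3.2, min = 2.0,
                                                max = 6.8, log_sd = 0.55),
                          seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients <= 0)
    stop("configuration error: n_patients must be a positive count")
  if (!is.numeric(grade_probs) || length(grade_probs) != 5L ||
      any(grade_probs < 0) || abs(sum(grade_probs) - 1) > 1e-12)
    stop("configuration error: grade_probs must be 5 nonnegative values summing to 1")
  for (m in list(ratio_model, if_ratio_model)) {
    for (s in c("lt2", "ge2")) {
      p <- m[[s]]
      if (is.null(p) || p$median <= 0 || p$log_sd <= 0 ||
          length(p$bounds) != 2L || any(p$bounds <= 0) ||
          !(p$bounds[1] < p$median && p$median < p$bounds[2]))
        stop("configuration error: each ratio model needs 0 < lower < median < upper and log_sd > 0")
    }
  }
  if (is.null(seed)) stop("configuration error: seed is mandatory")
  structure(list(n_patients = as.integer(n_patients),
                 grade_probs = grade_probs,
                 ratio_model = ratio_model,
                 if_ratio_model = if_ratio_model,
                 covariate_model = covariate_model,
                 followup_model = followup_model,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Truncated log-normal sampler parameterized by the median
#'
#' Inverse-CDF sampling of a log-normal restricted to
#' `[bounds[1], bounds[2]]`. The log-mean is calibrated (root-finding)
#' so that the median of the *truncated* distribution equals `median`
#' exactly; with an asymmetric truncation range the naive
#' `mu = log(median)` would shift the realized median away from the
#' configured one.
#'
#' @param n number of draws.
#' @param median target median of the truncated distribution.
#' @param log_sd standard deviation on the log scale.
#' @param bounds length-2 positive truncation range containing `median`.
#' @return Numeric vector of `n` draws inside the bounds.
#' @export
rlnorm_trunc <- function(n, median, log_sd, bounds) {
  stopifnot(median > 0, log_sd > 0, length(bounds) == 2L,
            bounds[1] < bounds[2], bounds[1] > 0,
            bounds[1] < median, median < bounds[2])
  trunc_median <- function(mu) {
    a <- pnorm((log(bounds[1]) - mu) / log_sd)
    b <- pnorm((log(bounds[2]) - mu) / log_sd)
    exp(mu + log_sd * qnorm((a + b) / 2))
  }
  mu <- stats::uniroot(function(m) trunc_median(m) - median,
                       lower = log(bounds[1]) - 5 * log_sd,
                       upper = log(bounds[2]) + 5 * log_sd,
                       tol = 1e-12)$root
  plo <- pnorm((log(bounds[1]) - mu) / log_sd)
  phi <- pnorm((log(bounds[2]) - mu) / log_sd)
  exp(mu + log_sd * qnorm(runif(n, plo, phi)))
}

draw_level <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Simulate a patient cohort
#'
#' Draws fibrosis grades from the configured grade distribution, then —
#' conditionally on the grade >= 2 stratum — covariates (independent
#' Bernoulli/categorical per covariate with stratum-specific prevalences),
#' truncated log-normal Western-blot and immunofluorescence ratios, and a
#' shifted log-normal follow-up clipped to the configured range.
#'
#' @param config a [cohort_config()].
#' @return A data.frame with one row per patient and columns `patient_id`,
#'   `age`, `age_ge65`, `sex`, `smoking`, `alcohol`, `site`, `stage_group`,
#'   `rt_technique`, `chemo`, `surgery`, `followup_years`,
#'   `fibrosis_grade`, `wb_ratio`, `if_ratio`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  grade <- sample(0:4, n, replace = TRUE, prob = config$grade_probs)
  stratum <- ifelse(grade >= 2, "ge2", "lt2")
  cm <- config$covariate_model

  pbern <- function(name) unname(cm[[name]][stratum])
  age_ge65 <- rbinom(n, 1L, pbern("age_ge65")) == 1L
  age <- ifelse(age_ge65,
                sample(65:78, n, replace = TRUE),
                sample(42:64, n, replace = TRUE))
  sex <- ifelse(rbinom(n, 1L, pbern("sex_male")) == 1L, "male", "female")
  yn <- function(p, yes = "ever", no = "never")
    ifelse(rbinom(n, 1L, p) == 1L, yes, no)
  smoking <- yn(pbern("smoking"))
  alcohol <- yn(pbern("alcohol"))
  chemo <- yn(pbern("chemo"), "yes", "no")
  surgery <- yn(pbern("surgery"), "yes", "no")

  pick_cat <- function(mat) {
    out <- character(n)
    for (s in c("lt2", "ge2")) {
      idx <- which(stratum == s)
      if (length(idx)) out[idx] <- draw_level(length(idx), mat[s, ])
    }
    out
  }
  site <- pick_cat(cm$site)
  stage_group <- pick_cat(cm$stage_group)
  rt_technique <- pick_cat(cm$rt_technique)

  draw_ratio <- function(model) {
    out <- numeric(n)
    for (s in c("lt2", "ge2")) {
      idx <- which(stratum == s)
      p <- model[[s]]
      if (length(idx))
        out[idx] <- rlnorm_trunc(length(idx), p$median, p$log_sd, p$bounds)
    }
    out
  }
  wb_ratio <- draw_ratio(config$ratio_model)
  if_ratio <- draw_ratio(config$if_ratio_model)

  fm <- config$followup_model
  # shifted log-normal: min + X with median(X) = median - min, clipped above
  fu <- fm$min + exp(log(fm$median - fm$min) + fm$log_sd * rnorm(n))
  followup_years <- pmin(fu, fm$max)

  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = age, age_ge65 = age_ge65, sex = sex,
    smoking = smoking, alcohol = alcohol, site = site,
    stage_group = stage_group, rt_technique = rt_technique,
    chemo = chemo, surgery = surgery,
    followup_years = followup_years,
    fibrosis_grade = grade, wb_ratio = wb_ratio, if_ratio = if_ratio,
    stringsAsFactors = FALSE
  )
}
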