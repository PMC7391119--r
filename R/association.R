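# Cohort statistics: fibrosis dichotomization at grade >= 2, Wilcoxon
# rank-sum comparison of the activation ratio, covariate-adjusted linear
# models, per-covariate contingency tests, and subgroup tables.

#' Dichotomize RTOG/EORTC fibrosis grades at grade 2
#'
#' @param records patient data.frame with a `fibrosis_grade` column, or a
#'   vector of grades.
#' @return Factor with levels `low` (< grade 2) and `high` (>= grade 2).
#' @export
dichotomize_fibrosis <- function(records) {
  grade <- if (is.data.frame(records)) records$fibrosis_grade else records
  if (is.null(grade)) stop("fibrosis_grade is required")
  if (any(!grade %in% 0:4))
    stop("validation error: fibrosis grades must be integers 0-4")
  factor(ifelse(grade >= 2, "high", "low"), levels = c("low", "high"))
}

#' Grade-distribution table
#'
#' Counts and percentages per fibrosis grade plus the fraction with
#' >= grade 2 disease, either from patient records or from printed
#' per-grade counts.
#'
#' @param counts integer vector of patient counts for grades 0-4.
#' @return data.frame (`grade`, `n`, `pct`) with attribute `ge2_pct`, the
#'   percentage of patients at grade >= 2.
#' @export
grade_distribution <- function(counts) {
  stopifnot(length(counts) == 5L, all(counts >= 0))
  n <- sum(counts)
  out <- data.frame(grade = 0:4, n = as.integer(counts),
                    pct = 100 * counts / n)
  attr(out, "ge2_pct") <- 100 * sum(counts[3:5]) / n
  out
}

#' @rdname grade_distribution
#' @param records patient data.frame with `fibrosis_grade`.
#' @export
grade_table <- function(records) {
  grade_distribution(tabulate(records$fibrosis_grade + 1L, 5L))
}

# Exact null distribution of the rank-sum statistic: the number of
# m-subsets of {1..N} with rank sum w is the coefficient of q^w z^m in
# prod_{i=1..N} (1 + z q^i), built up by convolution.
ranksum_null_counts <- function(m, n) {
  N <- m + n
  # counts[k + 1, w + 1] = number of k-subsets of {1..N} with sum w
  wmax <- sum((N - m + 1L):N)
  counts <- matrix(0, nrow = m + 1L, ncol = wmax + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(N)) {
    for (k in rev(seq_len(m))) {
      shifted <- c(rep(0, i), counts[k, seq_len(wmax + 1L - i)])
      counts[k + 1L, ] <- counts[k + 1L, ] + shifted
    }
  }
  counts[m + 1L, ]  # index w + 1 gives count of subsets summing to w
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. The p-value is exact —
#' by the full null distribution of the rank sum — whenever there are no
#' ties and both groups have fewer than 50 observations (the convention
#' of R's `wilcox.test`, which the study used); otherwise a normal
#' approximation with tie-corrected variance and continuity correction is
#' used. Identical samples give p = 1.
#'
#' @param x,y numeric samples for the two groups (both non-empty).
#' @return List with `statistic` (rank sum of `x`), `u` (Mann-Whitney U),
#'   `p.value`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))              # midranks
  W <- sum(r[seq_len(m)])
  U <- W - m * (m + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && m < 50L && n < 50L) {
    cnt <- ranksum_null_counts(m, n)
    probs <- cnt / choose(N, m)     # index w + 1
    w_idx <- W + 1L
    p_le <- sum(probs[seq_len(w_idx)])
    p_ge <- sum(probs[w_idx:length(probs)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = W, u = U, p.value = p, method = "exact"))
  }
  tie_tab <- table(c(x, y))
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(statistic = W, u = U, p.value = 1, method = "normal"))
  mu <- m * n / 2
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = W, u = U, p.value = p, method = "normal")
}

# Encode the adjusted-model design: age continuous, TNM stage collapsed
# to I-II vs III-IVa-b (unknown -> NA, excluded listwise), the rest as
# factors.
encode_covariates <- function(records, covariates) {
  df <- data.frame(row.names = seq_len(nrow(records)))
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.null(v)) stop(sprintf("covariate %s not found", cv))
    if (cv == "age") df$age <- as.numeric(v)
    else if (cv == "stage_group")
      df$stage_group <- factor(ifelse(v == "unknown", NA, v),
                               levels = c("I-II", "III-IVa-b"))
    else if (cv == "rt_technique")
      df$rt_technique <- factor(ifelse(v == "unknown", NA, v),
                                levels = c("3D-CRT", "IMRT"))
    else df[[cv]] <- factor(v)
  }
  df
}

#' Covariate-adjusted comparison of the activation ratio between strata
#'
#' Fits `ratio ~ group + covariates` by least squares; the adjusted
#' p-value is the two-sided t-test on the group coefficient. Also reports
#' per-stratum summaries and the crude Wilcoxon rank-sum p-value.
#' Records with missing covariates are excluded listwise and the count is
#' reported.
#'
#' @param records patient data.frame.
#' @param group factor from [dichotomize_fibrosis()] (levels `low`,
#'   `high`).
#' @param covariates character vector of adjustment covariates; default
#'   is the published model (age, sex, smoking, alcohol, TNM stage,
#'   chemotherapy, surgery).
#' @param biomarker response column, `"wb_ratio"` or `"if_ratio"`.
#' @param log_ratio fit the model on `log(ratio)`?
#' @return List of class `group_comparison`: `strata` (per-stratum n,
#'   median, IQR, range), `crude_p`, `adjusted_p`, `coefficient`, `se`,
#'   `covariates`, `n_excluded`.
#' @export
adjusted_comparison <- function(records, group,
                                covariates = c("age", "sex", "smoking",
                                               "alcohol", "stage_group",
                                               "chemo", "surgery"),
                                biomarker = "wb_ratio",
                                log_ratio = FALSE) {
  stopifnot(is.data.frame(records), length(group) == nrow(records))
  group <- factor(group, levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2L)
    stop("both fibrosis strata must be present for a group comparison")
  y <- records[[biomarker]]
  if (is.null(y)) stop(sprintf("biomarker column %s not found", biomarker))

  strata <- do.call(rbind, lapply(c("low", "high"), function(g) {
    v <- y[group == g & !is.na(y)]
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    data.frame(stratum = g, n = length(v), median = median(v),
               q25 = q[1], q75 = q[2], min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  crude_p <- wilcoxon_rank_sum(y[group == "high"], y[group == "low"])$p.value

  X <- encode_covariates(records, covariates)
  X$.y <- if (log_ratio) log(y) else y
  X$.group <- group
  ok <- complete.cases(X)
  n_excluded <- sum(!ok)
  X <- droplevels(X[ok, , drop = FALSE])
  if (min(table(X$.group)) < 10L)
    warning("fewer than 10 patients in a stratum: adjusted model is fragile")
  fit <- lm(.y ~ ., data = X)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    bad <- names(which(is.na(coef(fit))))
    stop(sprintf("singular design: collinear columns %s",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  row <- grep("^\\.grouphigh$", rownames(sm))
  structure(list(strata = strata,
                 crude_p = crude_p,
                 adjusted_p = sm[row, "Pr(>|t|)"],
                 coefficient = sm[row, "Estimate"],
                 se = sm[row, "Std. Error"],
                 covariates = covariates,
                 biomarker = biomarker,
                 n_excluded = n_excluded),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of %s (late fibrosis < 2 vs >= 2)\n",
              x$biomarker))
  print(x$strata, row.names = FALSE)
  cat(sprintf("crude P (Wilcoxon) = %.4g, adjusted P = %.4g (beta = %.3f, SE = %.3f)\n",
              x$crude_p, x$adjusted_p, x$coefficient, x$se))
  cat(sprintf("adjusted for: %s; %d record(s) excluded for missing covariates\n",
              paste(x$covariates, collapse = ", "), x$n_excluded))
  invisible(x)
}

#' Per-covariate contingency tests between fibrosis strata
#'
#' Chi-squared test without continuity correction when every expected
#' cell count is at least 5, otherwise Fisher's exact test; two-sided.
#' `unknown` levels are excluded from each test; covariates with a single
#' observed level are skipped with a message.
#'
#' @param records patient data.frame.
#' @param group factor from [dichotomize_fibrosis()].
#' @param covariates covariate columns to test.
#' @return data.frame with `variable`, `test`, `statistic`, `p_value`.
#' @export
covariate_tests <- function(records, group,
                            covariates = c("age_ge65", "sex", "smoking",
                                           "alcohol", "site", "stage_group",
                                           "rt_technique", "chemo",
                                           "surgery")) {
  stopifnot(is.data.frame(records), length(group) == nrow(records))
  rows <- lapply(covariates, function(cv) {
    v <- records[[cv]]
    if (is.null(v)) stop(sprintf("covariate %s not found", cv))
    keep <- !is.na(v) & v != "unknown"
    tab <- table(factor(v[keep]), droplevels(group[keep]))
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      message(sprintf("covariate %s has a single level: skipped", cv))
      return(NULL)
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(expected >= 5)) {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      data.frame(variable = cv, test = "chi-squared",
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value, stringsAsFactors = FALSE)
    } else {
      ft <- fisher.test(tab)
      data.frame(variable = cv, test = "fisher",
                 statistic = NA_real_,
                 p_value = ft$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Subgroup definitions: display name, a function of the records giving
# the level per patient, and the adjusted-model covariate dropped when
# stratifying on it (NA = nothing to drop).
subgroup_spec <- function() {
  list(
    age = list(levels = function(r) ifelse(r$age >= 65, ">=65", "<65"),
               drop = "age"),
    sex = list(levels = function(r) r$sex, drop = "sex"),
    smoking = list(levels = function(r) r$smoking, drop = "smoking"),
    alcohol = list(levels = function(r) r$alcohol, drop = "alcohol"),
    site = list(levels = function(r) ifelse(r$site == "nasopharynx",
                                            "nasopharynx", "non-nasopharynx"),
                drop = NA_character_),
    stage = list(levels = function(r) ifelse(r$stage_group == "unknown",
                                             NA, r$stage_group),
                 drop = "stage_group"),
    rt_technique = list(levels = function(r) ifelse(r$rt_technique == "unknown",
                                                    NA, r$rt_technique),
                        drop = NA_character_),
    chemo = list(levels = function(r) r$chemo, drop = "chemo"),
    surgery = list(levels = function(r) r$surgery, drop = "surgery")
  )
}

#' Subgroup analysis of the activation ratio
#'
#' Within each level of each clinical characteristic, reports per-stratum
#' medians and IQRs, the crude Wilcoxon p-value, and the adjusted p-value
#' from the linear model refitted inside the level with the stratifying
#' covariate dropped. No multiplicity adjustment is applied. Levels with
#' fewer than 5 patients in either stratum keep their medians but have
#' p-values suppressed and flagged.
#'
#' @param records patient data.frame.
#' @param group factor from [dichotomize_fibrosis()].
#' @param biomarker response column.
#' @param subgroups named list as from `p65trans:::subgroup_spec()`.
#' @param log_ratio passed to [adjusted_comparison()].
#' @return data.frame with one row per subgroup level: per-stratum `n`,
#'   `median`, `q25`, `q75`, `crude_p`, `adjusted_p`, `flag`.
#' @export
subgroup_analysis <- function(records, group, biomarker = "wb_ratio",
                              subgroups = subgroup_spec(),
                              log_ratio = FALSE) {
  stopifnot(is.data.frame(records), length(group) == nrow(records))
  full_cov <- c("age", "sex", "smoking", "alcohol", "stage_group",
                "chemo", "surgery")
  rows <- list()
  for (var in names(subgroups)) {
    lv <- subgroups[[var]]$levels(records)
    for (level in sort(unique(lv[!is.na(lv)]))) {
      idx <- which(!is.na(lv) & lv == level)
      sub <- records[idx, , drop = FALSE]
      g <- droplevels(group[idx])
      y <- sub[[biomarker]]
      summ <- function(s) {
        v <- y[group[idx] == s & !is.na(y)]
        if (length(v) == 0L) return(c(n = 0, median = NA, q25 = NA, q75 = NA))
        q <- quantile(v, c(0.25, 0.75), names = FALSE)
        c(n = length(v), median = median(v), q25 = q[1], q75 = q[2])
      }
      lo <- summ("low"); hi <- summ("high")
      flag <- ""
      crude_p <- adjusted_p <- NA_real_
      if (min(lo["n"], hi["n"]) < 5) {
        flag <- "sparse_stratum"
      } else {
        cov <- setdiff(full_cov, subgroups[[var]]$drop)
        cmp <- suppressWarnings(
          adjusted_comparison(sub, group[idx], covariates = cov,
                              biomarker = biomarker, log_ratio = log_ratio))
        crude_p <- cmp$crude_p
        adjusted_p <- cmp$adjusted_p
      }
      rows[[paste(var, level)]] <- data.frame(
        variable = var, level = level,
        n_low = lo["n"], median_low = lo["median"],
        q25_low = lo["q25"], q75_low = lo["q75"],
        n_high = hi["n"], median_high = hi["median"],
        q25_high = hi["q25"], q75_high = hi["q75"],
        crude_p = crude_p, adjusted_p = adjusted_p, flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
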