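# Western-blot densitometry: histone-H3 loading-control normalization,
# pre/post-irradiation activation ratio, peak-time selection, and
# nuclear/cytoplasmic fraction-purity QC.

band_value <- function(tab, sid, t, fraction, target) {
  v <- tab$gray_value[tab$sample_id == sid & tab$timepoint_h == t &
                      tab$fraction == fraction & tab$target == target]
  if (length(v) == 0L) return(NA_real_)
  if (length(v) > 1L)
    stop(sprintf("duplicate band rows for sample %s, t=%g h, %s/%s",
                 sid, t, fraction, target))
  v
}

#' Normalize nuclear p65 band densities to the histone H3 loading control
#'
#' Within each sample (one membrane), every nuclear-fraction lane's H3
#' gray value is divided by the maximum H3 gray value across that
#' sample's lanes — so exactly one lane gets normalized H3 = 1 — and the
#' p65 gray value of the same lane is divided by that lane's normalized
#' H3.
#'
#' @param table band-density table (`sample_id`, `timepoint_h`,
#'   `fraction`, `target`, `gray_value`).
#' @param sample_ids samples to process (default: all in the table).
#' @return data.frame with `sample_id`, `timepoint_h`, `normalized_h3`,
#'   `adjusted_p65`.
#' @export
normalize_h3 <- function(table, sample_ids = unique(table$sample_id)) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "timepoint_h", "fraction", "target",
                  "gray_value") %in% names(table)))
  out <- lapply(sample_ids, function(sid) {
    lanes <- sort(unique(table$timepoint_h[table$sample_id == sid &
                                           table$fraction == "nuclear"]))
    if (length(lanes) == 0L)
      stop(sprintf("sample %s has no nuclear-fraction lanes", sid))
    h3 <- vapply(lanes, function(t) band_value(table, sid, t, "nuclear", "H3"),
                 numeric(1))
    p65 <- vapply(lanes, function(t) band_value(table, sid, t, "nuclear", "p65"),
                  numeric(1))
    if (anyNA(h3) || anyNA(p65)) {
      bad <- lanes[is.na(h3) | is.na(p65)]
      stop(sprintf("sample %s: lane at %g h is missing an H3 or p65 band",
                   sid, bad[1]))
    }
    if (max(h3) <= 0)
      stop(sprintf("normalization error: sample %s has max H3 gray value 0",
                   sid))
    nh3 <- h3 / max(h3)
    data.frame(sample_id = sid, timepoint_h = lanes,
               normalized_h3 = nh3, adjusted_p65 = p65 / nh3,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pre/post-irradiation nuclear p65 activation ratio
#'
#' `R = adjusted_p65(post_time) / adjusted_p65(pre_time)`, the proxy for
#' the speed of NF-kB activation. Samples with a missing or zero pre
#' (0 h) density get a flagged record with `ratio = NA` rather than an
#' error.
#'
#' @param adjusted output of [normalize_h3()].
#' @param post_time hours after irradiation (default 1, the calibrated
#'   peak).
#' @param pre_time baseline time point (default 0).
#' @return data.frame with `sample_id`, `pre_time`, `post_time`, `ratio`,
#'   `flag`.
#' @export
activation_ratio <- function(adjusted, post_time = 1, pre_time = 0) {
  stopifnot(is.data.frame(adjusted),
            all(c("sample_id", "timepoint_h", "adjusted_p65") %in%
                  names(adjusted)))
  out <- lapply(unique(adjusted$sample_id), function(sid) {
    rows <- adjusted[adjusted$sample_id == sid, ]
    pre <- rows$adjusted_p65[rows$timepoint_h == pre_time]
    post <- rows$adjusted_p65[rows$timepoint_h == post_time]
    flag <- ""
    ratio <- NA_real_
    if (length(pre) != 1L || length(post) != 1L) flag <- "missing_timepoint"
    else if (pre == 0) flag <- "zero_baseline"
    else ratio <- post / pre
    data.frame(sample_id = sid, pre_time = pre_time, post_time = post_time,
               ratio = ratio, flag = flag, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Time of maximal nuclear p65 expression
#'
#' Grid argmax of the adjusted p65 density per sample (equivalently of
#' the ratio to 0 h); ties are broken to the earliest time point.
#'
#' @param adjusted output of [normalize_h3()]; each sample needs at least
#'   two time points including 0 h.
#' @return data.frame with `sample_id`, `peak_time_h`.
#' @export
find_peak_time <- function(adjusted) {
  stopifnot(is.data.frame(adjusted))
  out <- lapply(unique(adjusted$sample_id), function(sid) {
    rows <- adjusted[adjusted$sample_id == sid, ]
    rows <- rows[order(rows$timepoint_h), ]
    if (nrow(rows) < 2L)
      stop(sprintf("sample %s: need at least two time points", sid))
    if (!any(rows$timepoint_h == 0))
      stop(sprintf("sample %s: the 0-h baseline lane is required", sid))
    data.frame(sample_id = sid,
               peak_time_h = rows$timepoint_h[which.max(rows$adjusted_p65)],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction-purity QC from LAMP1/H3 sentinel bands
#'
#' The nuclear fraction passes when its LAMP1 (cytoplasmic marker) gray
#' value is at most `threshold` times the cytoplasmic LAMP1; the
#' cytoplasmic fraction passes when its H3 (nuclear marker) is at most
#' `threshold` times the nuclear H3. Evaluated lane-by-lane; a fraction
#' passes only if every lane passes.
#'
#' @param table band-density table including LAMP1 and H3 rows for both
#'   fractions.
#' @param sample_ids samples to check (default: all).
#' @param threshold maximum tolerated contamination fraction
#'   (default 0.10).
#' @return data.frame with `sample_id`, `fraction`, `pass`,
#'   `worst_contamination`.
#' @export
purity_qc <- function(table, sample_ids = unique(table$sample_id),
                      threshold = 0.10) {
  stopifnot(is.data.frame(table), threshold > 0)
  out <- lapply(sample_ids, function(sid) {
    lanes <- sort(unique(table$timepoint_h[table$sample_id == sid]))
    get <- function(t, fr, tg) band_value(table, sid, t, fr, tg)
    contam <- function(num_fr, tg, den_fr) vapply(lanes, function(t) {
      num <- get(t, num_fr, tg); den <- get(t, den_fr, tg)
      if (is.na(num) || is.na(den))
        stop(sprintf("sample %s: missing %s band in lane %g h", sid, tg, t))
      if (den == 0) return(ifelse(num == 0, 0, Inf))
      num / den
    }, numeric(1))
    nuc <- contam("nuclear", "LAMP1", "cytoplasmic")
    cyt <- contam("cytoplasmic", "H3", "nuclear")
    data.frame(sample_id = sid,
               fraction = c("nuclear", "cytoplasmic"),
               pass = c(all(nuc <= threshold), all(cyt <= threshold)),
               worst_contamination = c(max(nuc), max(cyt)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
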