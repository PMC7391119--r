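# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary fixtures.

# Binary image with disks at the given centers (rows of `centers`).
disk_image <- function(nr, nc, centers, radius, value = 200, background = 0) {
  img <- matrix(background, nr, nc)
  rr <- row(img); cc <- col(img)
  for (i in seq_len(nrow(centers))) {
    img[(rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radius^2] <- value
  }
  img
}

disk_mask <- function(nr, nc, center, radius) {
  m <- matrix(FALSE, nr, nc)
  m[(row(m) - center[1])^2 + (col(m) - center[2])^2 <= radius^2] <- TRUE
  m
}

# Noiseless single-cell field matching the two-plateau construction:
# background 0, cytoplasm 100, nucleus = 2 x cytoplasm = 200.
two_plateau_field <- function(ratio = 2, cyto = 100, seed = 4L) {
  simulate_field(field_config(
    size = c(96L, 96L), n_cells = c(1L, 1L),
    true_nc_ratio = list(median = ratio, log_sd = 0),
    psf_sigma = 0, background = 0, cyto_intensity = cyto,
    intensity_cv = 0, shot_noise = FALSE, read_noise_sd = 0,
    seed = seed))
}

# Independent Wilcoxon oracle: full enumeration of all C(N, m) rank
# assignments (no ties assumed).
enum_wilcoxon_p <- function(x, y) {
  m <- length(x); N <- m + length(y)
  W <- sum(rank(c(x, y))[seq_len(m)])
  sums <- utils::combn(N, m, sum)
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

# Independent Fisher oracle for a 2x2 table: hypergeometric enumeration.
enum_fisher_p <- function(tab) {
  stopifnot(all(dim(tab) == 2L))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Band table for one sample with explicit nuclear H3/p65 lanes.
band_fixture <- function(h3, p65, times = seq_along(h3) - 1,
                         sample_id = "S1") {
  rbind(
    data.frame(sample_id = sample_id, timepoint_h = times,
               fraction = "nuclear", target = "H3", gray_value = h3),
    data.frame(sample_id = sample_id, timepoint_h = times,
               fraction = "nuclear", target = "p65", gray_value = p65)
  )
}
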