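# Synthetic two-channel PBMC fluorescence fields (DAPI + p65) with
# ground-truth label masks and per-cell true nuclear:cytoplasmic ratios.
# The optics model is deliberately simple: elliptical nuclei with an
# annular cytoplasm, Gaussian PSF blur, Poisson shot noise plus Gaussian
# read noise, clipped to the camera bit depth.

#' Configuration for a synthetic fluorescence field
#'
#' Geometry is sized for PBMCs imaged at 40x: nuclei of 7-11 px semi-axes
#' in a 256 x 256 field with a 7 px cytoplasmic annulus — wide enough
#' that a 5 px measurement ring sits inside the cytoplasm rather than on
#' its boundary, as in real fields where the rim extends past the
#' sampled ring.
#'
#' @param size image dimensions, `c(rows, cols)`.
#' @param n_cells inclusive range for the number of cells per field.
#' @param nucleus_radii range of elliptical semi-axes in pixels.
#' @param annulus_width cytoplasm thickness around each nucleus (px).
#' @param true_nc_ratio list `(median, log_sd)` of the per-cell log-normal
#'   nuclear:cytoplasmic ratio distribution.
#' @param psf_sigma Gaussian point-spread sigma in pixels (0 = no blur).
#' @param background constant background offset (camera counts).
#' @param dapi_intensity,cyto_intensity mean nuclear DAPI and cytoplasmic
#'   p65 signal levels (counts above background).
#' @param intensity_cv per-cell multiplicative CV of both signal levels.
#' @param shot_noise apply Poisson shot noise?
#' @param read_noise_sd additive Gaussian read-noise SD (0 = off).
#' @param bit_depth camera bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param margin cells are kept this many pixels inside the frame.
#' @param seed integer seed (mandatory).
#' @return A validated list of class `field_config`.
#' @export
field_config <- function(size = c(256L, 256L),
                         n_cells = c(10L, 16L),
                         nucleus_radii = c(7, 11),
                         annulus_width = 7,
                         true_nc_ratio = list(median = 0.9, log_sd = 0.15),
                         psf_sigma = 1,
                         background = 100,
                         dapi_intensity = 3000,
                         cyto_intensity = 1000,
                         intensity_cv = 0.1,
                         shot_noise = TRUE,
                         read_noise_sd = 5,
                         bit_depth = 16L,
                         margin = 3L,
                         seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 32),
            length(n_cells) == 2L, n_cells[1] >= 1, n_cells[1] <= n_cells[2],
            length(nucleus_radii) == 2L, nucleus_radii[1] >= 2,
            nucleus_radii[1] <= nucleus_radii[2],
            annulus_width >= 1, true_nc_ratio$median > 0,
            true_nc_ratio$log_sd >= 0, psf_sigma >= 0, background >= 0,
            read_noise_sd >= 0, bit_depth %in% c(8L, 16L), margin >= 0)
  if (is.null(seed)) stop("configuration error: seed is mandatory")
  structure(as.list(environment()), class = "field_config")
}

# Rasterize an ellipse (center cr/cc, semi-axes a/b, orientation theta)
# into linear pixel indices of an nr x nc grid.
ellipse_pixels <- function(cr, cc, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(cr - a - b)); r1 <- min(nr, ceiling(cr + a + b))
  c0 <- max(1L, floor(cc - a - b)); c1 <- min(nc, ceiling(cc + a + b))
  rr <- seq(r0, r1); cc2 <- seq(c0, c1)
  dr <- outer(rr - cr, rep(1, length(cc2)))
  dc <- outer(rep(1, length(rr)), cc2 - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ri <- row(inside)[inside] + r0 - 1L
  ci <- col(inside)[inside] + c0 - 1L
  (ci - 1L) * nr + ri
}

#' Simulate a two-channel fluorescence field with ground truth
#'
#' Places non-overlapping cells (elliptical nucleus + annular cytoplasm)
#' by rejection sampling, paints the noiseless DAPI and p65 channels —
#' inside each nucleus the p65 intensity is exactly `true_ratio` times
#' that cell's cytoplasm intensity — then applies PSF blur, shot noise,
#' read noise and bit-depth clipping.
#'
#' @param config a [field_config()].
#' @param stratum optional fibrosis stratum label (`"lt2"` or `"ge2"`):
#'   overrides the configured ratio median with the calibrated
#'   immunofluorescence medians 0.80 / 0.92.
#' @param ratio_median optional explicit override of the per-cell ratio
#'   median (e.g. a patient-level true ratio); takes precedence over
#'   `stratum`.
#' @return A list of class `fluor_field` with elements `dapi`, `p65`
#'   (numeric matrices), `labels` (ground-truth integer label mask) and
#'   `truth` (data.frame of per-cell geometry, `true_ratio`, intensities).
#' @export
simulate_field <- function(config = field_config(), stratum = NULL,
                           ratio_median = NULL) {
  stopifnot(inherits(config, "field_config"))
  med <- config$true_nc_ratio$median
  if (!is.null(stratum)) {
    stratum <- match.arg(stratum, c("lt2", "ge2"))
    med <- if (stratum == "lt2") 0.80 else 0.92
  }
  if (!is.null(ratio_median)) med <- ratio_median
  set.seed(config$seed)
  nr <- config$size[1]; nc <- config$size[2]
  n_cells <- if (config$n_cells[1] == config$n_cells[2]) config$n_cells[1]
             else sample(config$n_cells[1]:config$n_cells[2], 1L)

  w <- config$annulus_width
  cells <- data.frame(cell_id = integer(), row = numeric(), col = numeric(),
                      a = numeric(), b = numeric(), theta = numeric())
  for (k in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      a <- runif(1, config$nucleus_radii[1], config$nucleus_radii[2])
      b <- runif(1, config$nucleus_radii[1], config$nucleus_radii[2])
      theta <- runif(1, 0, pi)
      outer_r <- max(a, b) + w
      pad <- outer_r + config$margin
      if (2 * pad >= min(nr, nc))
        stop("generation error: cells too large for the field size")
      cr <- runif(1, pad + 1, nr - pad)
      ccen <- runif(1, pad + 1, nc - pad)
      if (nrow(cells) == 0L ||
          all(sqrt((cells$row - cr)^2 + (cells$col - ccen)^2) >
              outer_r + pmax(cells$a, cells$b) + w + 2)) {
        cells <- rbind(cells, data.frame(cell_id = k, row = cr, col = ccen,
                                         a = a, b = b, theta = theta))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(paste("generation error: could not place cell %d of %d",
                         "without overlap after 1000 retries",
                         "(field too crowded)"), k, n_cells))
  }

  cv <- config$intensity_cv
  cells$true_ratio <- exp(log(med) +
                          config$true_nc_ratio$log_sd * rnorm(n_cells))
  cells$cyto_intensity <- config$cyto_intensity *
    exp(cv * rnorm(n_cells) - cv^2 / 2)
  cells$dapi_intensity <- config$dapi_intensity *
    exp(cv * rnorm(n_cells) - cv^2 / 2)

  dapi <- matrix(config$background, nr, nc)
  p65 <- matrix(config$background, nr, nc)
  labels <- matrix(0L, nr, nc)
  for (k in seq_len(n_cells)) {
    ce <- cells[k, ]
    nuc <- ellipse_pixels(ce$row, ce$col, ce$a, ce$b, ce$theta, nr, nc)
    ring <- setdiff(ellipse_pixels(ce$row, ce$col, ce$a + w, ce$b + w,
                                   ce$theta, nr, nc), nuc)
    labels[nuc] <- k
    dapi[nuc] <- dapi[nuc] + ce$dapi_intensity
    # inside the cell the background is replaced, not added, so that the
    # noiseless nuclear:cytoplasmic intensity quotient is exactly the
    # cell's true ratio
    cyto_total <- config$background + ce$cyto_intensity
    p65[nuc] <- ce$true_ratio * cyto_total
    p65[ring] <- cyto_total
  }

  degrade <- function(img) {
    if (config$psf_sigma > 0) img <- gaussian_blur(img, config$psf_sigma)
    if (config$shot_noise) img <- matrix(rpois(length(img), pmax(img, 0)),
                                         nrow(img), ncol(img))
    if (config$read_noise_sd > 0)
      img <- img + rnorm(length(img), 0, config$read_noise_sd)
    img <- round(img)
    pmin(pmax(img, 0), 2^config$bit_depth - 1)
  }
  structure(list(dapi = degrade(dapi), p65 = degrade(p65),
                 labels = labels, truth = cells, config = config),
            class = "fluor_field")
}

#' Simulate all fields of one patient
#'
#' Draws the fields of a single patient whose per-cell true ratios are
#' log-normal around that patient's true ratio; field seeds derive from
#' `seed` so patients and fields are independent but reproducible.
#'
#' @param patient_ratio the patient's true nuclear:cytoplasmic ratio.
#' @param n_fields number of fields to image.
#' @param config a [field_config()] template (its seed is ignored).
#' @param seed integer seed for this patient.
#' @return A list of `fluor_field` objects.
#' @export
simulate_patient_fields <- function(patient_ratio, n_fields = 3L,
                                    config = field_config(), seed = 1L) {
  stopifnot(patient_ratio > 0, n_fields >= 1)
  lapply(seq_len(n_fields), function(f) {
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("field", f))
    simulate_field(cfg, ratio_median = patient_ratio)
  })
}
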