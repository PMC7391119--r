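# Automated immunofluorescence quantification of p65 nuclear
# translocation: DAPI-based nuclear segmentation, eroded nuclear masks to
# limit cytoplasmic contamination, boundary-constrained cytoplasmic ring
# masks, and per-cell nuclear:cytoplasmic median-intensity ratios.

#' Segmentation and quantification parameters
#'
#' Free parameters of the image pipeline. Defaults are sized for PBMC
#' nuclei imaged at 40x (7-11 px semi-axes): Gaussian smoothing sigma 2,
#' Otsu global threshold, area gate 50-2000 px, 2 px nuclear erosion,
#' 5 px ring dilation, border-touching nuclei excluded, and at least 20
#' retained cells required per patient.
#'
#' @param smoothing_sigma Gaussian sigma (px) applied to DAPI before
#'   thresholding.
#' @param threshold_method global threshold method; only `"otsu"`.
#' @param min_area,max_area retained nucleus area range (px).
#' @param erosion_radius disk radius (px) for nuclear-mask erosion.
#' @param ring_dilation disk radius (px) for the cytoplasmic ring
#'   dilation.
#' @param exclude_border drop nuclei touching the image border?
#' @param min_cells minimum retained cells per patient before the summary
#'   is flagged `insufficient_cells`.
#' @param seed_window radius (px) of the neighbourhood used to detect
#'   distance-transform maxima that seed the watershed split.
#' @return A validated list of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 2,
                                threshold_method = c("otsu"),
                                min_area = 50L, max_area = 2000L,
                                erosion_radius = 2,
                                ring_dilation = 5,
                                exclude_border = TRUE,
                                min_cells = 20L,
                                seed_window = 5L) {
  threshold_method <- match.arg(threshold_method)
  if (erosion_radius < 1) stop("parameter error: erosion_radius must be >= 1")
  if (ring_dilation < 1) stop("parameter error: ring_dilation must be >= 1")
  if (!(min_area < max_area))
    stop("parameter error: min_area must be below max_area")
  stopifnot(smoothing_sigma >= 0, min_area >= 1, min_cells >= 1,
            seed_window >= 1)
  structure(as.list(environment()), class = "segmentation_params")
}

# Fill interior holes: background components not connected to the border
# become foreground.
fill_holes <- function(mask) {
  bg <- cpp_label_components(!mask, 4L)
  nr <- nrow(bg); nc <- ncol(bg)
  border_labels <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  hole <- bg > 0 & !(bg %in% border_labels)
  mask | hole
}

#' Segment nuclei from a DAPI image
#'
#' Gaussian smoothing, Otsu global threshold, hole filling, watershed
#' splitting of touching nuclei seeded at distance-transform maxima, and
#' an area gate. Optionally removes objects touching the image border.
#' A blank or constant image yields an empty mask with a warning rather
#' than an error.
#'
#' @param dapi numeric matrix (single-channel DAPI image).
#' @param params a [segmentation_params()].
#' @return Integer label mask (0 = background, labels `1..K`).
#' @export
segment_nuclei <- function(dapi, params = segmentation_params()) {
  stopifnot(is.matrix(dapi), inherits(params, "segmentation_params"))
  if (!all(is.finite(dapi))) stop("DAPI image has non-finite intensities")
  empty <- matrix(0L, nrow(dapi), ncol(dapi))
  smooth <- gaussian_blur(dapi, params$smoothing_sigma)
  thr <- otsu_threshold(smooth)
  if (is.na(thr)) {
    warning("blank or constant DAPI image: returning an empty mask")
    return(empty)
  }
  fg <- fill_holes(smooth > thr)
  if (!any(fg)) {
    warning("no foreground after thresholding: returning an empty mask")
    return(empty)
  }
  edt <- cpp_edt(fg)
  # smooth the EDT so a jagged boundary cannot split one ridge into
  # several seeds
  seeds <- cpp_local_maxima(gaussian_blur(edt, 1), as.integer(params$seed_window),
                            min_value = 2)
  markers <- cpp_label_components(seeds & fg, 8L)
  if (max(markers) == 0L) markers <- cpp_label_components(fg, 8L)
  lab <- cpp_watershed(edt, markers, fg)

  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  if (params$exclude_border) {
    nr <- nrow(lab); nc <- ncol(lab)
    on_border <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
    keep <- setdiff(keep, on_border)
  }
  lab[!(lab %in% keep)] <- 0L
  relabel_mask(lab)
}

# Apply a function to each object's own binary mask over a padded
# bounding box; f maps logical matrix -> logical matrix of same dims.
per_object_morph <- function(labels, pad, f) {
  out <- matrix(0L, nrow(labels), ncol(labels))
  for (k in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == k)
    rows <- (idx - 1L) %% nrow(labels) + 1L
    cols <- (idx - 1L) %/% nrow(labels) + 1L
    r0 <- max(1L, min(rows) - pad); r1 <- min(nrow(labels), max(rows) + pad)
    c0 <- max(1L, min(cols) - pad); c1 <- min(ncol(labels), max(cols) + pad)
    sub <- labels[r0:r1, c0:c1, drop = FALSE] == k
    res <- f(sub)
    ridx <- which(res)
    if (length(ridx)) {
      rr <- (ridx - 1L) %% nrow(res) + r0
      cc <- (ridx - 1L) %/% nrow(res) + c0
      out[(cc - 1L) * nrow(out) + rr] <- k
    }
  }
  out
}

#' Erode a nuclear label mask
#'
#' Per-object morphological erosion with a Euclidean disk; reduces
#' cytoplasmic contamination of the nuclear intensity sample. Objects that
#' erode to emptiness are dropped and reported in the `dropped_labels`
#' attribute.
#'
#' @param labels integer label mask.
#' @param radius disk radius in pixels (>= 1).
#' @return Eroded label mask (same label values); attribute
#'   `dropped_labels` lists labels erased by the erosion.
#' @export
erode_nuclear_mask <- function(labels, radius) {
  stopifnot(is.matrix(labels))
  if (radius < 1) stop("parameter error: erosion radius must be >= 1")
  eroded <- per_object_morph(labels, pad = 1L,
                             function(m) erode_disk(m, radius))
  dropped <- setdiff(unique(labels[labels > 0]), unique(eroded[eroded > 0]))
  attr(eroded, "dropped_labels") <- sort(dropped)
  eroded
}

#' Build cytoplasmic ring masks around nuclei
#'
#' For each nucleus: dilate the (uneroded) nuclear region by the ring
#' dilation radius, remove every nuclear pixel, and constrain the result
#' to (a) that cell's territory in the Voronoi partition of nuclear
#' centroids — so neighbouring rings never share pixels — and (b) the p65
#' foreground (Otsu threshold on the p65 channel), the proxy for "inside
#' the cell boundary". Cells whose ring comes out empty are reported in
#' the `ring_empty` attribute and excluded downstream.
#'
#' @param labels uneroded nuclear label mask.
#' @param params a [segmentation_params()].
#' @param p65 p65 channel image sharing the pixel grid of `labels`.
#' @return Integer ring label mask; attribute `ring_empty` lists labels
#'   with no ring pixels.
#' @export
make_ring_mask <- function(labels, params = segmentation_params(), p65) {
  stopifnot(is.matrix(labels), is.matrix(p65))
  if (!all(dim(labels) == dim(p65)))
    stop("dimension error: labels and p65 must share a pixel grid")
  labs <- sort(unique(labels[labels > 0]))
  empty <- matrix(0L, nrow(labels), ncol(labels))
  if (length(labs) == 0L) {
    attr(empty, "ring_empty") <- integer()
    return(empty)
  }
  thr <- otsu_threshold(p65)
  p65_fg <- if (is.na(thr)) matrix(TRUE, nrow(p65), ncol(p65)) else p65 > thr
  terr <- voronoi_partition(mask_centroids(labels), nrow(labels), ncol(labels))
  nuclear_any <- labels > 0
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- as.integer(ceiling(params$ring_dilation)) + 1L
  ring <- matrix(0L, nr, nc)
  for (k in labs) {
    idx <- which(labels == k)
    rows <- (idx - 1L) %% nr + 1L
    cols <- (idx - 1L) %/% nr + 1L
    r0 <- max(1L, min(rows) - pad); r1 <- min(nr, max(rows) + pad)
    c0 <- max(1L, min(cols) - pad); c1 <- min(nc, max(cols) + pad)
    sub <- labels[r0:r1, c0:c1, drop = FALSE] == k
    dil <- dilate_disk(sub, params$ring_dilation)
    keep <- dil & !nuclear_any[r0:r1, c0:c1] &
      terr[r0:r1, c0:c1] == k & p65_fg[r0:r1, c0:c1]
    ridx <- which(keep)
    if (length(ridx)) {
      rr <- (ridx - 1L) %% nrow(keep) + r0
      cc <- (ridx - 1L) %/% nrow(keep) + c0
      ring[(cc - 1L) * nr + rr] <- k
    }
  }
  attr(ring, "ring_empty") <-
    sort(setdiff(labs, unique(ring[ring > 0])))
  ring
}

#' Per-cell nuclear:cytoplasmic intensity ratios
#'
#' For every cell, the nuclear median is the median p65 intensity over the
#' eroded nucleus and the ring median over the cytoplasmic ring; the
#' ratio is their quotient. Cells with an empty mask or a zero ring
#' median are flagged and not retained.
#'
#' @param p65 p65 channel image.
#' @param eroded eroded nuclear label mask.
#' @param rings ring label mask from [make_ring_mask()].
#' @return data.frame with columns `cell_id`, `nuclear_median`,
#'   `ring_median`, `nc_ratio`, `nuclear_area_px`, `ring_area_px`,
#'   `qc_flags` (comma-separated) and `retained`.
#' @export
quantify_cells <- function(p65, eroded, rings) {
  stopifnot(is.matrix(p65), is.matrix(eroded), is.matrix(rings))
  if (!all(dim(p65) == dim(eroded)) || !all(dim(p65) == dim(rings)))
    stop("dimension error: p65 and masks must share a pixel grid")
  ids <- sort(union(unique(eroded[eroded > 0]), unique(rings[rings > 0])))
  rows <- lapply(ids, function(k) {
    nuc <- p65[eroded == k]
    rng <- p65[rings == k]
    flags <- character()
    if (length(nuc) == 0L) flags <- c(flags, "empty_nucleus")
    if (length(rng) == 0L) flags <- c(flags, "ring_empty")
    nm <- if (length(nuc)) median(nuc) else NA_real_
    rm_ <- if (length(rng)) median(rng) else NA_real_
    if (!is.na(rm_) && rm_ == 0) flags <- c(flags, "zero_ring_median")
    ok <- length(flags) == 0L
    data.frame(cell_id = k,
               nuclear_median = nm, ring_median = rm_,
               nc_ratio = if (ok) nm / rm_ else NA_real_,
               nuclear_area_px = length(nuc), ring_area_px = length(rng),
               qc_flags = paste(flags, collapse = ","),
               retained = ok, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(cell_id = integer(), nuclear_median = numeric(),
                      ring_median = numeric(), nc_ratio = numeric(),
                      nuclear_area_px = integer(), ring_area_px = integer(),
                      qc_flags = character(), retained = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Patient-level summary of per-cell ratios
#'
#' The patient value is the median `nc_ratio` across all retained cells
#' pooled over that patient's fields. Fewer retained cells than
#' `min_cells` raises the `insufficient_cells` QC flag; zero retained
#' cells yields a missing value with the `no_cells` flag (never an
#' error).
#'
#' @param records pooled [quantify_cells()] output for one patient.
#' @param params a [segmentation_params()] (supplies `min_cells`).
#' @return One-row data.frame: `patient_ratio`, `n_cells`, `qc_flags`.
#' @export
patient_image_summary <- function(records, params = segmentation_params()) {
  stopifnot(is.data.frame(records))
  kept <- records[records$retained & !is.na(records$nc_ratio), , drop = FALSE]
  flags <- character()
  if (nrow(kept) == 0L) {
    return(data.frame(patient_ratio = NA_real_, n_cells = 0L,
                      qc_flags = "no_cells", stringsAsFactors = FALSE))
  }
  if (nrow(kept) < params$min_cells) flags <- c(flags, "insufficient_cells")
  data.frame(patient_ratio = median(kept$nc_ratio), n_cells = nrow(kept),
             qc_flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Quantify one field end to end
#'
#' Convenience wrapper: segment nuclei on DAPI, erode, build rings on the
#' p65 channel, and compute per-cell ratios.
#'
#' @param dapi,p65 the two channel images, or a `fluor_field` in `dapi`.
#' @param params a [segmentation_params()].
#' @return Per-cell data.frame as from [quantify_cells()].
#' @export
quantify_field <- function(dapi, p65 = NULL,
                           params = segmentation_params()) {
  if (inherits(dapi, "fluor_field")) {
    p65 <- dapi$p65
    dapi <- dapi$dapi
  }
  labels <- segment_nuclei(dapi, params)
  eroded <- erode_nuclear_mask(labels, params$erosion_radius)
  rings <- make_ring_mask(labels, params, p65)
  quantify_cells(p65, eroded, rings)
}

#' Quantify all fields of a patient
#'
#' @param fields list of `fluor_field` objects (or `list(dapi=, p65=)`).
#' @param params a [segmentation_params()].
#' @return One-row patient summary as from [patient_image_summary()].
#' @export
quantify_patient <- function(fields, params = segmentation_params()) {
  records <- do.call(rbind, lapply(fields, quantify_field, params = params))
  patient_image_summary(records, params)
}
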