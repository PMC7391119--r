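# Shared numerical helpers: seed substreams, thresholding, blurring and
# binary morphology on top of the exact Euclidean distance transform.

#' Derive a per-stage random seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage name to a
#' 31-bit seed, so that one pipeline knob reproduces every stochastic
#' stage without the stages sharing a stream.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage (e.g. `"cohort"`).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483629  # largest prime < 2^31
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h)
}

#' Otsu's threshold for a grayscale image
#'
#' Maximizes between-class variance over a fixed-bin histogram; the
#' standard global threshold for bimodal fluorescence intensity data.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins.
#' @return Threshold value; pixels `> threshold` are foreground. `NA` when
#'   the input is constant (no two classes to separate).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NA_real_)
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE), n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- counts / sum(counts)
  cw <- cumsum(w)                       # class-0 weight at each cut
  cm <- cumsum(w * mids)                # class-0 cumulative mean mass
  mt <- cm[n_bins]
  valid <- cw > 0 & cw < 1
  sb2 <- rep(-Inf, n_bins)
  sb2[valid] <- (mt * cw[valid] - cm[valid])^2 / (cw[valid] * (1 - cw[valid]))
  breaks[which.max(sb2) + 1L]
}

# 1D Gaussian kernel, radius 3*sigma.
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one margin with edge renormalization (replicate-like
# behaviour: weights falling off the image are dropped and the remainder
# rescaled). margin = 1 blurs down columns, margin = 2 along rows.
blur_margin <- function(img, k, margin) {
  r <- (length(k) - 1L) / 2L
  acc <- img * 0
  wgt <- img * 0
  n <- dim(img)[margin]
  for (o in seq(-r, r)) {
    w <- k[o + r + 1L]
    src <- seq_len(n) + o
    keep <- src >= 1L & src <= n
    if (margin == 1L) {
      acc[keep, ] <- acc[keep, ] + w * img[src[keep], ]
      wgt[keep, ] <- wgt[keep, ] + w
    } else {
      acc[, keep] <- acc[, keep] + w * img[, src[keep]]
      wgt[, keep] <- wgt[, keep] + w
    }
  }
  acc / wgt
}

#' Gaussian smoothing of an image matrix
#'
#' Separable Gaussian blur with edge renormalization.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels; `0` returns `img` unchanged.
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  k <- gaussian_kernel(sigma)
  blur_margin(blur_margin(img, k, 1L), k, 2L)
}

#' Binary morphology with a Euclidean disk
#'
#' Erosion and dilation of a logical mask by the disk of the given radius,
#' computed exactly through the Euclidean distance transform: a pixel
#' survives erosion iff its distance to the background exceeds the radius,
#' and joins the dilation iff its distance to the foreground is at most
#' the radius.
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return Logical matrix of the same dimensions.
#' @export
erode_disk <- function(mask, radius) {
  stopifnot(is.matrix(mask), radius >= 1)
  mode(mask) <- "logical"
  cpp_edt(mask) > radius + 1e-9
}

#' @rdname erode_disk
#' @export
dilate_disk <- function(mask, radius) {
  stopifnot(is.matrix(mask), radius >= 1)
  mode(mask) <- "logical"
  d <- cpp_edt(!mask)
  d <= radius + 1e-9
}

#' Distance transform of a binary mask
#'
#' Exact Euclidean distance from each pixel to the nearest background
#' (`FALSE`) pixel; background pixels get 0.
#'
#' @param mask logical matrix.
#' @return Numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  stopifnot(is.matrix(mask))
  mode(mask) <- "logical"
  cpp_edt(mask)
}

#' Relabel a label mask to consecutive labels 1..K
#'
#' @param labels integer matrix, 0 = background.
#' @return Integer matrix whose positive labels are `1..K` in increasing
#'   order of the original labels.
#' @export
relabel_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  old <- sort(unique(labels[labels > 0]))
  if (length(old) == 0L) return(matrix(0L, nrow(labels), ncol(labels)))
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[labels > 0] <- match(labels[labels > 0], old)
  out
}

# Object centroids of a label mask: data.frame(label, row, col).
mask_centroids <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), row = numeric(), col = numeric()))
  lab <- labels[idx]
  rows <- (idx - 1L) %% nrow(labels) + 1L
  cols <- (idx - 1L) %/% nrow(labels) + 1L
  out <- data.frame(
    label = sort(unique(lab)),
    row = as.numeric(tapply(rows, lab, mean)),
    col = as.numeric(tapply(cols, lab, mean))
  )
  rownames(out) <- NULL
  out
}

# Voronoi territory of seed points over the full pixel grid: each pixel is
# assigned the label of the nearest centroid (ties to the lowest label).
voronoi_partition <- function(centroids, nr, nc) {
  stopifnot(nrow(centroids) >= 1L)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best_d <- matrix(Inf, nr, nc)
  best_l <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(centroids))) {
    d <- (rows - centroids$row[k])^2 + (cols - centroids$col[k])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_l[upd] <- centroids$label[k]
  }
  best_l
}
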