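# Image quantification: segmentation, mask morphology, ring masks and
# per-cell ratios.

test_that("well-separated disks segment one-to-one with high overlap", {
  centers <- as.matrix(expand.grid(c(45, 105, 165, 225), c(60, 130, 200)))
  centers <- centers[1:10, ]
  dapi <- disk_image(256, 256, centers, radius = 9, value = 200)
  lab <- segment_nuclei(dapi, segmentation_params())
  expect_equal(max(lab), 10L)
  for (i in seq_len(10)) {
    truth <- disk_mask(256, 256, centers[i, ], 9)
    k <- unique(lab[truth & lab > 0])
    expect_length(k, 1L)
    expect_gte(jaccard(lab == k, truth), 0.9)
  }
})

test_that("blank images give empty masks with a warning, not an error", {
  expect_warning(lab <- segment_nuclei(matrix(0, 64, 64)), "empty mask")
  expect_equal(max(lab), 0L)
})

test_that("a dumbbell of two fused disks is split by the watershed", {
  dapi <- disk_image(96, 96, rbind(c(48, 34), c(48, 50)), radius = 10,
                     value = 200)
  lab <- segment_nuclei(dapi, segmentation_params())
  expect_equal(max(lab), 2L)
})

test_that("nuclear erosion is anti-extensive, per object, and reports drops", {
  expect_error(erode_nuclear_mask(matrix(0L, 8, 8), 0), "parameter error")
  big <- disk_mask(64, 64, c(32, 32), 10)
  labels <- matrix(0L, 64, 64)
  labels[big] <- 1L
  labels[5, 5] <- 2L; labels[5, 6] <- 2L   # 2-px object
  er <- erode_nuclear_mask(labels, 2)
  expect_true(all(labels[er == 1L] == 1L))          # subset of parent
  expect_lt(sum(er == 1L), sum(labels == 1L))       # strictly smaller
  expect_false(any(er == 2L))                       # eroded to emptiness
  expect_identical(attr(er, "dropped_labels"), 2L)
  # subset property on a generated field
  f <- simulate_field(field_config(seed = 5))
  lab <- segment_nuclei(f$dapi)
  er2 <- erode_nuclear_mask(lab, 2)
  expect_true(all(lab[er2 > 0] == er2[er2 > 0]))
})

test_that("ring masks obey the set algebra and stay in their Voronoi cell", {
  p <- segmentation_params()
  labels <- matrix(0L, 96, 96)
  labels[disk_mask(96, 96, c(48, 30), 8)] <- 1L
  labels[disk_mask(96, 96, c(48, 52), 8)] <- 2L
  p65 <- matrix(500, 96, 96)  # constant: no foreground constraint
  rings <- make_ring_mask(labels, p, p65)
  expect_true(all(labels[rings > 0] == 0))                 # ring ^ nucleus = 0
  for (k in 1:2) {
    dil <- dilate_disk(labels == k, p$ring_dilation)
    expect_true(all(dil[rings == k]))                      # ring within dilation
  }
  terr <- p65trans:::voronoi_partition(p65trans:::mask_centroids(labels),
                                       96, 96)
  expect_true(all(terr[rings > 0] == rings[rings > 0]))    # disjoint territories
  expect_error(make_ring_mask(labels, p, matrix(0, 10, 10)),
               "dimension error")
})

test_that("the noiseless two-plateau fixture yields ring median exactly 100", {
  f <- two_plateau_field(ratio = 2, cyto = 100)
  lab <- segment_nuclei(f$dapi)
  rings <- make_ring_mask(lab, segmentation_params(), f$p65)
  expect_equal(max(lab), 1L)
  expect_equal(median(f$p65[rings == 1L]), 100)
  er <- erode_nuclear_mask(lab, 2)
  rec <- quantify_cells(f$p65, er, rings)
  expect_equal(rec$nc_ratio, 2)
})

test_that("per-cell ratios are median quotients with division guards", {
  p65 <- matrix(c(190, 200, 210, 90, 100, 110), 1, 6)
  er <- matrix(c(1L, 1L, 1L, 0L, 0L, 0L), 1, 6)
  ring <- matrix(c(0L, 0L, 0L, 1L, 1L, 1L), 1, 6)
  rec <- quantify_cells(p65, er, ring)
  expect_equal(rec$nc_ratio, 2.0)
  expect_equal(rec$nuclear_median, 200)
  # zero ring median: flagged, no ratio
  rec0 <- quantify_cells(matrix(c(5, 0), 1, 2),
                         matrix(c(1L, 0L), 1, 2), matrix(c(0L, 1L), 1, 2))
  expect_true(grepl("zero_ring_median", rec0$qc_flags))
  expect_true(is.na(rec0$nc_ratio))
  expect_false(rec0$retained)
  expect_error(quantify_cells(p65, er, matrix(0L, 2, 2)), "dimension error")
})

test_that("mask-algebra invariants hold on generated noisy fields", {
  p <- segmentation_params()
  for (i in 1:2) {
    f <- simulate_field(field_config(seed = derive_seed(5, paste0("inv", i))))
    lab <- segment_nuclei(f$dapi, p)
    er <- erode_nuclear_mask(lab, p$erosion_radius)
    rings <- make_ring_mask(lab, p, f$p65)
    expect_true(all(lab[er > 0] == er[er > 0]))      # eroded subset nuclear
    expect_true(all(lab[rings > 0] == 0))            # ring disjoint of nuclei
    for (k in unique(rings[rings > 0])) {
      dil <- dilate_disk(lab == k, p$ring_dilation)
      expect_true(all(dil[rings == k]))              # ring within dilation
    }
  }
})

test_that("nc ratios are invariant under p65 intensity rescaling", {
  f <- simulate_field(field_config(seed = 5))
  lab <- segment_nuclei(f$dapi)
  p <- segmentation_params()
  base <- quantify_cells(f$p65, erode_nuclear_mask(lab, p$erosion_radius),
                         make_ring_mask(lab, p, f$p65))
  scaled_img <- f$p65 * 3.7
  scaled <- quantify_cells(scaled_img,
                           erode_nuclear_mask(lab, p$erosion_radius),
                           make_ring_mask(lab, p, scaled_img))
  expect_equal(scaled$nc_ratio, base$nc_ratio, tolerance = 1e-12)
})

test_that("the pipeline recovers generated per-cell ratios within 10%", {
  f <- simulate_field(field_config(seed = 5))
  rec <- quantify_field(f)
  cen <- p65trans:::mask_centroids(segment_nuclei(f$dapi))
  gt <- f$truth
  nearest <- vapply(seq_len(nrow(cen)), function(i)
    which.min((gt$row - cen$row[i])^2 + (gt$col - cen$col[i])^2), integer(1))
  err <- abs(rec$nc_ratio[match(cen$label, rec$cell_id)] /
               gt$true_ratio[nearest] - 1)
  expect_gte(mean(err < 0.10, na.rm = TRUE), 0.90)
})

test_that("patient summaries are medians with cell-count QC", {
  rec <- data.frame(cell_id = 1:3, nuclear_median = 1, ring_median = 1,
                    nc_ratio = c(1, 2, 3), nuclear_area_px = 10,
                    ring_area_px = 10, qc_flags = "", retained = TRUE)
  s <- patient_image_summary(rec, segmentation_params(min_cells = 2))
  expect_equal(s$patient_ratio, 2.0)
  expect_equal(s$qc_flags, "")
  s2 <- patient_image_summary(rec, segmentation_params(min_cells = 20))
  expect_equal(s2$patient_ratio, 2.0)
  expect_match(s2$qc_flags, "insufficient_cells")
  s3 <- patient_image_summary(rec[0, ], segmentation_params())
  expect_true(is.na(s3$patient_ratio))
  expect_match(s3$qc_flags, "no_cells")
})

test_that("patient summaries concentrate around the true stratum ratio", {
  # scaled-down version of the repeated-patient experiment: 40 seeds, one
  # 320x320 field of ~26 cells per patient, true ratio median 0.92
  hits <- vapply(1:40, function(i) {
    cfg <- field_config(size = c(320L, 320L), n_cells = c(24L, 28L),
                        seed = derive_seed(5, paste0("pat", i)))
    f <- simulate_field(cfg, ratio_median = 0.92)
    s <- patient_image_summary(quantify_field(f), segmentation_params())
    abs(s$patient_ratio - 0.92) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
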