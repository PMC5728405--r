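test_that("segmentation recovers synthetic nuclei with high overlap", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)

  img <- generate_fish_image(small_fish_spec(seed = 12, n_cells = 5))
  labels <- segment_nuclei(img$channels$dapi, min_area_px = 100)
  expect_equal(max(labels), 5)
  truth <- img$truth$nucleus_labels
  # match each segmented label to the truth label under its centroid
  for (k in 1:5) {
    seg <- labels == k
    tk <- unique(truth[seg & truth > 0])
    expect_length(tk, 1)
    expect_gte(jaccard(seg, truth == tk), 0.9)
  }
  expect_error(segment_nuclei(array(0, c(4, 4, 2))), "2-D")
})

test_that("touching nuclei split under the watershed flag only", {
  dapi <- matrix(0, 64, 64)
  dapi[ddrquant:::ellipse_pixels(c(64, 64), 32, 24, 9, 9, 0)] <- 1000
  dapi[ddrquant:::ellipse_pixels(c(64, 64), 32, 41, 9, 9, 0)] <- 1000
  expect_equal(max(segment_nuclei(dapi, min_area_px = 20,
                                  split_touching = FALSE)), 1)
  expect_equal(max(segment_nuclei(dapi, min_area_px = 20,
                                  split_touching = TRUE)), 2)
})

test_that("region pairs honour erosion and ring geometry exactly", {
  labels <- matrix(0L, 64, 64)
  labels[20:39, 20:39] <- 1L  # 20x20 square
  reg <- build_region_pair(labels, erosion_px = 2, ring_gap_px = 2,
                           ring_width_px = 10)
  expect_equal(sum(reg$nuclear == 1L), 256)  # 16x16 after 2-px erosion
  expect_identical(reg$nuclear == 1L, oracle_erode(labels == 1L, 2))
  expect_identical(reg$ring, oracle_ring(labels, 2, 10))
  # degenerate parameters: nuclear region is the nucleus, ring empty
  reg0 <- build_region_pair(labels, 0, 0, 0)
  expect_identical(reg0$nuclear, labels)
  expect_equal(sum(reg0$ring), 0)
})

test_that("rings and nuclei are disjoint and vanishing nuclei are flagged", {
  labels <- matrix(0L, 48, 48)
  labels[10:12, 10:12] <- 1L   # 3x3: vanishes under 2-px erosion
  labels[25:40, 25:40] <- 2L
  reg <- build_region_pair(labels)
  expect_true(reg$cells$flag_empty_nucleus[1])
  expect_false(reg$cells$flag_empty_nucleus[2])
  expect_true(all(labels[reg$ring > 0L] == 0L))
  expect_true(all(reg$ring[reg$nuclear > 0L] == 0L))
})

test_that("N/C measurement is exact on generator masks and flags degenerate cells", {
  uni <- matrix(7, 48, 48)
  labels <- matrix(0L, 48, 48); labels[20:30, 20:30] <- 1L
  reg <- build_region_pair(labels, ring_width_px = 6)
  m <- measure_nc_ratio(uni, reg)
  expect_equal(m$nc_ratio, 1)

  img <- generate_fish_image(small_fish_spec(seed = 6, true_nc_ratio = 2))
  reg <- build_region_pair(img$truth$nucleus_labels)
  m <- measure_nc_ratio(img$channels$signal, reg)
  expect_equal(m$nc_ratio, rep(2, 6), tolerance = 1e-12)

  # scalar invariance of the ratio
  m2 <- measure_nc_ratio(3.7 * img$channels$signal, reg)
  expect_equal(m2$nc_ratio, m$nc_ratio, tolerance = 1e-12)

  # zero signal in the ring: zero-denominator flag, ratio undefined
  z <- matrix(0, 48, 48); z[20:30, 20:30] <- 5
  labels <- matrix(0L, 48, 48); labels[20:30, 20:30] <- 1L
  regz <- build_region_pair(labels, ring_width_px = 6)
  mz <- measure_nc_ratio(z, regz)
  expect_true(mz$flag_zero_denominator[1])
  expect_true(is.na(mz$nc_ratio[1]))
})

test_that("focus scoring recovers planted counts and the >= min_foci convention", {
  img <- generate_foci_image(foci_image_spec(foci_counts = c(0, 3, 5, 8),
                                             n_cells = 4, seed = 3))
  sc <- score_foci(img$channels$foci, img$truth$nucleus_labels, min_foci = 5)
  expect_equal(sc$cells$foci_count, c(0, 3, 5, 8))
  expect_equal(sc$fraction_positive, 0.5)  # two of four nuclei at >= 5

  # background-only channel
  flat <- generate_foci_image(foci_image_spec(foci_counts = 0, n_cells = 4,
                                              seed = 4))
  sc0 <- score_foci(flat$channels$foci, flat$truth$nucleus_labels)
  expect_equal(sc0$cells$foci_count, rep(0L, 4))
  expect_equal(sc0$fraction_positive, 0)

  # exactly min_foci in every nucleus scores 1 under the inclusive rule
  at5 <- generate_foci_image(foci_image_spec(foci_counts = 5, n_cells = 4,
                                             seed = 6))
  expect_equal(score_foci(at5$channels$foci, at5$truth$nucleus_labels,
                          min_foci = 5)$fraction_positive, 1)

  # fraction is monotone non-increasing in min_foci
  fr <- vapply(1:9, function(k)
    score_foci(img$channels$foci, img$truth$nucleus_labels,
               min_foci = k)$fraction_positive, numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_error(score_foci(img$channels$foci, img$truth$nucleus_labels,
                          min_foci = 0), "min_foci")
})

test_that("reporter ratios are recovered and low-denominator cells excluded", {
  spec <- reporter_image_spec(true_ratios = c(0.3, 1, 2), n_cells = 3, seed = 5)
  img <- generate_reporter_image(spec)
  rr <- reporter_ratio(img$channels$numerator, img$channels$denominator,
                       img$truth$cell_labels, min_denominator = 1000)
  expect_equal(sort(rr$cells$ratio), sort(spec$true_ratios), tolerance = 0.01)

  # per-channel scalars rescale the ratio by their quotient
  rr2 <- reporter_ratio(2 * img$channels$numerator, 4 * img$channels$denominator,
                        img$truth$cell_labels, min_denominator = 1000)
  expect_equal(rr2$cells$ratio, rr$cells$ratio / 2, tolerance = 1e-12)

  # identical channels give unit ratios
  rr1 <- reporter_ratio(img$channels$denominator, img$channels$denominator,
                        img$truth$cell_labels, min_denominator = 1000)
  expect_equal(rr1$cells$ratio, rep(1, 3))

  spec_u <- reporter_image_spec(true_ratios = 1, n_cells = 3,
                                untransfected = 2L, seed = 8)
  img_u <- generate_reporter_image(spec_u)
  rr_u <- reporter_ratio(img_u$channels$numerator, img_u$channels$denominator,
                         img_u$truth$cell_labels, min_denominator = 1000)
  expect_equal(rr_u$excluded, 2L)
  expect_false(2L %in% rr_u$cells$label)
  expect_error(reporter_ratio(img_u$channels$numerator,
                              img_u$channels$denominator,
                              img_u$truth$cell_labels,
                              min_denominator = 1e9),
               "all cells excluded")
})

test_that("mean nuclear signal aggregates per-nucleus means with SEM over cells", {
  uni <- matrix(42, 32, 32)
  labels <- matrix(0L, 32, 32); labels[4:10, 4:10] <- 1L; labels[20:26, 20:26] <- 2L
  out <- mean_nuclear_signal(uni, labels)
  expect_equal(out$mean, 42)
  expect_equal(out$sem, 0)

  two <- matrix(0, 32, 32); two[labels == 1L] <- 10; two[labels == 2L] <- 30
  expect_equal(mean_nuclear_signal(two, labels)$mean, 20)
  expect_error(mean_nuclear_signal(uni, matrix(0L, 32, 32)), "no nuclei")

  img <- generate_fish_image(small_fish_spec(seed = 13))
  got <- mean_nuclear_signal(img$channels$signal, img$truth$nucleus_labels)
  nl <- img$truth$nucleus_labels
  per_cell <- tapply(img$channels$signal[nl > 0], nl[nl > 0], mean)
  expect_equal(got$mean, mean(per_cell))
  expect_equal(got$cells$nuclear_mean, as.numeric(per_cell))
})
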