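test_that("a blank image yields zero records, not an error", {
  blank <- matrix(500L, 128L, 128L)
  out <- segment_nuclei(blank, seg_params(nucleus_radius = 12))
  expect_equal(nrow(out$records), 0L)
  expect_true(all(out$labels == 0L))
})

test_that("circularity matches closed forms", {
  r <- 10
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  s <- 7
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  # 2:1 ellipse via the Ramanujan perimeter approximation
  b <- 10; a <- 2 * b
  p_ram <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  expect_equal(circularity(pi * a * b, p_ram), 0.8412, tolerance = 1e-4)
  expect_error(circularity(0, 10), "positive")
  expect_error(circularity(10, -1), "positive")
})

test_that("isolated simulated nuclei are recovered with accurate geometry", {
  p <- sim_params(field_width = 700L, field_height = 700L, n_cells = 10L,
                  nucleus_radius_mean = 20, nucleus_radius_sd = 2)
  sf <- simulate_field(p, seed = 17)
  out <- segment_nuclei(sf$field, seg_params_for(p))
  expect_equal(nrow(out$records), 10L)
  expect_true(all(out$records$qc_status == "selected"))
  m <- match_truth(out$records, sf$truth)
  d <- sqrt((out$records$cy[m] - sf$truth$cy)^2 +
              (out$records$cx[m] - sf$truth$cx)^2)
  expect_true(all(d <= 2))
  expect_true(all(abs(out$records$area[m] / sf$truth$area - 1) < 0.1))
})

test_that("fused clumped pairs exceeding the size window are excluded as too large", {
  p <- sim_params(field_width = 600L, field_height = 600L, n_cells = 4L,
                  nucleus_radius_mean = 25, nucleus_radius_sd = 0,
                  eccentricity_max = 0.01, clump_fraction = 1)
  sf <- simulate_field(p, seed = 6)
  # fused unions are at least ~1.6x the single-nucleus area
  seg <- seg_params(nucleus_radius = 25, max_area = 1.5 * pi * 25^2)
  out <- segment_nuclei(sf$field, seg)
  expect_equal(nrow(out$records), 4L)
  expect_true(all(out$records$qc_status == "excluded_size"))
})

test_that("QC precedence is border, then size, then circularity", {
  rec <- data.frame(nucleus_id = 1:4, cy = 0, cx = 0, area = c(10, 10, 5000, 900),
                    perimeter = 1, circularity = c(0.5, 0.5, 0.5, 0.5),
                    mean_dna_intensity = 0,
                    touches_edge = c(TRUE, FALSE, FALSE, FALSE),
                    qc_status = NA_character_, pan_nuclear_flag = FALSE,
                    foci_count = NA_integer_, binucleate_id = NA_integer_,
                    mn_count = NA_integer_)
  seg <- seg_params(nucleus_radius = 15)  # area window ~ [212, 1555]
  out <- qc_filter(rec, seg)
  expect_equal(out$qc_status,
               c("excluded_border", "excluded_size", "excluded_size",
                 "excluded_circularity"))
})

test_that("every planted border-touching nucleus is excluded_border", {
  p <- sim_params(field_width = 512L, field_height = 512L, n_cells = 20L,
                  nucleus_radius_mean = 14, nucleus_radius_sd = 1.4,
                  edge_fraction = 0.4)
  for (s in 1:4) {
    sf <- simulate_field(p, seed = 300 + s)
    out <- segment_nuclei(sf$field, seg_params_for(p))
    edge_truth <- sf$truth[sf$truth$touches_edge, , drop = FALSE]
    if (nrow(edge_truth) == 0L) next
    m <- match_truth(out$records, edge_truth)
    expect_true(all(out$records$qc_status[m] == "excluded_border"))
  }
})

test_that("QC statuses partition the components and recall/precision reach 0.98", {
  total_truth <- 0L; total_sel <- 0L; matched_sel <- 0L
  for (s in 1:3) {
    p <- sim_params(field_width = 800L, field_height = 800L, n_cells = 60L,
                    nucleus_radius_mean = 15, nucleus_radius_sd = 1.5)
    sf <- simulate_field(p, seed = 40 + s)
    out <- segment_nuclei(sf$field, seg_params_for(p))
    r <- out$records
    # partition invariant
    expect_equal(sum(table(r$qc_status)), nrow(r))
    sel <- r[r$qc_status == "selected", ]
    total_truth <- total_truth + nrow(sf$truth)
    total_sel <- total_sel + nrow(sel)
    d <- vapply(seq_len(nrow(sel)), function(i)
      min(sqrt((sf$truth$cy - sel$cy[i])^2 + (sf$truth$cx - sel$cx[i])^2)),
      numeric(1))
    matched_sel <- matched_sel + sum(d <= 3)
  }
  expect_gte(matched_sel / total_truth, 0.98)  # recall
  expect_gte(matched_sel / total_sel, 0.98)    # precision
})

test_that("4-connectivity separates diagonally touching components", {
  img <- matrix(100L, 40L, 40L)
  img[5:12, 5:12] <- 60000L
  img[13:20, 13:20] <- 60000L   # touches the first block only at a corner
  seg8 <- seg_params(nucleus_radius = 5, smooth_sigma = 0,
                     threshold_method = "fixed", fixed_threshold = 30000,
                     connectivity = 8)
  seg4 <- seg_params(nucleus_radius = 5, smooth_sigma = 0,
                     threshold_method = "fixed", fixed_threshold = 30000,
                     connectivity = 4)
  expect_equal(nrow(segment_nuclei(img, seg8)$records), 1L)
  expect_equal(nrow(segment_nuclei(img, seg4)$records), 2L)
})

test_that("operator-fixed thresholds are honoured", {
  f <- manual_field(nuclei = cbind(60, 60, 15), noise_sd = 0)
  out_lo <- segment_nuclei(f, seg_params(nucleus_radius = 15, smooth_sigma = 0,
                                         threshold_method = "fixed",
                                         fixed_threshold = 1000))
  out_hi <- segment_nuclei(f, seg_params(nucleus_radius = 15, smooth_sigma = 0,
                                         threshold_method = "fixed",
                                         fixed_threshold = 3000))
  expect_equal(nrow(out_lo$records), 1L)
  expect_equal(nrow(out_hi$records), 0L)
  expect_error(seg_params(threshold_method = "fixed"), "fixed_threshold")
})
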