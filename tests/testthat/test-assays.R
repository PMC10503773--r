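wst_plate <- function(samples, control, blanks = 2L) {
  rbind(
    data.frame(well_id = paste0("s", seq_len(nrow(samples))), condition = "S",
               role = "sample", A450 = samples[, 1], A690 = samples[, 2]),
    data.frame(well_id = paste0("c", seq_len(nrow(control))), condition = "ctrl",
               role = "control", A450 = control[, 1], A690 = control[, 2]),
    data.frame(well_id = paste0("b", seq_len(blanks)), condition = "blank",
               role = "blank", A450 = 0, A690 = 0))
}

test_that("WST-1 viability is blank- and control-normalised", {
  pl <- wst_plate(samples = cbind(1.7, 0.1), control = cbind(1.7, 0.1))
  v <- wst1_viability(pl)
  expect_equal(v$viability[v$role == "sample"], 100)
  pl2 <- wst_plate(samples = cbind(0.9, 0.1), control = cbind(1.7, 0.1))
  v2 <- wst1_viability(pl2)
  expect_equal(v2$viability[v2$role == "sample"], 50)
  # floored at zero, blanks NA
  pl3 <- wst_plate(samples = cbind(0.0, 0.2), control = cbind(1.7, 0.1))
  v3 <- wst1_viability(pl3)
  expect_equal(v3$viability[v3$role == "sample"], 0)
  expect_true(all(is.na(v3$viability[v3$role == "blank"])))
  # failure modes
  no_blank <- pl[pl$role != "blank", ]
  expect_error(wst1_viability(no_blank), "blank")
  dead <- wst_plate(samples = cbind(1, 0.1), control = cbind(0.05, 0.1))
  dead$A450[dead$role == "blank"] <- 0.2
  expect_error(wst1_viability(dead), "control signal")
})

test_that("Cmax is the highest concentration passing mean and test criteria", {
  mk <- function(concs, means, n = 15L, sd = 0) {
    set.seed(3)
    rows <- do.call(rbind, lapply(seq_along(concs), function(i)
      data.frame(concentration = concs[i], role = "sample",
                 viability = means[i] + rnorm(n, 0, sd))))
    rbind(rows, data.frame(concentration = NA, role = "control",
                           viability = 100 + rnorm(n, 0, sd)))
  }
  # noiseless rule application
  v <- mk(c(1, 5, 10, 50, 100), c(100, 98, 95, 60, 20))
  expect_equal(find_cmax(v), 10)
  # everything viable and statistically flat: Cmax is the top tested
  v2 <- mk(c(1, 5, 10), c(100, 99, 98))
  expect_equal(find_cmax(v2), 10)
  # nothing qualifies
  v3 <- mk(c(1, 5), c(40, 20))
  expect_error(find_cmax(v3), "no concentration")
  # monotone: adding a higher, fully viable concentration never lowers Cmax
  v4 <- rbind(v2, mk(20, 98)[1:15, ])
  expect_gte(find_cmax(v4), find_cmax(v2))
  # planted 50 %-loss dose-response: Cmax falls below the planted IC15
  concs <- c(1, 2, 5, 10, 20, 50)
  true_v <- 100 / (1 + (concs / 10)^1.5)   # crosses 85 % near 3.4
  ic15 <- 10 * (100 / 85 - 1)^(1 / 1.5)
  v5 <- mk(concs, true_v)
  expect_lte(find_cmax(v5), max(concs[concs <= ic15]))
})

test_that("the concentration series is Cmax, half and one fifth", {
  expect_equal(series_from_cmax(50), c(50, 25, 10))
  expect_equal(series_from_cmax(10), c(10, 5, 2))
  expect_equal(series_from_cmax(1), c(1, 0.5, 0.2))
  s <- series_from_cmax(7.3)
  expect_equal(s / s[1], c(1, 1 / 2, 1 / 5))
  expect_error(series_from_cmax(-1), "positive")
})

test_that("DHR123 fold changes are time-matched and recover planted kinetics", {
  lay <- plate_layout(c("control", "condA"), control = "control", n_blanks = 1L)
  tp <- c(0, 0.5, 1, 3, 5, 24)
  # planted 3x at 24 h only, noiseless
  eff <- list(condA = c(1, 1, 1, 1, 1, 3))
  pl <- simulate_assay_plate(lay, eff, noise_sd = 0, seed = 1,
                             assay = "dhr123", timepoints = tp)
  out <- dhr123_fold_change(pl)
  sa <- out$summary[out$summary$condition == "condA", ]
  expect_equal(sa$mean_fold[sa$time_h == 24], 3)
  expect_equal(sa$mean_fold[sa$time_h < 24], rep(1, 5))
  ctrl <- out$summary[out$summary$condition == "control", ]
  expect_equal(ctrl$mean_fold, rep(1, length(tp)))
  # planted monotone increase is recovered monotone (noisy)
  eff2 <- list(condA = c(1, 1.2, 1.5, 2, 2.6, 3.5))
  pl2 <- simulate_assay_plate(lay, eff2, noise_sd = 0.03, seed = 5,
                              assay = "dhr123", timepoints = tp)
  s2 <- dhr123_fold_change(pl2)$summary
  fc <- s2$mean_fold[s2$condition == "condA"][order(tp)]
  expect_true(all(diff(fc) > 0))
  expect_error(dhr123_fold_change(transform(pl, fluorescence = 0)), "zero control")
})

test_that("repair halftime interpolates the half-excess crossing", {
  # crossing exactly at the middle timepoint
  out <- repair_halftime(c(0.5, 10, 24), c(8, 4.65, 1.3), baseline = 1.3)
  expect_false(out$censored)
  expect_equal(out$halftime, 10)
  # flat series never reaches half-excess: censored
  flat <- repair_halftime(c(0.5, 1, 24), c(5, 5, 5), baseline = 1)
  expect_true(flat$censored)
  expect_true(is.na(flat$halftime))
  # no excess at all is an error
  expect_error(repair_halftime(c(1, 2, 3), c(1, 1, 1), baseline = 2), "excess")
  # exponential decay sampled at assay timepoints: within 15 % of ln2 / rate
  k <- 0.7
  tp <- c(0.5, 1, 1.5, 2, 24)
  means <- 1.3 + 6.7 * exp(-k * (tp - 0.5))
  out2 <- repair_halftime(tp, means, baseline = 1.3)
  expect_lt(abs(out2$halftime - (0.5 + log(2) / k)) / (log(2) / k), 0.15)
})
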