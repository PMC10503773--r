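test_that("zero planted cells give an empty truth table and a noise-only image", {
  p <- tiny_sim(n_cells = 0L)
  sf <- simulate_field(p, seed = 1)
  expect_equal(nrow(sf$truth), 0L)
  expect_equal(nrow(sf$foci), 0L)
  expect_lt(abs(mean(sf$field$dna) - p$background_level), 2)
  expect_lt(abs(sd(as.numeric(sf$field$dna)) - p$noise_sd), 3)
})

test_that("clean fields conserve the planted cell count with all cells selectable", {
  p <- sim_params(field_width = 700L, field_height = 700L, n_cells = 50L,
                  nucleus_radius_mean = 14, nucleus_radius_sd = 1.4,
                  clump_fraction = 0, edge_fraction = 0)
  sf <- simulate_field(p, seed = 3)
  expect_equal(nrow(sf$truth), 50L)
  expect_true(all(sf$truth$expected_qc == "selected"))
  expect_false(any(sf$truth$is_binucleated))
})

test_that("identical parameters and seed give bit-identical output", {
  p <- tiny_sim(foci_lambda = 3, pan_nuclear_fraction = 0.1)
  a <- simulate_field(p, seed = 99)
  b <- simulate_field(p, seed = 99)
  expect_identical(a$field$dna, b$field$dna)
  expect_identical(a$field$foci, b$field$foci)
  expect_identical(a$truth, b$truth)
  expect_identical(a$foci, b$foci)
  d <- simulate_field(p, seed = 100)
  expect_false(identical(a$field$dna, d$field$dna))
  pm <- sim_params(field_width = 512L, field_height = 512L, n_cells = 8L,
                   nucleus_radius_mean = 12, nucleus_radius_sd = 1.2,
                   binucleation_rate = 0.5, mn_prob = 0.5)
  m1 <- simulate_mn_field(pm, seed = 21)
  m2 <- simulate_mn_field(pm, seed = 21)
  expect_identical(m1$field$dna, m2$field$dna)
  expect_identical(m1$truth, m2$truth)
})

test_that("planted foci counts are Poisson distributed with the requested mean", {
  lambda <- 8
  # nuclei large enough that focus placement never truncates Poisson counts
  p <- sim_params(field_width = 700L, field_height = 700L, n_cells = 50L,
                  nucleus_radius_mean = 24, nucleus_radius_sd = 2,
                  foci_radius = 2, foci_lambda = lambda)
  counts <- integer(0)
  f <- 0L
  while (length(counts) < 10000L) {
    f <- f + 1L
    sf <- simulate_field(p, seed = 5000L + f, render = FALSE)
    counts <- c(counts, sf$truth$planted_foci)
  }
  counts <- counts[seq_len(10000L)]
  # law-of-large-numbers check on the mean
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / length(counts)))
  # chi-square goodness of fit against the Poisson oracle, alpha = 0.01
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, kmax + 1L)
  pr <- dpois(0:kmax, lambda)
  pr[kmax + 1L] <- pr[kmax + 1L] + stats::ppois(kmax, lambda, lower.tail = FALSE)
  # merge low-expectation tail bins
  exp_n <- pr * length(counts)
  keep <- exp_n >= 5
  obs2 <- c(obs[keep], sum(obs[!keep]))
  exp2 <- c(exp_n[keep], sum(exp_n[!keep]))
  x2 <- sum((obs2 - exp2)^2 / exp2)
  expect_lt(x2, stats::qchisq(0.99, df = length(obs2) - 1L))
})

test_that("planted foci lie strictly inside their nucleus mask", {
  p <- tiny_sim(foci_lambda = 6)
  sf <- simulate_field(p, seed = 12)
  lab <- segment_nuclei(sf$field, seg_params_for(p))$labels
  at <- lab[cbind(round(sf$foci$row), round(sf$foci$col))]
  expect_true(all(at > 0L))
})

test_that("binucleation and micronucleus probabilities control the planted truth", {
  p0 <- sim_params(field_width = 512L, field_height = 512L, n_cells = 8L,
                   nucleus_radius_mean = 12, nucleus_radius_sd = 1.2,
                   binucleation_rate = 0)
  expect_false(any(simulate_mn_field(p0, seed = 2)$truth$is_binucleated))

  p1 <- sim_params(field_width = 900L, field_height = 900L, n_cells = 25L,
                   nucleus_radius_mean = 15, nucleus_radius_sd = 1.5,
                   binucleation_rate = 1, mn_prob = 1,
                   mn_count_given_positive = c("1" = 1))
  s1 <- simulate_mn_field(p1, seed = 4)
  expect_true(all(s1$truth$is_binucleated))
  expect_true(all(s1$truth$planted_mn == 1L))

  # 25 percent binucleation over >= 3000 cells, within 3 binomial SEs
  pr <- sim_params(field_width = 1024L, field_height = 1024L, n_cells = 40L,
                   nucleus_radius_mean = 15, nucleus_radius_sd = 1.5,
                   binucleation_rate = 0.25)
  n_b <- 0L; n_c <- 0L; f <- 0L
  while (n_c < 3000L) {
    f <- f + 1L
    tr <- simulate_mn_field(pr, seed = 700L + f, render = FALSE)$truth
    n_b <- n_b + sum(tr$is_binucleated); n_c <- n_c + nrow(tr)
  }
  expect_lt(abs(n_b / n_c - 0.25), 3 * sqrt(0.25 * 0.75 / n_c))
  # micronuclei only in binucleated cells, one truth row per planted cell
  expect_true(all(tr$planted_mn[!tr$is_binucleated] == 0L))
})

test_that("assay-plate simulation plants recoverable effects", {
  lay <- plate_layout(c("control", "condA"), control = "control", n_blanks = 3L)
  # noiseless round trips
  pl <- simulate_assay_plate(lay, effect = c(condA = 1), noise_sd = 0, seed = 1)
  v <- wst1_viability(pl)
  expect_equal(unique(v$viability[v$role != "blank"]), 100)
  pl50 <- simulate_assay_plate(lay, effect = c(condA = 0.5), noise_sd = 0, seed = 1)
  v50 <- wst1_viability(pl50)
  expect_equal(unique(v50$viability[v50$condition == "condA"]), 50)
  # noisy recovery: planted 70 percent recovered within 3 SEs over 15 wells
  pl70 <- simulate_assay_plate(lay, effect = c(condA = 0.7), noise_sd = 0.05,
                               seed = 42)
  v70 <- wst1_viability(pl70)$viability
  va <- v70[pl70$condition == "condA" & pl70$role != "blank"]
  expect_lt(abs(mean(va) - 70), 3 * sd(va) / sqrt(length(va)))
  # layout validation
  lay_nb <- plate_layout("control", control = "control")
  expect_error(simulate_assay_plate(lay_nb, effect = c(), noise_sd = 0),
               "blank")
})

test_that("invalid generator parameters and overfull fields are rejected", {
  expect_error(sim_params(field_width = 0), "positive")
  expect_error(sim_params(eccentricity_max = 1), "eccentricity")
  expect_error(sim_params(clump_fraction = 1.5), "probability")
  # far more cells than fit: bounded attempts, achieved count reported
  p <- sim_params(field_width = 200L, field_height = 200L, n_cells = 200L,
                  nucleus_radius_mean = 12, nucleus_radius_sd = 1)
  expect_warning(sf <- simulate_field(p, seed = 1, render = FALSE), "placed")
  expect_lt(nrow(sf$truth), 200L)
  expect_gt(nrow(sf$truth), 0L)
})

test_that("fields and generator settings round-trip through TIFF and YAML", {
  dir <- withr::local_tempdir()
  p <- tiny_sim(foci_lambda = 2)
  sf <- simulate_field(p, seed = 8)
  write_sim_field(sf, dir)
  back <- read_field_tiff(dir, "P1", "A01", 1L)
  expect_identical(back$dna, sf$field$dna)
  expect_identical(back$foci, sf$field$foci)
  cfg <- file.path(dir, "sim.yaml")
  save_sim_params(p, cfg, seed = 8L)
  loaded <- load_sim_params(cfg)
  expect_equal(loaded$seed, 8L)
  expect_equal(unclass(loaded$params), unclass(p))
})
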