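# Shared fixtures: a compact generator geometry for fast unit tests, plus a
# hand-rolled disc painter so image-level tests do not depend on the
# generator under test.

tiny_sim <- function(...) {
  defaults <- list(field_width = 256L, field_height = 256L, n_cells = 12L,
                   nucleus_radius_mean = 12, nucleus_radius_sd = 1.2,
                   foci_radius = 2)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

paint_disc <- function(img, row0, col0, r, value) {
  for (i in max(1, floor(row0 - r)):min(nrow(img), ceiling(row0 + r)))
    for (j in max(1, floor(col0 - r)):min(ncol(img), ceiling(col0 + r)))
      if ((i - row0)^2 + (j - col0)^2 <= r^2) img[i, j] <- value
  img
}

# two-channel field with hand-placed nuclei and foci
manual_field <- function(n = 128L, nuclei, foci = NULL, bg = 200,
                         nuclear = 2000, peak = 1500, noise_sd = 0,
                         noise_seed = 1) {
  dna <- matrix(bg, n, n)
  foc <- matrix(bg, n, n)
  for (k in seq_len(nrow(nuclei)))
    dna <- paint_disc(dna, nuclei[k, 1], nuclei[k, 2], nuclei[k, 3], nuclear)
  if (!is.null(foci))
    for (k in seq_len(nrow(foci)))
      foc <- paint_disc(foc, foci[k, 1], foci[k, 2], foci[k, 3], bg + peak)
  if (noise_sd > 0) {
    set.seed(noise_seed)
    dna <- matrix(as.integer(round(dna + rnorm(n * n, 0, noise_sd))), n, n)
    foc <- matrix(as.integer(round(foc + rnorm(n * n, 0, noise_sd))), n, n)
  }
  field_image(dna, foc)
}

# match each truth cell to its nearest segmentation record
match_truth <- function(records, truth) {
  vapply(seq_len(nrow(truth)), function(i) {
    which.min((records$cy - truth$cy[i])^2 + (records$cx - truth$cx[i])^2)
  }, integer(1))
}
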