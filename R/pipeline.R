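#' Analyse one two-channel field: segmentation, artifact guard, foci counting
#'
#' Runs [segment_nuclei()], flags pan-nuclear nuclei among the selected ones,
#' detects foci in the remaining selected nuclei and fills per-nucleus
#' counts.  Excluded and flagged nuclei keep `foci_count = NA`.
#'
#' @param field a [field_image()].
#' @param seg a [seg_params()] object.
#' @param fpar a [foci_params()] object.
#' @return A list: `records` (nucleus records with `field_index` attached),
#'   `foci` (focus records), `labels` (label matrix).
#' @export
analyze_field <- function(field, seg = seg_params(), fpar = foci_params()) {
  sg <- segment_nuclei(field, seg)
  rec <- sg$records
  if (nrow(rec) > 0L) {
    sel <- rec$nucleus_id[rec$qc_status == "selected"]
    if (length(sel)) {
      flags <- flag_pan_nuclear(field, sg$labels, fpar, nucleus_ids = sel)
      rec$pan_nuclear_flag[match(as.integer(names(flags)), rec$nucleus_id)] <- flags
    }
    count_ids <- rec$nucleus_id[rec$qc_status == "selected" & !rec$pan_nuclear_flag]
    fr <- if (length(count_ids))
      detect_foci(field, sg$labels, fpar, nucleus_ids = count_ids)
    else data.frame(nucleus_id = integer(0), row = integer(0),
                    col = integer(0), peak_intensity = numeric(0),
                    spot_area = numeric(0))
    rec <- count_foci_per_nucleus(rec, fr)
  } else {
    fr <- data.frame(nucleus_id = integer(0), row = integer(0),
                     col = integer(0), peak_intensity = numeric(0),
                     spot_area = numeric(0))
  }
  rec$field_index <- field$field_index
  list(records = rec, foci = fr, labels = sg$labels)
}

#' Analyse one micronucleus-assay field
#'
#' Segments the DNA channel, pairs selected nuclei into binucleated cells and
#' counts micronuclei per pair.
#'
#' @inheritParams analyze_field
#' @param mpar an [mn_params()] object.
#' @return A list: `records`, `pairs` (binucleate records with `mn_count`),
#'   `labels`.
#' @export
analyze_mn_field <- function(field, seg = seg_params(), mpar = mn_params()) {
  sg <- segment_nuclei(field, seg)
  pairs <- pair_binucleates(sg$records, mpar)
  pairs <- detect_micronuclei(sg$records, pairs, mpar)
  list(records = sg$records, pairs = pairs, labels = sg$labels)
}

field_seed_table <- function(seed, n_wells, max_fields) {
  set.seed(seed)
  matrix(sample.int(2^31 - 2, n_wells * max_fields), n_wells, max_fields)
}

#' Simulate and score one condition of the foci assay
#'
#' End-to-end parameter recovery: fields are generated with per-nucleus
#' Poisson focus counts at mean `lambda`, analysed by the full
#' segmentation / detection / counting pipeline, and aggregated exactly as
#' the assay prescribes (first `cells_per_well` selected nuclei per well,
#' `n_wells` replicate wells pooled over experiments).
#'
#' @param lambda planted mean foci per nucleus.
#' @param n_wells number of replicate wells (5 wells x 3 experiments = 15).
#' @param cells_per_well nuclei analysed per well.
#' @param sim generator settings; defaults to [sim_params()] with
#'   `foci_lambda = lambda`.
#' @param seed seed controlling the whole condition.
#' @return A list: `mean`, `sd` (over the well statistics), `well_values`,
#'   `n_analyzed` (total nuclei analysed).
#' @export
score_foci_condition <- function(lambda, n_wells = 15L, cells_per_well = 500L,
                                 sim = NULL, seed = 1L) {
  if (is.null(sim)) sim <- sim_params(foci_lambda = lambda)
  seg <- seg_params_for(sim)
  fpar <- foci_params_for(sim)
  max_fields <- ceiling(cells_per_well / max(1L, sim$n_cells)) + 3L
  seeds <- field_seed_table(seed, n_wells, max_fields)
  wells <- vector("list", n_wells)
  for (w in seq_len(n_wells)) {
    recs <- list(); got <- 0L; f <- 0L
    while (got < cells_per_well && f < max_fields) {
      f <- f + 1L
      sf <- simulate_field(sim, seed = seeds[w, f], well_id = sprintf("w%02d", w),
                           field_index = f)
      an <- analyze_field(sf$field, seg, fpar)
      recs[[f]] <- an$records
      got <- got + sum(an$records$qc_status == "selected" &
                         !an$records$pan_nuclear_flag)
    }
    wells[[w]] <- well_mean_foci(do.call(rbind, recs), cap = cells_per_well,
                                 well_id = sprintf("w%02d", w))
  }
  vals <- vapply(wells, `[[`, numeric(1), "statistic")
  n_tot <- sum(vapply(wells, `[[`, numeric(1), "n_analyzed"))
  cs <- condition_summary(vals, n_expected = n_wells)
  list(mean = cs$mean, sd = cs$sd, well_values = vals, n_analyzed = n_tot)
}

#' Simulate and score one condition of the micronucleus assay
#'
#' Generates micronucleus-assay fields until about `cells_per_well` cells per
#' well have been analysed, runs segmentation, binucleate pairing and
#' micronucleus scoring, and reports the detected binucleated fraction and
#' the micronucleus frequency per well and pooled.
#'
#' @param sim generator settings ([sim_params()]); `binucleation_rate` and
#'   `mn_prob` define the planted truth.
#' @param n_wells number of replicate wells.
#' @param cells_per_well cells (binucleate pairs count as one cell) analysed
#'   per well.
#' @param seed seed controlling the whole condition.
#' @return A list: `bn_fraction` (detected binucleated fraction, percent,
#'   pooled over wells), `mn_mean`, `mn_sd` (well-level micronucleus
#'   frequency), `well_mn`, `n_binucleated`, `n_cells`.
#' @export
score_mn_condition <- function(sim = sim_params(), n_wells = 15L,
                               cells_per_well = 1000L, seed = 1L) {
  seg <- seg_params_for(sim)
  mpar <- mn_params()
  max_fields <- ceiling(cells_per_well / max(1L, sim$n_cells)) + 5L
  seeds <- field_seed_table(seed, n_wells, max_fields)
  well_mn <- numeric(n_wells)
  tot_pairs <- 0L; tot_cells <- 0L; tot_mnp <- 0L
  for (w in seq_len(n_wells)) {
    n_pairs <- 0L; n_cells <- 0L; n_mn_pos <- 0L; f <- 0L
    while (n_cells < cells_per_well && f < max_fields) {
      f <- f + 1L
      sf <- simulate_mn_field(sim, seed = seeds[w, f],
                              well_id = sprintf("w%02d", w), field_index = f)
      an <- analyze_mn_field(sf$field, seg, mpar)
      np <- nrow(an$pairs)
      nsel <- sum(an$records$qc_status == "selected")
      n_pairs <- n_pairs + np
      n_cells <- n_cells + (nsel - 2L * np) + np
      n_mn_pos <- n_mn_pos + if (np) sum(an$pairs$micronucleated) else 0L
    }
    well_mn[w] <- if (n_pairs > 0L) 100 * n_mn_pos / n_pairs else NA_real_
    tot_pairs <- tot_pairs + n_pairs
    tot_cells <- tot_cells + n_cells
    tot_mnp <- tot_mnp + n_mn_pos
  }
  list(bn_fraction = 100 * tot_pairs / tot_cells,
       mn_mean = mean(well_mn, na.rm = TRUE),
       mn_sd = sd(well_mn, na.rm = TRUE),
       mn_pooled = if (tot_pairs) 100 * tot_mnp / tot_pairs else NA_real_,
       well_mn = well_mn,
       n_binucleated = tot_pairs, n_cells = tot_cells)
}
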