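#' Micronucleus-assay scoring parameters
#'
#' The micronucleus size window defaults to `[1/256, 1/9]` of the mean
#' main-nucleus area of the pair, i.e. a diameter between 1/16 and 1/3 of the
#' main nucleus — the standard scoring convention of the cytokinesis-block
#' assay.  Pairing accepts two QC-acceptable nuclei whose centroid gap is at
#' most `max_pair_gap` mean equivalent diameters and whose area ratio lies in
#' `area_ratio_range`; fused pairs (touching masks) never reach pairing
#' because they segment as a single over-size component and are rejected,
#' mirroring instrument rejection of overlapping binucleates.
#'
#' @param max_pair_gap maximum centroid gap between the two nuclei of a pair,
#'   as a multiple of the mean equivalent-circle diameter of candidate nuclei.
#' @param area_ratio_range admissible area ratio (larger/either order) of the
#'   two main nuclei; symmetric around 1.
#' @param mn_area_range micronucleus area window as fractions of the mean
#'   main-nucleus area of its pair.
#' @param mn_max_distance maximum gap (pixels) between a micronucleus centroid
#'   and the boundary of the nearer main nucleus of the pair.
#' @return An object of class `mn_params`.
#' @export
mn_params <- function(max_pair_gap = 2.5,
                      area_ratio_range = c(0.5, 2),
                      mn_area_range = c(1 / 256, 1 / 9),
                      mn_max_distance = 20) {
  stopifnot(max_pair_gap > 0, length(area_ratio_range) == 2L,
            length(mn_area_range) == 2L, mn_max_distance > 0)
  if (area_ratio_range[1L] > 1 || area_ratio_range[2L] < 1 ||
      abs(area_ratio_range[1L] * area_ratio_range[2L] - 1) > 1e-8)
    stop("area_ratio_range must be symmetric around 1 (e.g. c(0.5, 2))")
  if (mn_area_range[1L] <= 0 || mn_area_range[2L] >= 1 ||
      mn_area_range[1L] >= mn_area_range[2L])
    stop("mn_area_range must be an increasing interval inside (0, 1)")
  structure(list(max_pair_gap = max_pair_gap,
                 area_ratio_range = area_ratio_range,
                 mn_area_range = mn_area_range,
                 mn_max_distance = mn_max_distance),
            class = "mn_params")
}

#' Pair nuclei into binucleated cells
#'
#' Greedy nearest-neighbour pairing over QC-selected nuclei: candidate pairs
#' are those with centroid gap at most `max_pair_gap` times the mean
#' equivalent diameter of the candidates and area ratio inside
#' `area_ratio_range`; pairs are accepted in order of increasing gap (ties by
#' smaller `nucleus_id`), each nucleus joining at most one pair.  The result
#' is deterministic given the records.
#'
#' @param records segmentation records from [segment_nuclei()].
#' @param params an [mn_params()] object.
#' @return Data frame of binucleate records: `binucleate_id`, `nucleus_id1`,
#'   `nucleus_id2`, `gap` (pixels), `mean_area`, and `mn_count` initialised
#'   to `NA` until [detect_micronuclei()] fills it.
#' @export
pair_binucleates <- function(records, params = mn_params()) {
  empty <- data.frame(binucleate_id = integer(0), nucleus_id1 = integer(0),
                      nucleus_id2 = integer(0), gap = numeric(0),
                      mean_area = numeric(0), mn_count = integer(0),
                      micronucleated = logical(0))
  cand <- records[records$qc_status == "selected", , drop = FALSE]
  if (nrow(cand) < 2L) return(empty)
  eqd <- 2 * sqrt(cand$area / pi)
  max_gap <- params$max_pair_gap * mean(eqd)
  d <- as.matrix(dist(cbind(cand$cy, cand$cx)))
  ratio <- outer(cand$area, cand$area, "/")
  ok <- d <= max_gap & ratio >= params$area_ratio_range[1L] &
    ratio <= params$area_ratio_range[2L]
  ok[lower.tri(ok, diag = TRUE)] <- FALSE
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  gaps <- d[idx]
  o <- order(gaps, cand$nucleus_id[idx[, 1L]], cand$nucleus_id[idx[, 2L]])
  idx <- idx[o, , drop = FALSE]; gaps <- gaps[o]
  used <- logical(nrow(cand))
  out <- list()
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      binucleate_id = length(out) + 1L,
      nucleus_id1 = cand$nucleus_id[i], nucleus_id2 = cand$nucleus_id[j],
      gap = gaps[k], mean_area = (cand$area[i] + cand$area[j]) / 2,
      mn_count = NA_integer_, micronucleated = NA)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Count micronuclei for each binucleated cell
#'
#' A DNA-positive component counts as a micronucleus of a pair when it is not
#' itself a member of any pair, its area lies within `mn_area_range` times
#' the mean main-nucleus area of the pair, and its centroid is within
#' `mn_max_distance` pixels of the boundary of the nearer main nucleus
#' (components touching a main nucleus merge with it at segmentation and so
#' are never candidates).  Each component is credited to the nearest
#' qualifying pair.
#'
#' @param records all segmentation records of the field (small components that
#'   fail the nucleus size QC are the micronucleus candidates).
#' @param pairs output of [pair_binucleates()].
#' @param params an [mn_params()] object.
#' @return `pairs` with `mn_count` and `micronucleated` filled.
#' @export
detect_micronuclei <- function(records, pairs, params = mn_params()) {
  if (nrow(pairs) == 0L) return(pairs)
  pairs$mn_count <- 0L
  paired_ids <- c(pairs$nucleus_id1, pairs$nucleus_id2)
  cand <- records[!(records$nucleus_id %in% paired_ids) &
                    !records$touches_edge, , drop = FALSE]
  if (nrow(cand) > 0L) {
    rec_by_id <- records[match(paired_ids, records$nucleus_id), ]
    n1 <- records[match(pairs$nucleus_id1, records$nucleus_id), ]
    n2 <- records[match(pairs$nucleus_id2, records$nucleus_id), ]
    for (k in seq_len(nrow(cand))) {
      lo <- params$mn_area_range[1L] * pairs$mean_area
      hi <- params$mn_area_range[2L] * pairs$mean_area
      size_ok <- cand$area[k] >= lo & cand$area[k] <= hi
      # gap to the nearer main-nucleus boundary (equivalent-circle radius)
      g1 <- sqrt((cand$cy[k] - n1$cy)^2 + (cand$cx[k] - n1$cx)^2) -
        sqrt(n1$area / pi)
      g2 <- sqrt((cand$cy[k] - n2$cy)^2 + (cand$cx[k] - n2$cx)^2) -
        sqrt(n2$area / pi)
      gp <- pmin(g1, g2)
      qual <- which(size_ok & gp <= params$mn_max_distance)
      if (length(qual)) {
        best <- qual[which.min(gp[qual])]
        pairs$mn_count[best] <- pairs$mn_count[best] + 1L
      }
    }
  }
  pairs$micronucleated <- pairs$mn_count >= 1L
  pairs
}

#' Micronucleus frequency among binucleated cells
#'
#' @param pairs binucleate records with `mn_count` filled.
#' @return A list: `n_binucleated`, `n_micronucleated` and `mn_frequency`
#'   (percent of binucleated cells carrying at least one micronucleus).
#' @export
mn_frequency <- function(pairs) {
  if (nrow(pairs) == 0L)
    stop("micronucleus frequency is undefined when no binucleated cells were scored")
  if (any(is.na(pairs$mn_count)))
    stop("mn_count not filled; run detect_micronuclei() first")
  n_b <- nrow(pairs)
  n_m <- sum(pairs$mn_count >= 1L)
  list(n_binucleated = n_b, n_micronucleated = n_m,
       mn_frequency = 100 * n_m / n_b)
}
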