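#' Focus detection parameters
#'
#' The detector is deliberately local and robust: the decision statistic for
#' each candidate peak is the white top-hat response compared against
#' `median + k_mad * MAD` of the top-hat signal inside that same nucleus, so
#' the defaults carry across intensity regimes without operator re-tuning.
#' `mad()` uses the usual 1.4826 normal-consistency constant.
#'
#' @param foci_radius expected focus radius in pixels; only used to derive
#'   the defaults below.
#' @param tophat_radius radius of the structuring disc of the white top-hat
#'   (pixels); must exceed the focus radius so foci survive the transform.
#' @param k_mad multiplier of the per-nucleus MAD in the detection threshold.
#' @param min_spot_area,max_spot_area admissible connected bright-spot area
#'   (pixels squared).
#' @param min_separation peaks closer than this (pixels) are merged, keeping
#'   the brighter one.
#' @param response_sigma Gaussian smoothing (pixels) of the top-hat response
#'   before peak finding; localises each peak near its focus centre so that
#'   camera noise neither splits one focus into twin peaks nor pushes the
#'   peaks of two adjacent foci inside the merge distance.  0 disables.
#' @param pan_nuclear_quantile_ratio a nucleus whose 10th-percentile
#'   immunostain signal exceeds this multiple of the background median is
#'   flagged pan-nuclear (see [flag_pan_nuclear()]).
#' @return An object of class `foci_params`.
#' @export
foci_params <- function(foci_radius = 3,
                        tophat_radius = 2 * foci_radius + 1,
                        k_mad = 5,
                        min_spot_area = 2,
                        max_spot_area = 80,
                        min_separation = 2 * foci_radius,
                        response_sigma = 1,
                        pan_nuclear_quantile_ratio = 3) {
  stopifnot(tophat_radius > 0, k_mad > 0, min_spot_area > 0,
            min_separation > 0, response_sigma >= 0,
            pan_nuclear_quantile_ratio > 0)
  if (min_spot_area >= max_spot_area) stop("min_spot_area must be < max_spot_area")
  structure(list(tophat_radius = tophat_radius, k_mad = k_mad,
                 min_spot_area = min_spot_area, max_spot_area = max_spot_area,
                 min_separation = min_separation,
                 response_sigma = response_sigma,
                 pan_nuclear_quantile_ratio = pan_nuclear_quantile_ratio),
            class = "foci_params")
}

#' @rdname foci_params
#' @param sim a [sim_params()] object; the detector geometry follows its
#'   planted focus radius.
#' @param ... overrides passed on to [foci_params()].
#' @export
foci_params_for <- function(sim, ...) {
  foci_params(foci_radius = sim$foci_radius, ...)
}

odd_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
}

#' Detect bright sub-nuclear foci within selected nuclei
#'
#' The immunostain channel is passed through a white top-hat (structuring disc
#' of radius `tophat_radius`) which removes structures larger than a focus;
#' local maxima of the response are candidate peaks.  A peak survives if its
#' response exceeds `median + k_mad * MAD` of the top-hat signal inside its
#' nucleus, if it is not within `min_separation` of a brighter surviving peak,
#' and if the connected supra-threshold region beneath it has an area within
#' the spot-area window.
#'
#' @param field a [field_image()].
#' @param labels nucleus label matrix from [segment_nuclei()].
#' @param params a [foci_params()] object.
#' @param nucleus_ids which labels to search (default: all labels present);
#'   restrict to selected, non-pan-nuclear nuclei for assay use.
#' @return Data frame of focus records: `nucleus_id`, position (`row`,
#'   `col`), `peak_intensity` (raw immunostain counts) and `spot_area`.
#' @export
detect_foci <- function(field, labels, params = foci_params(),
                        nucleus_ids = NULL) {
  foc <- field$foci
  if (is.null(nucleus_ids)) nucleus_ids <- setdiff(unique(as.integer(labels)), 0L)
  if (length(nucleus_ids) == 0L || !any(labels > 0L))
    stop("no nuclei to search: empty nucleus mask")
  empty <- data.frame(nucleus_id = integer(0), row = integer(0),
                      col = integer(0), peak_intensity = numeric(0),
                      spot_area = numeric(0))

  th <- EBImage::whiteTopHat(foc / 65535, odd_brush(params$tophat_radius)) * 65535
  # peaks are located on a lightly smoothed copy of the response (stable,
  # centred positions); amplitudes, thresholds and spot geometry stay on the
  # raw response
  th_pk <- if (params$response_sigma > 0)
    EBImage::gblur(th, params$response_sigma) else th
  # per-nucleus robust threshold on the top-hat response
  inb <- labels > 0L & matrix(labels %in% nucleus_ids, nrow(labels), ncol(labels))
  lab_in <- labels[inb]
  th_in <- th[inb]
  grp <- split(th_in, lab_in)
  med <- vapply(grp, median, numeric(1))
  md <- vapply(grp, mad, numeric(1))
  thr <- med + params$k_mad * md
  thr_of <- function(l) thr[as.character(l)]

  # local maxima of the top-hat response; the window is half the merge
  # distance (about one focus radius) so a bright focus cannot shadow a
  # neighbour across the inter-focus gap, and the greedy merge below owns
  # the min_separation rule
  dil <- EBImage::dilate(th_pk, odd_brush(max(1, floor(params$min_separation / 2))))
  cand <- which(th_pk >= dil & inb & th > 0)
  if (length(cand) == 0L) return(empty)
  ci <- (cand - 1L) %% nrow(th) + 1L
  cj <- (cand - 1L) %/% nrow(th) + 1L
  cl <- labels[cand]
  cv <- th[cand]
  ok <- cv > thr_of(cl)
  if (!any(ok)) return(empty)
  ci <- ci[ok]; cj <- cj[ok]; cl <- cl[ok]; cv <- cv[ok]

  # greedy merge: brightest first, drop peaks within min_separation of a keeper
  o <- order(-cv, ci, cj)
  ci <- ci[o]; cj <- cj[o]; cl <- cl[o]; cv <- cv[o]
  keep <- logical(length(cv))
  for (k in seq_along(cv)) {
    if (k == 1L) { keep[1L] <- TRUE; next }
    kept <- which(keep)
    keep[k] <- all((ci[kept] - ci[k])^2 + (cj[kept] - cj[k])^2 >=
                     params$min_separation^2)
  }
  ci <- ci[keep]; cj <- cj[keep]; cl <- cl[keep]

  # connected supra-threshold spot beneath each surviving peak
  thr_img <- matrix(0, nrow(th), ncol(th))
  thr_img[inb] <- thr_of(lab_in)
  spot_mask <- inb & th > thr_img
  spots <- EBImage::bwlabel(spot_mask)
  spots <- matrix(as.integer(round(spots)), nrow(th), ncol(th))
  spot_area <- tabulate(spots[spots > 0L])
  sid <- spots[cbind(ci, cj)]
  a <- ifelse(sid > 0L, spot_area[pmax(sid, 1L)], 0)
  good <- sid > 0L & a >= params$min_spot_area & a <= params$max_spot_area
  data.frame(nucleus_id = cl[good], row = ci[good], col = cj[good],
             peak_intensity = foc[cbind(ci[good], cj[good])],
             spot_area = a[good])
}

#' Flag pan-nuclear staining artifacts
#'
#' A nucleus whose immunostain signal is elevated across essentially its whole
#' area cannot be focus-counted: its 10th-percentile in-nucleus signal is
#' compared with the median signal outside all nuclei, and the nucleus is
#' flagged when the ratio exceeds `pan_nuclear_quantile_ratio`.  Flagged
#' nuclei keep `foci_count = NA` and are dropped from per-well means.
#'
#' @inheritParams detect_foci
#' @return Logical vector, one entry per `nucleus_ids` (named by id).
#' @export
flag_pan_nuclear <- function(field, labels, params = foci_params(),
                             nucleus_ids = NULL) {
  foc <- field$foci
  if (is.null(nucleus_ids)) nucleus_ids <- setdiff(unique(as.integer(labels)), 0L)
  bg <- median(foc[labels == 0L])
  if (!is.finite(bg) || bg <= 0) bg <- 1
  idx <- which(labels > 0L)
  grp <- split(foc[idx], labels[idx])
  q10 <- vapply(as.character(nucleus_ids), function(l)
    quantile(grp[[l]], 0.1, names = FALSE), numeric(1))
  flags <- q10 / bg > params$pan_nuclear_quantile_ratio
  names(flags) <- nucleus_ids
  flags
}

#' Fill per-nucleus focus counts
#'
#' `foci_count` becomes the number of focus records per selected, unflagged
#' nucleus (0 when none were detected there); excluded or pan-nuclear-flagged
#' nuclei keep `foci_count = NA`.
#'
#' @param records segmentation records (with `qc_status` and
#'   `pan_nuclear_flag`).
#' @param focus_records output of [detect_foci()].
#' @return `records` with `foci_count` filled.
#' @export
count_foci_per_nucleus <- function(records, focus_records) {
  counts <- table(factor(focus_records$nucleus_id, levels = records$nucleus_id))
  eligible <- records$qc_status == "selected" & !records$pan_nuclear_flag
  records$foci_count <- ifelse(eligible, as.integer(counts), NA_integer_)
  records
}
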