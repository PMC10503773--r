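#' Nuclei segmentation parameters
#'
#' QC defaults follow the geometry of the nuclei being imaged: the size window
#' is `[0.3, 2.2]` times the area of the ideal disc of radius
#' `nucleus_radius`, which keeps fragmented nuclei (too small) and fused
#' clumps (too large) out of the analysis, and `min_circularity = 0.8` rejects
#' elongated or peanut-shaped objects.
#'
#' @param nucleus_radius expected equivalent-circle nucleus radius in pixels;
#'   only used to derive the default area window.
#' @param smooth_sigma Gaussian smoothing sigma (pixels) applied to the DNA
#'   channel before thresholding; geometry is measured on the binary mask.
#' @param threshold_method `"otsu"` (default) or `"fixed"`; the fixed
#'   threshold mirrors operator-set thresholds on HCS instruments.
#' @param fixed_threshold threshold in counts, used iff
#'   `threshold_method = "fixed"`.
#' @param min_area,max_area nucleus area window in pixels squared.
#' @param min_circularity minimum `4 * pi * area / perimeter^2` (clamped to 1).
#' @param connectivity pixel connectivity for component labelling, 4 or 8.
#' @return An object of class `seg_params`.
#' @seealso [seg_params_for()] to derive the parameters from generator
#'   settings.
#' @export
seg_params <- function(nucleus_radius = 30,
                       smooth_sigma = 2,
                       threshold_method = c("otsu", "fixed"),
                       fixed_threshold = NULL,
                       min_area = 0.3 * pi * nucleus_radius^2,
                       max_area = 2.2 * pi * nucleus_radius^2,
                       min_circularity = 0.8,
                       connectivity = 8L) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed" &&
      (is.null(fixed_threshold) || fixed_threshold <= 0))
    stop("fixed_threshold must be a positive count when threshold_method = 'fixed'")
  if (min_area >= max_area) stop("min_area must be < max_area")
  if (min_circularity <= 0 || min_circularity > 1)
    stop("min_circularity must be in (0, 1]")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(smooth_sigma = smooth_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 connectivity = as.integer(connectivity)),
            class = "seg_params")
}

#' @rdname seg_params
#' @param sim a [sim_params()] object whose nuclear geometry the segmentation
#'   defaults should match.
#' @param ... overrides passed on to [seg_params()].
#' @export
seg_params_for <- function(sim, ...) {
  seg_params(nucleus_radius = sim$nucleus_radius_mean, ...)
}

#' Circularity of a closed shape
#'
#' `4 * pi * area / perimeter^2`: 1 for an ideal circle, `pi / 4` for a
#' square, smaller for elongated shapes.  Digitised perimeters can slightly
#' overshoot the ideal, so the value is clamped at 1.
#'
#' @param area area in pixels squared (`> 0`).
#' @param perimeter perimeter in pixels (`> 0`).
#' @return Circularity in `(0, 1]`; vectorised.
#' @examples
#' circularity(pi * 10^2, 2 * pi * 10)  # 1
#' circularity(4, 8)                    # square: pi / 4
#' @export
circularity <- function(area, perimeter) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  pmin(1, 4 * pi * area / perimeter^2)
}

## Perimeter of a connected pixel set by Moore-neighbour contour tracing:
## chain length with unit steps for axial moves and sqrt(2) for diagonal
## moves, scaled by 0.95 to correct the systematic staircase overshoot of
## digitised smooth contours (calibrated so a digital disc measures 2*pi*r).
## `pix` is a 2-column (row, col) matrix of one component's pixels.
mask_perimeter <- function(pix) {
  np <- nrow(pix)
  if (np == 0L) return(0)
  if (np <= 2L) return(np + 1)          # degenerate 1-2 px objects
  i0 <- min(pix[, 1L]) - 2L; j0 <- min(pix[, 2L]) - 2L
  h <- max(pix[, 1L]) - i0 + 2L; w <- max(pix[, 2L]) - j0 + 2L
  m <- matrix(FALSE, h, w)
  m[cbind(pix[, 1L] - i0, pix[, 2L] - j0)] <- TRUE
  # start: topmost-leftmost pixel, entered from the west
  start <- which(m, arr.ind = TRUE)
  start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
  # Moore neighbourhood, clockwise from west
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L), ncol = 2L, byrow = TRUE)
  steplen <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  cur <- start; back <- 0L; total <- 0; first_dir <- NA_integer_
  max_steps <- 4L * (h * w)
  for (s in seq_len(max_steps)) {
    hit <- 0L
    for (k in 0:7) {
      d <- (back + k) %% 8L + 1L
      ci <- cur[1L] + nb[d, 1L]; cj <- cur[2L] + nb[d, 2L]
      if (m[ci, cj]) { hit <- d; break }
    }
    if (hit == 0L) return(4)           # isolated pixel cluster fallback
    total <- total + steplen[hit]
    cur <- c(cur[1L] + nb[hit, 1L], cur[2L] + nb[hit, 2L])
    # next scan starts just past the direction pointing back where we came from
    back <- (hit + 4L) %% 8L
    if (is.na(first_dir)) first_dir <- hit
    else if (cur[1L] == start[1L] && cur[2L] == start[2L]) break
  }
  0.95 * total
}

## connected-component labelling; EBImage's bwlabel is 4-connected, so the
## 8-connected variant (the default here) merges components that touch only
## diagonally with a small union-find pass over the diagonal adjacencies
label_mask <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  k <- max(lab)
  if (connectivity == 4L || k == 0L) return(lab)
  n <- nrow(lab); m <- ncol(lab)
  a1 <- lab[-n, -m]; b1 <- lab[-1L, -1L]   # (i, j) vs (i+1, j+1)
  a2 <- lab[-1L, -m]; b2 <- lab[-n, -1L]   # (i+1, j) vs (i, j+1)
  s1 <- a1 > 0L & b1 > 0L & a1 != b1
  s2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (p in seq_len(nrow(pairs))) {
    ra <- find(pairs[p, 1L]); rb <- find(pairs[p, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Segment nuclei from the DNA channel and apply QC selection rules
#'
#' Gaussian smoothing, global thresholding (Otsu by default, or an
#' operator-fixed value), hole filling and connected-component labelling,
#' followed by per-nucleus geometry (area, perimeter by contour tracing,
#' circularity, centroid, mean DNA intensity) measured on the binary mask and
#' QC assignment by [qc_filter()].
#'
#' A uniform (blank) image yields zero records rather than an error.
#'
#' @param field a [field_image()] (or a plain integer matrix taken as the DNA
#'   channel).
#' @param params a [seg_params()] object.
#' @return A list with
#'   \describe{
#'     \item{labels}{integer label matrix (0 = background),}
#'     \item{records}{data frame with one row per component: `nucleus_id`,
#'       centroid (`cy`, `cx`), `area`, `perimeter`, `circularity`,
#'       `mean_dna_intensity`, `touches_edge`, `qc_status`,
#'       `pan_nuclear_flag` (initialised `FALSE`), `foci_count` (`NA` until
#'       counted), `binucleate_id` and `mn_count` (`NA` until the
#'       micronucleus-assay scoring fills them).}
#'   }
#' @export
segment_nuclei <- function(field, params = seg_params()) {
  dna <- if (inherits(field, "field_image")) field$dna else field
  if (!is.matrix(dna) || length(dna) == 0L) stop("DNA channel must be a non-empty matrix")
  img <- dna / 65535
  sm <- if (params$smooth_sigma > 0) EBImage::gblur(img, params$smooth_sigma) else img
  empty <- list(labels = matrix(0L, nrow(dna), ncol(dna)),
                records = empty_records())
  if (params$threshold_method == "otsu") {
    if (diff(range(sm)) < 1e-9) return(empty)  # uniform image: nothing to segment
    thr <- EBImage::otsu(sm, range = range(sm), levels = 4096L)
  } else {
    thr <- params$fixed_threshold / 65535
  }
  mask <- sm > thr
  if (!any(mask) || all(mask)) return(empty)
  mask <- EBImage::fillHull(mask)
  labels <- label_mask(mask, params$connectivity)
  nlab <- max(labels)
  if (nlab == 0L) return(empty)

  idx <- which(labels > 0L)
  lab <- labels[idx]
  ii <- (idx - 1L) %% nrow(labels) + 1L
  jj <- (idx - 1L) %/% nrow(labels) + 1L
  area <- tabulate(lab, nlab)
  cy <- rowsum(ii, lab)[, 1L] / area
  cx <- rowsum(jj, lab)[, 1L] / area
  meandna <- rowsum(as.numeric(dna[idx]), lab)[, 1L] / area
  edge <- ii == 1L | ii == nrow(labels) | jj == 1L | jj == ncol(labels)
  touches <- rowsum(as.integer(edge), lab)[, 1L] > 0L
  per <- vapply(seq_len(nlab), function(l) {
    sel <- lab == l
    mask_perimeter(cbind(ii[sel], jj[sel]))
  }, numeric(1))

  records <- data.frame(
    nucleus_id = seq_len(nlab),
    cy = cy, cx = cx, area = as.numeric(area), perimeter = per,
    circularity = circularity(as.numeric(area), per),
    mean_dna_intensity = meandna,
    touches_edge = touches,
    qc_status = NA_character_,
    pan_nuclear_flag = FALSE,
    foci_count = NA_integer_,
    binucleate_id = NA_integer_,
    mn_count = NA_integer_,
    stringsAsFactors = FALSE)
  records <- qc_filter(records, params, dim(dna))
  list(labels = labels, records = records)
}

empty_records <- function() {
  data.frame(nucleus_id = integer(0), cy = numeric(0), cx = numeric(0),
             area = numeric(0), perimeter = numeric(0),
             circularity = numeric(0), mean_dna_intensity = numeric(0),
             touches_edge = logical(0), qc_status = character(0),
             pan_nuclear_flag = logical(0), foci_count = integer(0),
             binucleate_id = integer(0), mn_count = integer(0),
             stringsAsFactors = FALSE)
}

#' Assign QC status to segmented nuclei
#'
#' Exclusion precedence is border, then size, then circularity: a nucleus with
#' any pixel on the first or last row or column is `excluded_border`; then the
#' area window is applied (`excluded_size`), then the circularity floor
#' (`excluded_circularity`).  Everything else is `selected`.
#'
#' @param records segmentation records carrying `touches_edge`, `area` and
#'   `circularity`.
#' @param params a [seg_params()] object.
#' @param image_shape ignored (the border test is precomputed in
#'   `touches_edge`); kept so callers can state the field size explicitly.
#' @return `records` with `qc_status` filled in.
#' @export
qc_filter <- function(records, params = seg_params(), image_shape = NULL) {
  st <- rep("selected", nrow(records))
  st[records$circularity < params$min_circularity] <- "excluded_circularity"
  st[records$area < params$min_area | records$area > params$max_area] <- "excluded_size"
  st[records$touches_edge] <- "excluded_border"
  records$qc_status <- st
  records
}
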