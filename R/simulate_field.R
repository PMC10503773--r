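## Synthetic two-channel field generator.
##
## The generator draws all stochastic ground truth (cell geometry, placement,
## planted foci / micronuclei) *before* rendering and noise, so the truth
## table produced with render = FALSE is identical to the one produced with
## render = TRUE under the same seed.

#' @describeIn simulate_field two-channel image container; plain list with
#'   integer matrices `dna` and `foci` (rows = y, columns = x, 1-based R
#'   indexing) plus plate/well/field provenance.
#' @param dna,foci integer intensity matrices of identical dimensions.
#' @export
field_image <- function(dna, foci, plate_id = "P1", well_id = "A01",
                        field_index = 1L, experiment_index = 1L) {
  if (!identical(dim(dna), dim(foci)))
    stop("dna and foci channels must have identical dimensions")
  if (any(dna < 0) || any(foci < 0)) stop("intensities must be >= 0")
  structure(list(dna = dna, foci = foci, plate_id = plate_id,
                 well_id = well_id, field_index = as.integer(field_index),
                 experiment_index = as.integer(experiment_index)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image %s/%s field %d (experiment %d): %d x %d px, 2 channels\n",
              x$plate_id, x$well_id, x$field_index, x$experiment_index,
              nrow(x$dna), ncol(x$dna)))
  invisible(x)
}

## pixel indices of a filled ellipse clipped to the field; returns a 2-column
## matrix of (row, col)
ellipse_pixels <- function(row0, col0, a, b, theta, H, W) {
  ext <- ceiling(max(a, b)) + 1L
  i0 <- max(1L, floor(row0 - ext)); i1 <- min(H, ceiling(row0 + ext))
  j0 <- max(1L, floor(col0 - ext)); j1 <- min(W, ceiling(col0 + ext))
  if (i0 > i1 || j0 > j1) return(matrix(integer(0), 0, 2))
  ii <- i0:i1; jj <- j0:j1
  di <- ii - row0; dj <- jj - col0
  ct <- cos(theta); st <- sin(theta)
  # x along the major axis, y along the minor axis
  x <- outer(di, dj, function(u, v) v * ct + u * st)
  y <- outer(di, dj, function(u, v) -v * st + u * ct)
  inside <- (x / a)^2 + (y / b)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  cbind(ii[w[, 1L]], jj[w[, 2L]])
}

disc_pixels <- function(row0, col0, r, H, W) {
  ellipse_pixels(row0, col0, r, r, 0, H, W)
}

## sequential rejection-sampling placement of cell centres.
## ext: per-cell spatial extent (pixels); edge: logical, plant touching the
## border; min_dist: optional absolute lower bound on centre-centre distance.
## Cap of 100 attempts per cell on average, after which the achieved count is
## returned with a warning.
place_centers <- function(n, H, W, ext, edge, min_gap = 8, min_dist = 0) {
  rows <- numeric(0); cols <- numeric(0); placed <- integer(0)
  attempts_left <- 100L * n
  for (k in seq_len(n)) {
    ok <- FALSE
    while (attempts_left > 0L) {
      attempts_left <- attempts_left - 1L
      if (edge[k]) {
        side <- sample.int(4L, 1L)
        u <- runif(1, 0, 0.5) * ext[k]
        if (side <= 2L) {       # top / bottom border
          r0 <- if (side == 1L) 1 + u else H - u
          c0 <- runif(1, 1, W)
        } else {                # left / right border
          r0 <- runif(1, 1, H)
          c0 <- if (side == 3L) 1 + u else W - u
        }
      } else {
        m <- ext[k] + 2
        if (W - m <= m || H - m <= m) break
        r0 <- runif(1, m, H - m)
        c0 <- runif(1, m, W - m)
      }
      if (length(placed)) {
        d <- sqrt((rows - r0)^2 + (cols - c0)^2)
        lim <- pmax(ext[placed] + ext[k] + min_gap, min_dist)
        if (any(d < lim)) next
      }
      rows <- c(rows, r0); cols <- c(cols, c0); placed <- c(placed, k)
      ok <- TRUE
      break
    }
    if (!ok) break
  }
  if (length(placed) < n)
    warning(sprintf("placed %d of %d requested cells (non-overlap placement cap reached)",
                    length(placed), n))
  list(row = rows, col = cols, idx = placed)
}

## uniform points inside an ellipse (centred, rotated), pairwise >= min_sep
## apart and >= margin inside the boundary; returns achieved points
sample_foci_positions <- function(k, row0, col0, a, b, theta, margin, min_sep) {
  aa <- a - margin; bb <- b - margin
  if (k == 0L || aa <= 0 || bb <= 0)
    return(cbind(row = numeric(0), col = numeric(0)))
  ct <- cos(theta); st <- sin(theta)
  rows <- numeric(0); cols <- numeric(0)
  for (i in seq_len(k)) {
    placed <- FALSE
    for (att in 1:200) {
      ang <- runif(1, 0, 2 * pi); rad <- sqrt(runif(1))
      x <- aa * rad * cos(ang); y <- bb * rad * sin(ang)
      r0 <- row0 + x * st + y * ct
      c0 <- col0 + x * ct - y * st
      if (length(rows) && any(sqrt((rows - r0)^2 + (cols - c0)^2) < min_sep))
        next
      rows <- c(rows, r0); cols <- c(cols, c0); placed <- TRUE
      break
    }
    if (!placed) break
  }
  cbind(row = rows, col = cols)
}

apply_camera_noise <- function(x, params) {
  v <- as.numeric(x)
  if (params$shot_noise) v <- rpois(length(v), v)
  if (params$noise_sd > 0) v <- v + rnorm(length(v), 0, params$noise_sd)
  v <- round(pmin(65535, pmax(0, v)))
  matrix(as.integer(v), nrow(x), ncol(x))
}

## classify a rendered cell mask against the QC bounds implied by the
## generator geometry (same rules segment_nuclei() applies by default)
expected_qc_of_mask <- function(pix, H, W, r_mean) {
  if (nrow(pix) == 0L) return("excluded_size")
  if (any(pix[, 1L] == 1L | pix[, 1L] == H | pix[, 2L] == 1L | pix[, 2L] == W))
    return("excluded_border")
  area <- nrow(pix)
  lo <- 0.3 * pi * r_mean^2; hi <- 2.2 * pi * r_mean^2
  if (area < lo || area > hi) return("excluded_size")
  per <- mask_perimeter(pix)
  if (circularity(area, per) < 0.8) return("excluded_circularity")
  "selected"
}

#' Simulate a two-channel fluorescence field with planted ground truth
#'
#' Renders one microscope field: elliptical nuclei at `nuclear_level` on the
#' DNA channel and Poisson-distributed bright foci discs on the immunostain
#' channel, with optional fused (clumped) nuclei, border-touching nuclei and
#' pan-nuclear staining artifacts.  Optional Poisson shot noise and additive
#' Gaussian noise are applied last and the image is clipped to the 16-bit
#' range.  Identical `(params, seed)` give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @param seed integer random seed; all randomness in the field derives from it.
#' @param render if `FALSE`, skip image rendering and noise and return the
#'   ground truth only (the truth is drawn before rendering, so it is
#'   identical either way).  Rendered mask areas are then replaced by the
#'   analytic ellipse area.
#' @param plate_id,well_id,field_index,experiment_index provenance identifiers
#'   stored in the returned field image.
#'
#' @return A list of class `sim_field` with elements
#'   \describe{
#'     \item{field}{a [field_image()] (or `NULL` when `render = FALSE`),}
#'     \item{truth}{data frame with one row per planted cell: centroid(s),
#'       planted area and eccentricity, `planted_foci`, `is_binucleated`,
#'       `planted_mn`, `is_pan_nuclear`, `is_clumped`, `touches_edge` and the
#'       `expected_qc` status under the default QC rules,}
#'     \item{foci}{data frame of planted focus centres (`cell_id`, `row`,
#'       `col`),}
#'     \item{seed}{the seed used.}
#'   }
#' @seealso [simulate_mn_field()] for micronucleus-assay fields.
#' @export
simulate_field <- function(params, seed, render = TRUE,
                           plate_id = "P1", well_id = "A01",
                           field_index = 1L, experiment_index = 1L) {
  validate_sim_params(params)
  set.seed(seed)
  H <- params$field_height; W <- params$field_width
  n <- params$n_cells
  r_mean <- params$nucleus_radius_mean

  if (n > 0L) {
    r <- pmax(5, rnorm(n, r_mean, params$nucleus_radius_sd))
    ecc <- runif(n, 0, params$eccentricity_max)
    shape <- (1 - ecc^2)^0.25          # a = r / shape, b = r * shape
    a <- r / shape; b <- r * shape
    theta <- runif(n, 0, pi)
    is_edge <- runif(n) < params$edge_fraction
    is_clump <- !is_edge & runif(n) < params$clump_fraction
    is_pan <- runif(n) < params$pan_nuclear_fraction

    # clump partner geometry: a second ellipse fused at 30-60 % radius overlap
    cl_r <- r * runif(n, 0.85, 1)
    cl_d <- (2 - runif(n, 0.3, 0.6)) * r   # centre distance 1.4-1.7 r
    cl_ang <- runif(n, 0, 2 * pi)
    cl_ecc <- runif(n, 0, params$eccentricity_max)
    cl_shape <- (1 - cl_ecc^2)^0.25
    cl_theta <- runif(n, 0, pi)

    ext <- a
    ext[is_clump] <- pmax(a[is_clump],
                          cl_d[is_clump] + cl_r[is_clump] / cl_shape[is_clump])
    pl <- place_centers(n, H, W, ext, is_edge)
    keep <- pl$idx
    n_placed <- length(keep)

    rows <- pl$row; cols <- pl$col
    r <- r[keep]; a <- a[keep]; b <- b[keep]; ecc <- ecc[keep]
    theta <- theta[keep]
    is_edge <- is_edge[keep]; is_clump <- is_clump[keep]; is_pan <- is_pan[keep]
    cl_r <- cl_r[keep]; cl_d <- cl_d[keep]; cl_ang <- cl_ang[keep]
    cl_shape <- cl_shape[keep]; cl_theta <- cl_theta[keep]

    # planted foci (discrete foci only in non-pan-nuclear nuclei)
    k_foci <- integer(n_placed)
    foci_pos <- vector("list", n_placed)
    for (i in seq_len(n_placed)) {
      if (is_pan[i]) { foci_pos[[i]] <- cbind(row = numeric(0), col = numeric(0)); next }
      k <- rpois(1, params$foci_lambda)
      pos <- sample_foci_positions(k, rows[i], cols[i], a[i], b[i], theta[i],
                                   params$foci_border_margin,
                                   params$foci_min_separation)
      k_foci[i] <- nrow(pos)
      foci_pos[[i]] <- pos
    }
  } else {
    n_placed <- 0L
    rows <- cols <- r <- a <- b <- ecc <- theta <- numeric(0)
    is_edge <- is_clump <- is_pan <- logical(0)
    k_foci <- integer(0); foci_pos <- list()
    cl_r <- cl_d <- cl_ang <- cl_shape <- cl_theta <- numeric(0)
  }

  # --- rendering -----------------------------------------------------------
  area <- round(pi * r^2)
  expected_qc <- ifelse(is_edge, "excluded_border", "selected")
  fld <- NULL
  if (render) {
    dna <- matrix(params$background_level, H, W)
    foc <- matrix(params$background_level, H, W)
    for (i in seq_len(n_placed)) {
      pix <- ellipse_pixels(rows[i], cols[i], a[i], b[i], theta[i], H, W)
      if (is_clump[i]) {
        r2 <- rows[i] + cl_d[i] * sin(cl_ang[i])
        c2 <- cols[i] + cl_d[i] * cos(cl_ang[i])
        pix2 <- ellipse_pixels(r2, c2, cl_r[i] / cl_shape[i],
                               cl_r[i] * cl_shape[i], cl_theta[i], H, W)
        pix <- unique(rbind(pix, pix2))
      }
      dna[pix] <- params$nuclear_level
      area[i] <- nrow(pix)
      if (is_pan[i]) {
        foc[pix] <- params$nuclear_level + params$foci_peak / 2
      } else if (k_foci[i] > 0L) {
        for (f in seq_len(k_foci[i])) {
          fp <- disc_pixels(foci_pos[[i]][f, 1L], foci_pos[[i]][f, 2L],
                            params$foci_radius, H, W)
          foc[fp] <- params$background_level + params$foci_peak
        }
      }
      if (!is_edge[i])
        expected_qc[i] <- if (is_clump[i])
          expected_qc_of_mask(pix, H, W, r_mean) else "selected"
    }
    dna <- apply_camera_noise(dna, params)
    foc <- apply_camera_noise(foc, params)
    fld <- field_image(dna, foc, plate_id, well_id, field_index, experiment_index)
  } else {
    # analytic stand-in for the clump classification when nothing is rendered
    for (i in which(is_clump)) {
      d <- cl_d[i] / r[i]
      alpha <- acos(pmin(1, d / 2))
      lens <- r[i]^2 * (2 * alpha - sin(2 * alpha))
      area[i] <- round(pi * r[i]^2 + pi * cl_r[i]^2 - lens)
      expected_qc[i] <- if (area[i] > 2.2 * pi * r_mean^2)
        "excluded_size" else "excluded_circularity"
    }
  }

  truth <- data.frame(
    cell_id = seq_len(n_placed),
    cy = rows, cx = cols,
    cy2 = rep(NA_real_, n_placed), cx2 = rep(NA_real_, n_placed),
    area = as.numeric(area), eccentricity = ecc,
    planted_foci = k_foci, is_binucleated = rep(FALSE, n_placed),
    planted_mn = rep(0L, n_placed),
    is_pan_nuclear = is_pan, is_clumped = is_clump, touches_edge = is_edge,
    expected_qc = expected_qc, stringsAsFactors = FALSE)

  foci_df <- do.call(rbind, lapply(seq_len(n_placed), function(i) {
    p <- foci_pos[[i]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    data.frame(cell_id = i, row = p[, 1L], col = p[, 2L])
  }))
  if (is.null(foci_df))
    foci_df <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0))

  structure(list(field = fld, truth = truth, foci = foci_df, seed = seed),
            class = "sim_field")
}

#' Simulate a micronucleus-assay field (binucleated cells with micronuclei)
#'
#' Like [simulate_field()] but for the cytokinesis-block micronucleus assay:
#' each cell is binucleated with probability `binucleation_rate`, rendered as
#' two similar-size, nearly round nuclei with centroid gap at most 2.5 times
#' the mean nuclear radius.  A binucleated cell carries micronuclei with
#' probability `mn_prob`; micronuclei are small DNA-positive discs
#' (`mn_radius_fraction` of the main-nucleus radius) planted adjacent to the
#' pair, a few pixels clear of either main nucleus.  Cells are spaced so that
#' nuclei of different cells are farther apart than the binucleate-pairing
#' gap criterion, which is what the assay's own plating density achieves.
#'
#' The immunostain channel is background only.  The returned `truth` records
#' both nucleus centroids (`cy`/`cx`, `cy2`/`cx2`), `is_binucleated` and
#' `planted_mn`; micronucleus centres are returned in the `mn` element.
#'
#' @inheritParams simulate_field
#' @return As [simulate_field()], plus an `mn` data frame of planted
#'   micronucleus centres (`cell_id`, `row`, `col`, `radius`).
#' @export
simulate_mn_field <- function(params, seed, render = TRUE,
                              plate_id = "P1", well_id = "A01",
                              field_index = 1L, experiment_index = 1L) {
  validate_sim_params(params)
  set.seed(seed)
  H <- params$field_height; W <- params$field_width
  n <- params$n_cells
  r_mean <- params$nucleus_radius_mean
  mn_probs <- params$mn_count_given_positive
  mn_counts <- as.integer(names(mn_probs))

  if (n > 0L) {
    binuc <- runif(n) < params$binucleation_rate
    r <- pmax(5, rnorm(n, r_mean, params$nucleus_radius_sd))
    # main nuclei: nearly round (post-cytokinesis-block morphology)
    ecc <- runif(n, 0, min(0.3, params$eccentricity_max))
    shape <- (1 - ecc^2)^0.25
    theta <- runif(n, 0, pi)

    r1 <- ifelse(binuc, 0.8 * r, r)
    r2 <- r1 * runif(n, 0.95, 1.05)
    gap_lo <- r1 + r2 + 6
    gap_hi <- pmax(gap_lo, 2.5 * r)
    gap <- runif(n, gap_lo, gap_hi)
    pair_ang <- runif(n, 0, 2 * pi)

    has_mn <- binuc & runif(n) < params$mn_prob
    k_mn <- integer(n)
    k_mn[has_mn] <- mn_counts[sample.int(length(mn_counts), sum(has_mn),
                                         replace = TRUE, prob = mn_probs)]
    r_mn <- params$mn_radius_fraction * (r1 + r2) / 2

    ext <- ifelse(binuc, gap / 2 + pmax(r1, r2) / shape, r1 / shape)
    ext <- ext + ifelse(k_mn > 0L, 2 * r_mn + 12, 0)
    # keep nuclei of different cells beyond the pairing-gap criterion
    pl <- place_centers(n, H, W, ext, edge = rep(FALSE, n),
                        min_dist = 7.5 * r_mean)
    keep <- pl$idx
    n_placed <- length(keep)
    rows <- pl$row; cols <- pl$col
    for (v in c("binuc", "r", "ecc", "shape", "theta", "r1", "r2", "gap",
                "pair_ang", "has_mn", "k_mn", "r_mn"))
      assign(v, get(v)[keep])

    # per-cell nucleus centroids
    dy <- sin(pair_ang) * gap / 2; dx <- cos(pair_ang) * gap / 2
    n1_row <- ifelse(binuc, rows - dy, rows); n1_col <- ifelse(binuc, cols - dx, cols)
    n2_row <- rows + dy; n2_col <- cols + dx

    # micronucleus placement: adjacent to one of the two nuclei, pointing
    # away from the partner
    mn_list <- vector("list", n_placed)
    for (i in seq_len(n_placed)) {
      if (k_mn[i] == 0L) next
      pts <- matrix(numeric(0), 0, 2)
      for (m in seq_len(k_mn[i])) {
        j <- sample.int(2L, 1L)
        base_row <- if (j == 1L) n1_row[i] else n2_row[i]
        base_col <- if (j == 1L) n1_col[i] else n2_col[i]
        away <- if (j == 1L) pair_ang[i] + pi else pair_ang[i]
        psi <- away + runif(1, -pi / 3, pi / 3)
        rad <- (if (j == 1L) r1[i] else r2[i]) / shape[i] + r_mn[i] + runif(1, 4, 8)
        pts <- rbind(pts, c(base_row + rad * sin(psi), base_col + rad * cos(psi)))
      }
      mn_list[[i]] <- pts
    }
  } else {
    n_placed <- 0L
    rows <- cols <- r <- ecc <- shape <- theta <- numeric(0)
    binuc <- has_mn <- logical(0); k_mn <- integer(0)
    r1 <- r2 <- gap <- pair_ang <- r_mn <- numeric(0)
    n1_row <- n1_col <- n2_row <- n2_col <- numeric(0)
    mn_list <- list()
  }

  area <- round(pi * ifelse(binuc, r1^2 + r2^2, r1^2))
  fld <- NULL
  if (render) {
    dna <- matrix(params$background_level, H, W)
    foc <- matrix(params$background_level, H, W)
    for (i in seq_len(n_placed)) {
      pix <- ellipse_pixels(n1_row[i], n1_col[i], r1[i] / shape[i],
                            r1[i] * shape[i], theta[i], H, W)
      if (binuc[i]) {
        pix2 <- ellipse_pixels(n2_row[i], n2_col[i], r2[i] / shape[i],
                               r2[i] * shape[i], theta[i] + pi / 7, H, W)
        pix <- unique(rbind(pix, pix2))
      }
      dna[pix] <- params$nuclear_level
      area[i] <- nrow(pix)
      if (k_mn[i] > 0L)
        for (m in seq_len(k_mn[i])) {
          mp <- disc_pixels(mn_list[[i]][m, 1L], mn_list[[i]][m, 2L],
                            r_mn[i], H, W)
          dna[mp] <- params$nuclear_level
        }
    }
    dna <- apply_camera_noise(dna, params)
    foc <- apply_camera_noise(foc, params)
    fld <- field_image(dna, foc, plate_id, well_id, field_index, experiment_index)
  }

  truth <- data.frame(
    cell_id = seq_len(n_placed),
    cy = n1_row, cx = n1_col,
    cy2 = ifelse(binuc, n2_row, NA_real_),
    cx2 = ifelse(binuc, n2_col, NA_real_),
    area = as.numeric(area), eccentricity = ecc,
    planted_foci = rep(0L, n_placed), is_binucleated = binuc,
    planted_mn = k_mn,
    is_pan_nuclear = rep(FALSE, n_placed), is_clumped = rep(FALSE, n_placed),
    touches_edge = rep(FALSE, n_placed),
    expected_qc = rep("selected", n_placed), stringsAsFactors = FALSE)

  mn_df <- do.call(rbind, lapply(seq_len(n_placed), function(i) {
    p <- mn_list[[i]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    data.frame(cell_id = i, row = p[, 1L], col = p[, 2L], radius = r_mn[i])
  }))
  if (is.null(mn_df))
    mn_df <- data.frame(cell_id = integer(0), row = numeric(0),
                        col = numeric(0), radius = numeric(0))

  structure(list(field = fld, truth = truth,
                 foci = data.frame(cell_id = integer(0), row = numeric(0),
                                   col = numeric(0)),
                 mn = mn_df, seed = seed),
            class = "sim_field")
}
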