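#' Parameters of the synthetic two-channel field generator
#'
#' Builds the parameter set consumed by [simulate_field()] and
#' [simulate_mn_field()].  The generator renders elliptical nuclei on a DNA
#' counterstain channel and bright sub-nuclear foci (plus optional pan-nuclear
#' staining artifacts) on an immunostain channel, together with a ground-truth
#' table holding one row per planted cell.
#'
#' All geometric quantities are in pixels (the assay defines no physical pixel
#' size, so the simulator works in pixel units throughout) and all intensities
#' in camera counts on a 16-bit scale.
#'
#' @param field_width,field_height field size in pixels.
#' @param n_cells number of cells planted per field.
#' @param nucleus_radius_mean,nucleus_radius_sd mean and standard deviation of
#'   the equivalent-circle nuclear radius (pixels); radii are drawn from a
#'   normal distribution truncated below at 5 px.
#' @param eccentricity_max nuclei are ellipses with eccentricity drawn
#'   uniformly on `[0, eccentricity_max)`; must be `< 1`.  The semi-axes are
#'   scaled so the ellipse area equals that of the equivalent circle.
#' @param clump_fraction probability that a cell is rendered as a fused pair
#'   of overlapping ellipses (centre distance 1.4-1.7 radii), emulating nuclei
#'   too close to be identified separately.
#' @param edge_fraction probability that a nucleus is planted touching the
#'   field border (and therefore should be excluded by the border QC rule).
#' @param foci_lambda mean number of planted foci per nucleus; counts are
#'   Poisson distributed.
#' @param foci_radius focus disc radius in pixels.
#' @param foci_peak focus intensity in counts above the immunostain channel
#'   background.
#' @param nuclear_level,background_level DNA-channel intensity inside nuclei
#'   and channel background level (counts).
#' @param noise_sd standard deviation of additive Gaussian camera noise
#'   (counts), applied after rendering.
#' @param shot_noise logical; if `TRUE` the expected counts are Poisson
#'   resampled before the additive noise (shot + read noise camera model).
#' @param pan_nuclear_fraction probability that a nucleus is rendered with
#'   uniformly elevated immunostain signal (`nuclear_level + foci_peak / 2`)
#'   instead of discrete foci, emulating the pan-nuclear staining artifact.
#' @param binucleation_rate probability that a cell in a micronucleus-assay
#'   field is binucleated (two similar-size nuclei; see
#'   [simulate_mn_field()]).  The assay's cytochalasin-B conditions yield
#'   about 25 percent binucleated cells, the default.
#' @param mn_prob probability that a binucleated cell carries at least one
#'   micronucleus.
#' @param mn_count_given_positive named numeric vector of probabilities for
#'   the number of micronuclei in a micronucleated cell; names are the counts.
#' @param mn_radius_fraction micronucleus radius as a fraction of the main
#'   nucleus radius.
#' @param foci_min_separation minimum distance between planted focus centres
#'   (pixels); the default (one focus diameter plus 2 px) keeps planted foci
#'   resolvable by the default detector while leaving enough placement room
#'   that Poisson counts are essentially never truncated.
#' @param foci_border_margin minimum distance between a planted focus centre
#'   and the nuclear boundary (pixels).
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params(n_cells = 20, foci_lambda = 4)
#' sim <- simulate_field(p, seed = 1)
#' nrow(sim$truth)
#' @export
sim_params <- function(field_width = 1024L,
                       field_height = 1024L,
                       n_cells = 120L,
                       nucleus_radius_mean = 30,
                       nucleus_radius_sd = 3,
                       eccentricity_max = 0.6,
                       clump_fraction = 0,
                       edge_fraction = 0,
                       foci_lambda = 1.3,
                       foci_radius = 3,
                       foci_peak = 1500,
                       nuclear_level = 2000,
                       background_level = 200,
                       noise_sd = 50,
                       shot_noise = FALSE,
                       pan_nuclear_fraction = 0,
                       binucleation_rate = 0.25,
                       mn_prob = 0.02,
                       mn_count_given_positive = c("1" = 0.85, "2" = 0.12, "3" = 0.03),
                       mn_radius_fraction = 0.25,
                       foci_min_separation = 2 * foci_radius + 2,
                       foci_border_margin = foci_radius + 2) {
  p <- list(field_width = as.integer(field_width),
            field_height = as.integer(field_height),
            n_cells = as.integer(n_cells),
            nucleus_radius_mean = nucleus_radius_mean,
            nucleus_radius_sd = nucleus_radius_sd,
            eccentricity_max = eccentricity_max,
            clump_fraction = clump_fraction,
            edge_fraction = edge_fraction,
            foci_lambda = foci_lambda,
            foci_radius = foci_radius,
            foci_peak = foci_peak,
            nuclear_level = nuclear_level,
            background_level = background_level,
            noise_sd = noise_sd,
            shot_noise = isTRUE(shot_noise),
            pan_nuclear_fraction = pan_nuclear_fraction,
            binucleation_rate = binucleation_rate,
            mn_prob = mn_prob,
            mn_count_given_positive = mn_count_given_positive,
            mn_radius_fraction = mn_radius_fraction,
            foci_min_separation = foci_min_separation,
            foci_border_margin = foci_border_margin)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$field_width <= 0 || p$field_height <= 0)
    stop("field dimensions must be positive")
  if (p$n_cells < 0) stop("n_cells must be >= 0")
  num_nonneg <- c("nucleus_radius_mean", "nucleus_radius_sd", "foci_lambda",
                  "foci_radius", "foci_peak", "nuclear_level",
                  "background_level", "noise_sd", "mn_radius_fraction",
                  "foci_min_separation", "foci_border_margin")
  for (f in num_nonneg)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] < 0)
      stop("parameter '", f, "' must be a non-negative number")
  probs <- c("clump_fraction", "edge_fraction", "pan_nuclear_fraction",
             "binucleation_rate", "mn_prob")
  for (f in probs)
    if (p[[f]] < 0 || p[[f]] > 1)
      stop("parameter '", f, "' must be a probability in [0, 1]")
  if (p$eccentricity_max < 0 || p$eccentricity_max >= 1)
    stop("eccentricity_max must be in [0, 1)")
  m <- p$mn_count_given_positive
  if (length(m) < 1L || any(m < 0) || abs(sum(m) - 1) > 1e-8 ||
      is.null(names(m)) || any(is.na(as.integer(names(m)))) ||
      any(as.integer(names(m)) < 1L))
    stop("mn_count_given_positive must be named probabilities over counts >= 1 summing to 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic field generator parameters\n")
  cat(sprintf("  field: %d x %d px, %d cells\n",
              x$field_width, x$field_height, x$n_cells))
  cat(sprintf("  nuclei: r = %.1f +/- %.1f px, ecc < %.2f\n",
              x$nucleus_radius_mean, x$nucleus_radius_sd, x$eccentricity_max))
  cat(sprintf("  foci: lambda = %.2f, r = %.1f px, peak = %.0f counts\n",
              x$foci_lambda, x$foci_radius, x$foci_peak))
  cat(sprintf("  levels: nuclear %.0f, background %.0f, noise sd %.0f%s\n",
              x$nuclear_level, x$background_level, x$noise_sd,
              if (x$shot_noise) " + shot" else ""))
  cat(sprintf("  artifacts: clump %.2f, edge %.2f, pan-nuclear %.2f\n",
              x$clump_fraction, x$edge_fraction, x$pan_nuclear_fraction))
  cat(sprintf("  MN assay: binucleation %.2f, P(MN|binucleated) %.2f\n",
              x$binucleation_rate, x$mn_prob))
  invisible(x)
}
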