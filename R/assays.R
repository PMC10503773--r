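#' WST-1 viability from background-corrected absorbance
#'
#' Per-well signal is `(A450 - A690)` minus the mean blank signal; viability
#' is the signal as a percentage of the mean control-well signal, floored at
#' zero.
#'
#' @param plate data frame with columns `well_id`, `condition`, `role`
#'   (`"sample"`, `"control"`, `"positive_control"` or `"blank"`), `A450`,
#'   `A690`.
#' @return `plate` with columns `signal` and `viability` (percent) added;
#'   blank wells get `NA` viability.
#' @export
wst1_viability <- function(plate) {
  need <- c("well_id", "condition", "role", "A450", "A690")
  if (!all(need %in% names(plate))) stop("plate must have columns: ",
                                         paste(need, collapse = ", "))
  if (!any(plate$role == "blank")) stop("no blank wells on plate")
  if (!any(plate$role == "control")) stop("no control wells on plate")
  raw <- plate$A450 - plate$A690
  blank <- mean(raw[plate$role == "blank"])
  signal <- raw - blank
  ctrl <- mean(signal[plate$role == "control"])
  if (ctrl <= 0) stop("non-positive mean control signal")
  plate$signal <- signal
  plate$viability <- pmax(0, 100 * signal / ctrl)
  plate$viability[plate$role == "blank"] <- NA_real_
  plate
}

#' Highest concentration that does not affect viability (Cmax)
#'
#' "Does not affect viability" is operationalised as: mean viability at least
#' `threshold_pct` percent of control AND not statistically distinguishable
#' from control (Mann-Whitney p >= `alpha` on the per-well values).  Cmax is
#' the highest tested concentration meeting both.
#'
#' @param viab data frame with columns `concentration`, `viability` and
#'   `role`; control wells are the rows with `role == "control"`.
#' @param threshold_pct minimum mean viability (percent of control).
#' @param alpha significance level of the pairwise comparison.
#' @return The Cmax concentration (numeric scalar).  If no concentration
#'   qualifies an error reports the lowest tested concentration and its mean
#'   viability.
#' @export
find_cmax <- function(viab, threshold_pct = 85, alpha = 0.05) {
  ctrl <- viab$viability[viab$role == "control"]
  if (length(ctrl) == 0L) stop("no control wells in viability table")
  test <- viab[viab$role %in% c("sample", "positive_control") &
                 !is.na(viab$concentration), , drop = FALSE]
  concs <- sort(unique(test$concentration), decreasing = TRUE)
  if (length(concs) < 2L) stop("need at least two tested concentrations")
  for (cc in concs) {
    v <- test$viability[test$concentration == cc]
    if (mean(v) < threshold_pct) next
    # two internally constant groups carry no sampling variability, so the
    # rank test is vacuous there; only the mean-threshold rule applies
    p <- if (sd(v) == 0 && sd(ctrl) == 0) 1 else mann_whitney(v, ctrl)$p.value
    if (p >= alpha) return(cc)
  }
  low <- min(concs)
  stop(sprintf(
    "no concentration passes the viability criterion; lowest tested %g gives mean viability %.1f%%",
    low, mean(test$viability[test$concentration == low])))
}

#' Genotoxicity-testing concentration series from Cmax
#'
#' The assay tests the highest non-cytotoxic concentration, half of it and
#' one fifth of it.
#'
#' @param cmax positive concentration.
#' @return Numeric vector `c(cmax, cmax / 2, cmax / 5)`.
#' @examples
#' series_from_cmax(50)  # 50, 25, 10
#' @export
series_from_cmax <- function(cmax) {
  if (!is.numeric(cmax) || length(cmax) != 1L || cmax <= 0)
    stop("cmax must be a positive scalar")
  c(cmax, cmax / 2, cmax / 5)
}

#' DHR123 fold change versus the time-matched control
#'
#' Each well's fluorescence is divided by the mean control fluorescence at
#' the same timepoint; condition-level means and standard deviations are
#' taken over the replicate wells, and each condition is compared with
#' control per timepoint by the Mann-Whitney test.
#'
#' @param plate data frame with columns `well_id`, `condition`, `role`,
#'   `time_h`, `fluorescence`.
#' @param alpha significance level of the per-timepoint comparison.
#' @return A list with `wells` (per-well fold changes) and `summary`
#'   (condition x timepoint: `mean_fold`, `sd_fold`, `mw_p`, `significant`).
#' @export
dhr123_fold_change <- function(plate, alpha = 0.05) {
  need <- c("well_id", "condition", "role", "time_h", "fluorescence")
  if (!all(need %in% names(plate))) stop("plate must have columns: ",
                                         paste(need, collapse = ", "))
  times <- sort(unique(plate$time_h))
  ctrl_mean <- vapply(times, function(t)
    mean(plate$fluorescence[plate$role == "control" & plate$time_h == t]),
    numeric(1))
  if (any(!is.finite(ctrl_mean)))
    stop("control wells missing at some timepoint")
  if (any(ctrl_mean <= 0)) stop("zero control fluorescence")
  plate$fold <- plate$fluorescence / ctrl_mean[match(plate$time_h, times)]
  conds <- unique(plate$condition[plate$role != "blank"])
  ctrl_cond <- unique(plate$condition[plate$role == "control"])
  rows <- list()
  for (cn in conds) for (t in times) {
    f <- plate$fold[plate$condition == cn & plate$time_h == t]
    fc <- plate$fold[plate$condition == ctrl_cond & plate$time_h == t]
    p <- if (cn == ctrl_cond) NA_real_ else mann_whitney(f, fc)$p.value
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cn, time_h = t, mean_fold = mean(f), sd_fold = sd(f),
      mw_p = p, significant = !is.na(p) && p < alpha,
      stringsAsFactors = FALSE)
  }
  list(wells = plate, summary = do.call(rbind, rows))
}

#' Time to half-repair of the focus excess
#'
#' Linear interpolation of the mean focus count over time to the first time
#' at which the excess above the unexposed baseline has fallen to half of its
#' peak excess.  If the series never falls below that level within the
#' observed window the estimate is censored at the last timepoint.
#'
#' @param times timepoints (hours), increasing, length >= 3.
#' @param means mean foci per nucleus at each timepoint.
#' @param baseline unexposed-control mean foci per nucleus.
#' @return A list: `halftime` (hours, `NA` when censored), `censored`,
#'   `peak_time`, `peak_excess`.
#' @export
repair_halftime <- function(times, means, baseline) {
  if (length(times) < 3L || length(means) != length(times))
    stop("need >= 3 timepoints with matching means")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  excess <- means - baseline
  pk <- which.max(excess)
  if (excess[pk] <= 0) stop("no excess above baseline: repair halftime undefined")
  target <- excess[pk] / 2
  for (i in seq(pk, length(times) - 1L)) {
    if (excess[i] >= target && excess[i + 1L] <= target) {
      if (excess[i] == excess[i + 1L]) next
      t_half <- times[i] + (excess[i] - target) /
        (excess[i] - excess[i + 1L]) * (times[i + 1L] - times[i])
      return(list(halftime = t_half, censored = FALSE,
                  peak_time = times[pk], peak_excess = excess[pk]))
    }
  }
  list(halftime = NA_real_, censored = TRUE,
       peak_time = times[pk], peak_excess = excess[pk])
}

#' Simulate a plate-reader assay plate with planted condition effects
#'
#' Generates per-well WST-1 absorbance pairs (A450/A690) or DHR123
#' fluorescence time courses with multiplicative Gaussian noise on the
#' biological signal.  Control wells are centred on 100 percent of their own
#' truth, so a noiseless plate reproduces the planted effects exactly after
#' [wst1_viability()] / [dhr123_fold_change()].
#'
#' @param layout a [plate_layout()] with at least one blank well and a
#'   control condition.
#' @param effect for `assay = "wst1"`: named vector of true viability
#'   fractions per condition (control implicitly 1).  For `assay =
#'   "dhr123"`: named list per condition of true fold changes per timepoint.
#' @param noise_sd multiplicative noise standard deviation (fraction).
#' @param seed random seed.
#' @param assay `"wst1"` or `"dhr123"`.
#' @param timepoints DHR123 measurement times in hours.
#' @return A data frame in the format expected by [wst1_viability()] or
#'   [dhr123_fold_change()].
#' @export
simulate_assay_plate <- function(layout, effect, noise_sd = 0.05, seed = 1L,
                                 assay = c("wst1", "dhr123"),
                                 timepoints = c(0, 0.5, 1, 3, 5, 24)) {
  assay <- match.arg(assay)
  if (!any(layout$role == "blank")) stop("layout must include a blank well")
  if (!any(layout$role == "control")) stop("layout must name a control condition")
  set.seed(seed)
  if (assay == "wst1") {
    truth <- ifelse(layout$role == "blank", 0,
                    ifelse(layout$role == "control", 1,
                           unname(effect[layout$condition])))
    if (any(is.na(truth))) stop("effect missing for some conditions")
    base_a690 <- 0.05; signal_scale <- 1.2
    noise <- if (noise_sd > 0) rnorm(nrow(layout), 0, noise_sd) else 0
    data.frame(layout,
               A450 = base_a690 + signal_scale * truth * (1 + noise),
               A690 = base_a690, stringsAsFactors = FALSE)
  } else {
    rows <- list()
    for (w in seq_len(nrow(layout))) {
      if (layout$role[w] == "blank") next
      cond <- layout$condition[w]
      tr <- if (layout$role[w] == "control") rep(1, length(timepoints))
            else effect[[cond]]
      if (length(tr) != length(timepoints))
        stop("effect for condition '", cond, "' must give one fold per timepoint")
      noise <- if (noise_sd > 0) rnorm(length(timepoints), 0, noise_sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        well_id = layout$well_id[w], condition = cond, role = layout$role[w],
        time_h = timepoints, fluorescence = 1000 * tr * (1 + noise),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
}
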