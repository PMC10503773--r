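#' Build a plate layout (replicate wells by independent experiments)
#'
#' The assay design analysed here is 5 technical replicate wells per
#' independent experiment and 3 independent experiments, i.e. 15 wells per
#' condition; one condition is the unexposed control.
#'
#' @param conditions character vector of condition labels.
#' @param control which condition is the unexposed control.
#' @param concentrations optional named vector mapping condition to
#'   concentration.
#' @param n_replicates,n_experiments replicate wells per experiment and number
#'   of independent experiments.
#' @param positive_control optional condition label flagged as positive control.
#' @param n_blanks number of blank wells appended (role `"blank"`).
#' @return Data frame with columns `well_id`, `condition`, `concentration`,
#'   `experiment`, `replicate` and `role`.
#' @export
plate_layout <- function(conditions, control = conditions[1L],
                         concentrations = NULL,
                         n_replicates = 5L, n_experiments = 3L,
                         positive_control = NULL, n_blanks = 0L) {
  stopifnot(control %in% conditions)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      experiment = seq_len(n_experiments),
                      condition = conditions, stringsAsFactors = FALSE)
  role <- rep("sample", nrow(grid))
  role[grid$condition == control] <- "control"
  if (!is.null(positive_control))
    role[grid$condition == positive_control] <- "positive_control"
  out <- data.frame(
    well_id = sprintf("%s_e%d_r%d", grid$condition, grid$experiment,
                      grid$replicate),
    condition = grid$condition,
    concentration = if (is.null(concentrations)) NA_real_
                    else unname(concentrations[grid$condition]),
    experiment = grid$experiment, replicate = grid$replicate,
    role = role, stringsAsFactors = FALSE)
  if (n_blanks > 0L)
    out <- rbind(out, data.frame(
      well_id = sprintf("blank_%d", seq_len(n_blanks)),
      condition = "blank", concentration = NA_real_,
      experiment = NA_integer_, replicate = NA_integer_, role = "blank"))
  out
}

#' Per-well mean foci count
#'
#' Takes the first `cap` selected, unflagged nuclei in `(field_index,
#' nucleus_id)` order — the deterministic counterpart of an instrument
#' analysing a fixed number of cells per well — and averages their focus
#' counts.  Seed-controlled random subsampling is available instead via
#' `sample_seed`.
#'
#' @param records nucleus records for one well; must carry `field_index`,
#'   `nucleus_id`, `qc_status`, `pan_nuclear_flag` and `foci_count`.
#' @param cap maximum number of nuclei analysed per well.
#' @param well_id label stored in the summary.
#' @param sample_seed if non-`NULL`, sample `cap` nuclei at random under this
#'   seed instead of taking the first `cap`.
#' @return A list: `well_id`, `n_analyzed`, `statistic` (mean foci per
#'   nucleus).
#' @export
well_mean_foci <- function(records, cap = 500L, well_id = "well",
                           sample_seed = NULL) {
  use <- records[records$qc_status == "selected" & !records$pan_nuclear_flag &
                   !is.na(records$foci_count), , drop = FALSE]
  if (nrow(use) == 0L) stop("no analyzable nuclei in well ", well_id)
  if (is.null(use$field_index)) use$field_index <- 1L
  use <- use[order(use$field_index, use$nucleus_id), , drop = FALSE]
  if (!is.null(sample_seed)) {
    set.seed(sample_seed)
    use <- use[sample.int(nrow(use), min(cap, nrow(use))), , drop = FALSE]
  } else {
    use <- use[seq_len(min(cap, nrow(use))), , drop = FALSE]
  }
  list(well_id = well_id, n_analyzed = nrow(use),
       statistic = mean(use$foci_count))
}

#' Aggregate the 15 well statistics of one condition
#'
#' The condition estimate is the mean and sample standard deviation
#' (`n - 1` denominator) of the per-well statistics, pooled over replicate
#' wells and independent experiments (5 x 3 = 15 by default).
#'
#' @param values numeric vector of per-well statistics.
#' @param condition condition label.
#' @param n_expected required number of wells (error if different).
#' @return A list: `condition`, `n_wells`, `mean`, `sd`.
#' @export
condition_summary <- function(values, condition = "condition",
                              n_expected = 15L) {
  if (length(values) != n_expected)
    stop(sprintf("condition '%s' has %d well values, expected %d",
                 condition, length(values), n_expected))
  list(condition = condition, n_wells = length(values),
       mean = mean(values), sd = sd(values))
}

#' Kruskal-Wallis rank test across condition groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom (via [stats::kruskal.test()]).  The fully
#' degenerate case where every value in every group is identical returns
#' `H = 0, p = 1`.
#'
#' @param groups list of two or more numeric vectors (each of length >= 2).
#' @return A list: `statistic` (H), `p.value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("kruskal_wallis needs at least two groups")
  if (any(lengths(groups) < 2L)) stop("each group must have n >= 2")
  all_vals <- unlist(groups, use.names = FALSE)
  if (length(unique(all_vals)) == 1L)
    return(list(statistic = 0, p.value = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       df = unname(kt$parameter))
}

#' Two-sample Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U computed from rank sums with average ranks for ties.  The p-value is
#' exact by enumeration when both samples have at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction is used (via [stats::wilcox.test()]).
#'
#' @param a,b numeric samples (each non-empty).
#' @param exact_max largest per-group size for which the exact null
#'   distribution is enumerated.
#' @return A list: `U` (statistic for `a`), `p.value` (two-sided), `exact`.
#' @export
mann_whitney <- function(a, b, exact_max = 10L) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  ties <- any(duplicated(c(a, b)))
  use_exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  if (length(unique(c(a, b))) == 1L) {
    # all values identical: U is at its midpoint and there is no evidence
    return(list(U = length(a) * length(b) / 2, p.value = 1, exact = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = use_exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p.value = wt$p.value, exact = use_exact)
}

#' Compare every condition with the control (nonparametric battery)
#'
#' The omnibus Kruskal-Wallis test is run across all conditions, then each
#' non-control condition is compared with the control by the Mann-Whitney
#' test on its per-well values.  A condition is flagged significant when its
#' pairwise p-value is below `alpha`; no multiplicity correction is applied
#' by default (the assay's own convention), but Holm correction over the
#' pairwise family is available.
#'
#' @param values_by_condition named list of per-well statistic vectors.
#' @param control name of the control condition.
#' @param alpha significance level.
#' @param holm apply Holm correction to the pairwise p-values.
#' @return Data frame: `condition`, `n_wells`, `mean`, `sd`, `kw_p`,
#'   `mw_p_vs_control`, `significant`.
#' @export
compare_to_control <- function(values_by_condition, control, alpha = 0.05,
                               holm = FALSE) {
  if (!control %in% names(values_by_condition))
    stop("control condition '", control, "' not present")
  conds <- names(values_by_condition)
  if (length(conds) >= 2L) {
    kw <- kruskal_wallis(values_by_condition)$p.value
  } else {
    message("single condition: omnibus test skipped")
    kw <- NA_real_
  }
  mw <- vapply(conds, function(cn) {
    if (cn == control) return(NA_real_)
    mann_whitney(values_by_condition[[cn]],
                 values_by_condition[[control]])$p.value
  }, numeric(1))
  if (holm) mw[!is.na(mw)] <- stats::p.adjust(mw[!is.na(mw)], method = "holm")
  data.frame(condition = conds,
             n_wells = lengths(values_by_condition),
             mean = vapply(values_by_condition, mean, numeric(1)),
             sd = vapply(values_by_condition, sd, numeric(1)),
             kw_p = kw, mw_p_vs_control = mw,
             significant = !is.na(mw) & mw < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
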