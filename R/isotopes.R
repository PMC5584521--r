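# Apparent carbon isotope fractionation of methanogenesis.
#
# The apparent fractionation factor alpha_app = (d13CO2 + 1000) /
# (d13CH4 + 1000) is a coarse index of the dominant methanogenic pathway:
# CO2 reduction discriminates strongly against 13C (large alpha), acetate
# fermentation weakly (small alpha). Literature thresholds of 1.065 and
# 1.025 bracket hydrogenotrophic- and aceticlastic-dominated regimes.

#' Apparent methanogenesis fractionation factor
#'
#' `alpha_app = (d13CO2 + 1000) / (d13CH4 + 1000)`, both deltas in per mil
#' vs VPDB. Values below -1000 per mil are nonphysical (negative isotope
#' ratio) and rejected.
#'
#' @param d13co2 delta 13C of CO2, per mil vs VPDB.
#' @param d13ch4 delta 13C of CH4, per mil vs VPDB.
#' @return Dimensionless alpha_app; > 1 exactly when `d13co2 > d13ch4`.
#' @examples
#' alpha_app(-17.0, -61.5)  # ~1.047
#' alpha_app(-22.8, -50.7)  # ~1.029
#' @export
alpha_app <- function(d13co2, d13ch4) {
  stopifnot(is.numeric(d13co2), is.numeric(d13ch4))
  if (any(d13co2 <= -1000, na.rm = TRUE) ||
      any(d13ch4 <= -1000, na.rm = TRUE))
    stop("delta values must exceed -1000 per mil")
  (d13co2 + 1000) / (d13ch4 + 1000)
}

#' Classify the dominant methanogenic pathway from alpha_app
#'
#' Coarse classification by configurable thresholds: below the lower
#' threshold (default 1.025) aceticlastic methanogenesis dominates, above
#' the upper threshold (default 1.065) CO2 reduction dominates, between
#' them the signal is mixed. The labels deliberately say "dominated", not a
#' quantitative apportionment.
#'
#' @param alpha alpha_app values (> 0).
#' @param lower,upper classification thresholds; defaults 1.025 and 1.065.
#' @return Factor with levels `aceticlastic_dominated`, `intermediate`,
#'   `hydrogenotrophic_dominated`.
#' @export
classify_pathway <- function(alpha, lower = 1.025, upper = 1.065) {
  stopifnot(is.numeric(alpha), lower < upper)
  if (any(alpha <= 0, na.rm = TRUE)) stop("alpha must be positive")
  lev <- c("aceticlastic_dominated", "intermediate",
           "hydrogenotrophic_dominated")
  cls <- ifelse(alpha < lower, lev[1], ifelse(alpha > upper, lev[3], lev[2]))
  factor(cls, levels = lev)
}

#' Plateau estimate over the tail of an alpha_app series
#'
#' Mean and standard error over the final `window` sampled time points, with
#' a trend flag: if the absolute fitted change across the window (OLS slope
#' times window span, in index units) exceeds `tol`, the tail is still
#' drifting and `plateaued` is `FALSE`.
#'
#' @param series numeric vector of alpha_app values in time order.
#' @param window number of trailing points to average (>= 2); default 3.
#' @param tol absolute tolerated change across the window before it is
#'   flagged as non-plateau; default 0.002 (about one measurement SE).
#' @return List with `mean`, `se`, `n`, `slope` (per sampled step), and
#'   logical `plateaued`.
#' @export
plateau_estimate <- function(series, window = 3, tol = 0.002) {
  stopifnot(is.numeric(series), window >= 2)
  if (length(series) < window)
    stop("series shorter than the requested window")
  tail_vals <- utils::tail(series, window)
  idx <- seq_len(window)
  slope <- unname(stats::coef(stats::lm(tail_vals ~ idx))[2])
  list(mean = mean(tail_vals),
       se = stats::sd(tail_vals) / sqrt(window),
       n = window,
       slope = slope,
       plateaued = abs(slope * (window - 1)) <= tol)
}

#' Fractionation-factor table from an observation time series
#'
#' Computes alpha_app per replicate and then averages within treatment x day
#' (replicate-first, consistent with the mass-balance summaries), returning
#' a long table of mean deltas, alpha_app and the pathway class.
#'
#' @inheritParams replicate_balances
#' @param lower,upper classification thresholds, see [classify_pathway()].
#' @return Data frame with columns `treatment_id`, `initial_sulfate_mM`,
#'   `day`, `n`, `d13ch4`, `d13co2`, `alpha_app`, `alpha_se`,
#'   `pathway_class`.
#' @export
alpha_table <- function(obs, lower = 1.025, upper = 1.065) {
  need <- c("treatment_id", "day", "d13ch4_permil", "d13co2_permil")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "))
  d <- obs[!is.na(obs$d13ch4_permil) & !is.na(obs$d13co2_permil), ,
           drop = FALSE]
  if (!nrow(d)) stop("no isotope observations present")
  key <- interaction(d$treatment_id, d$day, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    a <- alpha_app(g$d13co2_permil, g$d13ch4_permil)
    data.frame(treatment_id = g$treatment_id[1],
               initial_sulfate_mM = if ("initial_sulfate_mM" %in% names(g))
                 g$initial_sulfate_mM[1] else NA_real_,
               day = g$day[1], n = nrow(g),
               d13ch4 = mean(g$d13ch4_permil),
               d13co2 = mean(g$d13co2_permil),
               alpha_app = mean(a),
               alpha_se = if (length(a) > 1) stats::sd(a) / sqrt(length(a))
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pathway_class <- classify_pathway(out$alpha_app, lower, upper)
  out[order(out$initial_sulfate_mM, out$treatment_id, out$day), ,
      drop = FALSE]
}
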