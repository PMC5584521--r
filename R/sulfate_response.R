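# Regression of the partition ratio S/M on initial sulfate.
#
# The central empirical claim the pipeline is built to detect: the ratio of
# net sulfate reduced to net methane produced is a linear function of the
# initial sulfate concentration, and the fitted line is stable across the
# whole methane production phase.

#' Fit the sulfate-response regression
#'
#' Ordinary least squares of the partition ratio S/M on initial sulfate
#' concentration, `S/M = intercept + slope * C0`. The intercept is estimated,
#' not forced through the origin. R-squared is the squared Pearson
#' correlation; the p-value is the two-sided t-test on the slope with n - 2
#' degrees of freedom.
#'
#' @param initial_sulfate initial sulfate concentrations, mM (>= 3 points
#'   with nonzero variance).
#' @param sm S/M ratios (same length).
#' @param day optional sampling day the ratios belong to (metadata only).
#' @return An object of class `"sm_fit"`: list with `slope` ((S/M) per mM),
#'   `intercept`, `r_squared`, `p_value`, `slope_se`, `n_points`, `day` and
#'   the underlying `lm` object as `$model`.
#' @examples
#' fit_sm_regression(c(0.5, 2, 4, 10, 15, 25),
#'                   c(0.028, 0.070, 0.270, 1.006, 1.161, 2.094))
#' @export
fit_sm_regression <- function(initial_sulfate, sm, day = NA_real_) {
  stopifnot(is.numeric(initial_sulfate), is.numeric(sm),
            length(initial_sulfate) == length(sm))
  ok <- is.finite(initial_sulfate) & is.finite(sm)
  x <- initial_sulfate[ok]
  y <- sm[ok]
  if (length(x) < 3)
    stop("at least 3 finite points are required")
  if (stats::sd(x) == 0)
    stop("initial sulfate has zero variance; regression is degenerate")
  fit <- stats::lm(y ~ x)
  # exactly collinear data (noise-free validation runs) trip lm's
  # "essentially perfect fit" warning; the fit itself is what we want
  sm_sum <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- stats::coef(sm_sum)
  structure(list(
    slope = cf["x", "Estimate"],
    intercept = cf["(Intercept)", "Estimate"],
    slope_se = cf["x", "Std. Error"],
    p_value = cf["x", "Pr(>|t|)"],
    r_squared = sm_sum$r.squared,
    n_points = length(x),
    day = day,
    model = fit
  ), class = "sm_fit")
}

#' @export
print.sm_fit <- function(x, ...) {
  cat("Sulfate-response regression: S/M ~ initial sulfate\n")
  if (!is.na(x$day)) cat(sprintf("  day %g\n", x$day))
  cat(sprintf("  slope     %.4f (S/M) per mM (SE %.4f, p = %.3g)\n",
              x$slope, x$slope_se, x$p_value))
  cat(sprintf("  intercept %.4f\n", x$intercept))
  cat(sprintf("  R-squared %.3f over %d points\n", x$r_squared, x$n_points))
  invisible(x)
}

#' @export
coef.sm_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.sm_fit <- function(object, ...) summary(object$model, ...)

#' @export
predict.sm_fit <- function(object, initial_sulfate, ...) {
  if (missing(initial_sulfate))
    return(stats::predict(object$model))
  object$intercept + object$slope * initial_sulfate
}

#' Per-day S/M table from an observation time series
#'
#' Background-corrects methane and sulfate at every sampled day and forms
#' the per-replicate partition ratio S/M. Days on which any replicate has
#' non-positive net methane (pre-lag) are dropped with a message rather than
#' producing unstable ratios.
#'
#' @inheritParams replicate_balances
#' @param days optional subset of sampling days to keep.
#' @return Data frame with columns `treatment_id`, `initial_sulfate_mM`,
#'   `replicate_id`, `day`, `M`, `S`, `sm`.
#' @export
sm_table <- function(obs, days = NULL,
                     background_methane = 0.66,
                     background_sulfate = 0.096,
                     liquid_volume = 0.2) {
  need <- c("treatment_id", "initial_sulfate_mM", "replicate_id", "day",
            "methane_mmol", "sulfate_mmol")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "))
  d <- obs[!is.na(obs$methane_mmol) & !is.na(obs$sulfate_mmol), ,
           drop = FALSE]
  if (!is.null(days)) d <- d[d$day %in% days, , drop = FALSE]
  M <- suppressWarnings(net_methane(d$methane_mmol, background_methane))
  consumed_raw <- pmax(d$initial_sulfate_mM * liquid_volume -
                         d$sulfate_mmol, 0)
  S <- suppressWarnings(net_sulfate(consumed_raw, background_sulfate))
  out <- data.frame(treatment_id = d$treatment_id,
                    initial_sulfate_mM = d$initial_sulfate_mM,
                    replicate_id = d$replicate_id,
                    day = d$day, M = M, S = S,
                    stringsAsFactors = FALSE)
  bad_days <- unique(out$day[out$M <= 0])
  if (length(bad_days)) {
    message("dropping day(s) with non-positive net methane (pre-lag): ",
            paste(sort(bad_days), collapse = ", "))
    out <- out[!out$day %in% bad_days, , drop = FALSE]
  }
  out$sm <- sm_ratio(out$M, out$S)
  rownames(out) <- NULL
  out
}

#' Fit the sulfate-response regression at each sampling day
#'
#' @inheritParams sm_table
#' @param use_means if `TRUE`, regress on treatment means instead of
#'   per-replicate points; default `FALSE`.
#' @return List of `"sm_fit"` objects, named by day.
#' @export
fit_sm_by_day <- function(obs, days = NULL,
                          background_methane = 0.66,
                          background_sulfate = 0.096,
                          liquid_volume = 0.2,
                          use_means = FALSE) {
  tab <- sm_table(obs, days = days,
                  background_methane = background_methane,
                  background_sulfate = background_sulfate,
                  liquid_volume = liquid_volume)
  fits <- lapply(split(tab, tab$day), function(d) {
    if (use_means) {
      agg <- stats::aggregate(sm ~ initial_sulfate_mM, data = d, FUN = mean)
      fit_sm_regression(agg$initial_sulfate_mM, agg$sm, day = d$day[1])
    } else {
      fit_sm_regression(d$initial_sulfate_mM, d$sm, day = d$day[1])
    }
  })
  fits[order(as.numeric(names(fits)))]
}

#' Stability of the sulfate-response slope across days
#'
#' Summarises a set of per-day regressions: slope range, maximum pairwise
#' slope difference, and a stability flag based on the max/min slope ratio.
#'
#' @param fits list of `"sm_fit"` objects (>= 2), e.g. from
#'   [fit_sm_by_day()].
#' @param max_ratio largest tolerated max/min slope ratio before the
#'   partition is flagged unstable; default 1.5.
#' @return List with `slope_min`, `slope_max`, `max_diff`, `stable`, and a
#'   per-day `table` (day, slope, intercept, r_squared, p_value, n_points).
#' @export
slope_stability <- function(fits, max_ratio = 1.5) {
  if (length(fits) < 2)
    stop("at least 2 per-day fits are required")
  stopifnot(all(vapply(fits, inherits, logical(1), "sm_fit")))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(day = f$day, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, p_value = f$p_value,
               n_points = f$n_points)))
  rownames(tab) <- NULL
  s <- tab$slope
  ratio <- if (min(s) > 0) max(s) / min(s) else Inf
  list(slope_min = min(s), slope_max = max(s),
       max_diff = max(s) - min(s),
       stable = is.finite(ratio) && ratio <= max_ratio,
       table = tab)
}
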