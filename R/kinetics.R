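# Logistic fitting of cumulative methane production curves.
#
# The cumulative curve is modelled as y(t) = a / (1 + exp(-k (t - tc))),
# a three-parameter sigmoid. The maximum specific methane production rate
# mu_max is identified with the rate constant k: for the logistic the
# per-capita rate (1/y) dy/dt = k (1 - y/a), whose supremum over the curve
# is reached in the y -> 0 limit and equals k. Time is converted from days
# to months before fitting so k is expressed in month^-1.

#' Fit a logistic model to a cumulative methane curve
#'
#' Least-squares fit of `y(t) = a / (1 + exp(-k (t - tc)))` by
#' Levenberg-Marquardt (via \pkg{minpack.lm}), with a deterministic
#' initialisation: `a0 = 1.05 max(y)`, `tc0` the first time the curve
#' crosses `a0 / 2` (linearly interpolated), and `k0` from the slope of a
#' logit-transformed linear regression. No random restarts are used by
#' default, so the fit is reproducible without a seed.
#'
#' Non-convergence (including degenerate flat series) yields a result with
#' `converged = FALSE` carrying the diagnostics rather than an error, so
#' batch fitting over many replicates does not abort.
#'
#' @param days time since inoculation, days (>= 4 distinct values).
#' @param methane cumulative methane, mmol (>= 0).
#' @param month_days days per month used for unit conversion; default
#'   30.4375 (Julian year / 12).
#' @param baseline optional constant background methane (mmol) subtracted
#'   before fitting; default `NULL` (fit the raw production curve).
#' @param restarts number of additional jittered restarts around the
#'   deterministic start (best RSS wins); requires a set seed for
#'   reproducibility. Default 0.
#' @param maxiter,ftol Levenberg-Marquardt control: iteration cap and
#'   relative RSS tolerance.
#' @return An object of class `"logistic_fit"`: list with `a` (mmol),
#'   `tc_days` (days), `k` (month^-1), `mu_max` (= `k`), `rss` (mmol^2),
#'   `converged`, `n_points`, `month_days`, and the data used.
#' @seealso [predict.logistic_fit()], [mu_max()]
#' @examples
#' t <- seq(0, 420, by = 30)
#' y <- 2.86 / (1 + exp(-0.41 * (t - 250) / 30.4375))
#' fit_logistic(t, y)
#' @export
fit_logistic <- function(days, methane, month_days = 30.4375,
                         baseline = NULL, restarts = 0,
                         maxiter = 1000, ftol = 1e-10) {
  stopifnot(is.numeric(days), is.numeric(methane),
            length(days) == length(methane))
  ok <- !is.na(days) & !is.na(methane)
  days <- days[ok]
  methane <- methane[ok]
  if (length(unique(days)) < 4)
    stop("at least 4 distinct time points are required")
  if (any(methane < 0))
    stop("methane amounts must be non-negative")
  if (!is.null(baseline)) methane <- methane - baseline

  tm <- days / month_days
  ymax <- max(methane)
  failed <- function() {
    structure(list(a = NA_real_, tc_days = NA_real_, k = NA_real_,
                   mu_max = NA_real_, rss = sum((methane - mean(methane))^2),
                   converged = FALSE, n_points = length(days),
                   month_days = month_days,
                   data = data.frame(day = days, methane = methane)),
              class = "logistic_fit")
  }
  if (ymax <= 0 || stats::sd(methane) < 1e-12 * max(1, ymax))
    return(failed())

  # deterministic initialisation
  a0 <- 1.05 * ymax
  ord <- order(tm)
  ts <- tm[ord]; ys <- methane[ord]
  above <- which(ys >= a0 / 2)
  tc0 <- if (length(above)) {
    i <- above[1]
    if (i == 1) ts[1]
    else ts[i - 1] + (a0 / 2 - ys[i - 1]) / (ys[i] - ys[i - 1]) *
      (ts[i] - ts[i - 1])
  } else stats::median(ts)
  z <- stats::qlogis(pmin(pmax(ys / a0, 1e-6), 1 - 1e-6))
  k0 <- tryCatch(unname(stats::coef(stats::lm(z ~ ts))[2]),
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1

  starts <- list(c(a = a0, k = k0, tc = tc0))
  if (restarts > 0) {
    for (i in seq_len(restarts)) {
      jit <- stats::runif(3, 0.5, 1.5)
      starts[[i + 1]] <- c(a = a0 * jit[1], k = k0 * jit[2],
                           tc = tc0 * jit[3])
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a / (1 + exp(-k * (t - tc))),
        data = list(y = methane, t = tm),
        start = as.list(st),
        control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol),
        lower = c(a = 1e-12, k = 1e-12, tc = -Inf)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(failed())

  cf <- stats::coef(best$fit)
  conv <- isTRUE(best$fit$convInfo$isConv) && cf[["a"]] > 0 && cf[["k"]] > 0
  structure(list(a = unname(cf[["a"]]),
                 tc_days = unname(cf[["tc"]]) * month_days,
                 k = unname(cf[["k"]]),
                 mu_max = unname(cf[["k"]]),
                 rss = best$rss,
                 converged = conv,
                 n_points = length(days),
                 month_days = month_days,
                 data = data.frame(day = days, methane = methane)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic methane production fit\n")
  if (!x$converged) cat("  ** did not converge **\n")
  cat(sprintf("  amplitude a : %.4g mmol\n", x$a))
  cat(sprintf("  midpoint tc : %.4g days\n", x$tc_days))
  cat(sprintf("  rate k = mu_max: %.4g month^-1\n", x$k))
  cat(sprintf("  RSS %.4g mmol^2 over %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(a = object$a, k = object$k, tc_days = object$tc_days,
    mu_max = object$mu_max)
}

#' Predict cumulative methane from a logistic fit
#'
#' @param object a converged `"logistic_fit"`.
#' @param days time points (days) at which to evaluate the fitted curve;
#'   default the fitted data's days.
#' @param ... unused.
#' @return Predicted cumulative methane (mmol); non-decreasing in `days` and
#'   bounded by the amplitude `a`.
#' @export
predict.logistic_fit <- function(object, days = object$data$day, ...) {
  if (!object$converged)
    stop("cannot predict from a non-converged logistic fit")
  tm <- days / object$month_days
  object$a / (1 + exp(-object$k * (tm - object$tc_days / object$month_days)))
}

#' @export
fitted.logistic_fit <- function(object, ...) {
  predict.logistic_fit(object)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$data$methane - predict.logistic_fit(object)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  out <- c(coef(object),
           rss = object$rss, n = object$n_points,
           converged = as.numeric(object$converged))
  class(out) <- "summary.logistic_fit"
  out
}

#' @export
print.summary.logistic_fit <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Maximum specific methane production rate
#'
#' @param fit a `"logistic_fit"` object.
#' @return mu_max in month^-1 (the fitted logistic rate constant).
#' @export
mu_max <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  fit$mu_max
}

#' Fit logistic curves for every replicate in an observation table
#'
#' @inheritParams replicate_balances
#' @inheritParams fit_logistic
#' @return Data frame, one row per treatment x replicate, with the logistic
#'   parameters, RSS and convergence flag.
#' @export
fit_kinetics_table <- function(obs, month_days = 30.4375, baseline = NULL) {
  key <- interaction(obs$treatment_id, obs$replicate_id, drop = TRUE)
  rows <- lapply(split(obs, key), function(d) {
    d <- d[!is.na(d$methane_mmol), , drop = FALSE]
    fit <- tryCatch(
      fit_logistic(d$day, d$methane_mmol, month_days = month_days,
                   baseline = baseline),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(treatment_id = d$treatment_id[1],
               initial_sulfate_mM = d$initial_sulfate_mM[1],
               replicate_id = d$replicate_id[1],
               a = fit$a, tc_days = fit$tc_days, k = fit$k,
               mu_max = fit$mu_max, rss = fit$rss,
               converged = fit$converged, n_points = fit$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$initial_sulfate_mM, out$replicate_id), , drop = FALSE]
}
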