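# Ingest, orchestration and report writing.
#
# The pipeline consumes a long observation CSV (one row per treatment x
# replicate x day) and produces a small bundle of TSV tables: the
# treatment-level growth/balance summary, the pathway contributions and
# electron-flow split, the per-day sulfate-response regression, the
# fractionation-factor trajectory, and the per-replicate logistic kinetics.
# Full precision is kept internally; rounding (1 dp for percentages, 2 dp
# for ratios, 3 dp for fractionation factors) is applied only at
# serialisation.

OBS_COLUMNS <- c("treatment_id", "initial_sulfate_mM", "replicate_id",
                 "day", "methane_mmol", "sulfate_mmol")

#' Read a culture observation table
#'
#' Reads and validates the standard long-format CSV schema: required columns
#' `treatment_id`, `initial_sulfate_mM`, `replicate_id`, `day`,
#' `methane_mmol`, and either `sulfate_mmol` or `sulfate_mM` (the latter is
#' converted to mmol with the configured liquid volume); optional columns
#' `d13ch4_permil`, `d13co2_permil`, `hexadecane_mmol`. Schema violations
#' are reported with the offending column or row numbers; non-monotone
#' methane within a replicate is a warning, not an error.
#'
#' @param path CSV file path.
#' @param liquid_volume culture liquid volume in litres, used to convert
#'   `sulfate_mM` to mmol on ingest; default 0.2.
#' @return Validated observation data frame.
#' @export
read_observations <- function(path, liquid_volume = 0.2) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observations(obs, liquid_volume = liquid_volume)
}

#' Validate an in-memory observation table
#'
#' @param obs observation data frame; see [read_observations()] for the
#'   schema.
#' @inheritParams read_observations
#' @return The validated (possibly unit-normalised) data frame.
#' @export
validate_observations <- function(obs, liquid_volume = 0.2) {
  if ("sulfate_mM" %in% names(obs) && !"sulfate_mmol" %in% names(obs))
    obs$sulfate_mmol <- obs$sulfate_mM * liquid_volume
  miss <- setdiff(OBS_COLUMNS, names(obs))
  if (length(miss))
    stop("observation table is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.na(obs$day) & obs$day < 0)
  if (length(bad))
    stop("negative day in row(s): ", paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.na(obs$methane_mmol) & obs$methane_mmol < 0)
  if (length(bad))
    stop("negative methane in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!is.na(obs$sulfate_mmol) & obs$sulfate_mmol < 0)
  if (length(bad))
    stop("negative sulfate in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- interaction(obs$treatment_id, obs$replicate_id, drop = TRUE)
  for (d in split(obs, key)) {
    d <- d[!is.na(d$methane_mmol), , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    if (nrow(d) > 1 && any(diff(d$methane_mmol) < 0))
      warning("non-monotone methane series in replicate ",
              d$treatment_id[1], "/", d$replicate_id[1], call. = FALSE)
  }
  obs
}

#' Write an observation table to CSV
#'
#' @param obs observation data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(obs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles every convention the report depends on; the defaults reproduce
#' the standard hexadecane-culture setup (0.34 mmol dose in 0.2 l, control
#' backgrounds 0.66 mmol methane and 0.096 mmol sulfate, 30.4375-day month,
#' fractionation thresholds 1.025/1.065).
#'
#' @param alkane alkane formula string or [alkane_formula()] object.
#' @param alkane_total dosed alkane per culture, mmol.
#' @param liquid_volume culture liquid volume, litres.
#' @param background_methane,background_sulfate control corrections, mmol.
#' @param month_days days per month for the kinetics fit.
#' @param alpha_lower,alpha_upper pathway-classification thresholds.
#' @param regression_days optional subset of days for the sulfate-response
#'   regression; default all post-lag days.
#' @param clip_negative clip negative net values to zero; default `FALSE`.
#' @param fit_baseline optional constant baseline subtracted before the
#'   logistic fit; default `NULL` (fit the raw curve).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(alkane = "C16H34",
                       alkane_total = 0.34,
                       liquid_volume = 0.2,
                       background_methane = 0.66,
                       background_sulfate = 0.096,
                       month_days = 30.4375,
                       alpha_lower = 1.025,
                       alpha_upper = 1.065,
                       regression_days = NULL,
                       clip_negative = FALSE,
                       fit_baseline = NULL) {
  structure(list(alkane = as_alkane(alkane),
                 alkane_total = alkane_total,
                 liquid_volume = liquid_volume,
                 background_methane = background_methane,
                 background_sulfate = background_sulfate,
                 month_days = month_days,
                 alpha_lower = alpha_lower, alpha_upper = alpha_upper,
                 regression_days = regression_days,
                 clip_negative = clip_negative,
                 fit_baseline = fit_baseline),
            class = "run_config")
}

round_cols <- function(df, digits) {
  for (nm in names(digits)) {
    hit <- grep(nm, names(df), value = TRUE)
    for (h in hit) if (is.numeric(df[[h]])) df[[h]] <- round(df[[h]], digits[[nm]])
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full partitioning report
#'
#' Orchestrates ingest, mass balance, kinetics, isotopes and the
#' sulfate-response regression over one observation table and writes the
#' report bundle to `out_dir`:
#' \describe{
#'   \item{balance_summary.tsv}{treatment-level means and SEs of alkane
#'     consumed, sulfate reduced, methane produced, carbon recovery, the
#'     combined product ratio and mu_max.}
#'   \item{contributions.tsv}{pathway contributions (alkane-normalised
#'     `E_M`/`E_S`, summing to recovery) and the electron-flow split
#'     (`flow_M`/`flow_S`, summing to 100), labelled distinctly.}
#'   \item{sm_regression.tsv}{per-day slope, intercept, R-squared and
#'     p-value of S/M vs initial sulfate, plus the stability summary.}
#'   \item{alpha.tsv}{per treatment and day: mean deltas, alpha_app and the
#'     pathway class.}
#'   \item{kinetics.tsv}{per-replicate logistic parameters.}
#'   \item{run_log.txt}{package version, configuration echo and hash.}
#' }
#' Outputs are deterministic for a given input and configuration; rounding
#' happens only at serialisation.
#'
#' @param input path to an observation CSV, or an already-validated
#'   observation data frame.
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()] object.
#' @return Invisibly, a list with the computed tables (`balances`,
#'   `summary`, `kinetics`, `alpha`, `sm_fits`, `stability`).
#' @export
run_report <- function(input, out_dir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  obs <- if (is.character(input))
    read_observations(input, config$liquid_volume)
  else validate_observations(input, config$liquid_volume)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  balances <- replicate_balances(
    obs, alkane = config$alkane, alkane_total = config$alkane_total,
    background_methane = config$background_methane,
    background_sulfate = config$background_sulfate,
    liquid_volume = config$liquid_volume,
    clip_negative = config$clip_negative)
  summ <- summarize_treatment(balances)

  kin <- fit_kinetics_table(obs, month_days = config$month_days,
                            baseline = config$fit_baseline)
  mu <- summarize_treatment(kin, stats = "mu_max")

  balance_out <- merge(
    summ[, c("treatment_id", "initial_sulfate_mM", "n",
             "alkane_consumed_mean", "alkane_consumed_se",
             "S_mean", "S_se", "M_mean", "M_se",
             "recovery_mean", "recovery_se",
             "combined_ratio_mean", "combined_ratio_se")],
    mu[, c("treatment_id", "mu_max_mean", "mu_max_se")],
    by = "treatment_id", all.x = TRUE)
  balance_out <- balance_out[order(balance_out$initial_sulfate_mM), ]
  balance_out <- round_cols(balance_out,
                            c(recovery = 1, ratio = 2, mu_max = 2,
                              alkane_consumed = 3, "^S_" = 3, "^M_" = 3))
  write_tsv(balance_out, file.path(out_dir, "balance_summary.tsv"))

  contrib_out <- summ[, c("treatment_id", "initial_sulfate_mM", "n",
                          "E_M_mean", "E_M_se", "E_S_mean", "E_S_se",
                          "flow_M_mean", "flow_M_se",
                          "flow_S_mean", "flow_S_se",
                          "sm_ratio_mean", "sm_ratio_se")]
  contrib_out <- round_cols(contrib_out,
                            c(E_M = 1, E_S = 1, flow = 1, sm_ratio = 2))
  write_tsv(contrib_out, file.path(out_dir, "contributions.tsv"))

  sm_fits <- fit_sm_by_day(obs, days = config$regression_days,
                           background_methane = config$background_methane,
                           background_sulfate = config$background_sulfate,
                           liquid_volume = config$liquid_volume)
  stability <- if (length(sm_fits) >= 2) slope_stability(sm_fits) else NULL
  sm_out <- do.call(rbind, lapply(sm_fits, function(f)
    data.frame(day = f$day, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, p_value = f$p_value,
               n_points = f$n_points)))
  rownames(sm_out) <- NULL
  write_tsv(round_cols(sm_out, c(slope = 4, intercept = 4, r_squared = 3)),
            file.path(out_dir, "sm_regression.tsv"))

  alpha <- tryCatch(
    alpha_table(obs, config$alpha_lower, config$alpha_upper),
    error = function(e) NULL)
  if (!is.null(alpha))
    write_tsv(round_cols(alpha, c(alpha = 3, d13 = 1)),
              file.path(out_dir, "alpha.tsv"))

  write_tsv(round_cols(kin, c(a = 3, tc_days = 1, "^k$" = 3, mu_max = 3,
                              rss = 4)),
            file.path(out_dir, "kinetics.tsv"))

  cfg_txt <- utils::capture.output(utils::str(unclass(config)))
  log_lines <- c(
    paste0("alkflux version ",
           as.character(utils::packageVersion("alkflux"))),
    paste0("config hash ",
           sum(utf8ToInt(paste(cfg_txt, collapse = "\n"))) %% 1000000L),
    cfg_txt)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(balances = balances, summary = summ, kinetics = kin,
                 alpha = alpha, sm_fits = sm_fits, stability = stability))
}

#' Packaged endpoint treatment means
#'
#' Loads the plain-text fixture shipped with the package transcribing the
#' endpoint treatment-level means and standard errors (n = 2-3 replicates)
#' of a 421-day hexadecane enrichment incubated at six initial sulfate
#' concentrations: alkane consumed, background-corrected sulfate consumed
#' and methane produced, carbon recovery, mu_max and the combined product
#' ratio.
#'
#' @return Data frame, one row per sulfate treatment.
#' @export
endpoint_means <- function() {
  utils::read.csv(system.file("extdata",
                              "hexadecane_culture_endpoint_means.csv",
                              package = "alkflux", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Packaged isotope plateau values
#'
#' End-of-incubation plateau delta 13C values of CH4 and CO2 for the
#' low-sulfate (0.5-4 mM) and high-sulfate (10-25 mM) culture groups.
#'
#' @return Data frame with columns `group`, `d13ch4_permil`,
#'   `d13co2_permil` (and their SEs).
#' @export
isotope_plateaus <- function() {
  utils::read.csv(system.file("extdata", "isotope_plateaus.csv",
                              package = "alkflux", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
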