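# Background-corrected mass balance and electron-flow accounting.
#
# Endpoint observations are turned into net methane produced (M) and net
# sulfate reduced (S) by subtracting the turnover of substrate-free control
# cultures, then into the derived partition statistics: carbon recovery,
# per-pathway contributions normalised to the alkane consumed, the
# electron-flow split M/(M+S) vs S/(M+S), and the partition ratio S/M.
# Two distinct percentage accountings coexist deliberately: the electron-flow
# split normalises by total measured product (and therefore always sums to
# 100), while the pathway contributions normalise by the stoichiometric
# equivalents of the alkane actually consumed (and therefore sum to the
# carbon recovery). Both are reported, labelled distinctly.

warn_negative <- function(x, what) {
  neg <- !is.na(x) & x < 0
  if (any(neg))
    warning(sum(neg), " negative net ", what,
            " value(s) after background correction; returned as-is",
            call. = FALSE)
  x
}

#' Net methane produced
#'
#' Detected cumulative headspace methane minus the background methane
#' accumulated by substrate-free control cultures (default 0.66 mmol).
#' Negative results are returned as-is with a warning so that questionable
#' background corrections stay visible.
#'
#' @param detected detected methane, mmol (>= 0).
#' @param background control-culture methane, mmol (>= 0); default 0.66.
#' @return Net methane M in mmol.
#' @export
net_methane <- function(detected, background = 0.66) {
  stopifnot(is.numeric(detected), is.numeric(background))
  if (any(detected < 0, na.rm = TRUE) || any(background < 0))
    stop("methane amounts must be non-negative")
  warn_negative(detected - background, "methane")
}

#' Net sulfate reduced
#'
#' Raw sulfate consumption minus the background consumption of control
#' cultures (default 0.096 mmol).
#'
#' @param consumed_raw raw sulfate consumption (initial minus detected),
#'   mmol (>= 0).
#' @param background control-culture sulfate consumption, mmol; default 0.096.
#' @return Net sulfate reduced S in mmol; negatives flagged, not clipped.
#' @export
net_sulfate <- function(consumed_raw, background = 0.096) {
  stopifnot(is.numeric(consumed_raw), is.numeric(background))
  if (any(consumed_raw < 0, na.rm = TRUE) || any(background < 0))
    stop("sulfate amounts must be non-negative")
  warn_negative(consumed_raw - background, "sulfate")
}

#' Combined product-to-substrate ratio
#'
#' (M + S) per mole of alkane consumed; compared against the theoretical
#' combined yield (12.25 for hexadecane) this measures how completely the
#' consumed substrate is accounted for.
#'
#' @param M net methane, mmol.
#' @param S net sulfate reduced, mmol.
#' @param alkane_consumed alkane consumed, mmol (> 0).
#' @return Dimensionless ratio.
#' @export
combined_ratio <- function(M, S, alkane_consumed) {
  if (any(!is.na(alkane_consumed) & alkane_consumed <= 0))
    stop("`alkane_consumed` must be positive")
  (M + S) / alkane_consumed
}

#' Carbon recovery
#'
#' Percentage of consumed alkane carbon recovered as the combined
#' stoichiometric equivalents of methane produced and sulfate reduced:
#' `100 * combined_ratio / Y`, with `Y` the theoretical combined yield.
#'
#' @param ratio combined product-to-substrate ratio, see [combined_ratio()].
#' @param yields a `"stoich_yields"` object (either pathway), or an alkane
#'   formula/string from which the combined yield is taken.
#' @return Recovery in percent.
#' @export
carbon_recovery <- function(ratio, yields = methanogenic_yields("C16H34")) {
  100 * ratio / theoretical_yield(yields)
}

theoretical_yield <- function(yields) {
  if (inherits(yields, "stoich_yields")) {
    y <- max(yields$ch4_per_alkane, yields$sulfate_per_alkane)
  } else {
    y <- combined_yield(yields)
  }
  if (y <= 0) stop("theoretical combined yield must be positive")
  y
}

#' Pathway contributions normalised to alkane consumed
#'
#' The percentage of degraded alkane routed through each pathway, in units of
#' the stoichiometric maximum: `E_M = 100 M / (Y * alkane_consumed)` and
#' `E_S = 100 S / (Y * alkane_consumed)`. By construction
#' `E_M + E_S = carbon recovery`, so the two contributions only sum to 100
#' when the balance closes perfectly.
#'
#' @inheritParams combined_ratio
#' @inheritParams carbon_recovery
#' @return Data frame with columns `E_M` and `E_S` (percent).
#' @export
pathway_contributions <- function(M, S, alkane_consumed,
                                  yields = methanogenic_yields("C16H34")) {
  if (any(!is.na(alkane_consumed) & alkane_consumed <= 0))
    stop("`alkane_consumed` must be positive")
  y <- theoretical_yield(yields)
  data.frame(E_M = 100 * M / (y * alkane_consumed),
             E_S = 100 * S / (y * alkane_consumed))
}

#' Electron-flow split between methanogenesis and sulfate reduction
#'
#' The classic partition of electron flow between the two sinks, in percent
#' of total measured product: `100 M / (M + S)` via methane and
#' `100 S / (M + S)` via sulfate. Always sums to 100. Both currencies carry
#' 8 electron equivalents per mole, which is what licenses comparing mol CH4
#' with mol SO4 directly.
#'
#' @param M net methane, mmol.
#' @param S net sulfate reduced, mmol.
#' @return Data frame with columns `flow_M` and `flow_S` (percent).
#' @export
electron_flow_split <- function(M, S) {
  tot <- M + S
  if (any(!is.na(tot) & tot <= 0))
    stop("electron-flow split undefined when M + S <= 0")
  data.frame(flow_M = 100 * M / tot, flow_S = 100 * S / tot)
}

#' Sulfate reduction to methane production ratio
#'
#' @inheritParams electron_flow_split
#' @return S/M, dimensionless.
#' @export
sm_ratio <- function(M, S) {
  if (any(!is.na(M) & M <= 0))
    stop("S/M ratio undefined when M <= 0")
  S / M
}

#' Per-replicate net balances from endpoint observations
#'
#' Reduces an observation table (see [read_observations()] for the schema) to
#' one row per treatment x replicate containing the background-corrected net
#' quantities and every derived partition statistic. The endpoint is the last
#' day with a methane measurement in each replicate.
#'
#' @param obs observation data frame with columns `treatment_id`,
#'   `initial_sulfate_mM`, `replicate_id`, `day`, `methane_mmol`,
#'   `sulfate_mmol`, and optionally `hexadecane_mmol` (residual alkane,
#'   endpoint only).
#' @param alkane alkane formula or [alkane_formula()] object; default
#'   hexadecane.
#' @param alkane_total total alkane dosed per culture, mmol; default 0.34.
#' @param background_methane,background_sulfate control-culture corrections,
#'   mmol; defaults 0.66 and 0.096.
#' @param liquid_volume culture liquid volume in litres (converts initial
#'   sulfate mM to mmol); default 0.2.
#' @param clip_negative if `TRUE`, negative net values are set to 0 instead
#'   of propagated; default `FALSE`.
#' @return Data frame, one row per replicate, with columns `treatment_id`,
#'   `initial_sulfate_mM`, `replicate_id`, `day`, `M`, `S`,
#'   `alkane_consumed`, `combined_ratio`, `recovery`, `E_M`, `E_S`,
#'   `flow_M`, `flow_S`, `sm_ratio`.
#' @export
replicate_balances <- function(obs,
                               alkane = alkane_formula("C16H34"),
                               alkane_total = 0.34,
                               background_methane = 0.66,
                               background_sulfate = 0.096,
                               liquid_volume = 0.2,
                               clip_negative = FALSE) {
  need <- c("treatment_id", "initial_sulfate_mM", "replicate_id", "day",
            "methane_mmol", "sulfate_mmol")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation table is missing column(s): ",
         paste(miss, collapse = ", "))
  yields <- methanogenic_yields(as_alkane(alkane))
  has_hex <- "hexadecane_mmol" %in% names(obs)

  key <- interaction(obs$treatment_id, obs$replicate_id, drop = TRUE)
  rows <- lapply(split(obs, key), function(d) {
    d <- d[!is.na(d$methane_mmol), , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    if (!nrow(d)) return(NULL)
    if (is.unsorted(d$methane_mmol, strictly = FALSE) &&
        any(diff(d$methane_mmol) < 0))
      warning("non-monotone methane series in replicate ",
              d$treatment_id[1], "/", d$replicate_id[1], call. = FALSE)
    end <- d[nrow(d), , drop = FALSE]
    consumed_raw <- end$initial_sulfate_mM * liquid_volume - end$sulfate_mmol
    consumed_raw <- max(consumed_raw, 0)
    M <- net_methane(end$methane_mmol, background_methane)
    S <- net_sulfate(consumed_raw, background_sulfate)
    if (clip_negative) {
      M <- max(M, 0)
      S <- max(S, 0)
    }
    hex_cons <- if (has_hex && !is.na(end$hexadecane_mmol))
      alkane_total - end$hexadecane_mmol else NA_real_
    data.frame(treatment_id = end$treatment_id,
               initial_sulfate_mM = end$initial_sulfate_mM,
               replicate_id = end$replicate_id,
               day = end$day, M = M, S = S,
               alkane_consumed = hex_cons,
               stringsAsFactors = FALSE)
  })
  bal <- do.call(rbind, rows)
  rownames(bal) <- NULL
  bal$combined_ratio <- combined_ratio(bal$M, bal$S, bal$alkane_consumed)
  bal$recovery <- carbon_recovery(bal$combined_ratio, yields)
  contr <- pathway_contributions(bal$M, bal$S, bal$alkane_consumed, yields)
  bal$E_M <- contr$E_M
  bal$E_S <- contr$E_S
  flow <- electron_flow_split(bal$M, bal$S)
  bal$flow_M <- flow$flow_M
  bal$flow_S <- flow$flow_S
  bal$sm_ratio <- sm_ratio(bal$M, bal$S)
  bal[order(bal$initial_sulfate_mM, bal$replicate_id), , drop = FALSE]
}

#' Treatment-level summary (mean and standard error)
#'
#' Averages per-replicate statistics within treatments. Every statistic is
#' computed per replicate first and then averaged — the order matters for
#' ratios, where the mean of per-replicate ratios is not the ratio of means.
#'
#' @param balances per-replicate balance table from [replicate_balances()].
#' @param stats character vector of statistic columns to summarise.
#' @return Data frame, one row per treatment, with `<stat>_mean` and
#'   `<stat>_se` columns (`se = sd / sqrt(n)`; `NA` for a single replicate).
#' @export
summarize_treatment <- function(balances,
                                stats = c("alkane_consumed", "S", "M",
                                          "combined_ratio", "recovery",
                                          "E_M", "E_S", "flow_M", "flow_S",
                                          "sm_ratio")) {
  if (!nrow(balances)) stop("empty balance table")
  stats <- intersect(stats, names(balances))
  rows <- lapply(split(balances, balances$treatment_id), function(d) {
    out <- data.frame(treatment_id = d$treatment_id[1],
                      initial_sulfate_mM = d$initial_sulfate_mM[1],
                      n = nrow(d), stringsAsFactors = FALSE)
    for (s in stats) {
      x <- d[[s]][!is.na(d[[s]])]
      out[[paste0(s, "_mean")]] <- if (length(x)) mean(x) else NA_real_
      out[[paste0(s, "_se")]] <- if (length(x) > 1)
        stats::sd(x) / sqrt(length(x)) else NA_real_
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$initial_sulfate_mM), , drop = FALSE]
}
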