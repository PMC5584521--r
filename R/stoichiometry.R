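# Balanced stoichiometry of complete anaerobic n-alkane oxidation.
#
# All coefficients of both pathways are exact multiples of 1/4, so they are
# carried internally as integer numerators over a fixed denominator of 4
# ("quarters") and only exported as decimals. Element and charge balances can
# then be checked in integer arithmetic, with no floating-point drift.

#' Parse an n-alkane molecular formula
#'
#' Accepts formulas of the form `C<n>H<m>` (e.g. `"C16H34"`; `"CH4"` is read
#' as `C1H4`) and validates that the composition is a saturated acyclic
#' alkane, i.e. `m = 2n + 2`. Anything else — including general hydrocarbons
#' or oxygenated species — is rejected rather than silently computed.
#'
#' @param text a single formula string such as `"C16H34"`.
#' @return An object of class `"alkane_formula"`: a list with integer fields
#'   `n_carbon` and `n_hydrogen`.
#' @examples
#' alkane_formula("C16H34")
#' alkane_formula("CH4")
#' @export
alkane_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("`text` must be a single formula string like \"C16H34\"")
  m <- regmatches(text, regexec("^C([0-9]*)H([0-9]+)$", text))[[1]]
  if (length(m) == 0L)
    stop("malformed alkane formula: ", sQuote(text),
         " (expected the pattern C<n>H<m>)")
  n_c <- if (m[2] == "") 1L else as.integer(m[2])
  n_h <- as.integer(m[3])
  if (is.na(n_c) || n_c < 1L)
    stop("alkane must contain at least one carbon atom")
  if (n_h != 2L * n_c + 2L)
    stop(sQuote(text), " is not a saturated n-alkane: expected H = 2n + 2 = ",
         2L * n_c + 2L, ", got ", n_h)
  structure(list(n_carbon = n_c, n_hydrogen = n_h),
            class = "alkane_formula")
}

#' @export
print.alkane_formula <- function(x, ...) {
  cat(sprintf("n-alkane C%dH%d (molar mass %.2f g/mol)\n",
              x$n_carbon, x$n_hydrogen, alkane_molar_mass(x)))
  invisible(x)
}

as_alkane <- function(x) {
  if (inherits(x, "alkane_formula")) return(x)
  if (is.character(x)) return(alkane_formula(x))
  stop("`alkane` must be an alkane_formula object or a formula string")
}

#' Molar mass of an alkane
#'
#' @param alkane an [alkane_formula()] object or formula string.
#' @return Molar mass in g/mol (IUPAC standard atomic weights C 12.011,
#'   H 1.008).
#' @export
alkane_molar_mass <- function(alkane) {
  a <- as_alkane(alkane)
  12.011 * a$n_carbon + 1.008 * a$n_hydrogen
}

# Exact coefficients (numerators over 4) for one pathway. Sign convention:
# h2o_q < 0 means water consumed; sulfate and H+ quantities are reported as
# positive amounts consumed.
yield_quarters <- function(n, pathway) {
  switch(pathway,
    methanogenic = c(ch4 = 3L * n + 1L, co2 = n - 1L,
                     h2o = -(2L * n - 2L), sulfate = 0L, h2s = 0L,
                     h_plus = 0L),
    sulfidogenic = c(ch4 = 0L, co2 = 4L * n, h2o = 4L * n + 4L,
                     sulfate = 3L * n + 1L, h2s = 3L * n + 1L,
                     h_plus = 6L * n + 2L),
    stop("unknown pathway: ", pathway))
}

new_stoich_yields <- function(alkane, pathway) {
  n <- alkane$n_carbon
  q <- yield_quarters(n, pathway)
  structure(list(
    pathway              = pathway,
    n_carbon             = n,
    ch4_per_alkane       = q[["ch4"]] / 4,
    co2_per_alkane       = q[["co2"]] / 4,
    h2o_per_alkane       = q[["h2o"]] / 4,
    sulfate_per_alkane   = q[["sulfate"]] / 4,
    h2s_per_alkane       = q[["h2s"]] / 4,
    h_plus_per_alkane    = q[["h_plus"]] / 4,
    electron_equivalents = 6 * n + 2
  ), quarters = q, class = "stoich_yields")
}

#' Stoichiometric yields of complete methanogenic alkane oxidation
#'
#' Balanced coefficients for the complete conversion of a saturated n-alkane
#' to methane and carbon dioxide under methanogenic conditions:
#' \deqn{C_nH_{2n+2} + \frac{n-1}{2} H_2O \rightarrow
#'       \frac{3n+1}{4} CH_4 + \frac{n-1}{4} CO_2.}
#' For hexadecane this gives 12.25 CH4 and 3.75 CO2 per mole, with 7.5 mol
#' water consumed. Cell growth is not accounted for.
#'
#' @param alkane an [alkane_formula()] object or formula string.
#' @return An object of class `"stoich_yields"` with per-mole coefficients
#'   `ch4_per_alkane`, `co2_per_alkane`, `h2o_per_alkane` (negative =
#'   consumed), `sulfate_per_alkane`, `h2s_per_alkane`, `h_plus_per_alkane`
#'   (amount consumed), and `electron_equivalents` (mol e- transferred per
#'   mol alkane, `6n + 2`).
#' @seealso [sulfidogenic_yields()], [element_balance()]
#' @examples
#' methanogenic_yields("C16H34")
#' @export
methanogenic_yields <- function(alkane) {
  new_stoich_yields(as_alkane(alkane), "methanogenic")
}

#' Stoichiometric yields of complete sulfate-coupled alkane oxidation
#'
#' Balanced coefficients for complete oxidation of a saturated n-alkane to
#' CO2 with sulfate as the terminal electron acceptor:
#' \deqn{C_nH_{2n+2} + \frac{3n+1}{4} SO_4^{2-} + \frac{3n+1}{2} H^+
#'       \rightarrow \frac{3n+1}{4} H_2S + n\, CO_2 + (n+1) H_2O.}
#' For hexadecane: 12.25 mol sulfate reduced (and H2S formed), 16 CO2 and
#' 17 H2O produced per mole. The sulfate coefficient equals the methane
#' coefficient of [methanogenic_yields()] — both carry `(6n + 2)` electron
#' equivalents at 8 e- per CH4 formed or SO4 reduced — which is what makes
#' methane produced and sulfate reduced directly comparable currencies in
#' the mass balance.
#'
#' @inheritParams methanogenic_yields
#' @return A `"stoich_yields"` object; see [methanogenic_yields()].
#' @examples
#' sulfidogenic_yields("C16H34")
#' @export
sulfidogenic_yields <- function(alkane) {
  new_stoich_yields(as_alkane(alkane), "sulfidogenic")
}

#' Combined theoretical yield
#'
#' The common per-mole coefficient `(3n + 1) / 4` — mol CH4 under complete
#' methanogenesis, equal to mol sulfate under complete sulfidogenesis —
#' against which combined methane production plus sulfate reduction is
#' compared to compute carbon recovery. 12.25 for hexadecane.
#'
#' @inheritParams methanogenic_yields
#' @return A single number, mol/mol.
#' @export
combined_yield <- function(alkane) {
  a <- as_alkane(alkane)
  (3 * a$n_carbon + 1) / 4
}

#' Exact element and charge balance of a yield set
#'
#' Recomputes the full reaction balance in integer arithmetic (products minus
#' reactants, in quarters of a mole) for carbon, hydrogen, oxygen, sulfur and
#' charge. A correctly balanced equation returns exact zeros.
#'
#' @param yields a `"stoich_yields"` object.
#' @return Named numeric vector of residuals `c(C, H, O, S, charge)` in mol
#'   per mol alkane; all exactly 0 for a balanced equation.
#' @export
element_balance <- function(yields) {
  stopifnot(inherits(yields, "stoich_yields"))
  q <- attr(yields, "quarters")
  n <- yields$n_carbon
  h2o_prod <- max(q[["h2o"]], 0L)
  h2o_cons <- max(-q[["h2o"]], 0L)
  res_c <- q[["ch4"]] + q[["co2"]] - 4L * n
  res_h <- (4L * q[["ch4"]] + 2L * q[["h2s"]] + 2L * h2o_prod) -
    (4L * (2L * n + 2L) + 2L * h2o_cons + q[["h_plus"]])
  res_o <- (2L * q[["co2"]] + h2o_prod) -
    (4L * q[["sulfate"]] + h2o_cons)
  res_s <- q[["h2s"]] - q[["sulfate"]]
  res_q <- q[["h_plus"]] - 2L * q[["sulfate"]]
  c(C = res_c, H = res_h, O = res_o, S = res_s, charge = res_q) / 4
}

#' @export
print.stoich_yields <- function(x, ...) {
  cat(sprintf("Complete %s oxidation of C%dH%d (per mol alkane)\n",
              x$pathway, x$n_carbon, 2 * x$n_carbon + 2))
  tab <- data.frame(
    species = c("CH4", "CO2", "H2O", "SO4^2-", "H2S", "H+"),
    mol = c(x$ch4_per_alkane, x$co2_per_alkane, x$h2o_per_alkane,
            -x$sulfate_per_alkane, x$h2s_per_alkane, -x$h_plus_per_alkane),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$mol != 0, , drop = FALSE]
  tab$role <- ifelse(tab$mol > 0, "produced", "consumed")
  print(tab, row.names = FALSE)
  cat(sprintf("electron equivalents: %g mol e-/mol\n",
              x$electron_equivalents))
  invisible(x)
}

#' @export
as.data.frame.stoich_yields <- function(x, ...) {
  data.frame(pathway = x$pathway, n_carbon = x$n_carbon,
             ch4_per_alkane = x$ch4_per_alkane,
             co2_per_alkane = x$co2_per_alkane,
             h2o_per_alkane = x$h2o_per_alkane,
             sulfate_per_alkane = x$sulfate_per_alkane,
             h2s_per_alkane = x$h2s_per_alkane,
             h_plus_per_alkane = x$h_plus_per_alkane,
             electron_equivalents = x$electron_equivalents,
             stringsAsFactors = FALSE)
}

#' Sulfate concentration needed for complete sulfidogenic oxidation
#'
#' Converts an alkane amount into the aqueous sulfate concentration required
#' to oxidise it completely to CO2 by sulfate reduction, given the culture
#' liquid volume. For the standard 0.34 mmol hexadecane dose in 0.2 l of
#' medium this is about 21 mM.
#'
#' @param alkane_amount alkane amount in mmol (> 0).
#' @param alkane an [alkane_formula()] object or formula string; default
#'   hexadecane.
#' @param liquid_volume culture liquid volume in litres (> 0); default 0.2.
#' @return Required sulfate concentration in mM.
#' @examples
#' sulfate_demand(0.34)  # ~21 mM
#' @export
sulfate_demand <- function(alkane_amount, alkane = alkane_formula("C16H34"),
                           liquid_volume = 0.2) {
  if (!is.numeric(alkane_amount) || any(alkane_amount <= 0))
    stop("`alkane_amount` must be positive (mmol)")
  if (!is.numeric(liquid_volume) || length(liquid_volume) != 1L ||
      liquid_volume <= 0)
    stop("`liquid_volume` must be a single positive number (litres)")
  combined_yield(alkane) * alkane_amount / liquid_volume
}

#' Convert a liquid alkane dose to millimoles
#'
#' @param volume_ul dosed volume in microlitres.
#' @param alkane an [alkane_formula()] object or formula string.
#' @param density liquid density in g/ml; the default 0.7734 g/ml is
#'   hexadecane at room temperature.
#' @return Amount in mmol.
#' @examples
#' alkane_dose_mmol(100)  # ~0.34 mmol hexadecane
#' @export
alkane_dose_mmol <- function(volume_ul, alkane = alkane_formula("C16H34"),
                             density = 0.7734) {
  if (!is.numeric(volume_ul) || any(volume_ul <= 0))
    stop("`volume_ul` must be positive")
  volume_ul / 1000 * density / alkane_molar_mass(alkane) * 1000
}

#' Coefficient table for one or both oxidation pathways
#'
#' @inheritParams methanogenic_yields
#' @param pathway `"methanogenic"`, `"sulfidogenic"` or `"both"` (default).
#' @return A data frame, one row per pathway.
#' @export
stoich_table <- function(alkane,
                         pathway = c("both", "methanogenic", "sulfidogenic")) {
  pathway <- match.arg(pathway)
  a <- as_alkane(alkane)
  out <- list()
  if (pathway %in% c("both", "methanogenic"))
    out <- c(out, list(as.data.frame(methanogenic_yields(a))))
  if (pathway %in% c("both", "sulfidogenic"))
    out <- c(out, list(as.data.frame(sulfidogenic_yields(a))))
  do.call(rbind, out)
}
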