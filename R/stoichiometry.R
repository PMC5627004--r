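#' Balance a biomass-coupled hydrocarbon oxidation reaction
#'
#' Element-balances the oxidation of a hydrocarbon CaHb under the fixed
#' convention of 1 mol microbial biomass (empirical formula C5H7O2N) and
#' 1 mol NH3 per mol substrate:
#' \deqn{C_aH_b + x\,O_2 + NH_3 \rightarrow C_5H_7O_2N + y\,CO_2 + z\,H_2O}
#' The carbon, hydrogen and oxygen balances give closed forms
#' `y = a - 5`, `z = (b - 4) / 2`, `x = 1 + y + z / 2`. Benzene (C6H6)
#' yields x = 2.5, y = 1, z = 1; naphthalene (C10H8) yields x = 7, y = 5,
#' z = 2. Substrates with a < 5 or b < 4 cannot supply one mole of biomass
#' and are rejected as infeasible.
#'
#' Coefficients are held internally as exact quarter-integers so element
#' balance can be verified in integer arithmetic (see [element_balance()]).
#'
#' @param a Carbon atoms in the substrate (integer >= 5).
#' @param b Hydrogen atoms in the substrate (integer >= 4).
#' @return An object of class `biomass_reaction` with fields `a`, `b`, `o2`,
#'   `co2`, `h2o`, `biomass` (1), `nh3` (1) and integer quarter-unit
#'   coefficients in `quarters`.
#' @examples
#' balance_biomass_reaction(6, 6)    # benzene
#' balance_biomass_reaction(10, 8)   # naphthalene
#' @export
balance_biomass_reaction <- function(a, b) {
  if (length(a) != 1 || length(b) != 1 || a %% 1 != 0 || b %% 1 != 0) {
    stop("`a` and `b` must be single integers", call. = FALSE)
  }
  if (a < 5 || b < 4) {
    stop(sprintf(paste0(
      "C%dH%d is infeasible under the 1 mol C5H7O2N per mol substrate ",
      "convention: need at least 5 C and 4 H"), a, b), call. = FALSE)
  }
  a <- as.integer(a); b <- as.integer(b)
  co2_q4 <- 4L * (a - 5L)
  h2o_q4 <- 2L * (b - 4L)
  o2_q4 <- 4L + co2_q4 + h2o_q4 %/% 2L

  structure(list(
    a = a, b = b,
    o2 = o2_q4 / 4, co2 = co2_q4 / 4, h2o = h2o_q4 / 4,
    biomass = 1, nh3 = 1,
    quarters = c(o2 = o2_q4, co2 = co2_q4, h2o = h2o_q4)
  ), class = "biomass_reaction")
}

#' Verify element balance of a biomass reaction
#'
#' Counts C, H, O and N atoms on each side in exact integer quarter-units
#' and returns `TRUE` only when every element balances exactly.
#'
#' @param reaction A `biomass_reaction` object.
#' @return Logical scalar; the per-element left/right atom counts (in
#'   quarter-units) are attached as attribute `atoms`.
#' @export
element_balance <- function(reaction) {
  q <- reaction$quarters
  lhs <- c(C = 4L * reaction$a,
           H = 4L * reaction$b + 12L,             # substrate + NH3
           O = 2L * q[["o2"]],
           N = 4L)
  rhs <- c(C = 20L + q[["co2"]],                  # biomass + CO2
           H = 28L + 2L * q[["h2o"]],             # biomass + H2O
           O = 8L + 2L * q[["co2"]] + q[["h2o"]], # biomass + CO2 + H2O
           N = 4L)
  ok <- identical(lhs, rhs)
  structure(ok, atoms = rbind(lhs = lhs, rhs = rhs))
}

#' @export
print.biomass_reaction <- function(x, ...) {
  fmt <- function(v) {
    if (v == 1) "" else sub("\\.?0+$", "", sprintf("%.2f", v))
  }
  cat(sprintf("C%dH%d + %sO2 + NH3 -> C5H7O2N + %sCO2 + %sH2O\n",
              x$a, x$b, fmt(x$o2), fmt(x$co2), fmt(x$h2o)))
  invisible(x)
}

#' @rdname balance_biomass_reaction
#' @param x A `biomass_reaction` object.
#' @param ... Unused.
#' @export
tidy.biomass_reaction <- function(x, ...) {
  tibble::tibble(
    species = c(sprintf("C%dH%d", x$a, x$b), "O2", "NH3", "C5H7O2N", "CO2", "H2O"),
    side = c("reactant", "reactant", "reactant", "product", "product", "product"),
    coefficient = c(1, x$o2, 1, 1, x$co2, x$h2o)
  )
}

#' Observed versus expected CO2 production
#'
#' Compares a measured CO2 production rate with the stoichiometric
#' expectation `reaction$co2 * substrate_rate`. A ratio above 1 indicates
#' less carbon assimilated than the biomass model predicts, or co-oxidation
#' of additional substrates stimulated by the amendment.
#'
#' @param observed_co2_rate Measured CO2 production rate, umol L^-1 d^-1
#'   (> 0).
#' @param substrate_rate Measured substrate oxidation rate, same units (> 0).
#' @param reaction A `biomass_reaction` giving the expected CO2 coefficient
#'   (must be > 0).
#' @return A one-row tibble: `observed_rate`, `expected_rate`, `ratio` (full
#'   precision) and `ratio_2sf` (two significant figures, the convention
#'   used when reporting such excesses).
#' @examples
#' co2_ratio(5.6, 4.3, balance_biomass_reaction(6, 6)) # ratio_2sf 1.3
#' @export
co2_ratio <- function(observed_co2_rate, substrate_rate, reaction) {
  if (observed_co2_rate <= 0 || substrate_rate <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  if (!inherits(reaction, "biomass_reaction")) {
    stop("`reaction` must come from balance_biomass_reaction()", call. = FALSE)
  }
  if (reaction$co2 == 0) {
    stop("reaction produces no CO2; expected rate is zero", call. = FALSE)
  }
  expected <- reaction$co2 * substrate_rate
  ratio <- observed_co2_rate / expected
  tibble::tibble(
    observed_rate = observed_co2_rate,
    expected_rate = expected,
    ratio = ratio,
    ratio_2sf = signif(ratio, 2)
  )
}

#' Parse a hydrocarbon formula of the form "CaHb"
#' @param formula String such as `"C6H6"` or `"C10H8"`.
#' @return Named integer vector `c(a = , b = )`.
#' @export
parse_hydrocarbon <- function(formula) {
  m <- regmatches(formula, regexec("^C([0-9]+)H([0-9]+)$", formula))[[1]]
  if (length(m) != 3) {
    stop("`formula` must look like 'C6H6' (carbons then hydrogens)", call. = FALSE)
  }
  c(a = as.integer(m[2]), b = as.integer(m[3]))
}
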