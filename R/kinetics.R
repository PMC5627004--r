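#' Fit a zero-order oxidation (or production) rate
#'
#' Ordinary least-squares regression of concentration against time; under
#' zero-order kinetics the slope magnitude is the potential rate (a V_max,
#' independent of substrate concentration). Depletion series report
#' `rate = -slope`, production series `rate = +slope`, so a well-behaved
#' series yields a positive rate either way. The standard error and 95%
#' confidence interval come from the t distribution with n - 2 degrees of
#' freedom.
#'
#' @param data A data frame of time-resolved concentrations.
#' @param time,value <[`data-masking`][rlang::args_data_masking]> columns
#'   holding times (days) and concentrations (umol L^-1).
#' @param mode `"depletion"` (default) or `"production"`; controls the sign
#'   fold.
#' @return An object of class `zero_order_fit` with elements `rate`,
#'   `intercept`, `stderr`, `r_squared`, `ci95`, `mode`, `n` and the
#'   underlying `lm` fit. Has [tidy()], [glance()], [autoplot()] and print
#'   methods.
#' @examples
#' d <- simulate_depletion_series(4.3, 0:23, c0 = 300, noise_cv = 0)
#' fit_zero_order_rate(d, time_d, substrate_uM)
#' @export
fit_zero_order_rate <- function(data, time, value,
                                mode = c("depletion", "production")) {
  mode <- match.arg(mode)
  t <- dplyr::pull(data, {{ time }})
  y <- dplyr::pull(data, {{ value }})
  if (length(t) < 3) stop("need at least 3 timepoints to fit a rate", call. = FALSE)
  if (length(unique(t)) < 2) stop("times have zero variance", call. = FALSE)

  fit <- lm(y ~ t)
  s <- summary(fit)
  slope <- unname(coef(fit)[2])
  se <- s$coefficients[2, 2]
  sgn <- if (mode == "depletion") -1 else 1
  rate <- sgn * slope
  hw <- qt(0.975, df = length(t) - 2) * se

  structure(list(
    rate = rate,
    intercept = unname(coef(fit)[1]),
    stderr = se,
    r_squared = s$r.squared,
    ci95 = sort(sgn * c(slope - hw, slope + hw)),
    mode = mode,
    n = length(t),
    model = fit,
    data = tibble::tibble(time = t, value = y)
  ), class = "zero_order_fit")
}

#' @export
print.zero_order_fit <- function(x, ...) {
  cat(sprintf("Zero-order %s rate: %.4g umol L-1 d-1 (se %.3g, 95%% CI [%.4g, %.4g], r2 %.4f, n = %d)\n",
              x$mode, x$rate, x$stderr, x$ci95[1], x$ci95[2], x$r_squared, x$n))
  invisible(x)
}

#' @rdname fit_zero_order_rate
#' @param x A `zero_order_fit` object.
#' @param ... Unused.
#' @export
tidy.zero_order_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rate", "intercept"),
    estimate = c(x$rate, x$intercept),
    std.error = c(x$stderr, summary(x$model)$coefficients[1, 2]),
    conf.low = c(x$ci95[1], NA_real_),
    conf.high = c(x$ci95[2], NA_real_)
  )
}

#' @rdname fit_zero_order_rate
#' @export
glance.zero_order_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma = summary(x$model)$sigma,
                 nobs = x$n, df.residual = x$n - 2L, mode = x$mode)
}

#' Convert a dispensed liquid volume to moles
#'
#' `volume_uL * density / molar_mass`, returned in micromoles; used to turn a
#' pipetted substrate volume into the amount added to a microcosm (1 uL of
#' benzene is about 11 umol).
#'
#' @param volume_uL Volume in microlitres (>= 0).
#' @param density_g_per_mL Liquid density (> 0).
#' @param molar_mass_g_per_mol Molar mass (> 0).
#' @return Amount in umol.
#' @examples
#' volume_to_moles(1, 0.8765, 78.11) # benzene, ~11.2 umol
#' @export
volume_to_moles <- function(volume_uL, density_g_per_mL, molar_mass_g_per_mol) {
  if (any(volume_uL < 0)) stop("`volume_uL` must be non-negative", call. = FALSE)
  if (any(density_g_per_mL <= 0) || any(molar_mass_g_per_mol <= 0)) {
    stop("density and molar mass must be positive", call. = FALSE)
  }
  volume_uL * density_g_per_mL * 1000 / molar_mass_g_per_mol
}

#' Closed-vessel Henry's-law partitioning
#'
#' Solves the equilibrium distribution of a volatile compound between the
#' liquid and headspace of a sealed vial. With Henry constant `H` (M atm^-1)
#' and partial pressure `p`, `c_liquid = H p` and `c_gas = p / (R T)`; the
#' closed-system constraint `n_total = v_liquid c_liquid + v_gas c_gas`
#' gives the closed form
#' \deqn{c_{gas} = n / (v_g + v_l H R T).}
#' Mass balance holds exactly by construction.
#'
#' @param n_total_umol Total amount in the vessel, umol.
#' @param v_liquid_L,v_gas_L Liquid and headspace volumes in litres (not both
#'   zero).
#' @param henry Henry's law constant, M atm^-1 (default 0.18, benzene at
#'   ~20 C).
#' @param temperature_K Temperature in kelvin (default 293.15).
#' @param R_gas Gas constant, L atm mol^-1 K^-1.
#' @return A one-row tibble: `c_liquid_mM`, `c_gas_mmol_L`, `p_atm`,
#'   `n_liquid_umol`, `n_gas_umol`.
#' @examples
#' henry_partition(11, 0.020, 0.100)
#' @export
henry_partition <- function(n_total_umol, v_liquid_L, v_gas_L,
                            henry = 0.18, temperature_K = 293.15,
                            R_gas = 0.082057) {
  if (n_total_umol < 0) stop("`n_total_umol` must be non-negative", call. = FALSE)
  if (v_liquid_L < 0 || v_gas_L < 0) stop("volumes must be non-negative", call. = FALSE)
  if (v_liquid_L == 0 && v_gas_L == 0) {
    stop("liquid and gas volumes cannot both be zero", call. = FALSE)
  }
  if (henry <= 0) stop("`henry` must be positive", call. = FALSE)

  hrt <- henry * R_gas * temperature_K
  if (v_gas_L == 0) {
    c_liq <- n_total_umol / v_liquid_L    # umol/L
    c_gas <- c_liq / hrt                  # equilibrium headspace it would have
  } else {
    c_gas <- n_total_umol / (v_gas_L + v_liquid_L * hrt)
    c_liq <- hrt * c_gas
  }
  tibble::tibble(
    c_liquid_mM = c_liq / 1000,
    c_gas_mmol_L = c_gas / 1000,
    p_atm = c_gas * 1e-6 * R_gas * temperature_K,
    n_liquid_umol = c_liq * v_liquid_L,
    n_gas_umol = c_gas * v_gas_L
  )
}
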