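#' DNA buoyant density in a CsCl gradient
#'
#' Linear model of equilibrium buoyant density as a function of G+C content
#' and 13C atom fraction:
#' \deqn{\rho = \rho_0 + k_{GC} \cdot GC + \Delta \cdot a_{13C}}
#' with defaults \eqn{\rho_0 = 1.660} g/mL, \eqn{k_{GC} = 0.098} g/mL per
#' unit G+C (Schildkraut-type relation) and a full-labeling shift
#' \eqn{\Delta = 0.036} g/mL. High-G+C genomes band heavy even without
#' labeling — the confound the two-control enrichment rule is designed to
#' resist. Absolute densities from this model are nominal; gradients are
#' compared relative to their own controls, not against an absolute
#' calibration.
#'
#' @param gc G+C content, fraction in `[0, 1]`.
#' @param atom13c 13C atom fraction in `[0, 1]`.
#' @param rho0,gc_coeff,label_shift Model constants in g/mL.
#' @return Buoyant density in g/mL (vectorised).
#' @examples
#' buoyant_density(0.5)            # 1.709
#' buoyant_density(0.5, 1)         # 1.745, fully labeled
#' @export
buoyant_density <- function(gc, atom13c = 0, rho0 = 1.660,
                            gc_coeff = 0.098, label_shift = 0.036) {
  check_fraction(gc, "gc")
  check_fraction(atom13c, "atom13c")
  rho0 + gc_coeff * gc + label_shift * atom13c
}

#' Simulate isopycnic centrifugation of community DNA
#'
#' Distributes each taxon's DNA (`total_dna * base_abundance`) across gradient
#' fractions as a Gaussian band centred at [buoyant_density()] of its G+C
#' content and 13C atom fraction, with band standard deviation `sigma_rho`.
#' Per-fraction masses are the Gaussian integral over each fraction's density
#' interval, renormalised per taxon so mass is conserved exactly even when a
#' band extends beyond the modelled density range.
#'
#' @param community A `sip_community` tibble (see [simulate_community()]).
#' @param n_fractions Number of equal-width fractions (>= 3).
#' @param density_range Ascending length-2 range, within `[1.60, 1.80]` g/mL.
#' @param sigma_rho Band standard deviation in g/mL (> 0); the default 0.006
#'   lets a gc ~ 0.67 unlabeled genome leave detectable DNA in the heaviest
#'   fractions, reproducing the high-G+C control confound.
#' @param total_dna Total DNA loaded onto the gradient (arbitrary mass units).
#' @param ... Passed to [buoyant_density()] (model constants).
#'
#' @return A long tibble of class `sip_gradient` with columns `taxon_id`,
#'   `fraction`, `density` (fraction midpoint, g/mL), `mass`. Fraction edges
#'   and the loaded mass are stored as attributes `edges` and `total_dna`.
#' @export
simulate_gradient <- function(community, n_fractions = 20,
                              density_range = c(1.66, 1.78),
                              sigma_rho = 0.006, total_dna = 100, ...) {
  stopifnot(is.data.frame(community))
  if (n_fractions < 3) stop("`n_fractions` must be at least 3", call. = FALSE)
  if (length(density_range) != 2 || diff(density_range) <= 0) {
    stop("`density_range` must be ascending and non-degenerate", call. = FALSE)
  }
  if (density_range[1] < 1.60 || density_range[2] > 1.80) {
    stop("`density_range` must lie within [1.60, 1.80] g/mL", call. = FALSE)
  }
  if (!is.numeric(sigma_rho) || sigma_rho <= 0) {
    stop("`sigma_rho` must be positive", call. = FALSE)
  }

  edges <- seq(density_range[1], density_range[2], length.out = n_fractions + 1)
  centres <- (edges[-1] + edges[-length(edges)]) / 2

  band_weights <- function(mu) {
    w <- diff(pnorm(edges, mean = mu, sd = sigma_rho))
    if (sum(w) <= 0) { # band essentially outside the range: nearest fraction
      w <- numeric(n_fractions)
      w[which.min(abs(centres - mu))] <- 1
    }
    w / sum(w)
  }

  mus <- buoyant_density(community$gc, community$atom13c, ...)
  out <- purrr::map2(community$taxon_id, seq_along(mus), function(id, k) {
    tibble::tibble(
      taxon_id = id,
      fraction = seq_len(n_fractions),
      density = centres,
      mass = total_dna * community$base_abundance[k] * band_weights(mus[k])
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "edges") <- edges
  attr(out, "total_dna") <- total_dna
  attr(out, "sigma_rho") <- sigma_rho
  class(out) <- c("sip_gradient", class(out))
  out
}

#' Per-fraction total DNA of a gradient
#' @param gradient A `sip_gradient` tibble.
#' @return Tibble with `fraction`, `density`, `total_mass`.
#' @export
fraction_totals <- function(gradient) {
  dplyr::summarise(dplyr::group_by(gradient, .data$fraction, .data$density),
                   total_mass = sum(.data$mass), .groups = "drop")
}

#' Select the heavy window of a gradient
#'
#' Mimics heavy-fraction selection in a SIP experiment: the heavy window is
#' the highest-density fraction from which a PCR product could still be
#' obtained, i.e. whose total DNA reaches the detection threshold, optionally
#' extended downward over contiguous detectable fractions to `width`
#' fractions. A fixed density window (such as the conventional 1.74--1.75
#' g/mL) can be forced with `density_window`, in which case detectability is
#' not consulted.
#'
#' @param gradient A `sip_gradient` tibble.
#' @param detection_threshold Minimum detectable per-fraction DNA, as a
#'   fraction of the total loaded DNA (default 0.5%).
#' @param width Maximum number of contiguous fractions in the window.
#' @param density_window Optional length-2 density range overriding selection.
#' @return Tibble with `fraction`, `density`, `total_mass` for the window,
#'   highest density last.
#' @export
select_heavy_window <- function(gradient, detection_threshold = 0.005,
                                width = 1, density_window = NULL) {
  totals <- fraction_totals(gradient)
  if (!is.null(density_window)) {
    sel <- dplyr::filter(totals, .data$density >= density_window[1],
                         .data$density <= density_window[2])
    if (nrow(sel) == 0) {
      stop("no fractions fall inside `density_window`", call. = FALSE)
    }
    return(sel)
  }
  thr <- detection_threshold * sum(totals$total_mass)
  detectable <- totals$total_mass >= thr
  if (!any(detectable)) {
    stop("no amplifiable heavy DNA: every fraction is below the detection threshold",
         call. = FALSE)
  }
  top <- max(which(detectable))
  lo <- top
  while (lo > 1 && detectable[lo - 1] && (top - lo + 1) < width) lo <- lo - 1
  totals[lo:top, ]
}
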