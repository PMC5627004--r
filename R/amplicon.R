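#' Simulate a fraction-resolved 16S rRNA amplicon count table
#'
#' Draws per-fraction OTU counts by multinomial sampling with probabilities
#' proportional to each taxon's DNA mass in that fraction. Fractions whose
#' total DNA falls below the detection threshold yield no PCR product and
#' are returned as all-zero columns.
#'
#' @param gradient A `sip_gradient` tibble (see [simulate_gradient()]).
#' @param depth Sequencing depth per amplifiable fraction (>= 1).
#' @param detection_threshold Minimum amplifiable per-fraction DNA, as a
#'   fraction of total loaded DNA.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A long tibble of class `fraction_counts` with columns `taxon_id`,
#'   `fraction`, `density`, `count`.
#' @export
simulate_amplicon_table <- function(gradient, depth = 10000,
                                    detection_threshold = 0.005, seed = NULL) {
  if (depth < 1) stop("`depth` must be at least 1 read per fraction", call. = FALSE)
  total <- sum(gradient$mass)
  if (total <= 0) stop("gradient carries no DNA mass", call. = FALSE)
  thr <- detection_threshold * total

  with_seed(seed, {
    out <- gradient |>
      dplyr::group_by(.data$fraction, .data$density) |>
      dplyr::group_modify(function(d, key) {
        counts <- if (sum(d$mass) < thr) {
          rep(0L, nrow(d))
        } else {
          as.integer(rmultinom(1, size = depth, prob = d$mass))
        }
        tibble::tibble(taxon_id = d$taxon_id, count = counts)
      }) |>
      dplyr::ungroup() |>
      dplyr::select("taxon_id", "fraction", "density", "count") |>
      dplyr::arrange(.data$fraction, .data$taxon_id)
    class(out) <- c("fraction_counts", class(out))
    out
  })
}

#' Relative abundances within one gradient fraction
#'
#' @param counts A `fraction_counts` tibble.
#' @param fraction Fraction index to normalise.
#' @return Tibble with `taxon_id` and `p` (counts over fraction depth; sums
#'   to 1).
#' @export
relative_abundances <- function(counts, fraction) {
  d <- dplyr::filter(counts, .data$fraction == !!fraction)
  if (nrow(d) == 0) stop("fraction not present in table", call. = FALSE)
  depth <- sum(d$count)
  if (depth == 0) {
    stop("fraction has zero depth (no PCR product); cannot normalise", call. = FALSE)
  }
  tibble::tibble(taxon_id = d$taxon_id, p = d$count / depth)
}

#' Pool counts over a set of fractions
#'
#' Sums counts across the given fractions (e.g. a heavy window) into a single
#' per-taxon count vector, the form consumed by [call_all()].
#'
#' @param counts A `fraction_counts` tibble.
#' @param fractions Integer fraction indices, or a window tibble from
#'   [select_heavy_window()].
#' @return Tibble with `taxon_id`, `count`.
#' @export
pool_fractions <- function(counts, fractions) {
  if (is.data.frame(fractions)) fractions <- fractions$fraction
  counts |>
    dplyr::filter(.data$fraction %in% fractions) |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
}

#' Multinomial sample of an unfractionated community
#'
#' Emulates sequencing total community DNA without density fractionation (the
#' unfractionated control of a SIP design).
#'
#' @param community A `sip_community` tibble.
#' @param depth Sequencing depth.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return Tibble with `taxon_id`, `count`.
#' @export
simulate_unfractionated <- function(community, depth = 10000, seed = NULL) {
  if (depth < 1) stop("`depth` must be at least 1", call. = FALSE)
  with_seed(seed, {
    tibble::tibble(
      taxon_id = community$taxon_id,
      count = as.integer(rmultinom(1, size = depth, prob = community$base_abundance))
    )
  })
}
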