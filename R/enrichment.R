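#' Two-control fold-enrichment call for a 13C-assimilating OTU
#'
#' Implements the SIP enrichment rule: an OTU is considered enriched in the
#' labeled substrate if its relative abundance in the SIP heavy fraction is
#' at least `fold_hi` (default 10) times its abundance in *both* controls
#' (the control heavy fraction and the unfractionated community), or at
#' least `fold_lo` (default 2) times both controls while being predominant
#' (heavy-fraction abundance above `dominance`, default 10%). The
#' two-control design separates true 13C labeling from the high-G+C
#' buoyant-density confound: genomes that band heavy for compositional
#' reasons are heavy in the control gradient too, so their fold-change stays
#' near 1.
#'
#' Fold-changes use pseudo-count-adjusted denominators: a control abundance
#' below `pseudo` is replaced by `pseudo` (zero stays zero when `pseudo = 0`,
#' giving an infinite fold for taxa absent from a control but present in the
#' heavy fraction). A taxon absent from the heavy fraction is never enriched.
#' Thresholds are inclusive (`>=` for folds) except dominance, which is
#' strict (`>`).
#'
#' @param p_heavy Relative abundance in the SIP heavy fraction.
#' @param p_ctrl_heavy Relative abundance in the control heavy fraction.
#' @param p_ctrl_unfrac Relative abundance in the unfractionated control.
#' @param fold_hi,fold_lo,dominance Rule thresholds (10, 2, 0.10).
#' @param pseudo Pseudo-abundance(s) for the two control denominators; a
#'   scalar or length-2 vector `(ctrl_heavy, ctrl_unfrac)`. [call_all()] sets
#'   these to half a count at each control's depth.
#' @return A tibble (one row per input element) with the three abundances,
#'   `fold_ctrl_heavy`, `fold_ctrl_unfrac`, `fold_vs_both` (the minimum),
#'   `branch` (`"tenfold"`, `"twofold_dominant"` or `"none"`) and `enriched`.
#' @examples
#' call_enrichment(0.869, 0.869 / 20, 0.869 / 20)  # 20-fold, enriched
#' call_enrichment(0.12, 0.05, 0.05)               # 2.4-fold + dominant
#' @export
call_enrichment <- function(p_heavy, p_ctrl_heavy, p_ctrl_unfrac,
                            fold_hi = 10, fold_lo = 2, dominance = 0.10,
                            pseudo = 0) {
  check_fraction(p_heavy, "p_heavy")
  check_fraction(p_ctrl_heavy, "p_ctrl_heavy")
  check_fraction(p_ctrl_unfrac, "p_ctrl_unfrac")
  stopifnot(fold_hi > 0, fold_lo > 0, dominance >= 0)
  pseudo <- rep_len(pseudo, 2)

  n <- max(length(p_heavy), length(p_ctrl_heavy), length(p_ctrl_unfrac))
  ph <- rep_len(p_heavy, n)
  pch <- pmax(rep_len(p_ctrl_heavy, n), pseudo[1])
  pcu <- pmax(rep_len(p_ctrl_unfrac, n), pseudo[2])

  fold1 <- ifelse(ph == 0, 0, ifelse(pch == 0, Inf, ph / pch))
  fold2 <- ifelse(ph == 0, 0, ifelse(pcu == 0, Inf, ph / pcu))
  fold <- pmin(fold1, fold2)

  branch <- dplyr::case_when(
    fold >= fold_hi & ph > 0 ~ "tenfold",
    fold >= fold_lo & ph > dominance ~ "twofold_dominant",
    TRUE ~ "none"
  )
  tibble::tibble(
    p_heavy = ph,
    p_ctrl_heavy = rep_len(p_ctrl_heavy, n),
    p_ctrl_unfrac = rep_len(p_ctrl_unfrac, n),
    fold_ctrl_heavy = fold1,
    fold_ctrl_unfrac = fold2,
    fold_vs_both = fold,
    branch = branch,
    enriched = branch != "none"
  )
}

#' Apply the enrichment rule across an OTU table
#'
#' Outer-joins the three count tables on `taxon_id` (absent taxa count 0),
#' converts counts to relative abundances at each table's own depth, and
#' calls [call_enrichment()] per taxon with pseudo-abundances of half a count
#' at each control's depth (the continuity correction that keeps folds
#' finite for taxa undetected in a control).
#'
#' @param heavy Counts in the SIP heavy window: tibble with `taxon_id`,
#'   `count` (see [pool_fractions()]).
#' @param ctrl_heavy Counts in the control heavy window, same form.
#' @param ctrl_unfrac Counts in the unfractionated control, same form.
#' @param ... Thresholds passed on to [call_enrichment()].
#' @return A tibble of class `enrichment_calls`, one row per taxon in the
#'   union of the three tables, sorted by `p_heavy` descending.
#' @export
call_all <- function(heavy, ctrl_heavy, ctrl_unfrac, ...) {
  tabs <- list(heavy = heavy, ctrl_heavy = ctrl_heavy, ctrl_unfrac = ctrl_unfrac)
  purrr::iwalk(tabs, function(t, nm) {
    if (!all(c("taxon_id", "count") %in% names(t))) {
      stop(sprintf("`%s` must have columns taxon_id and count", nm), call. = FALSE)
    }
  })
  shared <- Reduce(intersect, lapply(tabs, function(t) t$taxon_id))
  if (length(shared) == 0) {
    warning("count tables share no taxa; using their union with zero fills")
  }

  depths <- vapply(tabs, function(t) sum(t$count), numeric(1))
  if (any(depths == 0)) stop("a count table has zero total depth", call. = FALSE)

  joined <- tabs$heavy |>
    dplyr::full_join(tabs$ctrl_heavy, by = "taxon_id", suffix = c("", "_ch")) |>
    dplyr::full_join(tabs$ctrl_unfrac, by = "taxon_id", suffix = c("_h", "_cu")) |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("count"), ~ tidyr::replace_na(.x, 0L)))

  calls <- call_enrichment(
    p_heavy = joined$count_h / depths[["heavy"]],
    p_ctrl_heavy = joined$count_ch / depths[["ctrl_heavy"]],
    p_ctrl_unfrac = joined$count_cu / depths[["ctrl_unfrac"]],
    pseudo = c(0.5 / depths[["ctrl_heavy"]], 0.5 / depths[["ctrl_unfrac"]]),
    ...
  )
  out <- dplyr::bind_cols(tibble::tibble(taxon_id = joined$taxon_id), calls) |>
    dplyr::arrange(dplyr::desc(.data$p_heavy))
  class(out) <- c("enrichment_calls", class(out))
  out
}
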