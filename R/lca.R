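#' Minimal lowest-common-ancestor taxonomic assignment
#'
#' Assigns one read from its alignment hits the way a MEGAN-style LCA does:
#' hits within `top_percent` of the best score are retained and the read is
#' placed at the lowest taxonomic rank on which all retained hits agree
#' (agreement is prefix-wise from domain down). A read with no hits is
#' `"Unassigned"`; a read whose LCA sits above `report_rank` is reported as
#' `"Unclassified <taxon>"` at the deepest agreeing rank.
#'
#' @param hits Tibble of hits for one read: `record_id`, `score` (higher is
#'   better). Zero rows mean no hits.
#' @param lineages Lineage table: `record_id` plus the ranks
#'   `domain, phylum, class, order, family, genus`.
#' @param top_percent Retention band below the best score (default 10: keep
#'   hits scoring at least 90% of the best).
#' @param report_rank Rank at which downstream profiles are reported.
#' @return One-row tibble: `assignment`, `rank` (the LCA rank or `NA`), the
#'   six rank columns filled down to the LCA (NA below it), and `n_retained`.
#' @export
assign_lca <- function(hits, lineages, top_percent = 10, report_rank = "genus") {
  ranks <- taxonomy_ranks()
  report_rank <- match.arg(report_rank, ranks)
  empty_lineage <- tibble::as_tibble(setNames(as.list(rep(NA_character_, 6)), ranks))

  if (is.null(hits) || nrow(hits) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(assignment = "Unassigned", rank = NA_character_),
      empty_lineage, tibble::tibble(n_retained = 0L)))
  }
  keep <- hits$score >= (1 - top_percent / 100) * max(hits$score)
  retained <- hits[keep, , drop = FALSE]
  lin <- dplyr::left_join(retained["record_id"], lineages, by = "record_id")
  if (anyNA(lin$domain)) {
    missing <- lin$record_id[is.na(lin$domain)]
    stop(sprintf("no lineage for record(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }

  agreed <- empty_lineage
  lca_rank <- NA_character_
  for (r in ranks) {
    vals <- unique(lin[[r]])
    if (length(vals) == 1 && !is.na(vals)) {
      agreed[[r]] <- vals
      lca_rank <- r
    } else break
  }

  assignment <- if (is.na(lca_rank)) {
    "Unassigned"
  } else if (match(lca_rank, ranks) < match(report_rank, ranks)) {
    paste("Unclassified", agreed[[lca_rank]])
  } else {
    agreed[[lca_rank]]
  }
  dplyr::bind_cols(
    tibble::tibble(assignment = assignment, rank = lca_rank),
    agreed, tibble::tibble(n_retained = nrow(retained)))
}

#' LCA-assign every read in a hits table
#'
#' @param hits A `recruitment_hits` tibble (recruited hits; one best hit per
#'   read per gene as produced by [recruit_reads()]). To also emit
#'   `"Unassigned"` rows for reads without hits, pass their ids in
#'   `read_ids`.
#' @param lineages Lineage table (`record_id` + ranks).
#' @param read_ids Optional full set of read ids.
#' @inheritParams assign_lca
#' @return Tibble with `read_id` plus the columns of [assign_lca()].
#' @export
assign_reads <- function(hits, lineages, read_ids = NULL,
                         top_percent = 10, report_rank = "genus") {
  groups <- split(hits, hits$read_id)
  missing <- setdiff(read_ids %||% character(0), names(groups))
  out <- purrr::imap(groups, function(h, id) {
    dplyr::bind_cols(tibble::tibble(read_id = id),
                     assign_lca(h, lineages, top_percent, report_rank))
  })
  none <- purrr::map(missing, function(id) {
    dplyr::bind_cols(tibble::tibble(read_id = id),
                     assign_lca(hits[0, ], lineages, top_percent, report_rank))
  })
  rows <- c(unname(out), none)
  if (length(rows) == 0) {
    return(dplyr::bind_cols(tibble::tibble(read_id = character()),
                            assign_lca(hits[0, ], lineages)[0, ]))
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$read_id)
}

#' Taxon abundance profile of one gene's recruited reads
#'
#' Rolls LCA assignments up to `rank`, keeping `"Unassigned"` reads and
#' reporting reads whose LCA lies above `rank` as `"Unclassified <taxon>"`.
#' Named taxa with a share below `display_cutoff` (default 1%) are pooled
#' into `"other"`; Unassigned/Unclassified categories are never pooled.
#'
#' @param assignments Output of [assign_reads()] for one gene dataset.
#' @param rank Report rank (default `"order"`).
#' @param display_cutoff Minimum share for a named taxon to be displayed.
#' @return A `taxon_profile` tibble: `taxon`, `n_reads`, `share`, sorted by
#'   share descending.
#' @export
taxon_profile <- function(assignments, rank = "order", display_cutoff = 0.01) {
  rank <- match.arg(rank, taxonomy_ranks())
  if (nrow(assignments) == 0) stop("no assignments to profile", call. = FALSE)
  ranks <- taxonomy_ranks()
  depth <- function(r) match(r, ranks)

  lab <- purrr::pmap_chr(assignments, function(...) {
    row <- list(...)
    if (!is.na(row[[rank]])) return(row[[rank]])
    if (is.na(row$rank)) return("Unassigned")
    # LCA above the report rank
    paste("Unclassified", row[[row$rank]])
  })

  prof <- tibble::tibble(taxon = lab) |>
    dplyr::count(.data$taxon, name = "n_reads") |>
    dplyr::mutate(share = .data$n_reads / sum(.data$n_reads))
  pooled <- prof$share < display_cutoff &
    !grepl("^(Unassigned|Unclassified )", prof$taxon)
  if (any(pooled)) {
    other <- tibble::tibble(taxon = "other",
                            n_reads = sum(prof$n_reads[pooled]),
                            share = sum(prof$share[pooled]))
    prof <- dplyr::bind_rows(prof[!pooled, ], other)
  }
  out <- dplyr::arrange(prof, dplyr::desc(.data$share))
  attr(out, "rank") <- rank
  class(out) <- c("taxon_profile", class(out))
  out
}

#' Multi-gene prevalence of taxa
#'
#' A taxon's prevalence is the fraction of the gene sets in the panel in
#' which it is detected (at least one recruited read assigned to it). Taxa
#' are retained when prevalence strictly exceeds `retain_threshold`; with
#' the 14-gene panel and the default 60% threshold, detection in 9 or more
#' gene sets retains a taxon while 8 does not.
#'
#' @param detections Either a tibble with columns `gene` and `taxon` (one
#'   row per detection) or a named list of `taxon_profile` tibbles, one per
#'   gene. `"Unassigned"` reads and the pooled `"other"` category are not
#'   taxa and are ignored.
#' @param panel Gene panel defining the denominator (default the 14-gene
#'   aromatic panel).
#' @param retain_threshold Strict retention threshold on prevalence.
#' @return A `prevalence_matrix` tibble: `taxon`, `n_detected`, `n_genes`,
#'   `prevalence`, `retained`, sorted by prevalence descending; the
#'   taxon-by-gene logical detection matrix is attached as attribute
#'   `detection`.
#' @export
compute_prevalence <- function(detections, panel = aromatic_gene_panel(),
                               retain_threshold = 0.60) {
  if (length(panel) == 0) stop("gene panel is empty", call. = FALSE)
  if (is.data.frame(detections)) {
    det <- detections
  } else {
    det <- purrr::imap(detections, function(p, g) {
      tibble::tibble(gene = g, taxon = p$taxon)
    }) |> dplyr::bind_rows()
  }
  stopifnot(all(c("gene", "taxon") %in% names(det)))
  det <- det |>
    dplyr::filter(!.data$taxon %in% c("Unassigned", "other")) |>
    dplyr::distinct(.data$gene, .data$taxon)
  if (!all(det$gene %in% panel)) {
    stop("detections reference genes outside the panel", call. = FALSE)
  }

  wide <- det |>
    dplyr::mutate(present = TRUE) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "present",
                       values_fill = FALSE)
  for (g in setdiff(panel, names(wide))) wide[[g]] <- FALSE
  wide <- wide[, c("taxon", panel)]

  out <- tibble::tibble(
    taxon = wide$taxon,
    n_detected = rowSums(as.matrix(wide[, panel])),
    n_genes = length(panel)
  ) |>
    dplyr::mutate(prevalence = .data$n_detected / .data$n_genes,
                  retained = .data$prevalence > retain_threshold) |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$taxon)
  attr(out, "detection") <- wide
  class(out) <- c("prevalence_matrix", class(out))
  out
}
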