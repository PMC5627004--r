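#' Fig.-style abundance classes for bubble plots
#'
#' Maps a relative abundance to one of six display classes
#' (1--1.75%, 1.76--4.5%, 4.6--9%, 9.1--18.5%, 18.6--37.5%, >37.6%);
#' abundances at or below 1% are `"not displayed"`. The printed class labels
#' leave tiny gaps (e.g. 1.75% vs 1.76%); values falling inside a gap are
#' assigned to the nearest lower class by convention.
#'
#' @param p Relative abundance(s) in `[0, 1]`.
#' @return A factor with the class labels (plus `"not displayed"`) as levels.
#' @examples
#' abundance_class(c(0.869, 0.03, 0.005))
#' @export
abundance_class <- function(p) {
  check_fraction(p, "p")
  labels <- c("not displayed", "1-1.75%", "1.76-4.5%", "4.6-9%",
              "9.1-18.5%", "18.6-37.5%", ">37.6%")
  # lower bounds follow the printed labels; gap values (e.g. 1.755%) fall to
  # the lower class; ">37.6%" is strict, "only OTUs >1%" excludes p = 1%
  idx <- dplyr::case_when(
    p > 0.376 ~ 7L,
    p >= 0.186 ~ 6L,
    p >= 0.091 ~ 5L,
    p >= 0.046 ~ 4L,
    p >= 0.0176 ~ 3L,
    p > 0.01 ~ 2L,
    TRUE ~ 1L
  )
  factor(labels[idx], levels = labels)
}

#' Read and write fraction-resolved OTU tables as TSV
#'
#' The on-disk layout is one taxon per row and one gradient fraction per
#' column; fraction columns are named `f<index>_d<density>` with enough
#' digits that densities round-trip exactly. `write_otu_table()` accepts the
#' long `fraction_counts` form and `read_otu_table()` returns it.
#'
#' @param counts A `fraction_counts` tibble (`taxon_id`, `fraction`,
#'   `density`, `count`).
#' @param path File path.
#' @return `read_otu_table()` returns a `fraction_counts` tibble;
#'   `write_otu_table()` invisibly returns `path`.
#' @export
write_otu_table <- function(counts, path) {
  wide <- counts |>
    dplyr::mutate(col = sprintf("f%02d_d%.17g", .data$fraction, .data$density)) |>
    dplyr::select("taxon_id", "col", "count") |>
    tidyr::pivot_wider(names_from = "col", values_from = "count")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  fcols <- grep("^f[0-9]+_d", names(wide), value = TRUE)
  if (length(fcols) == 0 || names(wide)[1] != "taxon_id") {
    stop(sprintf("'%s' is not an OTU table: expected taxon_id + f<i>_d<density> columns",
                 path), call. = FALSE)
  }
  out <- wide |>
    tidyr::pivot_longer(dplyr::all_of(fcols), names_to = "col", values_to = "count") |>
    dplyr::mutate(
      fraction = as.integer(sub("^f([0-9]+)_d.*$", "\\1", .data$col)),
      density = as.numeric(sub("^f[0-9]+_d", "", .data$col)),
      count = as.integer(.data$count)
    ) |>
    dplyr::select("taxon_id", "fraction", "density", "count") |>
    dplyr::arrange(.data$fraction, .data$taxon_id)
  class(out) <- c("fraction_counts", class(out))
  out
}

#' Read and write FASTA
#'
#' Thin tidy wrappers around Biostrings: sequences come back as a tibble
#' with the first header token as `id`, the remainder as `desc`, and the
#' sequence upper-cased. Blank lines are tolerated.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: tibble with `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  set <- Biostrings::readDNAStringSet(tmp)
  full <- names(set)
  tibble::tibble(
    id = sub("\\s.*$", "", full),
    desc = ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), ""),
    seq = unname(toupper(as.character(set)))
  )
}

#' @rdname read_fasta
#' @param x Tibble with `id`, `seq` and optional `desc`.
#' @export
write_fasta <- function(x, path) {
  desc <- rep_len(if ("desc" %in% names(x)) x$desc else "", nrow(x))
  nm <- ifelse(nzchar(desc), paste(x$id, desc), x$id)
  set <- Biostrings::DNAStringSet(setNames(x$seq, nm))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a rank lineage table
#'
#' Expects a TSV with columns `record_id`, `domain`, `phylum`, `class`,
#' `order`, `family`, `genus`. Missing ranks are reported with the offending
#' row.
#'
#' @param path TSV path.
#' @return Tibble of lineages.
#' @export
read_lineages <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("record_id", taxonomy_ranks())
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop(sprintf("lineage table '%s' lacks column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (r in taxonomy_ranks()) {
    bad <- which(is.na(x[[r]]) | x[[r]] == "")
    if (length(bad) > 0) {
      stop(sprintf("lineage table '%s' row %d (record_id '%s'): missing rank '%s'",
                   path, bad[1], x$record_id[bad[1]], r), call. = FALSE)
    }
  }
  x[, need]
}

#' Read a kinetics time series TSV
#'
#' @param path TSV with a `time_d` column and one or more value columns
#'   (e.g. `substrate_uM`, `co2_uM`).
#' @return Tibble.
#' @export
read_kinetics <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"time_d" %in% names(x)) {
    stop(sprintf("'%s' lacks a time_d column", path), call. = FALSE)
  }
  x
}

#' Write an enrichment report TSV
#'
#' @param calls An `enrichment_calls` tibble.
#' @param path Output TSV path.
#' @export
write_enrichment_report <- function(calls, path) {
  readr::write_tsv(
    dplyr::select(calls, "taxon_id", "p_heavy", "p_ctrl_heavy",
                  "p_ctrl_unfrac", "fold_vs_both", "branch", "enriched"),
    path)
  invisible(path)
}
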