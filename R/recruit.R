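#' The 14-gene aromatic-degradation marker panel
#'
#' Names of the key catabolic genes used for gene-centric recruitment of
#' unassembled metagenomic reads: the meta-cleavage pathway of catechol
#' (dmpB/xylE catechol 2,3-dioxygenase and downstream steps), ring-attack
#' dioxygenases (todC1/bedC1 benzene/toluene dioxygenase, nahAc/ndoB
#' naphthalene 1,2-dioxygenase), the upper naphthalene pathway, salicylate
#' hydroxylase and phenol hydroxylase. Functionally identical low-abundance
#' pairs (nahC+nahD, nahE+nahF) are treated as combined sets.
#'
#' @return Character vector of 14 gene-set names.
#' @export
aromatic_gene_panel <- function() {
  c("dmpB/xylE", "dmpD/xylF", "dmpC/xylG", "praC/xylH", "dmpH/xylI/nahK",
    "mhpD", "mhpE", "mhpF", "todC1/bedC1", "nahAc/ndoB", "nahC+nahD",
    "nahE+nahF", "sal-hyd", "dmpK/poxA")
}

#' Expand a core gene reference set by an identity rule
#'
#' Admits candidate sequences into a gene's reference dataset when their
#' best alignment identity against *any core member* is at least
#' `min_identity` (default 70%). Admission is a single pass against the core
#' only — admitted candidates do not themselves recruit further candidates,
#' which prevents identity drift below the threshold relative to the core.
#'
#' @param core Tibble of core records (`record_id`, `seq`, optionally
#'   `gene`); must be non-empty.
#' @param candidates Tibble of candidate records, same columns (may be
#'   empty).
#' @param min_identity Admission threshold (inclusive).
#' @param ... Scoring parameters passed to [local_align_identity()].
#' @return A `gene_dataset` tibble: core rows (`role = "core"`) followed by
#'   admitted candidates (`role = "expanded"`, with their best
#'   `identity_vs_core`).
#' @export
expand_dataset <- function(core, candidates = NULL, min_identity = 0.70, ...) {
  stopifnot(is.data.frame(core))
  if (nrow(core) == 0) stop("`core` dataset must be non-empty", call. = FALSE)
  out <- dplyr::mutate(core, role = "core", identity_vs_core = NA_real_)
  if (!is.null(candidates) && nrow(candidates) > 0) {
    best <- vapply(candidates$seq, function(s) {
      max(local_align_identity(s, core$seq, ...)$identity)
    }, numeric(1), USE.NAMES = FALSE)
    admitted <- dplyr::mutate(candidates[best >= min_identity, , drop = FALSE],
                              role = "expanded",
                              identity_vs_core = best[best >= min_identity])
    out <- dplyr::bind_rows(out, admitted)
  }
  class(out) <- c("gene_dataset", class(out))
  out
}

#' Recruit reads to a gene reference dataset
#'
#' Aligns each read (both strands) against every record of the dataset,
#' keeps the single best-scoring hit per read, and recruits the read when
#' that hit reaches `min_identity` (default 50%) over at least `min_len`
#' aligned columns (default 75 bp). Both thresholds are inclusive. Identity
#' counts matches over all alignment columns, gaps included, under the
#' end-gap-free full-query alignment of [local_align_identity()].
#'
#' @param reads Tibble with `read_id` and `seq`.
#' @param dataset A non-empty `gene_dataset` (or any tibble with `record_id`,
#'   `seq`, optionally `gene`).
#' @param min_identity,min_len Recruitment thresholds.
#' @param keep_all Return non-recruited reads too (with `recruited = FALSE`)?
#'   Default keeps only recruited hits.
#' @param ... Scoring parameters passed to [local_align_identity()].
#' @return A `recruitment_hits` tibble: `read_id`, `record_id`, `gene` (if
#'   present in the dataset), `identity`, `aligned_cols`, `score`, `strand`,
#'   `recruited`.
#' @export
recruit_reads <- function(reads, dataset, min_identity = 0.50, min_len = 75,
                          keep_all = FALSE, ...) {
  stopifnot(is.data.frame(reads), is.data.frame(dataset))
  if (nrow(dataset) == 0) stop("`dataset` must be non-empty", call. = FALSE)
  if (nrow(reads) == 0) stop("`reads` must be non-empty", call. = FALSE)

  hits <- purrr::map(seq_len(nrow(reads)), function(i) {
    aln <- local_align_identity(reads$seq[i], dataset$seq, ...)
    best <- which.max(aln$score) # first record wins score ties
    dplyr::bind_cols(
      tibble::tibble(read_id = reads$read_id[i],
                     record_id = dataset$record_id[best]),
      if ("gene" %in% names(dataset)) tibble::tibble(gene = dataset$gene[best]),
      aln[best, ]
    )
  })
  hits <- dplyr::bind_rows(hits) |>
    dplyr::mutate(recruited = .data$identity >= min_identity &
                    .data$aligned_cols >= min_len)
  if (!keep_all) hits <- dplyr::filter(hits, .data$recruited)
  class(hits) <- c("recruitment_hits", class(hits))
  hits
}

#' Reads per kilobase per million (RPKM)
#'
#' `n_recruited / (gene_length_bp / 1000) / (total_reads / 1e6)` — the
#' library-size- and gene-length-normalised recruitment count. Invariant to
#' scaling read counts and library size together.
#'
#' @param n_recruited Recruited read count(s).
#' @param gene_length_bp Reference gene length in bp (> 0).
#' @param total_reads Total library size (> 0).
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(1000, 1000, 1e6) # 1000
#' @export
compute_rpkm <- function(n_recruited, gene_length_bp, total_reads) {
  if (any(gene_length_bp <= 0)) stop("`gene_length_bp` must be positive", call. = FALSE)
  if (any(total_reads <= 0)) stop("`total_reads` must be positive", call. = FALSE)
  n_recruited / (gene_length_bp / 1000) / (total_reads / 1e6)
}

#' Per-gene RPKM table from recruitment hits
#'
#' Summarises recruited reads per gene set and normalises by the mean core
#' reference length of each gene and the total library size.
#'
#' @param hits A `recruitment_hits` tibble (recruited rows are counted).
#' @param dataset The reference dataset used for recruitment (`gene`, `seq`;
#'   rows with `role == "core"` define gene length when present).
#' @param total_reads Total library size.
#' @return Tibble with `gene`, `n_reads`, `gene_length_bp`, `rpkm`.
#' @export
rpkm_table <- function(hits, dataset, total_reads) {
  stopifnot("gene" %in% names(dataset))
  lens <- dataset
  if ("role" %in% names(lens)) lens <- dplyr::filter(lens, .data$role == "core")
  lens <- lens |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(gene_length_bp = mean(nchar(.data$seq)), .groups = "drop")
  hits |>
    dplyr::filter(.data$recruited) |>
    dplyr::count(.data$gene, name = "n_reads") |>
    dplyr::right_join(lens, by = "gene") |>
    dplyr::mutate(n_reads = tidyr::replace_na(.data$n_reads, 0L),
                  rpkm = compute_rpkm(.data$n_reads, .data$gene_length_bp, total_reads))
}
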