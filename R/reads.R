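#' Simulate sequencing reads diverged from reference genes
#'
#' Draws reads as substrings of reference sequences with i.i.d. point
#' substitutions at rate `divergence` (each substituted site changes to one
#' of the three other bases), so the expected mismatch count of a length-L
#' read against its source is `L * divergence`. The true origin of every
#' read is recorded, giving ground truth for recruitment and taxonomic
#' assignment benchmarks.
#'
#' @param references Tibble of reference records with columns `record_id`,
#'   `seq` (and optionally `gene` and taxonomy columns, which are carried
#'   through as `origin_*`).
#' @param n_reads Number of reads.
#' @param divergence Per-site substitution probability in `[0, 0.75]`.
#' @param read_length Length-2 integer range `(min, max)`; lengths are drawn
#'   uniformly, capped at the chosen reference's length. References shorter
#'   than the minimum read length are an error.
#' @param weights Optional sampling weights over reference records (default
#'   uniform).
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return A tibble of class `sim_reads`: `read_id`, `seq`, `length`,
#'   `start`, `n_subs`, `origin_record` plus any carried origin columns.
#' @export
simulate_reads <- function(references, n_reads, divergence,
                           read_length = c(75, 150), weights = NULL,
                           seed = NULL) {
  stopifnot(is.data.frame(references), nrow(references) > 0)
  check_dna(references$seq, "references$seq")
  if (divergence < 0 || divergence > 0.75) {
    stop("`divergence` must lie in [0, 0.75]", call. = FALSE)
  }
  read_length <- as.integer(read_length)
  if (length(read_length) != 2 || read_length[1] < 1 || read_length[1] > read_length[2]) {
    stop("`read_length` must be an ascending (min, max) pair with min >= 1", call. = FALSE)
  }
  ref_len <- nchar(references$seq)
  if (any(ref_len < read_length[1])) {
    stop("read length exceeds reference length: shorten `read_length` or drop short references",
         call. = FALSE)
  }

  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ridx <- sample.int(nrow(references), n_reads, replace = TRUE, prob = weights)
    reads <- purrr::map(seq_len(n_reads), function(i) {
      k <- ridx[i]
      hi <- min(read_length[2], ref_len[k])
      L <- read_length[1] + sample.int(hi - read_length[1] + 1L, 1) - 1L
      s <- sample.int(ref_len[k] - L + 1L, 1)
      chars <- strsplit(substr(references$seq[k], s, s + L - 1L), "", fixed = TRUE)[[1]]
      hit <- which(runif(L) < divergence)
      for (j in hit) chars[j] <- sample(setdiff(bases, chars[j]), 1)
      tibble::tibble(seq = paste(chars, collapse = ""), length = L, start = s,
                     n_subs = length(hit))
    })
    out <- dplyr::bind_rows(reads)
    out <- dplyr::bind_cols(
      tibble::tibble(read_id = sprintf("read_%05d", seq_len(n_reads))), out,
      tibble::tibble(origin_record = references$record_id[ridx])
    )
    for (col in intersect(c("gene", taxonomy_ranks()), names(references))) {
      out[[paste0("origin_", col)]] <- references[[col]][ridx]
    }
    class(out) <- c("sim_reads", class(out))
    out
  })
}
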