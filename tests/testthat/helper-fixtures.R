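# fixture builders shared across test files

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute specific (1-based) positions to a different base, deterministically
mutate_at <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  chars[positions] <- rot[chars[positions]]
  paste(chars, collapse = "")
}

# a tiny two-gene reference set with lineages, used by recruitment/LCA tests
make_gene_refs <- function(len = 240, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(
      record_id = c("dmpB_thauera", "dmpB_pseudomonas", "nahAc_pseudomonas"),
      gene = c("dmpB/xylE", "dmpB/xylE", "nahAc/ndoB"),
      seq = c(random_dna(len), random_dna(len), random_dna(len))
    )
  })
}

make_lineages <- function() {
  tibble::tibble(
    record_id = c("dmpB_thauera", "dmpB_pseudomonas", "nahAc_pseudomonas",
                  "dmpB_azoarcus"),
    domain = "Bacteria",
    phylum = "Proteobacteria",
    class = c("Betaproteobacteria", "Gammaproteobacteria", "Gammaproteobacteria",
              "Betaproteobacteria"),
    order = c("Rhodocyclales", "Pseudomonadales", "Pseudomonadales",
              "Rhodocyclales"),
    family = c("Rhodocyclaceae", "Pseudomonadaceae", "Pseudomonadaceae",
               "Rhodocyclaceae"),
    genus = c("Thauera", "Pseudomonas", "Pseudomonas", "Azoarcus")
  )
}

# independent transcription of the two-control enrichment sentence: enriched
# if at least 10-fold above each control, or at least 2-fold above each
# control while exceeding 10% of the heavy fraction; a taxon absent from the
# heavy fraction is never enriched, a control zero gives an unbounded fold
oracle_enriched <- function(p_heavy, p_ctrl_heavy, p_ctrl_unfrac,
                            fold_hi = 10, fold_lo = 2, dominance = 0.10) {
  fold_vs <- function(ctrl) {
    ifelse(p_heavy == 0, 0, ifelse(ctrl == 0, Inf, p_heavy / ctrl))
  }
  f_ch <- fold_vs(p_ctrl_heavy)
  f_cu <- fold_vs(p_ctrl_unfrac)
  (f_ch >= fold_hi & f_cu >= fold_hi) |
    (f_ch >= fold_lo & f_cu >= fold_lo & p_heavy > dominance)
}
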