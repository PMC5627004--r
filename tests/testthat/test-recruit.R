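test_that("dataset expansion admits by identity against the core only", {
  refs <- make_gene_refs(len = 200)
  core <- refs[1, ]

  # identical candidate admitted, heavily mutated one rejected
  twin <- tibble::tibble(record_id = "twin", gene = core$gene, seq = core$seq)
  far <- tibble::tibble(record_id = "far", gene = core$gene,
                        seq = mutate_at(core$seq, seq(1, 200, by = 2)))
  expect_lte(oracle_align(far$seq, core$seq)$identity, 0.55)

  ds <- expand_dataset(core, dplyr::bind_rows(twin, far))
  expect_equal(ds$record_id, c(core$record_id, "twin"))
  expect_equal(ds$role, c("core", "expanded"))
  expect_equal(ds$identity_vs_core[2], 1)

  # no candidates: dataset is the core
  expect_equal(expand_dataset(core)$record_id, core$record_id)
  expect_error(expand_dataset(core[0, ]), "non-empty")

  # expansion is single-pass: a chain partner of an expanded member that is
  # below threshold against the core itself is not admitted
  mid <- mutate_at(core$seq, seq(1, 200, by = 5))      # 80% vs core
  chain <- mutate_at(mid, seq(2, 200, by = 5))         # ~80% vs mid, ~60% vs core
  cand <- tibble::tibble(record_id = c("mid", "chain"), gene = core$gene,
                         seq = c(mid, chain))
  ds2 <- expand_dataset(core, cand)
  expect_true("mid" %in% ds2$record_id)
  expect_false("chain" %in% ds2$record_id)
})

test_that("recruitment applies the joint identity and length thresholds", {
  refs <- make_gene_refs(len = 240)
  exact <- tibble::tibble(read_id = c("r100", "r60"),
                          seq = c(substr(refs$seq[1], 11, 110),
                                  substr(refs$seq[1], 11, 70)))
  hits <- recruit_reads(exact, refs, keep_all = TRUE)
  expect_equal(hits$recruited, c(TRUE, FALSE)) # 60 aligned columns < 75
  expect_equal(hits$identity, c(1, 1))
  expect_equal(hits$record_id[1], refs$record_id[1])
  expect_equal(hits$gene[1], refs$gene[1])

  # default return keeps only recruited hits
  expect_equal(recruit_reads(exact, refs)$read_id, "r100")

  # simulated divergence around the 50% threshold: every decision must match
  # the DP oracle exactly, whichever way the optimal alignment falls
  near <- simulate_reads(refs[1, ], 25, divergence = 0.40,
                         read_length = c(100, 100), seed = 5)
  farr <- simulate_reads(refs[1, ], 25, divergence = 0.55,
                         read_length = c(100, 100), seed = 6)
  reads <- dplyr::bind_rows(near, farr) |>
    dplyr::mutate(read_id = sprintf("rd_%02d", dplyr::row_number()))
  got <- recruit_reads(reads, refs, keep_all = TRUE)
  want <- vapply(reads$seq, function(s) oracle_recruit(s, refs$seq)$recruited,
                 logical(1), USE.NAMES = FALSE)
  expect_equal(got$recruited, want)
  # divergence 0.40 (expected identity 0.60) recruits essentially always
  expect_gt(mean(got$recruited[1:25]), 0.9)
  # score-optimal glocal alignment recovers substantially more matching
  # columns than the generating window at high divergence, so 0.55-diverged
  # reads sit at, not below, the 50% boundary: their best-alignment identity
  # stays close to the threshold rather than at the naive 0.45
  expect_lt(median(got$identity[26:50]), 0.58)
})

test_that("recruitment is razor-sharp at 50% identity and 75 columns", {
  withr::with_seed(9, {
    src <- random_dna(76)
  })
  # alternating mismatches: 38 matches over 76 columns = exactly 50%
  at_threshold <- mutate_at(src, seq(2, 76, by = 2))
  ref <- tibble::tibble(record_id = "ref", seq = src)
  h <- recruit_reads(tibble::tibble(read_id = "r", seq = at_threshold), ref,
                     keep_all = TRUE, both_strands = FALSE)
  expect_equal(h$identity, 0.5)
  expect_equal(h$aligned_cols, 76L)
  expect_true(h$recruited)

  # one more mismatch dips below 50%
  below <- mutate_at(at_threshold, 1)
  h2 <- recruit_reads(tibble::tibble(read_id = "r", seq = below), ref,
                      keep_all = TRUE, both_strands = FALSE)
  expect_false(h2$recruited)

  # exactly 75 exact columns pass; 74 fail on length alone
  h75 <- recruit_reads(tibble::tibble(read_id = "r", seq = substr(src, 1, 75)),
                       ref, keep_all = TRUE)
  expect_true(h75$recruited)
  h74 <- recruit_reads(tibble::tibble(read_id = "r", seq = substr(src, 1, 74)),
                       ref, keep_all = TRUE)
  expect_equal(h74$identity, 1)
  expect_false(h74$recruited)
})

test_that("RPKM normalises by gene length and library size", {
  expect_equal(compute_rpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_rpkm(37, 924, 2.5e6), 16.017, tolerance = 1e-3)
  # scale invariance in counts and library size jointly
  for (k in c(0.5, 2, 10)) {
    expect_equal(compute_rpkm(k * 37, 924, k * 2.5e6),
                 compute_rpkm(37, 924, 2.5e6))
  }
  expect_error(compute_rpkm(1, 0, 10), "positive")
  expect_error(compute_rpkm(1, 10, 0), "positive")
})

test_that("the per-gene RPKM table counts recruited reads per gene set", {
  refs <- make_gene_refs(len = 240)
  reads <- simulate_reads(refs, 60, divergence = 0.1,
                          read_length = c(80, 120), seed = 8)
  hits <- recruit_reads(reads, refs)
  tab <- rpkm_table(hits, refs, total_reads = 1e5)
  expect_setequal(tab$gene, unique(refs$gene))
  expect_equal(sum(tab$n_reads), nrow(hits))
  expect_equal(tab$rpkm,
               compute_rpkm(tab$n_reads, tab$gene_length_bp, 1e5))
})

test_that("the gene panel holds the 14 marker sets", {
  expect_length(aromatic_gene_panel(), 14)
  expect_true(all(c("dmpB/xylE", "nahAc/ndoB", "sal-hyd") %in% aromatic_gene_panel()))
})
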