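lin <- make_lineages()

test_that("LCA assignment follows hit agreement and the retention band", {
  # single hit: full lineage to genus
  one <- assign_lca(tibble::tibble(record_id = "dmpB_thauera", score = 50), lin)
  expect_equal(one$assignment, "Thauera")
  expect_equal(one$rank, "genus")

  # two genera in one family agree at family
  two <- assign_lca(tibble::tibble(record_id = c("dmpB_thauera", "dmpB_azoarcus"),
                                   score = c(50, 50)), lin, report_rank = "family")
  expect_equal(two$assignment, "Rhodocyclaceae")
  expect_equal(two$rank, "family")
  # the same pair reported at genus level becomes an Unclassified group
  two_g <- assign_lca(tibble::tibble(record_id = c("dmpB_thauera", "dmpB_azoarcus"),
                                     score = c(50, 50)), lin, report_rank = "genus")
  expect_equal(two_g$assignment, "Unclassified Rhodocyclaceae")
  # hits crossing classes agree only at phylum
  two_p <- assign_lca(tibble::tibble(record_id = c("dmpB_thauera", "dmpB_pseudomonas"),
                                     score = c(50, 50)), lin, report_rank = "family")
  expect_equal(two_p$assignment, "Unclassified Proteobacteria")

  # same pair reported at class keeps the agreed class
  two_cl <- assign_lca(tibble::tibble(record_id = c("dmpB_pseudomonas", "nahAc_pseudomonas"),
                                      score = c(50, 50)), lin, report_rank = "genus")
  expect_equal(two_cl$assignment, "Pseudomonas")

  # 10% band: scores 100, 95, 80 retain the first two only
  three <- assign_lca(tibble::tibble(
    record_id = c("dmpB_pseudomonas", "nahAc_pseudomonas", "dmpB_thauera"),
    score = c(100, 95, 80)), lin)
  expect_equal(three$n_retained, 2L)
  expect_equal(three$assignment, "Pseudomonas")

  # no hits
  none <- assign_lca(tibble::tibble(record_id = character(), score = numeric()), lin)
  expect_equal(none$assignment, "Unassigned")
  expect_true(is.na(none$rank))

  # unknown record
  expect_error(assign_lca(tibble::tibble(record_id = "nope", score = 1), lin),
               "no lineage")
})

test_that("adding a retained hit never deepens the assignment", {
  ranks <- c(sipcall:::taxonomy_ranks(), "none")
  depth <- function(r) match(ifelse(is.na(r), "none", r), ranks)
  pool <- lin$record_id
  withr::with_seed(12, {
    for (k in 1:20) {
      base <- sample(pool, sample(1:2, 1))
      extra <- sample(pool, 1)
      d0 <- depth(assign_lca(tibble::tibble(record_id = base, score = 10), lin)$rank)
      d1 <- depth(assign_lca(tibble::tibble(record_id = c(base, extra), score = 10),
                             lin)$rank)
      expect_lte(d1, d0)
    }
  })
})

test_that("taxon profiles roll up, preserve special categories, and pool rare taxa", {
  refs <- make_gene_refs()
  reads <- simulate_reads(refs, 40, divergence = 0.05,
                          read_length = c(90, 120), seed = 3)
  hits <- recruit_reads(reads, refs)
  asg <- assign_reads(hits, lin, read_ids = reads$read_id)
  expect_setequal(asg$read_id, reads$read_id)

  prof <- taxon_profile(asg, rank = "order")
  expect_equal(sum(prof$share), 1, tolerance = 1e-12)
  expect_true(all(prof$taxon %in% c("Rhodocyclales", "Pseudomonadales",
                                    "Unassigned", "other") |
                    startsWith(prof$taxon, "Unclassified")))

  # known 2:1:1 composition rolls up to exact shares when built directly
  mk <- function(order, n) {
    tibble::tibble(read_id = sprintf("%s_%d", order, 1:n),
                   assignment = order, rank = "order",
                   domain = "Bacteria", phylum = "P", class = "C",
                   order = order, family = NA_character_, genus = NA_character_,
                   n_retained = 1L)
  }
  asg2 <- dplyr::bind_rows(mk("O1", 20), mk("O2", 10), mk("O3", 10))
  prof2 <- taxon_profile(asg2, rank = "order")
  expect_equal(prof2$share[match(c("O1", "O2", "O3"), prof2$taxon)],
               c(0.5, 0.25, 0.25))

  # all-Unassigned profile
  none <- assign_reads(hits[0, ], lin, read_ids = c("a", "b"))
  pnone <- taxon_profile(none)
  expect_equal(pnone$taxon, "Unassigned")
  expect_equal(pnone$share, 1)

  # sub-cutoff named taxa pool into "other"; Unassigned is never pooled
  asg3 <- dplyr::bind_rows(mk("Big", 551), mk("Mid", 440), mk("Tiny", 9))
  prof3 <- taxon_profile(asg3, rank = "order")
  expect_false("Tiny" %in% prof3$taxon)
  expect_equal(prof3$n_reads[prof3$taxon == "other"], 9L)
  expect_error(taxon_profile(asg3[0, ]), "no assignments")
})

test_that("prevalence counts gene sets and applies the strict 60% retention", {
  panel <- aromatic_gene_panel()
  det <- dplyr::bind_rows(
    tibble::tibble(gene = panel[1:9], taxon = "Thauera"),
    tibble::tibble(gene = panel[1:8], taxon = "Methyloversatilis"),
    tibble::tibble(gene = panel, taxon = "Pseudomonas"),
    tibble::tibble(gene = panel[1:3], taxon = "Unassigned"))
  prev <- compute_prevalence(det)
  expect_false("Unassigned" %in% prev$taxon)

  th <- prev[prev$taxon == "Thauera", ]
  expect_equal(th$n_detected, 9)
  expect_equal(th$prevalence, 9 / 14, tolerance = 1e-12)
  expect_true(th$retained)

  mv <- prev[prev$taxon == "Methyloversatilis", ]
  expect_equal(mv$n_detected, 8)
  expect_false(mv$retained)

  expect_equal(prev$prevalence[prev$taxon == "Pseudomonas"], 1)

  # prevalence takes values on the k/14 grid; retention flips between 8 and 9
  ks <- purrr::map_dfr(0:14, function(k) {
    d <- if (k == 0) tibble::tibble(gene = character(), taxon = character())
    else tibble::tibble(gene = panel[seq_len(k)], taxon = "t")
    if (k == 0) return(tibble::tibble(k = 0, retained = FALSE))
    p <- compute_prevalence(d)
    tibble::tibble(k = k, retained = p$retained)
  })
  expect_equal(max(ks$k[!ks$retained]), 8)
  expect_equal(min(ks$k[ks$retained]), 9)

  expect_error(compute_prevalence(det, panel = character()), "empty")
  expect_error(compute_prevalence(tibble::tibble(gene = "nope", taxon = "t")),
               "outside the panel")
})
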