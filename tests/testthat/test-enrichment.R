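test_that("the fold-enrichment rule reproduces the canonical calls", {
  # dominant 86.9% OTU at 20-fold over both controls
  dom <- call_enrichment(0.869, 0.869 / 20, 0.0434)
  expect_equal(dom$fold_vs_both, 20, tolerance = 1e-9)
  expect_equal(dom$branch, "tenfold")
  expect_true(dom$enriched)

  # identical abundances: fold 1, not enriched
  same <- call_enrichment(0.05, 0.05, 0.05)
  expect_equal(same$fold_vs_both, 1)
  expect_false(same$enriched)

  # 2.4-fold but predominant: second branch
  two <- call_enrichment(0.12, 0.05, 0.05)
  expect_equal(two$fold_vs_both, 2.4)
  expect_equal(two$branch, "twofold_dominant")
  expect_true(two$enriched)

  # exact threshold ties count as enriched ("at least")
  expect_equal(call_enrichment(0.5, 0.05, 0.05)$branch, "tenfold")
  expect_equal(call_enrichment(0.2, 0.1, 0.1)$branch, "twofold_dominant")
  # the fold is the minimum over both controls
  expect_equal(call_enrichment(0.5, 0.05, 0.25)$fold_vs_both, 2)

  expect_error(call_enrichment(1.2, 0.1, 0.1), "\\[0, 1\\]")
})

test_that("rule and independent transcription agree on a dense grid", {
  g <- seq(0, 1, length.out = 50)
  grid <- expand.grid(ph = g, pch = g, pcu = g)
  mine <- call_enrichment(grid$ph, grid$pch, grid$pcu)
  want <- oracle_enriched(grid$ph, grid$pch, grid$pcu)
  expect_identical(mine$enriched, want)
})

test_that("enrichment is monotone in heavy-fraction abundance", {
  ph <- seq(0, 1, length.out = 201)
  for (ctrl in list(c(0.001, 0.001), c(0.04, 0.02), c(0.2, 0.1))) {
    e <- call_enrichment(ph, ctrl[1], ctrl[2])$enriched
    expect_true(all(diff(as.integer(e)) >= 0))
  }
})

test_that("an OTU at 10% of a control cannot reach the 10-fold branch", {
  ph <- seq(0, 0.999, length.out = 200)
  calls <- call_enrichment(ph, 0.10, 0.001)
  expect_true(all(calls$fold_vs_both < 10))
  expect_false(any(calls$branch == "tenfold"))
  # it remains callable through the dominant 2-fold branch
  expect_true(any(calls$branch == "twofold_dominant"))
})

test_that("table-wide calling joins controls, sorts, and warns on disjoint taxa", {
  t1 <- tibble::tibble(taxon_id = c("a", "b", "c"), count = c(500L, 300L, 200L))
  none <- call_all(t1, t1, t1)
  expect_false(any(none$enriched))
  expect_equal(none$taxon_id, c("a", "b", "c")) # sorted by p_heavy

  # missing taxa fill as zero counts and get pseudo-count folds
  heavy <- tibble::tibble(taxon_id = c("a", "b"), count = c(900L, 100L))
  ctrl <- tibble::tibble(taxon_id = c("b", "d"), count = c(500L, 500L))
  calls <- call_all(heavy, ctrl, ctrl)
  expect_setequal(calls$taxon_id, c("a", "b", "d"))
  a <- calls[calls$taxon_id == "a", ]
  expect_equal(a$p_ctrl_heavy, 0)
  expect_equal(a$fold_vs_both, 0.9 / (0.5 / 1000)) # half-count pseudo
  expect_true(a$enriched)

  disjoint <- tibble::tibble(taxon_id = c("x", "y"), count = c(1L, 1L))
  expect_warning(call_all(heavy, disjoint, disjoint), "no taxa")
  expect_error(call_all(heavy, tibble::tibble(taxon_id = "a", count = 0L), ctrl),
               "zero total depth")
})

test_that("the simulated SIP experiment recovers exactly the labeled taxa", {
  ex <- simulate_sip_experiment(seed = 101)
  truth <- ex$community$taxon_id[ex$community$labeled]
  called <- ex$calls$taxon_id[ex$calls$enriched]
  expect_setequal(called, truth)
  expect_true(all(ex$calls$branch[ex$calls$enriched] == "tenfold"))

  # the high-G+C confounder dominates the control heavy window but is not
  # called: its heavy abundance collapses in the labeled gradient
  confounder <- ex$community$taxon_id[!ex$community$labeled][1]
  conf <- ex$calls[ex$calls$taxon_id == confounder, ]
  expect_gt(conf$p_ctrl_heavy, 0.2)
  expect_false(conf$enriched)

  # determinism of the full pipeline
  ex2 <- simulate_sip_experiment(seed = 101)
  expect_identical(ex$calls, ex2$calls)
})

test_that("a truly labeled high-G+C taxon shifts out of the control window", {
  # same G+C and abundance as the confounder, but assimilating the substrate:
  # the labeled band moves 0.036 g/mL above its unlabeled position, so its
  # heavy-window abundance rises far above the control-heavy abundance ratio
  # seen for the unlabeled confounder
  ex <- simulate_sip_experiment(n_labeled = 1, labeled_abundance = 0.10,
                                labeled_gc_range = c(0.67, 0.67),
                                confounder = FALSE, seed = 11)
  lab <- ex$calls[ex$calls$taxon_id == "otu_001", ]
  expect_gt(lab$p_heavy, 0.9)
  expect_gte(max(ex$window_labeled$density), 1.76)
})
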