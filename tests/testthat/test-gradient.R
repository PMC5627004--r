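test_that("buoyant density follows the linear G+C / labeling model", {
  expect_equal(buoyant_density(0.5, 0), 1.709)
  expect_equal(buoyant_density(0.5, 1), 1.745)
  expect_equal(buoyant_density(0.675, 0), 1.72615)
  # full labeling shifts any G+C by the configured label shift
  gc <- seq(0, 1, by = 0.1)
  expect_equal(buoyant_density(gc, 1) - buoyant_density(gc, 0), rep(0.036, 11))
  expect_error(buoyant_density(1.2), "\\[0, 1\\]")
  expect_error(buoyant_density(0.5, -0.1), "\\[0, 1\\]")
})

test_that("gradient conserves per-taxon DNA mass exactly", {
  for (seed in 1:5) {
    comm <- simulate_community(30, seed = seed)
    grad <- simulate_gradient(comm, total_dna = 73)
    sums <- grad |>
      dplyr::group_by(taxon_id) |>
      dplyr::summarise(m = sum(mass)) |>
      dplyr::arrange(taxon_id)
    expect_equal(sums$m, 73 * comm$base_abundance[order(comm$taxon_id)],
                 tolerance = 1e-9)
    expect_true(all(grad$mass >= 0))
  }
})

test_that("a vanishing band width collapses a taxon into one fraction", {
  comm <- simulate_community(2, seed = 1, abundance = c(1, 1),
                             gc = c(0.50, 0.50))
  grad <- simulate_gradient(comm, sigma_rho = 1e-9)
  m1 <- grad$mass[grad$taxon_id == "otu_001"]
  expect_equal(sum(m1 > 0), 1)
  # the loaded fraction contains the band centre 1.709
  f <- grad$fraction[grad$taxon_id == "otu_001" & grad$mass > 0]
  edges <- attr(grad, "edges")
  expect_true(edges[f] <= 1.709 && 1.709 <= edges[f + 1])
})

test_that("full labeling moves a band heavier by the label shift", {
  comm <- simulate_community(2, seed = 1, labeled_ids = "otu_002",
                             abundance = c(1, 1), gc = c(0.50, 0.50))
  grad <- simulate_gradient(comm)
  centre <- function(id) {
    g <- grad[grad$taxon_id == id, ]
    sum(g$density * g$mass) / sum(g$mass)
  }
  expect_equal(centre("otu_002") - centre("otu_001"), 0.036, tolerance = 1e-3)
})

test_that("gradient input validation rejects degenerate settings", {
  comm <- simulate_community(3, seed = 1)
  expect_error(simulate_gradient(comm, sigma_rho = 0), "positive")
  expect_error(simulate_gradient(comm, density_range = c(1.78, 1.66)), "ascending")
  expect_error(simulate_gradient(comm, density_range = c(1.5, 1.78)), "1.60")
  expect_error(simulate_gradient(comm, n_fractions = 2), "at least 3")
})

test_that("heavy window tracks the heaviest detectable DNA", {
  # single low-G+C taxon: all DNA sits in its own band, lowest fractions
  comm <- simulate_community(2, seed = 1, abundance = c(1, 0),
                             gc = c(0.05, 0.50))
  grad <- simulate_gradient(comm, sigma_rho = 1e-6)
  win <- select_heavy_window(grad)
  expect_equal(nrow(win), 1)
  expect_equal(win$fraction, which(fraction_totals(grad)$total_mass > 0))

  # fully labeled gc = 0.5 taxon banding at 1.745 puts the window at/above 1.74
  comm <- simulate_community(2, seed = 1, labeled_ids = "otu_001",
                             abundance = c(0.5, 0.5), gc = c(0.50, 0.40))
  win <- select_heavy_window(simulate_gradient(comm))
  expect_gte(max(win$density), 1.74)

  # impossible threshold -> explicit no-amplifiable-DNA error
  expect_error(select_heavy_window(simulate_gradient(comm), detection_threshold = 2),
               "no amplifiable heavy DNA")

  # fixed density window override
  win2 <- select_heavy_window(simulate_gradient(comm),
                              density_window = c(1.74, 1.75))
  expect_true(all(win2$density >= 1.74 & win2$density <= 1.75))

  # window widening stays contiguous and ends at the heaviest detectable
  win3 <- select_heavy_window(simulate_gradient(comm), width = 3)
  expect_lte(nrow(win3), 3)
  expect_equal(diff(win3$fraction), rep(1, nrow(win3) - 1))
})
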