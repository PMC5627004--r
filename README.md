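# sipcall

Identifying which microorganisms actually eat a pollutant is harder than
showing that it disappears. In hydrocarbon-impacted waters such as oil sands
process-affected water (OSPW), three lines of quantitative evidence are
combined: **closed-vessel oxidation kinetics** (how fast benzene or
naphthalene is oxidised, and whether CO₂ production matches biomass-coupled
stoichiometry), **DNA stable-isotope probing** (SIP — feeding ¹³C-labeled
substrate so that assimilating genomes become denser and band deeper in a
CsCl gradient), and **gene-centric metagenomics** (recruiting unassembled
reads to catabolic gene reference sets). sipcall implements this inference
chain as a tested, tidyverse-native R package, together with synthetic-data
generators that reproduce the statistical structure each step assumes — so
every caller and estimator can be validated against known ground truth.

It is aimed at environmental microbiologists and bioinformaticians who work
with SIP amplicon tables, microcosm time series, or functional-gene read
screens, and want the decision rules behind such analyses as reusable,
testable functions rather than one-off scripts.

## The models in brief

**Buoyant density.** DNA bands at
ρ(GC, a₁₃) = 1.660 + 0.098·GC + 0.036·a₁₃ g/mL, so full ¹³C labeling mimics
a ~37-point G+C increase — which is why unlabeled high-G+C genomes confound
naive SIP calls. Gradients are simulated as Gaussian bands (σ = 0.006 g/mL)
integrated over fractions, with exact per-taxon mass conservation.

**Enrichment rule.** An OTU is called a ¹³C assimilator when its heavy-window
relative abundance is ≥10× *both* controls (control-gradient heavy window and
unfractionated community), or ≥2× both controls while exceeding 10% of the
heavy window. Zero-control denominators take a half-count pseudo-abundance.

**Kinetics.** Zero-order rates by OLS (rate = |slope|, t-based 95% CI);
Henry's-law closed-vessel partitioning solved mass-balance-exactly
(c_gas = n/(v_g + v_l·H·R·T)); hydrocarbon oxidation balanced with 1 mol
C₅H₇O₂N biomass + 1 mol NH₃ per mol substrate, e.g.

    C6H6  + 2.5 O2 + NH3 -> C5H7O2N + 1 CO2 + 1 H2O
    C10H8 + 7   O2 + NH3 -> C5H7O2N + 5 CO2 + 2 H2O

and observed/expected CO₂ ratios from measured rates.

**Recruitment.** An Rcpp end-gap-free affine aligner (full query, free
reference end gaps; +1/−1 with 2+L gap costs, both strands) recruits reads at
≥50% identity over ≥75 aligned columns; gene sets are expanded at ≥70%
identity to the core; genes are quantified as RPKM; reads are placed by a
minimal lowest-common-ancestor rule; and taxa are summarised by prevalence
across the 14-gene aromatic-degradation panel (retained above 60%, i.e. >8
gene sets).

## Worked example

```r
library(sipcall)

## --- kinetics: a benzene microcosm series shipped with the package
d <- read_kinetics(system.file("extdata", "example_benzene_kinetics.tsv",
                               package = "sipcall"))
fit <- fit_zero_order_rate(d, time_d, substrate_uM)
fit
#> Zero-order depletion rate: 4.129 umol L-1 d-1 (se 0.484, 95% CI [3.126, 5.133], r2 0.7680, n = 24)

co2 <- fit_zero_order_rate(d, time_d, co2_uM, mode = "production")
co2_ratio(co2$rate, fit$rate, balance_biomass_reaction(6, 6))
#> # A tibble: 1 × 4
#>   observed_rate expected_rate ratio ratio_2sf
#>           <dbl>         <dbl> <dbl>     <dbl>
#> 1          5.62          4.13  1.36       1.4
```

The series was simulated at a true rate of 4.3 µmol L⁻¹ d⁻¹ with CO₂
produced at 1.3× the stoichiometric expectation and 5% noise; the fit
recovers 4.13 [3.13, 5.13] and a CO₂ excess of 1.36. With the measured
rates themselves, `co2_ratio(5.6, 4.3, balance_biomass_reaction(6, 6))`
gives the canonical 1.3.

```r
## --- SIP: simulate a labeled + control gradient pair and call assimilators
ex <- simulate_sip_experiment(seed = 1)
ex
#> <sip_experiment>
#>   100 taxa (3 labeled), heavy window 1.741-1.753 g/mL
#>   3 taxa called enriched: otu_001, otu_003, otu_002

dplyr::filter(ex$calls, enriched) |>
  dplyr::select(taxon_id, p_heavy, fold_vs_both, branch)
#> # A tibble: 3 × 4
#>   taxon_id p_heavy fold_vs_both branch
#>   <chr>      <dbl>        <dbl> <chr>
#> 1 otu_001    0.366         14.8 tenfold
#> 2 otu_003    0.301         15.5 tenfold
#> 3 otu_002    0.297         15.5 tenfold
```

The three taxa simulated as fully labeled are exactly the three called, each
through the 10-fold branch; the unlabeled gc = 0.67 confounder dominates the
*control* heavy window and is not called. `autoplot(ex$gradient_labeled)`,
`autoplot(ex$calls)` and `autoplot(fit)` draw the corresponding figures, and
`abundance_class()` maps abundances to the six bubble-plot display classes.

A command-line front end covering the same pipeline
(`simulate`, `fractionate`, `call-enrichment`, `kinetics`, `recruit`,
`rpkm`, `prevalence`, `report`) ships at `inst/cli/sipcall.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/sipcall.R", package="sipcall"))')" simulate --seed 1 --out out/
```

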