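---
title: "Models and methods behind sipcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sipcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipcall)
```

sipcall implements the three quantitative strands used to identify aerobic
hydrocarbon degraders in oil sands process-affected water (OSPW) and similar
hydrocarbon-impacted systems: closed-vessel oxidation kinetics with
biomass-coupled stoichiometry, DNA stable-isotope probing (SIP) with a
two-control fold-enrichment caller, and gene-centric recruitment of
unassembled metagenomic reads with RPKM quantification and a multi-gene
prevalence statistic. Every input the pipeline consumes can be simulated
in-package with known ground truth, so each inferential step is testable
against the truth that generated its data. This vignette explains the models,
their assumptions, the defaults, and the choices made where the design was
genuinely open.

## DNA buoyant density and the gradient model

Equilibrium buoyant density of genomic DNA in a CsCl gradient is modelled
linearly in base composition and isotopic labeling:

$$\rho(\mathrm{GC}, a_{13}) = \rho_0 + k_{GC}\,\mathrm{GC} + \Delta\,a_{13}
\quad\text{g/mL},$$

with defaults $\rho_0 = 1.660$, $k_{GC} = 0.098$ (the classical
composition–density relation) and a full-labeling shift $\Delta = 0.036$
g/mL, all exposed through `buoyant_density()` and the configuration file.
Two consequences drive the whole SIP design:

* a fully ¹³C-labeled genome is about as dense as an unlabeled genome with
  ~37 percentage points more G+C, and
* high-G+C genomes band heavy *without* any labeling — the confound that
  makes single-control SIP calls unreliable.

Absolute densities from this model are nominal. Observed heavy windows in
real gradients (≈1.74–1.75 g/mL) sit above what the composition relation
predicts for any unlabeled genome, because gradient calibration offsets are
instrument- and run-specific. sipcall therefore treats densities as
*relative*: heavy windows are selected per gradient from detectability
(`select_heavy_window()`), and a fixed absolute window is available only as
an explicit override.

`simulate_gradient()` spreads each taxon's DNA
(`total_dna × base_abundance`) over fractions as a Gaussian band centred at
$\rho(\mathrm{GC}, a_{13})$ with standard deviation `sigma_rho` (default
0.006 g/mL). Per-fraction masses are Gaussian integrals over the fraction's
density interval, renormalised per taxon, so mass is conserved to machine
precision even for bands truncated by the modelled range. `sigma_rho` was
chosen so that a gc ≈ 0.67 unlabeled genome leaves detectable DNA in the
top fractions of a control gradient, reproducing the high-G+C control
confound; it is a dispersion parameter, not a calibration claim. Fractions
whose total DNA falls below `detection_threshold` (default 0.5% of loaded
DNA) yield no PCR product and appear as all-zero columns in the amplicon
table — amplicon counts are otherwise multinomial at the requested depth
with probabilities proportional to per-taxon DNA mass in the fraction.

The fraction count and range (20 fractions over 1.66–1.78 g/mL, giving
0.006 g/mL fractions equal to one band standard deviation) are conventions,
config-exposed, chosen to resemble a typical fractionated gradient.

## The two-control fold-enrichment rule

An OTU is called a ¹³C assimilator when its relative abundance in the SIP
heavy window is

* at least 10-fold that in **both** controls (the control gradient's heavy
  window and the unfractionated community), or
* at least 2-fold that in both controls while exceeding 10% of the heavy
  window ("predominant").

Both branches compare against both controls; published descriptions of the
2-fold branch are ambiguous on this point and the two-control reading is
the conservative one, consistent with the 10-fold branch. Ties at exactly
10× or 2× count as enriched ("at least"); the dominance cutoff is strict.
A taxon absent from the heavy window is never enriched. Control abundances
of zero are replaced by half a count at the control's depth (0.5/depth),
the standard continuity correction that keeps folds finite;
`call_enrichment()` exposes the pseudo-abundance directly for
abundance-level use.

The second branch exists because relative abundances saturate: a taxon
already at 10% of a control can never show a 10-fold increase (the maximum
is 1/0.10), so abundant high-G+C taxa that genuinely assimilate label would
be missed by the first branch alone. The caller reports which branch fired,
so downstream interpretation can weigh the weaker evidence of the
2-fold-dominant path.

## The reference simulation scenario

`simulate_sip_experiment()` bundles the study conditions the package uses
as its reference: 100 taxa with log-normal abundances; background G+C
uniform on [0.35, 0.62]; one unlabeled high-G+C confounder (gc 0.67, 10%
abundance) emulating an abundant high-G+C genus that dominates control
heavy fractions; three fully labeled degrader taxa at 2.5/2/2% abundance
with G+C on [0.50, 0.53]; sequencing depth 10⁴ per fraction; heavy windows
three fractions (~0.018 g/mL) wide.

The labeled G+C range and window width were fixed by a band-integral
argument, not by tuning on outcomes: the labeled bands (1.745–1.748 g/mL)
lie more than 3 band standard deviations above the confounder's band
(1.726 g/mL), so the heavy window is essentially pure labeled DNA; and
because the labeled G+C spread is only ~0.5 band standard deviations, a
three-fraction window covers every labeled band nearly evenly, which keeps
each labeled taxon's fold-change against the unfractionated control well
above 10 (the window's labeled purity divided by the summed labeled
abundance, ≈0.95/0.065, scaled by per-taxon window coverage ≥ 0.8). Under
these conditions the caller recovers exactly the labeled taxa through the
10-fold branch, with zero false positives among unlabeled taxa — the
property the test suite verifies over 20 seeded replicates.

What the generator does *not* emulate: PCR and primer bias, chimeras,
sequencing error in amplicons, gradient distortions and wall effects,
partial labeling heterogeneity within a population, and compositional
correlations between G+C and abundance. Passing tests therefore demonstrate
that the inference chain is correct *given* the density-band model, not
that any real gradient is this clean.

## Oxidation kinetics and stoichiometry

Substrate depletion in substrate-amended microcosms is treated as
zero-order (enzymes saturated; the fitted rate is a $V_{max}$):
`fit_zero_order_rate()` is ordinary least squares of concentration on time,
with the rate reported as a positive magnitude via a depletion/production
mode flag, standard error and a 95% confidence interval from the
$t_{n-2}$ distribution. The estimator is checked against a closed-form OLS
oracle to 10⁻¹⁰ and calibrated by simulation: at 5% multiplicative noise,
8 timepoints over 23 days and 1000 replicates, relative bias is below 1%
and CI coverage lies in [93%, 97%]. Simulated series use multiplicative
log-normal noise with mean exactly 1 (concentrations stay positive), with
the benzene-like defaults c₀ = 300 µM, rate 4.3 µmol L⁻¹ d⁻¹, CO₂
produced at `excess_factor` (default 1.3) times the stoichiometric
expectation.

Volatile substrates in sealed vials partition between liquid and headspace
by Henry's law. `henry_partition()` solves the closed system
$n = v_l H p + v_g p/(RT)$ exactly ($R = 0.082057$ L atm mol⁻¹ K⁻¹,
default 293.15 K), giving $c_{gas} = n/(v_g + v_l H R T)$. For the
canonical benzene vial (11 µmol, 20 mL liquid, 100 mL headspace,
H = 0.18 M atm⁻¹) this yields 0.255 mM dissolved and 0.059 mmol L⁻¹ in the
gas phase. Published figures for this vial (0.30 mM / 0.075 mmol L⁻¹) are
not simultaneously consistent with the stated amount, volumes and Henry
constant (they imply 13.5 µmol); sipcall reports the mass-balance-exact
solution and documents the discrepancy rather than reproducing the printed
pair.

Biomass-coupled oxidation of a hydrocarbon $C_aH_b$ is balanced under the
fixed convention of 1 mol biomass ($C_5H_7O_2N$) and 1 mol NH₃ per mol
substrate — the only convention consistent with both canonical equations
(benzene: 2.5 O₂, 1 CO₂, 1 H₂O; naphthalene: 7 O₂, 5 CO₂, 2 H₂O). The
closed forms are $y_{CO_2} = a - 5$, $z_{H_2O} = (b-4)/2$,
$x_{O_2} = 1 + y + z/2$; substrates with $a<5$ or $b<4$ are rejected as
infeasible. Coefficients are held as exact quarter-integers so element
balance is verified in integer arithmetic, with no floating-point
tolerance. `co2_ratio()` reports observed/expected CO₂ production both at
full precision and rounded to two significant figures, the convention used
when such excesses are reported; an excess above 1 indicates less carbon
assimilated than the biomass model predicts or co-oxidation of other
substrates.

## Read recruitment, RPKM, LCA and prevalence

Recruitment emulates a BLASTN-based gene-centric screen without external
dependencies. The aligner (`local_align_identity()`, Rcpp) performs
end-gap-free "glocal" alignment: the full query is aligned against its
best-scoring reference window under affine gaps (match +1, mismatch −1,
gap open −2, gap extend −1; a gap of length L costs 2 + L), both strands
searched. Full-query alignment keeps the joint identity/length filter
well defined — a purely local alignment could trim mismatch-dense read ends
and inflate identity. Identity counts matches over all alignment columns,
gap columns included (BLAST-style). Traceback tie-breaks are fully
specified (match state preferred over reference gap over query insertion;
earliest reference end wins), which makes results reproducible
bit-for-bit and lets the test suite demand *exact* agreement with an
independently coded dynamic-programming oracle on hundreds of simulated
reads.

A read is recruited when its best alignment to any dataset member reaches
50% identity over at least 75 aligned columns (both inclusive). Reference
sets are expanded by admitting candidates with ≥70% identity to any *core*
member, in a single pass — admitted sequences do not recruit further
candidates, preventing identity drift below the threshold relative to the
core. One behaviour worth knowing: because the decision uses the
score-optimal alignment, reads whose generating divergence implies ~45%
naive identity can still reach the 50% threshold — the optimizer re-phases
gaps around coincidental matches, recovering several extra matching
columns. The filter's sharpness is exact at the boundary (a constructed
read at exactly 50% identity over exactly 75/76 columns is recruited; one
extra mismatch or one fewer column flips it), but simulated divergence maps
onto best-alignment identity with an upward shift at high divergence. This
mirrors what permissive unit-cost alignment does in practice and is why
published screens pair such thresholds with statistically grounded search
tools.

Gene abundance is summarised as RPKM — recruited reads per kilobase of
gene per million library reads — using the mean core reference length of
each gene set as the length denominator. Taxonomic assignment is a minimal
MEGAN-style lowest common ancestor: hits within 10% of the best score are
retained (`top_percent`, config-exposed; the original tool's parameters are
not published) and the read is placed at the deepest rank on which all
retained lineages agree, reported as "Unclassified *taxon*" when that rank
is above the report rank and "Unassigned" when there are no hits. Profiles
roll assignments up to a report rank (default order) with named taxa below
1% pooled into "other"; Unassigned/Unclassified categories are never
pooled. Prevalence is the fraction of the 14 aromatic-degradation gene sets
in which a taxon is detected at least once; retention requires prevalence
strictly above 60%, so 9 of 14 gene sets retain a taxon and 8 do not.

## Numerical conventions and problem sizes

* Random draws are seeded explicitly everywhere; identical seeds give
  bit-identical communities, gradients, tables, reads and series. Internal
  seeding uses one stream per experiment (`with_seed`), restoring the
  caller's RNG state.
* Abundance display classes follow the printed bubble-plot bins
  (1–1.75%, 1.76–4.5%, 4.6–9%, 9.1–18.5%, 18.6–37.5%, >37.6%); values in
  the unprinted gaps between labels fall to the nearest lower class, and
  abundances at or below 1% are "not displayed".
* The test suite sizes its simulations to run in minutes on one core: the
  enrichment rule is checked against an independent transcription on a
  50×50×50 abundance grid; caller recovery over 20 seeded experiments;
  recruitment against the DP oracle on 500 reads (75–150 bp) with three
  420 bp references; estimator calibration on 1000 replicate series.
* OTU tables are written as TSV with density-bearing column headers printed
  at 17 significant digits so densities round-trip exactly; configuration
  round-trips through YAML losslessly.

## Limitations

The gradient model is deliberately minimal — one Gaussian band per taxon,
no gradient-to-gradient calibration drift, no DNA quantity effects on
banding — so the absolute heavy-window densities it produces should not be
compared against real gradients. The enrichment caller inherits the
limitations of relative abundances: heavily labeled but rare taxa below the
amplicon detection limit are invisible, and the 2-fold-dominant branch
trades specificity for sensitivity on abundant high-G+C taxa. The
recruitment module's unit-cost scoring is permissive at 50% identity (see
above); results at that margin characterise the filter, not gene presence.
The LCA implementation resolves only the six-rank lineage it is given and
has no notion of database coverage bias.
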