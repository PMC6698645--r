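---
title: "Single-fibre mtDNA deletion analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-fibre mtDNA deletion analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofibre)
```

# Scope

In adult-onset mtDNA maintenance disorders (pathogenic variants in *POLG*,
*TWNK*, *RRM2B*, *SLC25A4* and similar genes), skeletal muscle accumulates
multiple, clonally expanding mtDNA deletions, producing a mosaic of
respiratory-chain-deficient fibres. `mitofibre` implements the quantitative
single-fibre toolchain for such data:

1. quadruple-immunofluorescence densitometry (porin / NDUFB8 / COX-I)
   z-scoring and fibre classification;
2. triplex qPCR quantification of deletion level (MT-ND1, MT-ND4, D-loop);
3. deletion annotation on the circular rCRS genome and perfect
   direct-repeat detection at breakpoints;
4. limiting-dilution single-molecule PCR (smPCR) Poisson mathematics and
   species-proportion estimation;
5. a Moran-process simulator of clonal expansion under neutral drift or a
   length-dependent replicative advantage ("survival of the smallest");
6. seeded synthetic-data generators so every stage is testable end to end.

Two published single-cell result tables (the long-range PCR deletion
characterisation and the smPCR species summary) ship as checksummed
fixtures; `load_paper_fixtures()` returns them validated.

# Immunofluorescence model

Each fibre carries background-corrected optical densities for porin
(mitochondrial mass), NDUFB8 (complex I) and COX-I (complex IV).
Background correction subtracts the per-channel mean of a no-primary
control section and clips at zero (`background_correct()`); the upstream
image segmentation that produces the OD tables is out of scope.

Over control fibres, each probe channel is regressed on porin by ordinary
least squares (`fit_control_model()`); a patient fibre's z-score is its
residual from that control line in units of the control residual SD, and
porin gets a plain control z-score. Whether this referencing should happen
in linear or log OD space is not settled in the prior literature, so both
are provided (`log_transform`); linear space is the default.

Classification boundaries (`if_thresholds()`), all configurable:

* per-channel levels: normal (z >= -3), intermediate(+) (-4.5 <= z < -3),
  intermediate(-) (-6 <= z < -4.5), deficient (z < -6). The exact interior
  boundaries come from the prior method this assay family uses; the values
  here are the package defaults.
* three-group respiratory-chain (MRC) call: a channel is "-" when z < -3,
  giving CI+CIV+ / CI-CIV+ / CI+CIV- / CI-CIV-.
* mitochondrial-mass bands: porin z cut at -3, -2, +2, +3 into very_low /
  low / normal / high / very_high, mirroring the five colour bands of the
  standard MRC profile plot.
* ragged-red fibres (RRF): porin z strictly greater than 2.5, exactly as
  the operational definition is printed.

`summarize_cohort()` reports counts and percentages (one decimal place,
zero-filled categories) for the MRC mix, the MRC mix among RRF and fibre
types among RRF; `mrc_plot_data()` / `plot_mrc_profile()` produce the
profile scatter.

# Triplex qPCR model

Template copies come from inverting a plasmid standard curve
`Cq = m log10(copies) + b` (`fit_standard_curve()`, `cq_to_copies()`);
amplification efficiency is `10^(-1/m) - 1`. Replicates (typically
triplicate) aggregate by median with a QC flag when the replicate range
exceeds 0.5 cycles — a conventional plate-QC rule, configurable.

Deletion metrics per fibre:

* `del_nd4_nd1_pct = (1 - ND4/ND1) * 100` — the deletion level proper;
* `nd1_dloop_pct`, `nd4_dloop_pct` — each coding target relative to the
  D-loop.

The control region can carry a third (7S) DNA strand, so D-loop qPCR
counts up to 1.5 templates per molecule: a coding target can apparently be
"deleted" by up to 1/1.5 = 33.3% relative to the D-loop in a fibre with no
deletion at all. Hence the classification rule: a target counts as deleted
only when its D-loop-relative percentage is strictly above 33
(`classify_triplex()`), partitioning fibres into none / ND4_deleted /
ND1_deleted / both. Metrics are never clipped — small negative values are
legitimate measurement noise and classification uses the raw values. All
three metrics are reported; classification uses the two D-loop-relative
ones, which is what the shaded-region read-out of the published scatter
plots encodes.

# Genome annotation

Coordinates are 1-based inclusive in rCRS (NC_012920.1) numbering. A
deletion is stored by its last retained 5' base `bp5` and first retained
3' base `bp3`; the removed bases are the open interval `(bp5, bp3)`, so
`size = bp3 - bp5 - 1`. This convention is forced by the data: all 30
printed deletion sizes in the bundled table satisfy it exactly. Wrapping
deletions (`bp5 > bp3`) are rejected rather than normalised — none occur
in the data, and silent normalisation would mask coordinate errors.

A feature is *fully removed* iff its span lies inside the open interval,
*partially removed* iff it overlaps without containment
(`annotate_deletion()`; a per-position brute-force oracle checks this in
the tests). The built-in map carries the 13 protein genes, both rRNAs,
O~L~ (5721–5798) and the control region (16024–576, the only feature
allowed to wrap the origin of numbering). Note that the wrap makes
positions 1–576 part of the control region: a deletion removing np 101
*does* nick the control region. The minor arc is flagged as the interval
between the control-region 3' end and the O~L~ start; nothing downstream
depends on it.

`expected_triplex_class()` maps an annotation to the class the triplex
assay should report. Partial removal counts as removed: the qPCR probes
sit inside the genes and probe coordinates are not modelled, and the data
support this (e.g. a deletion ending inside MT-ND4 still abolishes the
ND4 signal). On the bundled table this cross-check (`concordance()`)
agrees for most products and surfaces genuine disagreements — e.g. one
product whose D-loop metrics say "both" while its sequenced breakpoints
spare MT-ND1 — rather than hiding them.

# Junction repeats

A deletion junction carries a perfect direct repeat when the retained
sequence ending at `bp5` and the retained sequence starting at `bp3`
share a common affix: the last *k* bases of the 5' flank equal the first
*k* bases of the 3' flank (`longest_junction_repeat()`). Repeats of 2 bp
or shorter are classed as "no repeat", following the printed >= 3 bp
convention; imperfect or shifted repeats are out of scope because every
repeat in the source data is perfect. Flanks can be supplied directly or
extracted from a circular reference (`flanks_from_reference()`), and both
paths feed the same finder.

Data-quality note: the bundled table's marked repeats (4–13 bp) all
reproduce exactly, and no "no repeat" row hides an affix of 4 bp or more;
four rows, however, carry a 3 bp common affix despite being printed "no
repeat" — the table's de facto marking threshold is 4 bp. Likewise its
companion text counts "13 (42%)" junctions with 2–11 bp repeats, which
matches neither the >= 2 (15/30) nor the >= 3 (14/30) tally.
`repeat_count_summary()` reports both thresholds and the package does not
attempt to reconcile the printed count.

# smPCR Poisson mathematics

At limiting dilution, molecules land in wells as Poisson(lambda); the
positive-well fraction `p = 1 - e^-lambda` inverts to
`lambda = -log(1 - p)` (`estimate_lambda()`, with a Wilson interval on
`p` transformed through the same map; a fully positive plate is an error
instructing further dilution). `dilution_factor()` plans the dilution to
the 1-in-4 operating point, and `multiplicity_probability()` quantifies
the residual chance a positive well held more than one molecule —
about 13.7% at p = 1/4.

Species proportions (`species_proportions()`) are raw positive-well
fractions per amplicon size with 95% Wilson intervals, deliberately
without Poisson co-occupancy correction, because that is the stated plate
read-out these data use; at the operating point the induced size bias is
small (the synthetic generator reproduces it, and the tests quantify it
at high lambda).

The replicative-advantage statistic: among cells with at least two
deletion species, how often does the species with the *largest* deletion
(the smallest, fastest-replicating molecule) have the highest proportion?
`largest_prevalence()` computes this per patient; cells with tied top
proportions or tied maximal sizes are excluded from the numerator and
reported separately, because the statistic claims strict prevalence. On
the bundled table this yields 4/10 (40.0%), 5/12 (41.7%) and 3/8 (37.5%)
for the three patients — reproducing the published fractions requires
recomputing from the size/proportion columns and *ignoring* the table's
own "is the largest deletion highest level?" column, which contradicts
its neighbouring columns for one fibre. `flag_smpcr_anomalies()` surfaces
that contradiction, a fibre whose proportions sum to 1.36, and a fibre
listing the same size twice; nothing is silently renormalised.

# Clonal-expansion simulator

The competing hypotheses for clonal expansion are random genetic drift
under relaxed replication and a replicative advantage for shorter
genomes. Neither comes with specified dynamics, so the package commits to
a Moran process: each event removes one molecule uniformly and copies one
chosen with probability proportional to `count_i * w_i`, with
`w_i = (L_wt / L_i)^alpha`. This makes `alpha = 0` exact neutrality and
`alpha = 1` replication rate inversely proportional to genome length (the
naive replication-time argument); both draws come from the pre-event
state. Total copy number is fixed — justified by the observation that
deficient fibres show no mtDNA depletion — and time is measured in Moran
events, with no calendar-time calibration attempted. De novo deletion
formation is off by default (cells start with existing species, matching
endpoint data); `simulate_cell()` offers a per-event formation
probability for exploratory runs.

`simulate_cohort()` reports heteroplasmy quantiles, fixation/loss counts
and the smPCR-comparable statistic: the fraction of multi-species cells
whose smallest genome is most prevalent. Two deliberate choices:

* the wild-type is excluded from the comparison set by default, because
  the smPCR assay sees only deleted molecules (configurable);
* cells with tied top counts or tied minimal lengths are excluded from
  numerator *and* denominator (strict ordering), unlike the data-side
  `largest_prevalence()`, which keeps ties in the denominator. The
  simulator's version makes the neutral symmetry exact: with two
  exchangeable deleted species the expected fraction is exactly 0.5,
  which the tests verify to Monte-Carlo precision.

`compare_to_observed()` closes the loop with a two-sided exact binomial
probability (minimum-likelihood method, no asymptotics) of an observed
prevalence count under a simulated fraction.

Verification: one-step transition frequencies match the exact Moran
kernel at small N; mean heteroplasmy is a martingale under neutrality;
neutral fixation probability equals initial frequency; and the prevalence
fraction is non-decreasing in alpha across paired seeds.

# Synthetic-data generators

All generators are pure functions of `(config, seed)`
(`synth_config()`); defaults were fixed once, before any result was
inspected, to describe a realistic mosaic biopsy:

* **IF cohort** (`gen_if_cohort()`): 100 controls, 300 patient fibres;
  controls scatter about known channel-on-porin lines (residual SD 0.05
  OD); half the patient fibres are unaffected, the rest carry
  Beta(2.5, 1.2) deletion levels (right-skewed, as clonal expansion
  produces); deficiency follows a thresholded linear link
  `z = -s * max(0, h - h0)` with `h0 = 0.45, s = 12` for complex I and
  `h0 = 0.60, s = 14` for complex IV — complex I deficits appear at lower
  deletion levels, the simplest shape consistent with the threshold
  behaviour these assays report; porin gains an RRF boost above `h = 0.8`.
  Ground-truth z-shifts and classes are emitted alongside, so zero-noise
  recovery is exact against the generating model and about 98% of fibres
  planted at least one z-unit from any boundary classify correctly under
  default noise (0.02 OD, i.e. 0.4 z-units).
* **Triplex plates** (`gen_triplex_plate()`): ideal slope -3.3219 (100%
  efficiency), intercept 38, Gaussian Cq noise (default SD 0.1 cycles,
  triplicates), standards 10^2..10^7. The triple-stranded D-loop fraction
  defaults to 0.5, midway between the all-double and all-triple limits of
  the 33% rule; the molecule-counting bookkeeping is exported
  (`true_triplex_copies()`) so tests can enumerate molecules
  independently. Because a fitted standard curve is shared by every fibre
  on a plate, unbiasedness of recovered deletion levels is assessed
  across independent plates (8 x 25 fibres in the tests), not across
  fibres within one plate.
* **smPCR plates** (`gen_smpcr_plates()`): Poisson occupancy at
  lambda = 0.25 over 96 wells, multinomial species identity, and a
  positive well labelled by the smallest genome present, modelling PCR
  preference for short templates. At the operating point this size bias
  is negligible; at high lambda the tests show it suppresses the
  small-deletion species, which is why the dilution step exists.
* **Deletion sets** (`gen_deletion_set()`): uniform-random circular
  reference; a configured fraction of deletions is repeat-mediated by
  writing a random k-mer at both junctions (junction windows kept
  disjoint across deletions, and the bases immediately outside the
  planted copies forced to differ, so recovery is exact at the planted
  length).

What the generators do *not* emulate: real patients' heteroplasmy
distributions, probe-level qPCR chemistry, inter-section fibre-matching
error, or amplification failure. Passing recovery tests therefore shows
the estimators are correct under their stated observation models, not
that those models exhaust real data.

# Numerical and data-quality choices

* Percentages print to one decimal place and empty categories report 0.
* The 33% rule, the RRF 2.5 cut, and the >= 3 bp repeat rule are strict
  inequalities / thresholds exactly as printed, all configurable.
* The `(100, 102)` style single-base deletions are valid; `bp5 >= bp3 - 1`
  (empty deletion) is an error.
* The bundled deletion table holds 30 products over 21 cells; the
  accompanying text's total of "31" disagrees with the table's own
  14/5/2 cell grouping (14 + 10 + 6 = 30), and the table rows are treated
  as authoritative. Similarly, the text's pooled smPCR multiplicity
  percentages (62.8/34.6/2.6) imply a different denominator than the 79
  table rows and are not recomputed here; `multiplicity_distribution()`
  reports the exact per-table counts instead.
* Fixture integrity is enforced by md5 checksums at load.

# Problem sizes

The stochastic test batteries use: 2,000 cells for the neutral symmetry
and martingale checks, 1,500–2,000 cells at N = 16 for fixation, 10^5
draws for the one-step kernel, 10^4 random flank pairs for the
finder-vs-oracle sweep, 8 plates x 25 fibres for qPCR unbiasedness and 50
plates x 96 wells for lambda recovery — sizes at which three standard
errors separate every asserted effect from its null by a comfortable
margin.

# Worked example

```{r example}
fx <- load_paper_fixtures()

# deletion sizes and junction repeats from the long-range PCR table
d <- fx$deletions
all(deletion_size(d$bp5, d$bp3) == d$size_printed)
longest_junction_repeat(
  d$five_prime_flank[d$product_id == "4Y"],
  d$three_prime_flank[d$product_id == "4Y"])

# the replicative-advantage statistic from the smPCR table
largest_prevalence(fx$smpcr)

# and its neutral-drift reference point
cfg <- sim_config(list(species_spec("delA", 11, 50L),
                       species_spec("delB", 6, 50L)),
                  alpha = 0, n_steps = 150L, n_cells = 500L, seed = 1)
sim <- simulate_cohort(cfg)
sim$smallest_prevalent$fraction
compare_to_observed(sim$smallest_prevalent$fraction, 4, 10)$p_value
```

# Known limitations

* No image segmentation, fibre matching or raw-fluorescence Cq calling:
  the package starts from exported OD and Cq tables.
* No breakpoint discovery from reads and no imperfect-repeat scoring.
* The smPCR proportion estimator inherits the raw-fraction convention of
  the assay; the Poisson co-occupancy EM correction is deliberately not
  the default.
* The simulator has no spatial (perinuclear-niche) structure and does not
  infer alpha from data beyond the exact binomial comparison.
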