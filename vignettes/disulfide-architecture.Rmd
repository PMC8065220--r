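---
title: "Profiling disulfide architecture of ER cargo under hypoxia"
author: "DisulfideArch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling disulfide architecture of ER cargo under hypoxia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DisulfideArch)
```

## The scientific problem

Proteins destined for secretion or the plasma membrane mature in the
endoplasmic reticulum (ER), where most of them acquire disulfide bonds.
Disulfide formation is a net oxidation that needs a terminal electron
acceptor, canonically molecular oxygen — yet many proteins that are
transcriptionally *induced* by hypoxia (such as VEGF-A and CA9) are
secreted or displayed efficiently with no oxygen at all, while others
(such as LDLR) stall in the ER. One candidate explanation is
architectural: proteins that depend less on post-translational disulfide
*isomerization* — fewer free cysteines that can form non-native pairings,
and shorter-range bonds whose first cysteine spends less time unpaired —
should fold better anoxically.

`DisulfideArch` implements the quantitative side of testing that idea:

1. an annotation model and TSV dialect for protein records (signal
   peptide, topological domains, disulfide features, locations);
2. an operational ER-cargo filter and a hypoxia-induction grouping driven
   by gene-level fold changes;
3. per-protein disulfide metrics with cytosolic portions of membrane
   proteins excluded;
4. two-group comparisons with exact or normal-approximation Mann–Whitney
   tests (plus a pooled-variance t-test for densitometry endpoints);
5. pulse-chase densitometry fractions and the oxidative-folding-fitness
   summary percentage;
6. membrane-localization quantification from calibrated fluorescence
   images;
7. synthetic-data generators for all of the above, with exactly
   recoverable ground truth.

## The data model and its conventions

All residue coordinates are 1-based inclusive, following UniProt; no
0-based representation is ever exposed. The interchange format is a TSV
dialect modeled on UniProt tab downloads: one protein per row and
flat-file-style feature strings (`DISULFID 27..39`,
`DISULFID 54..? /note=Interchain`), chosen because it is deterministic,
diff-able and easy to synthesize; XML/DAT parsing and isoform handling
are out of scope. Bonds with unknown coordinates (`?`) are retained and
flagged rather than dropped, and each downstream metric decides their
treatment. Subcellular locations are matched by case-insensitive
substring against a small controlled vocabulary, mirroring keyword-style
filtering of curated location phrases.

## Cargo selection

A record is ER cargo when it has a signal peptide, a location matching
`secreted` or `cell membrane`, and no location matching
`endoplasmic reticulum` or `golgi apparatus` (residents of the secretory
organelles are excluded; exclusion dominates). Induction grouping uses
linear fold changes after 24 h anoxia in two cell lines, HCT116 and
HepG2, with two bands: induced means above 2.0 in *at least one* line;
noninduced means below 1.2 in *every measured* line. The "at least one /
every" resolution keeps the induced call permissive and the noninduced
group conservative. The two bands are not exhaustive: intermediate genes
are assigned `EXCLUDED`, genes absent from the table `UNMEASURED`, and
both are reported rather than silently dropped — pooling versus dropping
single-line measurements is a genuinely open choice, so the package
exposes the ambiguity instead of guessing.

## Disulfide metrics

For each cargo protein we count intrachain bonds `D`, interchain bonds
`I`, and cysteines over the *effective region*: for membrane proteins,
all residues minus the union of topological domains annotated
`Cytoplasmic` (overlaps unioned); a bond is excluded iff either of its
known endpoints falls outside. Derived quantities:

* bonds per 100 amino acids, `100 (D + I) / effective length`;
* fraction of cysteines bonded, `(2D + I) / n_cys` — undefined (and
  omitted from comparisons) when no cysteine lies in the region;
* free cysteines, `n_cys − 2D − I`, since every cysteine not annotated in
  a bond is assumed to be a free thiol;
* bond range: the number of amino acids between the paired cysteines,
  read strictly as the residues *between* them, `cysB − cysA − 1`. The
  alternative `cysB − cysA` convention is one configuration switch away
  (`rangeConvention = "delta"`) because group means alone cannot
  adjudicate between the two readings.

Two further conventions are deliberate. The signal peptide is retained in
the effective length by default (removing cytosolic portions is stated;
removing the signal peptide is not), with `trimSignalPeptide = TRUE` as
the documented alternative. Unknown-position bonds count toward `D`/`I` —
the architecture exists even when coordinates are missing, and excluding
them would bias bond counts downward — but they contribute no range.

## Group statistics

Per-protein values are compared between induced and noninduced cargo
within each class with a two-sided Mann–Whitney test. `U = min(U_x, U_y)`
comes from midrank rank sums; the p-value is exact (full enumeration of
rank assignments through the standard counting recurrence) when the
pooled sample is tie-free and of size at most 14 — a threshold balancing
runtime against fidelity, configurable via `exactMax` — and otherwise a
tie-corrected, continuity-corrected normal approximation. All-equal
pooled samples are degenerate: `p = 1`, flagged. Bond ranges are compared
per *bond* (pooled across proteins) by default, matching
distribution-of-ranges plots; a per-protein mean-range option exists
because either unit of analysis is defensible. The six standard
comparisons are reported with raw p-values and no multiplicity
correction by default; Benjamini–Hochberg adjustment is available but
off by default. Densitometry endpoints use the pooled-variance
two-sample t-test.

## Pulse-chase densitometry

Band intensities are background-subtracted arbitrary units; lane
background modeling and image-to-band extraction are out of scope. The
conventions implemented are:

* secreted fraction: `SECRETED(t) / (SECRETED(15) + LYSATE(15))`,
* dimer fraction: `DIMER(t) / (DIMER(0) + MONOMER(0))`,
* Golgi fraction: `GOLGI(t) / (GOLGI(t) + ER(t))` (same-lane,
  contemporaneous).

"Relative to the X-min time point" is read as normalization by the
*total* signal at the reference time, so any loss or gain versus the
reference stays visible; this is well defined because total signal is
conserved over the chase (no degradation), an assumption the synthetic
gels enforce and the tests check. Dimer intensity is taken as-is — no
stoichiometric doubling for the two labeled monomers per dimer — with
`doubleDimer = TRUE` as the alternative, since neither convention is
forced by the arithmetic. Fractions are computed per replicate, then
summarized with
n−1 SD and SEM. Oxidative folding fitness is
`100 × fraction(anoxia) / fraction(normoxia)` at the longest assayed
chase time, capped at 100%.

## Membrane localization

The whole-cell area is the inverse of an externally supplied background
annotation (interactive segmentation is not reimplemented). The membrane
band is the morphological dilation of the background by an exact
Euclidean disk of radius `round(dilationUm / umPerPixel)` pixels
intersected with the cell area — equivalently, the cell pixels within the
dilation distance of background. At the reference calibration of
0.1083 µm/pixel, a 2 µm dilation gives radius `round(18.47) = 18` px.
A "2 µm dilation" protocol step is ambiguous about direction — dilating
the background annotation inward versus a cell annotation outward; the
inward dilation of the background (a band just inside the cell edge) is
what is implemented. Two
readouts are reported: the integrated-intensity `membraneFraction`
(bounded in [0, 1], the headline output — the natural scale for a
statement like "80% of the protein is at the membrane") and the
`meanIntensityRatio` of band to whole-cell mean intensities, which
matches a mean-intensity measurement protocol but is not bounded by 1.
The two conventions genuinely differ, which is why both are computed.

## The synthetic-data generators

`simulateProteome()` is the stand-in for an annotation snapshot and the
unpublished anoxia microarray lists; its defaults *are* the study
conditions:

* 112 induced and 313 noninduced cargo, split evenly between secreted and
  membrane classes (the per-class split is not part of the study
  conditions; an even split is the neutral choice), plus configurable
  excluded, unmeasured and non-cargo distractor records;
* group means of bonds/100aa: secreted 1.30/0.83, membrane 0.95/0.58;
  mean secreted bond ranges 24.25/31.02 (membrane ranges default to 28/28
  — no between-group difference);
* group SDs defaulting to the study-condition SEMs (0.16/0.08 secreted,
  0.19/0.08 membrane) scaled by √n at the group sizes 112/313, giving
  1.69/1.42 (secreted) and 2.01/1.42 (membrane) — calibrated once and not
  revisited. Bond counts are
  gamma-mixed Poisson, which reproduces both the means (exactly, in
  expectation) and these heavy-tailed spreads; the gamma shape is derived
  internally by subtracting the Poisson floor from the target variance;
* free-cysteine counts Poisson with means 1 (induced) vs 3 (noninduced) —
  not printed anywhere, chosen once as realistic anchors (a poor anoxic
  folder carries 3 free cysteines; a good one 2) that reproduce the
  direction of the bonded-fraction contrast;
* residue lengths log-normal (median 450, log-SD 0.45), floored at 150
  (secreted) / 230 (membrane) so every membrane protein can carry a
  signal peptide, an extracellular domain, a transmembrane helix and a
  30–80 residue cytosolic tail.

Records are emitted as cysteine-position lists plus length; a
deterministic placeholder-sequence emitter (`writeRecords(...,
withSequence = TRUE)`) exists for exercising sequence-derived parsing.
Bond placement retries bounded-many times per bond and falls back to any
free cysteine pair; a bond that cannot be placed at all is dropped *and
the ground truth records only what was planted*, so truth recovery stays
exact instead of failing a large run.

`simulateGel()` plants a conversion curve
`f(t) = fTarget (1 − e^{−kt}) / (1 − e^{−k t_max})` with conserved total
lane signal and multiplicative log-normal band noise of a configurable
CV, so the terminal fraction equals `fTarget` exactly and zero-noise runs
recover the curve exactly. Mode defaults plant the study-condition
terminal fractions (secreted 0.80/0.80 at 120 min with a slower anoxic
rate; dimer 0.80/0.50 at 60 min; Golgi 0.80/0.10 at 120 min).

`simulateCells()` draws non-overlapping disk cells and assigns the
planted membrane fraction of each cell's integrated signal uniformly to a
rim whose geometry uses the same Euclidean distance-to-background
criterion as the measurement band (via an exact distance transform).
This makes the planted fraction recoverable exactly at zero noise when
the rim width equals the band width — the default, 2 µm — and within a
small discretization error otherwise; pixel noise is Poisson. What these
images do *not* emulate: a microscope PSF, uneven illumination,
non-circular cells, cytoplasmic texture, or segmentation error in the
background annotation, so passing recovery tests demonstrates correct
mask geometry and intensity bookkeeping, not robustness to real staining
artifacts.

What passing the proteome-generator tests shows — and does not show: the
pipeline recovers planted architecture exactly and detects the planted
group contrasts at the study scale; it does not validate the biological
annotation quality of any real database snapshot, and group counts
obtained from a live database are release-dependent and not reproducible
at desk scale.

## Numerical choices and degenerate inputs

* Exactness threshold `n ≤ 14` (tie-free) for the Mann–Whitney exact
  path; the normal approximation is within 0.01 of exact by n = 20 + 20.
* Degenerate comparisons (all pooled values equal; zero pooled variance
  in the t-test) return `p = 1` (or `p = 0` for a zero-variance mean
  difference) with an explicit flag, never `NaN`.
* Zero reference totals in densitometry, empty comparison groups, empty
  cell masks, zero cell intensity and dilation radii that round to zero
  pixels raise explicit errors or flagged `NA`s.
* Records annotating more bonded cysteines than cysteines present are
  rejected as inconsistent rather than yielding negative free-cysteine
  counts.
* Ties in ranks use midranks; quantiles are type-7 (R default).

## Problem sizes used in the checks

The shipped tests run the oracle-equivalence recount on a 1,000-record
proteome, the planted-contrast power analysis on 100 replicate runs of
the 112-vs-313 secreted condition, the null-calibration of the
Mann–Whitney test on 1,000 simulations at n = 40 + 40, image recovery on
20 seeded 384×384 images, and exhaustive band-mask checks against a
brute-force distance oracle on images up to 64×64 — sizes chosen so the
whole suite completes in a few minutes on one core while keeping every
statistical tolerance at 3 standard errors or better.

## A short worked example

```{r example}
sim <- simulateProteome(proteomeSimConfig(), seed = 1)
asg <- buildGroups(sim$records, sim$expression)
mt  <- suppressMessages(metricsTable(sim$records, asg))
suppressMessages(compareGroups(mt, "bondsPer100aa", "SECRETED"))
```

```{r gel}
gel <- simulateGel("secreted", noiseCv = 0)
fractionSecreted(gel$bands, "21% O2", 120)$fraction
```

```{r image}
cells <- simulateCells(membraneFractionTrue = 0.8, seed = 1)
membraneFraction(localizationRatio(cells$image))
```

## Known limitations

* The cargo filter is operational, not mechanistic: it inherits every
  limitation of keyword location annotation, and proteins measured in
  only one cell line are grouped by that single measurement.
* Free-thiol status is inferred from the *absence* of a bond annotation;
  incomplete annotation inflates free-cysteine counts (assumed unbiased
  between groups, but untestable here).
* The interchain-bond count `I` counts bond records on the chain at hand;
  stoichiometry of the partner chain is not modeled.
* The image module accepts the background annotation as ground truth;
  segmentation quality is entirely upstream.
* Headline group counts and p-values from real data depend on a specific
  annotation release and on expression lists that are not distributable;
  the package reproduces the *procedure* and demonstrates it on synthetic
  data with known truth.
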