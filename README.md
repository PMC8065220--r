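# DisulfideArch

Disulfide-bond architecture profiling of endoplasmic reticulum (ER)
cargo proteins, split by hypoxia inducibility — plus the pulse-chase
densitometry fractions and the fluorescence membrane-localization ratio
that accompany such analyses.

## The problem

Most proteins that traverse the secretory pathway need disulfide bonds,
and disulfide formation is a net oxidation that canonically consumes
molecular oxygen. Yet hypoxia-*induced* ER cargo (VEGF-A, CA9) matures
and reaches the extracellular space without oxygen, while other cargo
(LDLR, influenza HA) stalls. If the difference is architectural —
hypoxia-induced proteins relying less on post-translational disulfide
*isomerization* — it should show up as fewer free cysteines and
shorter-range bonds in the induced group.

`DisulfideArch` implements that comparison as a tested, reusable
pipeline for R:

* **Annotation model** — parse/write a UniProt-style TSV dialect into
  validated `ProteinRecord`/`ProteinSet` S4 objects (1-based
  coordinates; `DISULFID 27..39`, `DISULFID 54..? /note=Interchain`).
* **Cargo selection** — ER cargo = signal peptide + location matching
  `secreted`/`cell membrane`, minus ER/Golgi residents; induction groups
  from linear fold changes after 24 h anoxia (induced `> 2.0` in ≥ 1
  cell line; noninduced `< 1.2` in all measured lines; intermediate and
  unmeasured genes reported, not dropped).
* **Disulfide metrics** — per protein, over the effective region
  (cytosolic portions of membrane proteins removed): intrachain bonds
  `D`, interchain bonds `I`, bonds per 100 aa
  `100(D+I)/effective length`, bond ranges `cysB − cysA − 1`, fraction
  of cysteines bonded `(2D+I)/n_cys`, free cysteines `n_cys − 2D − I`.
* **Group statistics** — two-sided Mann–Whitney tests (exact by full
  enumeration for tie-free pooled samples up to n = 14, tie-corrected
  normal approximation otherwise), group summaries (mean ± SEM, median,
  IQR), pooled-variance Student's t for densitometry endpoints.
* **Pulse-chase quantification** — secreted / dimer / Golgi fractions
  from band tables under the standard legend conventions, and the
  oxidative-folding-fitness percentage
  `100 · fraction(anoxia)/fraction(normoxia)`, capped at 100.
* **Membrane localization** — whole-cell mask as the inverse of a
  background annotation; membrane band as a micron-calibrated Euclidean
  dilation of the background (18 px for 2 µm at 0.1083 µm/pixel)
  intersected with the cell; integrated-intensity fraction and
  mean-intensity ratio.
* **Synthetic data** — generators for all three input classes with
  exactly recoverable ground truth; proteome defaults plant 112 induced
  vs 313 noninduced cargo with group means 1.3/0.83 (secreted) and
  0.95/0.58 (membrane) bonds per 100 aa and secreted mean ranges
  24.25/31.02.

See `vignettes/disulfide-architecture.Rmd` for the full methods account.

## Worked example

```r
library(DisulfideArch)

sim <- simulateProteome(proteomeSimConfig(), seed = 1)
asg <- buildGroups(sim$records, sim$expression)
mt  <- metricsTable(sim$records, asg)
compareGroups(mt, "bondsPer100aa", "SECRETED")
#> GroupComparison: bondsPer100aa (SECRETED)
#>   INDUCED: n=56 mean=1.23 (SEM 0.26) median=0.458 IQR [0.12, 1.735]
#>   NONINDUCED: n=156 mean=0.8433 (SEM 0.11) median=0.2845 IQR [0, 1.258]
#>   Mann-Whitney U = 3708.5, two-sided p = 0.08569 (NORMAL_APPROX)
```

One seeded run of the default configuration: the 112 induced / 313
noninduced cargo split evenly across classes, so this secreted contrast
has n = 56 vs 156; the recovered group means (1.23 vs 0.84 bonds per
100 aa) sit near the planted 1.30 vs 0.83, and the heavy planted
dispersion means a single run at this size is not always significant —
the power analysis in the acceptance suite runs the full 112-vs-313
contrast 100 times.

```r
gel <- simulateGel("secreted", noiseCv = 0)
fractionSecreted(gel$bands, "21% O2", 120)$fraction
#> [1] 0.8

cells <- simulateCells(membraneFractionTrue = 0.8, seed = 1)
membraneFraction(localizationRatio(cells$image))
#> [1] 0.8007126

ldlrLike <- computeMetrics(ldlr, "MEMBRANE")  # 30 bonds, 63 cysteines
ldlrLike$fractionCysBonded; ldlrLike$nFreeCys
#> [1] 0.952381
#> [1] 3
```

The zero-noise gel returns the planted 80%-secreted-by-120-min curve
exactly; the synthetic image recovers its planted membrane fraction to
three decimals; an LDLR-like architecture (30 intrachain bonds, 63
cysteines) gives the hand arithmetic 60/63 ≈ 0.952 bonded with 3 free
cysteines.

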