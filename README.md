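# mitoseg

Tools for studying how two mitochondrial DNA (mtDNA) variants segregate in
proliferating budding-yeast populations, at single-cell resolution.

Cells carry many mtDNA copies; when two sequence variants coexist in one
cell (*heteroplasmy*, quantified here by the h value — the share of one
fluorescently marked variant in the total signal), proliferation drives
descendants toward pure, *homoplasmic* states. `mitoseg` packages the
computational side of a live-imaging study of this process:

* **Segregation simulator** — each cell's mitochondrion is an ordered 0/1
  array of `n` copies (default 32). Per 1.5-h cycle a cell replicates to
  capacity by a Pólya-urn rule (random molecules copied, new copy placed
  next to its template), splits into `nspl` fragments that re-fuse in
  random order (fission–fusion proxy), and divides, passing the first
  `ndau` copies (at most `n/2`) to the daughter. Newborn daughters mature
  for one cycle before dividing. No death, no degradation, no selection.
* **Quantification** — background-subtracted, volume- and per-frame
  median-normalized channel intensities; `h = i_mkate / (i_ng + i_mkate)`;
  coefficients of variation; first-timepoint normalization for decay
  series.
* **Classification** — deterministic 3-component Gaussian-mixture EM on h
  distributions; homoplasmy thresholds from component-curve intersections
  (defaults 0.33 / 0.71); KDE valley thresholds for dark/bright scoring.
* **Model fitting** — logistic smoothing of empirical homoplasmy time
  courses and an exhaustive least-squares grid search over (`ndau`,
  `nspl`).
* **Lineage analysis** — pedigree trees from tracking tables, h sampled at
  matched growth stages (20% bud-to-mother volume ratio), Spearman
  correlations of mother–daughter / mother–self pairs, paired t tests.
* **Kinetics** — exponential decay fits `I(t) = A·e^{−kt} + C` for
  translation-shutoff (chloramphenicol) series, and the nucleoid-transfer
  estimate `rate / window × exchange-duration`.
* **Synthetic data** — a generator that emulates the per-cell tracking
  tables the imaging pipeline would export (protein turnover at
  k = 0.31 h⁻¹, autofluorescence, background, noise, budding volumes,
  optional mtDNA dropout and CAP windows), with ground truth attached, so
  the whole pipeline runs and is testable without any external data.

## A worked example

Simulate ten populations at the best-fitting parameters and measure
homoplasmy at 7.5 h:

```r
library(mitoseg)
library(dplyr)

cfg <- sim_config(ndau = 14, nspl = 4, n_generations = 5,
                  n_replicates = 10, seed = 1)
cfg
#> <sim_config> n = 32 | ndau = 14 | nspl = 4 | founder = mixed (f1 = 0.50) |
#>   5 generations x 1.5 h | 10 replicate(s), seed 1

sim <- simulate_population(cfg)
head(sim, 3)
#> # A tibble: 3 × 9
#>   replicate generation time_h cell_id parent_id allele1_count n_copies ...
#> 1         1          0    0         1        NA            16       32
#> 2         1          1    1.5       1        NA            10       18
#> 3         1          1    1.5       2         1             6       14

g5 <- filter(sim, generation == 5)
homoplasmic_fraction(g5, "thresholds", c(0.33, 0.71))
#> [1] 0.485
```

Each row is one cell in one generation snapshot: the founder starts with
16 of 32 copies of variant 1 (`0101…`); after the first division the
mother keeps 18 copies and the daughter receives 14. By generation 5
(t = 7.5 h) about half the cells are beyond the homoplasmy thresholds —
the regime in which the parameter pair (`ndau = 14`, `nspl = 4`) best
matches experimental segregation.

Kinetics from the synthetic chloramphenicol experiment, plus the
nucleoid-transfer arithmetic:

```r
ser <- generate_cap_series(generator_config(noise_cv = 0,
                                            background_sd = 0, seed = 3),
                           hours = 6)
fit_decay(ser, intensity = "intensity")
#> <decay_fit> I(t) = 3.097 * exp(-0.31 t) + 0.5   (k SEM 1.2e-16)

nucleoids_per_division(1.18, window_min = 5, exchange_min = 47.5)
#> [1] 11.2
```

The fitted decay rate recovers the generator's protein turnover constant
(0.31 per hour) exactly on noiseless input, and 1.18 foci per 5-minute
window sustained over a 47.5-minute exchange period amounts to ~11
nucleoids passed from mother to daughter per division.

The methods vignette (`vignettes/mtdna-heteroplasmy-model.Rmd`) describes
the model, the generator, and the numerical choices in detail, including
known limitations.

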