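---
title: "Microbiome-metabolome balance indices for neurocognitive status: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbiome-metabolome balance indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

People with HIV show excess rates of neurocognitive impairment, and gut
dysbiosis — with its downstream metabolic products — is one proposed
contributor.  In a small longitudinal cohort (18 participants followed at
baseline, post-intervention and end of study), cognitive performance is
summarised by the NPZ-6 composite: the arithmetic mean of six standardized
cognitive-domain z-scores.  Participants at or below −0.5 form the *Lower*
(impaired) group, those above it the *Higher* group — here 3 versus 15.

`gutbalance` condenses the discriminant signal of two omics layers —
species-level gut metagenomics and the plasma metabolome — into three
*balance indices* and follows them over time and against cognitive and
functional outcomes.

## The model

For disjoint feature sets $N$ (enriched in the Lower group at baseline) and
$D$ (enriched in the Higher group), the index of a sample with abundances
$x$ is the log-ratio of geometric means

$$ b(x) = \ln \frac{g(x_N)}{g(x_D)}, \qquad
   g(x_S) = \Big(\prod_{j \in S} x_j\Big)^{1/|S|}. $$

Three properties make this the right statistic for compositional data:

* **Scale invariance.** Multiplying all abundances of a sample by any
  positive constant leaves $b$ unchanged, so per-sample renormalization
  (sequencing depth, intensity calibration) cannot move the index.
* **Monotone interpretability.** $b$ increases in every numerator feature
  and decreases in every denominator feature.
* **Unit indifference.** Because each table only contributes through
  within-sample ratios, the *combined* index may pool relative abundances
  and normalized intensities; the group contrast is well-defined even
  though the units differ.  (The absolute level of the combined index still
  mixes units — only comparisons across samples are meaningful.)

Feature sets are selected **at baseline only** and then frozen; later
timepoints are scored with the same definition.  This is what
`fit_balance_indices()` returns as a fitted model object: the frozen
definitions are the "coefficients", and `predict()` evaluates any
timepoint.

### How the sets are chosen

* **Microbial index.** Every species is compared between groups with an
  exact two-sided rank-sum test; species with $p < 0.05$ and higher median
  in the Lower group form the numerator, mirror-image species the
  denominator.  An empty side leaves the index undefined — that is an
  error, not a NaN.
* **Metabolome index.** A two-stage cascade: sparse PLS-DA (two
  components, exactly `keepX = 100` non-zero loadings per component via
  soft-thresholding), then an exact rank-sum filter ($p < 0.05$, no
  multiplicity adjustment — this stage is a screen, not an inference) on
  the union of kept variables.  The surviving metabolites enter a PCA;
  PC1 is oriented so the Lower group scores positive, and metabolites with
  signed PC1 loading above 0.15 form the numerator, below −0.10 the
  denominator.
* **Combined index.** The union of the two numerators over the union of
  the two denominators; overlap between sides is an error.

### Exact inference for 3 versus 15

With groups this small and unbalanced, normal approximations are the wrong
tool.  `exact_rank_sum()` computes the exact null distribution of the
Mann–Whitney U (identical to enumerating all $\binom{18}{3} = 816$ group
assignments) whenever there are no ties and $n_1 + n_2 \le 20$; the
two-sided p is twice the smaller tail, capped at 1.  The smallest
achievable p is therefore $2/816 \approx 0.0025$ — which is also the
baseline p the indices reach under complete separation.  Ties or larger
samples fall back to the midrank normal approximation with tie and
continuity correction.  A consequence worth knowing: achievable two-sided
levels are multiples of $2/816$, so the effective level of a "$p<0.05$"
gate is $40/816 \approx 0.049$.

### Discriminant taxa (LEfSe-style)

`lefse()` follows the classical two-step recipe: a Kruskal–Wallis screen at
$\alpha = 0.05$, then an effect size from 30 rounds of balanced 2/3
subsampling with a one-dimensional LDA on the candidate set.  Abundances
are put on a parts-per-million scale; per round, a feature's score is the
average of its raw class-mean difference and its share of the
discriminant-axis separation, and the reported LDA score is
$\log_{10}(\max(\text{mean score}, 1))$, retained above 2.0.  A small
seeded jitter (5% of each feature's SD) regularizes the within-class
scatter, which with 2-per-class subsamples is otherwise frequently
singular.  Directions always follow the class-median difference of the raw
abundances.

### Associations, diversity, enrichment

Spearman correlations use midrank ties and the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$; perfect correlations report the exact
permutation minimum $2/n!$.  BH adjustment is applied within one
"heatmap-panel" family (one index set × one outcome set × one timepoint) by
default.  Correlation networks threshold at $|\rho| \ge 0.6$ with a
stricter 0.7 view.  Community-level testing is Bray–Curtis PERMANOVA
(`vegan::adonis2`, free permutations, $p = (1 + \#\{F^* \ge F\})/(1 +
n_\text{perm})$).  Metabolite set enrichment is the hypergeometric upper
tail against a user-supplied GMT library, with the universe restricted to
named metabolites.

## The synthetic cohort generator

No participant-level omics tables are distributable with this design, so
the package ships a generator whose defaults *are* the study conditions: 3
Lower / 15 Higher participants, 200 species, 1300 metabolites (64 planted
discriminant ones), three timepoints with group-effect attenuation
1 → 0.5 → 0.1.

Design choices, and why:

* **Species** are log-normal with heavy-tailed base means (SD 2 on the log
  scale), closed to sum 1, with values below a detection limit of $10^{-6}$
  recorded as structural zeros and rows re-closed.  Participant-level
  random intercepts (SD 0.6 of a unit total) make repeated measures
  positively correlated across timepoints.
* **Planted species effects** are `effect_size` total-SDs on the log scale,
  default 3.5 (~30-fold).  This is deliberate: with 3 versus 15, the exact
  test only detects near-complete separation (detection probability is
  ~0.76 at 2 SD, ~0.97 at 3 SD, ~0.995 at 3.5 SD), and the study regime the
  generator emulates is exactly that clean-separation regime — baseline
  index p at the $2/816$ floor.  Planted species sit at 0.1% base
  abundance: well above the detection limit, yet small enough that their
  30-fold expansion does not distort the closure of the remaining
  community (at 1% base abundance the shifted mass would depress every
  other species in the Lower group and flood the Higher-enriched side with
  compositional false positives — a real effect of dominance shifts, but
  not the regime under study).
* **Planted metabolite effects** are heterogeneous: 75% drawn from
  U(0.65, 1.0)× and 25% from U(1.4, 1.8)× the nominal effect.  Sets found
  by a $p<0.05$ screen are dominated by effects near the detection
  boundary with a strong minority — and that heterogeneity is also what
  gives the PC1 loadings of the shortlisting step a realistic spread.  The
  planted features additionally share one correlated module
  (communalities U(0.05, 0.3), the strong tier U(0.6, 0.9); total noise SD
  kept at 1), emulating co-regulated lipid families.
* **Outcomes.** One latent cognition factor per participant drives the six
  domain z-scores and six functional scales, with quality of life and
  daily functioning loading positively and depression, anxiety, stress and
  CNS symptoms negatively (loading 0.9 — the regime in which baseline
  index–outcome correlations are strong enough to survive BH adjustment at
  n = 18).  Lower participants are generated with baseline NPZ-6 ≤ −0.5,
  Higher > −0.5, by rejection.  As the planted omics effect attenuates,
  the Lower group's latent cognition recovers proportionally, so the
  final-timepoint indices retain a mild positive association with the
  NPZ-6 change score.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real taxonomies and phylogenetic correlation,
sequencing-depth variation and count noise, non-log-normal tails,
metabolite families beyond a single module, sex- or diet-linked microbiome
structure, and informative missingness.  Recovery rates on this generator
are statements about the method under its stated noise model, not about
field performance.

## Numerical choices

* **Log base:** natural; any base is a monotone rescaling and leaves all
  rank tests and correlations unchanged.
* **Zeros:** replaced by half the smallest non-zero value *of the same
  table* (not per feature) before geometric means; configurable.
* **PC1 loadings:** reported as signed feature–PC1 correlations
  (standardized loadings).  A unit-norm rotation vector over $k$
  co-selected features is bounded near $1/\sqrt{k}$; with the ~60–90
  features this cascade retains, no unit-norm loading can reach 0.15, so
  fixed signed thresholds are only meaningful in the correlation
  convention.
* **Orientation:** PC1 is signed so the Lower-group mean score is
  positive, making selections deterministic under eigenvector sign flips.
* **Chi-square tests:** Pearson, *without* Yates continuity correction —
  this exactly reproduces all four recomputable cohort-table p-values
  (0.021, 0.180, 1.000, 0.701); with correction none of them match.
* **Quartiles:** linear interpolation (R type 7) for the IQR summaries.
* **Metabolite preprocessing:** per-feature median scaling, natural log,
  unit-variance scaling before sPLS-DA/PCA/HCA.
* **Ward clustering:** `ward.D2` on Euclidean distances (the classical
  Ward criterion); validated against a naive $O(n^3)$ implementation.
* **Degenerate inputs:** all-tied rank tests return p = 1; a
  zero-variance feature is skipped with a warning; a constant delta vector
  yields a missing correlation; a distance matrix with zero total sum of
  squares reports pseudo-F 0, p 1.

## Decisions where the design was genuinely open

* sPLS-DA, PCA and index construction use **baseline samples only**;
  later timepoints are scored, never refitted.
* The BH family is one heatmap panel; wider families are a configuration
  choice, not a default.
* The enrichment universe is the named metabolites actually measured;
  unnamed (`X-`) biochemicals are excluded.  The pathway library is an
  explicit input (GMT) — enrichment against an unpinned external database
  snapshot is not reproducible and is not attempted.
* PERMANOVA permutes labels freely: the design has no blocking at
  baseline.  With $n_1 = 3$ only 816 distinct partitions exist, so a
  199-permutation p has an effective floor of 1–3/200 once the observed
  partition is redrawn.
* Within-group longitudinal change (n = 3) is reported with a paired test
  but flagged exploratory.

## Problem sizes used by the test-suite

Property checks run on reduced instances chosen for statistical clarity
per unit time: 60-species/40-metabolite cohorts for generator properties,
100 seeded default cohorts for recovery rates, 1000 null cohorts (199
permutations) for PERMANOVA calibration, 200 null cohorts for the
selection-cascade false-positive rate, and 100 cohorts each for
attenuation tracking and the baseline sign pattern.  The acceptance script
re-runs the same computations from scratch with seeds derived from its
`--seed` argument.

## Known limitations

The selection cascade inherits the discreteness of exact inference at
(3, 15): effective test levels are multiples of 2/816, and features must be
near-completely separated to be selected at all.  The two-stage metabolite
screen is selection-biased — among sPLS-DA-kept candidates the rank-sum
false-positive rate is far above nominal (only relative to *all* features
is the cascade calibrated), so retained sets should be read as enriched
candidate lists, not inferentially controlled discoveries.  With n = 18
the Spearman t-approximation is slightly liberal in the far tail.  And a
balance index with data-selected numerator and denominator is an
*in-sample* discriminant summary: its baseline separation is biased by
construction, which is why the longitudinal trajectory and outcome
associations — not the baseline gap — carry the scientific content.
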