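---
title: "nephrosig: models, parameters, and design decisions"
author: "nephrosig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{nephrosig: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic-data generators do and do not
emulate, and the numerical decisions that were genuinely open.

# The analysis chain

A nephrotoxic kinase inhibitor leaves traces at several scales.  In a
spontaneous adverse-event reporting database, it shows a disproportionate
rate of glomerular reports relative to its drug class.  In a
phosphotyrosine-enriched proteome of treated podocytes, it depletes a
coherent set of phosphoproteins.  Those proteins form a tight module in
the protein–protein interactome; the kinase responsible can be isolated
from an in vitro selectivity panel; and the cytoskeletal consequence is a
measurably softer cell under an AFM probe, at drug concentrations well
below the viability EC50.  `nephrosig` implements each link of that chain
as an independent, testable component, with seeded synthetic data that
plant known ground truth at every stage.

# Pharmacovigilance: reporting odds ratios and the dual-risk profile

## Model

For an index drug and a group of adverse-event terms, reports within the
drug class are folded into four cells: target-group reports for the index
drug ($f_{dt}$), its other reports ($f_{dn}$), and the same sums pooled
over all other class drugs ($f_{nt}$, $f_{nn}$).  The reporting odds
ratio, the standard error of its logarithm, and the log-scale confidence
interval are

$$ROR = \frac{f_{dt}/f_{dn}}{f_{nt}/f_{nn}}, \qquad
SE_{\log ROR} = \sqrt{\tfrac{1}{f_{dt}} + \tfrac{1}{f_{dn}} +
\tfrac{1}{f_{nt}} + \tfrac{1}{f_{nn}}}, \qquad
CI = \exp(\log ROR \pm z\,SE).$$

The comparator is deliberately *within-class* — all other drugs of the
supplied class, never the whole database — because class-wide reporting
behavior (indication, prescriber population, stimulated reporting) cancels
only within the class.

## Zero cells

The ratio is undefined when any cell is zero.  The default policy is the
Haldane–Anscombe correction: add 0.5 to all four cells and flag the result
`corrected`.  With `correction = "none"` a zero cell is an error that
names the offending cell.  The correction is applied to all four cells
(not only the zero ones) so the estimator keeps its usual small-sample
behavior.

## Dual-risk outliers

`dualRiskProfile()` formalizes the visual "off the trend line" argument:
an ordinary least-squares fit of $\log ROR_A$ on $\log ROR_B$ across the
class estimates the co-risk trend (most vascular-toxicity mechanisms raise
both glomerular and hypertension risk together); each drug's vertical
residual is standardized by the residual standard deviation, and
`|standardized residual| > 2` (configurable) flags a departure.  Plain
residual/SD standardization is used rather than leverage-corrected
studentization; with class sizes around 16 the difference is small and the
plain form matches the visual-argument semantics.

# Spectral-count differential phosphoproteomics

## Support filter

A protein enters the test only with summed spectral counts of at least 2
in *both* conditions (`filterMinSupport`, mode `"sum"`).  Spectral counts
conflate peptides and spectra at this granularity; a `"per-replicate"`
mode (every replicate must individually reach the threshold) is provided
for stricter designs.

## Test choice: pooled t by default

The per-protein test is a two-sample t-test on counts.  The default is
the pooled-variance Student t rather than Welch.  This was a measured
decision, not a stylistic one: at $n = 3$ per condition the
Welch–Satterthwaite approximation collapses the error degrees of freedom
from 4 to about 2.6 for count data with a strong mean difference
(Poisson 20 vs 3.3), which roughly halves the power of every downstream
selection.  At these replicate numbers the pooled test is the
low-replicate proteomics convention; Welch remains available via
`varEqual = FALSE`.  A `tFromSummary()` entry point reproduces published
contrasts from mean ± SEM summaries
($t = \Delta\bar{x} / \sqrt{SEM_1^2 + SEM_2^2}$).

## Multiplicity and selection

`bhAdjust()` wraps the Benjamini–Hochberg step-up procedure
(`stats::p.adjust`); the test suite verifies it against a brute-force
implementation of the step-up definition, exactly.  Two selection notions
coexist deliberately, mirroring how such studies report:

* the **BH rejection set** (`direction` column) controls the FDR and is
  what the pipeline's headline "differentially abundant" count uses;
* the **ranked raw-p selection** (`selectDownregulated`: down-regulated,
  raw $p < \alpha$, ranked by $p$, truncated to `topN = 76`) reproduces a
  "top-N with p < 0.05" seed list for network analysis.

One structural property is worth knowing: when the truncation `topN`
equals the number of truly perturbed proteins, sensitivity is bounded by
$1 - FDR$ of the selection — each false selection necessarily displaces a
true one.  At the default scale (76 of 2130 planted, counts 20 vs 3.3,
$n = 3$) that ceiling puts sensitivity in the mid-80s percent; the
calibration tests therefore measure sensitivity ≈ 0.91 with
`topN` set to the planted count at a 10% planted fraction, and the module
tests assert the ≥ 0.8 regime for the 76-protein scenario.

# Subnetwork expansion and the Monte Carlo null

## Expansion rule

Edges with evidence below `minEvidence = 2` (two literature sources) are
dropped.  "One intermediate" is formalized as: a non-seed node adjacent to
at least two distinct seeds after the evidence filter — a node touching a
single seed cannot connect anything.  The result is the induced subgraph
on seeds ∪ intermediates, with metrics (node count, edge count, mean
degree $2E/N$, component count, largest-component node and edge counts)
reported for the whole subgraph and its largest connected component.
Expansion is monotone in `minEvidence`: raising the threshold never adds
nodes or edges (a tested invariant).

## Null distribution

Specificity is tested by resampling: draw $k$ nodes without replacement
from the *experimentally detected universe* (not the whole interactome —
the sampling frame must match how the seeds could have arisen), expand
identically, record the chosen metric (default: largest-component edge
count, the most direct "interconnected island" measure), and report

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{1 + n_{iter}}.$$

The add-one form keeps $p$ in $(0, 1]$ and valid (never anti-conservative)
under the null; with an integer-valued metric it is mildly conservative,
which the calibration test (KS uniformity of $p$ over repeated null draws
at $\alpha = 0.01$) accommodates.  Iteration counts below 20 are rejected
as meaningless resolution.  All five metrics are computed and stored;
the comparison metric is a parameter.

# Kinome filtering

Residual activities are percent-of-control; values above 100%
(activation) are allowed and never count as inhibition.  The chain is:

1. `filterActive`: keep kinases with residual strictly below 50% under at
   least one panel drug ("more than 50% residual activity across all
   drugs" inverts to strict `<` retention; the boundary is excluded, and
   `strict = FALSE` is available);
2. `filterGeneSet`: case-folded membership in an actin gene set, built by
   `aggregateTermGenes()` as the union of member genes over terms matching
   the case-insensitive regex `"actin"` in a user-supplied term→genes
   library (GMT files load via `fgsea::gmtPathways`);
3. `meanResidual` per drug and `uniqueInhibition`: kinases inhibited under
   exactly one drug.

The two filters commute (tested), so the unstated order in the original
procedure is moot.  The whole chain is verified exactly against a
two-loop brute-force reference on random panels.

# AFM elastography

## Contact mechanics

The indenter model is the four-sided pyramid (Bilodeau):

$$F(\delta) = \frac{\tan\theta}{\sqrt{2}}\,\frac{E}{1-\nu^2}\,\delta^2$$

with half-angle $\theta$ (default 35°), Poisson ratio $\nu = 0.5$
(incompressible cell), and spring constant 0.1 N/m in the probe metadata.
No blunt-tip radius is modeled; the geometry coefficient is a single
overridable constant.  Only the approach phase is analyzed.

## Contact-point detection

The contact point is detected in three stages, a design forced by two
measured failure modes of the plain fit-residual grid search:

1. **Coarse grid search**: every sample as candidate $z_0$, pre-candidate
   mean as baseline, least-squares Hertz fit to the whole post-candidate
   segment, smallest total squared residual wins.  Robust, but under a
   depth-stiffening curve a *shifted* Hertz parabola absorbs the cubic
   term, biasing $z_0$ late by up to ~0.5 µm; and under multiplicative
   force noise the deep, high-noise points dominate the unweighted RSS,
   leaving $z_0$ ill-conditioned (~10 sample spacings of scatter).
2. **Kink localization**: the contact point is a geometric feature — the
   transition out of the flat baseline — so the baseline is extended
   sample by sample until the next force exceeds the running baseline
   mean plus its noise band ($5\sigma$, with a tiny relative floor).
3. **Local refinement**: continuous one-dimensional optimization of a
   two-regime objective (flat baseline before, Hertz parabola after,
   mean-squared residual within a ±250 nm window), bracketed two samples
   before and *capped one sample past* the kink so deep non-Hertzian
   behavior cannot drag the contact point inward.

On noiseless curves this recovers $z_0$ and $E$ essentially exactly; the
error budget under 5% multiplicative noise (median $z_0$ error ≈ 0.2
sample spacings, median modulus error well under 1%) and the artifact
behavior below are asserted in the test suite.

## Pointwise modulus and the substrate flag

$E(\delta_i) = F_i(1-\nu^2)\sqrt{2}/(\tan\theta\,\delta_i^2)$ for depths
beyond `deltaMin` (100 nm; shallower samples are dominated by
contact-point error), summarized by the median (the homogenized cellular
elasticity).  An ideal Hertzian curve has a flat profile; apparent
stiffening with depth is the accepted marker of substrate (bottom) effects
in thin samples.  The flag compares the least-squares slope of
$E(\delta)$ versus $\delta$, normalized by the median, against
`relSlopePerMicron = 0.2` (+20% per µm).  The threshold's sensitivity to
contact-point bias is why the detector's refinement is capped: a +80 nm
bias alone halves the apparent slope of a genuinely stiffening curve.

## Maps and group comparison

`assembleMap` analyzes a row-major grid of curves; failed pixels are
missing, never interpolated.  `compareGroupElasticity` is one-way ANOVA
with Tukey HSD on per-cell median moduli (`stats::aov`,
`stats::TukeyHSD`), requiring ≥ 2 groups of ≥ 3 cells.

# Dose–response

Plates are normalized to the vehicle-well mean (percent of vehicle).  The
four-parameter logistic is fitted by Levenberg–Marquardt
(`minpack.lm::nlsLM`) parameterized in $\log_{10} EC50$, bounded within
two decades of the tested concentration range, initialized from the data
quartiles, with a small ladder of Hill-slope starting values.  Top and
bottom are unconstrained by default (`fixTop` constrains the upper
asymptote when vehicle-anchored behavior is wanted).  An EC50 outside the
tested range sets `extrapolated`.  Replicate EC50s are summarized as
geometric mean $\exp(\overline{\log EC50})$ and geometric SD
$\exp(s_{\log EC50})$ with the sample ($n-1$) standard deviation of logs,
the appropriate summary for a log-normally distributed potency.

# The synthetic-data module

The generators define the study conditions; their defaults mirror the
motivating scales: 16 drugs with one planted at glomerular ROR 8 /
hypertension ROR 1; 2130 proteins × 3+3 replicates with 76 planted at
count ratio 0.165 (the 20 vs 3.3 contrast); a 2130-node interactome with
a 76-seed module at 5× background density; a 300-kinase × 6-drug panel
with one uniquely inhibited kinase; 6×6 grids of 4 µm indentations with a
0.1 N/m, 35° pyramidal probe; and an 8-point 0.5–50,000 nM dilution with
EC50 253 nM, 4 replicates.

Design choices worth noting:

* **One seed, independent substreams.**  Each stage draws from its own
  L'Ecuyer-CMRG substream of the scenario seed, so stages regenerate in
  isolation and never share draws; identical configurations are
  byte-identical across runs.
* **Poisson counts.**  Spectral counts and report counts are Poisson by
  default (an overdispersion knob switches counts to negative binomial);
  at $n = 3$ spectral counts are near-Poisson and no dispersion model is
  prescribed by the protocol being emulated.
* **Exact planting of the ROR pair.**  The planted drug's two group
  multipliers are solved *jointly*: scaling its hypertension terms changes
  the "all other ADR" denominator of its glomerular ROR and vice versa, so
  the two target equations are coupled linearly and solved in closed form
  (feasible whenever the product of the two target odds is below one).  A
  sequential solve leaves a structural bias of several percent.
  Background drugs share a latent lognormal "vascular co-risk" multiplier
  acting on both term groups (creating the class co-risk trend) and a
  report-volume multiplier that cancels from every ROR.
* **Force noise is multiplicative.**  "5% noise" is 5% relative error on
  force (plus an optional absolute floor), the natural repeatability
  figure for a calibrated instrument; likewise viability noise is 5%
  relative, the usual absorbance repeatability.  An additive
  percent-point reading would mean 50–100% relative error at low
  viability and makes EC50 recovery at the planted scenario's dilution
  unattainable.
* **Kinome background stays above threshold.**  Background residuals are
  truncated-normal (mean 90, SD 10, floor 55), promiscuous kinases are
  inhibited by 2–4 drugs, and the planted kinase by exactly one — so the
  planted pair is the unique single-drug hit by construction, and a null
  scenario has none.

What the generators do **not** emulate: MedDRA's real ontology (the term
map is flat), mass spectra and peptide-level identification, literature
evidence semantics, cantilever dynamics and deflection–piezo conversion,
plate-position or edge effects, and any correlation structure between
stages (each stage's data are generated independently given the
configuration).  Passing tests therefore demonstrate the correctness and
calibration of the *statistics* under their stated models, not robustness
to the full messiness of the corresponding real assays.

# The pipeline and its headline calls

`runPipeline()` executes the stages in dependency order on one scenario,
records per-stage errors without aborting, and writes a JSON report plus a
Markdown summary when an output directory is given.  The report's
headline calls are intentionally stricter than the per-module defaults,
because the report makes *one* claim per stage while the modules make one
test per drug, protein, or kinase:

* a dual-risk outlier must exceed the residual threshold *and* have a
  group-A ROR lower confidence limit above 1 (the standard signal
  criterion) — without the second condition a null class of 16 drugs
  would flag some drug in most runs at the ~5% per-drug rate;
* network specificity and the elasticity reduction use
  `headlineAlpha = 0.01`;
* the differential-phosphoprotein headline counts BH rejections (null
  expectation: zero), while the seed list for the network stage uses the
  ranked raw-p selection.

# Problem sizes used by the test suite

The calibration and acceptance tests run at the study's own scales where
that is affordable within a routine test run, and scale down only the
repetition counts: 1000 random tables for the ROR oracle; 2000 multinomial
tables for CI coverage; 200 planted and 200 null dual-risk scenarios; 500
count matrices (2130 × 6) for FDR/sensitivity; 1000 p-vectors for BH
exactness; 200 null repetitions × 500 iterations (plus 5 planted
scenarios) for network calibration on the full 2130-node graph; 100 panels
and 100 planted seeds for the kinome chain; 100 noisy curves for AFM
recovery; 100 plates for EC50 recovery; and two full pipeline runs.

# Known limitations

* The ROR is a reporting-disproportionality measure, not a risk estimate;
  the within-class comparator makes it a *relative* signal by design.
* The dual-risk outlier rule is a formalization of a visual argument; its
  threshold is a convention, not an estimate.
* At $n = 3$, count-level tests are power-limited; the truncated top-N
  selection inherits the $1 - FDR$ sensitivity ceiling described above.
* The empirical network p is bounded below by $1/(n_{iter}+1)$ and is
  conservative for discrete metrics.
* The sharp-pyramid Hertz model ignores tip bluntness and viscoelasticity;
  moduli are *apparent* moduli at the probed depth and rate.
* The 4PL fit is unweighted; strongly heteroscedastic plates would warrant
  a weighted variant.
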