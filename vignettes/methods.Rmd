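---
title: "Methods: screen normalization, regulator inference and signature survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen normalization, regulator inference and signature survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntitr)
```

# Overview

`wntitr` chains four analyses that together take a neuroblastoma study
from raw screening plates to patient stratification:

1. **Screen statistics** — spatial normalization of 384-well RNAi
   viability plates and robust hit calling, comparing MYCN-induced
   against un-induced conditions.
2. **Regulator inference (ITR)** — scoring candidate upstream regulators
   (e.g. β-catenin, WNT3A) against differential-expression results using
   a prior-knowledge regulator→target network.
3. **Signature pipeline** — assembling a regulator's target-gene
   signature, removing the MYCN-expression component from a tumour
   expression matrix, and assigning Signature(+)/Signature(−) groups.
4. **Survival statistics** — Kaplan–Meier curves, log-rank tests,
   expression-cutoff stratification and a Spearman correlation utility.

A synthetic-data module generates every input with planted ground truth,
so each stage is testable end to end without external downloads. The
numbered drivers under `analysis/` run the stages in order on those
synthetic inputs and write their tables under `results/`.

# Screen normalization and hit calling

## The spatial model

Plate-based viability readouts carry smooth spatial artifacts
(temperature and evaporation gradients, dispenser drift). We model the
log2 signal of plate $p$ in condition $c$ as

$$\log_2 y_{rck} = \mu_{pc} + f_{pc}(r, k) + \varepsilon,$$

where $f$ is a smooth surface over the (row, column) grid. $f$ is
estimated by local linear regression (loess, degree 1, default span
0.7) fitted on **sample wells only**: the control lines in columns 1, 2,
23 and 24 have a different biological baseline and must never shape the
surface. We fit with the robust (Tukey biweight) loess family because
genuine hit wells are exactly the outliers that must not bend the
surface toward themselves. Every non-empty well — controls included —
then receives

$$\tilde y = \log_2 y - \hat f + \operatorname{median}(\log_2 y_{\text{fit wells}}),$$

so normalized values stay on the plate's own log2 scale. Well
coordinates run rows 1–16 (A–P) and columns 1–24 throughout; the
excluded control lines are column indices, the only reading consistent
with indices up to 24 on a 16-row plate, and are configurable.

Degree-1 loess reproduces any plane exactly, which gives the
normalization a useful invariance: on a plate whose artifact is linear,
re-normalizing an already-normalized plate is a no-op to machine
precision (the test suite asserts `< 1e-6`).

## Robust scale: Huber's Proposal 2

Hit thresholds need a scale estimate that ignores the hits themselves.
We use Huber's Proposal 2: location $\mu$ and scale $\sigma$ solve,
simultaneously,

$$\mu = \frac{1}{n}\sum_i w_i, \qquad
  \sigma^2 = \frac{\sum_i (w_i - \mu)^2}{n\,\beta(k)},$$

where $w_i$ winsorizes $x_i$ at $\mu \pm k\sigma$ ($k = 1.5$ by
default) and $\beta(k) = E[\min(|Z|, k)^2]$ for standard-normal $Z$
makes $\hat\sigma$ consistent for the SD of Gaussian data:

$$\beta(k) = 2\Phi(k) - 1 - 2k\varphi(k) + 2k^2(1 - \Phi(k)).$$

The fixed point is found by direct iteration from the median/MAD start
(tolerance `1e-8`, cap 200 iterations). As $k \to \infty$ the estimate
reduces to the classical mean and population-divisor SD (asserted to
`1e-6` at $k = 100$). One honest degeneracy is handled explicitly: when
more than half the winsorized mass coincides (e.g. four identical
values and one outlier), the scale equation has no positive root and
the iteration collapses; we detect this and return $\sigma = 0$ with a
warning rather than a pseudo-converged positive value. The tests verify
the solver against an independent root-finding oracle and against
`MASS::hubers` (which uses an $(n-1)$-type divisor, hence the loose
cross-check tolerance).

## Hit calling

Per condition, the library-wide distribution of normalized sample wells
supplies the median and the Huber scale, and a well is a hit when

$$|\tilde y - \operatorname{median}| \ge 3\,\hat\sigma_{\text{Huber}},$$

boundary inclusive; hits below the median are anti-proliferative, above
it pro-proliferative. The robust z-scores reported alongside use the
median and normal-consistent MAD ($\times 1.4826$) of the same
distribution. Scoring library-wide per condition, rather than
per-plate, matches the "median of all samples" convention; a per-plate
mode exists behind `scope = "plate"` for screens with plate-level
batch structure. Genes whose z differs by ≥ 2 between the induced and
un-induced conditions are flagged as condition-dependent responses.

Under a pure null the three-sigma rule yields a hit rate of
$2\Phi(-3) \approx 0.27\%$; the tests check the observed count on a
10,000-gene null library against that rate within three binomial SDs.

# Regulator inference

Each regulator in the network is scored against each contrast twice:

* **Overlap p-value** — the right-tail hypergeometric probability of
  drawing at least the observed number of the regulator's targets when
  sampling the DE set (adjusted $p \le 0.05$ by default) from the
  background universe. The background defaults to the genes measured in
  the DE table, not the network's gene space: enrichment claims should
  be made against what was measurable.
* **Activation z-score** —
  $z = \sum_i w_i x_i / \sqrt{\sum_i w_i^2}$ over the regulator's edges
  whose target is DE and whose predicted sign is known, with
  $x_i = +1$ when the observed fold-change direction matches the
  prediction under the regulator-active hypothesis and $-1$ otherwise.
  $|z| \ge 2$ calls the state (activated/inhibited); with no scorable
  edge the state is *undetermined* and z is `NA`, never 0. We implement
  the uncorrected concordance z; commercial implementations add
  proprietary bias terms that are not publicly specified.

Regulators are ranked per contrast by overlap p, ties broken by $|z|$
then by identifier, so ranks are always a permutation. A direction-less
variant (`rank_regulators_binary`) serves bound-gene lists from
ChIP-type experiments, where only membership, not direction, is known.

Genes below the DE threshold contribute neither concordance nor
discordance. A consequence worth knowing: under a complete null with
few DE genes, a regulator has very few scorable edges and the discrete
$z = S_m/\sqrt m$ cannot approximate a standard normal; the null
calibration in the tests therefore drives the generator with all genes
DE at random directions (20 scorable edges per regulator), where the
$|z| \ge 2$ rate approaches $2\Phi(-2)$ up to binomial discreteness.

# Signature construction and MYCN correction

## Signature

The signature of a regulator is the set of its contributing genes
(targets that were DE) supported by at least `min_contrasts = 2`
contrasts — the "differentially expressed in at least two cell lines"
rule. Each gene's expected direction is the majority sign of its
observed fold changes across supporting contrasts; ties give direction
0 (unknown). Unknown-direction genes still enter clustering (their
standardized expression is informative) but are excluded from the
signed score. Signatures export to TSV and to GMT (one set per
direction) for interchange with gene-set tools.

## MYCN correction

In neuroblastoma cohorts MYCN expression dominates so much variance
that any MYCN-correlated signature trivially separates tumours. To ask
whether a signature carries information *beyond* MYCN level, each
matrix row is fitted by OLS:

$$y = b_0 + b_1\,\mathrm{MYCN}_{\text{expr}} + b_2\,\mathrm{amp} + \varepsilon,$$

and the corrected matrix subtracts only the expression component,
$y - b_1(\mathrm{MYCN}_{\text{expr}} - \overline{\mathrm{MYCN}}_{\text{expr}})$,
exactly the covariate-removal convention of limma's batch-effect
utilities (the test suite cross-checks against
`limma::removeBatchEffect` up to row centring). The amplification
effect $b_2$ is deliberately retained — amplification status is the
clinical variable whose separation we later test. By least-squares
algebra the corrected rows are exactly orthogonal to MYCN expression
given amplification, and a second correction pass is a no-op; both are
asserted numerically. The per-row partial $R^2$ of the MYCN term
(RSS reduction against the intercept+amplification model) quantifies
how much of each gene's expression MYCN level explains.

## Clustering and the separation test

Samples are clustered on the corrected signature rows (per-probe
z-standardized) with Ward linkage on Euclidean distances and the top
merge is cut into two groups. Defaults were chosen for robustness on
continuous expression data and are exposed as arguments. Group polarity
is fixed by the direction-aligned mean score — Signature(+) is the
group with the higher mean score — so labels are reproducible across
runs and never depend on dendrogram orientation or cluster size.
Many-to-one probe maps are supported (microarray designs often carry
several probe sets per gene, 117 probe sets for 77 genes in the
motivating data).

The MYCN-amplification separation is quantified by a one-way ANOVA F
(df 1, n−2) of the signature score by amplification status — the
composite-score reading of a heat-map "F-test" whose exact construction
is not printed; per-probe Welch tests with Benjamini–Hochberg
adjustment accompany it so both readings are available.

# Survival

Kaplan–Meier estimation and the log-rank test delegate to the
`survival` package behind thin, tidy-output wrappers; the tests verify
both against hand-computed product-limit and observed-minus-expected
oracles on a six-subject worked dataset. Expression stratification
offers a median split (default) and a best-cutoff scan over all
cutpoints leaving ≥ 10% of samples per side, as probe-level survival
platforms use. The scan's minimal raw p is anti-conservative by
construction, so the Bonferroni-adjusted p over the number of cutoffs
tried is always reported alongside and is the quantity to quote; the
null calibration test shows the adjusted rejection rate at or below
nominal while the raw rate is several-fold inflated.

`spearman_rho_t_pvalue` computes midrank Spearman ρ with the two-sided
t-approximation p-value
($t = \rho\sqrt{(n-2)/(1-\rho^2)}$, $n-2$ df). On the five-point worked
example with ρ = −0.9 this gives p = 0.0374, reproducing the printed
dose-response correlation analysis; at $|\rho| = 1$ the limiting p = 0
is returned with an exactness flag rather than an undefined t.

# The synthetic-data generators

The generators are first-class, tested code, and their defaults are the
study conditions the rest of the package is validated under:

* `simulate_screen` — 384-well plates, control columns 1/2/23/24 at a
  constant baseline, 320 gene wells per plate dispensed in randomized
  order (as libraries are plated; this also keeps planted effects from
  clustering spatially), a per-plate random low-order polynomial
  artifact scaled to a chosen peak-to-peak log2 range (default 1.0),
  well noise SD 0.3 log2, and spiked gene effects in noise-SD units.
* `simulate_contrasts` — planted per-contrast regulator activity
  states; regulated targets move by `state × sign × effect_mu`
  (default 2) plus N(0, 0.5) noise. Adjusted p-values are generated
  structurally — a monotone map of |log2FC| calibrated so 5% of null
  genes pass 0.05 — because the consuming statistic needs only DE
  membership and direction, not a simulated testing pipeline.
* `simulate_cohort` — 478 samples with 20% MYCN-amplified (the shape of
  the motivating tumour series), MYCN expression higher in the
  amplified group, a binary latent regulator activity carried by the
  amplified samples, signature genes shifted along their expected
  direction by 2 noise-SDs and coupled to MYCN expression, exponential
  survival with a per-activity-unit hazard ratio (default 3) and
  uniform censoring whose window is solved numerically to hit the
  requested censoring fraction (default 30%). A Weibull shape for the
  baseline hazard was considered and left out: the consuming tests are
  rank-based and gain nothing from it.

Everything is a pure function of its parameters and seed; identical
seeds give byte-identical outputs.

What the generators deliberately do **not** emulate: probe-level
microarray noise models, copy-number structure, batch effects,
correlated gene-gene noise, and informative censoring. Passing tests on
these inputs therefore demonstrate the statistics are implemented
correctly and recover planted truth under the stated noise model — not
that any particular biological cohort will separate as cleanly.

# Problem sizes and numerical choices

The test suite and the acceptance script run at the sizes the analyses
are specified at: 960-gene screens over three plates, 10,000-point null
libraries, networks of 5–10 regulators × 20 targets, 100-seed recovery
and calibration loops, 478-sample cohorts over 50 seeds, and 200-seed
log-rank power runs — small enough to re-run anywhere in minutes, large
enough that the Monte Carlo bands quoted in the tests are meaningful.

Other numerical choices: the Huber consistency constant is evaluated in
closed form via Φ and φ (no quadrature); loess uses exact ("direct")
surface computation so control-line predictions are extrapolations of
the fitted surface rather than interpolation artifacts; hypergeometric
tails come from `phyper`; ANOVA, `hclust`, `p.adjust`, and the survival
machinery are the standard R implementations. Ties in regulator ranking
break by |z| then identifier; ties in majority direction give
"unknown"; scan cutoffs are midpoints between consecutive observed
values and respect a configurable group-size floor.

# Limitations

* The activation z is the uncorrected concordance statistic; absolute
  values are not comparable with implementations that apply proprietary
  bias corrections, though signs and rankings are.
* The ITR analysis is depth-1: no reasoning through intermediate
  regulators.
* The signature clustering always cuts into two groups; cohorts with
  more structure need a different cut rule.
* Survival stratification covers a single endpoint; no Cox regression
  or multivariable modelling.
* The generators' independence assumptions (noise, censoring) are
  idealizations; see above for what passing tests do and do not show.
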