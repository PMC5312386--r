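# wntitr

Plate-based RNAi screen hit calling, upstream-regulator inference and
β-catenin signature survival stratification for neuroblastoma-style
studies — as one tested R pipeline, exercisable end to end on synthetic
data with planted ground truth.

## Who this is for

Groups analysing high-throughput viability screens and tumour
expression cohorts who need the computational chain between the two:
normalize 384-well plates and call knockdown hits; score candidate
upstream regulators (β-catenin, WNT3A, …) against
differential-expression contrasts; turn a regulator's contributing
genes into an expression signature; remove the dominant MYCN-expression
component from a tumour matrix so the signature can be judged on what
it adds beyond MYCN; and test whether the resulting
Signature(+)/Signature(−) groups separate MYCN amplification and
patient survival.

## The statistics at the core

* **Screen normalization** — per plate and condition, a robust loess
  surface $f(r,k)$ (degree 1, span 0.7) fitted on sample wells only
  (control columns 1, 2, 23, 24 excluded);
  $\tilde y = \log_2 y - \hat f + \mathrm{median}$.
* **Robust scale** — Huber's Proposal 2: iterate
  $\mu \leftarrow \mathrm{mean}(w)$,
  $\sigma^2 \leftarrow \sum (w-\mu)^2 / (n\,\beta(k))$ with $w$ the
  sample winsorized at $\mu \pm 1.5\sigma$ and
  $\beta(k) = E[\min(|Z|,k)^2]$. Hits are wells at least
  $3\hat\sigma$ from the library median (boundary inclusive);
  robust z-scores use median/MAD.
* **Regulator (ITR) scoring** — right-tail hypergeometric overlap
  p-value of a regulator's targets with the DE set, and the activation
  z-score $z = \sum w_i x_i / \sqrt{\sum w_i^2}$, $x_i = \pm 1$ for
  direction concordance; $|z| \ge 2$ calls activated/inhibited.
* **Signature & MYCN correction** — genes contributing in ≥ 2
  contrasts, majority-vote directions; per-gene OLS
  $y = b_0 + b_1\,\mathrm{MYCN} + b_2\,\mathrm{amp}$ and subtraction of
  the centred $b_1$ term only (limma-style covariate removal); Ward
  clustering of standardized signature rows into two groups; ANOVA F of
  the signature score by amplification status.
* **Survival** — Kaplan–Meier / log-rank (via the `survival` package),
  median-split and best-cutoff-scan stratification with Bonferroni
  adjustment over cutoffs, and Spearman ρ with the two-sided
  t-approximation p-value.

## Worked example

The numbered drivers under `analysis/` run the whole chain on synthetic
inputs (simulate → screen → ITR → signature → cohort → survival),
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_screen_hits.R
Rscript analysis/03_itr_signature.R
Rscript analysis/04_cohort_correction.R
Rscript analysis/05_survival.R
```

Stage 2 normalizes 3 plates × 2 induction conditions and calls hits:

```
spatial flatness after normalization: |cor(value, row)| = 0.0297
hits: 24 induced / 0 un-induced (of 960 genes)
planted -6 sigma spikes recalled: 100%
```

The planted spatial gradient (1 log2 unit peak-to-peak) is flattened to
a |correlation| of 0.03 with plate row, and all 20 genes spiked at −6σ
in the induced condition are recovered. Stage 3 scores 10 regulators
against 5 contrasts in which REG01 was planted as inhibited:

```
  contrast regulator overlap        p     z     state
 contrast1     REG01      20 1.12e-23 -4.47 inhibited
 ...
signature of REG01: 20 genes (10 down, 10 up, 0 unknown direction)
```

REG01 ranks first in every contrast with the correct state (the
all-concordant bound is $z = \pm\sqrt{20} = \pm 4.47$), and its
signature recovers all 20 planted targets with their directions. Stage
4 simulates a 478-tumour cohort (20% MYCN-amplified), corrects the
matrix for MYCN expression and clusters:

```
MYCN model: mean b1 over signature probes = 0.498 (planted 0.5); mean partial R2 = 0.46
signature groups: 96 Signature(+) / 382 Signature(-)
MNA separation of the signature score: F = 12098.8 (df 1, 476), p = 0
probes DE between MNA and non-MNA (padj < 0.05): 40 of 40
```

Stage 5 tests survival separation and prints the worked correlation
example:

```
signature groups log-rank: chi2 = 77.7 (df 1), p = 1.21e-18
worked Spearman example: rho = -0.9, n = 5, p = 0.03739
```

The Signature(+) group (which carries the planted high-activity,
hazard-ratio-3 samples) separates survival at p ≈ 1e-18, and the
five-point Spearman example reproduces ρ = −0.9, p = 0.0374 under the
t approximation.

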