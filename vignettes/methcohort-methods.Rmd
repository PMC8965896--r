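---
title: "Methods: peripheral-blood methylation analysis on synthetic cohorts"
author: "methcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peripheral-blood methylation analysis on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcohort)
```

# Scope and model of the data

`methcohort` implements a peripheral-blood DNA-methylation analysis workflow
for a three-group cohort design — patients with ulcerative colitis with and
without concomitant primary sclerosing cholangitis (PSC-UC, UC) and healthy
controls (HC) — together with a synthetic-data module that generates
EPIC-like cohorts with known ground truth. The measurement is the beta
value: the methylation fraction of a CpG in [0, 1], one value per probe and
sample, stored probes-as-rows. Because the real cohort of this design is
controlled-access, every stage is validated on synthetic cohorts whose
latent structure (cell mixtures, age signal, injected group effects) is
recorded and can be recovered.

The generator's model for a sample's beta value at probe $j$ is

$$\beta_{js} = \mathrm{logit}^{-1}\!\Big(\mathrm{logit}\big(\textstyle\sum_k
w_{ks}\,r_{jk}\big) + f_{js} + \delta_j\,\mathbb{1}[s \in g_j] +
\varepsilon_{js}\Big)$$

where $r_{jk}$ is the reference mean of cell type $k$, $w_{\cdot s}$ a
per-group Dirichlet mixing vector, $f$ a zero-mean AR(1) spatial field over
probe index, $\delta_j$ an injected logit-scale group shift and
$\varepsilon$ i.i.d. Gaussian noise. Combining on the logit scale and
mapping back through the inverse logit guarantees values strictly inside
(0, 1) with no clipping; clipping would distort the tails and break the
uniform-p null calibration that several tests rely on.

## Generator parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| group sizes | 17 / 17 / 12 | samples | the PSC-UC / UC / HC cohort design |
| `n_probes` | 20 000 | probes | desk-scale stand-in for the 850k array |
| `correlation_length` | 5 | probes | regional co-methylation decays over a few neighbouring probes |
| `spatial_sd` | 0.2 | logit units | inter-individual regional variation dominates technical noise |
| `noise_sd` | 0.1 | logit units | probe-level technical noise (~0.01–0.02 on the beta scale mid-range) |
| ages | U(25, 65) | years | adult IBD cohort, group medians in the 30s–40s |
| `steroids` | Bernoulli(0.5) | — | half of patients on immunomodulators |
| cell types | 6 | — | CD4T, CD8T, B, NK, Mono, Neu |
| `clock_probe_count` | 30 | probes | sparse clock, desk-scale analogue of published clocks |

The spatial field is defined over probe *index* distance with exponential
decay, restarted at chromosome boundaries — not over bp distance. This
matches the stretch-null construction below, which is likewise defined over
consecutive probes.

Dirichlet concentrations default to one whole-blood-like vector (Neu 60%,
CD4T 15%, CD8T 8%, Mono 7%, B 5%, NK 5%, concentration 80) for all groups,
which makes group labels exchangeable — the null that the calibration tests
require. `blood_preset_alphas()` provides an alternative with the NK
fraction lowered in both patient groups and the myeloid share raised in UC,
so that the deconvolution and ANOVA stages can be exercised against a
realistic alternative.

## What the generator does not emulate

Array chemistry (Type I/II probe designs, dye bias, control probes),
detection-p-value masking, batch structure, and bp-scale CpG-island
geometry. Passing tests therefore demonstrate the correctness and
calibration of the *algorithms* under a plausible correlation and mixture
structure — not robustness to raw-array artefacts, which are upstream of
this pipeline's inputs.

# Preprocessing

Probe filtering removes SNP-associated and cross-reactive probes by default;
allosomal probes are kept by default, which is the appropriate choice for a
single-sex cohort (a toggle drops them). Quantile normalization (the mean of
per-rank order statistics across samples) is the only built-in
normalization, and "none" is the default: intensity-level normalizations
require raw array data that beta-level inputs do not carry. The modelling
scale is the M-value $\log_2\frac{\beta+\epsilon}{1-\beta+\epsilon}$ with
$\epsilon = 0.01$, finite at 0 and 1 and variance-stabilizing; effects are
additionally reported as beta-scale group-mean differences, which is the
scale on which hyper/hypomethylation labels are read.

PCA-based sample QC flags a sample when its score on any of the first $k=2$
components exceeds 3 SD of that component's scores. The rule is a
convention, not an estimate; since dropping samples is destructive, the
function only ever *flags*, and the caller decides. Group association of
each component is tested per group pair with the two-sample rank-sum test —
the test behind published per-pair PC p-values is typically unstated, and
the rank-sum choice matches the nonparametric style used elsewhere in this
workflow.

# Differential methylation

Each probe is fit by ordinary least squares on intercept, age, steroid use
and the group factor, and a single contrast is tested: PSC-UC vs UC or
PSC-UC vs HC. The group term is a three-level factor, not a product
interaction: the two stated comparisons fix the estimand. Variance
moderation is a fixed-prior empirical-Bayes rule: per-probe residual
variances are shrunk toward their pooled mean with prior weight $d_0 = 4$
extra degrees of freedom, $\tilde s^2_j = (d_0 \bar s^2 + d\, s_j^2)/(d_0 +
d)$, and the t reference gains $d_0$ degrees of freedom. This approximates
moderated-t machinery while remaining fully explicit; `moderate = FALSE`
recovers the exact OLS t, which the tests verify against the closed-form
pooled two-sample t. Missing responses drop that sample for that probe only;
constant probes yield a defined degenerate row (effect 0, p missing).
Benjamini–Hochberg adjustment is applied over the non-missing p-values.

# The gene-region stretch-null test

For a candidate gene with $N$ probes, the observed statistic is Fisher's
$X = -2\sum_i \ln p_i$ over the gene's per-probe raw p-values. Under
independence $X \sim \chi^2_{2N}$ — but neighbouring probes are correlated,
so the analytic reference is anticonservative exactly where genes live. The
test therefore draws $B = 5000$ stretches of $N$ *consecutive*
genome-ordered probes at uniformly random positions, computes each
stretch's Fisher statistic, and reports the empirical p-value
$(\#\{X_b \ge X_{obs}\} + 1)/(B + 1)$ (add-one convention, never exactly
zero; since the Fisher map is monotone, comparing statistics is equivalent
to comparing aggregated p-values).

Design choices: stretches are confined to one chromosome by default (a
stretch spanning a boundary is not biologically contiguous; a toggle allows
genome-wide stretches); the null pool includes the tested gene's own probes
(no exclusion is the default, with a toggle); probes with missing p inside a
stretch or gene contribute nothing and $N$ is not re-matched; per-gene seeds
derive from the master seed and the gene *name*, so results are independent
of list order. Genome order is chromosome (numeric autosomes, then X, Y),
position, probe id.

On synthetic cohorts the package verifies both halves of the argument: on an
independent-probe genome, empirical and analytic p agree (rank correlation
above 0.99); with correlation length 5, the stretch test's type-I error at
$\alpha = 0.05$ stays near 0.05 while the analytic Fisher test's exceeds
0.10. Probe independence requires more than switching the spatial field
off: the per-sample cell mixture and the age-clock signal are shared latent
factors that correlate probes genome-wide, so the independence validation
additionally fixes the mixing fractions at the whole-blood average and
disables the clock signal, leaving i.i.d. probe noise only.

# Cell-type deconvolution

Fractions are estimated per sample by minimizing $\|b - Aw\|^2$ over the
discriminating probes, subject to $w \ge 0$ and $\sum w \le 1$ — the
standard constrained quadratic program of reference-based blood
deconvolution, solved with a dual active-set QP solver to 1e-8. Allowing
$\sum w < 1$ keeps the problem feasible when a sample contains populations
absent from the reference; the deficit is reported, and renormalization to
unit sum is an output option. Discriminating probes are chosen per cell
type as the largest positive and negative margins between that type's mean
and the mean of the others. Group comparison uses a two-way ANOVA of
fraction on group and cell type — emitted both with and without the
interaction, since either reading of "two-way ANOVA" is defensible —
followed by per-type Kruskal–Wallis tests (BH across types) and pairwise
rank-sum tests.

# Epigenetic clock

The clock is a sparse linear score over clock probes mapped through the
standard piecewise age calibration: logarithmic below `adult_age` (20
years), linear above, continuous at the knot. Published human clock
coefficients are external data and are deliberately not bundled; the clock
is a model-file input, and the synthetic generator builds self-consistent
clocks: clock probes carry a beta-scale signal $\beta_j = m_j + s_j F(age)$
and coefficients $u_j = 1/(K s_j)$ with intercept $-\sum u_j m_j$, so on a
noiseless cohort the predicted age equals the chronological age exactly (to
machine precision). The beta-linear construction at clock probes is what
makes exact self-consistency possible — an additive logit-scale age term
would make the score nonlinear in $F$ — and the noise/spatial field still
combine on the logit scale at those probes. Missing clock probes (up to
50%) are imputed with the clock's stored reference means. Age acceleration
is predicted minus chronological age; groups are compared by per-group
medians/ranges and a Kruskal–Wallis omnibus test. Because acceleration is
sensitive to normalization, the regression tests confirm that raw and
quantile-normalized inputs yield different median accelerations.

# Classification

The discrimination analysis trains a gradient-boosted tree ensemble
(xgboost, binary logistic) on probe features with a repeated stratified
2/3 train / 1/3 test protocol (default 25 repetitions). Within each
repetition, hyperparameters are selected on the training set only by
5-fold inner cross-validated AUROC over a deliberately small grid (depth
{2, 3}, learning rate {0.1, 0.3}, rounds {50, 200}); ties go to the first,
smallest grid row. AUROC is the normalized Mann–Whitney U (ties count one
half), verified against brute-force pair counting. The final AUROC is the
arithmetic mean of the per-repetition test AUROCs.

Determinism and invariance: splits and folds are keyed by hashes of
(seed, repetition, sample id), and features/samples are canonicalized by
name, so results are byte-identical under a seed and invariant to input
ordering. The R xgboost binding draws its column subsampling from R's
global RNG, so every fit runs inside a derived-seed RNG context. The
learner uses `colsample_bytree = 0.5`: methylation signal is carried by
*sets* of redundant CpGs, and with all columns available every tree reuses
one representative, collapsing gain importance onto a single probe;
per-tree column subsampling spreads importance across the contributing set
while remaining deterministic under the seed.

Feature significance substitutes a documented permutation-importance
criterion for information-decomposition importance methods (which are
defined in external literature, not here): observed importance is the mean
gain across repetitions; the null re-runs the full protocol on
label-permuted data `B_perm` times (with a reduced repetition count);
per-feature empirical p is add-one; selection is at BH-adjusted p < 0.05.

The classifier's *null AUROC* reference draws a fresh label permutation per
repetition. A single fixed permutation kept across repetitions is biased on
strongly clustered features: train and test label balances are negatively
dependent (sampling without replacement from a finite cohort), so the model
anti-learns and the mean AUROC can fall far below 0.5. Averaging over fresh
permutations removes this and centres the null at 0.5.

# Numerical choices and degenerate inputs

- Fisher statistics floor p at 1e-300 (counted and warned) to stay finite.
- The QP adds a 1e-10 ridge to keep the Cholesky stable; solver-tolerance
  negative weights are clipped to 0.
- Zero-variance probes are dropped inside PCA and yield degenerate DMP rows.
- Identical fractions or accelerations across samples yield missing
  p-values with a note, never failure.
- BED export converts the manifest's 1-based positions to 0-based half-open
  width-1 intervals; the beta reader rejects (never transposes) a
  column/sheet mismatch.

# Problem sizes used in the validation suite

The validation runs use 500 genes (independent-probe genome, 6 000 probes)
and 2 000 genes (correlated genome, 20 000 probes) at B = 5000 for the
gene-region calibration; 46-sample cohorts at 3 000–4 000 probes for the
deconvolution and clock recoveries; and a 34-sample, 5 000-feature cohort
with 20 injected probes for the classifier pair. These sizes were chosen so
the full suite completes on a single desk CPU while every estimate of a
rate or error stays within usefully tight Monte-Carlo bounds.

# Known limitations

- The generator's spatial field is index-based AR(1); real co-methylation
  has heavier-tailed, island-structured correlation.
- The fixed-prior variance moderation is an approximation; it does not
  estimate the prior weight from the data.
- Permutation feature significance is costly (B_perm full protocol reruns)
  and its null shares the classifier's small-sample variability.
- The deconvolution reference is synthetic; applying the stage to real
  cohorts requires an external sorted-cell reference matrix in the same
  probes-by-types format.
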