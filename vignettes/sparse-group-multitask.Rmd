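---
title: "Sparse group multitask regression for multi-omics integration: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse group multitask regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgmtreg)
```

## The problem

Individual omics studies of a complex trait are typically underpowered (small
n, large p) and poorly reproducible across platforms and cohorts. When several
studies of the *same phenotype* exist — say SNP genotypes on one cohort and
expression arrays on others, with disjoint subjects — no sample-level merge is
possible, but the studies share a gene universe. `sgmtreg` fits one linear
regression per study (a *task*) and couples the tasks through a penalty on
gene-level coefficient groups that span all studies, so evidence for a gene
accumulates across data types without requiring shared subjects.

## Model

For task $i$ with standardized feature matrix $X^{(i)}$ ($n_i \times d_i$) and
centered response $Y^{(i)}$, the stacked coefficient vector
$C = (C^{(1)\prime}, \dots, C^{(T)\prime})'$ minimizes

$$\sum_{i=1}^{T} \omega_{k(i)} \, \delta_i \, \lVert Y^{(i)} - X^{(i)} C^{(i)} \rVert_2^2 \;+\; \Phi(C),$$

with two penalty choices:

* **multitask sparse group lasso** (`model = "sglasso"`):
  $\Phi(C) = \lambda_1 \sum_{q=1}^{Q} \lVert C_{G_q} \rVert_2 + \lambda_2 \lVert C \rVert_1$,
  where $G_q$ collects *all* coefficients annotated to gene $q$ in *every*
  task. The group term removes whole genes; the elementwise term removes
  individual features inside retained genes.
* **multitask group ridge** (`model = "sgridge"`):
  $\Phi(C) = \lambda \sum_{q=1}^{Q} \lVert C_{G_q} \rVert_1^2$ — an inner
  $\ell_1$ for within-gene sparsity, an outer square that acts like ridge
  shrinkage *across* genes and never removes a gene entirely.

Weights: $\omega_k$ is a per-level prior weight, 1 by default for every level
(all omics levels presumed equally informative; override via
`study_collection(omega = ...)`). $\delta_i = n_i / \sum_{j \in \text{level}} n_j$
down-weights small studies within a level. Groups are defined *once across all
tasks* (one group per gene spanning every dataset); the grouping is the point
of the model — a single task with a single platform reduces to ordinary
sparse group regression.

### Data conventions

* Feature columns are standardized to mean 0, **sample** standard deviation 1
  (the $n-1$ convention). Constant columns are rejected by name.
* The response is centered per task (this absorbs the intercept); binary
  phenotypes are coded 0/1 and fitted with squared loss — the model is linear
  even for case/control data, which matches how the method is meant to be
  used and keeps the coefficient update analytic.
* Each gene must carry at least one feature in at least one dataset; a gene
  may be absent from individual datasets (its sub-block is simply empty
  there).

## Fitting by ADMM

The loss and the two non-smooth penalty pieces are decoupled by variable
splitting ($C = V_1$, and $C = V_2$ for the sparse group lasso), giving an
alternating scheme with scaled multipliers $D$:

1. **Coefficient step** — an independent per-task ridge solve
   $(2 w_i X^{(i)\prime} X^{(i)} + s\rho I)\, C^{(i)} = 2 w_i X^{(i)\prime} Y^{(i)} + \rho \sum_s (V_s + D_s)^{(i)}$,
   where $s$ is the number of splits and $w_i = \omega_{k(i)}\delta_i$.
   Implemented through a thin SVD of each $X^{(i)}$, cached once and reused
   across all iterations, the entire tuning grid, and every permutation refit
   (only $X'Y$ changes when the phenotype is permuted).
2. **Group step** — the exact proximal operator of the group penalty:
   block soft-thresholding for the group lasso
   ($V_{G_q} \gets \max(0, 1 - \tfrac{\lambda_1/\rho}{\lVert z_{G_q}\rVert_2}) z_{G_q}$;
   because groups do not overlap, this closed form is the exact minimizer, so
   no inner block-coordinate loop is needed), or the squared-$\ell_1$ prox for
   the group ridge (below).
3. **Elementwise step** (sparse group lasso only) — soft-thresholding at
   $\lambda_2/\rho$.
4. **Multiplier update** — $D \gets D - C + V$.

### The squared-$\ell_1$ proximal operator

Per group, $\min_v \tfrac{\rho}{2}\lVert z - v\rVert^2 + \lambda \lVert v\rVert_1^2$
is solved exactly: the minimizer is a soft-threshold at a self-consistent
level $t = (2\lambda/\rho) \sum |v_j|$. Sorting magnitudes in decreasing
order, the active set is a prefix: with $c = 2\lambda/\rho$ and $A_k$ the
partial sum of the $k$ largest magnitudes, the candidate level is
$t(k) = cA_k/(1+ck)$ and the solution takes the largest $k$ with
$a_k > t(k)$ — $O(d \log d)$ per group, vectorized across groups. Note
$t(1) < a_1$ always: the operator shrinks but never annihilates a nonzero
group. Both prox operators (and the solver itself) are verified in the test
suite against an independent general-purpose minimizer built from smooth
reformulations and box-constrained L-BFGS-B.

### Numerical choices

* Initialization $V = D = 0$, $\rho_0 = 1$; tolerances
  $\varepsilon_{abs} = 10^{-6}$, $\varepsilon_{rel} = 10^{-4}$;
  `max_iter = 2000`. Convergence requires both the primal residual
  $\max_s \lVert C - V_s\rVert_2$ and the dual residual
  $\rho \max_s \lVert V_s - V_s^{old}\rVert_2$ to fall below
  $\sqrt{p}\,\varepsilon_{abs} + \varepsilon_{rel}\cdot(\text{iterate scale})$.
* $\rho$ is adapted to keep the primal/dual residual ratio inside
  $[0.1, 10]$, doubling or halving with the scaled multipliers rescaled
  accordingly. One subtlety matters in practice: with heavy penalties the
  splitting variables sit exactly at zero, the dual residual is exactly 0 and
  the ratio is infinite — this *must* increase $\rho$, otherwise convergence
  degrades to $O(1/\sqrt{k})$.
* The reported coefficient vector takes its sparsity pattern from the
  splitting variables, which are *exactly* sparse (the analytic $C$ is dense
  up to tolerance): entries are zeroed where $V_1$ (and $V_2$) vanish, so the
  downstream gene statistic sees genuine zero groups.
* The solver contains no randomness; fits are reproducible bit for bit.

## Tuning and the gene-level test

Penalties are tuned on a log-spaced grid $10^{0.1}, 10^{0.2}, \dots, 10^{3}$
(30 values per axis; `grid_size` reduces it with the same endpoints) by
5-fold cross validation. Folds are drawn independently *within* each dataset
(subjects are disjoint across studies, so a global split is meaningless), and
the per-dataset assignment is seeded from the dataset id so results do not
depend on manifest order. Each training fold is re-standardized and its
parameters are reapplied to the held-out fold. The CV error is the
task-weighted, per-sample-normalized held-out squared error
$\sum_i \omega_i \delta_i \,\text{SSE}_i / n_i$; exact ties are broken toward
larger penalties (sparser models).

The gene-level statistic is $\hat S_q = \sum_j \lVert \hat C_q^{(j)} \rVert_2^2$,
the squared coefficient mass of gene $q$ across all tasks. Significance comes
from a permutation scheme: the phenotype is permuted independently within
every dataset, the model is refitted at the hyperparameters *frozen* at the
unpermuted-data CV optimum (re-running CV inside each of hundreds of
permutations would be prohibitive, and frozen-parameter score permutation is
the standard design), and $B$ null statistics per gene are collected. Each
gene's observed statistic is standardized by its own null mean and standard
deviation — this is the gene-size adjustment; no extra size covariate is
used — and the standardized null draws of all genes are pooled into one
reference set, against which the empirical p-value is the fraction of pooled
draws at least as large. The printed formula can return exactly 0; a
`smooth = TRUE` option gives the add-one version. A gene whose statistic
never varies across permutations carries no evidence and gets $p = 1$ with a
warning.

### Calibration, and a degeneracy worth knowing about

Under a *global null* (no causal genes anywhere), cross validation for the
sparse group lasso faces exactly tied CV errors across every grid point whose
fit is entirely zero; the tie-break selects the sparsest model, every
permutation refit is exactly zero, and all genes hit the $p = 1$ rule. The
test is then conservative — it makes no false claims — but its p-values are a
point mass, not uniform. This is a structural property of any exactly-sparse
statistic combined with empirical permutation p-values, not a solver or test
defect. The group-ridge model has no such degeneracy (its statistic is
continuous because groups are never annihilated), so distributional
calibration checks in the test suite use `sgridge`, while `sglasso` is
checked for conservativeness. With real signal present the selected penalties
keep coefficients alive and the sparse-group-lasso p-values are informative.

## The simulator

`sim_scenario()` + `build_scenario_collection()` generate the two-level
design the package targets: by default 3 SNP studies (600/400/200 subjects)
and 3 expression studies (70/50/30 subjects) over 200 genes, 20 causal.

* **Genotypes** use a latent-Gaussian haplotype surrogate: per haplotype, an
  AR(1) latent process (correlation `ld_decay`, default 0.8, independent
  across genes) is thresholded at the MAF quantile; the genotype is the sum
  of two independent haplotypes. Marginally each SNP is Binomial(2, MAF) —
  Hardy–Weinberg equilibrium holds *by construction* — with LD between
  nearby SNPs of a gene. Causal SNPs (2 per causal gene) draw MAF from
  (0.15, 0.25); other SNPs from (0.05, 0.5). A column that comes out constant
  in a small sample is redrawn with independent HWE-consistent alleles so
  standardization is always defined.
* **Expression** of a causal gene is additive in its causal SNP genotypes
  with effects from Unif(1, 1.2) plus N(0,1) noise; non-causal genes are
  jointly Gaussian with covariance $0.3^{|i-j|}$ over gene indices (generated
  exactly via the AR(1) representation).
* **Phenotype** is binary through
  $\text{logit}\,\Pr(Y=1) = \sum_j G_j^{causal}\tau_j + \varepsilon'$,
  $\varepsilon' \sim N(0,1)$ (a quantitative identity-link mode exists). For
  SNP-only studies, causal expression is first generated *latently* from that
  study's own genotypes and discarded after producing $Y$ — the only reading
  that routes SNP data to the phenotype through the stated causal chain.
  Expression studies likewise draw their own genotypes at their own sample
  sizes.
* **Effect designs**: baseline gene effects $\eta$ have magnitude
  Unif(0.2, 2) with random sign; the *fixed-effect* design sets
  $\tau = \eta \cdot \delta_{\text{effect}}$ identically in every dataset
  ($\delta_{\text{effect}} = 0$ is the global null), and the *dynamic-effect*
  design draws $\tau \sim N(\eta\,\delta_{\text{effect}},
  \sigma_{\text{dynamic}}^2)$ per dataset. $\sigma_{\text{dynamic}} = 0$
  takes the same code path as the fixed design, so the two coincide exactly
  at equal seeds.

What the surrogate does **not** emulate: real chromosomal LD maps and
recombination hotspots, allele-frequency spectra, population structure,
genotyping error, batch effects, heavy-tailed expression noise, or
correlation between causal and non-causal expression. Tests passing on this
generator therefore certify the *statistical machinery* (optimization,
calibration, ordering of methods under the stated generative model), not
performance on any particular real cohort.

## The meta-analysis baseline

The comparator combines per-study evidence the way sample-size-weighted
z-score meta-analysis does: per dataset and feature, a simple-regression
score test with normal approximation ($z = \sqrt{n}\,\mathrm{cor}(x, y)$);
signed z's combined across studies with $\sqrt{n}$ weights; a gene summarized
by its most significant feature. The min-p gene summary is deliberately left
uncorrected (matching common usage); it is anti-conservative under the null,
which is one reason gene-level ROC comparisons are made at matched truth
labels rather than at nominal thresholds.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run scaled-down designs chosen to
exercise every component at desk scale: solver/prox verification on random
problems with 3 tasks, 6 genes, up to 12 features per task; calibration at 50
genes, 10 SNPs per gene, 200/100 + 50/30 subjects, B = 200 permutations, a
5-value-per-axis CV grid; the power comparison keeps the full study sample
sizes (600/400/200 + 70/50/30) with the gene dimension scaled to 50 (5
causal), a 4-value-per-axis grid and B = 50. The full 30 × 30 grid and B = 500 remain the package
defaults for real analyses.

## Limitations

* Identity link only; binary traits are fitted with squared loss.
* Missing values are rejected, not imputed; features must be pre-annotated to
  genes (no probe re-annotation).
* Groups must not overlap (a feature maps to exactly one gene).
* Empirical p-values have resolution $1/(QB)$ and can be exactly 0 unless
  `smooth = TRUE`.
* The permutation test freezes hyperparameters at the observed-data CV
  optimum; selection uncertainty is not propagated.
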