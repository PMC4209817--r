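# sgmtreg — sparse group multitask regression for multi-omics integration

`sgmtreg` identifies phenotype-associated genes by jointly analyzing several
omics studies that share a gene universe but nothing else — different
molecular levels (SNP genotypes, gene expression), different platforms, and
**disjoint subject sets**. It is aimed at statistical geneticists who have,
say, a GWAS cohort and a few small expression cohorts of the same trait and
want one gene-level significance ranking that uses all of them.

## The model

Each study is a regression task. With standardized features `X_i`, centered
response `Y_i` and stacked coefficients `C`, the fit minimizes

    sum_i  omega_i * delta_i * || Y_i - X_i C_i ||^2  +  Phi(C)

where `omega` weights omics levels (default 1: all levels equally
informative), `delta_i = n_i / sum(n at level)` weights platforms by sample
size, and `Phi` couples the tasks through gene groups `G_q` spanning *all*
datasets:

* **multitask sparse group lasso** —
  `Phi(C) = lambda1 * sum_q ||C_{G_q}||_2 + lambda2 * ||C||_1`
  (gene-level selection plus within-gene feature selection);
* **multitask group ridge** —
  `Phi(C) = lambda * sum_q ||C_{G_q}||_1^2`
  (within-gene sparsity, ridge-like shrinkage across genes).

Both are fitted by an alternating direction method of multipliers with an
analytic per-task coefficient step (cached thin SVD) and exact proximal
steps. Gene significance comes from the statistic
`S_q = sum_j ||C_q^(j)||^2` (coefficient mass of gene `q` across tasks),
standardized against a phenotype-permutation null with hyperparameters frozen
at the cross-validated optimum, with empirical p-values taken from the pooled
standardized null. A sample-size-weighted z-score meta-analysis baseline, a
ROC/power harness and a full synthetic-data generator (LD-structured
genotypes, eQTL-driven expression, logistic phenotypes) are included.

## Worked example

Simulate a small two-level design (2 SNP studies, 2 expression studies,
12 genes of which 3 causal), then test every gene:

```r
library(sgmtreg)

scen <- sim_scenario(Q = 12, m = 3, snps_per_gene = c(5, 10),
                     snp_n = c(150, 100), expr_n = c(60, 40),
                     delta_effect = 1)
sim <- build_scenario_collection(scen, seed = 42)
sim$collection
#> study_collection: 4 dataset(s) across 2 level(s)
#>   snp_1        level=snp        platform=snp_chip_1 n=  150 d=    77 delta=0.600
#>   snp_2        level=snp        platform=snp_chip_2 n=  100 d=    77 delta=0.400
#>   expr_1       level=expression platform=expr_array_1 n=   60 d=    12 delta=0.600
#>   expr_2       level=expression platform=expr_array_2 n=   40 d=    12 delta=0.400

gt <- run_gene_test(sim$collection, sim$groups, model = "sglasso",
                    grid_size = 4, B = 100, seed = 42)
head(as.data.frame(gt)[order(gt$p_value), ], 5)
#>     gene_id    S_hat S_null_mean S_null_sd S_tilde p_value
#> 5  gene_005 0.013908    0.000870  0.001276  10.220 0.00000
#> 8  gene_008 0.020348    0.001056  0.001618  11.921 0.00000
#> 12 gene_012 0.015875    0.002083  0.002823   4.886 0.00333
#> 1  gene_001 0.000957    0.000604  0.001171   0.301 0.21333
#> 9  gene_009 0.000478    0.000389  0.000715   0.124 0.25583

sim$truth$causal_gene_ids
#> [1] "gene_005" "gene_008" "gene_012"

roc_curve(gt$p_value, sim$truth$gene_ids %in% sim$truth$causal_gene_ids)
#> sgm_roc: 11 cutoffs, AUC = 1
```

The three planted causal genes occupy the top three ranks (`S_hat` is the
observed coefficient mass, `S_tilde` its standardization against the
permutation null; `p_value` is empirical against the pooled null, so `0`
means "larger than every pooled null draw" — use `smooth = TRUE` for add-one
p-values). `roc_curve` scores the ranking against the simulated truth.

Real data enter through a YAML manifest plus TSV matrices and a
feature-to-gene annotation table; see `?load_study_collection` for the
schema. A command-line front-end with subcommands
`simulate | fit | cv | test | compare` is installed at
`inst/cli/sgmtreg.R` (e.g.
`Rscript inst/cli/sgmtreg.R simulate --seed 7 --out data/`).

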