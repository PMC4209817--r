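#' Simulation scenario parameters
#'
#' Describes the generative model for a multi-study SNP + expression design:
#' `Q` genes per dataset, `m` of them causal; per-gene SNP counts drawn
#' uniformly from `snps_per_gene`; two causal SNPs per causal gene with MAF in
#' `causal_maf` drive that gene's expression additively with effects in
#' `beta_range`; causal-gene expression drives a binary phenotype through a
#' logistic model with gene effects `tau = eta * delta_effect` (fixed-effect
#' design) or `tau ~ N(eta * delta_effect, sigma_dynamic^2)` drawn per dataset
#' (dynamic-effect design). Baseline effects `eta` have magnitude
#' `Unif(0.2, 2)` and random sign. Genotypes are LD-structured through a
#' latent-Gaussian AR(1) haplotype model with within-gene correlation
#' `ld_decay`; they satisfy Hardy-Weinberg equilibrium by construction.
#' Non-causal expression is multivariate normal with covariance
#' `expr_corr^|i-j|` over gene indices.
#'
#' Defaults: 3 SNP studies of 600/400/200 subjects, 3 expression studies of
#' 70/50/30 subjects, 200 genes with 10-100 SNPs each, 20 causal genes,
#' causal-SNP MAF in (0.15, 0.25), non-causal MAF in (0.05, 0.5), SNP-on-
#' expression effects in (1, 1.2).
#'
#' @param Q number of genes (default 200).
#' @param m number of causal genes (default 20).
#' @param snps_per_gene integer range of SNPs per gene (default `c(10, 100)`).
#' @param causal_snps_per_gene causal SNPs within each causal gene (default 2).
#' @param causal_maf MAF range of causal SNPs (default `c(0.15, 0.25)`).
#' @param maf_range MAF range of non-causal SNPs (default `c(0.05, 0.5)`).
#' @param snp_n sample sizes of the SNP datasets (default `c(600, 400, 200)`).
#' @param expr_n sample sizes of the expression datasets
#'   (default `c(70, 50, 30)`).
#' @param beta_range SNP-on-expression effect range (default `c(1, 1.2)`).
#' @param eta_magnitude magnitude range of baseline gene effects
#'   (default `c(0.2, 2)`; sign random).
#' @param delta_effect effect-scaling factor in `[0, 1]` (0 = global null).
#' @param sigma_dynamic across-dataset effect dispersion (0 = fixed effects).
#' @param expr_corr base of the expression correlation decay (default 0.3).
#' @param ld_decay within-gene latent haplotype AR(1) correlation
#'   (default 0.8).
#' @param phenotype `"binary"` (logistic, default) or `"quantitative"`
#'   (identity link, Gaussian noise).
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(Q = 200, m = 20, snps_per_gene = c(10, 100),
                         causal_snps_per_gene = 2,
                         causal_maf = c(0.15, 0.25), maf_range = c(0.05, 0.5),
                         snp_n = c(600, 400, 200), expr_n = c(70, 50, 30),
                         beta_range = c(1, 1.2), eta_magnitude = c(0.2, 2),
                         delta_effect = 1, sigma_dynamic = 0,
                         expr_corr = 0.3, ld_decay = 0.8,
                         phenotype = c("binary", "quantitative")) {
  phenotype <- match.arg(phenotype)
  stopifnot(m <= Q, m >= 1, causal_snps_per_gene <= snps_per_gene[1],
            maf_range[1] >= 0, maf_range[2] <= 0.5,
            causal_maf[1] >= maf_range[1], causal_maf[2] <= 0.5,
            delta_effect >= 0, sigma_dynamic >= 0,
            ld_decay >= 0, ld_decay < 1)
  structure(list(Q = Q, m = m, snps_per_gene = snps_per_gene,
                 causal_snps_per_gene = causal_snps_per_gene,
                 causal_maf = causal_maf, maf_range = maf_range,
                 snp_n = snp_n, expr_n = expr_n, beta_range = beta_range,
                 eta_magnitude = eta_magnitude, delta_effect = delta_effect,
                 sigma_dynamic = sigma_dynamic, expr_corr = expr_corr,
                 ld_decay = ld_decay, phenotype = phenotype),
            class = "sim_scenario")
}

#' Simulate LD-structured 0/1/2 genotypes
#'
#' Latent-Gaussian haplotype surrogate: for each of the two haplotypes of a
#' subject, latent standard normals follow an AR(1) process with correlation
#' `ld_decay` across the SNPs of one gene (independent across genes); a
#' haplotype carries the minor allele when its latent value falls below the
#' MAF quantile. The genotype is the minor-allele count (0/1/2), so each SNP
#' is Binomial(2, MAF) marginally and in Hardy-Weinberg equilibrium by
#' construction, with LD between nearby SNPs of the same gene. A column that
#' comes out constant in a finite sample is redrawn (independent alleles, same
#' MAF) so downstream standardization is always defined.
#'
#' @param n number of subjects.
#' @param maf per-SNP minor allele frequencies.
#' @param gene optional block labels (one per SNP) delimiting LD blocks;
#'   default puts all SNPs in one block.
#' @param ld_decay AR(1) latent correlation within a block, in `[0, 1)`.
#' @param seed optional seed.
#' @return n x length(maf) integer matrix of minor-allele counts.
#' @export
simulate_genotypes <- function(n, maf, gene = NULL, ld_decay = 0.8,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, all(maf > 0), all(maf <= 0.5), ld_decay >= 0, ld_decay < 1)
  s <- length(maf)
  if (is.null(gene)) gene <- rep(1L, s)
  stopifnot(length(gene) == s)
  hap <- function() {
    Z <- matrix(NA_real_, n, s)
    for (blk in split(seq_len(s), factor(gene, levels = unique(gene)))) {
      Z[, blk[1]] <- stats::rnorm(n)
      if (length(blk) > 1)
        for (j in blk[-1])
          Z[, j] <- ld_decay * Z[, j - 1] +
            sqrt(1 - ld_decay^2) * stats::rnorm(n)
    }
    Z
  }
  thr <- stats::qnorm(maf)
  G <- (sweep(hap(), 2, thr, "<") + 0) + (sweep(hap(), 2, thr, "<") + 0)
  # rare small-sample degeneracy: redraw constant columns with HWE-consistent
  # independent alleles (LD for that column is sacrificed)
  for (j in seq_len(s)) {
    tries <- 0
    while (length(unique(G[, j])) == 1 && tries < 100) {
      G[, j] <- stats::rbinom(n, 1, maf[j]) + stats::rbinom(n, 1, maf[j])
      tries <- tries + 1
    }
  }
  storage.mode(G) <- "integer"
  G
}

#' Simulate gene expression from genotypes
#'
#' Causal gene `q`: `G_q = sum_j SNP_causal_j * beta_j + eps`,
#' `eps ~ N(0, 1)`. Non-causal genes: jointly multivariate normal with
#' covariance `expr_corr^|i-j|` over the original gene indices (generated
#' exactly through the AR(1) representation across index gaps).
#'
#' @param genotypes n x S genotype matrix containing the causal SNP columns.
#' @param truth a `sgm_sim_truth` (from [build_scenario_collection()]) or a
#'   list with `Q`, `causal_genes` (indices), `causal_snp_cols` (list of
#'   column indices per causal gene), `beta` (list of effect vectors),
#'   `expr_corr`.
#' @param seed optional seed.
#' @return n x Q expression matrix, columns in gene order.
#' @export
simulate_expression <- function(genotypes, truth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  Q <- truth$Q
  E <- matrix(NA_real_, n, Q)
  for (k in seq_along(truth$causal_genes)) {
    cols <- truth$causal_snp_cols[[k]]
    if (any(cols > ncol(genotypes)))
      stop("causal SNP column missing from genotype matrix")
    E[, truth$causal_genes[k]] <-
      drop(genotypes[, cols, drop = FALSE] %*% truth$beta[[k]]) +
      stats::rnorm(n)
  }
  nc <- setdiff(seq_len(Q), truth$causal_genes)
  if (length(nc)) {
    phi <- truth$expr_corr
    E[, nc[1]] <- stats::rnorm(n)
    if (length(nc) > 1)
      for (j in 2:length(nc)) {
        gap <- nc[j] - nc[j - 1]
        r <- phi^gap
        E[, nc[j]] <- r * E[, nc[j - 1]] + sqrt(1 - r^2) * stats::rnorm(n)
      }
  }
  E
}

#' Simulate a phenotype from causal-gene expression
#'
#' Binary: `logit(Pr(Y = 1)) = sum_j G_causal_j * tau_j + eps'`,
#' `eps' ~ N(0, 1)`, `Y ~ Bernoulli`. Quantitative: `Y` equals the same linear
#' predictor (identity link).
#'
#' @param causal_expr n x m matrix of causal-gene expression values.
#' @param tau length-m vector of gene effects for this dataset.
#' @param type `"binary"` or `"quantitative"`.
#' @param seed optional seed.
#' @return numeric vector of length n (0/1 for binary).
#' @export
simulate_phenotype <- function(causal_expr, tau,
                               type = c("binary", "quantitative"),
                               seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  causal_expr <- as.matrix(causal_expr)
  stopifnot(ncol(causal_expr) == length(tau))
  lp <- drop(causal_expr %*% tau) + stats::rnorm(nrow(causal_expr))
  if (type == "binary") stats::rbinom(length(lp), 1, stats::plogis(lp))
  else lp
}

#' Generate a full multi-study collection from a scenario
#'
#' Draws the shared genetic architecture once (per-gene SNP counts, causal
#' genes, causal SNP positions, MAFs, SNP-on-expression effects `beta`,
#' baseline gene effects `eta`), then generates each dataset with an
#' independent sub-seed: SNP datasets contain genotypes as features, with the
#' phenotype produced by first generating that dataset's (latent, discarded)
#' causal expression from its own genotypes; expression datasets contain one
#' expression feature per gene, generated from a fresh genotype draw of the
#' dataset's own sample size. Per-dataset gene effects `tau` follow the fixed
#' (`tau = eta * delta_effect`) or dynamic
#' (`tau ~ N(eta * delta_effect, sigma_dynamic^2)`) design; `sigma_dynamic=0`
#' takes the same code path as the fixed design, so the two coincide exactly
#' at equal seeds. Byte-identical outputs for identical scenario + seed.
#'
#' @param scenario a [sim_scenario()].
#' @param seed master seed; per-dataset sub-seeds are drawn from it.
#' @return list with `collection` (normalized [study_collection()]), `groups`
#'   ([build_gene_index()]), and `truth` (class `sgm_sim_truth`): gene ids,
#'   causal gene ids/indices, causal SNP columns, `beta`, `eta`, `tau`
#'   (m x T matrix), per-SNP `maf` and gene labels, dataset sub-seeds.
#' @export
build_scenario_collection <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  Q <- scenario$Q; m <- scenario$m
  gene_ids <- sprintf("gene_%03d", seq_len(Q))
  s_vals <- seq(scenario$snps_per_gene[1], scenario$snps_per_gene[2])
  s_q <- s_vals[sample.int(length(s_vals), Q, replace = TRUE)]
  snp_gene <- rep(seq_len(Q), s_q)
  snp_ids <- unlist(lapply(seq_len(Q), function(q)
    sprintf("%s_snp_%03d", gene_ids[q], seq_len(s_q[q]))))
  maf <- stats::runif(sum(s_q), scenario$maf_range[1], scenario$maf_range[2])
  causal_genes <- sort(sample(Q, m))
  cs <- scenario$causal_snps_per_gene
  snp_offsets <- c(0L, cumsum(s_q))
  causal_snp_cols <- lapply(causal_genes, function(q)
    snp_offsets[q] + sort(sample(s_q[q], cs)))
  for (cols in causal_snp_cols)
    maf[cols] <- stats::runif(cs, scenario$causal_maf[1], scenario$causal_maf[2])
  beta <- lapply(causal_genes, function(q)
    stats::runif(cs, scenario$beta_range[1], scenario$beta_range[2]))
  eta <- sample(c(-1, 1), m, replace = TRUE) *
    stats::runif(m, scenario$eta_magnitude[1], scenario$eta_magnitude[2])
  n_all <- c(scenario$snp_n, scenario$expr_n)
  T_all <- length(n_all)
  ds_seed <- sample.int(2147483646L, T_all)
  base_tau <- eta * scenario$delta_effect
  tau <- matrix(NA_real_, m, T_all)
  for (t in seq_len(T_all))
    tau[, t] <- if (scenario$sigma_dynamic > 0)
      stats::rnorm(m, base_tau, scenario$sigma_dynamic) else base_tau
  truth <- structure(list(
    gene_ids = gene_ids, Q = Q,
    causal_genes = causal_genes, causal_gene_ids = gene_ids[causal_genes],
    causal_snp_cols = causal_snp_cols, beta = beta, eta = eta, tau = tau,
    snps_per_gene = s_q, snp_gene = snp_gene, snp_ids = snp_ids, maf = maf,
    expr_corr = scenario$expr_corr, delta_effect = scenario$delta_effect,
    sigma_dynamic = scenario$sigma_dynamic, dataset_seeds = ds_seed),
    class = "sgm_sim_truth")
  datasets <- vector("list", T_all)
  ann <- vector("list", T_all)
  for (t in seq_len(T_all)) {
    set.seed(ds_seed[t])
    n <- n_all[t]
    snp_level <- t <= length(scenario$snp_n)
    G <- simulate_genotypes(n, maf, gene = snp_gene,
                            ld_decay = scenario$ld_decay)
    if (snp_level) {
      latent <- simulate_expression(G, truth)
      Y <- simulate_phenotype(latent[, causal_genes, drop = FALSE], tau[, t],
                              type = scenario$phenotype)
      id <- paste0("snp_", t)
      datasets[[t]] <- omics_dataset(
        `colnames<-`(G, snp_ids), Y, id, "snp",
        platform = paste0("snp_chip_", t))
      ann[[t]] <- data.frame(feature_id = snp_ids, dataset_id = id,
                             gene_id = gene_ids[snp_gene])
    } else {
      E <- simulate_expression(G, truth)
      Y <- simulate_phenotype(E[, causal_genes, drop = FALSE], tau[, t],
                              type = scenario$phenotype)
      id <- paste0("expr_", t - length(scenario$snp_n))
      eids <- paste0(gene_ids, "_expr")
      datasets[[t]] <- omics_dataset(
        `colnames<-`(E, eids), Y, id, "expression",
        platform = paste0("expr_array_", t - length(scenario$snp_n)))
      ann[[t]] <- data.frame(feature_id = eids, dataset_id = id,
                             gene_id = gene_ids)
    }
  }
  collection <- study_collection(datasets)
  groups <- build_gene_index(collection, do.call(rbind, ann))
  list(collection = collection, groups = groups, truth = truth)
}

#' @export
print.sgm_sim_truth <- function(x, ...) {
  cat("sgm_sim_truth:", x$Q, "genes,", length(x$causal_genes),
      "causal; delta_effect =", x$delta_effect,
      ", sigma_dynamic =", x$sigma_dynamic, "\n")
  invisible(x)
}
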