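# In-code fixtures shared across test files.

# Random dense multitask problem: Tn tasks over two levels, Q genes,
# per-task dimensions <= d_max, sample sizes <= n_max.
rand_collection <- function(seed = 1, Tn = 3, Q = 6, d_max = 12, n_max = 25) {
  set.seed(seed)
  levels <- rep(c("a", "b"), length.out = Tn)
  datasets <- vector("list", Tn)
  ann <- list()
  for (i in seq_len(Tn)) {
    d <- sample(seq(Q, d_max), 1)
    n <- sample(seq(15, n_max), 1)
    X <- matrix(rnorm(n * d), n, d)
    colnames(X) <- sprintf("t%d_f%02d", i, seq_len(d))
    Y <- rnorm(n)
    id <- paste0("ds", i)
    datasets[[i]] <- omics_dataset(X, Y, id, levels[i],
                                   platform = paste0("p", i))
    # every gene gets at least one feature in the first dataset
    gene <- if (d >= Q) c(seq_len(Q), sample(Q, d - Q, replace = TRUE))
            else sample(Q, d, replace = TRUE)
    ann[[i]] <- data.frame(feature_id = colnames(X), dataset_id = id,
                           gene_id = sprintf("g%02d", gene))
  }
  collection <- study_collection(datasets)
  groups <- build_gene_index(collection, do.call(rbind, ann))
  list(collection = collection, groups = groups)
}

# Single-task, well-conditioned problem with n > d (for the OLS reduction).
single_task_collection <- function(seed = 1, n = 40, d = 6, Q = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  colnames(X) <- sprintf("f%02d", seq_len(d))
  beta <- rnorm(d)
  Y <- as.vector(scale(X) %*% beta) + rnorm(n, sd = 0.5)
  ds <- omics_dataset(X, Y, "solo", "expr")
  collection <- study_collection(list(ds))
  ann <- data.frame(feature_id = colnames(X), dataset_id = "solo",
                    gene_id = sprintf("g%d", rep_len(seq_len(Q), d)))
  groups <- build_gene_index(collection, ann)
  list(collection = collection, groups = groups)
}

# Small signal-bearing multi-omics scenario for pipeline tests.
tiny_scenario <- function(...) {
  sim_scenario(Q = 8, m = 2, snps_per_gene = c(3, 5),
               causal_snps_per_gene = 2, snp_n = c(60, 40),
               expr_n = c(35, 30), ...)
}

random_groups <- function(seed, n_groups, size_range = c(1, 10)) {
  set.seed(seed)
  sizes <- sample(seq(size_range[1], size_range[2]), n_groups, replace = TRUE)
  rep(seq_len(n_groups), sizes)
}
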