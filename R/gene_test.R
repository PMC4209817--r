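#' Gene-level association statistic
#'
#' For gene `q`, the statistic is the sum over tasks of the squared l2 norms
#' of the gene's fitted coefficient sub-vectors, i.e. the sum of squared
#' stacked coefficients over the gene's cross-task group:
#' `S_q = sum_j ||C_q^(j)||_2^2`.
#'
#' @param C stacked coefficient vector (e.g. `fit$C` of an [sgm_fit()]).
#' @param groups the gene index.
#' @return named numeric vector of length `Q` (names = gene ids).
#' @export
gene_statistic <- function(C, groups) {
  stopifnot(inherits(groups, "gene_group_index"), length(C) == groups$dim)
  s <- rowsum(C^2, factor(groups$stacked, levels = seq_len(groups$Q)))
  stats::setNames(as.numeric(s), groups$gene_ids)
}

#' Permutation null distribution of the gene statistics
#'
#' Permutes the phenotype independently within every dataset (subjects are
#' disjoint across studies), refits the model at frozen hyperparameters, and
#' records the gene statistics; repeated `B` times. Per gene, the null mean
#' and standard deviation are estimated from the `B` draws, each draw is
#' standardized, and the standardized draws of all genes are pooled into one
#' null set. Genes whose statistic never varies across permutations
#' (`sd = 0`) cannot be standardized; they are flagged and excluded from the
#' pool.
#'
#' @param collection a [study_collection()].
#' @param groups the matching gene index.
#' @param model `"sglasso"` or `"sgridge"`.
#' @param lambda1,lambda2,lambda penalty weights, frozen at the
#'   cross-validation optimum of the unpermuted data.
#' @param B number of permutations (>= 2).
#' @param seed seed for the permutations.
#' @param control an [sgm_control()].
#' @param init optional warm start reused for every refit (e.g. the state of
#'   the unpermuted fit).
#' @return object of class `sgm_perm_null`: list with `S0` (Q x B matrix of
#'   raw null statistics), `null_mean`, `null_sd` (per gene), `standardized`
#'   (Q x B, NA rows for degenerate genes), `pooled` (vector of length
#'   `<= Q*B`), `degenerate` (gene ids with zero null sd), `B`, `seed`.
#' @export
permutation_null <- function(collection, groups, model = c("sglasso", "sgridge"),
                             lambda1 = 0, lambda2 = 0, lambda = 0,
                             B = 500, seed = 1, control = sgm_control(),
                             init = NULL) {
  model <- match.arg(model)
  if (B < 2) stop("B must be at least 2")
  prob <- sgm_problem(collection, groups)
  S0 <- matrix(NA_real_, groups$Q, B, dimnames = list(groups$gene_ids, NULL))
  set.seed(seed)
  for (b in seq_len(B)) {
    Yperm <- lapply(collection$datasets, function(ds) ds$Y[sample.int(ds$n)])
    prob_b <- sgm_problem_set_Y(prob, Yperm)
    fit <- fit_problem(prob_b, groups, model, lambda1, lambda2, lambda,
                       control = control, init = init)
    S0[, b] <- gene_statistic(fit$C, groups)
  }
  mu <- rowMeans(S0)
  sdv <- apply(S0, 1, stats::sd)
  degenerate <- groups$gene_ids[sdv == 0]
  std <- (S0 - mu) / ifelse(sdv == 0, NA_real_, sdv)
  pooled <- as.numeric(std[sdv > 0, , drop = FALSE])
  structure(list(S0 = S0, null_mean = mu, null_sd = sdv, standardized = std,
                 pooled = pooled, degenerate = degenerate, B = B, seed = seed),
            class = "sgm_perm_null")
}

#' Empirical p-value against a pooled null
#'
#' `p = #(null >= s) / #(null)`. With `smooth = TRUE` the add-one version
#' `(1 + #(null >= s)) / (1 + #(null))` is used, which never returns an exact
#' zero.
#'
#' @param S_tilde numeric vector of standardized observed statistics.
#' @param pooled numeric vector, the pooled standardized null draws.
#' @param smooth logical, add-one smoothing (default `FALSE`).
#' @return numeric vector of p-values in `[0, 1]`, `NA` where `S_tilde` is
#'   `NA`.
#' @export
empirical_pvalue <- function(S_tilde, pooled, smooth = FALSE) {
  if (!length(pooled)) stop("empty null set")
  n <- length(pooled)
  cnt <- vapply(S_tilde, function(s)
    if (is.na(s)) NA_real_ else sum(pooled >= s), 0)
  if (smooth) (1 + cnt) / (1 + n) else cnt / n
}

#' Gene-level permutation test pipeline
#'
#' Runs the full testing pipeline: cross-validated tuning on the unpermuted
#' data, a full-data fit at the selected penalties, a `B`-permutation null
#' (hyperparameters frozen at the CV optimum), per-gene standardization of the
#' observed statistic against its own null mean and standard deviation, and
#' empirical p-values against the pooled standardized null. Genes whose
#' statistic never varies under permutation get `p = 1` with a warning (the
#' data carry no evidence about them). Deterministic given `seed`.
#'
#' @param collection a [study_collection()].
#' @param groups the matching gene index.
#' @param model `"sglasso"` or `"sgridge"`.
#' @param grid,grid_size,n_folds passed to [sgm_cv()]; ignored when
#'   `hyperparams` is supplied.
#' @param hyperparams optional named list (`lambda1`, `lambda2` or `lambda`)
#'   to skip cross validation.
#' @param B number of permutations (default 500).
#' @param seed master seed (fold plan and permutations are derived from it).
#' @param smooth use add-one smoothing in [empirical_pvalue()].
#' @param control an [sgm_control()].
#' @return data frame of class `sgm_gene_test` with columns `gene_id`,
#'   `S_hat`, `S_null_mean`, `S_null_sd`, `S_tilde`, `p_value`, plus
#'   attributes `fit`, `cv`, `null`, `B`.
#' @export
run_gene_test <- function(collection, groups, model = c("sglasso", "sgridge"),
                          grid = NULL, grid_size = 30, n_folds = 5,
                          hyperparams = NULL, B = 500, seed = 1,
                          smooth = FALSE, control = sgm_control()) {
  model <- match.arg(model)
  cv <- NULL
  if (is.null(hyperparams)) {
    cv <- sgm_cv(collection, groups, model, grid = grid,
                 grid_size = grid_size, n_folds = n_folds, seed = seed,
                 control = control)
    hyperparams <- cv$best
  }
  hp <- function(nm) hyperparams[[nm]] %||% 0
  fit <- sgm_fit(collection, groups, model,
                 lambda1 = hp("lambda1"), lambda2 = hp("lambda2"),
                 lambda = hp("lambda"), control = control)
  S_hat <- gene_statistic(fit$C, groups)
  perm_seed <- as.integer((as.numeric(seed) * 48271 + 11) %% 2147483647L)
  nul <- permutation_null(collection, groups, model,
                          lambda1 = hp("lambda1"), lambda2 = hp("lambda2"),
                          lambda = hp("lambda"), B = B, seed = perm_seed,
                          control = control, init = fit$state)
  S_tilde <- (S_hat - nul$null_mean) / ifelse(nul$null_sd == 0, NA_real_,
                                              nul$null_sd)
  p <- if (length(nul$pooled)) empirical_pvalue(S_tilde, nul$pooled,
                                                smooth = smooth)
       else rep(NA_real_, groups$Q)
  if (length(nul$degenerate)) {
    warning(length(nul$degenerate),
            " gene(s) with constant null statistic; p set to 1", call. = FALSE)
    p[is.na(p)] <- 1
  }
  out <- data.frame(gene_id = groups$gene_ids, S_hat = S_hat,
                    S_null_mean = nul$null_mean, S_null_sd = nul$null_sd,
                    S_tilde = S_tilde, p_value = p, row.names = NULL)
  attr(out, "fit") <- fit
  attr(out, "cv") <- cv
  attr(out, "null") <- nul
  attr(out, "B") <- B
  class(out) <- c("sgm_gene_test", "data.frame")
  out
}
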