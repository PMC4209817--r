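#' Sample-size-weighted z-score meta-analysis
#'
#' Baseline comparator: per dataset and feature, a simple-regression score
#' test of the (centered) phenotype on the standardized feature with normal
#' approximation, `z = sqrt(n) * cor(x, y)`; signed z-scores of the same
#' feature are combined across datasets with sample-size weights,
#' `z_comb = sum_j sqrt(n_j) z_j / sqrt(sum_j n_j)`, and a two-sided p-value
#' is taken from the normal distribution. A gene is represented by its most
#' significant feature (min-p, no multiplicity correction inside the gene;
#' this gives the combined p an optimistic bias under the null, which is the
#' conventional usage and is recorded in the output attributes). Features
#' absent from some datasets are combined over the datasets that contain
#' them; with a single dataset the combined z equals the single-study z.
#'
#' @param collection a [study_collection()] (typically restricted to one
#'   level, see [subset_collection()]).
#' @param groups the matching gene index.
#' @return data frame with `gene_id`, `p_value`, `best_feature`, `z`;
#'   attribute `features` holds the feature-level table
#'   (`feature_id`, `gene_id`, `z`, `p_value`, `n_datasets`).
#' @export
meta_analysis <- function(collection, groups) {
  ann <- collection_annotation(collection, groups)
  zs <- list()
  for (i in seq_along(collection$datasets)) {
    ds <- collection$datasets[[i]]
    yc <- ds$Y - mean(ds$Y)
    sy <- sqrt(sum(yc^2))
    z <- if (sy == 0) rep(0, ds$d) else
      sqrt(ds$n) * drop(crossprod(ds$X, yc)) / (sqrt(ds$n - 1) * sy)
    zs[[i]] <- data.frame(feature_id = ds$feature_ids, z = z, n = ds$n,
                          stringsAsFactors = FALSE)
  }
  zt <- do.call(rbind, zs)
  comb <- do.call(rbind, lapply(split(zt, zt$feature_id), function(d) {
    data.frame(feature_id = d$feature_id[1],
               z = sum(sqrt(d$n) * d$z) / sqrt(sum(d$n)),
               n_datasets = nrow(d))
  }))
  comb$p_value <- 2 * stats::pnorm(-abs(comb$z))
  comb$gene_id <- ann$gene_id[match(comb$feature_id, ann$feature_id)]
  genes <- do.call(rbind, lapply(split(comb, comb$gene_id), function(d) {
    at <- which.min(d$p_value)
    data.frame(gene_id = d$gene_id[1], p_value = d$p_value[at],
               best_feature = d$feature_id[at], z = d$z[at])
  }))
  rownames(genes) <- NULL
  genes <- genes[order(genes$gene_id), ]
  attr(genes, "features") <-
    comb[, c("feature_id", "gene_id", "z", "p_value", "n_datasets")]
  attr(genes, "note") <- "min-p gene summary; anti-conservative under the null"
  genes
}

#' ROC curve and AUC from per-gene p-values
#'
#' Sweeps p-value cutoffs: at cutoff `t`, `TPR = #(causal with p <= t)/m` and
#' `FPR = #(non-causal with p <= t)/(Q - m)`. AUC is the trapezoid area under
#' the swept curve with the endpoints (0,0) and (1,1) included. By default the
#' cutoffs are all distinct observed p-values plus 0 and 1 (a superset of any
#' fixed sweep, and invariant to strictly monotone transformations of p).
#'
#' @param p_values numeric vector of per-gene p-values.
#' @param causal logical vector, `TRUE` for causal genes.
#' @param thresholds optional increasing cutoff vector.
#' @return object of class `sgm_roc`: list with `thresholds`, `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_curve <- function(p_values, causal, thresholds = NULL) {
  stopifnot(length(p_values) == length(causal))
  causal <- as.logical(causal)
  if (all(causal) || !any(causal))
    stop("truth labels must contain both causal and non-causal genes")
  if (is.null(thresholds)) thresholds <- sort(unique(c(0, p_values, 1)))
  thresholds <- sort(thresholds)
  tpr <- vapply(thresholds, function(t) mean(p_values[causal] <= t), 0)
  fpr <- vapply(thresholds, function(t) mean(p_values[!causal] <= t), 0)
  xx <- c(0, fpr, 1); yy <- c(0, tpr, 1)
  ord <- order(xx, yy)
  xx <- xx[ord]; yy <- yy[ord]
  auc <- sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc),
            class = "sgm_roc")
}

#' @export
print.sgm_roc <- function(x, ...) {
  cat("sgm_roc:", length(x$thresholds), "cutoffs, AUC =",
      signif(x$auc, 4), "\n")
  invisible(x)
}

#' @keywords internal
parse_method <- function(method) {
  parts <- strsplit(method, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("method must look like '<model>-<subset>', got '", method, "'")
  model <- parts[1]; subset <- parts[2]
  if (!model %in% c("sglasso", "sgridge", "meta"))
    stop("unknown model in method '", method, "'")
  level <- switch(subset, all = NULL, snp = "snp", exp = "expression",
                  stop("unknown subset in method '", method, "'"))
  if (model == "meta" && is.null(level))
    stop("meta-analysis requires a single level ('meta-snp' or 'meta-exp')")
  list(model = model, level = level)
}

#' Per-gene p-values of one method on one simulated collection
#'
#' @param method one of `"sglasso-all"`, `"sglasso-snp"`, `"sglasso-exp"`,
#'   `"sgridge-all"`, `"sgridge-snp"`, `"sgridge-exp"`, `"meta-snp"`,
#'   `"meta-exp"`.
#' @param collection,groups the simulated collection and gene index.
#' @param B permutations for the multitask gene test.
#' @param grid_size per-axis CV grid size for the multitask models.
#' @param n_folds CV folds.
#' @param seed seed for CV folds and permutations.
#' @param control an [sgm_control()].
#' @return named numeric vector of p-values, one per gene.
#' @export
method_pvalues <- function(method, collection, groups, B = 100,
                           grid_size = 5, n_folds = 5, seed = 1,
                           control = sgm_control()) {
  spec <- parse_method(method)
  sub <- subset_collection(collection, groups, spec$level)
  if (spec$model == "meta") {
    res <- meta_analysis(sub$collection, sub$groups)
    stats::setNames(res$p_value, res$gene_id)
  } else {
    res <- run_gene_test(sub$collection, sub$groups, model = spec$model,
                         grid_size = grid_size, n_folds = n_folds,
                         B = B, seed = seed, control = control)
    stats::setNames(res$p_value, res$gene_id)
  }
}

#' Replicated power comparison across effect-size scenarios
#'
#' Replication harness: for every combination of `delta_effect` and
#' `sigma_dynamic`, simulates `replicates` collections, computes per-gene
#' p-values for each requested method, and summarizes detection accuracy as
#' the ROC AUC against the simulated causal-gene truth. Deterministic given
#' `seed` (each scenario/replicate gets a derived sub-seed).
#'
#' @param scenario base [sim_scenario()]; its `delta_effect`/`sigma_dynamic`
#'   are overridden by the grids.
#' @param deltas vector of effect-scaling factors (default the full
#'   `0, 0.2, ..., 1.0` sweep).
#' @param sigmas vector of dynamic-effect dispersions (default 0, the
#'   fixed-effect design).
#' @param methods character vector of method tags (see [method_pvalues()]).
#' @param replicates replicates per scenario (default 50).
#' @param B,grid_size,n_folds,control passed to the multitask gene test.
#' @param seed master seed.
#' @return object of class `sgm_comparison`: list with `summary` (data frame:
#'   `delta_effect`, `sigma_dynamic`, `method`, `replicate`, `auc`) and
#'   `pvalues` (long data frame of per-gene p-values with truth labels).
#' @export
run_comparison <- function(scenario = sim_scenario(),
                           deltas = seq(0, 1, by = 0.2), sigmas = 0,
                           methods = c("sglasso-all", "meta-exp"),
                           replicates = 50, B = 100, grid_size = 5,
                           n_folds = 5, seed = 1, control = sgm_control()) {
  rows <- list(); pv <- list(); k <- 0L
  for (sg in sigmas) for (de in deltas) {
    scen <- scenario
    scen$delta_effect <- de
    scen$sigma_dynamic <- sg
    for (r in seq_len(replicates)) {
      k <- k + 1L
      sub_seed <- as.integer((as.numeric(seed) * 100003 + k * 7907) %%
                               2147483647L)
      sim <- build_scenario_collection(scen, seed = sub_seed)
      causal <- sim$truth$gene_ids %in% sim$truth$causal_gene_ids
      for (mth in methods) {
        p <- method_pvalues(mth, sim$collection, sim$groups, B = B,
                            grid_size = grid_size, n_folds = n_folds,
                            seed = sub_seed, control = control)
        p <- p[sim$truth$gene_ids]
        auc <- roc_curve(p, causal)$auc
        rows[[length(rows) + 1L]] <- data.frame(
          delta_effect = de, sigma_dynamic = sg, method = mth,
          replicate = r, auc = auc)
        pv[[length(pv) + 1L]] <- data.frame(
          delta_effect = de, sigma_dynamic = sg, method = mth, replicate = r,
          gene_id = sim$truth$gene_ids, causal = causal, p_value = unname(p))
      }
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 pvalues = do.call(rbind, pv)),
            class = "sgm_comparison")
}

#' @export
print.sgm_comparison <- function(x, ...) {
  agg <- stats::aggregate(auc ~ delta_effect + sigma_dynamic + method,
                          data = x$summary, FUN = mean)
  cat("sgm_comparison: mean AUC by scenario and method\n")
  print(agg, row.names = FALSE)
  invisible(x)
}
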