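#' Log-spaced tuning-parameter grid
#'
#' The default grid of 30 penalty values `10^(0.1*j)`, `j = 1..30`, i.e. from
#' `10^0.1 ~ 1.26` up to `10^3 = 1000`. A smaller `size` keeps the same
#' endpoints with fewer, evenly log-spaced values (useful for desk-scale
#' runs).
#'
#' @param size number of grid values (default 30).
#' @return strictly increasing numeric vector of length `size`.
#' @export
lambda_grid <- function(size = 30) {
  stopifnot(size >= 1)
  if (size == 30) 10^(0.1 * seq_len(30)) else 10^seq(0.1, 3, length.out = size)
}

#' Default hyperparameter grid for a model
#'
#' @param model `"sglasso"` (full cross of `(lambda1, lambda2)`) or
#'   `"sgridge"` (`lambda` only).
#' @param size per-axis grid size; the sparse group lasso grid has `size^2`
#'   rows.
#' @return data frame with columns `lambda1`, `lambda2` or `lambda`.
#' @export
default_grid <- function(model = c("sglasso", "sgridge"), size = 30) {
  model <- match.arg(model)
  v <- lambda_grid(size)
  if (model == "sglasso") expand.grid(lambda1 = v, lambda2 = v)
  else data.frame(lambda = v)
}

#' @keywords internal
dataset_fold_seed <- function(seed, dataset_id) {
  h <- sum(utf8ToInt(dataset_id) * seq_along(utf8ToInt(dataset_id)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' Cross-validation fold plan
#'
#' Assigns every sample of every dataset to one of `n_folds` folds. Subjects
#' are disjoint across studies, so folds are drawn independently within each
#' dataset; the per-dataset assignment is seeded from the master seed and the
#' dataset id (not its position), so the plan is invariant to manifest order.
#'
#' @param collection a [study_collection()].
#' @param n_folds number of folds (default 5).
#' @param seed master seed.
#' @return object of class `cv_plan`: list with `folds` (named list of
#'   per-dataset integer fold assignments), `n_folds`, `seed`.
#' @export
cv_plan <- function(collection, n_folds = 5, seed = 1) {
  small <- vapply(collection$datasets, `[[`, 0L, "n") < n_folds
  if (any(small))
    stop("dataset(s) smaller than n_folds (",
         paste(names(collection$datasets)[small], collapse = ", "),
         "); use fewer folds")
  folds <- lapply(collection$datasets, function(ds) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(dataset_fold_seed(seed, ds$dataset_id))
    sample(rep_len(seq_len(n_folds), ds$n))
  })
  structure(list(folds = folds, n_folds = n_folds, seed = seed),
            class = "cv_plan")
}

#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

#' @keywords internal
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cross-validated hyperparameter selection
#'
#' K-fold cross validation over a penalty grid. In each fold the training
#' samples of every dataset are re-standardized (the training-fold centering
#' and scaling are reapplied to the held-out fold, as is the training-fold
#' phenotype mean), the model is fitted with warm starts along the grid, and
#' the held-out error is the task-weighted, per-sample-normalized sum of
#' squared errors `sum_i omega_i delta_i SSE_i / n_held_i`, averaged over
#' folds. Ties are broken toward larger penalties (sparser models).
#'
#' @param collection a [study_collection()].
#' @param groups the matching gene index.
#' @param model `"sglasso"` or `"sgridge"`.
#' @param grid data frame of hyperparameter combinations
#'   (columns `lambda1`, `lambda2` or `lambda`); defaults to
#'   [default_grid()] with `grid_size` values per axis.
#' @param grid_size per-axis size of the default grid (default 30, the full
#'   30 x 30 search for the sparse group lasso).
#' @param n_folds number of CV folds (default 5).
#' @param seed seed for the fold plan.
#' @param control an [sgm_control()] used for every fold fit.
#' @return object of class `sgm_cv`: list with `best` (named list of selected
#'   penalties), `surface` (grid + `cv_error`), `plan`, `model`.
#' @export
sgm_cv <- function(collection, groups, model = c("sglasso", "sgridge"),
                   grid = NULL, grid_size = 30, n_folds = 5, seed = 1,
                   control = sgm_control()) {
  model <- match.arg(model)
  if (is.null(grid)) grid <- default_grid(model, grid_size)
  grid <- as.data.frame(grid)
  if (model == "sglasso") {
    stopifnot(all(c("lambda1", "lambda2") %in% names(grid)))
    grid <- grid[order(grid$lambda1, grid$lambda2), , drop = FALSE]
  } else {
    stopifnot("lambda" %in% names(grid))
    grid <- grid[order(grid$lambda), , drop = FALSE]
  }
  rownames(grid) <- NULL
  plan <- cv_plan(collection, n_folds, seed)
  err <- numeric(nrow(grid))
  for (f in seq_len(n_folds)) {
    fold <- prepare_fold(collection, groups, plan, f)
    state <- NULL
    for (r in seq_len(nrow(grid))) {
      fit <- if (model == "sglasso")
        fit_problem(fold$prob, groups, model,
                    lambda1 = grid$lambda1[r], lambda2 = grid$lambda2[r],
                    control = control, init = state)
      else
        fit_problem(fold$prob, groups, model, lambda = grid$lambda[r],
                    control = control, init = state)
      state <- fit$state
      err[r] <- err[r] + fold_error(fold, fit$C, collection)
    }
  }
  err <- err / n_folds
  best_at <- max(which(err == min(err)))  # grid sorted ascending: prefer larger penalties
  best <- if (model == "sglasso")
    list(lambda1 = grid$lambda1[best_at], lambda2 = grid$lambda2[best_at])
  else list(lambda = grid$lambda[best_at])
  structure(list(best = best, surface = cbind(grid, cv_error = err),
                 plan = plan, model = model),
            class = "sgm_cv")
}

#' @export
print.sgm_cv <- function(x, ...) {
  cat("sgm_cv (", x$model, "): ", nrow(x$surface), " grid points, ",
      x$plan$n_folds, "-fold\n  best: ",
      paste(names(x$best), signif(unlist(x$best), 4),
            sep = " = ", collapse = ", "),
      " (cv error ", signif(min(x$surface$cv_error), 6), ")\n", sep = "")
  invisible(x)
}

# Build the training-fold problem and held-out design for fold f.
# Training-fold standardization parameters are reapplied to the held-out
# samples; a column constant within the training fold is centered only
# (scale 1), carrying no training signal.
#' @keywords internal
prepare_fold <- function(collection, groups, plan, f) {
  train <- vector("list", collection$T)
  val <- vector("list", collection$T)
  for (i in seq_along(collection$datasets)) {
    ds <- collection$datasets[[i]]
    fa <- plan$folds[[i]]
    tr <- fa != f
    Xt <- ds$X[tr, , drop = FALSE]
    ctr <- colMeans(Xt)
    scl <- apply(Xt, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    Xt <- sweep(sweep(Xt, 2, ctr), 2, scl, "/")
    Xv <- sweep(sweep(ds$X[!tr, , drop = FALSE], 2, ctr), 2, scl, "/")
    ym <- mean(ds$Y[tr])
    train[[i]] <- omics_dataset(Xt, ds$Y[tr], ds$dataset_id, ds$level,
                                ds$platform, normalize = FALSE)
    val[[i]] <- list(X = Xv, Y = ds$Y[!tr] - ym, n = sum(!tr))
  }
  coll_tr <- study_collection(train)
  # preserve the full-data delta weights so fold error matches training loss
  coll_tr$delta <- collection$delta
  coll_tr$weights <- collection$omega * collection$delta
  list(prob = sgm_problem(coll_tr, groups), val = val)
}

#' @keywords internal
fold_error <- function(fold, C, collection) {
  err <- 0
  for (i in seq_along(fold$val)) {
    v <- fold$val[[i]]
    off <- fold$prob$tasks[[i]]$offset
    Ci <- C[off + seq_len(fold$prob$tasks[[i]]$dim)]
    err <- err + collection$weights[i] * sum((v$Y - drop(v$X %*% Ci))^2) / v$n
  }
  err
}
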