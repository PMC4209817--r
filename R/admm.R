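#' Solver control parameters
#'
#' @param rho0 initial augmented-Lagrangian parameter.
#' @param eps_abs,eps_rel absolute/relative tolerances in the primal/dual
#'   stopping rule.
#' @param max_iter iteration cap; if reached the fit is returned with
#'   `converged = FALSE`.
#' @param adapt_rho adapt `rho` to keep the primal/dual residual ratio inside
#'   `rho_band` (multiplying/dividing by `rho_factor` and rescaling the scaled
#'   multipliers accordingly).
#' @param rho_band,rho_factor residual-ratio band and rescaling factor.
#' @param trace record the objective at every iteration (slower).
#' @return list of class `sgm_control`.
#' @export
sgm_control <- function(rho0 = 1, eps_abs = 1e-6, eps_rel = 1e-4,
                        max_iter = 2000, adapt_rho = TRUE,
                        rho_band = c(0.1, 10), rho_factor = 2, trace = FALSE) {
  stopifnot(rho0 > 0, eps_abs >= 0, eps_rel >= 0, max_iter >= 1,
            length(rho_band) == 2, rho_band[1] < rho_band[2], rho_factor > 1)
  structure(list(rho0 = rho0, eps_abs = eps_abs, eps_rel = eps_rel,
                 max_iter = max_iter, adapt_rho = adapt_rho,
                 rho_band = rho_band, rho_factor = rho_factor, trace = trace),
            class = "sgm_control")
}

# Precomputed per-task factorizations (thin SVD), reused across ADMM
# iterations, across the lambda grid, and across permutation refits.
#' @keywords internal
sgm_problem <- function(collection, groups) {
  stopifnot(inherits(collection, "study_collection"))
  tasks <- lapply(seq_along(collection$datasets), function(i) {
    ds <- collection$datasets[[i]]
    sv <- svd(ds$X)
    Yc <- ds$Y - mean(ds$Y)
    UtY <- drop(crossprod(sv$u, Yc))
    list(U = sv$u, d = sv$d, V = sv$v, dsq = sv$d^2,
         Yc = Yc, UtY = UtY, XtY = drop(sv$v %*% (sv$d * UtY)),
         w = collection$weights[i], n = ds$n, dim = ds$d,
         offset = groups$task_offsets[i])
  })
  list(tasks = tasks, g = groups$stacked, dim = groups$dim)
}

# Swap in new responses (e.g. permuted phenotypes) without refactorizing X.
#' @keywords internal
sgm_problem_set_Y <- function(prob, Ylist) {
  for (i in seq_along(prob$tasks)) {
    Yc <- Ylist[[i]] - mean(Ylist[[i]])
    prob$tasks[[i]]$Yc <- Yc
    prob$tasks[[i]]$UtY <- drop(crossprod(prob$tasks[[i]]$U, Yc))
    prob$tasks[[i]]$XtY <- drop(prob$tasks[[i]]$V %*%
                                  (prob$tasks[[i]]$d * prob$tasks[[i]]$UtY))
  }
  prob
}

# Per-task analytic coefficient update:
# (2 w X'X + c I) C = 2 w X'Y + rho * S, via the cached SVD.
# c = n_splits * rho, S = sum over splits of (V + D).
#' @keywords internal
c_update_problem <- function(prob, S, rho, n_splits) {
  cI <- n_splits * rho
  C <- numeric(prob$dim)
  for (tk in prob$tasks) {
    b <- 2 * tk$w * tk$XtY + rho * S[tk$offset + seq_len(tk$dim)]
    t1 <- drop(crossprod(tk$V, b))
    C[tk$offset + seq_len(tk$dim)] <-
      b / cI + drop(tk$V %*% ((1 / (2 * tk$w * tk$dsq + cI) - 1 / cI) * t1))
  }
  C
}

#' One analytic coefficient update of the ADMM scheme
#'
#' Solves, independently for every task `i`, the ridge-regularized least
#' squares system `(2 w_i X_i'X_i + s*rho*I) C_i = 2 w_i X_i'Y_i +
#' rho * sum_splits (V + D)_i`, where `s` is the number of splitting variables
#' (2 for sparse group lasso, 1 for group ridge) and `w_i = omega * delta` is
#' the task weight. Solved through a cached thin SVD of each `X_i`.
#'
#' @param collection a [study_collection()].
#' @param groups the matching gene index.
#' @param V1,D1 first splitting variable and scaled multiplier (stacked).
#' @param V2,D2 second pair, or `NULL` for the group-ridge model.
#' @param rho positive augmented-Lagrangian parameter.
#' @return stacked coefficient vector.
#' @export
sgm_c_update <- function(collection, groups, V1, D1, V2 = NULL, D2 = NULL,
                         rho = 1) {
  prob <- sgm_problem(collection, groups)
  if (is.null(V2)) c_update_problem(prob, V1 + D1, rho, 1L)
  else c_update_problem(prob, V1 + D1 + V2 + D2, rho, 2L)
}

#' Primal/dual residual stopping rule
#'
#' Declares convergence when both residuals fall below their tolerances:
#' `res_pri = max_s ||C - V_s||_2`, `res_dual = rho * max_s ||V_s - V_s_old||_2`,
#' `eps_pri = sqrt(p)*eps_abs + eps_rel * max(||C||, ||V_s||)`,
#' `eps_dual = sqrt(p)*eps_abs + eps_rel * rho * max ||D_s||`.
#'
#' @param C current coefficient iterate (stacked).
#' @param Vs list of splitting variables.
#' @param Vs_old their values at the previous iteration.
#' @param Ds list of scaled multipliers.
#' @param rho current augmented-Lagrangian parameter.
#' @param control an [sgm_control()].
#' @return list with `converged`, `res_pri`, `res_dual`, `eps_pri`, `eps_dual`.
#' @export
admm_convergence <- function(C, Vs, Vs_old, Ds, rho, control = sgm_control()) {
  nrm <- function(x) sqrt(sum(x^2))
  res_pri <- max(vapply(Vs, function(V) nrm(C - V), 0))
  res_dual <- rho * max(mapply(function(V, Vo) nrm(V - Vo), Vs, Vs_old))
  p <- length(C)
  eps_pri <- sqrt(p) * control$eps_abs +
    control$eps_rel * max(nrm(C), vapply(Vs, nrm, 0))
  eps_dual <- sqrt(p) * control$eps_abs +
    control$eps_rel * rho * max(vapply(Ds, nrm, 0))
  list(converged = (res_pri <= eps_pri && res_dual <= eps_dual),
       res_pri = res_pri, res_dual = res_dual,
       eps_pri = eps_pri, eps_dual = eps_dual)
}

#' Residual-balancing update of the augmented-Lagrangian parameter
#'
#' Keeps the ratio of primal to dual residual norms inside `control$rho_band`
#' (default \[0.1, 10\]): above the band `rho` is multiplied by
#' `control$rho_factor`, below it divided. The caller must rescale the scaled
#' multipliers by `rho_old/rho_new`.
#'
#' @param rho current value.
#' @param res_pri,res_dual current residual norms.
#' @param control an [sgm_control()].
#' @return the new `rho`.
#' @export
admm_rho_update <- function(rho, res_pri, res_dual, control = sgm_control()) {
  if (!control$adapt_rho || (res_pri == 0 && res_dual == 0)) return(rho)
  ratio <- if (res_dual == 0) Inf else res_pri / res_dual
  if (ratio > control$rho_band[2]) rho * control$rho_factor
  else if (ratio < control$rho_band[1]) rho / control$rho_factor
  else rho
}

#' @keywords internal
problem_loss <- function(prob, C) {
  loss <- 0
  for (tk in prob$tasks) {
    fit <- drop(tk$U %*% (tk$d * drop(crossprod(
      tk$V, C[tk$offset + seq_len(tk$dim)]))))
    loss <- loss + tk$w * sum((tk$Yc - fit)^2)
  }
  loss
}

#' Objective value of the multitask model
#'
#' `sum_i omega_i delta_i ||Yc_i - X_i C_i||^2` plus the penalty of the chosen
#' model (see [penalty_value()]). `Y` is centered per dataset, matching the
#' fitting convention.
#'
#' @inheritParams sgm_fit
#' @param C stacked coefficient vector.
#' @return scalar objective value.
#' @export
sgm_objective <- function(collection, groups, C, model = c("sglasso", "sgridge"),
                          lambda1 = 0, lambda2 = 0, lambda = 0) {
  model <- match.arg(model)
  loss <- 0
  for (i in seq_along(collection$datasets)) {
    ds <- collection$datasets[[i]]
    Ci <- C[groups$task_offsets[i] + seq_len(ds$d)]
    loss <- loss + collection$weights[i] *
      sum((ds$Y - mean(ds$Y) - drop(ds$X %*% Ci))^2)
  }
  loss + penalty_value(C, groups, model, lambda1, lambda2, lambda)
}

#' Fit a sparse group multitask regression model by ADMM
#'
#' Minimizes, over the stacked coefficient vector `C`,
#' `sum_i omega_i delta_i ||Yc_i - X_i C_i||^2 + Phi(C)` with
#' `Phi` either the sparse group lasso penalty
#' (`lambda1 * sum_q ||C_Gq||_2 + lambda2 * ||C||_1`, groups = genes spanning
#' all tasks) or the group ridge penalty (`lambda * sum_q ||C_Gq||_1^2`).
#' The loss and penalty are decoupled by variable splitting (`C = V1`, and
#' `C = V2` for sparse group lasso); the coefficient step is an analytic
#' per-task ridge solve, the splitting steps are the exact proximal operators
#' [prox_group_l2()], [prox_l1()] and [prox_squared_l1_group()], and the
#' scaled multipliers are updated as `D <- D - C + V`. The solver is
#' deterministic.
#'
#' The reported coefficients take their sparsity pattern from the splitting
#' variables (which are exactly sparse): entries where `V1` (and `V2`, for
#' sparse group lasso) are zero are set to exact zeros, so downstream
#' gene-level statistics see genuine zero groups.
#'
#' @param collection a normalized [study_collection()].
#' @param groups the matching [build_gene_index()].
#' @param model `"sglasso"` (sparse group lasso) or `"sgridge"` (group ridge).
#' @param lambda1,lambda2 sparse-group-lasso penalty weights.
#' @param lambda group-ridge penalty weight.
#' @param control an [sgm_control()].
#' @param init optional warm start: list with `V1`, `D1` (and `V2`, `D2`),
#'   `rho`, e.g. the `state` element of a previous fit.
#' @return object of class `sgm_fit`: list with `C` (sparsity-consistent
#'   stacked coefficients), `C_dense` (last analytic update), `V1`, `V2`,
#'   `objective`, `objective_trace`, `converged`, `iterations`, `res_pri`,
#'   `res_dual`, `rho`, `model`, the penalty weights, and `state` (for warm
#'   starts).
#' @export
sgm_fit <- function(collection, groups, model = c("sglasso", "sgridge"),
                    lambda1 = 0, lambda2 = 0, lambda = 0,
                    control = sgm_control(), init = NULL) {
  model <- match.arg(model)
  prob <- sgm_problem(collection, groups)
  fit_problem(prob, groups, model, lambda1, lambda2, lambda, control, init)
}

#' @keywords internal
fit_problem <- function(prob, groups, model, lambda1 = 0, lambda2 = 0,
                        lambda = 0, control = sgm_control(), init = NULL) {
  if (min(lambda1, lambda2, lambda) < 0)
    stop("penalty weights must be non-negative")
  p <- prob$dim
  g <- prob$g
  # exact zero solution (sparse group lasso KKT condition at C = 0): the
  # all-zero vector is optimal iff, per gene, the soft-thresholded loss
  # gradient has l2 norm at most lambda1
  if (model == "sglasso" && (lambda1 > 0 || lambda2 > 0)) {
    grad <- numeric(p)
    for (tk in prob$tasks)
      grad[tk$offset + seq_len(tk$dim)] <- 2 * tk$w * tk$XtY
    st <- prox_l1(grad, lambda2)
    if (all(rowsum(st^2, g) <= lambda1^2 + 1e-300)) {
      zero <- numeric(p)
      obj <- problem_loss(prob, zero)
      return(structure(list(
        C = zero, C_dense = zero, V1 = zero, V2 = zero,
        objective = obj, objective_trace = obj,
        converged = TRUE, iterations = 0L,
        res_pri = 0, res_dual = 0, rho = init$rho %||% control$rho0,
        model = model, lambda1 = lambda1, lambda2 = lambda2, lambda = lambda,
        state = list(V1 = zero, D1 = zero, V2 = zero, D2 = zero,
                     rho = init$rho %||% control$rho0)),
        class = "sgm_fit"))
    }
  }
  sglasso <- model == "sglasso"
  rho <- init$rho %||% control$rho0
  V1 <- init$V1 %||% numeric(p); D1 <- init$D1 %||% numeric(p)
  V2 <- if (sglasso) init$V2 %||% numeric(p) else NULL
  D2 <- if (sglasso) init$D2 %||% numeric(p) else NULL
  trace <- if (control$trace) numeric(control$max_iter) else NULL
  converged <- FALSE
  res <- list(res_pri = NA_real_, res_dual = NA_real_)
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    S <- if (sglasso) V1 + D1 + V2 + D2 else V1 + D1
    C <- c_update_problem(prob, S, rho, if (sglasso) 2L else 1L)
    V1_old <- V1
    V1 <- if (sglasso) prox_group_l2(C - D1, g, lambda1 / rho)
          else prox_squared_l1_group(C - D1, g, lambda, rho)
    D1 <- D1 - C + V1
    if (sglasso) {
      V2_old <- V2
      V2 <- prox_l1(C - D2, lambda2 / rho)
      D2 <- D2 - C + V2
    }
    if (!all(is.finite(C)))
      stop("non-finite values in ADMM iterate at iteration ", it)
    # inline residual/tolerance computation (same rule as admm_convergence)
    r1 <- sqrt(sum((C - V1)^2)); s1 <- sqrt(sum((V1 - V1_old)^2))
    nV <- sqrt(sum(V1^2)); nD <- sqrt(sum(D1^2))
    if (sglasso) {
      r1 <- max(r1, sqrt(sum((C - V2)^2)))
      s1 <- max(s1, sqrt(sum((V2 - V2_old)^2)))
      nV <- max(nV, sqrt(sum(V2^2)))
      nD <- max(nD, sqrt(sum(D2^2)))
    }
    sq <- sqrt(p)
    res <- list(
      res_pri = r1, res_dual = rho * s1,
      eps_pri = sq * control$eps_abs +
        control$eps_rel * max(sqrt(sum(C^2)), nV),
      eps_dual = sq * control$eps_abs + control$eps_rel * rho * nD)
    res$converged <- res$res_pri <= res$eps_pri &&
      res$res_dual <= res$eps_dual
    if (control$trace)
      trace[it] <- problem_loss(prob, C) +
        penalty_value(C, g, model, lambda1, lambda2, lambda)
    if (res$converged) { converged <- TRUE; break }
    rho_new <- admm_rho_update(rho, res$res_pri, res$res_dual, control)
    if (rho_new != rho) {
      scale <- rho / rho_new
      D1 <- D1 * scale
      if (sglasso) D2 <- D2 * scale
      rho <- rho_new
    }
  }
  mask <- if (sglasso) (V1 != 0) & (V2 != 0) else V1 != 0
  C_hat <- ifelse(mask, C, 0)
  obj <- problem_loss(prob, C_hat) +
    penalty_value(C_hat, g, model, lambda1, lambda2, lambda)
  structure(list(
    C = C_hat, C_dense = C, V1 = V1, V2 = V2,
    objective = obj,
    objective_trace = if (control$trace) trace[seq_len(it)] else obj,
    converged = converged, iterations = it,
    res_pri = res$res_pri, res_dual = res$res_dual, rho = rho,
    model = model, lambda1 = lambda1, lambda2 = lambda2, lambda = lambda,
    state = list(V1 = V1, D1 = D1, V2 = V2, D2 = D2, rho = rho)),
    class = "sgm_fit")
}

#' @export
print.sgm_fit <- function(x, ...) {
  cat("sgm_fit (", x$model, "): ", sum(x$C != 0), "/", length(x$C),
      " nonzero coefficients, objective ", format(x$objective),
      ", ", x$iterations, " iterations (",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  invisible(x)
}
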