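tight <- sgm_control(eps_abs = 1e-9, eps_rel = 1e-8, max_iter = 10000)

test_that("coefficient update solves the per-task normal equations", {
  rc <- rand_collection(seed = 11, Tn = 3)
  D <- rc$groups$dim
  set.seed(1)
  V1 <- rnorm(D); D1 <- rnorm(D); V2 <- rnorm(D); D2 <- rnorm(D)
  rho <- 1.7
  C <- sgm_c_update(rc$collection, rc$groups, V1, D1, V2, D2, rho)
  # brute-force dense solve, task by task
  for (i in seq_along(rc$collection$datasets)) {
    ds <- rc$collection$datasets[[i]]
    idx <- rc$groups$task_offsets[i] + seq_len(ds$d)
    w <- rc$collection$weights[i]
    A <- 2 * w * crossprod(ds$X) + 2 * rho * diag(ds$d)
    b <- 2 * w * crossprod(ds$X, ds$Y - mean(ds$Y)) +
      rho * (V1[idx] + D1[idx] + V2[idx] + D2[idx])
    expect_lt(max(abs(C[idx] - solve(A, b))), 1e-10)
  }
  # single-split (group ridge) variant
  C1 <- sgm_c_update(rc$collection, rc$groups, V1, D1, rho = rho)
  ds <- rc$collection$datasets[[1]]
  idx <- rc$groups$task_offsets[1] + seq_len(ds$d)
  w <- rc$collection$weights[1]
  A <- 2 * w * crossprod(ds$X) + rho * diag(ds$d)
  b <- 2 * w * crossprod(ds$X, ds$Y - mean(ds$Y)) + rho * (V1[idx] + D1[idx])
  expect_lt(max(abs(C1[idx] - solve(A, b))), 1e-10)
})

test_that("penalty-free single-task fit reduces to ordinary least squares", {
  st <- single_task_collection(seed = 12)
  ds <- st$collection$datasets[[1]]
  ols <- solve(crossprod(ds$X), crossprod(ds$X, ds$Y - mean(ds$Y)))
  for (model in c("sglasso", "sgridge")) {
    fit <- sgm_fit(st$collection, st$groups, model, control = tight)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$C - as.vector(ols))), 1e-6)
  }
})

test_that("l1 weight above the gradient bound kills every coefficient", {
  rc <- rand_collection(seed = 13, Tn = 3)
  bound <- 0
  for (i in seq_along(rc$collection$datasets)) {
    ds <- rc$collection$datasets[[i]]
    bound <- max(bound, 2 * rc$collection$weights[i] *
                   max(abs(crossprod(ds$X, ds$Y - mean(ds$Y)))))
  }
  fit <- sgm_fit(rc$collection, rc$groups, "sglasso",
                 lambda1 = 0, lambda2 = bound * 1.01, control = tight)
  expect_identical(unname(fit$C), rep(0, rc$groups$dim))
})

test_that("ADMM objective matches an independent convex minimizer on small problems", {
  for (s in 1:3) {
    rc <- rand_collection(seed = 20 + s, Tn = 3, Q = 6)
    for (model in c("sglasso", "sgridge")) {
      l1 <- runif(1, 0.2, 1.5); l2 <- runif(1, 0.1, 0.8)
      lam <- runif(1, 0.1, 0.8)
      fit <- sgm_fit(rc$collection, rc$groups, model, lambda1 = l1,
                     lambda2 = l2, lambda = lam, control = tight)
      C_or <- oracle_solver(rc$collection, rc$groups, model, l1, l2, lam)
      obj_fit <- oracle_objective(rc$collection, rc$groups, fit$C, model,
                                  l1, l2, lam)
      obj_or <- oracle_objective(rc$collection, rc$groups, C_or, model,
                                 l1, l2, lam)
      expect_lt(abs(obj_fit - obj_or) / abs(obj_or), 1e-4)
    }
  }
})

test_that("the solution is insensitive to the initial rho", {
  rc <- rand_collection(seed = 31, Tn = 3)
  objs <- sapply(c(0.1, 1, 10), function(r0)
    sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 0.8, lambda2 = 0.4,
            control = sgm_control(rho0 = r0, eps_abs = 1e-9, eps_rel = 1e-8,
                                  max_iter = 10000))$objective)
  expect_lt(diff(range(objs)) / abs(mean(objs)), 1e-4)
})

test_that("large group penalties zero out whole genes exactly", {
  rc <- rand_collection(seed = 32, Tn = 3)
  fit <- sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 20,
                 lambda2 = 0.01, control = tight)
  s <- gene_statistic(fit$C, rc$groups)
  expect_true(any(s == 0))  # entire groups exactly zero
  # support is consistent between V1 and the reported coefficients
  expect_true(all(fit$C[fit$V1 == 0] == 0))
})

test_that("convergence bookkeeping: residuals, flag and tolerances agree", {
  rc <- rand_collection(seed = 33, Tn = 2)
  fit <- sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 1,
                 lambda2 = 0.5)
  expect_true(fit$converged)
  p <- rc$groups$dim
  ctrl <- sgm_control()
  eps_pri <- sqrt(p) * ctrl$eps_abs +
    ctrl$eps_rel * max(sqrt(sum(fit$C_dense^2)), sqrt(sum(fit$V1^2)),
                       sqrt(sum(fit$V2^2)))
  expect_lte(fit$res_pri, eps_pri)
  # C identical to both splits and no movement -> converged immediately
  C <- rnorm(p)
  st <- admm_convergence(C, list(C, C), list(C, C), list(C * 0, C * 0), 1)
  expect_true(st$converged)
  expect_equal(st$res_pri, 0)
  # fresh zero-initialized iterate on a nontrivial problem is not converged
  C2 <- fit$C_dense
  st2 <- admm_convergence(C2, list(C2 * 0), list(C2), list(C2 * 0), 1)
  expect_false(st2$converged)
})

test_that("rho balancing follows the residual-ratio band", {
  ctrl <- sgm_control()
  expect_equal(admm_rho_update(1, 1, 1, ctrl), 1)
  expect_equal(admm_rho_update(1, 50, 1, ctrl), 2)
  expect_equal(admm_rho_update(1, 1, 50, ctrl), 0.5)
  expect_equal(admm_rho_update(2, 9, 1, ctrl), 2)  # inside the band
  expect_equal(admm_rho_update(1, 1, 0, ctrl), 2)  # stalled dual -> increase
  # adaptive and fixed rho land on the same objective
  rc <- rand_collection(seed = 34, Tn = 3)
  adapt <- sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 1,
                   lambda2 = 0.3,
                   control = sgm_control(eps_abs = 1e-9, eps_rel = 1e-8,
                                         max_iter = 10000))
  fixed <- sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 1,
                   lambda2 = 0.3,
                   control = sgm_control(adapt_rho = FALSE, eps_abs = 1e-9,
                                         eps_rel = 1e-8, max_iter = 10000))
  expect_lt(abs(adapt$objective - fixed$objective) /
              abs(fixed$objective), 1e-5)
})

test_that("the all-zero solution appears exactly at the group KKT boundary", {
  for (s in 1:4) {
    rc <- rand_collection(seed = 50 + s, Tn = 3)
    lambda2 <- runif(1, 0.1, 1)
    grad <- numeric(rc$groups$dim)
    for (i in seq_along(rc$collection$datasets)) {
      ds <- rc$collection$datasets[[i]]
      grad[rc$groups$task_offsets[i] + seq_len(ds$d)] <-
        2 * rc$collection$weights[i] *
        as.vector(crossprod(ds$X, ds$Y - mean(ds$Y)))
    }
    st <- sign(grad) * pmax(0, abs(grad) - lambda2)
    boundary <- sqrt(max(rowsum(st^2, rc$groups$stacked)))
    above <- sgm_fit(rc$collection, rc$groups, "sglasso",
                     lambda1 = boundary * 1.001, lambda2 = lambda2,
                     control = tight)
    below <- sgm_fit(rc$collection, rc$groups, "sglasso",
                     lambda1 = boundary * 0.95, lambda2 = lambda2,
                     control = tight)
    expect_identical(unname(above$C), rep(0, rc$groups$dim))
    expect_gt(sum(below$C != 0), 0)
  }
})

test_that("solver is deterministic and reports non-convergence honestly", {
  rc <- rand_collection(seed = 35, Tn = 2)
  f1 <- sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 1, lambda2 = 1)
  f2 <- sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 1, lambda2 = 1)
  expect_identical(f1$C, f2$C)
  f3 <- sgm_fit(rc$collection, rc$groups, "sglasso", lambda1 = 1, lambda2 = 1,
                control = sgm_control(max_iter = 3))
  expect_false(f3$converged)
  expect_equal(f3$iterations, 3)
})
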