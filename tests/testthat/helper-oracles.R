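# Independent numerical minimizers used as oracles. All are generic smooth
# reformulations solved with L-BFGS-B: l1 terms via the positive/negative
# split v = p - q with box constraints, group l2 norms via an
# epsilon-smoothed sqrt. None of them share code with the closed-form prox
# operators or the ADMM path they check.

group_map <- function(g) match(g, sort(unique(g)))

# L-BFGS-B with restarts until the objective stops improving (the smoothed
# group norm can stall the line search near a kink).
polish_optim <- function(par, fn, gr, lower = -Inf) {
  best <- stats::optim(par, fn, gr, method = "L-BFGS-B", lower = lower,
                       control = list(maxit = 10000, factr = 1))
  for (i in 1:8) {
    nxt <- stats::optim(best$par, fn, gr, method = "L-BFGS-B", lower = lower,
                        control = list(maxit = 10000, factr = 1))
    if (best$value - nxt$value < 1e-14) { best <- nxt; break }
    best <- nxt
  }
  best$par
}

oracle_prox_group_l2 <- function(z, g, threshold, eps = 1e-16) {
  gi <- group_map(g)
  fn <- function(v) 0.5 * sum((z - v)^2) +
    threshold * sum(sqrt(rowsum(v^2, gi) + eps))
  gr <- function(v) {
    nrm <- sqrt(rowsum(v^2, gi) + eps)
    (v - z) + threshold * v / nrm[gi]
  }
  polish_optim(z, fn, gr)
}

oracle_prox_l1 <- function(z, threshold) {
  n <- length(z)
  fn <- function(pq) {
    v <- pq[1:n] - pq[-(1:n)]
    0.5 * sum((z - v)^2) + threshold * sum(pq)
  }
  gr <- function(pq) {
    r <- (pq[1:n] - pq[-(1:n)]) - z
    c(r + threshold, -r + threshold)
  }
  res <- polish_optim(c(pmax(z, 0), pmax(-z, 0)), fn, gr, lower = 0)
  res[1:n] - res[-(1:n)]
}

oracle_prox_squared_l1_group <- function(z, g, lambda, rho) {
  n <- length(z)
  gi <- group_map(g)
  lam <- lambda / rho
  fn <- function(pq) {
    p <- pq[1:n]; q <- pq[-(1:n)]
    0.5 * sum((z - p + q)^2) + lam * sum(rowsum(p + q, gi)^2)
  }
  gr <- function(pq) {
    p <- pq[1:n]; q <- pq[-(1:n)]
    r <- (p - q) - z
    s <- 2 * lam * rowsum(p + q, gi)[gi]
    c(r + s, -r + s)
  }
  res <- polish_optim(c(pmax(z, 0), pmax(-z, 0)), fn, gr, lower = 0)
  res[1:n] - res[-(1:n)]
}

# Objective value of the multitask model at C (independent of sgm_objective's
# code path: explicit loops).
oracle_objective <- function(collection, groups, C, model,
                             lambda1 = 0, lambda2 = 0, lambda = 0) {
  loss <- 0
  for (i in seq_along(collection$datasets)) {
    ds <- collection$datasets[[i]]
    Ci <- C[groups$task_offsets[i] + seq_len(ds$d)]
    res <- (ds$Y - mean(ds$Y)) - as.vector(ds$X %*% Ci)
    loss <- loss + collection$weights[i] * sum(res^2)
  }
  pen <- 0
  for (q in seq_len(groups$Q)) {
    cg <- C[groups$slices[[q]]]
    pen <- pen + if (model == "sglasso") lambda1 * sqrt(sum(cg^2))
                 else lambda * sum(abs(cg))^2
  }
  if (model == "sglasso") pen <- pen + lambda2 * sum(abs(C))
  loss + pen
}

# Independent minimizer of the full multitask objective (smooth
# reformulation + L-BFGS-B), returning the stacked coefficient vector.
oracle_solver <- function(collection, groups, model,
                          lambda1 = 0, lambda2 = 0, lambda = 0,
                          eps = 1e-16) {
  D <- groups$dim
  g <- groups$stacked
  gi <- group_map(g)
  tasks <- lapply(seq_along(collection$datasets), function(i) {
    ds <- collection$datasets[[i]]
    list(X = ds$X, Yc = ds$Y - mean(ds$Y), w = collection$weights[i],
         idx = groups$task_offsets[i] + seq_len(ds$d))
  })
  fn <- function(pq) {
    C <- pq[1:D] - pq[-(1:D)]
    loss <- 0
    for (tk in tasks)
      loss <- loss + tk$w * sum((tk$Yc - as.vector(tk$X %*% C[tk$idx]))^2)
    pen <- if (model == "sglasso")
      lambda1 * sum(sqrt(rowsum(C^2, gi) + eps)) + lambda2 * sum(pq)
    else lambda * sum(rowsum(pq[1:D] + pq[-(1:D)], gi)^2)
    loss + pen
  }
  gr <- function(pq) {
    C <- pq[1:D] - pq[-(1:D)]
    gl <- numeric(D)
    for (tk in tasks)
      gl[tk$idx] <- gl[tk$idx] +
        2 * tk$w * as.vector(crossprod(tk$X, tk$X %*% C[tk$idx] - tk$Yc))
    if (model == "sglasso") {
      nrm <- sqrt(rowsum(C^2, gi) + eps)
      ggrp <- lambda1 * C / nrm[gi]
      c(gl + ggrp + lambda2, -(gl + ggrp) + lambda2)
    } else {
      s <- 2 * lambda * rowsum(pq[1:D] + pq[-(1:D)], gi)[gi]
      c(gl + s, -gl + s)
    }
  }
  res <- polish_optim(rep(0, 2 * D), fn, gr, lower = 0)
  res[1:D] - res[-(1:D)]
}
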