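test_that("compute_lv returns a unit-variance score aligned with X %*% w", {
  set.seed(2)
  x <- center_scale(matrix(rnorm(30), 30, 1))
  expect_equal(compute_lv(x, 1), drop(x), tolerance = 1e-12)

  X <- center_scale(matrix(rnorm(30 * 4), 30))
  w <- c(1, -2, 0, 3)
  z <- compute_lv(X, w)
  expect_lt(abs(var(z) - 1), 1e-10)
  expect_lt(abs(mean(z)), 1e-12)
  expect_gt(cor(z, drop(X %*% w)), 1 - 1e-12)

  expect_error(compute_lv(X, rep(0, 4)), "degenerate")
})

test_that("estimate_inner fills OLS coefficients then overwrites from responses", {
  n <- 25
  Z <- random_scores(n, 3, seed = 11)
  Theta <- estimate_inner(C3, Z)

  # symmetric pair entries are plain correlations
  expect_equal(Theta[2, 1], cor(Z[, 2], Z[, 1]), tolerance = 1e-12)
  expect_equal(Theta[1, 2], cor(Z[, 1], Z[, 2]), tolerance = 1e-12)
  expect_equal(Theta[3, 1], cor(Z[, 3], Z[, 1]), tolerance = 1e-12)
  expect_equal(Theta[3, 2], cor(Z[, 3], Z[, 2]), tolerance = 1e-12)
  # diagonal zero, no entries outside the relation pattern
  expect_equal(diag(Theta), rep(0, 3))

  # column 3 comes from the two-regressor least squares: independent
  # normal-equations oracle
  Z12 <- Z[, 1:2]
  oracle <- solve(t(Z12) %*% Z12, t(Z12) %*% Z[, 3])
  expect_equal(Theta[1:2, 3], drop(oracle), tolerance = 1e-12)
})

test_that("mutually identical LVs give overwritten correlations of 1", {
  z <- random_scores(20, 1, seed = 3)
  Z <- cbind(z, z)
  Theta <- estimate_inner(C2, Z)
  expect_equal(Theta[1, 2], 1, tolerance = 1e-12)
  expect_equal(Theta[2, 1], 1, tolerance = 1e-12)
})

test_that("reestimate_lvs is the plain linear combination Z Theta", {
  Z <- random_scores(15, 3, seed = 5)
  Theta <- matrix(0, 3, 3); Theta[1, 2] <- 1
  expect_error(reestimate_lvs(Z, matrix(0, 3, 3)), "identically zero")
  Theta[2, 1] <- 0.5; Theta[c(1, 2), 3] <- c(-1, 2)
  Zt <- reestimate_lvs(Z, Theta)
  expect_equal(Zt[, 2], Z[, 1], tolerance = 1e-14)
  # naive summation oracle
  naive <- matrix(0, 15, 3)
  for (q in 1:3) for (m in 1:3) naive[, q] <- naive[, q] + Z[, m] * Theta[m, q]
  expect_lt(max(abs(Zt - naive)), 1e-14)
})

test_that("mode-A update equals per-column simple regression slopes", {
  set.seed(9)
  zt <- rnorm(40); zt <- zt - mean(zt)
  X <- center_scale(matrix(rnorm(40 * 6), 40))
  X[, 2] <- zt / sd(zt)                       # a column equal (up to scale) to zt
  X[, 3] <- X[, 3] - zt * sum(X[, 3] * zt) / sum(zt^2)  # orthogonal column
  raw <- update_weights_modeA(X, zt, normalize = FALSE)
  # independent per-column least-squares oracle
  for (j in 1:6) {
    slope <- unname(coef(lm(X[, j] ~ zt))[2])
    expect_equal(raw[j], slope, tolerance = 1e-10)
  }
  expect_lt(abs(raw[3]), 1e-12)
  w <- update_weights_modeA(X, zt)
  expect_equal(sum(w^2), 1, tolerance = 1e-12)
  expect_gt(w[which.max(abs(w))], 0)
})

test_that("unpenalized symmetric two-block fit attains the first canonical correlation", {
  ds <- toy_pair(n = 30, p1 = 4, p2 = 4, seed = 21)
  fit <- mspls(ds, C2, penalty_enet(0, 0))
  expect_true(fit$converged)
  r_fit <- abs(cor(fit$scores[, 1], fit$scores[, 2]))
  ds_std <- center_scale(ds)
  cc <- cancor(ds_std$blocks[[1]]$values, ds_std$blocks[[2]]$values)
  expect_equal(r_fit, cc$cor[1], tolerance = 1e-6)
})

test_that("one-directional unpenalized fit solves the redundancy-analysis problem", {
  set.seed(31)
  n <- 50
  X1 <- matrix(rnorm(n * 5), n)
  X2 <- X1 %*% matrix(rnorm(5 * 3), 5) + 3 * matrix(rnorm(n * 3), n)
  ds <- multiblock_dataset(omics_block(X1, "expl"), omics_block(X2, "resp"))
  C <- rbind(c(0, 0), c(1, 0))   # block 2 is response for block 1
  fit <- mspls(ds, C, penalty_enet(0, 0))
  of <- fit$of_per_block["resp"]
  # oracle: dominant eigenvalue of S11^{-1} S12 S21 on standardized data
  ds_std <- center_scale(ds)
  S11 <- cov(ds_std$blocks[[1]]$values)
  S12 <- cov(ds_std$blocks[[1]]$values, ds_std$blocks[[2]]$values)
  lam <- max(Re(eigen(solve(S11) %*% S12 %*% t(S12))$values))
  expect_equal(unname(of), lam, tolerance = 1e-6)
})

test_that("fit contract: CRT below tolerance, unit-variance scores, Theta pattern", {
  sim <- toy_sim(seed = 17)
  fit <- mspls(sim$dataset, sim$C, penalty_ust(2))
  expect_true(fit$converged)
  expect_lt(fit$crt_trace[fit$n_iter], 1e-6)
  expect_lt(max(abs(apply(fit$scores, 2, var) - 1)), 1e-10)
  # Theta sparsity pattern mirrors the relation structure
  allowed <- (unclass(sim$C) + t(unclass(sim$C))) > 0
  expect_true(all(fit$theta[!allowed] == 0))
  # entries fed from responses are correlations, hence within [-1, 1]
  for (q in 1:3) {
    r <- which(unclass(sim$C)[, q] == 1)
    if (length(r)) expect_true(all(abs(fit$theta[r, q]) <= 1 + 1e-12))
  }
  expect_lte(fit$n_iter, 100)
})

test_that("compiled and reference iteration paths agree", {
  sim <- toy_sim(seed = 23)
  Xs <- lapply(sim$dataset$blocks, `[[`, "values")
  cinfo <- msplspm:::conn_info(unclass(sim$C), names(sim$dataset$blocks))
  fast <- msplspm:::mspls_core(Xs, cinfo, penalty_ust(1.5), quiet = TRUE)
  slow <- suppressMessages(
    msplspm:::mspls_core(Xs, cinfo, penalty_ust(1.5), quiet = FALSE))
  expect_equal(fast$n_iter, slow$n_iter)
  for (q in 1:3)
    expect_equal(fast$weights[[q]], slow$weights[[q]], tolerance = 1e-12)
  expect_equal(fast$theta, slow$theta, tolerance = 1e-12)
})

test_that("non-convergence is a warning carrying the trace, not an error", {
  sim <- toy_sim(seed = 29)
  expect_warning(fit <- mspls(sim$dataset, sim$C, penalty_ust(2), max_iter = 2L),
                 "did not converge")
  expect_false(fit$converged)
  expect_equal(length(fit$crt_trace), 2L)
  expect_true(all(is.finite(fit$crt_trace)))
})

test_that("unpenalized mode-B update is refused in high dimension", {
  sim <- toy_sim(n = 10, p = c(20, 20, 5), k = c(3, 3, 2), seed = 5)
  expect_error(mspls(sim$dataset, sim$C, penalty_enet(0, 0)), "p > n")
})
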