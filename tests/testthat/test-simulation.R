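test_that("the covariance recipe builds, reports, and repairs as specified", {
  cfg <- simulation_config(n = 20, p = c(40, 40, 10), k = c(10, 10, 5))
  bs <- msplspm:::with_seed(50, build_sigma(cfg))
  expect_equal(dim(bs$sigma), c(80, 80))
  # cross-block sub-block before repair averages near the nominal level
  expect_gt(bs$report$mean_cross_before, 0.2)
  expect_lt(bs$report$mean_cross_before, 0.4)
  # the nominal matrix is genuinely indefinite with a 10x10 block of ~0.3
  expect_lt(bs$report$min_eig_before, 0)
  # repaired matrix is PSD by an independent eigendecomposition
  ev <- eigen(bs$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # repair weakens the cross-correlation; the report says by how much
  expect_lt(bs$report$mean_cross_cor_after, bs$report$mean_cross_before)

  # zero cross-block: identity, repair is a no-op
  cfg0 <- simulation_config(n = 20, p = c(40, 40, 10), k = c(10, 10, 5),
                            h_mean = 0, h_sd = 0)
  bs0 <- build_sigma(cfg0)
  expect_equal(bs0$sigma, diag(80))
  expect_equal(bs0$report$min_eig_before, 1)
  expect_equal(bs0$report$clipped, 0L)
})

test_that("simulated datasets have the documented shape and ground truth", {
  cfg <- simulation_config(n = 30, p = c(50, 40, 12), k = c(5, 4, 3))
  sim <- simulate_dataset(cfg, seed = 60)
  dims <- sapply(sim$dataset$blocks, function(b) dim(b$values))
  expect_equal(unname(dims), rbind(c(30, 30, 30), c(50, 40, 12)))
  expect_equal(sim$truth, list(X1 = 1:5, X2 = 1:4, X3 = 1:3))
  expect_true(msplspm:::is_standardized(sim$dataset))
  expect_lt(max(abs(colMeans(sim$dataset$blocks$X1$values))), 1e-12)
  # connectivity encodes the symmetric X1-X2 pair with terminal X3
  expect_equal(unclass(sim$C)[, 3], c(0, 0, 0))
  expect_equal(unclass(sim$C)[3, ], c(1, 1, 0))
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n = 25, p = c(30, 30, 10), k = c(4, 4, 3))
  s1 <- simulate_dataset(cfg, seed = 123)
  s2 <- simulate_dataset(cfg, seed = 123)
  for (q in 1:3)
    expect_identical(s1$dataset$blocks[[q]]$values,
                     s2$dataset$blocks[[q]]$values)
  s3 <- simulate_dataset(cfg, seed = 124)
  expect_false(identical(s1$dataset$blocks[[1]]$values,
                         s3$dataset$blocks[[1]]$values))
})

test_that("achieved cross-correlations match the repaired covariance at large n", {
  cfg <- simulation_config(n = 4000, p = c(60, 60, 10), k = c(10, 10, 3))
  sim <- simulate_dataset(cfg, seed = 70)
  emp <- mean(cor(sim$dataset$blocks$X1$values[, 1:10],
                  sim$dataset$blocks$X2$values[, 1:10]))
  expect_lt(abs(emp - sim$sigma_report$mean_cross_cor_after), 0.05)
})

test_that("recovery rates count selections exactly as defined", {
  w <- numeric(1000)
  w[c(1:7, sample(11:1000, 93))] <- rnorm(100)   # 7 true + 93 false positives
  expect_equal(tpr(w, 1:10), 7 / min(10, 100))
  expect_equal(tnr(w, 1:10), (990 - 93) / 990)
  # perfect recovery
  w2 <- numeric(50); w2[1:5] <- 1
  expect_equal(tpr(w2, 1:5), 1)
  expect_equal(tnr(w2, 1:5), 1)
  # degenerate all-zero model
  expect_equal(tpr(numeric(20), 1:4), 0)
  expect_equal(tnr(numeric(20), 1:4), 1)
  # fewer selections than k: denominator is the selection count
  w3 <- numeric(20); w3[1:2] <- 1
  expect_equal(tpr(w3, 1:4), 1)
})

test_that("replicated studies aggregate and reproduce deterministically", {
  cfg <- simulation_config(n = 40, p = c(40, 40, 10), k = c(5, 5, 3))
  st <- suppressWarnings(run_study(cfg, replicates = 1, folds = 5, seed = 81))
  expect_equal(nrow(st$results), 1L)
  expect_equal(st$aggregates["tpr_X1"], c(tpr_X1 = st$results$tpr_X1[1]))
  expect_true(all(st$results[, c("tpr_X1", "tpr_X2", "tnr_X1", "tnr_X2")] >= 0 &
                  st$results[, c("tpr_X1", "tpr_X2", "tnr_X1", "tnr_X2")] <= 1))

  st2 <- suppressWarnings(run_study(cfg, replicates = 3, folds = 5, seed = 82))
  st3 <- suppressWarnings(run_study(cfg, replicates = 3, folds = 5, seed = 82))
  expect_equal(st2$results, st3$results, tolerance = 0)
})

test_that("configurations are validated", {
  expect_error(simulation_config(n = 30, k = c(10, 10, 200)), "k")
  expect_error(simulation_config(n = 30, w_assoc = c(0.7, 0.6, 1)), "w_assoc")
  expect_silent(simulation_config(n = 37, p = c(360000, 18000, 47),
                                  k = c(40, 40, 10)))
})
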