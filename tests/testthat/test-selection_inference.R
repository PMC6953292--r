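test_that("objective values equal a brute-force correlation double loop", {
  sim <- toy_sim(n = 30, p = c(6, 6, 4), k = c(2, 2, 2), seed = 2)
  fit <- mspls(sim$dataset, sim$C, penalty_ust(0.5))
  rep_df <- objective_function(fit, sim$C, sim$dataset)

  Z <- fit$scores
  Xs <- lapply(sim$dataset$blocks, `[[`, "values")
  Cm <- unclass(sim$C)
  for (q in 1:3) {
    r <- which(Cm[, q] == 1); e <- which(Cm[q, ] == 1)
    if (length(r)) {
      val <- 0
      for (m in r) val <- val + cor(Z[, m], Z[, q])^2
      expect_equal(rep_df$value[q], val, tolerance = 1e-12)
      expect_equal(rep_df$branch[q], "response")
      expect_lte(rep_df$value[q], length(r))          # analytic bound R_q
    } else {
      val <- 0
      for (i in seq_len(ncol(Xs[[q]]))) for (m in e)
        val <- val + cor(Z[, m], Xs[[q]][, i])^2
      expect_equal(rep_df$value[q], val, tolerance = 1e-12)
      expect_equal(rep_df$branch[q], "terminal")
      expect_lte(rep_df$value[q], ncol(Xs[[q]]) * length(e))  # p_q * M_q
    }
  }
  # same values as recorded on the fit itself
  expect_equal(rep_df$value, unname(fit$of_per_block), tolerance = 1e-12)
})

test_that("cross-validation partitions samples once and is deterministic", {
  sim <- toy_sim(n = 40, seed = 3)
  cv <- cross_validate(sim$dataset, sim$C, grid = c(0.5, 1, 2), folds = 5,
                       seed = 99)
  expect_equal(sort(unique(cv$fold_assign)), 1:5)
  expect_equal(length(cv$fold_assign), 40L)
  expect_true(all(table(cv$fold_assign) == 8))
  expect_true(cv$lambda1 %in% cv$grid)
  expect_equal(cv$lambda1, max(cv$grid[cv$mean_score == max(cv$mean_score)]))

  cv2 <- cross_validate(sim$dataset, sim$C, grid = c(0.5, 1, 2), folds = 5,
                        seed = 99)
  expect_identical(cv$fold_assign, cv2$fold_assign)
  expect_equal(cv$mean_score, cv2$mean_score, tolerance = 0)
  expect_equal(cv$lambda1, cv2$lambda1)

  # a different seed may only change the fold assignment, not the grid
  cv3 <- cross_validate(sim$dataset, sim$C, grid = c(0.5, 1, 2), folds = 5,
                        seed = 100)
  expect_equal(cv3$grid, cv$grid)
})

test_that("single-value grids are chosen trivially and empty grids refused", {
  sim <- toy_sim(n = 30, seed = 4)
  cv <- cross_validate(sim$dataset, sim$C, grid = 1.3, folds = 3, seed = 1)
  expect_equal(cv$lambda1, 1.3)
  expect_error(cross_validate(sim$dataset, sim$C, grid = numeric(0)), "empty")
})

test_that("cross-validation scores are invariant to block order", {
  sim <- toy_sim(n = 30, seed = 12)
  ds <- sim$dataset
  # swap X1 and X2 and permute the connectivity accordingly
  perm <- c(2, 1, 3)
  ds_swap <- multiblock_dataset(ds$blocks[perm])
  C_swap <- connectivity_matrix(unclass(sim$C)[perm, perm])
  cv1 <- cross_validate(ds, sim$C, grid = c(1, 2), folds = 5, seed = 7)
  cv2 <- cross_validate(ds_swap, C_swap, grid = c(1, 2), folds = 5, seed = 7)
  expect_equal(cv1$mean_score, cv2$mean_score, tolerance = 1e-10)
  expect_equal(cv1$lambda1, cv2$lambda1)
})

test_that("permutation p-values respect the (1 + exceedances)/(B + 1) bound", {
  sim <- toy_sim(n = 40, seed = 6)
  pt <- permutation_test(sim$dataset, sim$C, penalty_ust(1), B = 49, seed = 5)
  expect_gte(pt$p_value, 1 / (pt$B + 1))
  expect_lte(pt$p_value, 1)
  expect_equal(length(pt$null), pt$B)
  expect_error(permutation_test(sim$dataset, sim$C, penalty_ust(1), B = 0),
               "at least 1")

  # determinism under a fixed seed
  pt2 <- permutation_test(sim$dataset, sim$C, penalty_ust(1), B = 49, seed = 5)
  expect_equal(pt$null, pt2$null, tolerance = 0)
  expect_equal(pt$p_value, pt2$p_value)
})

test_that("clearly associated data are declared significant", {
  sim <- toy_sim(n = 60, p = c(40, 40, 10), k = c(6, 6, 4), seed = 8)
  cv <- cross_validate(sim$dataset, sim$C, folds = 5, seed = 2)
  pt <- permutation_test(sim$dataset, sim$C, penalty_ust(cv$lambda1),
                         B = 99, seed = 3)
  expect_lte(pt$p_value, 0.05)
})

test_that("bootstrap intervals are ordered, deterministic, and on the OF scale", {
  sim <- toy_sim(n = 40, seed = 10)
  bt <- bootstrap_ci(sim$dataset, sim$C, penalty_ust(1), B = 60, seed = 4)
  expect_lte(bt$ci[1], bt$ci[2])
  expect_true(all(bt$replicates >= 0))
  bt2 <- bootstrap_ci(sim$dataset, sim$C, penalty_ust(1), B = 60, seed = 4)
  expect_equal(bt$replicates, bt2$replicates, tolerance = 0)
  # same-row resampling across blocks preserves association: replicate OFs
  # should concentrate around the observed value rather than near zero
  expect_gt(median(bt$replicates), 0.5 * bt$observed)
})

test_that("the default penalty grid spans dense to empty models", {
  sim <- toy_sim(n = 40, seed = 13)
  grid <- default_lambda_grid(sim$dataset, sim$C, length = 10)
  expect_equal(length(grid), 10L)
  expect_true(all(diff(grid) > 0))
  # smallest value keeps a dense model, largest empties it
  fit_lo <- mspls(sim$dataset, sim$C, penalty_ust(grid[1]))
  expect_gt(sum(fit_lo$weights$X1 != 0), ncol(sim$dataset$blocks$X1$values) / 2)
  expect_error(mspls(sim$dataset, sim$C, penalty_ust(grid[10])), "empty model")
})
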