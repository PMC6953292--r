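# evaluate `code` under `seed` and restore the caller's RNG stream afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# default block whose objective is tracked: the terminal (response-free)
# block when one exists, otherwise the first block with a defined objective
default_of_block <- function(cinfo) {
  terminal <- which(!cinfo$modeB &
                    vapply(cinfo$expl, length, integer(1)) > 0L)
  if (length(terminal)) return(terminal[1L])
  withresp <- which(cinfo$modeB)
  if (length(withresp)) return(withresp[1L])
  stop("no block has a defined objective function")
}

resolve_block <- function(block, cinfo) {
  if (is.null(block)) return(default_of_block(cinfo))
  if (is.character(block)) {
    idx <- match(block, cinfo$names)
    if (is.na(idx)) stop("unknown block: ", block)
    return(idx)
  }
  as.integer(block)
}

#' Model objective function, per block
#'
#' The fitted model's goodness criterion, evaluated per block on the final
#' unit-variance LVs and the original standardized manifest variables. For a
#' block q' *with* response blocks the value is the sum of squared
#' correlations between its LV and each response LV (at most R_q', the number
#' of responses). For a terminal block (no responses) it is the sum over its
#' manifest variables and its explanatory LVs of the squared LV-MV
#' correlations (at most `p_q' * M_q'`). A block with neither responses nor
#' explanatory sources has no defined value (`NA`).
#'
#' @param fit an `mspls_fit`.
#' @param C connectivity matrix used for the fit.
#' @param dataset the `multiblock_dataset` the model was fitted to.
#' @return data.frame with columns `block`, `branch`
#'   (`"response"`/`"terminal"`/`NA`), and `value`.
#' @export
objective_function <- function(fit, C, dataset) {
  C <- connectivity_matrix(unclass(C))
  if (!is_standardized(dataset)) dataset <- center_scale(dataset)
  cinfo <- conn_info(unclass(C), names(dataset$blocks))
  Z <- fit$scores
  vals <- numeric(cinfo$Q)
  branch <- character(cinfo$Q)
  for (q in seq_len(cinfo$Q)) {
    r <- cinfo$resp[[q]]; e <- cinfo$expl[[q]]
    if (length(r)) {
      branch[q] <- "response"
      vals[q] <- sum(drop(stats::cor(Z[, r, drop = FALSE], Z[, q]))^2)
    } else if (length(e)) {
      branch[q] <- "terminal"
      vals[q] <- sum(stats::cor(dataset$blocks[[q]]$values,
                                Z[, e, drop = FALSE])^2)
    } else {
      branch[q] <- NA_character_
      vals[q] <- NA_real_
    }
  }
  data.frame(block = cinfo$names, branch = branch, value = vals,
             stringsAsFactors = FALSE)
}

#' Default penalty grid for cross-validation
#'
#' Heuristic grid of 20 log-spaced `lambda1` values between `0.01 *
#' lambda_max` and `lambda_max`, where `lambda_max = 2 max_j |x_j' zt|` is
#' taken over all penalized blocks at the *converged* unpenalized fit (at
#' that level the soft threshold empties every model). The covariances
#' `x_j' zt` must be measured at convergence: their scale depends on the
#' inner coefficients and is far smaller during the first iterations, so a
#' ceiling read off early would leave the whole sparse regime outside the
#' grid.
#'
#' @param dataset a `multiblock_dataset`.
#' @param C connectivity matrix.
#' @param length number of grid points.
#' @return Increasing numeric vector of `lambda1` values.
#' @export
default_lambda_grid <- function(dataset, C, length = 20L) {
  if (!is_standardized(dataset)) dataset <- center_scale(dataset)
  Xs <- block_matrices(dataset)
  cinfo <- conn_info(unclass(connectivity_matrix(unclass(C))),
                     names(dataset$blocks))
  if (!any(cinfo$modeB)) stop("no penalized block; grid is undefined")
  fit0 <- mspls_core(Xs, cinfo, penalty_ust(0), max_iter = 200L)
  Zt <- fit0$scores %*% fit0$theta
  lam_max <- 0
  for (q in which(cinfo$modeB))
    lam_max <- max(lam_max, 2 * max(abs(crossprod(Xs[[q]], Zt[, q]))))
  exp(seq(log(0.01 * lam_max), log(lam_max), length.out = length))
}

# standardize train/test with training moments; test rows never leak into
# the scaling parameters
scale_train_test <- function(X, test_idx) {
  tr <- X[-test_idx, , drop = FALSE]
  m <- colMeans(tr)
  ctr <- sweep(tr, 2L, m)
  s <- sqrt(colSums(ctr * ctr) / (nrow(tr) - 1))
  if (any(s < 1e-12)) stop("constant column in training fold")
  list(train = sweep(ctr, 2L, s, `/`),
       test = sweep(sweep(X[test_idx, , drop = FALSE], 2L, m), 2L, s, `/`))
}

# held-out objective for one block: project test rows on trained weights,
# then evaluate the relevant branch of the objective on the test fold only
heldout_of <- function(w, Xte, cinfo, block) {
  Zte <- vapply(seq_len(cinfo$Q),
                function(q) drop(Xte[[q]] %*% w[[q]]), numeric(nrow(Xte[[1]])))
  r <- cinfo$resp[[block]]; e <- cinfo$expl[[block]]
  val <- if (length(r)) {
    suppressWarnings(
      sum(drop(stats::cor(Zte[, r, drop = FALSE], Zte[, block]))^2,
          na.rm = TRUE))
  } else {
    suppressWarnings(
      sum(stats::cor(Xte[[block]], Zte[, e, drop = FALSE])^2, na.rm = TRUE))
  }
  val
}

#' Cross-validate the sparsity penalty
#'
#' Samples are partitioned once (seeded) into `folds` folds. For each
#' `lambda1` in the grid the model is fitted on every training set
#' (standardized with training means and standard deviations), test rows are
#' standardized with the *training* parameters and projected onto the fitted
#' weights, and the objective of `of_block` is evaluated on the held-out
#' scores. The `lambda1` maximizing the mean held-out objective is chosen;
#' ties go to the largest (sparsest) value. A `lambda1` that empties a model
#' in some fold scores 0 there — the natural held-out value of a model that
#' captures no correlation — so aggressive grids are safe to include.
#'
#' @param dataset a `multiblock_dataset` (raw or standardized; folds are
#'   always re-standardized from training rows).
#' @param C connectivity matrix.
#' @param grid increasing vector of `lambda1` values; default
#'   [default_lambda_grid()].
#' @param folds number of folds (default 10).
#' @param penalty_kind `"ust"` (default) or `"enet"`.
#' @param lambda2 ridge parameter when `penalty_kind = "enet"`.
#' @param of_block block (name or index) whose objective drives the
#'   selection; default: the terminal block.
#' @param seed seed for the fold assignment (the only randomness here).
#' @param max_iter iteration cap per fold fit.
#' @return Object of class `cv_result`: `grid`, `fold_scores`
#'   (folds x grid), `mean_score`, `lambda1` (chosen), `fold_assign`, `seed`.
#' @export
cross_validate <- function(dataset, C, grid = NULL, folds = 10L,
                           penalty_kind = c("ust", "enet"), lambda2 = 0,
                           of_block = NULL, seed = NULL, max_iter = 200L) {
  penalty_kind <- match.arg(penalty_kind)
  stopifnot(inherits(dataset, "multiblock_dataset"))
  if (folds < 2L) stop("need at least 2 folds")
  n <- dataset$n
  if (n < folds) stop("more folds than samples")
  if (is.null(grid)) grid <- default_lambda_grid(dataset, C)
  if (!length(grid)) stop("empty penalty grid")
  grid <- sort(as.numeric(grid))
  C <- connectivity_matrix(unclass(C))
  cinfo <- conn_info(unclass(C), names(dataset$blocks))
  block <- resolve_block(of_block, cinfo)
  Xraw <- block_matrices(dataset)
  fold_assign <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  fold_scores <- matrix(NA_real_, folds, length(grid))
  for (f in seq_len(folds)) {
    test_idx <- which(fold_assign == f)
    st <- lapply(Xraw, scale_train_test, test_idx = test_idx)
    Xtr <- lapply(st, `[[`, "train")
    Xte <- lapply(st, `[[`, "test")
    w_prev <- NULL
    for (g in seq_along(grid)) {         # smallest lambda first: warm starts
      pen <- if (penalty_kind == "ust") penalty_ust(grid[g])
             else penalty_enet(grid[g], lambda2)
      res <- tryCatch(
        mspls_core(Xtr, cinfo, pen, max_iter = max_iter, w_init = w_prev),
        error = function(e) NULL)
      if (is.null(res)) { fold_scores[f, g] <- 0; next }
      w_prev <- res$weights
      fold_scores[f, g] <- heldout_of(res$weights, Xte, cinfo, block)
    }
  }
  mean_score <- colMeans(fold_scores)
  best <- max(mean_score)
  chosen <- max(grid[mean_score == best])  # tie -> sparsest
  structure(list(grid = grid, fold_scores = fold_scores,
                 mean_score = mean_score, lambda1 = chosen,
                 penalty_kind = penalty_kind, lambda2 = lambda2,
                 of_block = cinfo$names[block], folds = folds,
                 fold_assign = fold_assign, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d-fold CV over %d lambda1 values (%s)\n  chosen lambda1 = %.5g  (mean held-out OF %.4f, block %s)\n",
    x$folds, length(x$grid), x$penalty_kind, x$lambda1,
    max(x$mean_score), x$of_block))
  invisible(x)
}

#' Permutation test of model significance
#'
#' The null distribution of the objective function is generated by refitting
#' the model `B` times on row-permuted data, permuting the sample order of
#' *each block independently*. Permutation destroys the correlation between
#' data sources while leaving each source's internal correlation structure
#' intact. The penalty must be fixed beforehand (typically the CV-chosen
#' one). The p-value is `(1 + #[null >= observed]) / (B + 1)` and is
#' therefore never smaller than `1 / (B + 1)`.
#'
#' @param dataset a `multiblock_dataset`.
#' @param C connectivity matrix.
#' @param penalty fixed [penalty_spec][penalty_enet].
#' @param B number of permutation replicates.
#' @param of_block block whose objective is tested; default: terminal block.
#' @param seed RNG seed.
#' @param max_iter iteration cap per refit. Non-converged refits still
#'   contribute their objective value and are counted in `n_nonconverged`.
#'   A permutation that empties the model under the fixed penalty has
#'   captured no cross-source correlation at all, so it contributes a null
#'   objective of 0 (counted in `n_emptied`); refits failing for any other
#'   reason are dropped and counted in `n_failed`, reducing `B`.
#' @return Object of class `permutation_result`: `observed`, `null`,
#'   `p_value`, `B`, `n_nonconverged`, `n_failed`, `of_block`, `seed`.
#' @export
permutation_test <- function(dataset, C, penalty, B = 1000L, of_block = NULL,
                             seed = NULL, max_iter = 200L) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  if (B < 1L) stop("B must be at least 1")
  if (!is_standardized(dataset)) dataset <- center_scale(dataset)
  C <- connectivity_matrix(unclass(C))
  cinfo <- conn_info(unclass(C), names(dataset$blocks))
  block <- resolve_block(of_block, cinfo)
  Xs <- block_matrices(dataset)
  n <- dataset$n
  # an observed model emptied by the fixed penalty captures no correlation:
  # its objective is 0 and the test will (rightly) not reject
  observed <- tryCatch(
    mspls_core(Xs, cinfo, penalty, max_iter = max_iter)$of_per_block[block],
    error = function(e) {
      if (grepl("empty model", conditionMessage(e))) 0 else stop(e)
    })
  with_seed(seed, {
    null_of <- numeric(B)
    nonconv <- 0L; failed <- 0L; emptied <- 0L
    for (b in seq_len(B)) {
      Xp <- lapply(Xs, function(X) X[sample.int(n), , drop = FALSE])
      res <- tryCatch(mspls_core(Xp, cinfo, penalty, max_iter = max_iter),
                      error = function(e) e)
      if (inherits(res, "error")) {
        # a permutation that empties the model under the fixed penalty has
        # captured no correlation: its null objective is 0
        if (grepl("empty model", conditionMessage(res))) {
          emptied <- emptied + 1L
          null_of[b] <- 0
        } else {
          failed <- failed + 1L
          null_of[b] <- NA
        }
        next
      }
      if (!res$converged) nonconv <- nonconv + 1L
      null_of[b] <- res$of_per_block[block]
    }
    null_of <- null_of[!is.na(null_of)]
    Beff <- length(null_of)
    p <- (1 + sum(null_of >= observed)) / (Beff + 1)
    structure(list(observed = observed, null = null_of, p_value = p,
                   B = Beff, n_nonconverged = nonconv, n_failed = failed,
                   n_emptied = emptied,
                   of_block = cinfo$names[block], seed = seed),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed OF (%s) = %.4f, B = %d, p = %.4g\n",
    x$of_block, x$observed, x$B, x$p_value))
  if (x$n_failed) cat("  failed refits:", x$n_failed, "\n")
  invisible(x)
}

#' Bootstrap confidence interval for the objective function
#'
#' Sample indices are drawn with replacement once per replicate and the
#' *same* index vector is applied to every block, preserving the cross-block
#' correlation structure. Each resample is re-standardized and refitted with
#' the penalty of the original model, and the objective recorded; empirical
#' (inverse-CDF) quantiles of the replicates give the interval.
#'
#' @inheritParams permutation_test
#' @param levels quantile pair, default `c(0.025, 0.975)`.
#' @return Object of class `bootstrap_result`: `replicates`, `ci` (named
#'   quantiles), `observed`, `levels`, `B`, `n_nonconverged`, `n_failed`,
#'   `of_block`, `seed`.
#' @export
bootstrap_ci <- function(dataset, C, penalty, B = 1000L,
                         levels = c(0.025, 0.975), of_block = NULL,
                         seed = NULL, max_iter = 200L) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  if (B < 1L) stop("B must be at least 1")
  stopifnot(length(levels) == 2L, levels[1] <= levels[2])
  C <- connectivity_matrix(unclass(C))
  cinfo <- conn_info(unclass(C), names(dataset$blocks))
  block <- resolve_block(of_block, cinfo)
  Xraw <- block_matrices(dataset)
  ds_std <- if (is_standardized(dataset)) dataset else center_scale(dataset)
  obs_fit <- mspls_core(block_matrices(ds_std), cinfo, penalty,
                        max_iter = max_iter)
  observed <- obs_fit$of_per_block[block]
  n <- dataset$n
  with_seed(seed, {
    reps <- numeric(B)
    nonconv <- 0L; failed <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)   # same rows for every block
      res <- tryCatch({
        Xb <- lapply(Xraw,
                     function(X) center_scale(X[idx, , drop = FALSE]))
        mspls_core(Xb, cinfo, penalty, max_iter = max_iter)
      }, error = function(e) NULL)
      if (is.null(res)) { failed <- failed + 1L; reps[b] <- NA; next }
      if (!res$converged) nonconv <- nonconv + 1L
      reps[b] <- res$of_per_block[block]
    }
    reps <- reps[!is.na(reps)]
    ci <- stats::quantile(reps, probs = levels, type = 1, names = TRUE)
    structure(list(replicates = reps, ci = ci, observed = observed,
                   levels = levels, B = length(reps),
                   n_nonconverged = nonconv, n_failed = failed,
                   of_block = cinfo$names[block], seed = seed),
              class = "bootstrap_result")
  })
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_result> observed OF (%s) = %.4f, B = %d\n  %g%%/%g%% quantiles: [%.4f, %.4f]\n",
    x$of_block, x$observed, x$B, 100 * x$levels[1], 100 * x$levels[2],
    x$ci[1], x$ci[2]))
  invisible(x)
}
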