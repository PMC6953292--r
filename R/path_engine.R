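#' Compute a block's latent variable
#'
#' The latent variable (LV) of a block is the linear combination of its
#' manifest variables with the outer weights, normalized to unit sample
#' variance: `zeta = X w / sd(X w)`. With a standardized `X` the score has
#' mean zero and correlates perfectly with `X w`.
#'
#' @param X standardized block matrix (n x p).
#' @param w weight vector of length p with at least one nonzero entry.
#' @return Numeric vector of length n with mean 0 and unit sample variance.
#' @export
compute_lv <- function(X, w) {
  if (all(w == 0)) stop("degenerate weights: all entries zero")
  z <- drop(X %*% w)
  z <- z - mean(z)
  s <- sqrt(sum(z^2) / (length(z) - 1))
  if (s < 1e-12) stop("X %*% w is constant; cannot normalize")
  z / s
}

# fast path: X assumed centered, so Xw has mean zero already
lv_core <- function(X, w) {
  z <- drop(X %*% w)
  s <- sqrt(sum(z * z) / (length(z) - 1))
  if (s < 1e-12) stop("degenerate latent variable (constant score)")
  z / s
}

# relation structure in index form, derived once per fit
conn_info <- function(C, nms = NULL) {
  Q <- nrow(C)
  expl <- lapply(seq_len(Q), function(q) which(C[q, ] == 1))
  resp <- lapply(seq_len(Q), function(q) which(C[, q] == 1))
  if (is.null(nms)) nms <- paste0("block", seq_len(Q))
  list(Q = Q, expl = expl, resp = resp,
       expl0 = lapply(expl, function(i) i - 1L),   # 0-based, for the C++ path
       resp0 = lapply(resp, function(i) i - 1L),
       modeB = vapply(resp, length, integer(1)) > 0L, names = nms)
}

inner_core <- function(cinfo, Z) {
  Q <- cinfo$Q
  n <- nrow(Z)
  Theta <- matrix(0, Q, Q)
  # Z columns are mean-zero unit-variance, so crossprod(Z)/(n-1) is both the
  # Gram matrix of the regressions and the correlation matrix of the LVs
  G <- crossprod(Z)
  for (q in seq_len(Q)) {        # step (b-i): regression on explanatory LVs
    e <- cinfo$expl[[q]]
    if (length(e)) {
      Theta[e, q] <- tryCatch(
        solve(G[e, e, drop = FALSE], G[e, q]),
        error = function(err)
          stop("collinear latent variables among explanatory sources of ",
               cinfo$names[q], " (", paste(cinfo$names[e], collapse = ", "),
               ")", call. = FALSE))
    }
  }
  for (q in seq_len(Q)) {        # step (b-ii): overwrite with correlations
    r <- cinfo$resp[[q]]
    if (length(r)) Theta[r, q] <- G[r, q] / (n - 1)
  }
  Theta
}

#' Estimate the inner-model coefficient matrix
#'
#' Fills the Q x Q matrix Theta in two passes. First, for every block with
#' explanatory sources, the coefficients feeding it (its column of Theta) are
#' the ordinary multiple-regression coefficients of its LV on the column-bound
#' explanatory LVs. Second, for every block with responses, those incoming
#' coefficients are *overwritten* by the plain correlations between its LV and
#' each response LV (so for a symmetric pair both directions end up as the
#' correlation). Entries not addressed by either pass stay zero; the sparsity
#' pattern of Theta therefore mirrors the connectivity structure exactly.
#'
#' @param C connectivity matrix.
#' @param Z n x Q matrix of column-bound latent variables, each unit variance.
#' @return Q x Q coefficient matrix; `Theta[m, q]` multiplies `Z[, m]` in the
#'   re-estimation of block q's LV.
#' @export
estimate_inner <- function(C, Z) {
  C <- connectivity_matrix(unclass(C))
  if (ncol(Z) != nrow(C)) stop("Z has ", ncol(Z), " columns but C is ",
                               nrow(C), "x", nrow(C))
  if (max(abs(colMeans(Z))) > 1e-8 ||
      max(abs(apply(Z, 2L, stats::var) - 1)) > 1e-6)
    stop("LV columns must be centered with unit sample variance")
  inner_core(conn_info(C, colnames(Z)), Z)
}

#' Re-estimate latent variables from the inner model
#'
#' `Ztilde = Z %*% Theta`: each block's new score is the Theta-weighted sum of
#' its neighbours' LVs. Columns are deliberately *not* re-normalized here;
#' they feed the outer weight updates as-is.
#'
#' @param Z n x Q matrix of latent variables.
#' @param Theta inner coefficient matrix from [estimate_inner()].
#' @return n x Q matrix of re-estimated scores.
#' @export
reestimate_lvs <- function(Z, Theta) {
  Zt <- Z %*% Theta
  zero <- apply(Zt, 2L, function(col) all(col == 0))
  if (any(zero))
    stop("re-estimated LV is identically zero for block(s) ",
         paste(which(zero), collapse = ", "),
         " (block has no relations in the inner model)")
  Zt
}

#' Mode-A outer weight update
#'
#' For blocks without response blocks the outer weights are per-variable
#' simple regression slopes of each manifest variable on the re-estimated LV:
#' `w = X' zt / (zt' zt)`.
#'
#' @param X standardized block matrix.
#' @param zt re-estimated latent variable.
#' @param normalize rescale to unit Euclidean norm and sign-align (the
#'   engine's convention); set `FALSE` to obtain the raw slopes.
#' @return Weight vector of length `ncol(X)`.
#' @export
update_weights_modeA <- function(X, zt, normalize = TRUE) {
  ss <- sum(zt^2)
  if (ss == 0) stop("re-estimated LV is identically zero")
  w <- drop(crossprod(X, zt)) / ss
  if (normalize) normalize_weights(w) else w
}

#' Normalize a weight vector to unit norm with a fixed sign convention
#'
#' Rescales to unit Euclidean norm and flips the sign so that the entry of
#' largest absolute value is positive. Both steps make the convergence
#' criterion invariant to the scale drift and sign flips that penalized
#' updates would otherwise introduce between iterations.
#'
#' @param w numeric weight vector, not all zero.
#' @return Normalized, sign-aligned vector.
#' @export
normalize_weights <- function(w) {
  nrm <- sqrt(sum(w * w))
  if (nrm == 0) stop("cannot normalize an all-zero weight vector")
  w <- w / nrm
  if (w[which.max(abs(w))] < 0) w <- -w
  w
}

# one penalized (mode B) update, dispatching on the penalty kind
penalized_update <- function(X, zt, penalty, q, nm) {
  wq <- tryCatch(switch(penalty$kind,
    ust = ust_update(X, zt, pen_param(penalty$lambda1, q, nm)),
    enet = enet_update(X, zt, pen_param(penalty$lambda1, q, nm),
                       penalty$lambda2),
    cardinality = {
      lam <- suppressWarnings(
        lambda_for_cardinality(X, zt, pen_param(penalty$k_target, q, nm)))
      ust_update(X, zt, lam)
    },
    stop("unknown penalty kind: ", penalty$kind)),
    error = function(e) stop("block '", nm, "': ", conditionMessage(e),
                             call. = FALSE))
  wq
}

# objective function values on final unit-variance LVs (standardized X)
of_core <- function(Xs, cinfo, Z) {
  n <- nrow(Z)
  vapply(seq_len(cinfo$Q), function(q) {
    r <- cinfo$resp[[q]]; e <- cinfo$expl[[q]]
    if (length(r)) {
      sum(drop(stats::cor(Z[, r, drop = FALSE], Z[, q]))^2)
    } else if (length(e)) {
      sum((crossprod(Xs[[q]], Z[, e, drop = FALSE]) / (n - 1))^2)
    } else NA_real_
  }, numeric(1))
}

mspls_core <- function(Xs, cinfo, penalty, gamma = 1e-6, max_iter = 500L,
                       quiet = TRUE, w_init = NULL) {
  Q <- cinfo$Q
  n <- nrow(Xs[[1L]])
  p <- vapply(Xs, ncol, integer(1))
  iso <- !cinfo$modeB & vapply(cinfo$expl, length, integer(1)) == 0L
  if (any(iso))
    stop("block(s) without any relation in the connectivity matrix: ",
         paste(cinfo$names[iso], collapse = ", "))
  # Sparse fits are warm-started from the unpenalized solution: the soft
  # threshold compares lambda1/2 with X' zt, whose scale only settles once
  # the inner model has converged, so thresholding from the flat all-ones
  # start would empty models that are perfectly well-defined at convergence.
  penalizing <- switch(penalty$kind, ust = any(penalty$lambda1 > 0),
                       enet = any(penalty$lambda1 > 0), cardinality = TRUE)
  if (is.null(w_init) && penalizing) {
    # the warm start is only an initialization: a loose tolerance settles
    # the scale of X' zt in a handful of iterations (weak-signal data would
    # otherwise spend hundreds of iterations polishing a start vector)
    w_init <- mspls_core(Xs, cinfo, penalty_ust(0),
                         gamma = max(gamma, 1e-3),
                         max_iter = max_iter, quiet = TRUE)$weights
  }
  if (is.null(w_init))
    w_init <- lapply(p, function(pq) rep(1 / sqrt(pq), pq)) # normalized ones
  if (penalty$kind == "ust" && quiet) {
    # compiled hot path (numerically identical scheme)
    lam <- vapply(seq_len(Q), function(q)
      if (cinfo$modeB[q]) pen_param(penalty$lambda1, q, cinfo$names[q]) else 0,
      numeric(1))
    res <- .ust_engine(Xs, cinfo$expl0, cinfo$resp0,
                       cinfo$modeB, lam, w_init, gamma, as.integer(max_iter))
    res$weights <- lapply(res$weights, as.numeric)
    res$of_per_block <- of_core(Xs, cinfo, res$scores)
    return(res)
  }
  w <- w_init
  Z <- matrix(0, n, Q)
  crt_trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (q in seq_len(Q)) Z[, q] <- lv_core(Xs[[q]], w[[q]])  # step (a)
    Theta <- inner_core(cinfo, Z)                             # step (b)
    Zt <- Z %*% Theta                                         # step (c)
    crt <- 0                                                  # step (d)
    for (q in seq_len(Q)) {
      ztq <- Zt[, q]
      wq <- if (cinfo$modeB[q]) {
        if (penalty$kind == "ust") {  # inline hot path
          cj <- drop(crossprod(Xs[[q]], ztq))
          wj <- soft_threshold(cj, pen_param(penalty$lambda1, q,
                                             cinfo$names[q]) / 2)
          if (all(wj == 0))
            stop("block '", cinfo$names[q],
                 "': lambda1 too large: empty model ",
                 "(all weights thresholded to zero)")
          wj
        } else penalized_update(Xs[[q]], ztq, penalty, q, cinfo$names[q])
      } else {
        ss <- sum(ztq * ztq)
        if (ss == 0) stop("re-estimated LV of ", cinfo$names[q],
                          " is identically zero")
        drop(crossprod(Xs[[q]], ztq)) / ss
      }
      wq <- as.numeric(normalize_weights(wq))
      crt <- crt + sum((wq - w[[q]])^2)                       # step (e)
      w[[q]] <- wq
    }
    crt_trace[it] <- crt
    if (!quiet) message(sprintf("iter %3d  CRT = %.3e", it, crt))
    if (crt < gamma) { converged <- TRUE; break }
  }
  for (q in seq_len(Q)) Z[, q] <- lv_core(Xs[[q]], w[[q]])    # final scores
  Theta <- inner_core(cinfo, Z)
  list(weights = w, scores = Z, theta = Theta,
       of_per_block = of_core(Xs, cinfo, Z),
       n_iter = it, converged = converged,
       crt_trace = crt_trace[seq_len(it)])
}

#' Fit a multiset sparse PLS path model
#'
#' Iterates the estimation scheme until convergence: (a) compute each block's
#' LV from the current outer weights and normalize to unit variance; (b)
#' estimate the inner coefficients Theta (multiple regression on explanatory
#' LVs, then overwrite from responses with correlations); (c) re-estimate the
#' LVs as `Z %*% Theta`; (d) update the outer weights — per-variable
#' regression slopes (mode A) for blocks without responses, penalized
#' multivariate regression (mode B) otherwise; (e) measure the summed squared
#' change of the normalized, sign-aligned weights (CRT) and stop when it
#' falls below `gamma`. Initial weights are the all-ones vector, normalized;
#' the fit is deterministic.
#'
#' @param dataset a `multiblock_dataset`; standardized internally unless all
#'   blocks are already flagged standardized.
#' @param C connectivity matrix (Q x Q binary, zero diagonal): `C[q, q'] = 1`
#'   means block q is a response for block q'.
#' @param penalty a [penalty_spec][penalty_enet] applied to every mode-B
#'   block. The default, Elastic Net with `lambda1 = lambda2 = 0`, is plain
#'   (unpenalized) multivariate regression and is refused for blocks with
#'   more variables than samples.
#' @param gamma convergence tolerance for the CRT (default `1e-6`).
#' @param max_iter iteration cap; non-convergence is returned with a warning,
#'   not an error.
#' @param quiet suppress the per-iteration trace.
#' @return An object of class `mspls_fit` with elements `weights` (named list
#'   of unit-norm outer weight vectors), `scores` (n x Q matrix of final
#'   unit-variance LVs), `theta`, `of_per_block` (objective value per block:
#'   sum of squared LV-LV correlations for blocks with responses, sum of
#'   squared LV-MV correlations for terminal blocks), `modes`, `n_iter`,
#'   `converged`, `crt_trace`, and `penalty`.
#' @examples
#' set.seed(1)
#' X1 <- matrix(rnorm(120), 30); X2 <- X1 %*% matrix(rnorm(16), 4) +
#'   matrix(rnorm(120), 30)
#' ds <- multiblock_dataset(omics_block(X1, "A"), omics_block(X2, "B"))
#' C <- rbind(c(0, 1), c(1, 0))
#' fit <- mspls(ds, C)
#' fit$theta
#' @export
mspls <- function(dataset, C, penalty = penalty_enet(0, 0), gamma = 1e-6,
                  max_iter = 500L, quiet = TRUE) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  if (!inherits(penalty, "penalty_spec")) stop("penalty must be a penalty_spec")
  modes <- validate_connectivity(C, dataset)
  standardized_in <- is_standardized(dataset)
  if (!standardized_in) dataset <- center_scale(dataset)
  Xs <- block_matrices(dataset)
  cinfo <- conn_info(unclass(connectivity_matrix(unclass(C))),
                     names(dataset$blocks))
  res <- mspls_core(Xs, cinfo, penalty, gamma = gamma, max_iter = max_iter,
                    quiet = quiet)
  if (!res$converged)
    warning("msPLS did not converge in ", max_iter,
            " iterations (final CRT = ",
            signif(res$crt_trace[length(res$crt_trace)], 3), ")")
  nms <- names(dataset$blocks)
  names(res$weights) <- nms
  for (q in seq_along(nms))
    names(res$weights[[q]]) <- dataset$blocks[[q]]$variable_ids
  dimnames(res$scores) <- list(dataset$blocks[[1L]]$sample_ids, nms)
  dimnames(res$theta) <- list(nms, nms)
  names(res$of_per_block) <- nms
  res$modes <- modes
  res$penalty <- penalty
  res$gamma <- gamma
  res$standardized_internally <- !standardized_in
  class(res) <- "mspls_fit"
  res
}

#' @export
print.mspls_fit <- function(x, ...) {
  cat(sprintf("<mspls_fit> %d blocks, %s after %d iterations\n",
              ncol(x$scores),
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  nz <- vapply(x$weights, function(w) sum(w != 0), integer(1))
  p <- vapply(x$weights, length, integer(1))
  for (q in seq_along(x$weights))
    cat(sprintf("  %-12s %-24s %5d / %5d nonzero weights   OF = %s\n",
                names(x$weights)[q], x$modes$mode[q], nz[q], p[q],
                ifelse(is.na(x$of_per_block[q]), "-",
                       sprintf("%.4f", x$of_per_block[q]))))
  invisible(x)
}

#' Selected (nonzero-weight) variables of a fitted model
#'
#' @param fit an `mspls_fit`.
#' @param block block name or index.
#' @return Character vector of variable ids with nonzero outer weight.
#' @export
selected_variables <- function(fit, block) {
  w <- fit$weights[[block]]
  names(w)[w != 0]
}
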