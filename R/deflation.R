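#' Residualize a block on a latent variable
#'
#' Removes from every column of `X` its projection on the score vector:
#' `X_res = X - zeta (zeta' zeta)^{-1} zeta' X`. Residual columns are *not*
#' re-standardized — the objective works on correlations, which are
#' scale-free, while explained-variance bookkeeping needs the original-scale
#' column variances. The operation is idempotent and leaves any column
#' already orthogonal to `zeta` untouched.
#'
#' @param X block matrix (n x p).
#' @param zeta score vector of length n (unit variance in normal use).
#' @return Residual matrix of the same dimension, orthogonal to `zeta`.
#' @export
deflate_block <- function(X, zeta) {
  ss <- sum(zeta^2)
  if (ss < 1e-14 || stats::sd(zeta) < 1e-14)
    stop("cannot deflate on a constant score vector")
  X - zeta %*% (crossprod(zeta, X) / ss)
}

#' Fraction of block variance explained by a latent variable
#'
#' Average communality: the mean over columns of the squared correlation
#' between the score and each column. For residual matrices the fraction is
#' relative to the residual variance; [extract_components()] converts it to
#' an original-scale fraction for cumulative reporting. Columns with (near)
#' zero variance — fully absorbed by an earlier component — contribute 0,
#' with a warning.
#'
#' @param X block matrix (standardized, or a residual of a standardized
#'   block).
#' @param zeta score vector of length n.
#' @return Fraction in `[0, 1]`.
#' @export
explained_variance <- function(X, zeta) {
  s <- apply(X, 2L, stats::sd)
  degenerate <- s < 1e-12
  if (any(degenerate))
    warning(sum(degenerate),
            " zero-variance column(s) contribute 0 to explained variance")
  r2 <- numeric(ncol(X))
  if (any(!degenerate))
    r2[!degenerate] <-
      drop(stats::cor(X[, !degenerate, drop = FALSE], zeta))^2
  mean(r2)
}

#' Extract successive orthogonal latent-variable sets
#'
#' Component 1 is a plain fit on the original data. For each further
#' component the blocks flagged in `deflate_mask` are replaced by their
#' residuals after projecting out the current component's score, and the
#' model is refitted; scores of a deflated block are therefore mutually
#' orthogonal across components. By default every block *with* responses is
#' deflated while terminal (response-free) blocks keep their original data,
#' so each round extracts a fresh set of explanatory variables for the same
#' responses; an all-`TRUE` mask deflates everything.
#'
#' Explained variance is tracked per block on the original standardized
#' scale: the cumulative fraction after component `a` is the mean multiple
#' R-squared of the original columns regressed on the first `a` scores
#' (which reduces to the running sum of per-component fractions when scores
#' are orthogonal), so it is non-decreasing and bounded by 1.
#'
#' @param dataset a `multiblock_dataset`.
#' @param C connectivity matrix.
#' @param penalty [penalty_spec][penalty_enet] used for every component.
#' @param n_components number of latent-variable sets to extract.
#' @param deflate_mask logical vector (length Q) marking blocks to
#'   residualize between components; default: blocks with responses.
#' @param gamma,max_iter passed to [mspls()].
#' @return Object of class `mspls_components`: `components` (list of
#'   `mspls_fit`), `explained` (per-component fractions, block x component),
#'   `cumulative` (same shape), `deflate_mask`. Extraction stops early with
#'   a warning if a deflated block runs out of variance.
#' @export
extract_components <- function(dataset, C, penalty = penalty_enet(0, 0),
                               n_components = 2L, deflate_mask = NULL,
                               gamma = 1e-6, max_iter = 500L) {
  stopifnot(inherits(dataset, "multiblock_dataset"), n_components >= 1L)
  if (!is_standardized(dataset)) dataset <- center_scale(dataset)
  C <- connectivity_matrix(unclass(C))
  cinfo <- conn_info(unclass(C), names(dataset$blocks))
  if (is.null(deflate_mask)) deflate_mask <- cinfo$modeB
  stopifnot(length(deflate_mask) == cinfo$Q)
  Q <- cinfo$Q
  nms <- names(dataset$blocks)
  X_orig <- block_matrices(dataset)
  work <- dataset
  components <- vector("list", n_components)
  expl_frac <- matrix(NA_real_, Q, n_components,
                      dimnames = list(nms, paste0("comp", 1:n_components)))
  cum_frac <- expl_frac
  scores <- vector("list", Q)   # accumulated per-block score matrices
  for (a in seq_len(n_components)) {
    fit <- suppressWarnings(mspls(work, C, penalty, gamma = gamma,
                                  max_iter = max_iter))
    components[[a]] <- fit
    for (q in seq_len(Q)) {
      z <- fit$scores[, q]
      scores[[q]] <- cbind(scores[[q]], z)
      # original-scale cumulative fraction: mean multiple R^2 on all scores
      cum_frac[q, a] <- mean_multiple_r2(X_orig[[q]], scores[[q]])
      expl_frac[q, a] <- cum_frac[q, a] - if (a > 1L) cum_frac[q, a - 1L] else 0
    }
    if (a == n_components) break
    # residualize masked blocks for the next round
    stopped <- FALSE
    for (q in which(deflate_mask)) {
      res <- deflate_block(work$blocks[[q]]$values, fit$scores[, q])
      if (max(apply(res, 2L, stats::sd)) < 1e-10) {
        warning("block '", nms[q], "' has no residual variance after ",
                "component ", a, "; returning ", a, " component(s)")
        stopped <- TRUE
        break
      }
      # residuals stay centered; flag them engine-ready so they are not
      # rescaled before the next fit (correlations are scale-free anyway)
      work$blocks[[q]] <- omics_block(
        res, name = nms[q],
        variable_ids = work$blocks[[q]]$variable_ids,
        sample_ids = work$blocks[[q]]$sample_ids,
        standardized = TRUE)
    }
    if (stopped) {
      components <- components[seq_len(a)]
      expl_frac <- expl_frac[, seq_len(a), drop = FALSE]
      cum_frac <- cum_frac[, seq_len(a), drop = FALSE]
      break
    }
  }
  structure(list(components = components, explained = expl_frac,
                 cumulative = cum_frac, deflate_mask = deflate_mask),
            class = "mspls_components")
}

# mean over columns of the multiple R^2 of each column on the score matrix
mean_multiple_r2 <- function(X, S) {
  qrS <- qr(cbind(1, S))
  fitted <- qr.fitted(qrS, X)
  ctr <- scale(X, center = TRUE, scale = FALSE)
  ss_tot <- colSums(ctr^2)
  ss_fit <- colSums(scale(fitted, center = TRUE, scale = FALSE)^2)
  mean(ifelse(ss_tot > 0, pmin(ss_fit / ss_tot, 1), 0))
}

#' @export
print.mspls_components <- function(x, ...) {
  cat(sprintf("<mspls_components> %d component(s)\n", length(x$components)))
  cat("cumulative explained variance (per block):\n")
  print(round(x$cumulative, 3))
  invisible(x)
}
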