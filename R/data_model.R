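#' Construct a data block
#'
#' A block is one data source: a numeric `n x p` matrix of manifest variables
#' (MVs) measured on `n` samples, together with variable and sample
#' identifiers. All blocks entering a model must share the same samples in the
#' same order.
#'
#' @param values numeric matrix, samples in rows, variables in columns.
#' @param name block label used in reports.
#' @param variable_ids,sample_ids character vectors; default to the dimnames of
#'   `values`, or generated identifiers when absent.
#' @param standardized logical; set by [center_scale()], `TRUE` when every
#'   column has mean 0 and unit sample standard deviation.
#' @return An object of class `omics_block`.
#' @export
omics_block <- function(values, name = "X", variable_ids = NULL,
                        sample_ids = NULL, standardized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("block '", name, "': values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("block '", name, "': missing or non-finite entries are not allowed")
  n <- nrow(values); p <- ncol(values)
  if (n < 3L) stop("block '", name, "': need at least 3 samples, got ", n)
  if (p < 1L) stop("block '", name, "': need at least 1 variable")
  if (is.null(variable_ids)) variable_ids <- colnames(values)
  if (is.null(variable_ids)) variable_ids <- paste0(name, "_v", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (length(variable_ids) != p)
    stop("block '", name, "': variable_ids length ", length(variable_ids),
         " does not match ", p, " columns")
  if (length(sample_ids) != n)
    stop("block '", name, "': sample_ids length ", length(sample_ids),
         " does not match ", n, " rows")
  dimnames(values) <- list(sample_ids, variable_ids)
  structure(
    list(name = name, values = values,
         variable_ids = as.character(variable_ids),
         sample_ids = as.character(sample_ids),
         standardized = isTRUE(standardized)),
    class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block '%s'> %d samples x %d variables%s\n",
              x$name, nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' Bundle blocks measured on the same samples
#'
#' @param ... `omics_block` objects (or one list of them). Q >= 2 blocks
#'   sharing identical `sample_ids` in identical order; a mismatch is an
#'   error, never a silent join.
#' @return An object of class `multiblock_dataset`: a list with elements
#'   `blocks` (named list), `n`, and `Q`.
#' @export
multiblock_dataset <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 1L && !inherits(blocks[[1L]], "omics_block"))
    blocks <- blocks[[1L]]
  if (length(blocks) < 2L) stop("need at least two blocks")
  if (!all(vapply(blocks, inherits, logical(1), "omics_block")))
    stop("all elements must be omics_block objects")
  ref <- blocks[[1L]]$sample_ids
  for (b in blocks[-1L]) {
    if (length(b$sample_ids) != length(ref) || any(b$sample_ids != ref)) {
      bad <- if (length(b$sample_ids) != length(ref)) 1L
             else which(b$sample_ids != ref)[1L]
      stop("block '", b$name, "': sample ids differ from block '",
           ref_name <- blocks[[1L]]$name, "' (first discrepancy at position ",
           bad, ")")
    }
  }
  names(blocks) <- vapply(blocks, `[[`, character(1), "name")
  if (anyDuplicated(names(blocks))) stop("block names must be unique")
  structure(list(blocks = blocks, n = length(ref), Q = length(blocks)),
            class = "multiblock_dataset")
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat(sprintf("<multiblock_dataset> %d blocks, %d shared samples\n", x$Q, x$n))
  for (b in x$blocks)
    cat(sprintf("  %-12s %5d variables%s\n", b$name, ncol(b$values),
                if (b$standardized) "  [standardized]" else ""))
  invisible(x)
}

block_matrices <- function(dataset) lapply(dataset$blocks, `[[`, "values")

#' Center and scale a block to zero mean and unit variance
#'
#' Columns are centered to mean 0 and scaled to sample standard deviation 1
#' (denominator `n - 1`). The operation is idempotent; an already standardized
#' input is returned essentially unchanged. Constant columns are a hard error
#' (silently dropping them would shift variable indices and corrupt any
#' selection bookkeeping downstream).
#'
#' @param x an `omics_block`, a `multiblock_dataset`, or a plain numeric
#'   matrix.
#' @param ... unused.
#' @return Object of the same class with standardized values; for blocks the
#'   `standardized` flag is set.
#' @export
center_scale <- function(x, ...) UseMethod("center_scale")

#' @export
center_scale.matrix <- function(x, ...) {
  if (anyNA(x)) stop("missing values are not allowed")
  ctr <- sweep(x, 2L, colMeans(x))
  s <- sqrt(colSums(ctr * ctr) / (nrow(x) - 1))
  if (any(s < 1e-14)) {
    bad <- colnames(x)[which(s < 1e-14)[1L]]
    if (is.null(bad)) bad <- paste0("column ", which(s < 1e-14)[1L])
    stop("constant column cannot be scaled: ", bad)
  }
  sweep(ctr, 2L, s, `/`)
}

#' @export
center_scale.omics_block <- function(x, ...) {
  v <- tryCatch(center_scale(x$values),
                error = function(e) stop("block '", x$name, "': ",
                                         conditionMessage(e), call. = FALSE))
  omics_block(v, name = x$name, variable_ids = x$variable_ids,
              sample_ids = x$sample_ids, standardized = TRUE)
}

#' @export
center_scale.multiblock_dataset <- function(x, ...) {
  x$blocks <- lapply(x$blocks, center_scale)
  x
}

is_standardized <- function(dataset)
  all(vapply(dataset$blocks, `[[`, logical(1), "standardized"))

#' Construct and validate a connectivity matrix
#'
#' The Q x Q binary matrix `C` encodes the hypothesized relations between
#' blocks: `C[q, q'] = 1` means block `q` is a *response* for block `q'`
#' (equivalently, row `q` lists the explanatory sources of block `q`, and
#' column `q'` lists the responses of block `q'`). A symmetric pair
#' `C[q, q'] = C[q', q] = 1` models a CCA-like mutual relation; a one-sided
#' entry models an RDA-like asymmetric relation.
#'
#' @param C square binary matrix with zero diagonal.
#' @return A validated matrix of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("connectivity matrix must be square")
  if (!all(C %in% c(0, 1))) stop("connectivity entries must be 0 or 1")
  if (any(diag(C) != 0)) stop("connectivity diagonal must be zero")
  storage.mode(C) <- "double"
  class(C) <- c("connectivity_matrix", class(C))
  C
}

#' Per-block relation structure and estimation mode
#'
#' Derives, for every block, its explanatory-source set (row support of `C`),
#' its response set (column support), and the outer-estimation mode:
#' `"UNIVARIATE"` (mode A, per-variable regression) for blocks without any
#' response block, `"PENALIZED_MULTIVARIATE"` (mode B, penalized multivariate
#' regression) for blocks with at least one response.
#'
#' @param C connectivity matrix (validated with [connectivity_matrix()]).
#' @param dataset optional `multiblock_dataset`; when given, dimensions must
#'   match and block names are attached.
#' @return data.frame with one row per block: `block`, `mode`, `n_explanatory`
#'   (M_q), `n_response` (R_q), plus list-columns `explanatory` and
#'   `response` holding index vectors.
#' @export
validate_connectivity <- function(C, dataset = NULL) {
  C <- connectivity_matrix(unclass(C))
  Q <- nrow(C)
  nms <- paste0("block", seq_len(Q))
  if (!is.null(dataset)) {
    if (dataset$Q != Q)
      stop("connectivity is ", Q, "x", Q, " but dataset has ",
           dataset$Q, " blocks")
    nms <- names(dataset$blocks)
  }
  expl <- lapply(seq_len(Q), function(q) which(C[q, ] == 1))
  resp <- lapply(seq_len(Q), function(q) which(C[, q] == 1))
  iso <- which(vapply(expl, length, integer(1)) == 0L &
               vapply(resp, length, integer(1)) == 0L)
  if (length(iso))
    warning("isolated block(s) with no relations: ",
            paste(nms[iso], collapse = ", "))
  out <- data.frame(
    block = nms,
    mode = ifelse(vapply(resp, length, integer(1)) > 0L,
                  "PENALIZED_MULTIVARIATE", "UNIVARIATE"),
    n_explanatory = vapply(expl, length, integer(1)),
    n_response = vapply(resp, length, integer(1)),
    stringsAsFactors = FALSE)
  out$explanatory <- expl
  out$response <- resp
  out
}
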