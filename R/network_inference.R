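## Message-passing network inference.
##
## A TF-to-gene edge-weight matrix seeded by the z-scored motif prior is
## iteratively refined by passing messages between a TF-TF interaction
## layer and a gene-gene co-expression layer, using a continuous Tanimoto
## similarity as the message kernel.  The final weights are interpreted as
## edge Z-scores; one-sided upper-tail normal p-values with a
## Benjamini-Hochberg correction (q < 0.05) call significant edges.

#' Gene-gene Pearson co-expression within one condition
#'
#' @param expr An [expression_matrix()].
#' @param condition Condition whose samples are used (`NORM`, `nTNBC`,
#'   `TNBC`).
#' @param genes Rows to correlate; defaults to all rows.
#' @return Symmetric correlation matrix with unit diagonal.  Rows with
#'   zero variance get 0 off-diagonal correlations; their ids are attached
#'   as attribute `zero_variance` and a warning is raised.
#' @export
coexpression <- function(expr, condition, genes = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  cond <- conditions_of(expr)
  samples <- names(cond)[cond == condition]
  stop_if_not(length(samples) >= 3,
              sprintf("need >= 3 samples in condition %s", condition))
  genes <- genes %||% rownames(expr)
  m <- unclass(expr)[genes, samples, drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  flat <- sds == 0
  cc <- suppressWarnings(stats::cor(t(m)))
  if (any(flat)) {
    warning(sprintf("%d zero-variance rows; correlations set to 0",
                    sum(flat)))
    cc[flat, ] <- 0
    cc[, flat] <- 0
  }
  diag(cc) <- 1
  attr(cc, "zero_variance") <- genes[flat]
  cc
}

#' Matrix-wide z-score normalization
#'
#' Centers and scales by the population standard deviation of all entries,
#' so the output has overall mean 0 and standard deviation 1; a constant
#' matrix maps to all zeros.
#'
#' @param m Numeric matrix (finite entries).
#' @return Matrix of the same shape.
#' @export
zscore_normalize <- function(m) {
  stop_if_not(is.numeric(m) && all(is.finite(m)), "matrix must be finite")
  mu <- mean(m)
  s <- sqrt(mean((m - mu)^2))
  if (s == 0) return(m * 0)
  (m - mu) / s
}

#' Continuous Tanimoto similarity between rows of X and columns of Y
#'
#' `T[i,j] = (X[i,] . Y[,j]) / sqrt(|X[i,]|^2 + |Y[,j]|^2 - |X[i,] . Y[,j]|)`.
#' Non-positive squared denominators (degenerate all-zero vectors) give 0.
#'
#' @param X n x k matrix.
#' @param Y k x m matrix.
#' @return n x m similarity matrix.
#' @export
tanimoto <- function(X, Y) {
  stop_if_not(ncol(X) == nrow(Y), "inner dimensions must agree")
  dot <- X %*% Y
  d2 <- outer(rowSums(X^2), colSums(Y^2), "+") - abs(dot)
  out <- matrix(0, nrow(dot), ncol(dot), dimnames = dimnames(dot))
  ok <- d2 > 0
  out[ok] <- dot[ok] / sqrt(d2[ok])
  out
}

## Rate at which the self-affinity diagonal grows per iteration (times
## alpha); larger values freeze the iteration sooner, smaller values give
## the expression layer more refinement rounds.
PANDA_ANNEAL_RATE <- 2

#' Configuration for message-passing inference
#'
#' @param alpha Update rate in `[0, 1]`; 0 leaves the z-scored prior
#'   untouched.  Default 0.25.
#' @param tol Convergence threshold on the mean absolute edge-weight change
#'   per iteration.
#' @param max_iter Iteration cap; hitting it flags, but does not fail, the
#'   run.
#' @return A `panda_config` list.
#' @export
panda_config <- function(alpha = 0.25, tol = 1e-3, max_iter = 200L) {
  stop_if_not(is_scalar_number(alpha) && alpha >= 0 && alpha <= 1,
              "`alpha` must be in [0, 1]")
  stop_if_not(is_scalar_number(tol) && tol > 0, "`tol` must be > 0")
  stop_if_not(is_scalar_number(max_iter) && max_iter >= 0,
              "`max_iter` must be >= 0")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "panda_config")
}

#' Infer a condition-specific TF-gene network by message passing
#'
#' Starting from `W0 = zscore(prior)`, `P0 = zscore(ppi)` and
#' `C0 = zscore(coexpression)`, each iteration computes a responsibility
#' message `R = tanimoto(P, W)` and an availability message
#' `A = tanimoto(W, C)` and updates `W <- (1 - alpha) W + alpha (R + A)/2`;
#' the TF layer `P` and the gene layer `C` are then moved toward the
#' Tanimoto self-similarity of the updated `W` rows and columns.  The
#' self-similarity diagonals are set to
#' `sd(column) * dim * exp(2 * alpha * step)`: the exponentially growing
#' self-affinity progressively damps the messages, which keeps the
#' iteration bounded and anneals `W` to a fixed point on a Z-score scale
#' (without damping, the Tanimoto kernel grows with the norm of its
#' arguments and the iteration diverges).  Iteration stops when the mean
#' absolute change of `W` falls below `tol`.  With `alpha = 0` the update
#' is the identity and the z-scored prior is returned unchanged.
#'
#' @param prior Binary TF x gene motif prior with dimnames.
#' @param ppi Symmetric TF x TF interaction matrix.
#' @param expr An [expression_matrix()] covering the prior's genes.
#' @param condition Which condition's samples feed the co-expression layer.
#' @param cfg A [panda_config()].
#' @param fdr Edge significance threshold on BH-adjusted upper-tail normal
#'   p-values of the final Z-scores.
#' @return A `panda_network`: list with `z`, `pvalues`, `qvalues`,
#'   `significant`, `condition`, `iterations`, `converged` and the
#'   per-iteration convergence trace `h`.
#' @export
panda <- function(prior, ppi, expr, condition, cfg = panda_config(),
                  fdr = 0.05) {
  stopifnot(inherits(cfg, "panda_config"))
  stop_if_not(all(is.finite(prior)) && all(is.finite(ppi)),
              "prior and PPI must be finite")
  tfs <- rownames(prior)
  genes <- colnames(prior)
  stop_if_not(!is.null(tfs) && !is.null(genes), "prior needs dimnames")
  stop_if_not(identical(rownames(ppi), tfs) && identical(colnames(ppi), tfs),
              "PPI ids must match the prior's TFs")
  stop_if_not(all(genes %in% rownames(expr)),
              "expression matrix must cover the prior's genes")

  W <- zscore_normalize(prior)
  P <- zscore_normalize(ppi)
  C <- zscore_normalize(coexpression(expr, condition, genes = genes))

  ## annealed self-affinity: grows with the step count so the messages
  ## fade and the iteration settles
  anneal_diagonal <- function(m, step) {
    d <- `diag<-`(m, NA)
    diag(m) <- apply(d, 2, stats::sd, na.rm = TRUE) * nrow(m) *
      exp(PANDA_ANNEAL_RATE * cfg$alpha * step)
    m
  }

  h_trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  while (cfg$alpha > 0 && iter < cfg$max_iter) {
    R <- tanimoto(P, W)
    A <- tanimoto(W, C)
    W_new <- (1 - cfg$alpha) * W + cfg$alpha * (R + A) / 2
    h <- mean(abs(W_new - W))
    h_trace <- c(h_trace, h)
    W <- W_new

    Tp <- anneal_diagonal(tanimoto(W, t(W)), iter)
    P <- (1 - cfg$alpha) * P + cfg$alpha * Tp
    Tc <- anneal_diagonal(tanimoto(t(W), W), iter)
    C <- (1 - cfg$alpha) * C + cfg$alpha * Tc

    iter <- iter + 1L
    if (h < cfg$tol) { converged <- TRUE; break }
  }
  if (!converged && cfg$max_iter > 0 && cfg$alpha > 0) {
    warning(sprintf("message passing did not converge in %d iterations (h = %.3g)",
                    cfg$max_iter, utils::tail(h_trace, 1)))
  }
  if (cfg$alpha == 0) converged <- TRUE

  p <- stats::pnorm(W, lower.tail = FALSE)
  q <- matrix(stats::p.adjust(p, method = "BH"), nrow(p),
              dimnames = dimnames(p))
  structure(list(
    z = W, pvalues = p, qvalues = q, significant = q < fdr,
    condition = condition, iterations = iter, converged = converged,
    h = h_trace, fdr = fdr
  ), class = "panda_network")
}

#' @export
print.panda_network <- function(x, ...) {
  cat(sprintf("panda_network [%s]: %d TFs x %d genes, %d significant edges (q < %g), %d iterations%s\n",
              x$condition, nrow(x$z), ncol(x$z), sum(x$significant),
              x$fdr, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Significant-edge mask at a given FDR
#'
#' Benjamini-Hochberg over the flattened upper-tail edge p-values.
#'
#' @param net A `panda_network`.
#' @param fdr FDR threshold (default 0.05).
#' @return Logical TF x gene mask.
#' @export
significant_edges <- function(net, fdr = 0.05) {
  stopifnot(inherits(net, "panda_network"))
  q <- matrix(stats::p.adjust(net$pvalues, method = "BH"),
              nrow(net$pvalues), dimnames = dimnames(net$pvalues))
  q < fdr
}

#' Venn overlap of significant edge sets across the three networks
#'
#' @param nets Named list of three `panda_network`s over an identical
#'   TF x gene universe.
#' @return List with `regions` (counts of the 7 Venn regions, names like
#'   `"NORM&TNBC"`), `shared_all` and `shared_fraction` (triple
#'   intersection over the union).
#' @export
network_overlap <- function(nets) {
  stop_if_not(length(nets) == 3, "need exactly three networks")
  masks <- lapply(nets, function(n) {
    stopifnot(inherits(n, "panda_network"))
    n$significant
  })
  dn <- dimnames(masks[[1]])
  for (m in masks) {
    stop_if_not(identical(dimnames(m), dn), "edge universes differ")
  }
  labs <- names(nets) %||% CONDITIONS
  a <- masks[[1]]; b <- masks[[2]]; c <- masks[[3]]
  regions <- c(
    sum(a & !b & !c), sum(!a & b & !c), sum(!a & !b & c),
    sum(a & b & !c), sum(a & !b & c), sum(!a & b & c),
    sum(a & b & c)
  )
  names(regions) <- c(labs[1], labs[2], labs[3],
                      paste(labs[1], labs[2], sep = "&"),
                      paste(labs[1], labs[3], sep = "&"),
                      paste(labs[2], labs[3], sep = "&"),
                      paste(labs, collapse = "&"))
  union_n <- sum(a | b | c)
  list(regions = regions, shared_all = sum(a & b & c),
       shared_fraction = if (union_n == 0) NA_real_ else sum(a & b & c) / union_n)
}
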