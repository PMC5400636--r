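## Signature-based patient stratification and survival analysis.

#' Build the core-module expression signature
#'
#' The signature rows are the core target genes together with their
#' regulators: TFs holding significant TNBC-network edges to strictly more
#' than `t_inter` core targets (the intermediator rule).  Rows are
#' z-normalized across samples; constant rows become all zeros and are
#' flagged.
#'
#' @param core Core gene set: a character vector, a `coreg_module` or an
#'   `extended_core`.
#' @param net The TNBC [panda()] network (used to find regulators); may be
#'   `NULL` when `regulators` is supplied directly.
#' @param expr An [expression_matrix()] containing the signature genes.
#' @param t_inter Strict regulator threshold (default 10).
#' @param regulators Optional explicit regulator set overriding the
#'   network rule.
#' @return A `signature_matrix`: row-normalized genes x samples matrix
#'   with attributes `condition`, `core`, `regulators` and
#'   `constant_rows`.
#' @export
build_signature <- function(core, net, expr, t_inter = 10,
                            regulators = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (inherits(core, "coreg_module")) core <- core$shared_targets
  if (inherits(core, "extended_core")) core <- core$core_targets
  stop_if_not(length(core) > 0, "`core` must be nonempty")
  if (is.null(regulators)) {
    stopifnot(inherits(net, "panda_network"))
    hits <- rowSums(net$significant[, intersect(core, colnames(net$significant)),
                                    drop = FALSE])
    regulators <- rownames(net$significant)[hits > t_inter]
  }
  genes <- union(core, regulators)
  genes <- genes[genes %in% rownames(expr)]
  stop_if_not(length(genes) > 0, "no signature genes present in expression")
  m <- unclass(expr)[genes, , drop = FALSE]
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning(sprintf("%d constant signature rows set to zero", sum(constant)))
  }
  z <- (m - rowMeans(m)) / ifelse(sds == 0, 1, sds)
  z[constant, ] <- 0
  structure(z, condition = conditions_of(expr),
            core = intersect(core, genes), regulators = regulators,
            constant_rows = rownames(m)[constant],
            class = c("signature_matrix", "matrix"))
}

#' k-means clustering of samples on the signature
#'
#' Runs [stats::kmeans()] on the sample (column) profiles with 20 random
#' restarts under a fixed seed, so results are reproducible.
#'
#' @param sig A [build_signature()] matrix.
#' @param k Number of clusters (k <= number of samples).
#' @param seed RNG seed for the restarts.
#' @return List with `cluster` (named sample labels) and `centers`.
#' @export
kmeans_cluster <- function(sig, k, seed = 1L) {
  stopifnot(inherits(sig, "signature_matrix") || is.matrix(sig))
  stop_if_not(k >= 1 && k <= ncol(sig),
              "`k` must lie between 1 and the number of samples")
  x <- t(unclass(sig))
  if (k == nrow(x)) {
    # every sample is its own cluster; within-cluster SS is zero
    return(list(cluster = stats::setNames(seq_len(nrow(x)), colnames(sig)),
                centers = x, tot_withinss = 0))
  }
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = 20))
  list(cluster = stats::setNames(km$cluster, colnames(sig)),
       centers = km$centers, tot_withinss = km$tot.withinss)
}

#' Split nTNBC samples into TNBC-like and other
#'
#' k = 2 k-means on the nTNBC signature profiles; the cluster whose
#' centroid lies closer (Euclidean) to the mean TNBC profile is labeled
#' `TNBC-like`.  An exact tie labels every nTNBC sample `TNBC-like`.
#' By default the similarity is measured on the core-target rows only:
#' the core targets carry the pattern whose resemblance defines the
#' subgroup, whereas regulator rows -- flat across conditions by the
#' activation model -- contribute only row-normalized noise that can
#' dominate the within-nTNBC variance and mask the split.
#'
#' @param sig A [build_signature()] matrix carrying condition labels.
#' @param seed RNG seed for the k-means restarts.
#' @param core_only Cluster on the core-target rows only (default); set
#'   `FALSE` to use the full signature including regulator rows.
#' @return Named character vector over the nTNBC samples with values
#'   `TNBC-like` / `other`.
#' @export
tnbc_like_split <- function(sig, seed = 1L, core_only = TRUE) {
  cond <- attr(sig, "condition")
  stop_if_not(!is.null(cond), "signature lacks condition labels")
  nt <- names(cond)[cond == "nTNBC"]
  stop_if_not(sum(cond == "TNBC") >= 1, "no TNBC samples present")
  stop_if_not(length(nt) >= 2, "need >= 2 nTNBC samples")
  rows <- if (core_only && length(attr(sig, "core"))) {
    attr(sig, "core")
  } else {
    rownames(sig)
  }
  m <- unclass(sig)[rows, , drop = FALSE]
  tnbc_centroid <- rowMeans(m[, cond == "TNBC", drop = FALSE])
  pts <- t(m[, nt, drop = FALSE])
  if (nrow(unique(pts)) < 2) {
    # indistinguishable profiles: degenerate tie, everything TNBC-like
    return(stats::setNames(rep("TNBC-like", length(nt)), nt))
  }
  km <- with_seed(seed, stats::kmeans(pts, centers = 2, nstart = 20))
  d <- apply(km$centers, 1, function(ct) sqrt(sum((ct - tnbc_centroid)^2)))
  like_cluster <- if (d[1] == d[2]) c(1L, 2L) else which.min(d)
  out <- ifelse(km$cluster %in% like_cluster, "TNBC-like", "other")
  stats::setNames(out, nt)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator via [survival::survfit()]; right-continuous,
#' starts at `S(0) = 1`; censored times reduce the risk set only.
#'
#' @param records `data.frame` with `time` (>= 0) and `event` (1 = event,
#'   0 = censored) columns.
#' @return `data.frame(time, n_risk, n_event, surv)` including the
#'   `time = 0, surv = 1` anchor.
#' @export
km_curve <- function(records) {
  stop_if_not(nrow(records) > 0, "no survival records")
  stop_if_not(all(records$time >= 0), "negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = c(0, fit$time), n_risk = c(fit$n, fit$n.risk),
             n_event = c(0, fit$n.event), surv = c(1, fit$surv))
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square with (number of groups - 1) degrees of
#' freedom via [survival::survdiff()].  With no events at all the test is
#' undefined; `p = 1` is returned with a warning.
#'
#' @param records `data.frame` with `time`, `event` and `group` columns
#'   (>= 2 groups).
#' @return List with `chi2`, `df` and `p`.
#' @export
logrank <- function(records) {
  stop_if_not(length(unique(records$group)) >= 2, "need >= 2 groups")
  stop_if_not(all(records$time >= 0), "negative survival time")
  if (sum(records$event) == 0) {
    warning("no events in any group; log-rank p set to 1")
    return(list(chi2 = 0, df = length(unique(records$group)) - 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Pearson correlation test
#'
#' Two-sided p-value from `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom; [corr_pvalue()] exposes the same computation for a
#' correlation coefficient given directly (as printed in a report).
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return `corr_test`: list with `r`, `n`, `p`.
#' @export
corr_test <- function(x, y) {
  stop_if_not(length(x) == length(y) && length(x) >= 3,
              "need equal-length vectors with n >= 3")
  stop_if_not(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for zero-variance input")
  r <- stats::cor(x, y)
  list(r = r, n = length(x), p = corr_pvalue(r, length(x)))
}

#' @rdname corr_test
#' @param r Pearson correlation coefficient.
#' @param n Number of paired observations.
#' @export
corr_pvalue <- function(r, n) {
  stop_if_not(is_scalar_number(r) && abs(r) <= 1, "`r` must lie in [-1, 1]")
  stop_if_not(is_scalar_number(n) && n >= 3, "`n` must be >= 3")
  if (abs(r) == 1) return(0)  # degenerate perfect correlation
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}
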