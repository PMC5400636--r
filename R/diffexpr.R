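## Pairwise differential expression among the three conditions.

#' Benjamini-Hochberg adjustment with input validation
#'
#' Thin wrapper over [stats::p.adjust()] that enforces p-values in
#' `[0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(p) {
  stop_if_not(is.numeric(p) && all(!is.na(p)) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

welch_or_pooled <- function(x, y, var_equal) {
  ok <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(ok) || !is.finite(ok$p.value)) {
    ## degenerate variance: equal means give p = 1 by convention,
    ## differing constant groups are an unambiguous difference
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(list(statistic = 0, p.value = 1))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0))
  }
  list(statistic = unname(ok$statistic), p.value = ok$p.value)
}

#' Pairwise differential expression (Welch t-tests, BH within comparison)
#'
#' Every gene is tested in the three pairwise comparisons NORM vs nTNBC,
#' NORM vs TNBC and nTNBC vs TNBC.  The t statistic follows the
#' (first - second) convention of [stats::t.test()]; the reported
#' `direction` is the sign of the second condition's mean minus the
#' first's, so `up` means higher in the later (more malignant) condition.
#' BH adjustment is applied within each comparison; `direction = "ns"`
#' whenever `q >= fdr_de`.
#'
#' @param expr An [expression_matrix()] with at least two samples per
#'   condition.
#' @param fdr_de FDR threshold for calling a direction (default 0.1).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return A `de_table`: data.frame with columns `gene`, `comparison`,
#'   `t`, `p`, `q`, `direction`.
#' @export
pairwise_de <- function(expr, fdr_de = 0.1, var_equal = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  cond <- conditions_of(expr)
  for (cc in CONDITIONS) {
    stop_if_not(sum(cond == cc) >= 2,
                sprintf("need >= 2 samples in condition %s", cc))
  }
  m <- unclass(expr)
  pairs <- list(c("NORM", "nTNBC"), c("NORM", "TNBC"), c("nTNBC", "TNBC"))
  out <- lapply(seq_along(pairs), function(i) {
    g1 <- m[, cond == pairs[[i]][1], drop = FALSE]
    g2 <- m[, cond == pairs[[i]][2], drop = FALSE]
    res <- vapply(seq_len(nrow(m)), function(r) {
      tt <- welch_or_pooled(g1[r, ], g2[r, ], var_equal)
      c(tt$statistic, tt$p.value, mean(g2[r, ]) - mean(g1[r, ]))
    }, numeric(3))
    q <- bh_adjust(res[2, ])
    data.frame(
      gene = rownames(m), comparison = DE_COMPARISONS[i],
      t = res[1, ], p = res[2, ], q = q,
      direction = ifelse(q < fdr_de,
                         ifelse(res[3, ] > 0, "up", "down"), "ns"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fdr_de") <- fdr_de
  class(res) <- c("de_table", "data.frame")
  res
}

## gene x comparison matrix of direction labels
de_direction_matrix <- function(de) {
  stopifnot(inherits(de, "de_table") || is.data.frame(de))
  genes <- unique(de$gene)
  dir <- matrix("ns", length(genes), length(DE_COMPARISONS),
                dimnames = list(genes, DE_COMPARISONS))
  dir[cbind(match(de$gene, genes), match(de$comparison, DE_COMPARISONS))] <-
    de$direction
  dir
}
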