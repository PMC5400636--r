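## Edge classification into regulatory patterns.
##
## UM (universal malignancy progression): the edge is significant in all
## three networks and both the TF and the target are differentially
## expressed with the same sign in NORM vs nTNBC and in nTNBC vs TNBC
## (stepwise monotone change).
## TNBCov (TF overexpression driven): the edge is significant in the TNBC
## network and both the TF and the target are DE with the same sign in
## NORM vs TNBC and nTNBC vs TNBC while not DE in NORM vs nTNBC
## (TNBC-only change).
## TNBCac (TF activation driven): the edge is significant in the TNBC
## network only (not in NORM, not in nTNBC) and the target changes only
## in TNBC as in TNBCov; the TF itself need not change expression (the
## driving event is an activity change).  An optional stricter reading
## additionally demands that the TF is not DE in any comparison.
## Precedence UM > TNBCac > TNBCov resolves rare multi-matches: an edge
## absent from the NORM and nTNBC networks is condition-specific in its
## wiring, which is the activation pattern's defining trait, so it is not
## handed to the overexpression pattern on TF-expression evidence alone.

## "changes only in TNBC": DE with one consistent sign against both NORM
## and nTNBC, and no NORM-vs-nTNBC difference.
tnbc_only_change <- function(dir) {
  dir[, "NORM_vs_TNBC"] != "ns" &
    dir[, "NORM_vs_TNBC"] == dir[, "nTNBC_vs_TNBC"] &
    dir[, "NORM_vs_nTNBC"] == "ns"
}

## "stepwise": same DE sign in both consecutive comparisons.
stepwise_change <- function(dir) {
  dir[, "NORM_vs_nTNBC"] != "ns" &
    dir[, "NORM_vs_nTNBC"] == dir[, "nTNBC_vs_TNBC"]
}

#' Classify every TF-gene edge into a regulatory pattern
#'
#' @param nets Named list of the three condition networks (`NORM`,
#'   `nTNBC`, `TNBC`), as returned by [panda()], over an identical edge
#'   universe.
#' @param de A [pairwise_de()] table covering both the TFs and the genes
#'   of the edge universe.
#' @param require_tf_silent Optionally demand that a TNBCac TF is not DE
#'   in any comparison (a stricter reading of activation without
#'   expression change).  Off by default: the pattern definition
#'   constrains the edges and the targets only, and a truly inactive
#'   clause avoids discarding TFs over marginal chance DE calls.
#' @return A `pattern_assignment`: list with `labels` (TF x gene character
#'   matrix over `UM`, `TNBCov`, `TNBCac`, `none`), the significance masks
#'   and the direction matrix used as evidence.
#' @export
classify_edges <- function(nets, de, require_tf_silent = FALSE) {
  stop_if_not(all(CONDITIONS %in% names(nets)),
              "`nets` must be named NORM, nTNBC, TNBC")
  masks <- lapply(nets[CONDITIONS], function(n) {
    stopifnot(inherits(n, "panda_network"))
    n$significant
  })
  dn <- dimnames(masks[[1]])
  for (m in masks) stop_if_not(identical(dimnames(m), dn),
                               "edge universes differ between networks")
  tfs <- dn[[1]]; genes <- dn[[2]]
  dir <- de_direction_matrix(de)
  stop_if_not(all(c(tfs, genes) %in% rownames(dir)),
              "DE table must cover all TFs and genes")

  tf_step <- stepwise_change(dir[tfs, , drop = FALSE])
  tf_only <- tnbc_only_change(dir[tfs, , drop = FALSE])
  tf_silent <- rowSums(dir[tfs, , drop = FALSE] != "ns") == 0
  g_step <- stepwise_change(dir[genes, , drop = FALSE])
  g_only <- tnbc_only_change(dir[genes, , drop = FALSE])

  um <- masks$NORM & masks$nTNBC & masks$TNBC &
    outer(tf_step, g_step, "&")
  ov <- masks$TNBC & outer(tf_only, g_only, "&")
  ac <- masks$TNBC & !masks$NORM & !masks$nTNBC &
    outer(if (require_tf_silent) tf_silent else rep(TRUE, length(tfs)),
          g_only, "&")

  labels <- matrix("none", length(tfs), length(genes),
                   dimnames = list(tfs, genes))
  labels[ov] <- "TNBCov"
  labels[ac] <- "TNBCac"
  labels[um] <- "UM"

  structure(list(labels = labels, significance = masks,
                 directions = dir,
                 require_tf_silent = require_tf_silent),
            class = "pattern_assignment")
}

## internal constructor used by downstream code and tests
new_pattern_assignment <- function(labels) {
  stop_if_not(is.matrix(labels) && !is.null(dimnames(labels)),
              "`labels` must be a named TF x gene matrix")
  stop_if_not(all(labels %in% c("UM", "TNBCov", "TNBCac", "none")),
              "unknown pattern label")
  structure(list(labels = labels, significance = NULL, directions = NULL),
            class = "pattern_assignment")
}

#' @export
print.pattern_assignment <- function(x, ...) {
  tab <- table(factor(x$labels, c("UM", "TNBCov", "TNBCac", "none")))
  cat("pattern_assignment:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

## TF -> target sets restricted to one pattern label
pattern_target_sets <- function(pa, pattern) {
  stopifnot(inherits(pa, "pattern_assignment"))
  hits <- pa$labels == pattern
  tfs <- rownames(pa$labels)[rowSums(hits) > 0]
  stats::setNames(lapply(tfs, function(t)
    colnames(pa$labels)[hits[t, ]]), tfs)
}

#' Summarize a pattern assignment
#'
#' @param pa A [classify_edges()] result.
#' @return List with per-pattern edge counts, TF sets, target sets, and
#'   pairwise TF / target overlap counts between patterns.
#' @export
pattern_summary <- function(pa) {
  stopifnot(inherits(pa, "pattern_assignment"))
  pats <- c("UM", "TNBCov", "TNBCac")
  tf_sets <- lapply(pats, function(p) {
    hits <- pa$labels == p
    rownames(pa$labels)[rowSums(hits) > 0]
  })
  names(tf_sets) <- pats
  target_sets <- lapply(pats, function(p) {
    hits <- pa$labels == p
    colnames(pa$labels)[colSums(hits) > 0]
  })
  names(target_sets) <- pats
  combos <- utils::combn(pats, 2, simplify = FALSE)
  overlap <- function(sets) {
    ov <- vapply(combos, function(cp)
      length(intersect(sets[[cp[1]]], sets[[cp[2]]])), 0L)
    names(ov) <- vapply(combos, paste, "", collapse = "&")
    ov
  }
  list(
    edge_counts = vapply(pats, function(p) sum(pa$labels == p), 0L),
    tf_counts = lengths(tf_sets), target_counts = lengths(target_sets),
    tf_sets = tf_sets, target_sets = target_sets,
    tf_overlap = overlap(tf_sets), target_overlap = overlap(target_sets)
  )
}
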