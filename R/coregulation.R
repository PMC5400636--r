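## TF co-regulation modules, network-walk core extension, enrichment.

#' Upper-tail hypergeometric overlap test
#'
#' Probability that two random gene sets of the observed sizes drawn from
#' a universe of `universe_size` genes share at least as many members as
#' observed: `P(X >= overlap)`.
#'
#' @param a,b Gene sets (character vectors).
#' @param universe_size Size of the gene universe.
#' @return The upper-tail p-value.
#' @export
overlap_test <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  stop_if_not(is_scalar_number(universe_size) && universe_size >= 1,
              "`universe_size` must be a positive integer")
  stop_if_not(length(a) <= universe_size && length(b) <= universe_size,
              "set sizes exceed the universe")
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                lower.tail = FALSE)
}

#' Jaccard similarity of pattern-restricted TF target profiles
#'
#' @param pa A [classify_edges()] result.
#' @param pattern Pattern label (`UM`, `TNBCov`, `TNBCac`).
#' @return Symmetric TF x TF Jaccard matrix with unit diagonal; pairs of
#'   empty sets score 0.
#' @export
profile_similarity <- function(pa, pattern) {
  sets <- pattern_target_sets(pa, pattern)
  stop_if_not(length(sets) >= 2,
              sprintf("pattern %s has fewer than 2 TFs", pattern))
  tfs <- names(sets)
  sim <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (i in seq_along(tfs)) {
    for (j in seq_len(i)) {
      u <- length(union(sets[[i]], sets[[j]]))
      sim[i, j] <- sim[j, i] <-
        if (u == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  diag(sim) <- 1
  sim
}

## Quorum gene set: genes present in at least `quorum` of the given sets.
quorum_genes <- function(sets, quorum) {
  counts <- table(unlist(lapply(sets, unique)))
  names(counts)[counts >= quorum]
}

## Monte-Carlo null for the joint overlap of k >= 3 target sets: draw
## random sets of the observed sizes and count how often the number of
## genes hitting the quorum reaches the observed count.
mc_overlap_p <- function(sizes, quorum, observed, universe_size,
                         draws = 1e4) {
  if (observed == 0) return(1)
  hits <- 0L
  for (b in seq_len(draws)) {
    idx <- unlist(lapply(sizes, function(s) sample.int(universe_size, s)))
    if (sum(tabulate(idx, universe_size) >= quorum) >= observed) {
      hits <- hits + 1L
    }
  }
  (1 + hits) / (1 + draws)
}

new_coreg_module <- function(tfs, targets, p, level) {
  structure(list(tfs = sort(tfs), shared_targets = sort(targets),
                 p = p, q = NA_real_, level = level),
            class = "coreg_module")
}

#' @export
print.coreg_module <- function(x, ...) {
  cat(sprintf("coreg_module: {%s} sharing %d targets (p = %.3g, q = %.3g)\n",
              paste(x$tfs, collapse = ", "), length(x$shared_targets),
              x$p, x$q))
  invisible(x)
}

#' Discover multi-TF co-regulation modules by level-wise merging
#'
#' Level 2 collects every TF pair whose pattern-restricted target sets
#' overlap more than expected by the hypergeometric test (BH q < `fdr`).
#' Levels 3-4 merge pairs of significant 2-TF sets (TF-set unions of size
#' 3 or 4) and intersect the member TFs' gene sets.  Levels 5-8 merge
#' pairs of significant 4-TF sets: the merged TF set is the union, and
#' the merged gene set is the union of the parents' intersections --
#' equivalently, the genes shared by at least `k - 1` of the `k` member
#' TFs' target sets (a quorum rule; merging gene sets, unlike
#' re-intersecting them, does not discard a co-target over a single
#' missing edge).  Gene sets of three or more TFs are scored against a
#' Monte-Carlo null (random sets of the observed sizes, `mc_draws` draws,
#' fixed `mc_seed`, same statistic as observed) with BH adjustment within
#' each level.  Only maximal significant modules (TF set not contained in
#' a larger significant module) are returned, sorted by TF-set size then
#' significance.
#'
#' @param pa A [classify_edges()] result.
#' @param pattern Pattern whose target profiles are merged.
#' @param universe_size Gene universe size for the overlap null (all genes
#'   in the network by default choice of the caller).
#' @param fdr Significance threshold on BH-adjusted overlap p-values.
#' @param mc_draws,mc_seed Monte-Carlo draws and seed for >= 3-TF
#'   intersections.
#' @return List of `coreg_module` objects (possibly empty).
#' @export
find_modules <- function(pa, pattern, universe_size, fdr = 0.05,
                         mc_draws = 1e4, mc_seed = 7L) {
  sets <- pattern_target_sets(pa, pattern)
  sets <- sets[lengths(sets) > 0]
  if (length(sets) < 2) return(list())
  tfs <- names(sets)

  ## level 2: exact hypergeometric on all pairs
  pairs <- utils::combn(tfs, 2, simplify = FALSE)
  l2 <- lapply(pairs, function(pr) {
    inter <- intersect(sets[[pr[1]]], sets[[pr[2]]])
    new_coreg_module(pr, inter,
                     overlap_test(sets[[pr[1]]], sets[[pr[2]]], universe_size),
                     level = 2L)
  })
  l2 <- adjust_level(l2, fdr)
  sig <- Filter(function(m) m$q < fdr && length(m$shared_targets) > 0, l2)
  if (length(sig) == 0) return(list())

  ## level <= 4: strict intersection of member sets (quorum = k);
  ## level >= 5: union-merge of the parents' gene sets (quorum = k - 1)
  eval_level <- function(parents, quorum_gap) {
    cand <- list()
    seen <- character(0)
    idx <- utils::combn(seq_along(parents), 2, simplify = FALSE)
    for (ij in idx) {
      u <- sort(union(parents[[ij[1]]]$tfs, parents[[ij[2]]]$tfs))
      key <- paste(u, collapse = "|")
      if (key %in% seen || length(u) <= length(parents[[ij[1]]]$tfs)) next
      seen <- c(seen, key)
      genes <- quorum_genes(sets[u], length(u) - quorum_gap)
      cand[[length(cand) + 1L]] <-
        new_coreg_module(u, genes, NA_real_, level = length(u))
    }
    cand
  }
  score_mc <- function(cand, quorum_gap) {
    if (length(cand) == 0) return(list())
    with_seed(mc_seed, {
      for (i in seq_along(cand)) {
        cand[[i]]$p <- mc_overlap_p(lengths(sets[cand[[i]]$tfs]),
                                    length(cand[[i]]$tfs) - quorum_gap,
                                    length(cand[[i]]$shared_targets),
                                    universe_size, mc_draws)
      }
    })
    adjust_level(cand, fdr)
  }

  l34 <- score_mc(eval_level(sig, 0L), 0L)
  sig34 <- Filter(function(m) m$q < fdr && length(m$shared_targets) > 0, l34)
  sig4 <- Filter(function(m) m$level == 4L, sig34)
  l58 <- if (length(sig4) >= 2) score_mc(eval_level(sig4, 1L), 1L) else list()
  sig58 <- Filter(function(m) m$q < fdr && length(m$shared_targets) > 0, l58)

  all_sig <- c(sig, sig34, sig58)
  keys <- lapply(all_sig, `[[`, "tfs")
  maximal <- vapply(seq_along(all_sig), function(i) {
    !any(vapply(seq_along(all_sig), function(j) {
      j != i && length(keys[[j]]) > length(keys[[i]]) &&
        all(keys[[i]] %in% keys[[j]])
    }, logical(1)))
  }, logical(1))
  out <- all_sig[maximal]
  ord <- order(-vapply(out, function(m) length(m$tfs), 0L),
               vapply(out, `[[`, 0, "p"))
  out[ord]
}

adjust_level <- function(mods, fdr) {
  if (length(mods) == 0) return(mods)
  q <- bh_adjust(vapply(mods, `[[`, 0, "p"))
  for (i in seq_along(mods)) mods[[i]]$q <- q[i]
  mods
}

#' Extend a core gene set by network walking
#'
#' Step 1 selects intermediators: TFs with significant TNBC edges to
#' strictly more than `t_inter` core genes.  Step 2 selects neighbors:
#' genes significantly targeted by strictly more than `t_neigh`
#' intermediators.  The extended set is the union of core and neighbors.
#' Thresholds that no TF or gene can clear yield an empty (not failed)
#' extension.
#'
#' @param core Character vector of core genes.
#' @param net A [panda()] network (its significance mask is walked).
#' @param t_inter,t_neigh Strict thresholds ("more than") for
#'   intermediators and neighbors.
#' @return An `extended_core`: list with `core_targets`, `intermediators`,
#'   `neighbors` and `total`.
#' @export
extend_core <- function(core, net, t_inter = 10, t_neigh = 20) {
  stopifnot(inherits(net, "panda_network"))
  stop_if_not(length(core) > 0, "`core` must be nonempty")
  core <- intersect(core, colnames(net$significant))
  sig <- net$significant
  n_core_hits <- rowSums(sig[, core, drop = FALSE])
  intermediators <- rownames(sig)[n_core_hits > t_inter]
  neighbors <- character(0)
  if (length(intermediators) > 0) {
    n_inter_hits <- colSums(sig[intermediators, , drop = FALSE])
    neighbors <- colnames(sig)[n_inter_hits > t_neigh]
  }
  structure(list(core_targets = core, intermediators = intermediators,
                 neighbors = neighbors, total = union(core, neighbors),
                 t_inter = t_inter, t_neigh = t_neigh),
            class = "extended_core")
}

#' @export
print.extended_core <- function(x, ...) {
  cat(sprintf("extended_core: %d core genes, %d intermediators (> %g core hits), %d neighbors (> %g intermediators), %d total\n",
              length(x$core_targets), length(x$intermediators), x$t_inter,
              length(x$neighbors), x$t_neigh, length(x$total)))
  invisible(x)
}

#' Hypergeometric gene-set enrichment over a supplied collection
#'
#' @param genes Query gene set (must lie within `universe`).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return data.frame (`set`, `set_size`, `overlap`, `p`, `q`) sorted by
#'   ascending p; BH adjustment across the collection.
#' @export
enrich <- function(genes, collection, universe) {
  stop_if_not(length(universe) > 0, "`universe` must be nonempty")
  genes <- unique(genes)
  stop_if_not(all(genes %in% universe), "`genes` must lie within `universe`")
  rows <- lapply(names(collection), function(nm) {
    s <- intersect(unique(collection[[nm]]), universe)
    data.frame(set = nm, set_size = length(s),
               overlap = length(intersect(genes, s)),
               p = overlap_test(genes, s, length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}
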