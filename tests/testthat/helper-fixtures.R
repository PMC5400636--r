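# Shared fixtures, built in code and cached for the duration of a test run.

# Minimal network stub carrying only what classification and walking need.
fake_network <- function(significant, condition = "TNBC") {
  z <- (significant * 1) * 3
  structure(list(z = z, pvalues = 1 - significant * 0.999,
                 qvalues = 1 - significant * 0.999,
                 significant = significant == 1, condition = condition,
                 iterations = 0L, converged = TRUE, h = numeric(0),
                 fdr = 0.05),
            class = "panda_network")
}

# Direction table for classify_edges: `dirs` is a named list mapping
# entity id to a length-3 direction vector (NORM_vs_nTNBC, NORM_vs_TNBC,
# nTNBC_vs_TNBC).
fake_de <- function(dirs) {
  comps <- c("NORM_vs_nTNBC", "NORM_vs_TNBC", "nTNBC_vs_TNBC")
  do.call(rbind, lapply(names(dirs), function(g)
    data.frame(gene = g, comparison = comps, t = 0, p = 1,
               q = ifelse(dirs[[g]] == "ns", 1, 0),
               direction = dirs[[g]], stringsAsFactors = FALSE)))
}

# All 27 direction triples over {up, down, ns}.
direction_grid <- function() {
  lv <- c("up", "down", "ns")
  g <- expand.grid(d1 = lv, d2 = lv, d3 = lv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) unlist(g[i, ], use.names = FALSE))
}

# Default synthetic cohort with inferred networks, computed once per run.
cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(cohort_cache$value)) {
    cfg <- sim_config()
    truth <- generate_truth(cfg)
    expr <- simulate_expression(truth, cfg)
    pp <- simulate_prior_ppi(truth, cfg)
    nets <- suppressWarnings(lapply(
      stats::setNames(c("NORM", "nTNBC", "TNBC"), c("NORM", "nTNBC", "TNBC")),
      function(cc) panda(pp$prior, pp$ppi, expr, cc)))
    de <- pairwise_de(expr)
    cohort_cache$value <- list(cfg = cfg, truth = truth, expr = expr,
                               prior = pp$prior, ppi = pp$ppi, nets = nets,
                               de = de, pa = classify_edges(nets, de))
  }
  cohort_cache$value
}

# Brute-force AUC by concordant-pair counting with the half-tie rule.
auc_by_pairs <- function(scores, positives) {
  lab <- names(scores) %in% positives
  pos <- scores[lab]; neg <- scores[!lab]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive hypergeometric upper tail by enumerating the pmf.
hyper_upper_by_enumeration <- function(k, size_a, size_b, universe) {
  i <- k:min(size_a, size_b)
  sum(choose(size_a, i) * choose(universe - size_a, size_b - i)) /
    choose(universe, size_b)
}

# Exhaustive PWM score p-value: enumerate all 4^L words with the same
# floored, grid-discretized log2-odds scoring the package documents.
pwm_pvalue_by_enumeration <- function(pwm, score, background = rep(0.25, 4)) {
  ints <- round(log2(pmax(unclass(pwm), 1e-10) /
                       matrix(background, 4, ncol(pwm))) / 1e-3)
  L <- ncol(pwm)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  word_scores <- vapply(seq_len(nrow(words)), function(i)
    sum(ints[cbind(words[i, ], seq_len(L))]), numeric(1))
  probs <- apply(matrix(background[words], nrow(words), L), 1, prod)
  thr <- ceiling(score / 1e-3 - 1e-9)
  sum(probs[word_scores >= thr])
}

withr_like_tempdir <- function() {
  d <- tempfile("tnbcnet")
  dir.create(d)
  d
}
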