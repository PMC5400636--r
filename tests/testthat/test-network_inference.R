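make_expr <- function(values, condition) {
  rownames(values) <- rownames(values) %||% paste0("g", seq_len(nrow(values)))
  colnames(values) <- colnames(values) %||% paste0("s", seq_len(ncol(values)))
  expression_matrix(values, condition)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("co-expression reproduces hand-computed Pearson correlations", {
  v <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1), d = c(1, 2, 4))
  colnames(v) <- paste0("s", 1:3)
  expr <- expression_matrix(v, stats::setNames(rep("TNBC", 3), colnames(v)))
  cc <- coexpression(expr, "TNBC")
  expect_equal(cc["a", "b"], 1)
  expect_equal(cc["a", "c"], -1)
  expect_equal(cc["a", "d"], 0.9819805, tolerance = 1e-6)
  expect_identical(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 4))
})

test_that("co-expression flags zero-variance genes and refuses tiny groups", {
  v <- rbind(a = c(1, 2, 3), flat = c(2, 2, 2))
  colnames(v) <- paste0("s", 1:3)
  expr <- expression_matrix(v, stats::setNames(rep("TNBC", 3), colnames(v)))
  expect_warning(cc <- coexpression(expr, "TNBC"), "zero-variance")
  expect_equal(cc["a", "flat"], 0)
  expect_equal(cc["flat", "flat"], 1)
  expect_identical(attr(cc, "zero_variance"), "flat")
  expect_error(coexpression(expr, "NORM"), "3 samples")
})

test_that("z-score normalization has the documented fixed points", {
  expect_equal(zscore_normalize(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(zscore_normalize(matrix(c(1, 3), 1)), matrix(c(-1, 1), 1))
  set.seed(1)
  m <- matrix(rnorm(60), 6)
  z <- zscore_normalize(m)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-12)
})

test_that("the Tanimoto kernel matches hand-evaluated cases and guards degeneracy", {
  e1 <- matrix(c(1, 0), 1)
  expect_equal(tanimoto(e1, t(e1))[1, 1], 1)
  expect_equal(tanimoto(matrix(c(1, 0), 1), matrix(c(0, 1), 2))[1, 1], 0)
  expect_equal(tanimoto(matrix(c(1, 1), 1), matrix(c(1, 0), 2))[1, 1],
               1 / sqrt(2))
  # all-zero row: denominator guard returns 0
  expect_equal(tanimoto(matrix(0, 1, 2), matrix(c(0, 0), 2))[1, 1], 0)
  expect_error(tanimoto(matrix(1, 2, 3), matrix(1, 2, 3)), "dimensions")
})

small_instance <- function(seed) {
  set.seed(seed)
  tfs <- paste0("T", 1:8)
  genes <- paste0("g", 1:12)
  prior <- matrix(rbinom(96, 1, 0.3), 8, 12, dimnames = list(tfs, genes))
  ppi <- matrix(runif(64, 0, 0.3), 8, 8)
  ppi <- (ppi + t(ppi)) / 2
  diag(ppi) <- 1
  dimnames(ppi) <- list(tfs, tfs)
  v <- matrix(rnorm(12 * 9), 12, 9,
              dimnames = list(genes, paste0("s", 1:9)))
  expr <- expression_matrix(v, stats::setNames(rep("TNBC", 9), colnames(v)))
  list(prior = prior, ppi = ppi, expr = expr)
}

test_that("alpha = 0 and max_iter = 0 both return the z-scored prior exactly", {
  inst <- small_instance(1)
  net0 <- panda(inst$prior, inst$ppi, inst$expr, "TNBC",
                panda_config(alpha = 0, max_iter = 50))
  expect_identical(net0$z, zscore_normalize(inst$prior))
  netm <- panda(inst$prior, inst$ppi, inst$expr, "TNBC",
                panda_config(alpha = 0.25, max_iter = 0))
  expect_identical(netm$z, zscore_normalize(inst$prior))
})

test_that("raising a prior entry never lowers that edge's score after one update", {
  for (seed in 1:10) {
    inst <- small_instance(seed)
    zeros <- which(inst$prior == 0, arr.ind = TRUE)
    pick <- zeros[1 + (seed %% nrow(zeros)), ]
    prior2 <- inst$prior
    prior2[pick[1], pick[2]] <- 1L
    cfg <- panda_config(alpha = 0.25, max_iter = 1)
    z1 <- suppressWarnings(panda(inst$prior, inst$ppi, inst$expr, "TNBC", cfg))$z
    z2 <- suppressWarnings(panda(prior2, inst$ppi, inst$expr, "TNBC", cfg))$z
    expect_gte(z2[pick[1], pick[2]], z1[pick[1], pick[2]] - 1e-8)
  }
})

test_that("message passing converges with a finite decreasing-to-zero distance", {
  co <- default_cohort()
  net <- co$nets$TNBC
  expect_true(net$converged)
  expect_true(all(is.finite(net$h)))
  expect_lt(utils::tail(net$h, 1), 1e-3)
})

test_that("significant_edges applies Benjamini-Hochberg over the flattened edges", {
  z <- matrix(c(3, 0, -1), 1, dimnames = list("T1", paste0("g", 1:3)))
  net <- structure(list(z = z, pvalues = pnorm(z, lower.tail = FALSE),
                        condition = "TNBC"), class = "panda_network")
  expect_equal(as.vector(pnorm(z, lower.tail = FALSE)),
               c(0.001349898, 0.5, 0.8413447), tolerance = 1e-6)
  mask <- significant_edges(net, fdr = 0.05)
  expect_identical(as.vector(mask), c(TRUE, FALSE, FALSE))
  expect_false(any(significant_edges(net, fdr = 0)))
  # ties: identical scores give an all-or-nothing mask
  z2 <- matrix(2.5, 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  net2 <- structure(list(z = z2, pvalues = pnorm(z2, lower.tail = FALSE)),
                    class = "panda_network")
  m2 <- significant_edges(net2, 0.05)
  expect_true(all(m2) || !any(m2))
})

test_that("network overlap counts Venn regions by enumeration", {
  dn <- list("T1", paste0("g", 1:3))
  m <- function(bits) matrix(as.logical(bits), 1, 3, dimnames = dn)
  mk <- function(bits) structure(list(significant = m(bits)),
                                 class = "panda_network")
  # masks {e1,e2}, {e2,e3}, {e2}: triple = {e2}, union = 3
  ov <- network_overlap(list(A = mk(c(1, 1, 0)), B = mk(c(0, 1, 1)),
                             C = mk(c(0, 1, 0))))
  expect_equal(ov$shared_all, 1)
  expect_equal(ov$shared_fraction, 1 / 3)
  expect_equal(unname(ov$regions[["A"]]), 1)
  expect_equal(unname(ov$regions[["B"]]), 1)
  expect_equal(unname(ov$regions[["A&B&C"]]), 1)
  # identical masks: all edges in the triple intersection
  ov2 <- network_overlap(list(A = mk(c(1, 1, 0)), B = mk(c(1, 1, 0)),
                              C = mk(c(1, 1, 0))))
  expect_equal(ov2$shared_fraction, 1)
  # disjoint masks
  ov3 <- network_overlap(list(A = mk(c(1, 0, 0)), B = mk(c(0, 1, 0)),
                              C = mk(c(0, 0, 1))))
  expect_equal(ov3$shared_all, 0)
})
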