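test_that("planted truth is deterministic and satisfies its structural invariants", {
  cfg <- sim_config(n_tfs = 30, n_genes = 300, seed = 42)
  truth <- generate_truth(cfg)
  truth2 <- generate_truth(cfg)
  expect_identical(truth, truth2)

  expect_length(truth$module_tfs, 5)
  expect_length(truth$module_targets, 35)
  # module wiring only in TNBC
  expect_true(all(truth$wiring$TNBC[truth$module_tfs, truth$module_targets] == 1))
  expect_true(all(truth$wiring$NORM[truth$module_tfs, truth$module_targets] == 0))
  expect_true(all(truth$wiring$nTNBC[truth$module_tfs, truth$module_targets] == 0))
  # binary wiring, identical background across conditions
  for (w in truth$wiring) expect_true(all(w %in% c(0L, 1L)))
  off_module <- setdiff(truth$gene_ids, truth$module_targets)
  expect_identical(truth$wiring$NORM[, off_module], truth$wiring$TNBC[, off_module])
  expect_identical(truth$wiring$NORM, truth$wiring$nTNBC)
  # planted TF sets disjoint
  expect_length(intersect(truth$module_tfs, c(truth$um_tfs, truth$ov_tfs)), 0)
  expect_length(intersect(truth$um_tfs, truth$ov_tfs), 0)
})

test_that("the smallest admissible config still hosts the module plus one UM TF", {
  truth <- generate_truth(sim_config(n_tfs = 6, n_genes = 40))
  expect_length(truth$module_tfs, 5)
  expect_length(truth$module_targets, 35)
  expect_length(truth$um_tfs, 1)
  expect_length(truth$ov_tfs, 0)
})

test_that("undersized configs are rejected", {
  expect_error(sim_config(n_tfs = 5), "n_tfs")
  expect_error(sim_config(n_genes = 30), "n_genes")
  expect_error(sim_config(sigma = -1), "sigma")
  expect_error(sim_config(prior_fp_rate = 1.2), "prior_fp_rate")
})

test_that("noise-free expression equals baseline plus summed module activity", {
  cfg <- sim_config(sigma = 0, beta = 1, seed = 3)
  truth <- generate_truth(cfg)
  expr <- simulate_expression(truth, cfg)
  cond <- attr(expr, "condition")
  a <- attr(expr, "activities")$TNBC
  base <- attr(expr, "baseline")
  g <- truth$module_targets[1]
  tnbc <- names(cond)[cond == "TNBC"]
  expected <- base[g] + colSums(a[truth$module_tfs, tnbc])
  expect_equal(unclass(expr)[g, tnbc], expected, tolerance = 1e-12)
  expect_equal(cor(unclass(expr)[g, tnbc], colSums(a[truth$module_tfs, tnbc])), 1)
})

test_that("beta = 0 yields differential expression only at the type-I rate", {
  frac <- vapply(1:20, function(s) {
    cfg <- sim_config(n_tfs = 10, n_genes = 80, n_samples_per_condition = 25,
                      beta = 0, seed = 1000 + s)
    truth <- generate_truth(cfg)
    expr <- simulate_expression(truth, cfg)
    de <- pairwise_de(expr)
    mean(de$q < 0.1)
  }, numeric(1))
  expect_lte(mean(frac), 0.15)
})

test_that("module TF expression carries no condition signal", {
  pvals <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 2000 + s)
    truth <- generate_truth(cfg)
    expr <- simulate_expression(truth, cfg)
    cond <- attr(expr, "condition")
    tf <- truth$module_tfs[1 + (s %% 5)]
    stats::t.test(unclass(expr)[tf, cond == "TNBC"],
                  unclass(expr)[tf, cond == "NORM"])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
  ks <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 3000 + s)
    truth <- generate_truth(cfg)
    expr <- simulate_expression(truth, cfg)
    cond <- attr(expr, "condition")
    suppressWarnings(stats::ks.test(
      unclass(expr)[truth$module_tfs[1], cond == "TNBC"],
      unclass(expr)[truth$module_tfs[1], cond == "NORM"]))$p.value
  }, numeric(1))
  expect_gte(mean(ks > 0.01), 0.9)
})

test_that("the motif prior reproduces the union wiring at zero noise and a calibrated error otherwise", {
  cfg0 <- sim_config(prior_fp_rate = 0, prior_fn_rate = 0, seed = 42)
  truth <- generate_truth(cfg0)
  pp <- simulate_prior_ppi(truth, cfg0)
  union_w <- pmax(truth$wiring$NORM, truth$wiring$nTNBC, truth$wiring$TNBC)
  expect_identical(unname(pp$prior), unname(union_w))

  cfg <- sim_config(prior_fp_rate = 0.1, prior_fn_rate = 0.1, seed = 42)
  pp2 <- simulate_prior_ppi(truth, cfg)
  hamming <- mean(pp2$prior != union_w)
  expect_gte(hamming, 0.07)
  expect_lte(hamming, 0.13)
})

test_that("the PPI matrix is symmetric with unit diagonal", {
  cfg <- sim_config(seed = 5)
  truth <- generate_truth(cfg)
  ppi <- simulate_prior_ppi(truth, cfg)$ppi
  expect_identical(ppi, t(ppi))
  expect_equal(unname(diag(ppi)), rep(1, nrow(ppi)))
})

test_that("peak simulation respects its dropout and false-positive rates", {
  cfg <- sim_config(peak_fn_rate = 0, peak_fp_rate = 0, seed = 9)
  truth <- generate_truth(cfg)
  ann <- simulate_annotation(truth)
  peaks <- simulate_peaks(truth, ann, n_cell_lines = 6, cfg)
  win <- promoter_windows(ann)
  tf <- truth$module_tfs[1]
  per_line <- lapply(peaks, peak_targets, windows = win, tf = tf)
  common <- common_targets(per_line, min_lines = 5)
  truth_targets <- colnames(truth$wiring$TNBC)[truth$wiring$TNBC[tf, ] == 1]
  expect_setequal(common, truth_targets)

  cfg_empty <- sim_config(peak_fn_rate = 1, peak_fp_rate = 0, seed = 9)
  peaks_empty <- simulate_peaks(truth, ann, 3, cfg_empty)
  expect_true(all(vapply(peaks_empty, nrow, 0L) == 0))

  # fn = 0.3 over 10 lines: a true target is hit in 7 lines on average
  cfg_fn <- sim_config(peak_fn_rate = 0.3, peak_fp_rate = 0, seed = 11)
  peaks_fn <- simulate_peaks(truth, ann, 10, cfg_fn)
  per_line_fn <- lapply(peaks_fn, peak_targets, windows = win, tf = tf)
  counts <- table(factor(unlist(per_line_fn), levels = truth_targets))
  expect_lt(abs(mean(counts) - 7), 1)
})

test_that("survival simulation censors as configured", {
  groups <- stats::setNames(rep(c("TNBC", "nTNBC-other"), each = 20),
                            sprintf("s%02d", 1:40))
  cfg <- sim_config(censor_fraction = 1, seed = 2)
  rec <- simulate_survival(groups, cfg)
  expect_true(all(rec$event == 0))
  expect_equal(km_curve(rec)$surv, rep(1, nrow(km_curve(rec))))

  cfg0 <- sim_config(censor_fraction = 0, seed = 2)
  rec0 <- simulate_survival(groups, cfg0)
  expect_true(all(rec0$event == 1))
  expect_error(simulate_survival(stats::setNames(character(0), character(0)), cfg0))
})
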