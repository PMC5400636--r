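test_that("the hypergeometric overlap test matches exact enumeration", {
  expect_equal(overlap_test(paste0("g", 1:10), paste0("g", c(1:8, 11, 12)), 20),
               2126 / 184756, tolerance = 1e-12)
  # no overlap: P(X >= 0) = 1
  expect_equal(overlap_test(c("a", "b"), c("c", "d"), 10), 1)
  # both sets are the whole universe: the overlap is forced
  u <- paste0("g", 1:6)
  expect_equal(overlap_test(u, u, 6), 1)
  expect_error(overlap_test(paste0("g", 1:5), "g1", 3), "universe")

  set.seed(7)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    universe <- paste0("x", seq_len(n))
    a <- sample(universe, sample(1:n, 1))
    b <- sample(universe, sample(1:n, 1))
    k <- length(intersect(a, b))
    expect_equal(overlap_test(a, b, n),
                 hyper_upper_by_enumeration(k, length(a), length(b), n),
                 tolerance = 1e-12)
  }
})

test_that("target-profile similarity is the Jaccard index", {
  labels <- matrix("none", 3, 5,
                   dimnames = list(c("A", "B", "C"), paste0("g", 1:5)))
  labels["A", c("g1", "g2", "g3")] <- "TNBCac"
  labels["B", c("g2", "g3", "g4")] <- "TNBCac"
  labels["C", c("g1", "g2", "g3")] <- "TNBCac"
  pa <- tnbcnet:::new_pattern_assignment(labels)
  sim <- profile_similarity(pa, "TNBCac")
  expect_equal(sim["A", "B"], 0.5)      # {g1,g2,g3} vs {g2,g3,g4}
  expect_equal(sim["A", "C"], 1)        # identical sets
  expect_equal(unname(diag(sim)), rep(1, 3))
  expect_identical(sim, t(sim))
  labels["A", ] <- "none"
  expect_error(profile_similarity(tnbcnet:::new_pattern_assignment(labels[1, , drop = FALSE]), "TNBCac"),
               "fewer than 2")
})

test_that("three TFs sharing one geneset collapse into a single module", {
  genes <- paste0("g", 1:100)
  labels <- matrix("none", 3, 100,
                   dimnames = list(c("A", "B", "C"), genes))
  labels[, 1:20] <- "TNBCac"
  pa <- tnbcnet:::new_pattern_assignment(labels)
  mods <- find_modules(pa, "TNBCac", universe_size = 100, mc_draws = 2000)
  expect_length(mods, 1)
  expect_identical(mods[[1]]$tfs, c("A", "B", "C"))
  expect_setequal(mods[[1]]$shared_targets, genes[1:20])
  expect_lt(mods[[1]]$q, 0.05)
})

test_that("disjoint target profiles yield no modules", {
  labels <- matrix("none", 2, 40,
                   dimnames = list(c("A", "B"), paste0("g", 1:40)))
  labels["A", 1:10] <- "TNBCac"
  labels["B", 21:30] <- "TNBCac"
  pa <- tnbcnet:::new_pattern_assignment(labels)
  expect_length(find_modules(pa, "TNBCac", universe_size = 40), 0)
  expect_length(find_modules(pa, "UM", universe_size = 40), 0)
})

test_that("module genesets are intersections (pairs to quadruples) of member profiles", {
  co <- default_cohort()
  mods <- find_modules(co$pa, "TNBCac", universe_size = 300, mc_draws = 2000)
  sets <- tnbcnet:::pattern_target_sets(co$pa, "TNBCac")
  for (m in mods) {
    if (length(m$tfs) <= 4) {
      expect_setequal(m$shared_targets, Reduce(intersect, sets[m$tfs]))
    } else {
      # union-merge: shared by at least |tfs| - 1 member profiles
      counts <- table(unlist(lapply(sets[m$tfs], unique)))
      expect_setequal(m$shared_targets,
                      names(counts)[counts >= length(m$tfs) - 1])
    }
  }
})

test_that("network walking applies its strict thresholds", {
  tfs <- paste0("T", 1:4)
  genes <- paste0("g", 1:40)
  sig <- matrix(FALSE, 4, 40, dimnames = list(tfs, genes))
  core <- genes[1:35]
  sig["T1", genes[1:12]] <- TRUE   # 12 core hits  -> intermediator
  sig["T2", genes[1:10]] <- TRUE   # 10 core hits  -> excluded (strict >)
  sig["T3", genes[1:11]] <- TRUE   # 11 core hits  -> intermediator
  sig["T1", "g36"] <- TRUE
  sig["T3", "g36"] <- TRUE         # g36 hit by 2 intermediators
  net <- fake_network(sig * 1)
  net$significant <- sig
  ext <- extend_core(core, net, t_inter = 10, t_neigh = 1)
  expect_setequal(ext$intermediators, c("T1", "T3"))
  # neighbors: hit by both intermediators (strictly more than 1)
  expect_setequal(ext$neighbors, c(genes[1:11], "g36"))
  expect_true(all(ext$core_targets %in% ext$total))
})

test_that("the 17-gene walking toy resolves by hand enumeration", {
  tfs <- paste0("T", 1:3)
  genes <- paste0("g", 1:17)
  sig <- matrix(FALSE, 3, 17, dimnames = list(tfs, genes))
  sig[, 1:12] <- TRUE   # all 3 TFs regulate the whole 12-gene core
  sig[, 13:17] <- TRUE  # 5 extra genes each hit by all 3 TFs
  net <- fake_network(sig * 1)
  net$significant <- sig
  ext <- extend_core(genes[1:12], net, t_inter = 10, t_neigh = 2)
  expect_setequal(ext$intermediators, tfs)
  expect_length(ext$total, 17)
})

test_that("unreachable walking thresholds give an empty, not failed, extension", {
  sig <- matrix(TRUE, 2, 5, dimnames = list(c("T1", "T2"), paste0("g", 1:5)))
  net <- fake_network(sig * 1)
  net$significant <- sig
  ext <- extend_core(paste0("g", 1:5), net, t_inter = 10, t_neigh = 20)
  expect_length(ext$intermediators, 0)
  expect_length(ext$neighbors, 0)
  expect_setequal(ext$total, paste0("g", 1:5))
})

test_that("enlarging the significance mask never shrinks the walked sets", {
  set.seed(11)
  for (i in 1:10) {
    sig <- matrix(runif(8 * 30) < 0.4, 8, 30,
                  dimnames = list(paste0("T", 1:8), paste0("g", 1:30)))
    bigger <- sig | (matrix(runif(8 * 30) < 0.2, 8, 30))
    core <- paste0("g", 1:12)
    n1 <- fake_network(sig * 1); n1$significant <- sig
    n2 <- fake_network(bigger * 1); n2$significant <- bigger
    e1 <- extend_core(core, n1, t_inter = 3, t_neigh = 2)
    e2 <- extend_core(core, n2, t_inter = 3, t_neigh = 2)
    expect_true(all(e1$intermediators %in% e2$intermediators))
    expect_true(all(e1$neighbors %in% e2$neighbors))
  }
})

test_that("gene-set enrichment matches single-term enumeration", {
  universe <- paste0("g", 1:100)
  collection <- list(hit = paste0("g", 1:5), miss = paste0("g", 50:60))
  res <- enrich(paste0("g", 1:5), collection, universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)
  expect_equal(res$set[1], "hit")  # sorted ascending p
  # single-set collection: q equals p
  res1 <- enrich(paste0("g", 1:5), collection["hit"], universe)
  expect_equal(res1$q, res1$p)
  expect_error(enrich("g1", collection, character(0)), "universe")
  expect_error(enrich("zz", collection, universe), "within")
})
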