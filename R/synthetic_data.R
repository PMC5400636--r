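## Synthetic cohort generator.
##
## The generator plants, in a three-condition breast-tissue cohort
## (NORM, nTNBC, TNBC), the regulatory structure the downstream analysis
## is designed to detect:
##   * a TF-activation-driven core module (default 5 TFs x 35 targets)
##     wired only in TNBC, whose TFs change latent activity but not
##     expression;
##   * a universal-malignancy (UM) block wired in all conditions whose TFs
##     and targets shift monotonically NORM -> nTNBC -> TNBC;
##   * a TF-overexpression (OV) block wired in all conditions whose TFs
##     and targets shift only in TNBC;
##   * background wiring identical across conditions.
## Expression follows a linear-Gaussian activity model: each TF carries a
## latent per-sample activity and each wired target receives
## beta * activity plus independent Gaussian noise.

#' Configuration for the synthetic cohort generator
#'
#' Collects the sizes, effect sizes and noise rates used by
#' [generate_truth()] and the `simulate_*` functions.  Defaults describe the
#' benchmark cohort: 30 TFs, 300 genes, 50 samples per condition, unit
#' activity-to-expression effect (`beta`), residual noise `sigma = 0.5`
#' (log-intensity units) and 5\% error rates on the motif prior.
#'
#' @param n_tfs Number of transcription factors (>= 6).
#' @param n_genes Number of non-TF genes (>= 40 so the planted 35-target
#'   core module fits).
#' @param n_samples_per_condition Samples simulated per condition.
#' @param beta Activity-to-expression effect size; `beta = 0` disconnects
#'   regulation from expression entirely.
#' @param sigma Standard deviation of residual expression noise (>= 0).
#' @param prior_fp_rate,prior_fn_rate False-positive / false-negative rates
#'   applied to the motif prior relative to the true union wiring.
#' @param peak_fp_rate,peak_fn_rate Per-pair rates of spurious / dropped
#'   ChIP peaks.
#' @param hazard_ratio Hazard multiplier for poor-prognosis groups in
#'   [simulate_survival()] (> 0).
#' @param censor_fraction Probability that a survival record is censored.
#' @param tnbc_like_fraction Fraction of nTNBC samples planted as a
#'   TNBC-like subgroup (partial core-target activation).
#' @param seed Integer master seed; every simulator derives its stream
#'   from it, so identical configs give bit-identical outputs.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_tfs = 30L, n_genes = 300L,
                       n_samples_per_condition = 50L,
                       beta = 1, sigma = 0.5,
                       prior_fp_rate = 0.05, prior_fn_rate = 0.05,
                       peak_fp_rate = 0.05, peak_fn_rate = 0.05,
                       hazard_ratio = 3, censor_fraction = 0.2,
                       tnbc_like_fraction = 0.2,
                       seed = 42L) {
  stop_if_not(is_scalar_number(n_tfs) && n_tfs >= 6,
              "`n_tfs` must be >= 6 (the planted module needs 5 TFs plus at least one UM TF)")
  stop_if_not(is_scalar_number(n_genes) && n_genes >= 40,
              "`n_genes` must be >= 40 to host the 35 planted core targets")
  stop_if_not(is_scalar_number(n_samples_per_condition) &&
                n_samples_per_condition >= 2,
              "`n_samples_per_condition` must be >= 2")
  stop_if_not(is_scalar_number(beta), "`beta` must be a finite number")
  stop_if_not(is_scalar_number(sigma) && sigma >= 0, "`sigma` must be >= 0")
  for (nm in c("prior_fp_rate", "prior_fn_rate", "peak_fp_rate",
               "peak_fn_rate", "censor_fraction", "tnbc_like_fraction")) {
    check_rate(get(nm), nm)
  }
  stop_if_not(is_scalar_number(hazard_ratio) && hazard_ratio > 0,
              "`hazard_ratio` must be > 0")
  stop_if_not(is_scalar_number(seed), "`seed` must be a single integer")
  structure(list(
    n_tfs = as.integer(n_tfs), n_genes = as.integer(n_genes),
    n_samples_per_condition = as.integer(n_samples_per_condition),
    beta = beta, sigma = sigma,
    prior_fp_rate = prior_fp_rate, prior_fn_rate = prior_fn_rate,
    peak_fp_rate = peak_fp_rate, peak_fn_rate = peak_fn_rate,
    hazard_ratio = hazard_ratio, censor_fraction = censor_fraction,
    tnbc_like_fraction = tnbc_like_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

## Module geometry shared by all simulators; sizes mirror the scale of the
## core findings (5 TFs / 35 co-targets) in a reduced gene universe.
MODULE_N_TFS <- 5L
MODULE_N_TARGETS <- 35L
BACKGROUND_DENSITY <- 0.20
ACTIVITY_SD <- 1
MODULE_ACTIVITY_SHIFT <- 1    # TNBC activity elevation of core TFs
UM_STEP <- 0.75               # per-condition monotone shift of UM TFs
OV_SHIFT <- 1.5               # TNBC-only shift of OV TFs
TNBC_LIKE_SHIFT <- 0.4        # core-target offset in TNBC-like nTNBC samples
PPI_MODULE_WEIGHT <- 0.15     # PPI elevation between core-module TF pairs
PPI_NOISE_SD <- 0.1           # half-normal scale of background PPI weights
PLANTED_BLOCK_TARGETS <- 30L  # targets per UM / OV planted block
BASELINE_MEAN <- 7
BASELINE_SD <- 1

#' Generate the planted ground truth
#'
#' Lays out per-condition binary TF-to-gene wiring with three planted
#' regulatory patterns and background edges identical across conditions.
#' The core module block (5 TFs x 35 targets) is wired only in TNBC; UM and
#' OV blocks are wired in all three conditions; core targets carry no
#' background edges so their regulation is exclusively module-driven.
#'
#' @param config A [sim_config()].
#' @return An object of class `planted_truth` with TF/gene identifiers,
#'   `wiring` (list of three binary TF x gene matrices), the planted TF and
#'   target sets, and the effect sizes used downstream.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_tfs <- config$n_tfs
  n_genes <- config$n_genes
  tf_ids <- sprintf("TF%02d", seq_len(n_tfs))
  gene_ids <- sprintf("G%03d", seq_len(n_genes))

  module_tfs <- tf_ids[1:MODULE_N_TFS]
  rem_tfs <- tf_ids[-(1:MODULE_N_TFS)]
  n_um_tf <- min(3L, length(rem_tfs))
  um_tfs <- rem_tfs[seq_len(n_um_tf)]
  rem_tfs <- setdiff(rem_tfs, um_tfs)
  n_ov_tf <- min(3L, length(rem_tfs))
  ov_tfs <- rem_tfs[seq_len(n_ov_tf)]

  module_targets <- gene_ids[1:MODULE_N_TARGETS]
  rem_genes <- gene_ids[-(1:MODULE_N_TARGETS)]
  ## keep at least 5 background genes free of planted targets
  room <- max(length(rem_genes) - 5L, 0L)
  n_um_tg <- min(PLANTED_BLOCK_TARGETS, room %/% 2L)
  um_targets <- rem_genes[seq_len(n_um_tg)]
  rem_genes2 <- setdiff(rem_genes, um_targets)
  n_ov_tg <- min(PLANTED_BLOCK_TARGETS, max(room - n_um_tg, 0L))
  ov_targets <- rem_genes2[seq_len(n_ov_tg)]
  if (length(ov_tfs) == 0L) ov_targets <- character(0)
  if (length(um_tfs) == 0L) um_targets <- character(0)

  planted_genes <- c(module_targets, um_targets, ov_targets)
  background_genes <- setdiff(gene_ids, planted_genes)

  wiring <- with_seed(config$seed, {
    base <- matrix(0L, n_tfs, n_genes, dimnames = list(tf_ids, gene_ids))
    bg <- matrix(stats::rbinom(n_tfs * length(background_genes), 1L,
                               BACKGROUND_DENSITY),
                 n_tfs, length(background_genes))
    base[, background_genes] <- bg
    if (length(um_tfs)) base[um_tfs, um_targets] <- 1L
    if (length(ov_tfs)) base[ov_tfs, ov_targets] <- 1L
    w <- list(NORM = base, nTNBC = base, TNBC = base)
    w$TNBC[module_tfs, module_targets] <- 1L
    w
  })

  structure(list(
    tf_ids = tf_ids, gene_ids = gene_ids, wiring = wiring,
    module_tfs = module_tfs, module_targets = module_targets,
    um_tfs = um_tfs, um_targets = um_targets,
    ov_tfs = ov_tfs, ov_targets = ov_targets,
    beta = config$beta, sigma = config$sigma,
    activity_sd = ACTIVITY_SD,
    module_activity_shift = MODULE_ACTIVITY_SHIFT,
    um_step = UM_STEP, ov_shift = OV_SHIFT,
    tnbc_like_shift = TNBC_LIKE_SHIFT,
    tnbc_like_fraction = config$tnbc_like_fraction,
    seed = config$seed
  ), class = "planted_truth")
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("Planted regulatory truth\n")
  cat(sprintf("  %d TFs, %d genes; module %d TFs x %d targets (TNBC only)\n",
              length(x$tf_ids), length(x$gene_ids),
              length(x$module_tfs), length(x$module_targets)))
  cat(sprintf("  UM: %d TFs x %d targets; OV: %d TFs x %d targets\n",
              length(x$um_tfs), length(x$um_targets),
              length(x$ov_tfs), length(x$ov_targets)))
  invisible(x)
}

## Per-TF mean activity (and, except for module TFs, mean expression shift)
## in each condition.
tf_condition_means <- function(truth) {
  mu <- matrix(0, length(truth$tf_ids), 3,
               dimnames = list(truth$tf_ids, CONDITIONS))
  if (length(truth$um_tfs)) {
    mu[truth$um_tfs, ] <- rep(c(0, truth$um_step, 2 * truth$um_step),
                              each = length(truth$um_tfs))
  }
  if (length(truth$ov_tfs)) {
    mu[truth$ov_tfs, "TNBC"] <- truth$ov_shift
  }
  act <- mu
  act[truth$module_tfs, "TNBC"] <- truth$module_activity_shift
  list(activity = act, expression = mu)
}

#' Simulate the expression matrix
#'
#' Linear-Gaussian activity model.  For sample `s` in condition `c`, TF `t`
#' has latent activity `a[t,s] ~ N(mu[t,c], 1)`; its own expression is
#' `baseline + shift[t,c] + N(0, sigma^2)` where the shift is zero for core
#' module TFs in every condition (activation without expression change).
#' A target gene's expression is
#' `baseline + beta * sum_t wiring_c[t,g] * a[t,s] + N(0, sigma^2)`.
#' A planted fraction of nTNBC samples ("TNBC-like") additionally receives
#' a constant `beta * 0.7` offset on the core targets, giving the
#' stratification stage a recoverable subgroup without making the core
#' targets differentially expressed between NORM and nTNBC.
#'
#' @param truth A [generate_truth()] result.
#' @param config The matching [sim_config()].
#' @return An [expression_matrix()] over all TFs and genes, with attributes
#'   `sample_groups` (NORM / nTNBC-other / nTNBC-TNBC-like / TNBC),
#'   `activities` (per-condition TF x sample latent activity matrices) and
#'   `baseline` (per-row baseline means).
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "sim_config"))
  stop_if_not(config$sigma >= 0, "`sigma` must be >= 0")
  n <- config$n_samples_per_condition
  tf_ids <- truth$tf_ids
  gene_ids <- truth$gene_ids
  beta <- config$beta
  sigma <- config$sigma
  mu <- tf_condition_means(truth)

  with_seed(config$seed + 1L, {
    baseline <- stats::rnorm(length(tf_ids) + length(gene_ids),
                             BASELINE_MEAN, BASELINE_SD)
    names(baseline) <- c(tf_ids, gene_ids)

    sample_ids <- unlist(lapply(CONDITIONS, function(cc)
      sprintf("%s_%03d", cc, seq_len(n))))
    condition <- stats::setNames(rep(CONDITIONS, each = n), sample_ids)

    ## planted TNBC-like nTNBC subgroup
    ntnbc_samples <- sample_ids[condition == "nTNBC"]
    n_like <- round(config$tnbc_like_fraction * length(ntnbc_samples))
    tnbc_like <- sort(sample(ntnbc_samples, n_like))
    groups <- ifelse(condition == "nTNBC",
                     ifelse(sample_ids %in% tnbc_like,
                            "nTNBC-TNBC-like", "nTNBC-other"),
                     condition)
    names(groups) <- sample_ids

    values <- matrix(NA_real_, length(baseline), length(sample_ids),
                     dimnames = list(names(baseline), sample_ids))
    activities <- list()
    for (cc in CONDITIONS) {
      sc <- sample_ids[condition == cc]
      a <- matrix(stats::rnorm(length(tf_ids) * n, mean = mu$activity[, cc],
                               sd = truth$activity_sd),
                  length(tf_ids), n, dimnames = list(tf_ids, sc))
      activities[[cc]] <- a
      ## TF expression
      values[tf_ids, sc] <- baseline[tf_ids] + mu$expression[, cc] +
        matrix(stats::rnorm(length(tf_ids) * n, 0, sigma), ncol = n)
      ## gene expression
      reg <- beta * crossprod(truth$wiring[[cc]], a)   # gene x sample
      values[gene_ids, sc] <- baseline[gene_ids] + reg +
        matrix(stats::rnorm(length(gene_ids) * n, 0, sigma), ncol = n)
    }
    if (length(tnbc_like)) {
      values[truth$module_targets, tnbc_like] <-
        values[truth$module_targets, tnbc_like] + beta * truth$tnbc_like_shift
    }
    expr <- expression_matrix(values, condition)
    attr(expr, "sample_groups") <- groups
    attr(expr, "activities") <- activities
    attr(expr, "baseline") <- baseline
    expr
  })
}

#' Simulate the motif prior and the TF-TF PPI matrix
#'
#' The prior is the union over conditions of the true wiring with each 1
#' dropped with probability `prior_fn_rate` and each 0 added with
#' probability `prior_fp_rate`.  The PPI matrix is symmetric with unit
#' diagonal, small positive background weights, and elevated weight between
#' core-module TF pairs.
#'
#' @inheritParams simulate_expression
#' @return A list with elements `prior` (binary TF x gene matrix) and
#'   `ppi` (symmetric TF x TF matrix).
#' @export
simulate_prior_ppi <- function(truth, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "sim_config"))
  union_w <- pmax(truth$wiring$NORM, truth$wiring$nTNBC, truth$wiring$TNBC)
  with_seed(config$seed + 2L, {
    flip_to_0 <- matrix(stats::runif(length(union_w)) < config$prior_fn_rate,
                        nrow(union_w))
    flip_to_1 <- matrix(stats::runif(length(union_w)) < config$prior_fp_rate,
                        nrow(union_w))
    prior <- union_w
    prior[union_w == 1L & flip_to_0] <- 0L
    prior[union_w == 0L & flip_to_1] <- 1L
    dimnames(prior) <- dimnames(union_w)

    k <- length(truth$tf_ids)
    ppi <- matrix(0, k, k, dimnames = list(truth$tf_ids, truth$tf_ids))
    noise <- matrix(abs(stats::rnorm(k * k, 0, PPI_NOISE_SD)), k, k)
    ppi[upper.tri(ppi)] <- noise[upper.tri(noise)]
    ppi[truth$module_tfs, truth$module_tfs] <-
      ppi[truth$module_tfs, truth$module_tfs] + PPI_MODULE_WEIGHT
    ppi[lower.tri(ppi)] <- t(ppi)[lower.tri(ppi)]
    diag(ppi) <- 1
    list(prior = prior, ppi = ppi)
  })
}

#' Deterministic gene annotation for the synthetic genome
#'
#' Places every gene on a single synthetic chromosome with TSS spaced
#' 10 kb apart and alternating strands, so promoter windows never overlap.
#'
#' @param truth A [generate_truth()] result.
#' @return A `data.frame` with columns `gene`, `chrom`, `tss`, `strand`.
#' @export
simulate_annotation <- function(truth) {
  stopifnot(inherits(truth, "planted_truth"))
  genes <- truth$gene_ids
  data.frame(
    gene = genes,
    chrom = "chrS1",
    tss = 5000L + (seq_along(genes) - 1L) * 10000L,
    strand = rep(c("+", "-"), length.out = length(genes)),
    stringsAsFactors = FALSE
  )
}

#' Simulate ChIP-seq-like peak collections
#'
#' For every cell line and every TNBC-wired (TF, gene) pair, a 100 bp peak
#' is placed inside the gene's promoter window with probability
#' `1 - peak_fn_rate`; unwired pairs gain a spurious promoter peak with
#' probability `peak_fp_rate`.  Intervals are 0-based half-open.
#'
#' @inheritParams simulate_expression
#' @param annotation Gene annotation as returned by [simulate_annotation()].
#' @param n_cell_lines Number of synthetic cell lines.
#' @return Named list (one element per cell line) of `data.frame`s with
#'   columns `chrom`, `start`, `end`, `name` (TF:cell_line) and `tf`.
#' @export
simulate_peaks <- function(truth, annotation, n_cell_lines = 8L, config) {
  stopifnot(inherits(truth, "planted_truth"), inherits(config, "sim_config"))
  stop_if_not(all(truth$gene_ids %in% annotation$gene),
              "annotation must cover all gene_ids")
  win <- promoter_windows(annotation)
  wired <- truth$wiring$TNBC
  with_seed(config$seed + 3L, {
    lines <- sprintf("CL%02d", seq_len(n_cell_lines))
    out <- lapply(lines, function(cl) {
      keep_true <- wired == 1L &
        matrix(stats::runif(length(wired)) >= config$peak_fn_rate, nrow(wired))
      add_false <- wired == 0L &
        matrix(stats::runif(length(wired)) < config$peak_fp_rate, nrow(wired))
      hits <- which(keep_true | add_false, arr.ind = TRUE)
      if (nrow(hits) == 0L) {
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          tf = character(0), stringsAsFactors = FALSE))
      }
      tf <- rownames(wired)[hits[, 1]]
      gene <- colnames(wired)[hits[, 2]]
      w <- win[match(gene, win$gene), ]
      width <- 100L
      slack <- pmax(w$end - w$start - width, 1L)
      start <- w$start + floor(stats::runif(nrow(hits)) * slack)
      data.frame(chrom = w$chrom, start = as.integer(start),
                 end = as.integer(start + width),
                 name = paste(tf, cl, sep = ":"), tf = tf,
                 stringsAsFactors = FALSE)
    })
    stats::setNames(out, lines)
  })
}

#' Simulate survival records
#'
#' Event times are exponential with baseline hazard `baseline_hazard`
#' (per month); samples in `poor_groups` have their hazard multiplied by
#' `hazard_ratio`.  Each record is independently censored with probability
#' `censor_fraction`, at a uniform time before its event.
#'
#' @param sample_groups Named character vector mapping sample id to group.
#' @param config A [sim_config()]; uses `hazard_ratio`, `censor_fraction`
#'   and `seed`.
#' @param poor_groups Group labels whose hazard is multiplied.
#' @param baseline_hazard Events per month in the reference groups.
#' @return A `data.frame` with columns `sample`, `time` (months), `event`
#'   (1 = event, 0 = censored) and `group`.
#' @export
simulate_survival <- function(sample_groups, config,
                              poor_groups = c("TNBC", "nTNBC-TNBC-like"),
                              baseline_hazard = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  stop_if_not(length(sample_groups) > 0 && !is.null(names(sample_groups)),
              "`sample_groups` must be a non-empty named vector")
  stop_if_not(all(nzchar(sample_groups)), "empty group labels")
  with_seed(config$seed + 4L, {
    rate <- baseline_hazard *
      ifelse(sample_groups %in% poor_groups, config$hazard_ratio, 1)
    t_event <- stats::rexp(length(rate), rate)
    censored <- stats::runif(length(rate)) < config$censor_fraction
    time <- ifelse(censored, stats::runif(length(rate)) * t_event, t_event)
    data.frame(sample = names(sample_groups), time = time,
               event = as.integer(!censored),
               group = unname(sample_groups), stringsAsFactors = FALSE)
  })
}
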