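## End-to-end orchestration on synthetic or user-supplied inputs.

#' Pipeline configuration
#'
#' Gathers the analysis constants in one place: the message-passing update
#' rate (0.25), the edge FDR (0.05), the differential-expression FDR
#' (0.1), the network-walking thresholds (more than 10 core hits for
#' intermediators, more than 20 intermediators for neighbors), the
#' ChIP common-target rule (more than 5 cell lines) and the clustering
#' k values (3 for the three-condition view, 2 for the nTNBC split).
#'
#' @param sim A [sim_config()] describing the synthetic cohort.
#' @param alpha Message-passing update rate.
#' @param fdr_edges Edge significance FDR.
#' @param fdr_de Differential-expression FDR.
#' @param t_inter,t_neigh Network-walking thresholds.
#' @param min_lines ChIP common-target threshold (strictly more than).
#' @param n_cell_lines Number of synthetic ChIP cell lines.
#' @param k Number of clusters for the all-sample view.
#' @param max_iter,tol Message-passing iteration controls.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 0.25,
                            fdr_edges = 0.05, fdr_de = 0.1,
                            t_inter = 10, t_neigh = 20, min_lines = 5,
                            n_cell_lines = 8L, k = 3L,
                            max_iter = 200L, tol = 1e-3) {
  stopifnot(inherits(sim, "sim_config"))
  for (nm in c("fdr_edges", "fdr_de")) check_rate(get(nm), nm)
  stop_if_not(t_inter >= 0 && t_neigh >= 0 && min_lines >= 0,
              "thresholds must be nonnegative")
  structure(list(sim = sim, alpha = alpha, fdr_edges = fdr_edges,
                 fdr_de = fdr_de, t_inter = t_inter, t_neigh = t_neigh,
                 min_lines = min_lines, n_cell_lines = as.integer(n_cell_lines),
                 k = as.integer(k), max_iter = as.integer(max_iter),
                 tol = tol),
            class = "pipeline_config")
}

#' Run the full analysis on a simulated cohort
#'
#' Generates the planted cohort, infers the three condition networks,
#' computes pairwise differential expression, classifies edges into
#' regulatory patterns, discovers TNBCac co-regulation modules, extends
#' the largest module's core by network walking, validates each TF's edge
#' ranking against simulated ChIP peaks, builds the core signature,
#' splits nTNBC into TNBC-like and other, and compares their survival.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there as plain-text files.
#' @param stages Character subset of
#'   `c("modules", "chip", "stratify")` allowing expensive stages to be
#'   skipped; network inference, DE and pattern classification always run.
#' @return A `pipeline_report` list with per-stage results and summary
#'   numbers.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         stages = c("modules", "chip", "stratify")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- cfg$sim
  truth <- generate_truth(sim)
  expr <- simulate_expression(truth, sim)
  pp <- simulate_prior_ppi(truth, sim)
  ann <- simulate_annotation(truth)

  pcfg <- panda_config(alpha = cfg$alpha, tol = cfg$tol,
                       max_iter = cfg$max_iter)
  nets <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(cc)
    panda(pp$prior, pp$ppi, expr, cc, pcfg, fdr = cfg$fdr_edges))
  overlap <- network_overlap(nets)

  de <- pairwise_de(expr, fdr_de = cfg$fdr_de)
  pa <- classify_edges(nets, de)
  psum <- pattern_summary(pa)

  report <- list(
    config = cfg, truth = truth, networks = nets, overlap = overlap,
    de = de, patterns = pa, pattern_summary = psum
  )

  if ("modules" %in% stages) {
    modules <- find_modules(pa, "TNBCac",
                            universe_size = length(truth$gene_ids),
                            fdr = 0.05)
    report$modules <- modules
    if (length(modules) > 0) {
      largest <- modules[[1]]
      report$largest_module <- largest
      report$extended <- extend_core(largest$shared_targets, nets$TNBC,
                                     t_inter = cfg$t_inter,
                                     t_neigh = cfg$t_neigh)
      report$module_recovery <- list(
        tf_match = setequal(largest$tfs, truth$module_tfs),
        target_fraction = length(intersect(largest$shared_targets,
                                           truth$module_targets)) /
          length(truth$module_targets)
      )
    }
  }

  if ("chip" %in% stages) {
    peaks <- simulate_peaks(truth, ann, cfg$n_cell_lines, sim)
    win <- promoter_windows(ann)
    tf_aucs <- vapply(truth$tf_ids, function(tf) {
      per_line <- lapply(peaks, peak_targets, windows = win, tf = tf)
      common <- common_targets(per_line, min_lines = cfg$min_lines)
      scores <- nets$TNBC$z[tf, ]
      if (length(common) == 0 || length(common) == length(scores)) {
        return(NA_real_)
      }
      rank_roc(scores, common)$auc
    }, numeric(1))
    report$chip <- list(per_tf_auc = tf_aucs,
                        median_auc = stats::median(tf_aucs, na.rm = TRUE))
  }

  if ("stratify" %in% stages) {
    core <- if (!is.null(report$largest_module)) {
      report$largest_module$shared_targets
    } else {
      truth$module_targets
    }
    sig <- build_signature(core, nets$TNBC, expr, t_inter = cfg$t_inter)
    clusters <- kmeans_cluster(sig, k = cfg$k, seed = sim$seed)
    split <- tnbc_like_split(sig, seed = sim$seed)
    groups <- attr(expr, "sample_groups")
    surv_groups <- groups
    surv <- simulate_survival(surv_groups, sim)
    nt <- surv[surv$sample %in% names(split), ]
    nt$group <- unname(split[nt$sample])
    lr <- logrank(nt)
    report$stratification <- list(
      signature_genes = rownames(sig), clusters = clusters,
      split = split, survival = surv, logrank = lr,
      split_agreement = mean(
        (split == "TNBC-like") ==
          (groups[names(split)] == "nTNBC-TNBC-like"))
    )
  }

  ## planted-edge recovery of the TNBC network
  report$edge_auc <- rank_roc(
    stats::setNames(as.vector(nets$TNBC$z),
                    paste(rep(rownames(nets$TNBC$z), ncol(nets$TNBC$z)),
                          rep(colnames(nets$TNBC$z),
                              each = nrow(nets$TNBC$z)), sep = "->")),
    paste(rep(rownames(nets$TNBC$z), ncol(nets$TNBC$z)),
          rep(colnames(nets$TNBC$z), each = nrow(nets$TNBC$z)),
          sep = "->")[as.vector(truth$wiring$TNBC == 1L)])$auc

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Regulatory-pattern pipeline report\n")
  cat(sprintf("  significant edges: %s\n",
              paste(sprintf("%s=%d", names(x$networks),
                            vapply(x$networks, function(n)
                              sum(n$significant), 0L)), collapse = ", ")))
  cat(sprintf("  shared edge fraction: %.3f\n", x$overlap$shared_fraction))
  cat(sprintf("  pattern edges: %s\n",
              paste(sprintf("%s=%d", names(x$pattern_summary$edge_counts),
                            x$pattern_summary$edge_counts), collapse = ", ")))
  if (!is.null(x$largest_module)) {
    cat(sprintf("  largest TNBCac module: %d TFs, %d shared targets (recovered %.0f%% of planted targets)\n",
                length(x$largest_module$tfs),
                length(x$largest_module$shared_targets),
                100 * x$module_recovery$target_fraction))
  }
  if (!is.null(x$chip)) {
    cat(sprintf("  ChIP validation median AUC: %.3f\n", x$chip$median_auc))
  }
  if (!is.null(x$stratification)) {
    cat(sprintf("  TNBC-like vs other nTNBC log-rank p: %.3g\n",
                x$stratification$logrank$p))
  }
  cat(sprintf("  TNBC edge-ranking AUC vs planted wiring: %.3f\n",
              x$edge_auc))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (cc in names(report$networks)) {
    write_edge_list(report$networks[[cc]],
                    file.path(out_dir, sprintf("network_%s.tsv", cc)))
  }
  utils::write.table(report$de, file.path(out_dir, "de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- report$patterns$labels
  pat <- data.frame(tf = rep(rownames(lab), ncol(lab)),
                    gene = rep(colnames(lab), each = nrow(lab)),
                    label = as.vector(lab))
  utils::write.table(pat[pat$label != "none", ],
                     file.path(out_dir, "patterns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$modules)) {
    mods <- do.call(rbind, lapply(report$modules, function(m)
      data.frame(tfs = paste(m$tfs, collapse = ","),
                 n_targets = length(m$shared_targets), p = m$p, q = m$q)))
    utils::write.table(mods, file.path(out_dir, "modules.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$stratification)) {
    write_survival_tsv(report$stratification$survival,
                       file.path(out_dir, "survival.tsv"))
    utils::write.table(
      data.frame(sample = names(report$stratification$split),
                 subgroup = unname(report$stratification$split)),
      file.path(out_dir, "ntnbc_split.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Write the complete synthetic input set to disk
#'
#' Materializes every pipeline input as plain text: expression matrix and
#' condition labels, motif prior, PPI, per-cell-line peak BED files, gene
#' annotation, survival table and the planted-truth JSON.
#'
#' @param cfg A [pipeline_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
make_fixtures <- function(cfg = pipeline_config(), dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- cfg$sim
  truth <- generate_truth(sim)
  expr <- simulate_expression(truth, sim)
  pp <- simulate_prior_ppi(truth, sim)
  ann <- simulate_annotation(truth)
  peaks <- simulate_peaks(truth, ann, cfg$n_cell_lines, sim)
  surv <- simulate_survival(attr(expr, "sample_groups"), sim)

  paths <- c(
    expr = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "sample_conditions.tsv"),
    prior = file.path(dir, "motif_prior.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    annotation = file.path(dir, "gene_annotation.tsv"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "planted_truth.json")
  )
  write_expression_tsv(expr, paths["expr"], paths["labels"])
  write_matrix_tsv(pp$prior, paths["prior"])
  write_matrix_tsv(pp$ppi, paths["ppi"])
  write_annotation_tsv(ann, paths["annotation"])
  write_survival_tsv(surv, paths["survival"])
  write_truth_json(truth, paths["truth"])
  peak_paths <- vapply(names(peaks), function(cl) {
    p <- file.path(dir, sprintf("peaks_%s.bed", cl))
    write_bed(peaks[[cl]], p)
    p
  }, "")
  invisible(c(paths, peak_paths))
}
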