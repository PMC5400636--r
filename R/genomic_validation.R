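## Promoter-window target calling, PWM scanning with exact score
## p-values, and ROC validation of edge rankings.
##
## Coordinates are 0-based half-open (BED-native) throughout.

#' Position weight matrix
#'
#' @param m Numeric 4 x L matrix of base probabilities in A, C, G, T row
#'   order; every column must sum to 1 (tolerance 1e-6) and contain at
#'   least one positive entry.
#' @param id Motif identifier.
#' @return A validated `pwm` object.
#' @export
pwm <- function(m, id = "motif") {
  stop_if_not(is.matrix(m) && nrow(m) == 4 && ncol(m) >= 1,
              "`m` must be a 4 x L matrix")
  stop_if_not(all(m >= 0), "probabilities must be nonnegative")
  stop_if_not(all(abs(colSums(m) - 1) <= 1e-6),
              "every PWM column must sum to 1")
  stop_if_not(all(colSums(m) > 0), "degenerate all-zero PWM column")
  rownames(m) <- c("A", "C", "G", "T")
  structure(m, id = id, class = c("pwm", "matrix"))
}

## Log-odds scores (log2, probabilities floored at 1e-10) and their
## integer discretization on a fixed 1e-3 score-unit grid.  All p-values
## and scans operate on the discretized scores, which makes the dynamic
## program exact for the documented score definition.
PWM_GRANULARITY <- 1e-3
PWM_PROB_FLOOR <- 1e-10

pwm_score_ints <- function(pwm, background) {
  s <- log2(pmax(unclass(pwm), PWM_PROB_FLOOR) /
              matrix(background, 4, ncol(pwm)))
  round(s / PWM_GRANULARITY)
}

## Exact distribution of the discretized score of an iid-background word:
## list(support = integer grid values, prob = probabilities).
pwm_score_distribution <- function(pwm, background = rep(0.25, 4)) {
  stop_if_not(abs(sum(background) - 1) <= 1e-6 && all(background > 0),
              "`background` must be positive and sum to 1")
  ints <- pwm_score_ints(pwm, background)
  dist <- 1
  base <- 0
  for (j in seq_len(ncol(ints))) {
    lo <- min(ints[, j]); hi <- max(ints[, j])
    new <- numeric(length(dist) + hi - lo)
    for (b in 1:4) {
      sh <- ints[b, j] - lo
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[b]
    }
    base <- base + lo
    dist <- new
  }
  list(support = base + seq_along(dist) - 1L, prob = dist)
}

#' Exact p-value of a PWM log-odds score
#'
#' Probability that a random word drawn from the iid background scores at
#' least `score` under the motif's log2 odds scoring (probabilities
#' floored at 1e-10, scores discretized to a 1e-3 score-unit grid).
#' Computed by dynamic programming over the exact discretized score
#' distribution.
#'
#' @param pwm A [pwm()].
#' @param score Score threshold in log2-odds units.
#' @param background Base probabilities (A, C, G, T), summing to 1.
#' @return `P(word score >= score)`; 1 whenever `score` is at or below the
#'   minimum achievable score.
#' @export
pwm_site_pvalue <- function(pwm, score, background = rep(0.25, 4)) {
  d <- pwm_score_distribution(pwm, background)
  thr <- ceiling(score / PWM_GRANULARITY - 1e-9)
  sum(d$prob[d$support >= thr])
}

#' Discretized log-odds score of a single word
#'
#' @inheritParams pwm_site_pvalue
#' @param word Character string over A/C/G/T of the motif's length.
#' @return Score in log2-odds units, on the same 1e-3 grid used by
#'   [pwm_site_pvalue()]; `NA` if the word contains other letters.
#' @export
pwm_word_score <- function(pwm, word, background = rep(0.25, 4)) {
  ints <- pwm_score_ints(pwm, background)
  codes <- match(strsplit(toupper(word), "")[[1]], c("A", "C", "G", "T"))
  stop_if_not(length(codes) == ncol(ints),
              "word length must equal the motif length")
  if (anyNA(codes)) return(NA_real_)
  sum(ints[cbind(codes, seq_along(codes))]) * PWM_GRANULARITY
}

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(seq, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

scan_one_strand <- function(codes, ints, thr_v) {
  L <- ncol(ints)
  n <- length(codes)
  if (n < L) return(FALSE)
  for (k in seq_len(n - L + 1L)) {
    w <- codes[k:(k + L - 1L)]
    if (anyNA(w)) next                      # windows containing N skipped
    if (sum(ints[cbind(w, seq_len(L))]) >= thr_v) return(TRUE)
  }
  FALSE
}

#' Scan promoter sequences for motif sites
#'
#' A gene is called a target when at least one window, on either strand,
#' reaches the minimal score whose exact p-value (see
#' [pwm_site_pvalue()]) is below `p_thresh`.  Windows containing `N` are
#' skipped; sequences shorter than the motif score 0.
#'
#' @param sequences Named character vector of promoter sequences over
#'   A/C/G/T/N.
#' @param pwm A [pwm()].
#' @param p_thresh Site-level p-value threshold (default 1e-5).
#' @param background Base probabilities (A, C, G, T).
#' @return Named integer vector (0/1), one motif-prior row.
#' @export
pwm_scan <- function(sequences, pwm, p_thresh = 1e-5,
                     background = rep(0.25, 4)) {
  stop_if_not(length(sequences) > 0 && !is.null(names(sequences)),
              "`sequences` must be a named character vector")
  d <- pwm_score_distribution(pwm, background)
  tail_p <- rev(cumsum(rev(d$prob)))
  attainable <- which(tail_p < p_thresh)
  ints <- pwm_score_ints(pwm, background)
  out <- stats::setNames(integer(length(sequences)), names(sequences))
  if (length(attainable) == 0) return(out)   # threshold unreachable
  thr_v <- d$support[attainable[1]]
  letters4 <- c("A", "C", "G", "T")
  for (g in names(sequences)) {
    fwd <- match(strsplit(toupper(sequences[[g]]), "")[[1]], letters4)
    rev_codes <- match(strsplit(revcomp(toupper(sequences[[g]])), "")[[1]],
                       letters4)
    hit <- scan_one_strand(fwd, ints, thr_v) ||
      scan_one_strand(rev_codes, ints, thr_v)
    out[g] <- as.integer(hit)
  }
  out
}

#' Strand-aware promoter windows around the TSS
#'
#' For a gene on the plus strand the window is `[tss - up, tss + down)`;
#' on the minus strand `[tss - down, tss + up)`; starts are clipped at 0.
#'
#' @param ann Annotation `data.frame` with columns `gene`, `chrom`, `tss`,
#'   `strand`.
#' @param up,down Bases upstream / downstream of the TSS (defaults 750 and
#'   250).
#' @return `data.frame(gene, chrom, start, end)` in 0-based half-open
#'   coordinates.
#' @export
promoter_windows <- function(ann, up = 750, down = 250) {
  stop_if_not(all(c("gene", "chrom", "tss", "strand") %in% names(ann)),
              "annotation needs gene, chrom, tss, strand columns")
  stop_if_not(all(ann$strand %in% c("+", "-")), "strand must be + or -")
  stop_if_not(all(ann$tss >= 0), "tss must be nonnegative")
  plus <- ann$strand == "+"
  start <- ifelse(plus, ann$tss - up, ann$tss - down)
  end <- ifelse(plus, ann$tss + down, ann$tss + up)
  data.frame(gene = ann$gene, chrom = ann$chrom,
             start = pmax(start, 0), end = pmax(end, 0),
             stringsAsFactors = FALSE)
}

#' Genes whose promoter window overlaps at least one peak
#'
#' Half-open interval overlap of at least 1 bp on the same chromosome.
#'
#' @param peaks `data.frame` with `chrom`, `start`, `end` and optionally
#'   `tf` columns (0-based half-open).
#' @param windows Promoter windows from [promoter_windows()].
#' @param tf When given and the peaks carry TF labels, only that TF's
#'   peaks are considered.
#' @return Character vector of target genes.
#' @export
peak_targets <- function(peaks, windows, tf = NULL) {
  if (!is.null(tf) && "tf" %in% names(peaks)) {
    peaks <- peaks[peaks$tf == tf, , drop = FALSE]
  }
  if (nrow(peaks) == 0) return(character(0))
  hit <- vapply(seq_len(nrow(windows)), function(i) {
    same <- peaks$chrom == windows$chrom[i]
    any(same & peaks$start < windows$end[i] & peaks$end > windows$start[i])
  }, logical(1))
  windows$gene[hit]
}

#' Common targets across cell lines
#'
#' @param per_line_targets Named list: cell line to target gene set.
#' @param min_lines A gene is common when present in strictly more than
#'   `min_lines` cell lines (default 5, i.e. at least 6).
#' @return Character vector of common target genes.
#' @export
common_targets <- function(per_line_targets, min_lines = 5) {
  stop_if_not(length(per_line_targets) >= 1, "need at least one cell line")
  counts <- table(unlist(lapply(per_line_targets, unique)))
  names(counts)[counts > min_lines]
}

#' ROC analysis of an edge-score ranking against a positive gene set
#'
#' AUC is the Mann-Whitney concordance probability (ties count one half);
#' the curve gives TPR/FPR at every distinct threshold and the decile
#' histogram bins the positives' rank positions (rank 1 = best score)
#' into tenths of the gene list.
#'
#' @param scores Named numeric vector, e.g. one TF's Z-score row.
#' @param positives Gene set; must be a subset of `names(scores)` and
#'   leave both classes nonempty.
#' @return List with `auc`, `curve` (`data.frame(threshold, tpr, fpr)`)
#'   and `decile_counts` (length-10 integer vector).
#' @export
rank_roc <- function(scores, positives) {
  stop_if_not(!is.null(names(scores)), "`scores` must be named")
  stop_if_not(all(positives %in% names(scores)),
              "`positives` must be scored genes")
  lab <- names(scores) %in% positives
  stop_if_not(any(lab) && any(!lab),
              "AUC undefined: need both positives and negatives")
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(lab); n_neg <- sum(!lab)
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(scores, decreasing = TRUE)
  lab_o <- lab[ord]
  sc_o <- scores[ord]
  keep <- !duplicated(sc_o, fromLast = TRUE) | !duplicated(sc_o)
  tp <- cumsum(lab_o); fp <- cumsum(!lab_o)
  last <- which(!duplicated(sc_o, fromLast = TRUE))
  curve <- data.frame(threshold = sc_o[last],
                      tpr = tp[last] / n_pos, fpr = fp[last] / n_neg)

  pct <- (rank(-scores, ties.method = "average") - 0.5) / length(scores)
  decile <- cut(pct[lab], breaks = seq(0, 1, 0.1), labels = FALSE,
                include.lowest = TRUE)
  decile_counts <- tabulate(decile, nbins = 10)
  list(auc = auc, curve = curve, decile_counts = decile_counts)
}
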