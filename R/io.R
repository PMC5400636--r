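## Containers and plain-text readers/writers.
##
## All tabular formats are TSV; peak intervals are BED (0-based,
## half-open); the planted truth round-trips through JSON.

#' Expression matrix with condition labels
#'
#' @param values Numeric genes x samples matrix with row and column names.
#' @param condition Named character vector mapping every sample to one of
#'   `NORM`, `nTNBC`, `TNBC` (names may be omitted if in column order).
#' @return An object of class `expression_matrix`: the matrix itself with
#'   a `condition` attribute.
#' @export
expression_matrix <- function(values, condition) {
  stop_if_not(is.matrix(values) && is.numeric(values),
              "`values` must be a numeric matrix")
  stop_if_not(all(is.finite(values)), "expression values must be finite")
  stop_if_not(!is.null(rownames(values)) && !anyDuplicated(rownames(values)),
              "rows must carry unique gene ids")
  stop_if_not(!is.null(colnames(values)) && !anyDuplicated(colnames(values)),
              "columns must carry unique sample ids")
  if (is.null(names(condition))) {
    stop_if_not(length(condition) == ncol(values),
                "`condition` must label every sample")
    names(condition) <- colnames(values)
  }
  stop_if_not(all(colnames(values) %in% names(condition)),
              "every sample must be labeled in `condition`")
  condition <- condition[colnames(values)]
  structure(values, condition = condition, class = c("expression_matrix", "matrix"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cond <- attr(x, "condition")
  cat(sprintf("expression_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s=%d", names(table(cond)), table(cond)),
                    collapse = ", ")))
  invisible(x)
}

conditions_of <- function(expr) attr(expr, "condition")

#' Write / read an expression matrix as TSV plus a sample-label sidecar
#'
#' The matrix file has genes as rows and a header of sample ids; the
#' sidecar has columns `sample` and `condition`.
#'
#' @param expr An [expression_matrix()].
#' @param path,labels_path Paths for the matrix and the sidecar TSV.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an [expression_matrix()].
#' @export
write_expression_tsv <- function(expr, path, labels_path) {
  utils::write.table(data.frame(gene = rownames(expr),
                                as.data.frame(unclass(expr)),
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(expr),
                                condition = unname(conditions_of(expr))),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, labels_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  lab <- utils::read.table(labels_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  expression_matrix(values, stats::setNames(lab$condition, lab$sample))
}

#' Write / read a named numeric matrix (prior, PPI, wiring) as TSV
#'
#' @param m Matrix with row and column names.
#' @param path File path.
#' @return The matrix (reader) or `path` invisibly (writer).
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(data.frame(id = rownames(m), as.data.frame(m),
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Write / read peak intervals as BED (0-based half-open)
#'
#' Three to six columns are tolerated on read; the fourth column, when
#' present, is kept as `name` and any `TF:cellline` prefix is split into a
#' `tf` column.
#'
#' @param peaks `data.frame` with `chrom`, `start`, `end` and optional
#'   `name` columns.
#' @param path File path.
#' @return Reader: a `data.frame(chrom, start, end, name, tf)`.
#' @export
write_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(peaks))
  utils::write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  stop_if_not(ncol(tab) >= 3, "BED needs at least chrom, start, end")
  tab <- tab[, seq_len(min(ncol(tab), 6L)), drop = FALSE]
  names(tab) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(tab))]
  stop_if_not(all(tab$start < tab$end), "BED intervals need start < end")
  if (is.null(tab$name)) tab$name <- NA_character_
  tab$tf <- sub(":.*$", "", tab$name)
  tab[, c("chrom", "start", "end", "name", "tf")]
}

#' Write / read the gene annotation table (gene, chrom, tss, strand)
#' @param ann Annotation `data.frame`.
#' @param path File path.
#' @export
write_annotation_tsv <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stop_if_not(all(c("gene", "chrom", "tss", "strand") %in% names(ann)),
              "annotation needs gene, chrom, tss, strand columns")
  ann
}

#' Write / read survival records (sample, time, event, group)
#' @param records Survival `data.frame`.
#' @param path File path.
#' @export
write_survival_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  rec <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stop_if_not(all(c("sample", "time", "event", "group") %in% names(rec)),
              "survival table needs sample, time, event, group columns")
  rec
}

#' Round-trip the planted truth through JSON
#' @param truth A [generate_truth()] result.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- unclass(truth)
  obj$wiring <- lapply(obj$wiring, function(w)
    list(tf = rownames(w), gene = colnames(w), values = unname(w)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$wiring <- lapply(obj$wiring, function(w) {
    m <- matrix(as.integer(w$values), length(w$tf), length(w$gene),
                dimnames = list(w$tf, w$gene))
    m
  })
  for (nm in c("module_tfs", "module_targets", "um_tfs", "um_targets",
               "ov_tfs", "ov_targets", "tf_ids", "gene_ids")) {
    obj[[nm]] <- as.character(obj[[nm]])
  }
  structure(obj, class = "planted_truth")
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name <tab> description <tab> gene...`.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}

#' Read promoter sequences from a FASTA file
#'
#' @param path FASTA file; record names are gene ids.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(toupper(as.character(seqs)),
                           sub("\\s.*$", "", names(seqs))))
  }
  lines <- readLines(path)
  idx <- grepl("^>", lines)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[idx]))
  grp <- cumsum(idx)
  seqs <- vapply(split(lines[!idx], grp[!idx]),
                 function(x) toupper(paste(x, collapse = "")), "")
  stats::setNames(unname(seqs), ids)
}

#' Read JASPAR-style position weight matrices
#'
#' Parses the four-row `A [ ... ]` text layout (counts or probabilities);
#' counts are converted to column probabilities.
#'
#' @param path JASPAR text file with `>id name` headers.
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  stop_if_not(length(starts) > 0, "no PWM records found")
  out <- lapply(seq_along(starts), function(i) {
    from <- starts[i] + 1L
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    rows <- lapply(block[seq_len(4)], function(l) {
      body <- sub("^\\s*[ACGTacgt]", "", l)
      as.numeric(regmatches(body, gregexpr("[0-9.eE+-]+", body))[[1]])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    m <- sweep(m, 2, colSums(m), "/")
    id <- sub("^>\\s*", "", lines[starts[i]])
    pwm(m, id = strsplit(id, "\\s+")[[1]][1])
  })
  names(out) <- vapply(out, function(p) attr(p, "id"), "")
  out
}

#' Write a significant-edge list as TSV
#'
#' @param net A [panda()] network.
#' @param path File path.
#' @param only_significant Drop non-significant edges when `TRUE`.
#' @export
write_edge_list <- function(net, path, only_significant = FALSE) {
  stopifnot(inherits(net, "panda_network"))
  df <- data.frame(
    tf = rep(rownames(net$z), times = ncol(net$z)),
    gene = rep(colnames(net$z), each = nrow(net$z)),
    condition = net$condition,
    z = as.vector(net$z), p = as.vector(net$pvalues),
    q = as.vector(net$qvalues), significant = as.vector(net$significant),
    stringsAsFactors = FALSE
  )
  if (only_significant) df <- df[df$significant, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
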