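# Depth normalization and log-scale heatmap matrices for the developmental
# opsin expression series.

#' Construct a gene-by-sample count matrix
#'
#' @param counts Numeric matrix, genes in rows, samples in columns, with
#'   dimnames; counts must be non-negative.
#' @param normalized Whether the columns have already been depth-normalized.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, normalized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, normalized = normalized),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples", if (x$normalized) " (depth-normalized)", "\n", sep = "")
  invisible(x)
}

#' Library depths (column sums)
#' @param m A [count_matrix()].
#' @return Named numeric vector of per-sample depths.
#' @export
sample_depths <- function(m) colSums(m$counts)

#' Read a gene-by-sample count table from TSV
#'
#' First column holds gene labels; remaining columns are samples (header row
#' of stage labels).
#'
#' @param path TSV file.
#' @param normalized Whether the table is already depth-normalized.
#' @return A [count_matrix()].
#' @export
read_count_table <- function(path, normalized = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m, normalized = normalized)
}

#' Write a count matrix as TSV
#'
#' @param m A [count_matrix()].
#' @param path Output file.
#' @param gene_col Name of the gene-label column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path, gene_col = "gene") {
  df <- data.frame(rownames(m$counts), m$counts, check.names = FALSE)
  names(df)[1] <- gene_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Normalize a count table to the lowest-depth sample
#'
#' Each column is scaled by (minimum column sum / its column sum), so all
#' post-normalization column sums equal the original minimum depth and
#' within-sample proportions are preserved exactly.
#'
#' @param m A [count_matrix()].
#' @return A depth-normalized [count_matrix()].
#' @export
normalize_to_min_depth <- function(m) {
  depths <- sample_depths(m)
  zero <- depths <= 0
  if (any(zero)) {
    stop("zero-depth sample(s): ",
         paste(colnames(m$counts)[zero], collapse = ", "))
  }
  scaled <- sweep(m$counts, 2, min(depths) / depths, "*")
  count_matrix(scaled, normalized = TRUE)
}

#' Log-scale heatmap matrix of a normalized count table
#'
#' Default mode is `log2(normalized count + pseudocount)`. Mode `"logfc"`
#' instead reports the log2 fold change against a reference stage:
#' `log2((c + pseudocount) / (c_ref + pseudocount))`, reference column given
#' by `reference` (default: first column, the earliest stage).
#'
#' @param m A depth-normalized [count_matrix()].
#' @param pseudocount Non-negative pseudocount (default 1).
#' @param mode `"log2"` or `"logfc"`.
#' @param reference Reference column (index or name) for `"logfc"` mode.
#' @return Numeric matrix of log2 values with the dimnames of `m`.
#' @export
log_heatmap_matrix <- function(m, pseudocount = 1,
                               mode = c("log2", "logfc"), reference = 1L) {
  mode <- match.arg(mode)
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (!m$normalized) stop("count matrix must be depth-normalized first")
  lm <- log2(m$counts + pseudocount)
  if (mode == "logfc") lm <- lm - lm[, reference]
  lm
}

#' Per-stage means of replicate columns
#'
#' @param m A [count_matrix()] (typically depth-normalized replicates), or a
#'   list of single-stage [count_matrix()] objects with identical gene sets.
#' @param stages Factor or character vector assigning each column of `m` to
#'   a developmental stage (ignored when `m` is a list; the list names are
#'   the stages).
#' @return A [count_matrix()] with one column per stage, in first-appearance
#'   order.
#' @export
stage_mean <- function(m, stages = NULL) {
  if (is.list(m) && !inherits(m, "count_matrix")) {
    gene_sets <- lapply(m, function(x) rownames(x$counts))
    if (!all(vapply(gene_sets, identical, logical(1), gene_sets[[1]]))) {
      stop("mismatched gene sets across replicates")
    }
    stages <- rep(names(m), vapply(m, function(x) ncol(x$counts), integer(1)))
    norm <- unique(vapply(m, function(x) x$normalized, logical(1)))
    m <- count_matrix(do.call(cbind, lapply(m, function(x) x$counts)),
                      normalized = all(norm))
  }
  if (is.null(stages)) stop("stage assignment required")
  if (length(stages) != ncol(m$counts)) {
    stop("one stage label per column required")
  }
  lev <- unique(as.character(stages))
  out <- vapply(lev, function(s) {
    rowMeans(m$counts[, stages == s, drop = FALSE])
  }, numeric(nrow(m$counts)))
  out <- matrix(out, nrow = nrow(m$counts),
                dimnames = list(rownames(m$counts), lev))
  count_matrix(out, normalized = m$normalized)
}

#' Render the developmental heatmap (optional convenience)
#'
#' Thin wrapper around pheatmap when it is installed; the contract of the
#' module is the numeric matrix from [log_heatmap_matrix()], not the figure.
#'
#' @param log_matrix Matrix from [log_heatmap_matrix()].
#' @param path Optional PNG path.
#' @param ... Passed to `pheatmap::pheatmap`.
#' @return The pheatmap object, invisibly.
#' @export
render_heatmap <- function(log_matrix, path = NULL, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("pheatmap is not installed")
  }
  args <- list(mat = log_matrix, cluster_cols = FALSE, ...)
  if (!is.null(path)) args$filename <- path
  invisible(do.call(pheatmap::pheatmap, args))
}
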