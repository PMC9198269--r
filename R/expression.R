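#' Expression matrix container
#'
#' Lightweight S3 wrapper around a dense numeric matrix of gene expression
#' (rows = genes, columns = cell lines) carrying a normalization `state` flag:
#' `"raw_counts"` for untransformed read counts, `"prenormalized"` for
#' matrices already processed upstream (e.g. RMA microarray summaries), and
#' `"normalized"` once the in-package pipeline has run.
#'
#' @param values numeric matrix, genes in rows, cell lines in columns; must
#'   have unique non-empty dimnames, no missing entries and no negative values.
#' @param state one of `"raw_counts"`, `"prenormalized"`, `"normalized"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, state = c("raw_counts", "prenormalized", "normalized")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and cell-line ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ", paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell-line ids: ", paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values))
    stop("missing values are not allowed in an expression matrix")
  if (any(values < 0))
    stop("negative expression values are not allowed")
  structure(list(values = values, state = state), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cell lines, state = %s\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV
#'
#' Expects gene symbols in the first column and cell-line ids as the header
#' row. Any missing or non-numeric body cell is an error naming the offending
#' gene/cell-line coordinate; duplicated gene or cell-line ids are errors.
#'
#' @param path path to a tab-separated file.
#' @param state_hint provenance of the values: `"raw_counts"` or
#'   `"prenormalized"`.
#' @return An [expr_matrix].
#' @export
read_expression <- function(path, state_hint = c("raw_counts", "prenormalized")) {
  state_hint <- match.arg(state_hint)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop("expression TSV needs a gene column plus at least one cell line: ", path)
  genes <- raw[[1L]]
  lines <- colnames(raw)[-1L]
  if (anyDuplicated(lines))
    stop("duplicated cell-line column name(s): ",
         paste(unique(lines[duplicated(lines)]), collapse = ", "))
  if (anyDuplicated(genes))
    stop("duplicated gene id(s): ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | body == "", arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("missing or non-numeric value at gene '%s', cell line '%s'",
                 genes[bad[1L, 1L]], lines[bad[1L, 2L]]))
  }
  dimnames(num) <- list(genes, lines)
  expr_matrix(num, state = state_hint)
}

#' DESeq-style median-of-ratios size factors
#'
#' The reference set is every gene with strictly positive counts in all cell
#' lines; the size factor of a column is the median, over reference genes, of
#' the count divided by that gene's geometric mean across columns.
#'
#' @param m an [expr_matrix] with `state = "raw_counts"`.
#' @return Named numeric vector of positive size factors, one per cell line.
#' @export
deseq_size_factors <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$state != "raw_counts")
    stop("size factors are defined for raw counts, got state = ", m$state)
  v <- m$values
  ref <- rowSums(v > 0) == ncol(v)
  if (!any(ref))
    stop("no gene has positive counts in every cell line; filter genes first")
  lg <- log(v[ref, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2L, stats::median)
  names(sf) <- colnames(v)
  sf
}

#' Quantile normalization
#'
#' Forces every column to share one empirical distribution: the value at rank
#' r in each column is replaced by the mean across columns of the r-th order
#' statistics. Ties within a column receive the mean of the reference values
#' over the positions the tie group spans (Bolstad convention).
#'
#' @param m numeric matrix without missing values.
#' @return Matrix of the same shape; every column holds the same multiset.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("quantile normalization requires a complete matrix")
  if (ncol(m) == 1L) return(m)
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    o <- order(x)
    pos <- integer(length(x))
    pos[o] <- seq_along(x)
    # tie groups share the mean of the reference values they span
    repl <- stats::ave(ref[pos], match(x, x), FUN = mean)
    out[, j] <- repl
  }
  out
}

#' Scale each column to a target mean
#'
#' @param m numeric matrix.
#' @param target positive target mean per column (default 1000).
#' @return Matrix with every column rescaled so its mean equals `target`.
#' @export
scale_to_mean <- function(m, target = 1000) {
  stopifnot(is.numeric(target), length(target) == 1L, target > 0)
  mu <- colMeans(m)
  zero <- mu <= 0
  if (any(zero))
    stop("cell line(s) with non-positive mean expression: ",
         paste(colnames(m)[zero], collapse = ", "))
  sweep(m, 2L, target / mu, `*`)
}

#' Drop genes that are zero in more than half of the cell lines
#'
#' A gene is removed iff its number of zero entries strictly exceeds n/2,
#' where n is the number of cell lines; gene order is preserved.
#'
#' @param m an [expr_matrix].
#' @return An [expr_matrix] restricted to the surviving genes.
#' @export
filter_zero_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  zeros <- rowSums(m$values == 0)
  keep <- zeros <= ncol(m$values) / 2
  expr_matrix(m$values[keep, , drop = FALSE], state = m$state)
}

#' Full normalization pipeline
#'
#' For raw counts: zero-gene filtering, size-factor division, quantile
#' normalization, then per-cell-line scaling to mean `target`. Pre-normalized
#' matrices only receive the final scaling step. The result carries
#' `state = "normalized"` and every column mean equals `target` to within
#' 1e-9 relative tolerance.
#'
#' @param m an [expr_matrix] with state `"raw_counts"` or `"prenormalized"`.
#' @param target per-cell-line target mean (default 1000).
#' @return A normalized [expr_matrix].
#' @export
normalize_pipeline <- function(m, target = 1000) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$state == "normalized") return(m)
  if (m$state == "raw_counts") {
    m <- filter_zero_genes(m)
    sf <- deseq_size_factors(m)
    v <- sweep(m$values, 2L, sf, `/`)
    v <- quantile_normalize(v)
  } else {
    v <- m$values
  }
  v <- scale_to_mean(v, target = target)
  expr_matrix(v, state = "normalized")
}
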