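#' Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. The U statistic is reported for the
#' first group (`x`). The p-value is exact (via the null Wilcoxon
#' distribution) when both groups have at most 20 observations and there are
#' no ties; otherwise a normal approximation with tie correction and
#' continuity correction is used. Two-sided.
#'
#' @param x,y numeric vectors, each with at least 2 values.
#' @return list(U = statistic for `x`, p = two-sided p-value).
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L)
    stop("each group needs at least 2 values")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  if (!has_ties && nx <= 20L && ny <= 20L) {
    p <- if (U > nx * ny / 2)
      2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    else
      2 * stats::pwilcox(U, nx, ny)
    p <- min(1, p)
  } else {
    N <- nx + ny
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- nx * ny / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
  }
  list(U = U, p = max(p, .Machine$double.xmin))
}

#' Single-gene ROC statistics against a response labeling
#'
#' Computes the ROC AUC with the resistant class as positive and expression
#' as score. The raw AUC equals U_resistant / (n_s * n_r) with midranks; the
#' reported `auc` is folded to \[0.5, 1\] and orientation is carried by
#' `direction` (`"higher_in_resistant"` when resistant lines express more,
#' `"higher_in_sensitive"` when sensitive lines do, `"none"` at exactly 0.5).
#' The associated p-value is the two-sided Mann-Whitney p on the same groups,
#' as the two tests are equivalent.
#'
#' @param expression named numeric vector of expression per cell line.
#' @param labeling a `response_labeling`.
#' @return list(auc, raw_auc, U, direction, mw_p, n_sensitive, n_resistant);
#'   `U` is the midrank Mann-Whitney statistic of the resistant group, so
#'   `raw_auc = U / (n_sensitive * n_resistant)` by construction.
#' @export
roc_auc <- function(expression, labeling) {
  stopifnot(inherits(labeling, "response_labeling"))
  lab <- labeling$labels[labeling$labels != "excluded"]
  have <- names(lab) %in% names(expression)
  if (sum(!have) > length(lab) / 2)
    stop("expression missing for more than half of the labeled cell lines")
  if (any(!have))
    warning(sprintf("%d labeled cell line(s) lack expression and were dropped", sum(!have)))
  lab <- lab[have]
  e <- expression[names(lab)]
  ns <- sum(lab == "sensitive"); nr <- sum(lab == "resistant")
  if (ns < 2L || nr < 2L)
    stop("need at least 2 sensitive and 2 resistant cell lines with expression")
  mw <- mann_whitney(e[lab == "resistant"], e[lab == "sensitive"])
  a <- mw$U / (ns * nr)
  direction <- if (a > 0.5) "higher_in_resistant" else if (a < 0.5) "higher_in_sensitive" else "none"
  list(auc = max(a, 1 - a), raw_auc = a, U = mw$U, direction = direction,
       mw_p = mw$p, n_sensitive = ns, n_resistant = nr)
}

#' Spearman correlation between expression and response values
#'
#' Midrank-based Spearman rho over all cell lines carrying both an
#' expression and a response (typically AUDRC) value — not only the
#' tertile-labeled subset. Two-sided p-value by the t approximation.
#'
#' @param expression named numeric vector.
#' @param audrc named numeric vector of response values.
#' @return list(rho, p, n).
#' @export
spearman_vs_response <- function(expression, audrc) {
  shared <- intersect(names(expression), names(audrc))
  shared <- shared[!is.na(expression[shared]) & !is.na(audrc[shared])]
  n <- length(shared)
  if (n < 4L) stop("need at least 4 cell lines with both expression and response")
  rho <- stats::cor(rank(expression[shared]), rank(audrc[shared]))
  if (is.na(rho)) rho <- 0  # zero-variance input
  if (abs(rho) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
  }
  list(rho = rho, p = p, n = n)
}

#' Mean expression of a gene list
#'
#' Per cell line, the arithmetic mean over the listed genes present in the
#' matrix; genes absent from the matrix are reported via a warning.
#'
#' @param genes character vector of gene symbols.
#' @param m an [expr_matrix].
#' @return Named numeric vector, one mean per cell line.
#' @export
mean_signature <- function(genes, m) {
  stopifnot(inherits(m, "expr_matrix"))
  present <- intersect(genes, rownames(m$values))
  if (length(present) == 0L)
    stop("none of the listed genes are in the matrix: ", paste(genes, collapse = ", "))
  absent <- setdiff(genes, present)
  if (length(absent) > 0L)
    warning("gene(s) absent from the matrix: ", paste(absent, collapse = ", "))
  colMeans(m$values[present, , drop = FALSE])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; the result preserves input order,
#' satisfies q >= p, and is monotone along the sorted p-values.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pvalues[o] * m / seq(m, 1)))[ro]
  pmax(q, pvalues)  # q >= p holds exactly; guard against rounding
}

#' Screen genes for association with drug response
#'
#' For every gene (or a requested subset) computes the folded ROC AUC,
#' direction, Mann-Whitney p against the sensitive/resistant labeling, the
#' Spearman correlation against the continuous response values, and applies
#' Benjamini-Hochberg FDR across exactly the screened set. Results are
#' sorted by AUC descending with ties broken by gene symbol.
#'
#' @param m a normalized [expr_matrix].
#' @param labeling a `response_labeling`.
#' @param audrc optional named numeric vector of continuous response values
#'   for the Spearman column; NULL omits it.
#' @param genes optional character vector restricting the screen.
#' @return data.frame with columns `gene, n_sensitive, n_resistant, auc,
#'   direction, mw_p, spearman_rho, spearman_p, fdr_q`.
#' @export
gene_screen <- function(m, labeling, audrc = NULL, genes = NULL) {
  stopifnot(inherits(m, "expr_matrix"), inherits(labeling, "response_labeling"))
  lab <- labeling$labels[labeling$labels != "excluded"]
  shared <- intersect(names(lab), colnames(m$values))
  if (length(shared) < 6L)
    stop("labeling and expression matrix share fewer than 6 cell lines")
  if (is.null(genes)) genes <- rownames(m$values)
  missing_genes <- setdiff(genes, rownames(m$values))
  if (length(missing_genes) > 0L)
    warning("gene(s) not in the matrix skipped: ", paste(missing_genes, collapse = ", "))
  genes <- intersect(genes, rownames(m$values))
  if (length(genes) == 0L) stop("no requested gene is present in the matrix")

  rows <- lapply(genes, function(g) {
    expr <- m$values[g, ]
    st <- roc_auc(expr, labeling)
    sp <- if (!is.null(audrc)) spearman_vs_response(expr, audrc) else list(rho = NA_real_, p = NA_real_)
    data.frame(gene = g, n_sensitive = st$n_sensitive, n_resistant = st$n_resistant,
               auc = st$auc, direction = st$direction, mw_p = st$mw_p,
               spearman_rho = sp$rho, spearman_p = sp$p)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- bh_fdr(out$mw_p)
  out <- out[order(-out$auc, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman correlation matrix of response metrics and retained genes
#'
#' Genes are screened first; a gene enters the matrix only if it is
#' significant (`mw_p < alpha`) and its Spearman rho against the continuous
#' response reaches `rho_threshold` in absolute value. The matrix covers the
#' response metrics (AUDRC and, when given, IC50) plus the retained genes,
#' computed over cell lines carrying all measurements.
#'
#' @param m a normalized [expr_matrix].
#' @param genes candidate gene symbols.
#' @param labeling a `response_labeling` used for the significance screen.
#' @param audrc named numeric vector of continuous response values.
#' @param ic50 optional named numeric vector of IC50 values.
#' @param rho_threshold minimum |rho vs response| for retention (default 0.20).
#' @param alpha significance cutoff on the Mann-Whitney p (default 0.05).
#' @return Symmetric numeric matrix of Spearman rho with unit diagonal; empty
#'   (0 x 0) with a warning when no gene survives. The screen is attached as
#'   attribute `screen`.
#' @export
correlation_matrix <- function(m, genes, labeling, audrc, ic50 = NULL,
                               rho_threshold = 0.20, alpha = 0.05) {
  screen <- gene_screen(m, labeling, audrc = audrc, genes = genes)
  keep <- screen$gene[screen$mw_p < alpha & abs(screen$spearman_rho) >= rho_threshold]
  if (length(keep) == 0L) {
    warning("no gene passes the significance and |rho| >= ", rho_threshold, " filters")
    out <- matrix(numeric(0), 0, 0)
    attr(out, "screen") <- screen
    return(out)
  }
  cols <- list(AUDRC = audrc)
  if (!is.null(ic50)) cols$IC50 <- ic50
  shared <- Reduce(intersect, c(list(colnames(m$values)), lapply(cols, names)))
  block <- cbind(do.call(cbind, lapply(cols, function(v) v[shared])),
                 t(m$values[keep, shared, drop = FALSE]))
  colnames(block) <- c(names(cols), keep)
  out <- stats::cor(apply(block, 2L, rank))
  diag(out) <- 1
  attr(out, "screen") <- screen
  out
}
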