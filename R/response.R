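#' Read a drug-response table
#'
#' TSV with columns `dataset, compound, cell_line, ic50, audrc`; empty
#' strings mark missing measurements. Records where both IC50 and AUDRC are
#' missing are dropped at ingestion.
#'
#' @param path TSV path.
#' @return data.frame with columns `dataset`, `compound`, `cell_line`,
#'   `ic50`, `audrc` (NA = missing) and attribute `n_dropped` counting
#'   records excluded for lacking both measurements.
#' @export
read_responses <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  need <- c("dataset", "compound", "cell_line", "ic50", "audrc")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("response table is missing column(s): ", paste(miss, collapse = ", "))
  df <- df[need]
  df$ic50 <- suppressWarnings(as.numeric(ifelse(nzchar(df$ic50), df$ic50, NA)))
  df$audrc <- suppressWarnings(as.numeric(ifelse(nzchar(df$audrc), df$audrc, NA)))
  if (any(df$ic50 <= 0, na.rm = TRUE))
    stop("IC50 values must be positive concentrations")
  drop <- is.na(df$ic50) & is.na(df$audrc)
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

new_labeling <- function(dataset, compound, metric, scheme, lower, upper, labels) {
  structure(list(dataset = dataset, compound = compound, metric = metric,
                 scheme = scheme, lower_cutoff = lower, upper_cutoff = upper,
                 labels = labels),
            class = "response_labeling")
}

#' @export
print.response_labeling <- function(x, ...) {
  cat(sprintf("<response_labeling> %s / %s, %s %s: cutoffs [%.4g, %.4g], %d sensitive / %d resistant / %d excluded\n",
              x$dataset, x$compound, x$scheme, x$metric,
              x$lower_cutoff, x$upper_cutoff,
              sum(x$labels == "sensitive"), sum(x$labels == "resistant"),
              sum(x$labels == "excluded")))
  invisible(x)
}

#' Tertile-based sensitive/resistant classification
#'
#' The lower tertile of the response metric (IC50 or AUDRC; low = strong
#' growth inhibition) is labeled sensitive, the upper tertile resistant, and
#' the intermediate tertile excluded. Cutoffs are the 33.33rd and 66.67th
#' percentiles by linear interpolation between order statistics (quantile
#' type 7). A value satisfying both cutoff conditions (possible only when the
#' cutoffs coincide) is excluded.
#'
#' @param values named numeric vector, one response value per cell line.
#' @param dataset,compound,metric provenance strings carried on the result.
#' @return A `response_labeling` with `scheme = "tertile"`.
#' @export
classify_tertile <- function(values, dataset = "", compound = "", metric = "audrc") {
  if (length(values) < 6L)
    stop("insufficient cell lines: tertile classification needs at least 6 values")
  if (anyNA(values)) stop("response values must not be missing")
  q <- stats::quantile(values, probs = c(1, 2) / 3, type = 7, names = FALSE)
  s <- values <= q[1L]
  r <- values >= q[2L]
  labels <- rep("excluded", length(values))
  labels[s & !r] <- "sensitive"
  labels[r & !s] <- "resistant"
  names(labels) <- names(values)
  new_labeling(dataset, compound, metric, "tertile", q[1L], q[2L], labels)
}

#' Median-based sensitive/resistant classification
#'
#' Values strictly below the median are sensitive, strictly above resistant,
#' and exact ties with the median excluded.
#'
#' @inheritParams classify_tertile
#' @return A `response_labeling` with `scheme = "median"`.
#' @export
classify_median <- function(values, dataset = "", compound = "", metric = "audrc") {
  if (length(values) < 4L)
    stop("insufficient cell lines: median classification needs at least 4 values")
  if (anyNA(values)) stop("response values must not be missing")
  med <- stats::median(values)
  labels <- rep("excluded", length(values))
  labels[values < med] <- "sensitive"
  labels[values > med] <- "resistant"
  names(labels) <- names(values)
  new_labeling(dataset, compound, metric, "median", med, med, labels)
}

#' Pick the response metric for one (dataset, compound)
#'
#' Prefers the requested metric when at least `min_lines` distinct cell lines
#' report it, otherwise falls back to the other; duplicate measurements for a
#' cell line are averaged.
#'
#' @param records data.frame of response records sharing one
#'   (dataset, compound) pair.
#' @param preference `"audrc_first"` or `"ic50_first"`.
#' @param min_lines minimum distinct cell lines for a metric to be usable.
#' @return list(metric = "ic50"|"audrc", values = named numeric vector).
#' @export
select_metric <- function(records, preference = c("audrc_first", "ic50_first"),
                          min_lines = 6L) {
  preference <- match.arg(preference)
  if (length(unique(records$dataset)) > 1L || length(unique(records$compound)) > 1L)
    stop("records must share a single (dataset, compound) pair")
  collapse <- function(col) {
    ok <- !is.na(records[[col]])
    if (!any(ok)) return(numeric(0))
    tapply(records[[col]][ok], records$cell_line[ok], mean)
  }
  order_try <- if (preference == "audrc_first") c("audrc", "ic50") else c("ic50", "audrc")
  for (metric in order_try) {
    vals <- collapse(metric)
    if (length(vals) >= min_lines)
      return(list(metric = metric, values = vals))
  }
  stop(sprintf("neither IC50 nor AUDRC is reported for %d or more cell lines", min_lines))
}

#' Filter compounds by per-dataset cohort size
#'
#' A compound is retained iff, in at least one dataset, the number of
#' distinct cell lines with at least one of IC50/AUDRC reported reaches
#' `min_cell_lines`. Counts are per dataset, never pooled.
#'
#' @param records response data.frame (see [read_responses()]).
#' @param min_cell_lines minimum per-dataset cohort size (default 100).
#' @return Character vector of retained compound names, sorted.
#' @export
filter_compounds <- function(records, min_cell_lines = 100L) {
  has <- !is.na(records$ic50) | !is.na(records$audrc)
  rec <- records[has, , drop = FALSE]
  if (nrow(rec) == 0L) return(character(0))
  key <- paste(rec$dataset, rec$compound, sep = "\r")
  counts <- tapply(rec$cell_line, key, function(x) length(unique(x)))
  compounds <- vapply(strsplit(names(counts), "\r", fixed = TRUE), `[`, "", 2L)
  sort(unique(compounds[counts >= min_cell_lines]))
}
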