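#' Standardize an AUDRC value to \[0, 1\]
#'
#' Divides the raw area under the dose-response curve by its theoretical
#' maximum (dose-range width times the maximal response), i.e. the mean
#' response over the tested dose range. Order-preserving and linear, so
#' rankings from raw and standardized AUDRC agree when the dose range is
#' shared.
#'
#' @param audrc non-negative area(s) under the dose-response curve.
#' @param dose_range_width positive width of the tested dose range (on the
#'   axis the area was computed over, e.g. log10 units).
#' @param max_response maximal response value (default 1, viability fraction).
#' @return Numeric value(s) in \[0, 1\].
#' @export
standardize_audrc <- function(audrc, dose_range_width, max_response = 1) {
  stopifnot(dose_range_width > 0, max_response > 0)
  if (any(audrc < 0)) stop("AUDRC must be non-negative")
  top <- dose_range_width * max_response
  if (any(audrc > top * (1 + 1e-12)))
    stop("AUDRC exceeds the theoretical maximum area ", top)
  pmin(audrc / top, 1)
}

#' Rank cell-line models by standardized AUDRC
#'
#' The most sensitive models are those with the smallest standardized AUDRC.
#' Ties share order by cell-line name, so the full ranking is a deterministic
#' permutation of the input.
#'
#' @param values named numeric vector of standardized AUDRC per cell line.
#' @param annotations optional named character vector of disease annotations.
#' @param k panel size for the top lists (default 10).
#' @return list(sensitive, resistant, full): `sensitive` holds the k smallest
#'   values ascending, `resistant` the k largest descending, `full` the whole
#'   ranking with 1-based ranks; all are data.frames with columns
#'   `cell_line`, `disease`, `standardized_audrc` (+ `rank` in `full`).
#' @export
rank_cell_lines <- function(values, annotations = NULL, k = 10L) {
  if (length(values) == 0L) stop("no cell lines to rank")
  if (length(values) < 2L * k)
    warning(sprintf("fewer than 2k = %d cell lines; panels will overlap", 2L * k))
  o <- order(values, names(values))
  full <- data.frame(cell_line = names(values)[o],
                     disease = if (is.null(annotations)) NA_character_
                               else unname(annotations[names(values)[o]]),
                     standardized_audrc = unname(values[o]),
                     rank = seq_along(values))
  kk <- min(k, length(values))
  sensitive <- full[seq_len(kk), c("cell_line", "disease", "standardized_audrc")]
  resistant <- full[rev(seq.int(nrow(full) - kk + 1L, nrow(full))),
                    c("cell_line", "disease", "standardized_audrc")]
  rownames(sensitive) <- rownames(resistant) <- NULL
  list(sensitive = sensitive, resistant = resistant, full = full)
}

#' Cross-dataset overlap (Venn) report
#'
#' For 2-4 datasets, counts every exclusive Venn region (elements belonging
#' to exactly that combination of datasets) plus the "in at least two" and
#' "in all" aggregates with their percentages of the union.
#'
#' @param sets named list (length 2-4) of character vectors.
#' @param category optional label (`"compounds"`, `"cell_lines"`, `"genes"`).
#' @return list(category, n_union, regions, in_ge2, in_all, pct_ge2,
#'   pct_all, per_dataset). `regions` is a data.frame with one row per
#'   non-empty dataset combination and its exclusive count.
#' @export
overlap_report <- function(sets, category = "items") {
  k <- length(sets)
  if (k < 2L || k > 4L) stop("overlap report supports 2 to 4 datasets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("datasets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L, dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1L, function(b) paste(names(sets)[b], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(names(sets), sz, paste, collapse = "&", simplify = FALSE)))
  counts <- vapply(combos, function(cb) sum(pattern == cb), integer(1))
  n_sets <- rowSums(member)
  in_ge2 <- sum(n_sets >= 2L)
  in_all <- sum(n_sets == k)
  list(category = category,
       n_union = length(universe),
       regions = data.frame(combination = combos, exclusive_count = unname(counts)),
       in_ge2 = in_ge2, in_all = in_all,
       pct_ge2 = 100 * in_ge2 / length(universe),
       pct_all = 100 * in_all / length(universe),
       per_dataset = vapply(sets, length, integer(1)))
}
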