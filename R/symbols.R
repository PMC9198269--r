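#' Read an HGNC-style symbol map
#'
#' Expects a TSV with columns `approved_symbol`, `alias_symbols` and
#' `previous_symbols`; the latter two hold pipe-separated lists and may be
#' empty. Aliases pointing at more than one approved symbol are ambiguous:
#' they are dropped from the mapping and recorded. An alias that is itself an
#' approved symbol never overrides the approved meaning.
#'
#' @param path TSV path.
#' @return A `symbol_map`: list with `approved` (character vector),
#'   `alias_to_approved` (named character vector) and `ambiguous` (character
#'   vector of dropped aliases).
#' @export
read_symbol_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  need <- c("approved_symbol", "alias_symbols", "previous_symbols")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop("symbol map is missing column(s): ", paste(miss, collapse = ", "))
  split_pipe <- function(s) {
    parts <- strsplit(s, "|", fixed = TRUE)
    lapply(parts, function(p) p[nzchar(p)])
  }
  approved <- unique(df$approved_symbol[nzchar(df$approved_symbol)])
  alias_list <- Map(c, split_pipe(df$alias_symbols), split_pipe(df$previous_symbols))
  alias <- rep(df$approved_symbol, lengths(alias_list))
  names(alias) <- unlist(alias_list, use.names = FALSE)
  alias <- alias[!(names(alias) %in% approved)]
  # an alias naming several approved symbols is ambiguous and unusable
  tab <- tapply(alias, names(alias), function(a) length(unique(a)))
  ambiguous <- names(tab)[tab > 1L]
  alias <- alias[!(names(alias) %in% ambiguous)]
  alias <- alias[!duplicated(names(alias))]
  structure(list(approved = approved, alias_to_approved = alias,
                 ambiguous = ambiguous),
            class = "symbol_map")
}

#' Map gene ids to approved symbols
#'
#' Approved symbols pass through; known aliases are renamed; unmappable ids
#' are kept verbatim and listed in the report. When two rows end up with the
#' same approved symbol, the row with the higher mean expression wins and the
#' collision is reported.
#'
#' @param m an [expr_matrix].
#' @param sm a `symbol_map` from [read_symbol_map()].
#' @return An [expr_matrix] with attributes `unmapped` (ids left verbatim)
#'   and `collisions` (data.frame of kept/dropped rows per approved symbol).
#' @export
map_symbols <- function(m, sm) {
  stopifnot(inherits(m, "expr_matrix"), inherits(sm, "symbol_map"))
  ids <- rownames(m$values)
  mapped <- ifelse(ids %in% sm$approved, ids,
                   ifelse(ids %in% names(sm$alias_to_approved),
                          unname(sm$alias_to_approved[ids]), ids))
  unmapped <- ids[!(ids %in% sm$approved) & !(ids %in% names(sm$alias_to_approved))]
  keep <- rep(TRUE, length(ids))
  collisions <- list()
  for (sym in unique(mapped[duplicated(mapped)])) {
    rows <- which(mapped == sym)
    means <- rowMeans(m$values[rows, , drop = FALSE])
    win <- rows[which.max(means)]
    keep[setdiff(rows, win)] <- FALSE
    collisions[[sym]] <- data.frame(approved = sym,
                                    kept = ids[win],
                                    dropped = paste(ids[setdiff(rows, win)], collapse = ","))
  }
  v <- m$values[keep, , drop = FALSE]
  rownames(v) <- mapped[keep]
  out <- expr_matrix(v, state = m$state)
  attr(out, "unmapped") <- unmapped
  attr(out, "collisions") <- if (length(collisions) > 0L)
    do.call(rbind, unname(collisions))
  else
    data.frame(approved = character(), kept = character(), dropped = character())
  out
}

#' Read gene sets from a GMT file
#'
#' Standard Broad dialect: each line is `name<TAB>description<TAB>gene...`.
#' Duplicate genes within a line are deduplicated with a warning; lines with
#' fewer than three fields are errors naming the line number.
#'
#' @param path GMT path.
#' @return A named list of character vectors (one gene set per line); an
#'   empty file yields an empty list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(fields)))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): duplicated gene(s) removed", i, fields[1L]))
      genes <- unique(genes)
    }
    sets[[fields[1L]]] <- genes
  }
  sets
}
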