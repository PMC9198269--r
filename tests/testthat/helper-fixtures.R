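# Shared fixtures and independent oracles for the suite.

make_expr <- function(values, state = "raw_counts",
                      genes = sprintf("G%d", seq_len(nrow(values))),
                      lines = sprintf("L%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, lines)
  expr_matrix(values, state = state)
}

write_expr_tsv <- function(values, path = tempfile(fileext = ".tsv"),
                           genes = sprintf("G%d", seq_len(nrow(values))),
                           lines = sprintf("L%d", seq_len(ncol(values)))) {
  header <- paste(c("gene", lines), collapse = "\t")
  rows <- vapply(seq_len(nrow(values)), function(i)
    paste(c(genes[i], values[i, ]), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  path
}

write_response_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  df$ic50 <- ifelse(is.na(df$ic50), "", as.character(df$ic50))
  df$audrc <- ifelse(is.na(df$audrc), "", as.character(df$audrc))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_labeling <- function(sensitive, resistant, dataset = "DS1",
                          compound = "DRUG1", metric = "audrc") {
  labels <- c(setNames(rep("sensitive", length(sensitive)), sensitive),
              setNames(rep("resistant", length(resistant)), resistant))
  structure(list(dataset = dataset, compound = compound, metric = metric,
                 scheme = "tertile", lower_cutoff = NA_real_,
                 upper_cutoff = NA_real_, labels = labels),
            class = "response_labeling")
}

# Brute-force midrank Mann-Whitney U for group x: all pairwise comparisons.
brute_U <- function(x, y) {
  wins <- 0
  for (xi in x) for (yi in y) wins <- wins + (xi > yi) + 0.5 * (xi == yi)
  wins
}

# Brute-force Venn region counts by membership pattern enumeration.
brute_regions <- function(sets) {
  universe <- unique(unlist(sets))
  out <- list()
  k <- length(sets)
  for (sz in seq_len(k)) {
    for (cb in utils::combn(names(sets), sz, simplify = FALSE)) {
      cnt <- sum(vapply(universe, function(el) {
        inside <- vapply(sets, function(s) el %in% s, logical(1))
        all(inside[cb]) && !any(inside[setdiff(names(sets), cb)])
      }, logical(1)))
      out[[paste(cb, collapse = "&")]] <- cnt
    }
  }
  out
}

# Small labeled cohort: expression matrix + labeling from true AUDRC tertiles.
labeled_cohort <- function(seed, n_genes = 50, n = 60, planted = NULL,
                           noise_sd = 0.1) {
  cohort <- generate_cohort(cohort_spec(
    n_genes = n_genes, n_cell_lines = n, planted = planted,
    noise_sd = noise_sd, seed = seed))
  rec <- cohort$responses
  vals <- setNames(rec$audrc, rec$cell_line)
  labeling <- classify_tertile(vals, "DS1", "DRUG1", "audrc")
  m <- normalize_pipeline(cohort$expression$DS1)
  list(m = m, labeling = labeling, audrc = vals, cohort = cohort)
}
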