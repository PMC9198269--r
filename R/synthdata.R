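#' Specification of a synthetic drug-screen cohort
#'
#' Describes a multi-dataset cohort with a shared latent resistance score per
#' cell line, log-normal raw read counts, planted biomarker genes whose
#' log-expression shifts with the latent score, and Hill-curve dose-response
#' (IC50 and AUDRC) driven by the same score.
#'
#' @param n_genes number of genes.
#' @param n_cell_lines number of distinct cell lines in the cohort.
#' @param n_datasets number of datasets (1-4) sharing cell lines.
#' @param cell_line_overlap_fraction fraction of cell lines present in every
#'   dataset; the remainder is distributed round-robin across datasets.
#' @param planted data.frame with columns `gene` (index in 1..n_genes),
#'   `effect_size` (log-scale shift, in units of the log-expression noise SD,
#'   per SD of the latent resistance score) and `sign` (+1: higher expression
#'   marks resistance; -1: marks sensitivity). NULL plants nothing.
#' @param hill_slope positive Hill coefficient of the viability curve.
#' @param doses geometric dose ladder, list(min, max, n_points).
#' @param noise_sd SD of the log-IC50 measurement noise.
#' @param seed integer seed; all randomness flows from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_genes = 500L, n_cell_lines = 150L, n_datasets = 1L,
                        cell_line_overlap_fraction = 1, planted = NULL,
                        hill_slope = 1, doses = list(min = 1e-3, max = 10, n_points = 9L),
                        noise_sd = 0.1, seed = 1L) {
  stopifnot(n_genes >= 1L, n_cell_lines >= 1L,
            n_datasets >= 1L, n_datasets <= 4L,
            cell_line_overlap_fraction >= 0, cell_line_overlap_fraction <= 1,
            hill_slope > 0, noise_sd >= 0,
            doses$min > 0, doses$max > doses$min, doses$n_points >= 2L)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("gene", "effect_size", "sign") %in% colnames(planted)),
              all(planted$gene >= 1L & planted$gene <= n_genes),
              all(planted$sign %in% c(-1, 1)))
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_cell_lines = as.integer(n_cell_lines),
                 n_datasets = as.integer(n_datasets),
                 cell_line_overlap_fraction = cell_line_overlap_fraction,
                 planted = planted, hill_slope = hill_slope, doses = doses,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic multi-dataset cohort
#'
#' Generative model, all draws from a single seed:
#' 1. latent resistance score z_j ~ N(0, 1) per cell line, shared across
#'    datasets;
#' 2. raw counts: per-gene baseline log-mean ~ N(log 300, 1); per-dataset
#'    entry = round(exp(baseline + delta_gj + eps)), eps ~ N(0, 1), where
#'    delta_gj = effect_size * sign * z_j for planted genes and 0 otherwise;
#' 3. log IC50 = z_j + N(0, noise_sd) (resistant lines need more drug); the
#'    recorded IC50 and AUDRC carry independent noise draws;
#' 4. viability v(d) = 1 / (1 + (d / IC50)^hill_slope); the true AUDRC is
#'    the trapezoid area of v over log10-spaced doses, and response records
#'    carry the standardized mean viability (area / log10 dose-range width);
#' 5. records are spread over the datasets with the requested cell-line
#'    overlap.
#'
#' @param spec a [cohort_spec].
#' @return A `synthetic_cohort`: `expression` (named list of raw-count
#'   [expr_matrix], one per dataset), `responses` (pooled response
#'   data.frame), `truth` (z, noise-free IC50/AUDRC, planted genes, dose
#'   ladder, dose-range width).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  n <- spec$n_cell_lines; g <- spec$n_genes; d <- spec$n_datasets
  lines <- sprintf("CL%04d", seq_len(n))
  genes <- sprintf("GENE%05d", seq_len(g))
  datasets <- paste0("DS", seq_len(d))

  z <- stats::rnorm(n)
  names(z) <- lines

  # cell line -> datasets assignment
  n_core <- round(spec$cell_line_overlap_fraction * n)
  if (d > 1L && n_core == 0L && n < d)
    stop("infeasible overlap: not enough cell lines to populate every dataset")
  membership <- lapply(seq_len(d), function(k) {
    extra <- setdiff(seq_len(n), seq_len(n_core))
    own <- extra[(extra - n_core - 1L) %% d + 1L == k]
    lines[c(seq_len(n_core), own)]
  })
  names(membership) <- datasets
  if (any(lengths(membership) == 0L))
    stop("infeasible overlap: a dataset would receive no cell lines")

  # planted log-scale shifts (genes x cell lines)
  delta <- matrix(0, g, n)
  if (!is.null(spec$planted)) {
    for (i in seq_len(nrow(spec$planted))) {
      gi <- spec$planted$gene[i]
      delta[gi, ] <- delta[gi, ] +
        spec$planted$effect_size[i] * spec$planted$sign[i] * z
    }
  }
  base_log <- stats::rnorm(g, mean = log(300), sd = 1)

  expression <- lapply(datasets, function(ds) {
    cols <- membership[[ds]]
    eps <- matrix(stats::rnorm(g * length(cols), sd = 1), g, length(cols))
    counts <- round(exp(base_log + delta[, match(cols, lines), drop = FALSE] + eps))
    dimnames(counts) <- list(genes, cols)
    expr_matrix(counts, state = "raw_counts")
  })
  names(expression) <- datasets

  # Hill-curve dose response on a geometric ladder
  dose <- exp(seq(log(spec$doses$min), log(spec$doses$max),
                  length.out = spec$doses$n_points))
  lx <- log10(dose)
  width <- lx[length(lx)] - lx[1L]
  audrc_of <- function(ic50) {
    vapply(ic50, function(ic) {
      v <- 1 / (1 + (dose / ic)^spec$hill_slope)
      sum(diff(lx) * (v[-1L] + v[-length(v)]) / 2)
    }, numeric(1))
  }
  true_ic50 <- exp(z)
  true_audrc <- audrc_of(true_ic50)
  names(true_audrc) <- lines

  responses <- do.call(rbind, lapply(datasets, function(ds) {
    cols <- membership[[ds]]
    ic50 <- exp(z[cols] + stats::rnorm(length(cols), sd = spec$noise_sd))
    # AUDRC carries its own measurement noise, independent of the IC50 record
    audrc <- audrc_of(exp(z[cols] + stats::rnorm(length(cols), sd = spec$noise_sd)))
    data.frame(dataset = ds, compound = "DRUG1", cell_line = cols,
               ic50 = unname(ic50), audrc = unname(audrc) / width)
  }))
  rownames(responses) <- NULL

  structure(list(expression = expression, responses = responses,
                 truth = list(z = z, true_ic50 = true_ic50,
                              true_audrc = true_audrc,
                              planted = spec$planted, doses = dose,
                              dose_range_width = width),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes, %d cell lines, %d dataset(s), %d planted gene(s)\n",
              x$spec$n_genes, x$spec$n_cell_lines, x$spec$n_datasets,
              if (is.null(x$spec$planted)) 0L else nrow(x$spec$planted)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one expression TSV per dataset (`expr_<dataset>.tsv`, gene column
#' plus cell-line header — the [read_expression()] contract), the pooled
#' response TSV (`responses.tsv`, the [read_responses()] contract) and a
#' ground-truth JSON (`truth.json`).
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (ds in names(cohort$expression)) {
    v <- cohort$expression[[ds]]$values
    df <- data.frame(gene = rownames(v), v, check.names = FALSE)
    p <- file.path(dir, paste0("expr_", ds, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[paste0("expr_", ds)]] <- p
  }
  rp <- file.path(dir, "responses.tsv")
  utils::write.table(cohort$responses, rp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$responses <- rp
  tp <- file.path(dir, "truth.json")
  tr <- cohort$truth
  jsonlite::write_json(list(z = as.list(tr$z),
                            true_ic50 = as.list(tr$true_ic50),
                            true_audrc = as.list(tr$true_audrc),
                            planted = tr$planted,
                            doses = tr$doses,
                            dose_range_width = tr$dose_range_width),
                       tp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths$truth <- tp
  invisible(paths)
}
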