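#' Stratified train/test split of labeled cell lines
#'
#' Assigns `round(train_fraction * n)` cell lines to the training set,
#' stratified by class so both classes appear in both partitions; per-class
#' training counts are apportioned by largest remainder so the overall
#' training size is exact. Deterministic given `seed`.
#'
#' @param labeling a `response_labeling`; only non-excluded lines are split.
#' @param seed integer seed.
#' @param train_fraction fraction assigned to training (default 0.66).
#' @return list(train, test) of cell-line id vectors.
#' @export
split_train_test <- function(labeling, seed, train_fraction = 0.66) {
  stopifnot(inherits(labeling, "response_labeling"),
            train_fraction > 0, train_fraction < 1)
  lab <- labeling$labels[labeling$labels != "excluded"]
  n <- length(lab)
  if (n < 12L) stop("need at least 12 labeled cell lines to split")
  classes <- sort(unique(lab))
  if (length(classes) < 2L) stop("both classes must be present to split")

  n_train <- round(train_fraction * n)
  n_class <- table(lab)[classes]
  ideal <- train_fraction * as.numeric(n_class)
  base <- floor(ideal)
  rem <- n_train - sum(base)
  if (rem > 0) {
    # largest fractional remainder first; ties to the larger class, then name
    ord <- order(-(ideal - base), -as.numeric(n_class), classes)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }

  withr_seed <- function(expr) { # local RNG scope
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
  }
  train <- withr_seed({
    unlist(lapply(seq_along(classes), function(k) {
      members <- sort(names(lab)[lab == classes[k]])
      sample(members, size = base[k])
    }), use.names = FALSE)
  })
  test <- setdiff(sort(names(lab)), train)
  counts <- function(ids) table(factor(lab[ids], levels = classes))
  if (any(counts(train) < 2L) || any(counts(test) < 2L))
    stop("a class has fewer than 2 members in train or test; use a different seed or more data")
  list(train = sort(train), test = test)
}

#' Select signature genes on the training set
#'
#' Candidate genes with a two-sided Mann-Whitney p below `alpha`, computed on
#' training cell lines only. Candidates absent from the matrix are skipped
#' with a warning; an empty selection is a legal result.
#'
#' @param m an [expr_matrix].
#' @param labeling a `response_labeling`.
#' @param train character vector of training cell-line ids.
#' @param candidate_genes character vector of candidate symbols.
#' @param alpha selection cutoff (default 0.05).
#' @return data.frame(gene, mw_p, auc) sorted by p ascending, gene as tie-break.
#' @export
select_genes <- function(m, labeling, train, candidate_genes, alpha = 0.05) {
  stopifnot(inherits(m, "expr_matrix"), inherits(labeling, "response_labeling"))
  absent <- setdiff(candidate_genes, rownames(m$values))
  if (length(absent) > 0L)
    warning("candidate gene(s) not in the matrix skipped: ", paste(absent, collapse = ", "))
  genes <- intersect(candidate_genes, rownames(m$values))
  if (length(genes) == 0L) stop("no candidate gene is present in the matrix")
  lab <- labeling$labels[labeling$labels != "excluded"]
  lab <- lab[intersect(train, names(lab))]
  res <- lab[lab == "resistant"]; sen <- lab[lab == "sensitive"]
  if (length(res) < 2L || length(sen) < 2L)
    stop("training set needs at least 2 cell lines of each class")
  rows <- lapply(genes, function(g) {
    e <- m$values[g, ]
    mw <- mann_whitney(e[names(res)], e[names(sen)])
    a <- mw$U / (length(res) * length(sen))
    data.frame(gene = g, mw_p = mw$p, auc = max(a, 1 - a))
  })
  out <- do.call(rbind, rows)
  out <- out[out$mw_p < alpha, , drop = FALSE]
  out <- out[order(out$mw_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a random-forest signature classifier
#'
#' Trains the in-package random forest (CART/Gini, bootstrap per tree) on
#' the training-set expression of the selected genes, predicting the
#' resistant class. Defaults: 500 trees, `floor(sqrt(p))` features per
#' split, trees grown to purity. Deterministic given `seed`.
#'
#' @param m an [expr_matrix].
#' @param labeling a `response_labeling`.
#' @param train training cell-line ids.
#' @param selected character vector of selected gene symbols (>= 1).
#' @param seed integer seed.
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; default `floor(sqrt(p))`, minimum 1.
#' @return An `rf_signature` model object.
#' @export
fit_signature <- function(m, labeling, train, selected, seed,
                          ntree = 500L, mtry = NULL) {
  if (length(selected) == 0L) stop("no significant genes: cannot fit a signature")
  stopifnot(all(selected %in% rownames(m$values)))
  lab <- labeling$labels[labeling$labels != "excluded"]
  train <- intersect(train, names(lab))
  X <- t(m$values[selected, train, drop = FALSE])
  y <- as.integer(lab[train] == "resistant")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(length(selected))))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  forest <- .rf_fit_cpp(X, y, as.integer(ntree), as.integer(mtry), 1L)
  structure(list(forest = forest, genes = selected, ntree = ntree, mtry = mtry,
                 positive_class = "resistant", seed = seed),
            class = "rf_signature")
}

#' @export
print.rf_signature <- function(x, ...) {
  cat(sprintf("<rf_signature> %d genes, %d trees, mtry %d (positive class: %s)\n",
              length(x$genes), x$ntree, x$mtry, x$positive_class))
  invisible(x)
}

#' Predicted resistant-class probability
#'
#' @param object an `rf_signature`.
#' @param m an [expr_matrix] holding the genes the model was trained on.
#' @param cell_lines cell-line ids to score (default: all columns).
#' @param ... unused.
#' @return Named numeric vector of resistant-class vote fractions in \[0, 1\].
#' @export
predict.rf_signature <- function(object, m, cell_lines = NULL, ...) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(cell_lines)) cell_lines <- colnames(m$values)
  X <- t(m$values[object$genes, cell_lines, drop = FALSE])
  p <- .rf_predict_cpp(object$forest, X)
  names(p) <- cell_lines
  p
}

#' Evaluate a fitted signature on the held-out test set
#'
#' Predictions at probability threshold 0.5 (>= 0.5 is called resistant)
#' yield the confusion matrix with resistant as the positive class; the test
#' ROC AUC uses the predicted resistant probability as score, unfolded
#' because the model fixes orientation, with the Mann-Whitney p of the
#' probabilities between the two test classes attached.
#'
#' @param model an `rf_signature`.
#' @param m an [expr_matrix].
#' @param labeling a `response_labeling`.
#' @param test test cell-line ids (both classes must be present).
#' @return list with confusion counts (TP, FP, TN, FN), accuracy,
#'   sensitivity, specificity, precision (NA when the denominator is 0),
#'   test_auc, test_auc_p, n_test.
#' @export
evaluate_signature <- function(model, m, labeling, test) {
  lab <- labeling$labels[labeling$labels != "excluded"]
  test <- intersect(test, names(lab))
  if (length(test) == 0L) stop("empty test set")
  truth <- lab[test]
  if (length(unique(truth)) < 2L) stop("test set holds a single class")
  prob <- predict(model, m, cell_lines = test)
  called_res <- prob >= 0.5
  TP <- sum(called_res & truth == "resistant")
  FP <- sum(called_res & truth == "sensitive")
  TN <- sum(!called_res & truth == "sensitive")
  FN <- sum(!called_res & truth == "resistant")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mw <- mann_whitney(prob[truth == "resistant"], prob[truth == "sensitive"])
  test_auc <- mw$U / (sum(truth == "resistant") * sum(truth == "sensitive"))
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = safe_div(TP + TN, TP + TN + FP + FN),
       sensitivity = safe_div(TP, TP + FN),
       specificity = safe_div(TN, TN + FP),
       precision = safe_div(TP, TP + FP),
       test_auc = test_auc, test_auc_p = mw$p, n_test = length(test))
}

#' Run the full gene-signature pipeline
#'
#' Deterministic composition: stratified 66/34 split, Mann-Whitney gene
#' selection on the training set (p < `alpha`), random-forest integration of
#' the selected genes, held-out ROC evaluation. Also emits radar-chart data:
#' the full-cohort folded per-gene AUC of each selected gene.
#'
#' @param m a normalized [expr_matrix].
#' @param labeling a `response_labeling`.
#' @param gene_set character vector of candidate genes.
#' @param seed integer seed driving split and forest.
#' @param gene_set_name label stored in the result.
#' @param alpha selection cutoff (default 0.05).
#' @param train_fraction training fraction (default 0.66).
#' @param ntree,mtry forest hyperparameters (see [fit_signature()]).
#' @return A `signature_result`: selection table, confusion matrix and
#'   derived metrics, test AUC and p, radar data, split bookkeeping.
#' @export
run_signature_pipeline <- function(m, labeling, gene_set, seed,
                                   gene_set_name = "custom", alpha = 0.05,
                                   train_fraction = 0.66, ntree = 500L,
                                   mtry = NULL) {
  parts <- split_train_test(labeling, seed, train_fraction)
  sel <- select_genes(m, labeling, parts$train, gene_set, alpha = alpha)
  if (nrow(sel) == 0L)
    stop("no significant genes: cannot fit a signature")
  model <- fit_signature(m, labeling, parts$train, sel$gene, seed,
                         ntree = ntree, mtry = mtry)
  ev <- evaluate_signature(model, m, labeling, parts$test)
  radar <- vapply(sel$gene, function(g) roc_auc(m$values[g, ], labeling)$auc,
                  numeric(1))
  structure(list(compound = labeling$compound, dataset = labeling$dataset,
                 gene_set_name = gene_set_name, selected_genes = sel,
                 split_seed = seed, n_train = length(parts$train),
                 n_test = length(parts$test), train = parts$train,
                 test = parts$test, model = model, evaluation = ev,
                 radar_auc = radar),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  ev <- x$evaluation
  cat(sprintf("<signature_result> %s / %s (%s): %d genes selected, n_train %d, n_test %d\n",
              x$dataset, x$compound, x$gene_set_name, nrow(x$selected_genes),
              x$n_train, x$n_test))
  cat(sprintf("  confusion TP=%d FP=%d TN=%d FN=%d | accuracy %.3f, sens %.3f, spec %.3f, prec %.3f\n",
              ev$TP, ev$FP, ev$TN, ev$FN, ev$accuracy, ev$sensitivity,
              ev$specificity, ev$precision))
  cat(sprintf("  test ROC AUC %.3f (p = %.3g)\n", ev$test_auc, ev$test_auc_p))
  invisible(x)
}

#' Serialize a signature result to JSON
#'
#' @param x a `signature_result`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_signature_json <- function(x, path) {
  stopifnot(inherits(x, "signature_result"))
  ev <- x$evaluation
  obj <- list(compound = x$compound, dataset = x$dataset,
              gene_set_name = x$gene_set_name,
              selected_genes = x$selected_genes,
              split_seed = x$split_seed, n_train = x$n_train, n_test = x$n_test,
              confusion = list(TP = ev$TP, FP = ev$FP, TN = ev$TN, FN = ev$FN),
              accuracy = ev$accuracy, sensitivity = ev$sensitivity,
              specificity = ev$specificity, precision = ev$precision,
              test_auc = ev$test_auc, test_auc_p = ev$test_auc_p,
              radar_auc = as.list(x$radar_auc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
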