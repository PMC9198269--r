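sig_fixture <- function(seed = 303, n = 120, effects = c(2.5, 2.5),
                        n_genes = 20) {
  planted <- data.frame(gene = seq_along(effects),
                        effect_size = effects,
                        sign = rep(1, length(effects)))
  labeled_cohort(seed = seed, n_genes = n_genes, n = n, planted = planted)
}

test_that("split_train_test sizes, stratification and determinism", {
  lb <- make_labeling(paste0("s", 1:50), paste0("r", 1:50))
  sp <- split_train_test(lb, seed = 1)
  expect_identical(length(sp$train), 66L)
  expect_identical(length(sp$test), 34L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), names(lb$labels))
  # per-class split within rounding of 66/34
  for (cls in c("s", "r")) {
    in_train <- sum(startsWith(sp$train, cls))
    expect_true(in_train %in% c(33L, 34L))
  }
  expect_identical(split_train_test(lb, seed = 1), sp)
  expect_false(identical(split_train_test(lb, seed = 2)$train, sp$train))

  unbalanced <- make_labeling(paste0("s", 1:5), paste0("r", 1:20))
  sp2 <- split_train_test(unbalanced, seed = 3)
  expect_gte(sum(startsWith(sp2$train, "s")), 2L)
  expect_gte(sum(startsWith(sp2$test, "s")), 2L)

  tiny <- make_labeling(paste0("s", 1:2), paste0("r", 1:10))
  expect_error(split_train_test(tiny, seed = 1), "fewer than 2")
  expect_error(split_train_test(make_labeling("s1", paste0("r", 1:20)), 1),
               "at least 12|fewer than 2")
})

test_that("select_genes finds planted markers on training rows only", {
  fix <- sig_fixture()
  sp <- split_train_test(fix$labeling, seed = 5)
  sel <- select_genes(fix$m, fix$labeling, sp$train, rownames(fix$m$values))
  expect_true(all(c("GENE00001", "GENE00002") %in% sel$gene))
  expect_true(all(sel$mw_p < 0.05))

  expect_warning(
    sel2 <- select_genes(fix$m, fix$labeling, sp$train,
                         c("GENE00001", "NOPE")), "NOPE")
  expect_identical(sel2$gene, "GENE00001")
  suppressWarnings(
    expect_error(select_genes(fix$m, fix$labeling, sp$train, c("NO1", "NO2")),
                 "no candidate"))
})

test_that("selection ignores test-set labels entirely (leakage guard)", {
  fix <- sig_fixture(seed = 404)
  for (seed in 1:5) {
    sp <- split_train_test(fix$labeling, seed = seed)
    sel <- select_genes(fix$m, fix$labeling, sp$train, rownames(fix$m$values))
    scr <- fix$labeling
    test_idx <- names(scr$labels) %in% sp$test
    perm <- scr$labels[test_idx]
    set.seed(seed)
    scr$labels[test_idx] <- sample(perm)
    sel_perm <- select_genes(fix$m, scr, sp$train, rownames(fix$m$values))
    expect_identical(sel_perm, sel)
  }
})

test_that("fit_signature is seed-deterministic and learns a separating gene", {
  fix <- sig_fixture()
  sp <- split_train_test(fix$labeling, seed = 7)
  model <- fit_signature(fix$m, fix$labeling, sp$train, "GENE00001", seed = 7)
  model2 <- fit_signature(fix$m, fix$labeling, sp$train, "GENE00001", seed = 7)
  p1 <- predict(model, fix$m); p2 <- predict(model2, fix$m)
  expect_identical(p1, p2)
  expect_error(fit_signature(fix$m, fix$labeling, sp$train, character(0), 1),
               "no significant genes")

  # a perfectly separating feature yields perfect training predictions
  lab <- fix$labeling$labels[fix$labeling$labels != "excluded"]
  v <- fix$m$values
  v["GENE00010", ] <- 0
  v["GENE00010", names(lab)[lab == "resistant"]] <- 100
  m2 <- expr_matrix(v, state = fix$m$state)
  sep <- fit_signature(m2, fix$labeling, sp$train, "GENE00010", seed = 1)
  pr <- predict(sep, m2, cell_lines = intersect(sp$train, names(lab)))
  expect_identical(unname(pr >= 0.5), unname(lab[names(pr)] == "resistant"))
})

test_that("a one-gene forest approximates the single-gene test AUC", {
  fix <- sig_fixture(seed = 511, n = 180, effects = 2.5, n_genes = 15)
  sp <- split_train_test(fix$labeling, seed = 2)
  model <- fit_signature(fix$m, fix$labeling, sp$train, "GENE00001", seed = 2)
  ev <- evaluate_signature(model, fix$m, fix$labeling, sp$test)
  lab <- fix$labeling$labels
  test_lab <- make_labeling(sp$test[lab[sp$test] == "sensitive"],
                            sp$test[lab[sp$test] == "resistant"])
  gene_auc <- roc_auc(fix$m$values["GENE00001", ], test_lab)$auc
  expect_lt(abs(ev$test_auc - gene_auc), 0.1)
})

test_that("evaluate_signature computes the confusion metrics exactly", {
  # synthetic model stub: constant trees that echo a fixed probability per line
  fix <- sig_fixture(seed = 606, n = 90)
  sp <- split_train_test(fix$labeling, seed = 11)
  model <- fit_signature(fix$m, fix$labeling, sp$train, c("GENE00001", "GENE00002"),
                         seed = 11)
  ev <- evaluate_signature(model, fix$m, fix$labeling, sp$test)
  expect_identical(ev$TP + ev$FP + ev$TN + ev$FN, ev$n_test)
  # recompute every metric independently from the confusion counts
  expect_equal(ev$accuracy, (ev$TP + ev$TN) / ev$n_test)
  expect_equal(ev$sensitivity, ev$TP / (ev$TP + ev$FN))
  expect_equal(ev$specificity, ev$TN / (ev$TN + ev$FP))
  expect_equal(ev$precision, ev$TP / (ev$TP + ev$FP))
  # and against a by-hand confusion matrix from the predicted probabilities
  prob <- predict(model, fix$m, cell_lines = intersect(sp$test, names(fix$labeling$labels)))
  truth <- fix$labeling$labels[names(prob)]
  truth <- truth[truth != "excluded"]
  expect_identical(ev$TP, sum(prob[names(truth)] >= 0.5 & truth == "resistant"))
  expect_identical(ev$FN, sum(prob[names(truth)] < 0.5 & truth == "resistant"))

  bad <- make_labeling(character(0), paste0("r", 1:10))
  expect_error(evaluate_signature(model, fix$m, bad, paste0("r", 1:10)),
               "single class|empty")
})

test_that("formula arithmetic example: TP=7 TN=8 FP=2 FN=3", {
  # the documented metric formulas on a fixed confusion matrix
  TP <- 7; TN <- 8; FP <- 2; FN <- 3
  expect_equal((TP + TN) / (TP + TN + FP + FN), 0.75)
  expect_equal(TP / (TP + FN), 0.7)
  expect_equal(TN / (TN + FP), 0.8)
  expect_equal(TP / (TP + FP), 0.778, tolerance = 1e-3)
})

test_that("run_signature_pipeline composes deterministically and serializes", {
  fix <- sig_fixture(seed = 707, n = 120)
  res <- run_signature_pipeline(fix$m, fix$labeling, rownames(fix$m$values),
                                seed = 42, gene_set_name = "ALL", ntree = 200)
  expect_s3_class(res, "signature_result")
  expect_identical(res$n_train + res$n_test,
                   sum(fix$labeling$labels != "excluded"))
  expect_true(all(res$selected_genes$mw_p < 0.05))
  expect_identical(names(res$radar_auc), res$selected_genes$gene)
  expect_true(all(res$radar_auc >= 0.5 & res$radar_auc <= 1))

  res2 <- run_signature_pipeline(fix$m, fix$labeling, rownames(fix$m$values),
                                 seed = 42, gene_set_name = "ALL", ntree = 200)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_signature_json(res, f1); write_signature_json(res2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
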