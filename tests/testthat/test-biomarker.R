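test_that("mann_whitney matches hand examples and the stats oracle", {
  expect_equal(mann_whitney(1:3, 4:6)$U, 0)
  sym <- mann_whitney(c(1, 3, 5, 7), c(1, 3, 5, 7))
  expect_equal(sym$U, 8)  # n^2/2
  expect_gt(sym$p, 0.9)
  expect_equal(mann_whitney(c(1, 2), c(1, 2))$U, 2)  # midranks
  expect_error(mann_whitney(1, 1:5), "at least 2")

  # oracle: stats::wilcox.test across random instances, exact and approximate
  set.seed(19)
  for (i in 1:40) {
    nx <- sample(2:25, 1); ny <- sample(2:25, 1)
    tied <- i %% 2 == 0
    x <- if (tied) sample(1:6, nx, TRUE) else rnorm(nx)
    y <- if (tied) sample(1:6, ny, TRUE) else rnorm(ny)
    ours <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(
      x, y, exact = !tied && nx <= 20 && ny <= 20, correct = TRUE))
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("raw AUC times n_s*n_r equals the brute-force pairwise U everywhere", {
  set.seed(23)
  for (i in 1:120) {
    ns <- sample(2:15, 1); nr <- sample(2:15, 1)
    pool <- if (i %% 2 == 0) sample(1:5, ns + nr, TRUE) else rnorm(ns + nr)
    sens <- paste0("s", seq_len(ns)); res <- paste0("r", seq_len(nr))
    expr <- setNames(pool, c(sens, res))
    st <- roc_auc(expr, make_labeling(sens, res))
    expect_identical(st$U, brute_U(expr[res], expr[sens]))
  }
})

test_that("roc_auc folds orientation and reports direction", {
  lb <- make_labeling(c("s1", "s2", "s3"), c("r1", "r2", "r3"))
  up <- setNames(c(1, 1, 1, 10, 10, 10), c("s1", "s2", "s3", "r1", "r2", "r3"))
  st <- roc_auc(up, lb)
  expect_equal(st$auc, 1); expect_identical(st$direction, "higher_in_resistant")

  down <- setNames(c(4, 5, 6, 1, 2, 3), c("s1", "s2", "s3", "r1", "r2", "r3"))
  st2 <- roc_auc(down, lb)
  expect_equal(st2$auc, 1); expect_equal(st2$raw_auc, 0)
  expect_identical(st2$direction, "higher_in_sensitive")

  flat <- setNames(rep(2, 6), names(up))
  st3 <- roc_auc(flat, lb)
  expect_equal(st3$auc, 0.5); expect_identical(st3$direction, "none")

  # swapping the class labels keeps auc, flips direction
  set.seed(4)
  e <- setNames(rnorm(12), paste0("c", 1:12))
  a <- roc_auc(e, make_labeling(paste0("c", 1:6), paste0("c", 7:12)))
  b <- roc_auc(e, make_labeling(paste0("c", 7:12), paste0("c", 1:6)))
  expect_equal(a$auc, b$auc)
  if (a$direction != "none")
    expect_true(setequal(c(a$direction, b$direction),
                         c("higher_in_resistant", "higher_in_sensitive")))

  # monotone-transform invariance of the AUC
  expect_equal(roc_auc(exp(e), make_labeling(paste0("c", 1:6), paste0("c", 7:12)))$auc,
               a$auc)

  # missing expression: tolerated below 50%, fatal above
  lb8 <- make_labeling(paste0("s", 1:4), paste0("r", 1:4))
  partial <- setNames(c(1:4, 8, 9), c(paste0("s", 1:4), "r1", "r2"))
  expect_warning(st <- roc_auc(partial, lb8), "dropped")
  expect_equal(st$n_resistant, 2L)
  tiny <- setNames(1:3, c("s1", "s2", "r1"))
  expect_error(roc_auc(tiny, lb8), "more than half")
})

test_that("spearman_vs_response gives exact small-sample values", {
  nm <- letters[1:4]
  expect_equal(spearman_vs_response(setNames(1:4, nm), setNames(c(2, 1, 4, 3), nm))$rho, 0.6)
  nm3 <- letters[1:5]
  expect_equal(spearman_vs_response(setNames(1:5, nm3), setNames(5:1, nm3))$rho, -1)
  expect_equal(spearman_vs_response(setNames(1:5, nm3), setNames(1:5, nm3))$rho, 1)
  expect_error(spearman_vs_response(setNames(1:3, letters[1:3]),
                                    setNames(1:3, letters[1:3])), "at least 4")
  # midranks + t approximation agree with cor.test
  set.seed(31)
  x <- setNames(sample(1:8, 12, TRUE), paste0("c", 1:12))
  y <- setNames(rnorm(12), paste0("c", 1:12))
  ours <- spearman_vs_response(x, y)
  ref <- suppressWarnings(stats::cor.test(unname(x), unname(y),
                                          method = "spearman", exact = FALSE))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
})

test_that("mean_signature averages present genes and reports misses", {
  m <- make_expr(rbind(c(100, 10), c(300, 30)), genes = c("A", "B"),
                 state = "prenormalized")
  expect_equal(unname(mean_signature(c("A", "B"), m)), c(200, 20))
  expect_equal(mean_signature("A", m), m$values["A", ])
  expect_warning(out <- mean_signature(c("A", "B", "ZZZ"), m), "ZZZ")
  expect_equal(unname(out), c(200, 20))
  expect_error(mean_signature(c("X", "Y"), m), "X, Y")
})

test_that("bh_fdr matches the step-up definition and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")

  set.seed(13)
  p <- runif(200)^2
  q <- bh_fdr(p)
  expect_equal(q, stats::p.adjust(p, "BH"))
  expect_true(all(q >= p))
  # nested rejection sets across thresholds
  for (alpha in c(0.01, 0.05, 0.2))
    expect_true(all(which(q <= alpha / 2) %in% which(q <= alpha)))
})

test_that("gene_screen ranks a strongly planted marker first and scopes FDR", {
  planted <- data.frame(gene = 7L, effect_size = 3, sign = 1)
  fix <- labeled_cohort(seed = 91, n_genes = 40, n = 90, planted = planted)
  screen <- gene_screen(fix$m, fix$labeling, audrc = fix$audrc)
  expect_identical(screen$gene[1], "GENE00007")
  expect_gt(screen$auc[1], 0.9)
  expect_identical(screen$direction[1], "higher_in_resistant")
  # planted marker tracks resistance, so expression rises with AUDRC
  expect_gt(screen$spearman_rho[1], 0.5)
  expect_true(all(screen$fdr_q >= screen$mw_p))
  expect_true(all(diff(screen$auc) <= 0))

  sub <- gene_screen(fix$m, fix$labeling, audrc = fix$audrc,
                     genes = c("GENE00001", "GENE00002", "GENE00007"))
  expect_identical(nrow(sub), 3L)
  # FDR over exactly the screened m = 3 genes
  expect_equal(sort(sub$fdr_q),
               sort(bh_fdr(sub$mw_p)))
})

test_that("correlation_matrix retains only significant, correlated genes", {
  planted <- data.frame(gene = c(3L, 5L), effect_size = c(3, 3), sign = c(1, -1))
  fix <- labeled_cohort(seed = 55, n_genes = 30, n = 90, planted = planted)
  ic50 <- setNames(fix$cohort$responses$ic50, fix$cohort$responses$cell_line)
  cm <- correlation_matrix(fix$m, rownames(fix$m$values), fix$labeling,
                           audrc = fix$audrc, ic50 = ic50)
  expect_true(all(c("AUDRC", "IC50", "GENE00003", "GENE00005") %in% colnames(cm)))
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
  expect_equal(cm, t(cm))
  screen <- attr(cm, "screen")
  kept <- setdiff(colnames(cm), c("AUDRC", "IC50"))
  crit <- screen$gene[screen$mw_p < 0.05 & abs(screen$spearman_rho) >= 0.20]
  expect_setequal(kept, crit)

  # nothing survives on pure noise with a sky-high threshold
  nullfix <- labeled_cohort(seed = 60, n_genes = 10, n = 60)
  expect_warning(
    empty <- correlation_matrix(nullfix$m, rownames(nullfix$m$values),
                                nullfix$labeling, audrc = nullfix$audrc,
                                rho_threshold = 0.99),
    "no gene")
  expect_identical(dim(empty), c(0L, 0L))
})
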