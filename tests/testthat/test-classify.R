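# Splitting, likelihood-ratio scoring, ROC analysis, baselines, pipeline.

test_that("train/test splits are disjoint, exhaustive and honour the unit", {
  ds <- make_two_class_study(synthetic_study_spec(
    n_subjects_per_class = 10L, reps_per_subject = 4L, seed = 130))
  sp <- split_train_test(ds, split_spec(0.2, unit = "subject", seed = 131))
  n_all <- nrow(ds$coords)
  got <- c(nrow(sp$train_A$coords), nrow(sp$test_A$coords),
           nrow(sp$train_B$coords), nrow(sp$test_B$coords))
  expect_equal(sum(got), n_all)
  expect_equal(length(unique(sp$train_A$subject_id)), 2L)  # 20% of 10
  expect_length(intersect(sp$train_A$subject_id, sp$test_A$subject_id), 0)
  expect_length(intersect(sp$train_B$subject_id, sp$test_B$subject_id), 0)

  spv <- split_train_test(ds, split_spec(0.2, unit = "vector", seed = 132))
  key <- function(d) paste(d$subject_id, d$rep_index)
  all_keys <- paste(ds$subject_id, ds$rep_index)
  train_keys <- c(key(spv$train_A), key(spv$train_B))
  test_keys <- c(key(spv$test_A), key(spv$test_B))
  expect_setequal(c(train_keys, test_keys), all_keys)
  expect_length(intersect(train_keys, test_keys), 0)

  expect_error(split_train_test(ds, split_spec(0.001, seed = 1)), "small")
})

test_that("likelihood-ratio scores match the closed-form Gaussian difference", {
  set.seed(133)
  ca <- matrix(c(1, 0.3, 0.3, 1), 2); cb <- matrix(c(2, -0.4, -0.4, 1), 2)
  ma <- c(0.5, 0); mb <- c(-0.5, 0.2)
  mom <- function(m, cv) structure(
    list(mean = m, cov = cv + tcrossprod(m), third = NULL,
         n_samples = 100L, max_order = 2L, d = 2L),
    class = "moment_statistics")
  fa <- fit_gaussian_maxent(mom(ma, ca))
  fb <- fit_gaussian_maxent(mom(mb, cb))
  x <- matrix(rnorm(20), 10, 2)
  s <- likelihood_ratio_scores(fa, fb, x)
  hand <- ref_mvn_logpdf(x, ma, ca) - ref_mvn_logpdf(x, mb, cb)
  expect_equal(s, hand, tolerance = 1e-9)
  # identical models score zero
  expect_equal(likelihood_ratio_scores(fa, fa, x), rep(0, 10))
  # antisymmetry and ROC reflection
  lab <- rep(c(TRUE, FALSE), 5)
  r1 <- roc_analysis(s, lab)
  r2 <- roc_analysis(likelihood_ratio_scores(fb, fa, x), lab)
  expect_equal(likelihood_ratio_scores(fb, fa, x), -s)
  expect_equal(r2$auroc, 1 - r1$auroc, tolerance = 1e-12)
})

test_that("ROC analysis agrees with brute force and handles ties", {
  r <- roc_analysis(c(1, 2, -1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auroc, 1)
  expect_equal(r$max_accuracy, 1)

  r2 <- roc_analysis(c(0.9, 0.8, 0.3), c("A", "B", "A"))
  expect_equal(r2$auroc, 0.5)
  expect_equal(r2$max_accuracy, 2 / 3)

  set.seed(134)
  sc <- round(rnorm(200), 1)                 # many ties
  lab <- sample(c(TRUE, FALSE), 200, TRUE)
  r3 <- roc_analysis(sc, lab)
  expect_equal(r3$auroc, brute_auroc(sc, lab), tolerance = 1e-12)
  expect_true(all(diff(r3$fpr) >= 0))
  expect_true(all(diff(r3$tpr) >= 0))
  # independent implementation cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(r3$auroc,
                 as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE))),
                 tolerance = 1e-12)
  }
  # monotone transforms leave the ROC unchanged
  r4 <- roc_analysis(exp(2 * sc + 1), lab)
  expect_equal(r4$auroc, r3$auroc, tolerance = 1e-12)
  expect_equal(r4$max_accuracy, r3$max_accuracy, tolerance = 1e-12)

  expect_error(roc_analysis(sc, rep(TRUE, 200)), "both classes")
})

test_that("shuffled labels give chance-level auROC", {
  set.seed(135)
  sc <- rnorm(400)
  aucs <- replicate(20, roc_analysis(sc, sample(rep(c(TRUE, FALSE), 200)))$auroc)
  se <- sqrt((400 + 1) / (12 * 200 * 200))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se / sqrt(20))
})

test_that("PC t-test scores behave like a linear discriminant baseline", {
  set.seed(136)
  # mean shift along the first coordinate only
  xa <- cbind(rnorm(300, 1), matrix(rnorm(300 * 3), 300))
  xb <- cbind(rnorm(300, -1), matrix(rnorm(300 * 3), 300))
  xt <- rbind(cbind(rnorm(100, 1), matrix(rnorm(300), 100)),
              cbind(rnorm(100, -1), matrix(rnorm(300), 100)))
  s <- pc_ttest_scores(xa, xb, xt)
  r <- roc_analysis(s, rep(c(TRUE, FALSE), each = 100))
  expect_gt(r$auroc, 0.9)
  # test vectors play no role in axis estimation
  s_head <- pc_ttest_scores(xa, xb, xt[1:10, , drop = FALSE])
  expect_equal(s_head, s[1:10])
  # identical training classes: chance on exchangeable test points
  set.seed(137)
  xa0 <- matrix(rnorm(400 * 4), 400)
  xb0 <- matrix(rnorm(400 * 4), 400)
  xt0 <- matrix(rnorm(400 * 4), 400)
  s0 <- pc_ttest_scores(xa0, xb0, xt0)
  r0 <- roc_analysis(s0, rep(c(TRUE, FALSE), 200))
  expect_lt(abs(r0$auroc - 0.5), 3 * sqrt(401 / (12 * 200 * 200)))
})

test_that("random forest separates separable classes and is seeded", {
  set.seed(138)
  tr <- rbind(cbind(rnorm(150, 3), rnorm(150)), cbind(rnorm(150, -3), rnorm(150)))
  lab <- rep(c(TRUE, FALSE), each = 150)
  te <- rbind(cbind(rnorm(80, 3), rnorm(80)), cbind(rnorm(80, -3), rnorm(80)))
  s1 <- rf_scores(tr, lab, te, seed = 139)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_gt(roc_analysis(s1, rep(c(TRUE, FALSE), each = 80))$auroc, 0.99)
  s2 <- rf_scores(tr, lab, te, seed = 139)
  expect_identical(s1, s2)
})

test_that("fitted likelihood-ratio auROC approaches the analytic optimum", {
  set.seed(140)
  ca <- matrix(c(1, 0.5, 0.5, 1), 2); cb <- diag(c(1.5, 0.8))
  ma <- c(0.4, 0); mb <- c(-0.4, 0.1)
  xa <- MASS::mvrnorm(20000, ma, ca); xb <- MASS::mvrnorm(20000, mb, cb)
  ta <- MASS::mvrnorm(5000, ma, ca); tb <- MASS::mvrnorm(5000, mb, cb)
  xt <- rbind(ta, tb)
  lab <- rep(c(TRUE, FALSE), each = 5000)
  # Monte-Carlo oracle: ROC of the true log-likelihood ratio
  true_s <- ref_mvn_logpdf(xt, ma, ca) - ref_mvn_logpdf(xt, mb, cb)
  opt <- roc_analysis(true_s, lab)$auroc
  fa <- fit_gaussian_maxent(moment_statistics(xa, 2L))
  fb <- fit_gaussian_maxent(moment_statistics(xb, 2L))
  got <- roc_analysis(likelihood_ratio_scores(fa, fb, xt), lab)$auroc
  expect_lt(abs(got - opt), 0.01)
})

test_that("the planted third-order study separates model orders", {
  spec <- synthetic_study_spec(n_subjects_per_class = 60L,
                               difference_order = 3, seed = 11)
  ds <- make_two_class_study(spec)
  rep <- run_gender_pipeline(ds, spec = split_spec(seed = 21),
                             methods = c("maxent1", "maxent2", "maxent3"),
                             seed = 31)
  a1 <- rep$methods$maxent1$auroc
  a2 <- rep$methods$maxent2$auroc
  a3 <- rep$methods$maxent3$auroc
  # matched first/second moments leave the linear and pairwise models blind
  expect_lt(abs(a2 - 0.5), 0.1)
  expect_lte(a1, a2 + 0.05)
  expect_gt(a3 - a2, 0.1)
})

test_that("the pipeline reports all six methods deterministically", {
  ds <- make_two_class_study(synthetic_study_spec(
    n_subjects_per_class = 24L, reps_per_subject = 8L,
    difference_order = 1, seed = 141))
  methods <- c("maxent1", "maxent2", "rf", "pc_ttest")
  r1 <- run_gender_pipeline(ds, spec = split_spec(seed = 142),
                            methods = methods, seed = 143)
  r2 <- run_gender_pipeline(ds, spec = split_spec(seed = 142),
                            methods = methods, seed = 143)
  expect_identical(names(r1$methods), methods)
  for (m in methods) {
    expect_identical(r1$methods[[m]]$auroc, r2$methods[[m]]$auroc)
  }
  # a planted mean shift is visible to every method
  expect_gt(r1$methods$maxent1$auroc, 0.6)
  expect_gt(r1$methods$rf$auroc, 0.6)

  d <- tempfile()
  write_gender_report(r1, d)
  js <- jsonlite::read_json(file.path(d, "report.json"))
  expect_setequal(names(js$methods), methods)
  roc_file <- file.path(d, "maxent2_roc.tsv")
  expect_true(file.exists(roc_file))
  tsv <- utils::read.delim(roc_file)
  expect_identical(names(tsv), c("threshold", "fpr", "tpr"))
})
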