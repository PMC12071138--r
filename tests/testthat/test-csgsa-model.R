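make_toy_cohort <- function(seed = 3, n = 60, n_egp = 40) {
  set.seed(seed)
  markers <- matrix(10^rnorm(n * 9), n, dimnames = list(sprintf("S%02d", 1:n),
                                                        paste0("M", 1:9)))
  glyco <- matrix(runif(n * 2), n, dimnames = list(rownames(markers),
                                                   c("MG1", "MG2")))
  egp <- matrix(10^rnorm(n * n_egp), n,
                dimnames = list(rownames(markers), paste0("E", 1:n_egp)))
  labels <- rep(c("cancer", "healthy"), each = n / 2)
  list(markers = markers, glyco = glyco, egp = egp, labels = labels)
}

test_that("feature tables have the model-set composition and leak-free PCA", {
  tc <- make_toy_cohort()
  tr <- c(1:20, 31:50)
  f1 <- buildFeatures(tc$markers, tc$glyco, tc$egp, modelSet = 1,
                      trainIndex = tr)
  expect_equal(ncol(f1$train), 9)
  f2 <- buildFeatures(tc$markers, tc$glyco, tc$egp, modelSet = 2,
                      trainIndex = tr)
  expect_equal(ncol(f2$train), 11)
  f3 <- buildFeatures(tc$markers, tc$glyco, tc$egp, modelSet = 3, k = 10,
                      trainIndex = tr)
  expect_equal(ncol(f3$train), 21)   # 9 markers + 2 glycopeptides + 10 PCs
  expect_equal(as.integer(table(f3$roles)[c("marker", "glycopeptide", "pc")]),
               c(9L, 2L, 10L))
  expect_error(buildFeatures(tc$markers, tc$glyco, tc$egp, modelSet = 3,
                             k = 1000, trainIndex = tr), "feasible")

  # PCA self-consistency: the train block reproduces prcomp scores fit on
  # the training fold only (up to the final column standardization)
  z <- scale(tc$egp[tr, ])
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  sc <- pc$x[, 1:10]
  expected <- sweep(sweep(sc, 2, colMeans(sc)), 2, apply(sc, 2, sd), `/`)
  expect_equal(unname(f3$train[, paste0("PC", 1:10)]), unname(expected),
               tolerance = 1e-8)
})

test_that("both learners separate a linearly separable toy and are seed-deterministic", {
  set.seed(1)
  n <- 200
  x <- cbind(a = c(rnorm(n / 2, 3), rnorm(n / 2)),
             b = c(rnorm(n / 2, -3), rnorm(n / 2)))
  y <- rep(c(1, 0), each = n / 2)
  for (lr in c("nn", "gbt")) {
    m <- trainClassifier(x, y, learner = lr, seed = 3)
    p <- predict(m, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_gte(rocAUC(p, y, positive = 1)$auc, 0.99)
    p2 <- predict(trainClassifier(x, y, learner = lr, seed = 3), x)
    expect_identical(p, p2)
  }
  expect_error(trainClassifier(x, rep(1, n), learner = "nn"), "single class")
})

test_that("repeated stratified splits pool the expected predictions", {
  tc <- make_toy_cohort(seed = 9, n = 100)
  ev <- repeatedSplitEvaluate(tc$markers, tc$glyco, tc$egp, tc$labels,
                              modelSet = 1, learner = "gbt", nRepeats = 4,
                              seed = 7)
  # 100 samples, 70/30 stratified: 30 test predictions per repeat
  expect_equal(nrow(ev$predictions), 4 * 30)
  expect_equal(length(ev$per_repeat_auc), 4)
  # stratification: each repeat's test fold has 15 of each class
  by_rep <- split(ev$predictions$label, ev$predictions$rep)
  for (b in by_rep) expect_equal(sum(b), 15)
  # determinism of the full protocol
  ev2 <- repeatedSplitEvaluate(tc$markers, tc$glyco, tc$egp, tc$labels,
                               modelSet = 1, learner = "gbt", nRepeats = 4,
                               seed = 7)
  expect_identical(ev$predictions, ev2$predictions)
})

test_that("the CSGSA score transform is the capped -log10 complement with exact inverse", {
  expect_equal(csgsaScore(c(0, 0.9, 0.99, 1)), c(0, 1, 2, 10))
  p <- c(0, 10^-(1:9), 0.5, 0.9, 1 - 10^-(1:10))
  expect_equal(csgsaProb(csgsaScore(p)), pmin(p, 1 - 1e-10), tolerance = 1e-9)
  expect_true(all(diff(csgsaScore(seq(0, 1, by = 0.01))) >= 0))
  expect_error(csgsaScore(1.2), "\\[0, 1\\]")
  expect_error(csgsaScore(-0.1), "\\[0, 1\\]")
})

test_that("learner comparison is a paired t-test with symmetric p and degenerate care", {
  a <- c(0.90, 0.91, 0.89, 0.92, 0.90)
  expect_equal(compareLearners(a, a), 1)
  set.seed(13)
  b <- a - 0.05 + rnorm(5, sd = 1e-3)
  p <- compareLearners(a, b)
  expect_lt(p, 0.01)
  expect_equal(compareLearners(b, a), p)
  expect_equal(p, t.test(a, b, paired = TRUE)$p.value)
  expect_error(compareLearners(0.9, 0.8), "2 repeats")
})

test_that("tree feature importance counts splits and finds the informative feature", {
  set.seed(17)
  n <- 300
  x <- cbind(signal = c(rnorm(n / 2, 3), rnorm(n / 2)),
             junk1 = rnorm(n), junk2 = rnorm(n))
  y <- rep(c(1, 0), each = n / 2)
  # a short ensemble: long boosting runs spend late splits on noise
  m <- trainClassifier(x, y, learner = "gbt", seed = 1,
                       params = list(nrounds = 25))
  fi <- featureImportance(m)
  expect_identical(names(fi)[1], "signal")
  # conservation: counts sum to the ensemble's total split count
  dump <- xgboost::xgb.dump(m$fit)
  expect_equal(sum(fi), sum(grepl("<", dump, fixed = TRUE)))

  # a depth-1 single-tree ensemble has exactly one split
  m1 <- trainClassifier(x, y, learner = "gbt", seed = 1,
                        params = list(nrounds = 1, max_depth = 1))
  expect_identical(featureImportance(m1), c(signal = 1L))
  expect_error(featureImportance(trainClassifier(x, y, "nn", seed = 1)),
               "tree")
})
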