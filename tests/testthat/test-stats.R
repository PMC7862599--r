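test_that("AUC reproduces the enumerable examples", {
  expect_identical(auc(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))), 1)
  expect_identical(auc(rocAuc(c(1, 3, 2, 4), c(0, 0, 1, 1))), 0.75)
  expect_error(rocAuc(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals brute-force pair counting and is label-swap antisymmetric", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    scores <- round(runif(n, 0, 10), sample(0:1, 1))  # ties likely
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    a <- auc(rocAuc(scores, labels))
    expect_equal(a, bruteAuc(scores, labels), tolerance = 1e-12)
    expect_equal(auc(rocAuc(scores, 1 - labels)), 1 - a, tolerance = 1e-12)
  }
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5)
  r <- rocAuc(scores, labels)
  pr <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(pr, method = "delong")))
  expect_equal(auc(r), as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  expect_equal(c(r@ciLo, r@ciHi), ci[c(1, 3)], tolerance = 1e-8)
})

test_that("Youden cutoff equals exhaustive search with low-threshold ties", {
  y <- youdenCutoff(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_identical(y$youden, 1)
  set.seed(17)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    scores <- round(runif(n, 0, 10), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    got <- youdenCutoff(scores, labels)
    ref <- bruteYouden(scores, labels)
    expect_equal(got$youden, ref$j, tolerance = 1e-12)
    expect_identical(got$cutoff, ref$t)
  }
  # thresholds 2 and 4 share J = 0.5 here; the lower one must win
  tie <- youdenCutoff(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_identical(tie$cutoff, 2)
})

test_that("exact Wilcoxon reproduces enumerable p-values", {
  expect_equal(exactWilcoxon(c(1, 2), c(3, 4))$p_two_sided, 1 / 3,
               tolerance = 1e-12)
  expect_identical(exactWilcoxon(5, 5)$p_two_sided, 1)
  expect_error(exactWilcoxon(numeric(0), 1), "non-empty")
})

test_that("exact Wilcoxon equals full enumeration including ties", {
  set.seed(19)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    na <- sample(seq_len(n - 1), 1)
    v <- sample(1:5, n, replace = TRUE)      # heavy ties
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    got <- exactWilcoxon(a, b)
    expect_true(got$exact)
    expect_equal(got$p_two_sided, bruteWilcoxonP(a, b), tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with the distribution-based reference", {
  set.seed(23)
  a <- rnorm(6); b <- rnorm(7) + 1
  got <- exactWilcoxon(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(got$p_two_sided, ref, tolerance = 1e-12)
})

test_that("large samples fall back to a flagged normal approximation", {
  set.seed(29)
  a <- rnorm(25); b <- rnorm(25) + 0.8
  got <- exactWilcoxon(a, b)
  expect_false(got$exact)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p_two_sided, ref, tolerance = 0.01)
})

test_that("Spearman correlation matches the rank formula and reference", {
  expect_equal(spearmanRank(1:10, 2 * (1:10))$rho, 1, tolerance = 1e-12)
  expect_equal(spearmanRank(1:10, rev(1:10))$rho, -1, tolerance = 1e-12)
  set.seed(31)
  x <- rnorm(15); y <- x + rnorm(15)
  got <- spearmanRank(x, y)
  expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
})

test_that("ordinal trend test matches hand-computed normal equations", {
  # 6 points, grades 1..3, two per grade
  vals <- c(10, 12, 8, 9, 5, 6)
  grades <- c(1, 1, 2, 2, 3, 3)
  got <- ordinalTrend(vals, grades)
  # closed form: slope = Sxy / Sxx
  sx <- grades - mean(grades); sy <- vals - mean(vals)
  slope <- sum(sx * sy) / sum(sx^2)
  expect_equal(got$slope, slope, tolerance = 1e-12)
  expect_lt(got$p, 0.05)
  flat <- ordinalTrend(c(5, 5, 7, 7, 5, 5, 7, 7),
                       c(1, 1, 1, 1, 2, 2, 2, 2))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  # declining means with tight noise: strongly negative trend
  set.seed(37)
  v <- rep(c(50, 40, 30, 20), each = 5) + rnorm(20, 0, 0.5)
  g <- rep(1:4, each = 5)
  tr <- ordinalTrend(v, g)
  expect_lt(tr$slope, -9)
  expect_lt(tr$p, 1e-6)
})
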