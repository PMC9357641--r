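test_that("blank tiles are tallied as predicted negatives", {
  blank64 <- data.frame(truth_label = "no_cancer", is_blank = TRUE,
                        score = NA_real_)[rep(1, 64), ]
  cm <- tileOutcomes(blank64)
  expect_equal(c(cm@tp, cm@fp, cm@fn, cm@tn), c(0, 0, 0, 64))
  blankCancer <- transform(blank64, truth_label = "cancer")
  cm2 <- tileOutcomes(blankCancer)
  expect_equal(c(cm2@tp, cm2@fp, cm2@fn, cm2@tn), c(0, 0, 64, 0))
  expect_error(tileOutcomes(transform(blank64, truth_label = NA)),
               "data error")
})

test_that("confusion totals conserve tiles on a synthetic manifest", {
  set.seed(30)
  n <- 64 * 7
  man <- data.frame(
    truth_label = sample(c("cancer", "no_cancer"), n, TRUE),
    is_blank = runif(n) < 0.2,
    score = NA_real_)
  man$score[!man$is_blank] <- runif(sum(!man$is_blank))
  cm <- tileOutcomes(man)
  expect_equal(totalCount(cm), n)
  ## independent recount
  pos <- with(man, !is_blank & score >= 0.5 & !is.na(score))
  expect_equal(cm@tp, sum(pos & man$truth_label == "cancer"))
  expect_equal(cm@tn, sum(!pos & man$truth_label == "no_cancer"))
})

test_that("metrics reproduce the published tile-level confusion matrix", {
  m <- matrixMetrics(confusionMatrix(37267, 7815, 2283, 105787))
  expect_equal(round(unname(m), 3), c(0.934, 0.827, 0.942, 0.881))
})

test_that("metric edge cases: perfect and degenerate classifiers", {
  expect_equal(unname(matrixMetrics(confusionMatrix(10, 0, 0, 10))),
               c(1, 1, 1, 1))
  m <- matrixMetrics(confusionMatrix(0, 0, 5, 5))
  expect_equal(unname(m["accuracy"]), 0.5)
  expect_equal(unname(m["recall"]), 0)
  expect_true(is.nan(m["precision"]))
})

test_that("malignant probability lives on the /64 grid", {
  expect_equal(malignantProbability(0), 0)
  expect_equal(malignantProbability(4), 0.0625)
  expect_equal(malignantProbability(64), 1)
  expect_error(malignantProbability(65), "geometry error")
  expect_error(malignantProbability(rep(TRUE, 63)), "geometry error")
  ## the clinical operating point: 4 positive tiles is called malignant
  cfg <- verdictConfig()
  expect_true(malignantProbability(4) >= cfg@threshold)
  expect_false(malignantProbability(3) >= cfg@threshold)
})

test_that("image-level rates reproduce the published sensitivity/specificity", {
  v <- data.frame(
    predicted_class = c(rep("malignant", 1314), rep("nonmalignant", 42),
                        rep("nonmalignant", 974), rep("malignant", 63)),
    truth_class = c(rep("cancerous", 1356), rep("normal", 1037)))
  r <- imageLevelRates(v)
  expect_equal(round(unname(r), 3), c(0.969, 0.939))
  perfect <- data.frame(predicted_class = c("malignant", "nonmalignant"),
                        truth_class = c("cancerous", "normal"))
  expect_equal(unname(imageLevelRates(perfect)), c(1, 1))
})

test_that("ROC handles perfect, tied and swapped score configurations", {
  mk <- function(s, y) data.frame(malignant_probability = s, truth_class = y)
  perfect <- mk(c(0.8, 0.7, 0.1, 0.2),
                c("cancerous", "cancerous", "normal", "normal"))
  expect_equal(rocCurve(perfect)$auc, 1)
  tied <- mk(rep(0.25, 6), rep(c("cancerous", "normal"), 3))
  expect_equal(rocCurve(tied)$auc, 0.5)
  ## one swapped middle pair: brute-force pair counting gives 0.75
  swap <- mk(c(0.8, 0.4, 0.6, 0.2),
             c("cancerous", "cancerous", "normal", "normal"))
  expect_equal(rocCurve(swap)$auc, 0.75)
  single <- mk(c(0.1, 0.2), c("normal", "normal"))
  expect_true(is.na(rocCurve(single)$auc))
})

test_that("trapezoid AUC equals the concordant-pair statistic", {
  set.seed(31)
  for (rep in 1:5) {
    nC <- sample(5:25, 1); nN <- sample(5:25, 1)
    sC <- sample(0:64, nC, TRUE) / 64
    sN <- sample(0:64, nN, TRUE) / 64
    v <- data.frame(malignant_probability = c(sC, sN),
                    truth_class = rep(c("cancerous", "normal"), c(nC, nN)))
    pairs <- outer(sC, sN, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(rocCurve(v)$auc, mean(pairs))
    ## and the Mann-Whitney machinery agrees: U / (n1 n2)
    expect_equal(mannWhitneyU(sC, sN)$U / (nC * nN), mean(pairs))
    ## independent reference implementation
    expect_equal(rocCurve(v)$auc,
                 as.numeric(suppressMessages(
                   pROC::auc(rep(c(1, 0), c(nC, nN)), c(sC, sN),
                             levels = c(0, 1), direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("image verdict thresholds are monotone in the expected direction", {
  set.seed(32)
  n <- 12
  man <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(0:64, 1)
    data.frame(image_id = sprintf("im%02d", i),
               truth_label = if (i %% 2) "cancer" else "no_cancer",
               is_blank = FALSE,
               score = c(rep(0.9, k), rep(0.1, 64 - k)))
  }))
  prev <- c(sensitivity = 1, specificity = 0)
  for (th in c(0.01, 0.0625, 0.25, 0.5, 0.9)) {
    v <- imageVerdicts(man, verdictConfig(threshold = th))
    r <- imageLevelRates(v)
    expect_lte(r["sensitivity"], prev["sensitivity"] + 1e-12)
    expect_gte(r["specificity"], prev["specificity"] - 1e-12)
    prev <- r
  }
})

test_that("Mann-Whitney U covers separation, ties and the exact path", {
  full <- mannWhitneyU(c(5, 6, 7), c(1, 2, 3))
  expect_equal(full$U, 9)
  expect_lt(full$p.value, 0.11)   # exact two-sided floor at n = 3/3
  tie <- mannWhitneyU(1, 1)
  expect_equal(tie$p.value, 1)
  ## exact path vs wilcox.test on tie-free samples
  set.seed(33)
  x <- rnorm(8); y <- rnorm(9, 0.8)
  ours <- mannWhitneyU(x, y)
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
  ## normal-approximation path vs wilcox.test without continuity correction
  x2 <- rnorm(30); y2 <- rnorm(35, 0.5)
  ours2 <- mannWhitneyU(x2, y2)
  ref2 <- wilcox.test(x2, y2, exact = FALSE, correct = FALSE)
  expect_equal(ours2$p.value, ref2$p.value, tolerance = 1e-10)
})

test_that("Cohen's kappa matches hand computations and e1071", {
  expect_equal(cohensKappa(matrix(c(25, 0, 0, 30), 2, byrow = TRUE)), 1)
  expect_equal(cohensKappa(matrix(c(6, 4, 0, 0), 2, byrow = TRUE)), 0)
  expect_equal(cohensKappa(matrix(c(20, 5, 10, 15), 2, byrow = TRUE)), 0.4)
  expect_error(cohensKappa(matrix(0, 2, 2)), "positive total")
  tab <- matrix(c(18, 7, 3, 22), 2, byrow = TRUE)
  expect_equal(cohensKappa(tab),
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})
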