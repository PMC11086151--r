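test_that("confusion counts match a brute-force tally", {
  labels <- rep(c("ES", "PNES"), c(4, 6))
  cm <- confusion(labels, labels)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(4L, 0L, 0L, 6L))

  cm2 <- confusion(labels, rep("PNES", 10))
  expect_equal(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(0L, 0L, 4L, 6L))

  set.seed(51)
  lab <- sample(c("ES", "PNES"), 50, replace = TRUE)
  pred <- sample(c("ES", "PNES"), 50, replace = TRUE)
  cm3 <- confusion(lab, pred)
  tab <- table(factor(lab, c("ES", "PNES")), factor(pred, c("ES", "PNES")))
  expect_equal(cm3$tp, unname(tab["ES", "ES"]))
  expect_equal(cm3$fp, unname(tab["PNES", "ES"]))
  expect_equal(cm3$fn, unname(tab["ES", "PNES"]))
  expect_equal(cm3$tn, unname(tab["PNES", "PNES"]))

  expect_error(confusion(lab, pred[-1]), "equal length")
  expect_error(confusion(character(0), character(0)), "empty")
})

test_that("metrics reproduce the published site-level values", {
  a <- seizure_metrics(confusion_matrix(90, 4, 48, 254))
  expect_equal(round(100 * a["accuracy", "estimate"], 1), 86.9)
  expect_equal(round(100 * a["sensitivity", "estimate"], 1), 65.2)
  expect_equal(round(100 * a["specificity", "estimate"], 1), 98.4)
  expect_equal(round(100 * a["ppv", "estimate"], 1), 95.7)
  expect_equal(round(100 * a["npv", "estimate"], 1), 84.1)

  b <- seizure_metrics(confusion_matrix(390, 155, 18, 802))
  expect_equal(round(100 * b["accuracy", "estimate"], 1), 87.3)
  expect_equal(round(100 * b["sensitivity", "estimate"], 1), 95.6)
  expect_equal(round(100 * b["specificity", "estimate"], 1), 83.8)
  expect_equal(round(100 * b["ppv", "estimate"], 1), 71.6)
  expect_equal(round(100 * b["npv", "estimate"], 1), 97.8)
})

test_that("perfect and undefined metrics are handled explicitly", {
  perf <- seizure_metrics(confusion_matrix(7, 0, 0, 13))
  expect_true(all(perf$estimate == 1))
  # no predicted positives -> PPV undefined, reported NA rather than 0
  m <- seizure_metrics(confusion_matrix(0, 0, 4, 6))
  expect_true(is.na(m["ppv", "estimate"]))
  expect_false(is.na(m["npv", "estimate"]))
})

test_that("pooling sums counts and reproduces the combined metrics", {
  cms <- site_confusions()
  pooled <- pool_confusions(unname(cms))
  expect_equal(c(pooled$tp, pooled$fp, pooled$fn, pooled$tn),
               c(480L, 159L, 66L, 1056L))
  m <- seizure_metrics(pooled)
  expect_equal(round(100 * m["accuracy", "estimate"], 1), 87.2)
  expect_equal(round(100 * m["sensitivity", "estimate"], 1), 87.9)
  expect_equal(round(100 * m["specificity", "estimate"], 1), 86.9)
  one <- pool_confusions(cms["site_a"])
  expect_equal(one, cms$site_a)
  expect_error(pool_confusions(list()), "at least one")
})

test_that("wilson interval matches score-test inversion", {
  # independent oracle: the score test accepts p iff
  # |phat - p| <= z * sqrt(p (1 - p) / n); invert numerically
  oracle <- function(k, n, conf = 0.95) {
    z <- qnorm(1 - (1 - conf) / 2)
    phat <- k / n
    g <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
    lo <- if (k == 0) 0 else
      uniroot(g, c(1e-12, min(phat, 1 - 1e-9)), tol = 1e-12)$root
    hi <- if (k == n) 1 else
      uniroot(g, c(max(phat, 1e-9), 1 - 1e-12), tol = 1e-12)$root
    c(lo = lo, hi = hi)
  }
  for (case in list(c(90, 138), c(254, 302), c(0, 10), c(10, 10),
                    c(1, 1000), c(480, 546))) {
    got <- wilson_interval(case[1], case[2])
    want <- oracle(case[1], case[2])
    expect_equal(got, want, tolerance = 1e-6,
                 info = paste(case, collapse = "/"))
  }
})

test_that("wilson interval has score-interval boundary and scaling properties", {
  expect_equal(wilson_interval(0, 10)[["lo"]], 0)
  expect_equal(wilson_interval(10, 10)[["hi"]], 1)
  # shrinks with n at fixed k/n; contains the point estimate; inside [0,1]
  prev_width <- Inf
  for (n in c(10, 100, 1000)) {
    ci <- wilson_interval(0.3 * n, n)
    expect_true(ci[["lo"]] >= 0 && ci[["hi"]] <= 1)
    expect_true(ci[["lo"]] <= 0.3 && 0.3 <= ci[["hi"]])
    width <- ci[["hi"]] - ci[["lo"]]
    expect_lt(width, prev_width)
    prev_width <- width
  }
  expect_error(wilson_interval(5, 0), "n must be")
  expect_error(wilson_interval(11, 10), "k must lie")
})

test_that("AUC equals the pairwise Mann-Whitney oracle", {
  pairwise_auc <- function(scores, labels) {
    pos <- scores[labels == "ES"]
    neg <- scores[labels == "PNES"]
    grid <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(grid)
  }
  # perfectly separated and all-tied edge cases
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("ES", "ES", "PNES", "PNES"))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6),
                       rep(c("ES", "PNES"), 3))$auc, 0.5)
  set.seed(61)
  for (rep in 1:10) {
    n <- 30
    labels <- sample(c("ES", "PNES"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    # discrete scores force ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_auc(scores, labels)$auc,
                 pairwise_auc(scores, labels), tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep("ES", 5)), "both classes")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(62)
  labels <- sample(c("ES", "PNES"), 40, replace = TRUE)
  labels[1:2] <- c("ES", "PNES")
  scores <- runif(40)
  base <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(qlogis(scores), labels)$auc, base,
               tolerance = 1e-12)
  expect_equal(roc_auc(scores^3 + 2, labels)$auc, base, tolerance = 1e-12)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  labels <- sample(c("ES", "PNES"), 60, replace = TRUE)
  labels[1:2] <- c("ES", "PNES")
  scores <- round(runif(60), 2)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labels, c("PNES", "ES")), predictor = scores,
    quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
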