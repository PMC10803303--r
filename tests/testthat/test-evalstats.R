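# Metric formulas against independent brute-force oracles.

# exhaustive pairwise-comparison AUC: P(score+ > score-) + 0.5 P(tie)
auc_pairwise_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

test_that("auc_rank equals the exhaustive pairwise oracle for all n <= 30", {
  set.seed(101)
  for (n in 2:30) {
    for (rep in 1:4) {
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
      scores <- if (rep %% 2 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)
                else runif(n)                   # heavy ties on even reps
      expect_equal(auc_rank(scores, labels), auc_pairwise_oracle(scores, labels),
                   tolerance = 1e-12)
    }
  }
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc_rank(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc_rank(runif(5), rep(1, 5)), "both classes")
})

test_that("dice equals a set-overlap oracle on 100 random mask pairs", {
  set.seed(7)
  for (i in 1:100) {
    d <- c(sample(3:6, 1), sample(3:6, 1), sample(3:6, 1))
    p <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.9)), d)
    g <- array(rbinom(prod(d), 1, runif(1, 0.1, 0.9)), d)
    ip <- which(p == 1); ig <- which(g == 1)
    tp <- length(intersect(ip, ig))
    expected <- if (length(ip) + length(ig) == 0) 1.0
                else 2 * tp / (length(ip) + length(ig))
    expect_equal(dice(p, g), expected)
  }
  m <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
  expect_equal(dice(m, m), if (sum(m) > 0) 1.0 else 1.0)
  expect_equal(dice(array(c(1, rep(0, 7)), c(2, 2, 2)),
                    array(c(0, 1, rep(0, 6)), c(2, 2, 2))), 0.0)
  expect_equal(dice(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1.0)
  expect_error(dice(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))), "match")
})

test_that("confusion metrics match direct substitution and brute-force counts", {
  # TP=3, FP=1, FN=2, TN=4 arranged explicitly
  scores <- c(rep(0.9, 3), 0.9, rep(0.1, 2), rep(0.1, 4))
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(m$counts, list(TP = 3L, FP = 1L, FN = 2L, TN = 4L))
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 2 / 3)
  expect_equal(m$f1, 3 / 4.5)

  # all-positive degenerate: sens 1, spec 0, NPV undefined -> NA with warning
  expect_warning(m2 <- confusion_metrics(runif(8, 0.3, 0.9),
                                         c(1, 1, 0, 0, 1, 0, 1, 0), 0.0),
                 "NPV undefined")
  expect_equal(m2$sensitivity, 1.0)
  expect_equal(m2$specificity, 0.0)
  expect_true(is.na(m2$npv))

  set.seed(12)
  sc <- runif(50); lb <- c(0, 1, rbinom(48, 1, 0.4)); th <- 0.45
  m3 <- confusion_metrics(sc, lb, th)
  tp <- sum(sc >= th & lb == 1); fp <- sum(sc >= th & lb == 0)
  fn <- sum(sc < th & lb == 1); tn <- sum(sc < th & lb == 0)
  expect_equal(m3$sensitivity, tp / (tp + fn))
  expect_equal(m3$specificity, tn / (tn + fp))
  expect_equal(m3$f1, tp / (tp + 0.5 * (fp + fn)))
  # count consistency: sens*(TP+FN) and spec*(TN+FP) are integers
  expect_equal(m3$sensitivity * (tp + fn), round(m3$sensitivity * (tp + fn)))
  expect_equal(m3$specificity * (tn + fp), round(m3$specificity * (tn + fp)))
})

test_that("youden threshold maximises J over an exhaustive scan, smallest-tie", {
  op <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(op$youden_J, 1.0)

  op2 <- youden_threshold(c(0.2, 0.3, 0.6, 0.8), c(0, 1, 0, 1))
  expect_equal(op2$youden_J, 0.5)
  expect_equal(op2$threshold, 0.3)  # ties at 0.3 and 0.8 -> smallest

  set.seed(3)
  sc <- runif(40); lb <- c(0, 1, rbinom(38, 1, 0.5))
  op3 <- youden_threshold(sc, lb)
  Js <- vapply(sort(unique(sc)), function(t) {
    s <- sum(sc >= t & lb == 1) / sum(lb == 1)
    p <- sum(sc < t & lb == 0) / sum(lb == 0)
    s + p - 1
  }, numeric(1))
  expect_equal(op3$youden_J, max(Js))

  # label-score independence keeps J small at large n
  set.seed(4)
  opn <- youden_threshold(runif(2000), rbinom(2000, 1, 0.5))
  expect_lt(opn$youden_J, 0.15)
})

test_that("bootstrap_ci is seeded, degenerate on perfect separation, shrinks with n", {
  sc <- c(0.1, 0.15, 0.2, 0.8, 0.85, 0.9); lb <- c(0, 0, 0, 1, 1, 1)
  ci <- bootstrap_ci(auc_rank, sc, lb, n_boot = 200, seed = 42)
  expect_equal(as.numeric(ci), c(1.0, 1.0))
  ci2 <- bootstrap_ci(auc_rank, sc, lb, n_boot = 200, seed = 42)
  expect_identical(as.numeric(ci), as.numeric(ci2))

  set.seed(9)
  width <- function(n) {
    mean(replicate(25, {
      lb <- rep(c(0, 1), n / 2)
      sc <- rnorm(n, lb * 1.19)
      ci <- bootstrap_ci(auc_rank, sc, lb, n_boot = 150,
                         seed = sample.int(1e6, 1))
      ci[2] - ci[1]
    }))
  }
  expect_lt(width(400), width(50))
})

test_that("kruskal_wallis matches hand-ranked arithmetic and detects shifts", {
  same <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(same$H, 1e-9)
  expect_equal(same$p_value, 1)

  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6)
  kw <- kruskal_wallis(list(g1, g2))
  # hand ranks: 1..6, rank sums 6 and 15, no ties
  H_manual <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(kw$H, H_manual, tolerance = 1e-12)
  expect_equal(kw$p_value, pchisq(H_manual, df = 1, lower.tail = FALSE))

  set.seed(11)
  shifted <- kruskal_wallis(list(rnorm(200), rnorm(200) + 0.5))
  expect_lt(shifted$p_value, 0.05)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
})

test_that("mann_whitney: exact small-sample enumeration and the U identity", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  ident <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_gt(ident$p_value, 0.9)

  set.seed(13)
  x <- rnorm(15); y <- rnorm(12)
  expect_equal(unname(mann_whitney(x, y)$U + mann_whitney(y, x)$U),
               length(x) * length(y))
})

test_that("roc_curve is a staircase whose area equals auc_rank", {
  perfect <- roc_curve(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_equal(perfect$fpr[1], 0); expect_equal(perfect$tpr[1], 0)
  expect_equal(perfect$fpr[nrow(perfect)], 1)
  expect_equal(perfect$tpr[nrow(perfect)], 1)

  set.seed(21)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    lb <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    rc <- roc_curve(sc, lb)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(roc_auc(rc), auc_rank(sc, lb), tolerance = 1e-9)
  }

  sc <- runif(30); lb <- c(0, 1, rbinom(28, 1, 0.5))
  a <- auc_rank(sc, lb)
  expect_equal(auc_rank(-sc, lb), 1 - a, tolerance = 1e-12)
})

test_that("clinical_lr recovers planted effects and reports separation", {
  set.seed(33)
  # null covariates: age coefficient CI covers 0
  mk <- function(n, beta_cT = 0) {
    lapply(seq_len(n), function(i) {
      cT <- sample(c("1-2", "3", "4"), 1)
      eta <- -0.5 + beta_cT * (cT == "4")
      fake_case(i, emvi = rbinom(1, 1, plogis(eta)), cr = 0,
                age = round(runif(1, 30, 85)),
                sex = sample(c("F", "M"), 1), cT = cT,
                cN = sample(c("0", "1", "2"), 1))
    })
  }
  dev <- mk(500); ext <- mk(200)
  fit <- clinical_lr(dev, ext, target = "emvi")
  ci <- suppressMessages(confint.default(fit$model))["age", ]
  expect_true(ci[1] < 0 && ci[2] > 0)
  expect_true(all(fit$scores$score >= 0 & fit$scores$score <= 1))

  # strong planted cT effect is recovered on external cases
  dev2 <- mk(600, beta_cT = 3); ext2 <- mk(300, beta_cT = 3)
  fit2 <- clinical_lr(dev2, ext2, target = "emvi")
  expect_gt(auc_rank(fit2$scores), 0.7)

  # intercept-only structure: predictions equal the prevalence
  dev3 <- lapply(1:80, function(i) fake_case(i, emvi = as.integer(i <= 20), cr = 0,
                                             age = 60, sex = "M", cT = "3", cN = "1"))
  fit3 <- clinical_lr(dev3, dev3, target = "emvi")
  expect_equal(unname(fit3$scores$score), rep(0.25, 80), tolerance = 1e-6)

  # perfect separation is an error, not a silent fit
  dev4 <- lapply(1:60, function(i) {
    s <- if (i <= 30) "F" else "M"
    fake_case(i, emvi = as.integer(s == "F"), cr = 0, age = 60, sex = s,
              cT = "3", cN = "1")
  })
  expect_error(clinical_lr(dev4, dev4, target = "emvi"), "separation")
})

test_that("metric_report orders CIs around points and transfers thresholds", {
  set.seed(55)
  lb <- rep(c(0, 1), 30)
  sc <- pmin(pmax(rnorm(60, 0.4 + 0.25 * lb, 0.15), 0), 1)
  ss <- score_set(sprintf("P%02d", 1:60), sc, lb)
  op <- youden_threshold(ss)
  rep <- metric_report(ss, op$threshold, n_boot = 300, seed = 8)
  for (m in c("auc", "sensitivity", "specificity", "ppv", "npv", "f1")) {
    v <- rep[[m]]
    expect_true(v["lo"] <= v["point"] + 1e-9 && v["point"] <= v["hi"] + 1e-9)
    expect_true(v["point"] >= 0 && v["point"] <= 1)
  }
  expect_identical(rep$threshold, op$threshold)  # bit-identical transfer
})
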