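test_that("AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5))$auc, 0.5)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      n <- sample(10:40, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # forces ties
      labels <- rbinom(n, 1, 0.4)
      if (sum(labels) == 0 || sum(labels) == n) labels[1:2] <- c(0, 1)
      expect_equal(roc_auc(scores, labels)$auc, pair_count_auc(scores, labels))
    })
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(9, {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.5)
  })
  a <- roc_auc(scores, labels)
  b <- roc_auc(qlogis(scores), labels)
  expect_equal(a$auc, b$auc)
  expect_equal(a$se, b$se)
})

test_that("DeLong self-comparison and label antisymmetry behave as expected", {
  withr::with_seed(4, {
    s1 <- runif(50)
    s2 <- s1 + rnorm(50, sd = 0.2)
    labels <- rbinom(50, 1, 0.5)
  })
  self <- delong_test(s1, s1, labels)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  ab <- delong_test(s1, s2, labels)
  swapped <- delong_test(s1, s2, !as.logical(labels))
  expect_equal(swapped$z, -ab$z, tolerance = 1e-12)
  expect_equal(swapped$p_value, ab$p_value, tolerance = 1e-12)
})

test_that("DeLong variance of the AUC difference agrees with a bootstrap", {
  withr::with_seed(7, {
    n <- 30
    labels <- rep(c(1, 0), each = 15)
    s1 <- rnorm(n, mean = labels)
    s2 <- 0.7 * s1 + rnorm(n, sd = 0.6)
  })
  dl <- delong_test(s1, s2, labels)
  analytic <- dl$var_a + dl$var_b - 2 * dl$cov_ab
  boot <- withr::with_seed(8, {
    replicate(10000, {
      idx <- sample.int(n, replace = TRUE)
      if (sum(labels[idx]) %in% c(0, n)) return(NA_real_)
      pair_count_auc(s1[idx], labels[idx]) - pair_count_auc(s2[idx], labels[idx])
    })
  })
  expect_equal(analytic, var(boot, na.rm = TRUE), tolerance = 0.1)
})

test_that("DeLong cross-checks against an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    labels <- rbinom(80, 1, 0.5)
    s1 <- labels + rnorm(80)
    s2 <- 0.5 * labels + rnorm(80)
  })
  mine <- delong_test(s1, s2, labels)
  ref <- pROC::roc.test(
    pROC::roc(labels, s1, quiet = TRUE, direction = "<"),
    pROC::roc(labels, s2, quiet = TRUE, direction = "<"),
    method = "delong"
  )
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Hosmer-Lemeshow matches term-by-term hand arithmetic on a planted fixture", {
  # 10 bins of 10 records; constant predicted risk per bin, planted events
  risk_levels <- seq(0.05, 0.50, by = 0.05)
  observed <- c(1, 0, 2, 1, 3, 2, 4, 5, 4, 6)
  predictions <- rep(risk_levels, each = 10)
  labels <- unlist(lapply(observed, function(o) c(rep(1, o), rep(0, 10 - o))))
  rep_hl <- hosmer_lemeshow(predictions, labels)
  e <- 10 * risk_levels
  chi_oracle <- sum((observed - e)^2 / (e * (1 - e / 10)))
  expect_equal(rep_hl$chi_square, chi_oracle, tolerance = 1e-12)
  expect_equal(rep_hl$chi_square, 4.0955962, tolerance = 1e-6)
  expect_equal(rep_hl$df, 8)
  expect_equal(rep_hl$p_value, pchisq(chi_oracle, 8, lower.tail = FALSE))
  # conservation
  expect_equal(sum(rep_hl$bins$observed_events), sum(labels))
  expect_equal(sum(rep_hl$bins$n), length(labels))
  # order invariance
  perm <- withr::with_seed(2, sample(length(labels)))
  expect_equal(hosmer_lemeshow(predictions[perm], labels[perm])$chi_square,
               rep_hl$chi_square)
  # the plain Pearson variant is the documented alternative
  pear <- hosmer_lemeshow(predictions, labels, variant = "pearson")
  expect_equal(pear$chi_square, sum((observed - e)^2 / e), tolerance = 1e-12)
})

test_that("perfectly calibrated deciles give chi-square 0", {
  predictions <- rep(c(0.2, 0.5), each = 10)
  labels <- c(rep(1, 2), rep(0, 8), rep(1, 5), rep(0, 5))
  rep_hl <- hosmer_lemeshow(predictions, labels, bins = 2)
  expect_equal(rep_hl$chi_square, 0)
  expect_equal(rep_hl$p_value, 1)
})

test_that("the operating point maximizes Youden's J with sensitivity tie-break", {
  perfect <- operating_point(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  flat <- operating_point(rep(0.4, 8), rep(c(1, 0), 4))
  expect_equal(flat$sensitivity, 100)
  expect_equal(flat$specificity, 0)
  expect_equal(flat$youden_j, 0)
  # brute-force threshold scan oracle on a 12-point vector
  withr::with_seed(13, {
    scores <- round(runif(12), 2)
    labels <- rbinom(12, 1, 0.5)
  })
  if (sum(labels) %in% c(0, 12)) labels[1:2] <- c(0, 1)
  op <- operating_point(scores, labels)
  scan <- sapply(sort(unique(scores)), function(t) {
    sens <- sum(labels == 1 & scores >= t) / sum(labels == 1)
    spec <- sum(labels == 0 & scores < t) / sum(labels == 0)
    sens + spec - 1
  })
  expect_equal(op$youden_j, max(scan), tolerance = 1e-12)
})

test_that("calibration plot method returns a ggplot", {
  predictions <- rep(seq(0.05, 0.5, by = 0.05), each = 10)
  labels <- rbinom(100, 1, predictions)
  if (sum(labels) == 0) labels[1] <- 1
  p <- autoplot(hosmer_lemeshow(predictions, labels))
  expect_s3_class(p, "ggplot")
})
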