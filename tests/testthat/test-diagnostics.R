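# Rank tests, chi-square, screening, logistic fit, ROC / DeLong.

test_that("Mann-Whitney z handles the degenerate and fully separated cases", {
  r <- mann_whitney_z(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- mann_whitney_z(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u, 0)
  expect_lt(r$statistic, 0) # group_a stochastically smaller
  expect_error(mann_whitney_z(numeric(0), 1:3), "non-empty")
})

test_that("tie-corrected z reproduces the classical test", {
  set.seed(4)
  for (i in 1:20) {
    a <- sample(1:8, 15, replace = TRUE) # heavy ties
    b <- sample(2:9, 12, replace = TRUE)
    mine <- mann_whitney_z(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    expect_equal(mine$u, unname(ref$statistic))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("normal-approximation p stays near the exact permutation p at small n", {
  set.seed(5)
  for (i in 1:15) {
    a <- rnorm(sample(6:8, 1))
    b <- rnorm(sample(6:8, 1), mean = runif(1, 0, 2))
    p_approx <- mann_whitney_z(a, b)$p_value
    p_exact <- oracle_mw_exact_p(a, b)
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
})

test_that("chi-square matches the direct Pearson formula", {
  r <- chi_square(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  r <- chi_square(matrix(c(20, 10, 10, 20), 2))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(round(r$statistic, 3), 6.667)
  expect_equal(r$df, 1)
  set.seed(6)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square(tab)$statistic, sum((tab - e)^2 / e))
    ref <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(chi_square(tab)$p_value, ref$p.value)
  }
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("screening drops group-matched features and keeps separated ones", {
  set.seed(7)
  n <- 200
  s <- data.frame(group = rep(c("case", "control"), each = n),
                  same = rnorm(2 * n),
                  apart = c(rnorm(n, 3), rnorm(n, 0)))
  sc <- screen_features(s, features = c("same", "apart"))
  expect_true("apart" %in% sc$retained)
  expect_true("same" %in% sc$excluded)
})

test_that("logistic slope on a 2x2-derived dataset equals the log odds ratio", {
  df <- data.frame(
    group = rep(c("case", "control", "case", "control"), c(30, 10, 10, 30)),
    x = rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  )
  fit <- fit_logistic(df, "x")
  expect_equal(unname(fit$coefficients["x"]), log(9), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("an uninformative feature yields a null slope and the prevalence intercept", {
  set.seed(8)
  df <- data.frame(group = rep(c("case", "control"), c(120, 280)),
                   x = rnorm(400))
  fit <- fit_logistic(df, "x")
  expect_equal(unname(fit$coefficients["x"]), 0, tolerance = 0.3)
  expect_equal(unname(fit$coefficients["(Intercept)"]), qlogis(120 / 400),
               tolerance = 0.3)
})

test_that("converged fits satisfy the likelihood stationarity and probability contracts", {
  set.seed(9)
  n <- 300
  df <- data.frame(group = rep(c("case", "control"), each = n / 2),
                   a = rnorm(n), b = rnorm(n))
  df$a <- df$a + (df$group == "case") * 1.2
  fit <- fit_logistic(df, c("a", "b"))
  X <- cbind(1, as.matrix(df[c("a", "b")]))
  p <- plogis(drop(X %*% fit$coefficients))
  grad <- drop(t(X) %*% (fit$y - p))
  expect_lt(max(abs(grad)), 1e-6)
  expect_true(all(fit$fitted > 0 & fit$fitted < 1))
  expect_equal(p, fit$fitted, tolerance = 1e-8)
  expect_equal(predict(fit, df), fit$fitted, tolerance = 1e-12)
})

test_that("perfect separation and rank deficiency are refused with clear messages", {
  df <- data.frame(group = rep(c("case", "control"), each = 10),
                   sep = c(rnorm(10, 10), rnorm(10, -10)),
                   ok = rnorm(20))
  expect_error(fit_logistic(df, c("sep", "ok")), "sep")
  expect_warning(fit_logistic(df, c("sep", "ok"), on_separation = "warn"),
                 "sep")
  df$dup <- df$ok * 2
  expect_error(fit_logistic(df, c("ok", "dup")), "rank-deficient")
})

test_that("ROC evaluation matches the pair-counting oracle, with ties", {
  set.seed(10)
  for (i in 1:40) {
    n1 <- sample(5:25, 1)
    n0 <- sample(5:25, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), sample(0:1, 1))
    labels <- rep(c("case", "control"), c(n1, n0))
    rr <- roc_evaluate(scores, labels)
    expect_equal(rr$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(rr$auc,
                 as.numeric(suppressWarnings(pROC::auc(
                   pROC::roc(labels, scores, levels = c("control", "case"),
                             direction = "<", quiet = TRUE)))),
                 tolerance = 1e-12)
  }
})

test_that("perfectly separated scores give AUC 1 and Youden 1", {
  rr <- roc_evaluate(c(5, 6, 7, 1, 2, 3), rep(c("case", "control"), each = 3))
  expect_equal(rr$auc, 1)
  expect_equal(rr$youden_index, 1)
})

test_that("the reported Youden index is sensitivity + specificity - 1 at its cutoff", {
  set.seed(11)
  for (i in 1:10) {
    scores <- c(rnorm(30, 1.5), rnorm(40))
    labels <- rep(c("case", "control"), c(30, 40))
    rr <- roc_evaluate(scores, labels, decision_rule = "youden")
    expect_equal(rr$youden_index, rr$sensitivity + rr$specificity - 1,
                 tolerance = 1e-12)
    expect_gte(rr$auc, 0)
    expect_lte(rr$auc, 1)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  scores <- rexp(80) + 0.1
  labels <- rep(c("case", "control"), 40)
  a1 <- roc_evaluate(scores, labels)$auc
  expect_equal(roc_evaluate(log(scores), labels)$auc, a1)
  expect_equal(roc_evaluate(scores^3, labels)$auc, a1)
})

test_that("uninformative scores give chance-level AUC most of the time", {
  set.seed(13)
  aucs <- replicate(60, {
    oracle_auc(rnorm(500), rep(c("case", "control"), 250))
  })
  expect_gte(mean(aucs >= 0.45 & aucs <= 0.55), 0.9)
})

test_that("paired AUC comparison is null on itself and extreme on its negation", {
  set.seed(14)
  scores <- c(rnorm(60, 2), rnorm(60))
  labels <- rep(c("case", "control"), each = 60)
  same <- compare_auc(scores, scores, labels)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  flip <- compare_auc(scores, -scores, labels)
  expect_gt(abs(flip$delta_auc), 0.8)
  expect_lt(flip$p_value, 0.001)
  expect_error(compare_auc(scores[-1], scores, labels), "length")
})

test_that("the DeLong variance of an AUC difference tracks a bootstrap", {
  set.seed(15)
  n <- 200
  y <- rep(c("case", "control"), each = n / 2)
  base <- rnorm(n) + (y == "case") * 1
  sa <- base + rnorm(n, sd = 0.8)
  sb <- base + rnorm(n, sd = 0.8)
  cmp <- compare_auc(sa, sb, y)
  v_delong <- (cmp$delta_auc / cmp$statistic)^2
  boot <- replicate(1000, {
    idx1 <- sample(which(y == "case"), replace = TRUE)
    idx0 <- sample(which(y == "control"), replace = TRUE)
    idx <- c(idx1, idx0)
    oracle_auc(sa[idx], y[idx]) - oracle_auc(sb[idx], y[idx])
  })
  expect_lt(abs(v_delong - var(boot)), 0.2 * var(boot))
})
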