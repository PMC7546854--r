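# Kaplan-Meier, log-rank, Cox, DeLong, cross-tabulation, group comparisons

test_that("product-limit estimator matches hand computation", {
  # no events: survival identically 1
  km0 <- kmEstimate(c(3, 7, 12), c(0, 0, 0))
  expect_true(all(km0$table$survival == 1))
  expect_equal(km0$cumLTPAt(c(5, 20)), c(0, 0))
  # all events at distinct times: steps 2/3, 1/3, 0
  km1 <- kmEstimate(c(2, 4, 6), c(1, 1, 1))
  expect_equal(km1$table$survival, c(2 / 3, 1 / 3, 0))
  # censoring at 4: risk set of 1 at t = 6, survival 2/3 then 0 * 2/3...
  km2 <- kmEstimate(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km2$survivalAt(c(3, 5, 7)), c(2 / 3, 2 / 3, 0))
  # KM with no censoring equals the empirical survival function
  set.seed(50)
  t <- rexp(40, 0.1)
  km3 <- kmEstimate(t, rep(1, 40))
  ecdfS <- vapply(km3$table$time, function(ti) mean(t > ti), 0)
  expect_equal(km3$table$survival, ecdfS, tolerance = 1e-12)
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank matches the observed-minus-expected oracle", {
  # duplicated groups: statistic 0, p 1
  t <- c(2, 5, 8, 2, 5, 8); e <- c(1, 1, 0, 1, 1, 0)
  lr0 <- logrankTest(rep(c("a", "b"), each = 3), t, e)
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # textbook toy with distinct event times
  g <- rep(0:1, each = 3)
  tt <- c(1, 4, 7, 2, 5, 9); ee <- rep(1, 6)
  lr <- logrankTest(g, tt, ee)
  oracle <- handLogrank(g, tt, ee)
  expect_equal(lr$statistic, oracle$statistic, tolerance = 1e-9)
  expect_equal(lr$p, oracle$p, tolerance = 1e-9)
  # label swap leaves the statistic unchanged
  lrSwap <- logrankTest(1 - g, tt, ee)
  expect_equal(lrSwap$statistic, lr$statistic, tolerance = 1e-12)
  expect_error(logrankTest(rep(1, 6), tt, ee), "two groups")
})

test_that("log-rank detects a strong margin effect most of the time", {
  hits <- vapply(1:30, function(s) {
    ch <- makeCohort(cohortSpec(nPatients = 500L, hrMargin = 3.2,
                                baselineHazard = 0.003, seed = 300 + s))
    logrankTest(ch$margin_le5, ch$months, ch$ltp_event)$p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("Cox fit recovers a null effect and flags degenerate data", {
  ch <- makeCohort(cohortSpec(nPatients = 500L, hrMargin = 1, hrAge = 1,
                              baselineHazard = 0.004, seed = 77))
  fit <- coxFit(ch, "margin_le5")
  se <- (log(fit$table$upper95) - log(fit$table$lower95)) / (2 * 1.96)
  expect_lt(abs(fit$table$coef), 3 * se)
  # zero events: validation error
  ch0 <- ch; ch0$ltp_event <- 0
  expect_error(coxFit(ch0, "margin_le5"), "2 events")
  # monotone likelihood (perfect separation) is flagged, not silent
  n <- 60
  sep <- data.frame(months = c(seq(1, 5, length.out = 30),
                               seq(10, 30, length.out = 30)),
                    ltp_event = rep(c(1, 0), each = 30),
                    bad = rep(c(1, 0), each = 30))
  fitSep <- suppressWarnings(coxFit(sep, "bad"))
  expect_false(fitSep$converged)
})

test_that("forward stepwise keeps true risk factors and drops noise", {
  ch <- makeCohort(cohortSpec(nPatients = 1500L, baselineHazard = 0.003,
                              seed = 12))
  fit <- coxFit(ch, c("sex", "comorbidity", "cirrhosis", "afp_gt200",
                      "size_3to5", "abutting_vessel", "margin_le5", "age_ge65"),
                forwardStepwise = TRUE)
  expect_true(all(c("margin_le5", "age_ge65") %in% fit$selected))
  expect_true(fit$converged)
  # pure-noise candidates: usually nothing enters; at most chance picks
  expect_lte(length(setdiff(fit$selected, c("margin_le5", "age_ge65"))), 2)
})

test_that("DeLong AUC equals brute-force pair counting", {
  set.seed(51)
  y <- rbinom(200, 1, 0.4)
  s1 <- rnorm(200) + y
  s2 <- rnorm(200)
  dc <- delongCompare(y, s1, s2)
  expect_equal(dc$auc1, bruteAUC(y, s1), tolerance = 1e-12)
  expect_equal(dc$auc2, bruteAUC(y, s2), tolerance = 1e-12)
  # identical scores: zero difference, p = 1
  same <- delongCompare(y, s1, s1)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  # a perfect separator has AUC 1
  perfect <- delongCompare(y, y + 0.001 * rnorm(200), s2)
  expect_equal(perfect$auc1, 1)
  expect_error(delongCompare(rep(1, 10), rnorm(10), rnorm(10)), "classes")
})

test_that("DeLong p-value agrees with the pROC reference implementation", {
  set.seed(52)
  y <- rbinom(150, 1, 0.35)
  s1 <- rnorm(150) + 0.8 * y
  s2 <- rnorm(150) + 0.5 * y
  dc <- delongCompare(y, s1, s2)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE),
                        pROC::roc(y, s2, quiet = TRUE), method = "delong")
  expect_equal(dc$p, as.numeric(ref$p.value), tolerance = 1e-9)
  expect_equal(dc$auc1, as.numeric(ref$estimate[1]), tolerance = 1e-12)
})

test_that("cross-tabulation summaries reproduce the printed comparison table", {
  ct <- makeCrossTab(rbind(c(8, 34, 8, 11),
                           c(3, 26, 0, 51)))
  s <- crosstabSummaries(ct)
  expect_equal(unname(s$dirN), c(61, 80))
  expect_equal(unname(s$ltpByDir), c(16, 3))
  expect_equal(unname(s$ltpByConv), c(11, 8))
  expect_equal(s$ltpTotal, 19)
  expect_equal(s$total, 141)
  expect_equal(s$ltpProportion, 19 / 141)
  expect_equal(unname(s$convN), c(71, 70))
  expect_equal(s$agreement, 42 + 51)
  # single-cell table: that marginal only
  one <- array(0, c(2, 2, 2)); one[1, 2, 1] <- 10
  s1 <- crosstabSummaries(one)
  expect_equal(unname(s1$dirN), c(10, 0))
  expect_equal(unname(s1$convN), c(0, 10))
  expect_equal(s1$ltpTotal, 10)
  # zero cells trigger the Haldane-corrected odds ratio
  expect_true(is.finite(s$orConv))
  expect_gt(s$orDir, 1)
})

test_that("two-group comparison picks the conventional test", {
  # identical samples: Mann-Whitney p = 1
  x <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(c("a", "b"), each = 5)
  mw <- groupCompare(x, g)
  expect_identical(mw$method, "mann-whitney")
  expect_equal(mw$p, 1)
  # fully separated 2x2 table with small expected counts: Fisher,
  # hypergeometric enumeration gives p = 2 / C(16, 8)
  xf <- rep(c(1, 0), each = 8)
  gf <- rep(c("a", "b"), each = 8)
  fi <- groupCompare(xf, gf)
  expect_identical(fi$method, "fisher")
  expect_equal(fi$p, 2 / choose(16, 8), tolerance = 1e-9)
  expect_lt(fi$p, 0.001)
  # all expected counts >= 5: chi-square, statistic from the hand formula
  tab <- matrix(c(20, 10, 10, 20), 2)
  xc <- rep(rep(c(1, 0), 2), c(20, 10, 10, 20))
  gc_ <- rep(c("a", "b"), c(30, 30))
  cs <- groupCompare(xc, gc_)
  expect_identical(cs$method, "chi-square")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(cs$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
  expect_error(groupCompare(1:5, rep("a", 5)), "two groups")
})

test_that("cohort-level report assembles all the pieces", {
  ch <- makeCohort(cohortSpec(nPatients = 400L, baselineHazard = 0.004,
                              seed = 21))
  rep_ <- cohortStats(ch)
  expect_equal(rep_$n, 400L)
  expect_equal(nrow(rep_$ltpRates), 3L)
  expect_true(all(diff(rep_$ltpRates$groupA) >= 0))
  expect_true(rep_$logrank$p >= 0 && rep_$logrank$p <= 1)
  expect_true("margin_le5" %in% rep_$univariate$covariate)
  expect_true(is.list(rep_$crosstab))
  expect_error(cohortStats(ch, horizons = c(12, 6)), "increasing")
})
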