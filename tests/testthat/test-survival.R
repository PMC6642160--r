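test_that("log-rank statistic matches brute-force enumeration and survdiff", {
  # symmetric groups: statistic 0, p 1
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- rep(1, 8)
  gr <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(tm, ev, gr)
  expect_equal(lr$statistic, 0)
  expect_equal(lr$p_value, 1)

  # 10-patient worked set: all group-A events precede group-B events
  tm2 <- 1:10; ev2 <- rep(1, 10); gr2 <- rep(c("A", "B"), each = 5)
  lr2 <- logrank_test(tm2, ev2, gr2)
  expect_equal(lr2$statistic, oracle_logrank(tm2, ev2, gr2))
  sd2 <- survival::survdiff(survival::Surv(tm2, ev2) ~ gr2)
  expect_equal(lr2$statistic, sd2$chisq, tolerance = 1e-9)

  # label swap leaves the squared statistic unchanged
  lr2b <- logrank_test(tm2, ev2, rev(gr2))
  expect_equal(lr2$statistic, lr2b$statistic)

  set.seed(51)
  for (k in 1:20) {
    n <- sample(6:30, 1)
    tm3 <- round(rexp(n, 0.2), 2)
    ev3 <- rbinom(n, 1, 0.8)
    gr3 <- sample(c("x", "y"), n, replace = TRUE)
    if (length(unique(gr3)) < 2) gr3[1:2] <- c("x", "y")
    if (sum(ev3) == 0) ev3[1] <- 1
    lr3 <- logrank_test(tm3, ev3, gr3)
    expect_equal(lr3$statistic, oracle_logrank(tm3, ev3, gr3))
    sd3 <- survival::survdiff(survival::Surv(tm3, ev3) ~ gr3)
    if (!is.na(lr3$statistic))
      expect_equal(lr3$statistic, sd3$chisq, tolerance = 1e-9)
  }
  expect_error(logrank_test(tm2, ev2, rep("a", 10)), "two groups")
})

test_that("Kaplan-Meier curve is the product-limit estimator", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3L, 2L, 1L))

  # all censored: the curve never drops
  expect_equal(nrow(km_curve(c(1, 2, 3), c(0, 0, 0))), 0)

  # censoring removes a subject from later risk sets
  km2 <- km_curve(c(1, 1.5, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$survival, c(2 / 3, 0))
  expect_equal(km2$n_risk, c(3L, 1L))

  set.seed(52)
  for (k in 1:10) {
    n <- sample(5:40, 1)
    tm <- round(rexp(n, 0.1), 1)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    km3 <- km_curve(tm, ev)
    sf <- survival::survfit(survival::Surv(tm, ev) ~ 1)
    at_events <- sf$n.event > 0
    expect_equal(km3$survival, sf$surv[at_events], tolerance = 1e-12)
    expect_true(all(diff(km3$survival) <= 1e-12))  # non-increasing
    expect_true(all(km3$survival <= 1))
  }
})

test_that("lasso-Cox selects nothing under a dominating penalty", {
  co <- generate_survival_cohort(cohort_spec(100, 3, beta = c(1, 0, 0), seed = 1))
  fit <- fit_lasso_cox(co[, c("f1", "f2", "f3")], co$time, co$event,
                       lambda = c(1000, 999), seed = 1)
  expect_true(all(fit$beta == 0))
  expect_error(fit_lasso_cox(matrix(rnorm(20), 10), co$time[1:10],
                             rep(0, 10)), "2 events")
  X <- matrix(c(rnorm(10), NA, rnorm(9)), 10)
  expect_error(fit_lasso_cox(X, co$time[1:10], co$event[1:10]), "non-finite")
})

test_that("cross-validated lasso mostly rejects pure-noise features", {
  nulls <- 0L
  for (r in 1:50) {
    co <- generate_survival_cohort(cohort_spec(100, 5, beta = rep(0, 5),
                                               seed = 7000 + r))
    fit <- fit_lasso_cox(co[, paste0("f", 1:5)], co$time, co$event,
                         seed = r)
    # near-zero: under 15% of the unit log-hazard used as a real signal
    if (all(abs(fit$beta) < 0.15)) nulls <- nulls + 1L
  }
  expect_gte(nulls / 50, 0.8)
})

test_that("risk index is the linear predictor", {
  beta <- c(f1 = 0.5, f2 = -1)
  X <- data.frame(f1 = c(2, 4), f2 = c(1, 1))
  expect_equal(risk_index(beta, X), c(0, 1))
  expect_equal(risk_index(c(f1 = 0, f2 = 0), X), c(0, 0))
  # doubling a positive-coefficient feature raises risk
  expect_gt(risk_index(beta, data.frame(f1 = 4, f2 = 1)),
            risk_index(beta, data.frame(f1 = 2, f2 = 1)))
  expect_error(risk_index(c(f9 = 1), X), "missing")
})

test_that("two-level CV stratifies without using the held-out outcome", {
  co <- generate_survival_cohort(cohort_spec(24, 2, beta = c(2, 0),
                                             censor_rate = 0.2, seed = 60))
  s1 <- two_level_cv_stratify(co, c("f1", "f2"), seed = 1, nfolds = 5)
  # patient 1's own outcome must not influence their assignment
  co2 <- co
  co2$time[1] <- co2$time[1] * 10 + 5
  co2$event[1] <- 1 - co2$event[1]
  s2 <- two_level_cv_stratify(co2, c("f1", "f2"), seed = 1, nfolds = 5)
  expect_identical(s1$group[1], s2$group[1])
  expect_equal(s1$risk_index[1], s2$risk_index[1])
})

test_that("median-split groups are near-balanced on a strong signal", {
  co <- generate_survival_cohort(cohort_spec(30, 1, beta = 2,
                                             censor_rate = 0, seed = 61))
  s <- two_level_cv_stratify(co, "f1", seed = 2, nfolds = 5)
  expect_false(s$degenerate)
  expect_lte(abs(sum(s$group == "high") - sum(s$group == "low")), 2)
  expect_lt(s$logrank$p_value, 0.05)
  expect_gt(s$hr, 1)
  expect_error(two_level_cv_stratify(co[1:10, ], "f1"), "20 patients")
})

test_that("multivariate Cox recovers a known binary hazard ratio", {
  set.seed(62)
  n <- 400
  grp <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.05 * exp(log(2) * grp))
  d <- data.frame(time = tm, event = 1, grp = grp,
                  age = rnorm(n, 60, 10))
  res <- multivariate_cox(d, c("grp", "age"))
  hr <- res$hr[res$variable == "grp"]
  expect_gt(hr, 1.6)
  expect_lt(hr, 2.5)
  expect_true(res$ci_lower[res$variable == "age"] <= 1.05)

  d$flat <- 1
  expect_error(multivariate_cox(d, c("grp", "flat")), "zero variance")
})

test_that("the univariate screen discriminates signal from noise", {
  hits <- 0L; false_pos <- 0L
  for (r in 1:3) {
    co <- generate_survival_cohort(cohort_spec(60, 2, beta = c(1.5, 0),
                                               seed = 80 + r))
    sc <- two_level_cv_stratify(co, "f1", seed = r, nfolds = 10)
    ns <- two_level_cv_stratify(co, "f2", seed = r, nfolds = 10)
    if (!is.na(sc$logrank$p_value) && sc$logrank$p_value < 0.05)
      hits <- hits + 1L
    if (!is.na(ns$logrank$p_value) && ns$logrank$p_value < 0.05)
      false_pos <- false_pos + 1L
  }
  expect_gte(hits, 2)
  expect_lte(false_pos, 1)
})

test_that("screen bookkeeping: duplicates, empty lists, BH flag", {
  co <- generate_survival_cohort(cohort_spec(30, 1, beta = 1.5, seed = 90))
  co$f_dup <- co$f1
  tab <- univariate_feature_screen(co, c("f1", "f_dup"), seed = 3, nfolds = 5)
  expect_equal(tab$p_value[1], tab$p_value[2])
  empty <- univariate_feature_screen(co, character(0))
  expect_equal(nrow(empty), 0)
})
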