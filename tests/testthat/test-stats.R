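test_that("KM estimate equals 1 - ECDF without censoring and matches the
           hand product-limit with censoring", {
  # no censoring: survival steps through 1 - empirical CDF
  tm <- c(1, 2, 3, 4); ev <- rep(1, 4)
  km <- km_estimate(tm, ev)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km_surv_at(km, 2), 0.5)
  set.seed(1)
  tm <- round(rexp(40, 0.2), 2)
  km <- km_estimate(tm, rep(1, 40))
  expect_equal(km$surv[km$n_event > 0],
               1 - ecdf(tm)(sort(unique(tm))))
  # hand product-limit: (1 - 1/3) then (1 - 1/1)
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km_surv_at(km2, 1), 2 / 3)
  expect_equal(km_surv_at(km2, 3), 0)
  # all censored: flat at 1
  km3 <- km_estimate(c(1, 5, 9), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  # oracle equality on a censored fixture
  fx <- four_group_fixture()
  km4 <- km_estimate(fx$time, fx$event)
  ora <- oracle_km(fx$time, fx$event)
  expect_equal(km_surv_at(km4, max(ora$time)), ora$surv[nrow(ora)])
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("log-rank statistic matches the brute-force O-E/V oracle", {
  fx <- four_group_fixture()
  lr <- logrank_test(fx$time, fx$event, fx$group)
  expect_equal(lr$df, 3)
  expect_equal(lr$statistic, oracle_logrank(fx$time, fx$event, fx$group),
               tolerance = 1e-10)
  # two-group case against the oracle as well
  g2 <- rep(c("x", "y"), 6)
  lr2 <- logrank_test(fx$time, fx$event, g2)
  expect_equal(lr2$statistic, oracle_logrank(fx$time, fx$event, g2),
               tolerance = 1e-10)
  expect_equal(lr2$p_value, pchisq(lr2$statistic, 1, lower.tail = FALSE))
})

test_that("log-rank degenerate and invariance properties hold", {
  # identical time/event pattern in both groups: observed = expected
  tm <- c(1, 2, 3, 1, 2, 3); ev <- c(1, 0, 1, 1, 0, 1)
  gr <- rep(c("a", "b"), each = 3)
  expect_equal(logrank_test(tm, ev, gr)$statistic, 0, tolerance = 1e-12)
  # zero events: statistic 0, p 1
  lr0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), rep(c("a", "b"), 2))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "two groups")
  # relabelling the groups and permuting rows changes nothing
  fx <- four_group_fixture()
  relab <- c(a = "w", b = "x", c = "y", d = "z")[fx$group]
  perm <- sample(nrow(fx))
  expect_equal(logrank_test(fx$time, fx$event, relab)$statistic,
               logrank_test(fx$time[perm], fx$event[perm],
                            fx$group[perm])$statistic)
})

test_that("Cox fit recovers known effects and honours its contracts", {
  set.seed(101)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.1 * exp(log(2) * x))
  t_cn <- rexp(n, 0.045)  # roughly 30% censoring
  tm <- pmin(t_ev, t_cn); ev <- as.integer(t_ev <= t_cn)
  fit <- cox_fit(tm, ev, data.frame(x = x))
  expect_equal(fit$terms$coef, log(2), tolerance = 0.1)
  expect_true(fit$terms$ci_lower < fit$terms$hr &
                fit$terms$hr < fit$terms$ci_upper)
  expect_equal(fit$terms$ci_upper / fit$terms$hr,
               exp(1.959964 * fit$terms$se))
  # permuted (null) covariate: HR near 1, CI covering 1
  fit0 <- cox_fit(tm, ev, data.frame(x = sample(x)))
  expect_true(fit0$terms$ci_lower < 1 & 1 < fit0$terms$ci_upper)
  # rank invariance: strictly increasing time transform leaves beta alone
  fit_tr <- cox_fit(tm^3 + 2 * tm, ev, data.frame(x = x))
  expect_equal(fit_tr$terms$coef, fit$terms$coef, tolerance = 1e-5)
  # Efron and Breslow agree exactly on tie-free data
  expect_equal(cox_fit(tm, ev, data.frame(x = x), ties = "breslow")$terms$coef,
               fit$terms$coef, tolerance = 1e-8)
  # constant covariate is non-identifiable
  expect_error(cox_fit(tm, ev, data.frame(x = rep(1, n))), "constant")
})

test_that("Cox handles categorical covariates and complete-case deletion", {
  set.seed(7)
  n <- 500
  g <- sample(c("I", "II", "III"), n, replace = TRUE)
  tm <- rexp(n, 0.1 * exp(0.5 * (g == "III")))
  ev <- rep(1L, n)
  g_missing <- g
  g_missing[sample(n, 60)] <- NA
  fit <- cox_fit(tm, ev, data.frame(grade = g_missing))
  expect_equal(fit$n_used, n - 60)
  expect_equal(fit$n_supplied, n)
  expect_equal(fit$terms$term, c("gradeII", "gradeIII"))  # ref = I
  fit2 <- cox_fit(tm, ev, data.frame(grade = g_missing),
                  reference = list(grade = "III"))
  expect_equal(fit2$terms$term, c("gradeI", "gradeII"))
})

test_that("chi-square test matches the Pearson statistic and conventions", {
  # exact independence
  r <- chi_square_test(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # published nodal x panel-score table: p ~ 0.029
  nod <- t(published_nodal_counts())
  r2 <- chi_square_test(nod)
  expect_equal(r2$df, 3)
  expect_lt(abs(r2$p_value - 0.029), 0.002)
  # permutation invariance
  expect_equal(chi_square_test(nod[c(3, 1, 4, 2), c(2, 1)])$statistic,
               r2$statistic)
  # zero margins dropped with a warning before df
  expect_warning(r3 <- chi_square_test(rbind(nod, c(0, 0))), "zero-margin")
  expect_equal(r3$df, 3)
  expect_error(chi_square_test(matrix(0, 2, 2)), "empty")
})

test_that("Fisher exact matches hypergeometric enumeration on 2x2 tables", {
  tabs <- list(matrix(c(3, 1, 1, 3), 2),
               matrix(c(8, 2, 1, 5), 2),
               matrix(c(10, 0, 3, 9), 2),
               matrix(c(2, 7, 8, 2), 2))
  for (m in tabs) {
    expect_equal(fisher_exact(m)$p_value, oracle_fisher2x2(m),
                 tolerance = 1e-9)
  }
  # zero margin: conditional distribution degenerate, p = 1
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$p_value, 1)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Monte Carlo Fisher agrees with exact within 3 MC standard errors", {
  m <- matrix(c(3, 9, 7, 2), 2)
  p_exact <- oracle_fisher2x2(m)
  set.seed(20)
  p_mc <- fisher_exact(m, simulate = TRUE)  # force the Monte Carlo path
  se <- sqrt(p_exact * (1 - p_exact) / 1e5)
  expect_lt(abs(p_mc$p_value - p_exact), 3 * se + 2e-5)
})

test_that("chi-square and Fisher p agree on well-populated tables with a
           real association signal", {
  # all expected counts > 20 and a non-null association; in this regime
  # the Pearson approximation and the exact two-sided p estimate the
  # same tail (for near-null tables the probability-mass two-sided
  # Fisher p is conservative by design, and the two deviate)
  tabs <- list(matrix(c(60, 40, 40, 60), 2),
               matrix(c(75, 50, 48, 70), 2),
               matrix(c(120, 90, 85, 130), 2),
               matrix(c(55, 30, 35, 52), 2))
  for (m in tabs) {
    expect_lt(abs(chi_square_test(m)$p_value - fisher_exact(m)$p_value), 0.02)
  }
})

test_that("Pearson correlation returns r and the t-transform p-value", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(5)
  a <- rnorm(10000); b <- rnorm(10000)
  r <- pearson_correlation(a, b)
  expect_lt(abs(r$r), 0.05)
  expect_equal(r$df, 9998)
  # p matches the closed-form t transform
  rr <- pearson_correlation(c(1, 3, 2, 5, 4), c(2, 3, 1, 5, 6))
  tstat <- rr$r * sqrt(3 / (1 - rr$r^2))
  expect_equal(rr$p_value, 2 * pt(-abs(tstat), 3))
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "3 complete pairs")
})

test_that("association tests are invariant to input row ordering", {
  set.seed(9)
  x <- rnorm(50); y <- rnorm(50) + 0.3 * x
  perm <- sample(50)
  expect_equal(pearson_correlation(x, y)$r,
               pearson_correlation(x[perm], y[perm])$r)
  tm <- rexp(50); ev <- rbinom(50, 1, 0.7); gr <- rep(c("a", "b"), 25)
  expect_equal(logrank_test(tm, ev, gr)$statistic,
               logrank_test(tm[perm], ev[perm], gr[perm])$statistic)
  fit1 <- cox_fit(tm, ev, data.frame(x = x))
  fit2 <- cox_fit(tm[perm], ev[perm], data.frame(x = x[perm]))
  expect_equal(fit1$terms$coef, fit2$terms$coef, tolerance = 1e-8)
})
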