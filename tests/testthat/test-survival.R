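test_that("median split labels above-median subjects HIGH, ties LOW", {
  expect_equal(dichotomize_by_median(c(1, 2, 3, 4)),
               c("LOW", "LOW", "HIGH", "HIGH"))
  expect_equal(dichotomize_by_median(c(1, 2, 2, 3)),
               c("LOW", "LOW", "LOW", "HIGH"))
  # translation invariance
  set.seed(4)
  x <- rnorm(20)
  expect_equal(dichotomize_by_median(x), dichotomize_by_median(x + 100))
  expect_error(dichotomize_by_median(rep(1, 10)), "degenerate")
  expect_error(dichotomize_by_median(c(1, 2, 2, 2)), "degenerate")
  expect_error(dichotomize_by_median(c(1, 2, 3)), "at least 4")
})

test_that("product-limit estimate matches closed forms and a naive recount", {
  # all censored -> S = 1 everywhere
  km <- km_estimate(1:5, rep(0, 5))
  expect_true(all(km$surv == 1))

  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv, c(2/3, 2/3, 0))  # (2/3) then (2/3)*(0/1)

  set.seed(14)
  time <- round(rexp(50, 0.1), 1) + 0.1
  event <- rbinom(50, 1, 0.6)
  km50 <- km_estimate(time, event)
  oracle <- naive_km(time, event)
  expect_equal(km50$surv, oracle$surv[match(km50$time, oracle$time)])

  # S is a non-increasing step function in [0, 1]
  expect_true(all(diff(km50$surv) <= 0))
  expect_true(all(km50$surv >= 0 & km50$surv <= 1))

  # rescaling time rescales the axis, not the probabilities
  km_scaled <- km_estimate(time * 12, event)
  expect_equal(km_scaled$time, km50$time * 12)
  expect_equal(km_scaled$surv, km50$surv)

  expect_error(km_estimate(numeric(0), integer(0)), "empty")
})

test_that("log-rank test matches survdiff, symmetry and a permutation null", {
  # two identical groups -> statistic 0, p 1
  time <- c(1, 2, 3, 4, 5); event <- c(1, 0, 1, 1, 0)
  lr0 <- logrank_test(rep(time, 2), rep(event, 2),
                      rep(c("HIGH", "LOW"), each = 5))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)

  set.seed(24)
  for (i in 1:40) {
    n <- sample(8:40, 1)
    t <- rexp(n, 0.1); if (i %% 2 == 0) t <- ceiling(t)  # tied half the time
    e <- rbinom(n, 1, 0.7)
    g <- sample(c("HIGH", "LOW"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    lr <- logrank_test(t, e, g)
    sd <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
    # label symmetry
    sw <- logrank_test(t, e, ifelse(g == "HIGH", "LOW", "HIGH"))
    expect_equal(sw$statistic, lr$statistic)
  }

  # permutation-null oracle on a small mixed-censoring fixture
  t12 <- c(2, 5, 7, 8, 8, 12, 14, 16, 20, 24, 30, 33)
  e12 <- c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0)
  g12 <- rep(c("HIGH", "LOW"), 6)
  obs <- logrank_test(t12, e12, g12)
  set.seed(34)
  perm <- replicate(10000, logrank_test(t12, e12, sample(g12))$statistic)
  p_perm <- mean(perm >= obs$statistic - 1e-12)
  mc_se <- sqrt(p_perm * (1 - p_perm) / 10000)
  expect_lt(abs(obs$p_value - p_perm), 3 * mc_se + 0.02)

  expect_error(logrank_test(t12, e12, rep("HIGH", 12)), "two non-empty groups")
})

test_that("binary Cox fit recovers symmetry, a grid-search oracle and known HR", {
  # identical groups -> HR 1
  time <- rep(c(1, 2, 3, 4, 5), 2); event <- rep(c(1, 0, 1, 1, 1), 2)
  cx <- cox_hr_binary(time, event, rep(c("HIGH", "LOW"), each = 5))
  expect_equal(cx$hr, 1, tolerance = 1e-8)
  expect_true(cx$ci_low <= cx$hr && cx$hr <= cx$ci_high)

  # n = 8 fixture: beta matches a grid search over the Breslow partial likelihood
  t8 <- c(3, 5, 6, 8, 10, 12, 15, 17)
  e8 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g8 <- c("HIGH", "LOW", "HIGH", "HIGH", "LOW", "LOW", "HIGH", "LOW")
  x8 <- as.integer(g8 == "HIGH")
  breslow_loglik <- function(beta) {
    ll <- 0
    for (i in which(e8 == 1)) {
      risk <- t8 >= t8[i]
      ll <- ll + beta * x8[i] - log(sum(exp(beta * x8[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_grid <- grid[which.max(vapply(grid, breslow_loglik, 0))]
  cx8 <- cox_hr_binary(t8, e8, g8)
  expect_equal(cx8$beta, beta_grid, tolerance = 1e-3)

  # exponential simulation with true HR 2, n = 2000, ~20% censoring
  cfg <- sim_config(seed = 77, cohort_n = 2000,
                    true_hr_by_gene = c(G0001 = 2), censor_fraction = 0.2)
  sv <- gen_survival_cohort(cfg)
  lab <- dichotomize_by_median(sv$cohort$expression[, "G0001"])
  cx2 <- cox_hr_binary(sv$cohort$time, sv$cohort$event, lab)
  expect_lt(abs(cx2$hr - 2) / 2, 0.10)

  expect_error(cox_hr_binary(1:5, rep(0, 5), rep(c("HIGH", "LOW"), c(2, 3))),
               "no events")

  # complete separation flagged as diverging with an unbounded CI
  sep <- cox_hr_binary(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0),
                       rep(c("HIGH", "LOW"), each = 3))
  expect_true(sep$diverged)
  expect_equal(sep$ci_high, Inf)
})

test_that("Cox score test equals the log-rank statistic on tie-free data", {
  set.seed(44)
  for (i in 1:25) {
    n <- sample(15:60, 1)
    t <- rexp(n, 0.05)  # continuous: ties have probability zero
    e <- rbinom(n, 1, 0.75)
    g <- sample(c("HIGH", "LOW"), n, replace = TRUE)
    if (sum(e) == 0 || length(unique(g)) < 2) next
    if (anyDuplicated(survival::aeqSurv(survival::Surv(t, e))[, 1L])) next
    fit <- survival::coxph(survival::Surv(t, e) ~ I(g == "HIGH"),
                           ties = "breslow")
    expect_equal(logrank_test(t, e, g)$statistic, unname(fit$score),
                 tolerance = 1e-8)
  }
})

test_that("BH adjustment equals the direct step-up evaluation", {
  expect_equal(bh_adjust(0.03), 0.03)  # n = 1 unchanged
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(54)
  for (i in 1:20) {
    p <- runif(sample(1:100, 1))
    q <- bh_adjust(p)
    expect_equal(q, manual_bh(p))
    expect_true(all(q >= p) && all(q <= 1))
    expect_equal(order(q[order(p)]), seq_along(p))  # order-preserving
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the panel screen splits, tests, adjusts and flags per gene", {
  cfg <- sim_config(seed = 64, cohort_n = 400,
                    true_hr_by_gene = c(G0001 = 3, G0002 = 1, G0003 = 1))
  sv <- gen_survival_cohort(cfg)
  scr <- screen_panel(sv$cohort, alpha = 0.05)
  expect_equal(scr$gene, c("G0001", "G0002", "G0003"))
  g1 <- scr[scr$gene == "G0001", ]
  expect_equal(g1$worse_survival_level, "HIGH")  # planted harmful HIGH group
  expect_true(g1$significant)
  expect_true(all(scr$fdr_p >= scr$p_value))
  expect_true(all(scr$hr_ci_low <= scr$hr & scr$hr <= scr$hr_ci_high))

  # single-gene panel: FDR equals the raw p-value
  one <- screen_panel(sv$cohort, genes = "G0002")
  expect_equal(one$fdr_p, one$p_value)

  # a degenerate gene is skipped and excluded from the BH family
  expr2 <- cbind(sv$cohort$expression, FLAT = 1)
  cohort2 <- survival_cohort(sv$cohort$time, sv$cohort$event, expr2)
  expect_warning(scr2 <- screen_panel(cohort2), "FLAT")
  expect_equal(attr(scr2, "skipped")$gene, "FLAT")
  expect_equal(scr2$fdr_p, scr$fdr_p)

  expect_error(screen_panel(sv$cohort, genes = "NOPE"), "absent")
})

test_that("HR estimation is nearly unbiased with nominal CI coverage", {
  hrs <- cover <- numeric(200)
  for (r in 1:200) {
    cfg <- sim_config(seed = 7000 + r, cohort_n = 1000,
                      true_hr_by_gene = c(G0001 = 2), censor_fraction = 0.2)
    sv <- gen_survival_cohort(cfg)
    lab <- dichotomize_by_median(sv$cohort$expression[, "G0001"])
    cx <- cox_hr_binary(sv$cohort$time, sv$cohort$event, lab)
    hrs[r] <- cx$hr
    cover[r] <- cx$ci_low <= 2 && 2 <= cx$ci_high
  }
  expect_lt(abs(stats::median(hrs) - 2) / 2, 0.05)
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})
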