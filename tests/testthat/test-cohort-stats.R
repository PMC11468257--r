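# Rank tests, correlation, ROC/Youden/DeLong, regression models, KM.

test_that("rank tests match exact and asymptotic references", {
  # identical samples: U sits at its mean, p = 1 under tie-corrected normal
  expect_equal(rank_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))$p_value, 1)
  # complete separation at n = 3 vs 3: exact two-sided p = 2 * 1/choose(6,3)
  r <- rank_tests(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "mann-whitney")
  # rank statistics ignore location shifts
  set.seed(41)
  x <- rnorm(30); g <- rep(c("a", "b"), 15)
  expect_equal(rank_tests(x, g)$p_value, rank_tests(x + 100, g)$p_value)
  # three groups dispatch to Kruskal-Wallis
  g3 <- rep(c("a", "b", "c"), 10)
  expect_equal(rank_tests(x, g3)$method, "kruskal-wallis")
  expect_equal(rank_tests(x, g3)$p_value,
               stats::kruskal.test(x, factor(g3))$p.value)
  expect_error(rank_tests(x, rep("a", 30)), "two nonempty groups")
})

test_that("Spearman correlation matches the hand computation", {
  expect_equal(spearman_corr(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_corr(1:8, -(1:8))$rho, -1)
  # d^2 sum = 4 -> rho = 1 - 6*4/(5*24) = 0.8
  s <- spearman_corr(1:5, c(1, 3, 2, 5, 4))
  expect_equal(s$rho, 0.8)
  expect_equal(s$p_value, 2 * pt(-0.8 * sqrt(3 / (1 - 0.64)), df = 3))
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  # agrees with the reference implementation on untied data
  set.seed(42)
  x <- rnorm(40); y <- 0.3 * x + rnorm(40)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  s2 <- spearman_corr(x, y)
  expect_equal(s2$rho, unname(ref$estimate))
  expect_equal(s2$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("ROC handles separation, saturation and the frozen toy value", {
  r <- roc_youden(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_true(r$cutoff > 2 && r$cutoff < 3)
  expect_equal(r$sensitivity_pct, 100)
  expect_equal(r$specificity_pct, 100)
  expect_equal(r$direction, ">")

  expect_equal(roc_youden(rep(2, 10), rep(c(0, 1), 5))$auc, 0.5)

  # alternating toy: brute-force pair counting gives 6/9
  sc <- 1:6; lb <- c(0, 1, 0, 1, 0, 1)
  expect_equal(roc_youden(sc, lb)$auc, 6 / 9)
  expect_equal(roc_youden(sc, lb)$auc, oracle_auc(sc, lb))
  expect_error(roc_youden(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals exhaustive pair counting on random cohorts", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # force ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    r <- roc_youden(scores, labels)
    a_or <- oracle_auc(scores, labels)
    a_oriented <- if (a_or >= 0.5) a_or else oracle_auc(-scores, labels)
    expect_identical(r$auc, a_oriented)
  }
})

test_that("Youden cutoff is self-consistent as a classifier", {
  set.seed(44)
  for (i in 1:10) {
    n <- 60
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) %in% c(0, n)) next
    scores <- rnorm(n, mean = ifelse(labels == 1, 1, 0))
    r <- roc_youden(scores, labels)
    pred_pos <- if (r$direction == ">") scores > r$cutoff else scores < r$cutoff
    expect_equal(100 * mean(pred_pos[labels == 1]), r$sensitivity_pct)
    expect_equal(100 * mean(!pred_pos[labels == 0]), r$specificity_pct)
  }
})

test_that("DeLong comparison: identity, rank invariance, bootstrap oracle", {
  set.seed(45)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- rnorm(40, mean = 2 * labels)
  expect_equal(delong_compare(a, a, labels)$p_value, 1)
  expect_equal(delong_compare(a, exp(a), labels)$p_value, 1)  # monotone map

  b <- rnorm(40)  # uninformative competitor
  dl <- delong_compare(a, b, labels)
  # bootstrap oracle: resample subjects, z-test on the AUC difference
  nb <- 2000
  d_obs <- abs(auc_mw(a, labels == 1) - max(auc_mw(b, labels == 1),
                                            1 - auc_mw(b, labels == 1)))
  ds <- replicate(nb, {
    ix <- sample(40, replace = TRUE)
    while (length(unique(labels[ix])) < 2) ix <- sample(40, replace = TRUE)
    aa <- auc_mw(a[ix], labels[ix] == 1)
    bb <- auc_mw(b[ix], labels[ix] == 1)
    aa - max(bb, 1 - bb)
  })
  p_boot <- 2 * pnorm(-abs(mean(ds)) / sd(ds))
  expect_lt(abs(dl$p_value - p_boot), 0.02)
})

test_that("logistic model flags degenerate input and covers the null", {
  set.seed(46)
  df <- data.frame(pcr = rep(TRUE, 50), x = rnorm(50))
  expect_error(logistic_or(df, "x"), "no variation")
  df2 <- data.frame(pcr = rbinom(50, 1, 0.5), x = rep(1, 50))
  expect_error(logistic_or(df2, "x"), "constant")

  # 95% Wald CI covers OR = 1 for an unrelated parameter in >= 93% of
  # replicates (1000 used to keep the Monte-Carlo error well below the bound)
  cover <- 0; N <- 1000
  for (i in 1:N) {
    dd <- data.frame(pcr = rbinom(500, 1, 0.3), x = rnorm(500))
    m <- logistic_or(dd, "x")
    cover <- cover + (m$ci95[1] <= 1 && 1 <= m$ci95[2])
  }
  expect_gte(cover / N, 0.93)
})

test_that("logistic and Cox effects rescale as log-linear models must", {
  set.seed(47)
  n <- 400
  x <- runif(n)
  df <- data.frame(pcr = rbinom(n, 1, plogis(-1 + 1.5 * x)), x = x,
                   x10 = 10 * x,
                   pfs_months = rexp(n, 0.02 * exp(0.8 * x)),
                   event = TRUE)
  m1 <- logistic_or(df, "x"); m10 <- logistic_or(df, "x10")
  expect_equal(m10$log_effect, m1$log_effect / 10, tolerance = 1e-6)
  c1 <- cox_hr(df, "x"); c10 <- cox_hr(df, "x10")
  expect_equal(c10$log_effect, c1$log_effect / 10, tolerance = 1e-6)
  # PH is invariant to the time unit
  df_days <- df; df_days$pfs_months <- df$pfs_months * 30.44
  expect_equal(cox_hr(df_days, "x")$effect, c1$effect, tolerance = 1e-8)
  expect_equal(cox_hr(df_days, "x")$p_value, c1$p_value, tolerance = 1e-8)
})

test_that("Cox model rejects eventless or constant input", {
  df <- data.frame(pfs_months = rexp(20), event = FALSE, x = rnorm(20))
  expect_error(cox_hr(df, "x"), "no events")
  df2 <- data.frame(pfs_months = rexp(20), event = TRUE, x = 1)
  expect_error(cox_hr(df2, "x"), "constant")
})

test_that("adjusted models use the fixed clinical covariate set", {
  set.seed(48)
  cs <- cohort_spec(n = 200, seed = 5)
  cohort <- generate_cohort(cs)$cohort
  m <- logistic_or(cohort, "nhoc_max", adjusted = TRUE)
  expect_true(m$adjusted)
  expect_equal(m$covariates, c("age", "clinical_t", "clinical_n",
                               "molecular_subtype"))
  c2 <- cox_hr(cohort, "nhoc_peak", adjusted = TRUE)
  expect_equal(c2$effect_name, "hazard_ratio")
  expect_true(is.finite(c2$p_value) && c2$effect > 0)
  expect_true(c2$ci95[1] <= c2$effect && c2$effect <= c2$ci95[2])
})

test_that("Kaplan-Meier toy case matches the permutation oracle", {
  df <- data.frame(pfs_months = c(2, 4, 10, 12), event = c(1, 1, 0, 0),
                   score = c(1, 1, 0, 0))
  km <- km_logrank(df, "score", 0.5, horizon_months = 5)
  expect_equal(unname(km$survival_at_horizon["high"]), 0)
  expect_equal(unname(km$survival_at_horizon["low"]), 1)
  expect_false(km$degenerate)
  # permutation oracle over all choose(4,2) = 6 labelings of the log-rank
  # statistic: the observed split is maximal, permutation p = 2/6
  obs <- survival::survdiff(survival::Surv(pfs_months, event) ~ score > 0.5,
                            data = df)$chisq
  perms <- combn(4, 2)
  chis <- apply(perms, 2, function(ix) {
    g <- rep(0, 4); g[ix] <- 1
    survival::survdiff(survival::Surv(df$pfs_months, df$event) ~ g)$chisq
  })
  expect_equal(mean(chis >= obs - 1e-9), 2 / 6)
  # both the asymptotic and the exact test agree on non-significance
  expect_gt(km$logrank_p, 0.05)
  expect_equal(km$logrank_p, pchisq(obs, 1, lower.tail = FALSE))
})

test_that("Kaplan-Meier degenerate cases report p = 1", {
  df <- data.frame(pfs_months = c(5, 6, 7, 8), event = 0, score = c(0, 0, 1, 1))
  km <- km_logrank(df, "score", 0.5)
  expect_true(km$degenerate)
  expect_equal(km$logrank_p, 1)
  expect_true(all(km$curves$survival == 1))
  # identical event patterns in both groups
  df2 <- data.frame(pfs_months = rep(c(3, 6, 9), 2), event = rep(1, 6),
                    score = rep(c(0, 1), each = 3))
  expect_equal(km_logrank(df2, "score", 0.5)$logrank_p, 1)
  expect_error(km_logrank(df2, "score", 99), "nonempty")
})
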