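test_that("the logrank kernel agrees with survival::survdiff", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    time <- round(rexp(n, 0.03), 1)  # rounding forces ties
    event <- rbinom(n, 1, 0.7)
    group <- rbinom(n, 1, 0.5)
    if (length(unique(group)) < 2 || sum(event) == 0) next
    ours <- logrank_chisq(time, event, group)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)$chisq
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  expect_equal(logrank_chisq(c(1, 2, 3), c(1, 1, 1), c(1, 1, 1)), 0)
})

test_that("univariate Cox is calibrated under the null and recovers HRs", {
  set.seed(72)
  pvals <- replicate(200, {
    score <- rnorm(100)
    st <- toy_survival(rnorm(100), beta = 0, seed = sample.int(1e6, 1))
    univariate_cox(score, st)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  set.seed(73)
  z <- rnorm(500)
  st <- toy_survival(z, beta = log(0.5), seed = 73)
  fit <- univariate_cox(z, st)
  expect_true(fit$hr >= 0.4 && fit$hr <= 0.62)
  expect_lt(fit$p, 0.001)

  flat <- univariate_cox(rep(2, 100), toy_survival(rnorm(100), seed = 74))
  expect_false(flat$ok)
  expect_match(flat$reason, "non-identifiable")
})

test_that("stepwise multiple Cox screens collinearity and tests added value", {
  set.seed(75)
  n <- 150
  st <- toy_survival(rnorm(n), beta = 0, seed = 75)
  # candidate nearly collinear with average expression -> screened out
  m <- cbind(shadow = st$avg_expression + rnorm(n, 0, 0.01),
             noise = rnorm(n))
  res <- multiple_cox_stepwise(as_score_table(m), st)
  expect_true("shadow" %in% res$screened_out)
  expect_false("shadow" %in% res$kept)
  expect_true(res$lr$p >= 0 && res$lr$p <= 1)

  # planted additive signal beyond avg_expression: LR p < 0.05 in most runs
  hits <- replicate(20, {
    sig <- rnorm(n)
    sv <- simulate_survival(sig, beta = log(2.5))
    st2 <- survival_table(data.frame(
      sample_id = sprintf("s%03d", 1:n), os_time = sv$os_time,
      os_event = sv$os_event, age = rnorm(n, 65, 10),
      gender = factor(sample(c("F", "M"), n, TRUE)),
      grade = factor(sample(c("G1", "G2", "G3"), n, TRUE)),
      avg_expression = rnorm(n)))
    m2 <- cbind(planted = sig, junk = rnorm(n))
    r <- multiple_cox_stepwise(as_score_table(m2), st2)
    r$lr$p < 0.05 && "planted" %in% r$kept
  })
  expect_gte(mean(hits), 0.8)
})

test_that("quantile stratification finds planted group differences", {
  set.seed(76)
  # null: identical survival in both groups, p should not be small
  ps <- replicate(20, {
    score <- rep(c(0, 1), each = 50)
    st <- toy_survival(rnorm(100), beta = 0, seed = sample.int(1e6, 1))
    quantile_stratify(score, st)$per_cutoff$p[1]
  })
  expect_gt(median(ps), 0.05)

  # planted two-group hazard ratio 3 at the median cutoff
  hits <- replicate(20, {
    score <- rep(c(0, 1), each = 50)
    sv <- simulate_survival(score, beta = log(3) / 2, censoring_rate = 0.2)
    # beta per SD: a balanced binary score has SD 0.5, so halve the log-HR
    st <- survival_table(data.frame(sample_id = sprintf("s%03d", 1:100),
                                    os_time = sv$os_time,
                                    os_event = sv$os_event))
    res <- quantile_stratify(score, st, quantiles = 0.5)
    res$per_cutoff$p[1] < 0.01
  })
  expect_gte(mean(hits), 0.9)

  st <- toy_survival(rnorm(40), seed = 77)
  expect_warning(res <- quantile_stratify(rep(1, 40), st), "constant")
  expect_true(is.na(res$best))

  # reported cutoffs come from the candidate quantiles; groups nonempty
  set.seed(78)
  score <- rnorm(60)
  st2 <- toy_survival(score, beta = log(2), seed = 78)
  res2 <- quantile_stratify(score, st2)
  expect_true(all(res2$per_cutoff$cutoff %in%
                    quantile(score, c(0.25, 0.5, 0.75), names = FALSE)))
  expect_true(all(res2$per_cutoff$n_high > 0 & res2$per_cutoff$n_low > 0))
})

test_that("CV permutation p-values respect the add-one floor and sample order", {
  set.seed(79)
  score <- rnorm(30)
  st <- toy_survival(score, beta = log(3), seed = 79, censoring = 0.2)
  r1 <- repeated_cv_permutation(score, st, n = 2, k = 5, m = 1, seed = 11)
  expect_true(all(r1$empirical_p %in% c(0.5, 1)))

  r2 <- repeated_cv_permutation(score, st, n = 3, k = 5, m = 50, seed = 12)
  expect_true(all(r2$empirical_p >= 1 / 51))
  expect_true(all(r2$empirical_p <= 1))

  # shuffling the cohort rows (consistently) leaves results identical
  perm <- sample(nrow(st))
  st_perm <- survival_table(as.data.frame(st)[perm, ])
  r3 <- repeated_cv_permutation(score[perm], st_perm, n = 3, k = 5, m = 50,
                                seed = 12)
  expect_identical(r2$observed, r3$observed)
  expect_identical(r2$empirical_p, r3$empirical_p)
})

test_that("bivariate grouping crosses the two dichotomies", {
  set.seed(80)
  n <- 80
  sp <- rep(c(0, 1), each = n / 2)
  ae <- rep(c(0, 1), times = n / 2)
  st <- toy_survival(rnorm(n), beta = 0, seed = 80)
  st$avg_expression <- ae
  bg <- bivariate_group(sp, st, score_cutoff = 0.5, expr_cutoff = 0.5)
  expect_equal(sort(unique(as.character(bg$groups))),
               sort(c("low/low", "low/high", "high/low", "high/high")))
  expect_equal(unname(table(bg$groups)), rep(n / 4, 4), ignore_attr = TRUE)

  st$avg_expression <- rep(1, n)
  expect_warning(bg2 <- bivariate_group(sp, st, 0.5, 0.5), "constant")
  expect_equal(sum(bg2$table$n > 0), 2L)
})
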