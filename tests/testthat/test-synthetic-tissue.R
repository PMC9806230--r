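test_that("the generator honors its field models and seeds", {
  spec <- tissue_spec(window = c(500, 500), n_cells = 200,
                      field = "constant", mu = 20, sd_noise = 0)
  ct <- generate_tissue(spec, seed = 1)
  expect_true(all(ct$od == 20))
  expect_equal(nrow(ct), 200L)

  a <- generate_tissue(tissue_spec(n_cells = 500, field = "patchy"), seed = 5)
  b <- generate_tissue(tissue_spec(n_cells = 500, field = "patchy"), seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))

  gr <- generate_tissue(tissue_spec(window = c(1000, 1000), n_cells = 3000,
                                    field = "gradient", mu_start = 5,
                                    mu_end = 30, sd_noise = 0.5), seed = 6)
  left <- mean(gr$od[gr$x < 200]); right <- mean(gr$od[gr$x > 800])
  expect_gt(right, left + 15)

  expect_error(tissue_spec(window = c(-1, 100)), "window")
  expect_error(tissue_spec(high_fraction = 1.2), "high_fraction")
})

test_that("patchy samples hit their designed high-area fraction on average", {
  set.seed(91)
  fr <- replicate(20, {
    ct <- generate_tissue(tissue_spec(window = c(2000, 2000), n_cells = 4000,
                                      field = "patchy", patch_scale = 200,
                                      high_fraction = 0.5))
    mean(ct$od >= 17.5)
  })
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 0.01)
})

test_that("Matern clustering produces aggregated patterns", {
  set.seed(92)
  cl <- generate_tissue(tissue_spec(window = c(1000, 1000), n_cells = 1500,
                                    positions = "matern",
                                    parent_intensity = 2e-5,
                                    cluster_radius = 60))
  un <- generate_tissue(tissue_spec(window = c(1000, 1000),
                                    n_cells = nrow(cl)))
  # clustered patterns pack far more close pairs than uniform ones
  pairs_cl <- nrow(build_graph(cl, 25)$edges) / nrow(cl)
  pairs_un <- nrow(build_graph(un, 25)$edges) / nrow(un)
  expect_gt(pairs_cl, 2 * pairs_un)
})

test_that("survival simulation respects censoring and effect sizes", {
  set.seed(93)
  sv0 <- simulate_survival(rnorm(300), beta = 0, censoring_rate = 0)
  expect_true(all(sv0$os_event == 1))
  sv3 <- simulate_survival(rnorm(300), beta = 0, censoring_rate = 0.3)
  expect_gt(mean(sv3$os_event == 0), 0.15)
  expect_lt(mean(sv3$os_event == 0), 0.45)

  # beta = 0 -> null association
  set.seed(94)
  p0 <- replicate(20, {
    z <- rnorm(100)
    st <- toy_survival(z, beta = 0, seed = sample.int(1e6, 1))
    univariate_cox(z, st)$p
  })
  expect_lte(mean(p0 < 0.05), 0.25)
})

test_that("cohorts recover a planted hazard ratio on the driver score", {
  cohort <- generate_cohort(n_samples = 200, beta = log(3), n_cells = 300,
                            seed = 95)
  fit <- univariate_cox(cohort$driver, cohort$survival)
  expect_true(fit$hr >= 2.3 && fit$hr <= 3.9)
  expect_equal(length(cohort$cells), 200L)
  expect_equal(cohort$survival$sample_id, names(cohort$cells))
})

test_that("patchy and homogeneous samples separate on heterogeneity scores", {
  # fine-grained patches put patch boundaries within reach of 10 µm
  # neighbor pairs; 15k cells keep the homogeneity estimate's sampling
  # noise well below the effect
  set.seed(96)
  het_frac <- function(ct) unname(
    tessellation_scores(ct, thetas = 15)[["frac_heterogenous_od15"]])
  hom_r10 <- function(ct) unname(cooccurrence_scores(ct, 10)[["homogeneity_r10"]])
  patchy <- replicate(4, {
    ct <- generate_tissue(tissue_spec(window = c(1500, 1500), n_cells = 15000,
                                      field = "patchy", patch_scale = 60,
                                      mu_high = 30, mu_low = 5))
    c(hf = het_frac(ct), hg = hom_r10(ct))
  })
  homog <- replicate(4, {
    ct <- generate_tissue(tissue_spec(window = c(1500, 1500), n_cells = 15000,
                                      field = "constant", mu = 17.5))
    c(hf = het_frac(ct), hg = hom_r10(ct))
  })
  expect_gt(min(patchy["hf", ]), max(homog["hf", ]))
  expect_lt(max(patchy["hg", ]), min(homog["hg", ]))
})

test_that("finer patches (longer boundaries) raise the heterogenous-tile fraction", {
  set.seed(97)
  hf <- function(ps) mean(replicate(3, {
    ct <- generate_tissue(tissue_spec(window = c(1500, 1500), n_cells = 6000,
                                      field = "patchy", patch_scale = ps))
    unname(tessellation_scores(ct, thetas = 15)[["frac_heterogenous_od15"]])
  }))
  expect_gt(hf(150), hf(600))
})
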