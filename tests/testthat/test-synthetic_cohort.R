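small_spec <- function(...) {
  cohort_spec(n_per_group = c(ASD = 10, TD = 12),
              region_labels = canonical_regions(3), n_sites = 2L,
              n_volumes = 96L, seed = 7, ...)
}

test_that("cohort sampling is deterministic and has the declared shape", {
  spec <- cohort_spec(seed = 5)
  expect_equal(sum(spec$n_per_group), 359)        # 166 + 193
  expect_equal(spec$n_sites, 8L)

  a <- sample_cohort(small_spec())
  b <- sample_cohort(small_spec())
  expect_identical(a$records, b$records)
  expect_identical(a$truth$theta, b$truth$theta)
  expect_equal(nrow(a$records), 22L)
  expect_equal(as.vector(table(a$records$group)), c(10L, 12L))
  expect_true(all(a$records$age >= 6.5 & a$records$age <= 50))
  expect_true(all(a$records$mean_fd > 0))
  # SRS separated by group and partially missing
  srs <- a$truth$spec$srs_mean
  expect_gt(srs[["ASD"]], srs[["TD"]])
})

test_that("zero effects and zero subject noise give a shared baseline", {
  spec <- small_spec(effect_table = data.frame(param = character(),
                                               covariate = character(),
                                               value = numeric()),
                     subject_sd = 0)
  cohort <- sample_cohort(spec)
  expect_equal(max(apply(cohort$truth$theta, 2, sd)), 0)
  expect_equal(unname(cohort$truth$theta[1, 1:4]),
               unname(spec$baseline[1:4]))
})

test_that("every sampled coupling matrix is stable", {
  cohort <- sample_cohort(small_spec())
  mask <- cohort$truth$spec$mask
  ok <- apply(cohort$truth$theta, 1, function(th)
    is_stable_A(assemble_A(th, mask)))
  expect_true(all(ok))
})

test_that("effect table validation rejects unknown keys", {
  expect_error(small_spec(effect_table = data.frame(
    param = "nope->nada", covariate = "age", value = 0.1)), "unknown")
  expect_error(small_spec(effect_table = data.frame(
    param = "self_SubC", covariate = "height", value = 0.1)), "covariates")
})

test_that("simulated BOLD has the contracted degenerate and stochastic
           behaviour", {
  d <- demo_theta3()
  A <- assemble_A(d$theta, d$mask)
  # no noise at all: trajectory decays to a constant
  ts0 <- simulate_subject_bold(A, 2, 96, seed = 1, neural_sd = 0,
                               obs_noise_frac = 0)
  expect_lt(max(abs(ts0$data)), 1e-8)
  # different seeds give different series with similar variance
  t1 <- simulate_subject_bold(A, 2, 1024, seed = 1)
  t2 <- simulate_subject_bold(A, 2, 1024, seed = 2)
  expect_gt(max(abs(t1$data - t2$data)), 0.01)
  # second-order statistics agree within sampling error (power-law input
  # makes low-frequency variance heavy-tailed across realizations)
  v1 <- apply(t1$data, 2, var); v2 <- apply(t2$data, 2, var)
  expect_lt(max(abs(log(v1 / v2))), log(3))
  # same seed reproduces exactly
  expect_identical(t1$data,
                   simulate_subject_bold(A, 2, 1024, seed = 1)$data)
})

test_that("simulated spectra match the analytic prediction (1-node)", {
  # decoupled 2-node system carries two independent 1-node processes
  m2 <- build_connectivity_mask(c("SubC", "V1"))
  lay <- spdcmr:::param_layout(m2)
  th <- numeric(lay$n)
  th[lay$ix_neural] <- c(log(2 * pi * 0.03), 0)  # matches generator gain
  th[lay$ix_obs] <- c(-30, 0)
  A <- assemble_A(th, m2)
  ts <- simulate_subject_bold(A, 2, 16384, seed = 4, obs_noise_frac = 0)
  grid <- frequency_grid(2, n_freq = 16, fmin = 0.02, fmax = 0.2)
  Sw <- csd_welch(ts, grid, seg_len = 512)
  Sp <- predict_csd(th, m2, grid)
  rel <- abs(Re(Sw$csd[1, 1, ]) - Re(Sp$csd[1, 1, ])) / Re(Sp$csd[1, 1, ])
  expect_lt(median(rel), 0.1)
})

test_that("confounded sites scale monotonically and drive an age ANOVA", {
  spec <- cohort_spec(seed = 42)
  s0 <- make_confounded_sites(spec, 0)
  expect_equal(max(abs(s0$site_age_shift)), 0)
  s1 <- make_confounded_sites(spec, 1)
  s2 <- make_confounded_sites(spec, 2)
  expect_true(var(s2$site_age_shift) >= var(s1$site_age_shift))
  expect_true(var(s1$site_age_shift) >= var(s0$site_age_shift))

  # severity 1 at the study's N: age-on-site ANOVA p < 0.001 in >= 9/10
  pvals <- vapply(1:10, function(s) {
    cohort <- sample_cohort(make_confounded_sites(
      cohort_spec(seed = 400 + s), 1))
    summary(aov(age ~ factor(site),
                data = cohort$records))[[1]]$`Pr(>F)`[1]
  }, numeric(1))
  expect_gte(sum(pvals < 0.001), 9)

  # severity 0: no systematic site-age association (uniform-ish p)
  p0 <- vapply(1:6, function(s) {
    cohort <- sample_cohort(make_confounded_sites(
      cohort_spec(seed = 500 + s), 0))
    summary(aov(age ~ factor(site),
                data = cohort$records))[[1]]$`Pr(>F)`[1]
  }, numeric(1))
  expect_gt(max(p0), 0.05)
})

test_that("written cohorts are read back by the ingest stage", {
  dir <- tempfile()
  cohort <- sample_cohort(small_spec())
  write_cohort(cohort, dir)
  man <- read_manifest(file.path(dir, "manifest.json"))
  expect_equal(nrow(man$records), 22L)
  ts <- read_timeseries(man$series_paths[[1]], man$tr,
                        canonical_regions(3))
  expect_equal(nrow(ts$data), 96L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(dim(as.matrix(truth$theta)), dim(cohort$truth$theta))

  # byte-identical participant tables on re-simulation with the same seed
  dir2 <- tempfile()
  write_cohort(sample_cohort(small_spec()), dir2, simulate_bold = FALSE)
  expect_identical(readLines(file.path(dir, "participants.csv")),
                   readLines(file.path(dir2, "participants.csv")))
})

test_that("synthetic first-level posteriors sit near the truth", {
  cohort <- sample_cohort(small_spec())
  set.seed(1)
  posts <- simulate_first_level_posteriors(cohort$truth, est_sd = 0.01,
                                           post_sd = 0.05)
  lay <- posts[[1]]$priors$layout
  est <- t(vapply(posts, function(p) as.numeric(p$mean)[lay$ix_coupling],
                  numeric(7)))
  expect_lt(max(abs(est - cohort$truth$theta)), 0.05)
  expect_true(all(vapply(posts, function(p)
    all(eigen(p$cov, only.values = TRUE)$values > 0), logical(1))))
})
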