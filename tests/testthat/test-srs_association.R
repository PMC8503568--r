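sim_lmm_data <- function(n = 60, n_sites = 4, site_sd = 0.3, seed = 1,
                         b = c(srs = 0.2, age = -0.1, srs_x_age = 0,
                               fd = 0)) {
  set.seed(seed)
  site <- sample(rep_len(sprintf("site%d", seq_len(n_sites)), n))
  covs <- data.frame(srs = rnorm(n), age = rnorm(n))
  covs$srs_x_age <- covs$srs * covs$age
  covs$fd <- rnorm(n)
  u <- rnorm(n_sites, 0, site_sd)
  names(u) <- sprintf("site%d", seq_len(n_sites))
  y <- as.matrix(covs) %*% b + u[site] + rnorm(n, 0, 0.5)
  list(y = as.numeric(y), covs = covs, site = site)
}

test_that("forcing zero site variance reproduces ordinary least squares", {
  d <- sim_lmm_data(seed = 2)
  fit <- fit_lmm_random_intercept(d$y, d$covs, d$site,
                                  site_variance = "zero")
  ols <- lm(d$y ~ srs + age + srs_x_age + fd, data = d$covs)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-8)
  expect_equal(fit$sigma2_site, 0)
  expect_equal(fit$coefficients$se[-1],
               coef(summary(ols))[-1, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a pure site shift is absorbed by the random intercept", {
  # balanced two-site design: identical, site-centered covariates in both
  # sites make the shift orthogonal to every slope column, so slope
  # estimates are invariant for any estimated variance ratio
  set.seed(3)
  m <- 20
  base <- data.frame(srs = rnorm(m), age = rnorm(m))
  base <- as.data.frame(scale(base, scale = FALSE))
  base$srs_x_age <- base$srs * base$age - mean(base$srs * base$age)
  covs <- rbind(base, base)
  site <- rep(c("site1", "site2"), each = m)
  y <- 0.2 * covs$srs - 0.1 * covs$age + rnorm(2 * m, 0, 0.5)
  fit0 <- fit_lmm_random_intercept(y, covs, site)
  y_shift <- y + ifelse(site == "site1", 1, 0)
  fit1 <- fit_lmm_random_intercept(y_shift, covs, site)
  keep <- fit0$coefficients$term %in% c("srs", "age", "srs_x_age")
  expect_lt(max(abs(fit0$coefficients$estimate[keep] -
                    fit1$coefficients$estimate[keep])), 1e-6)
  expect_gt(fit1$sigma2_site, 0)
})

test_that("REML estimates agree with nlme on a random-intercept model", {
  skip_if_not_installed("nlme")
  d <- sim_lmm_data(n = 80, n_sites = 5, site_sd = 0.5, seed = 4)
  fit <- fit_lmm_random_intercept(d$y, d$covs, d$site)
  df <- cbind(y = d$y, d$covs, site = d$site)
  ref <- nlme::lme(y ~ srs + age + srs_x_age + fd, random = ~ 1 | site,
                   data = df, method = "REML")
  expect_equal(fit$coefficients$estimate,
               unname(nlme::fixed.effects(ref)), tolerance = 1e-4)
  expect_equal(sqrt(fit$sigma2), ref$sigma, tolerance = 1e-3)
  vc <- as.numeric(nlme::VarCorr(ref)[1, 1])
  expect_equal(fit$sigma2_site, vc, tolerance = 0.02 * max(vc, 0.01))
  # between-within denominator df for subject-level covariates
  expect_equal(fit$coefficients$df[2], unname(ref$fixDF$X["srs"]))
})

test_that("the interaction Wald test is calibrated under the null", {
  rej <- vapply(1:200, function(s) {
    d <- sim_lmm_data(n = 50, n_sites = 4, site_sd = 0.3, seed = 1000 + s)
    fit <- fit_lmm_random_intercept(d$y, d$covs, d$site)
    fit$coefficients$p[fit$coefficients$term == "srs_x_age"] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("LMM rejects degenerate inputs", {
  d <- sim_lmm_data(n = 20, n_sites = 2)
  expect_error(fit_lmm_random_intercept(d$y, d$covs,
                                        rep("siteA", 20)), "one site")
  covs_bad <- d$covs
  covs_bad$dup <- covs_bad$srs
  expect_error(fit_lmm_random_intercept(d$y, covs_bad, d$site), "singular")
})

test_that("BH adjustment matches the hand-computed step-up rule", {
  expect_equal(bh_fdr(c(0.005, 0.03, 0.04, 0.2)),
               c(0.02, 0.0533333333, 0.0533333333, 0.2),
               tolerance = 1e-9)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(0.04), 0.04)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("BH matches a brute-force step-up implementation", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    prev <- 1
    for (i in rev(seq_len(m))) {
      prev <- min(prev, p[o[i]] * m / i)
      q[o[i]] <- prev
    }
    pmin(q, 1)
  }
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("SRS strata use mean +/- 1 SD with boundaries inclusive to mid", {
  expect_equal(as.character(stratify_srs(c(0, 50, 100))),
               c("mid", "mid", "mid"))
  s <- stratify_srs(c(0, 10, 50, 90, 100))
  expect_equal(as.character(s[c(1, 5)]), c("low", "high"))
  # location invariance
  x <- c(3, 20, 45, 80, 120, 60)
  expect_equal(stratify_srs(x), stratify_srs(x + 500))
  expect_error(stratify_srs(rep(10, 5)), "variance")
  expect_error(stratify_srs(c(1, 2)), "three")
  # NA propagates, complete values stratified on the subsample
  s2 <- stratify_srs(c(NA, 0, 10, 50, 90, 100))
  expect_true(is.na(s2[1]))
})

test_that("the connection-wise LMM table restricts to SRS-complete subjects
           and adjusts within terms", {
  set.seed(9)
  n <- 50
  rec <- data.frame(
    subject_id = sprintf("s%d", 1:n),
    group = factor(rep(c("ASD", "TD"), length.out = n)),
    age = runif(n, 8, 40), mean_fd = runif(n, 0.05, 0.3),
    site = sample(rep_len(c("a", "b", "c"), n)),
    srs_total = c(rep(NA, 10), runif(n - 10, 5, 150)))
  strengths <- matrix(rnorm(n * 3, 0, 0.1), n, 3,
                      dimnames = list(NULL, c("SubC->V1", "V1->SubC",
                                              "self_V1")))
  tab <- srs_lmm_table(strengths, rec)
  expect_setequal(unique(tab$connection), colnames(strengths))
  expect_false("(Intercept)" %in% tab$term)
  for (tm in unique(tab$term)) {
    sel <- tab$term == tm
    expect_equal(tab$q[sel], bh_fdr(tab$p[sel]))
    expect_true(all(tab$q[sel] >= tab$p[sel] - 1e-12))
  }
})

test_that("the SRS-by-age PEB variant finds an injected effect", {
  d <- demo_theta3()
  set.seed(31)
  n <- 80
  rec <- data.frame(
    subject_id = sprintf("s%d", 1:n),
    group = factor(rep(c("ASD", "TD"), length.out = n)),
    age = runif(n, 8, 40), mean_fd = runif(n, 0.05, 0.3),
    site = sample(rep_len(c("a", "b"), n)),
    srs_total = c(rep(NA, 8), runif(n - 8, 5, 150)))
  ok <- !is.na(rec$srs_total)
  zs <- za <- rep(0, n)
  zs[ok] <- scale(rec$srs_total[ok]); za[ok] <- scale(rec$age[ok])[, 1]
  theta <- matrix(0.1, n, 7, dimnames = list(NULL, d$lay$names[1:7]))
  theta[, "self_dS1"] <- 0.1 - 0.12 * zs * za     # negative SRS-by-age
  truth <- list(theta = theta, spec = list(mask = d$mask))
  posts <- simulate_first_level_posteriors(truth, est_sd = 0.03,
                                           post_sd = 0.03)
  bma <- peb_srs_interaction(posts, rec, site_mode = "dummies")
  # design rows = SRS-complete N; injected cell significant and negative
  expect_true(bma$significant["self_dS1", "srs_x_age"])
  expect_lt(bma$effect_mean["self_dS1", "srs_x_age"], 0)
  other <- bma$significant[, "srs_x_age"]
  expect_lte(sum(other) - 1, 1)   # at most one stray flag
})
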