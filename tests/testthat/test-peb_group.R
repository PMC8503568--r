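make_records <- function(n = 24, n_sites = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = factor(rep(c("ASD", "TD"), length.out = n),
                   levels = c("ASD", "TD")),
    age = runif(n, 8, 40),
    mean_fd = runif(n, 0.05, 0.3),
    site = sprintf("site%d", sample(rep_len(seq_len(n_sites), n))),
    srs_total = c(NA, runif(n - 1, 5, 150)),
    stringsAsFactors = FALSE)
}

test_that("main design has the documented columns, coding and rank", {
  rec <- make_records(40, n_sites = 8)
  d <- build_design(rec, "dummies")
  expect_equal(d$column_labels[1:5],
               c("mean", "age", "group", "age_x_group", "fd"))
  expect_equal(ncol(d$matrix), 5 + 7)          # 8 sites -> 7 dummies
  expect_equal(unname(d$matrix[, 1]), rep(1, 40))
  expect_equal(sd(d$matrix[, "age"]), 1)
  expect_setequal(unique(d$matrix[, "group"]), c(0.5, -0.5))
  expect_equal(d$matrix[, "age_x_group"],
               d$matrix[, "age"] * d$matrix[, "group"])
  expect_equal(qr(d$matrix)$rank, ncol(d$matrix))
  # site dummies are centered
  expect_lt(max(abs(colMeans(d$matrix[, 6:12]))), 1e-12)
})

test_that("degenerate designs are rejected", {
  rec <- make_records(6, n_sites = 1)
  expect_error(build_design(rec, "dummies"), "fewer than two sites")
  rec2 <- make_records(4, n_sites = 2)
  rec2$age <- 20                              # constant age
  expect_error(build_design(rec2, "none"), "rank deficient")
})

test_that("orthogonalized site dummies are orthogonal to the age columns
           and preserve the design span", {
  rec <- make_records(60, n_sites = 5)
  d <- build_design(rec, "orthogonalized")
  site_cols <- grep("^site_", d$column_labels)
  for (j in site_cols) {
    expect_lt(abs(sum(d$matrix[, j] * d$matrix[, "age"])), 1e-10)
    expect_lt(abs(sum(d$matrix[, j] * d$matrix[, "age_x_group"])), 1e-10)
    for (k in site_cols[site_cols < j])
      expect_lt(abs(sum(d$matrix[, j] * d$matrix[, k])), 1e-8)
  }
  # projection matrices (fitted-value spans) identical with raw dummies
  draw <- build_design(rec, "dummies")
  P1 <- draw$matrix %*% solve(crossprod(draw$matrix), t(draw$matrix))
  P2 <- d$matrix %*% solve(crossprod(d$matrix), t(d$matrix))
  expect_lt(max(abs(P1 - P2)), 1e-10)
})

test_that("within-group age design partitions the age column", {
  rec <- make_records(30, n_sites = 2)
  d <- build_within_group_age_design(rec, "none")
  expect_equal(d$column_labels,
               c("mean", "group", "age_TD", "age_ASD", "fd"))
  # a TD subject has zero in the ASD age column
  td <- rec$group == "TD"
  expect_true(all(d$matrix[td, "age_ASD"] == 0))
  expect_true(all(d$matrix[!td, "age_TD"] == 0))
  # the two columns sum to the group-wise centered (scaled) age
  gw <- ave(rec$age, rec$group, FUN = function(a) a - mean(a)) / sd(rec$age)
  expect_equal(unname(d$matrix[, "age_TD"] + d$matrix[, "age_ASD"]), gw)
})

test_that("PEB shrinks identical subjects toward zero, vanishing with N", {
  d <- demo_theta3()
  m_shared <- c(0.2, -0.1, 0.1, 0.05, 0.1, -0.05, 0.08)
  make_posts <- function(N) {
    truth <- list(theta = matrix(rep(m_shared, each = N), N, 7,
                                 dimnames = list(NULL, d$lay$names[1:7])),
                  spec = list(mask = d$mask))
    simulate_first_level_posteriors(truth, est_sd = 0, post_sd = 0.1)
  }
  fit_mean_only <- function(N) {
    posts <- make_posts(N)
    design <- structure(list(matrix = matrix(1, N, 1,
                                             dimnames = list(NULL, "mean")),
                             column_labels = "mean", site_mode = "none"),
                        class = "peb_design")
    fit_peb(posts, design)$beta_mean[, 1]
  }
  b10 <- fit_mean_only(10)
  b80 <- fit_mean_only(80)
  # shrinkage: between 0 and the shared mean, vanishing as N grows
  expect_true(all(abs(b10) <= abs(m_shared) + 1e-6))
  expect_true(all(sign(b10) == sign(m_shared)))
  expect_lt(mean(abs(b80 - m_shared)), mean(abs(b10 - m_shared)) + 1e-9)
  expect_lt(mean(abs(b80 - m_shared)), 0.01)
})

test_that("PEB equals weighted least squares in the tight-data limit", {
  d <- demo_theta3()
  set.seed(4)
  N <- 40
  rec <- make_records(N, n_sites = 2, seed = 4)
  design <- build_design(rec, "none")
  X <- design$matrix
  K <- 7
  btrue <- matrix(rnorm(K * ncol(X), 0, 0.1), K, ncol(X))
  theta <- t(apply(X, 1, function(x) btrue %*% x))
  colnames(theta) <- d$lay$names[1:7]
  truth <- list(theta = theta, spec = list(mask = d$mask))
  posts <- simulate_first_level_posteriors(truth, est_sd = 0,
                                           post_sd = 1e-4)
  peb <- fit_peb(posts, design)
  ols <- t(solve(crossprod(X), crossprod(X, theta)))
  expect_lt(max(abs(peb$beta_mean - ols)), 1e-3)
})

test_that("PEB is invariant to subject permutation", {
  d <- demo_theta3()
  set.seed(5)
  N <- 20
  rec <- make_records(N, n_sites = 2, seed = 5)
  theta <- matrix(rnorm(N * 7, 0, 0.1), N, 7,
                  dimnames = list(NULL, d$lay$names[1:7]))
  truth <- list(theta = theta, spec = list(mask = d$mask))
  set.seed(6)
  posts <- simulate_first_level_posteriors(truth, est_sd = 0.05,
                                           post_sd = 0.05)
  design <- build_design(rec, "none")
  peb <- fit_peb(posts, design)
  perm <- sample(N)
  design_p <- design
  design_p$matrix <- design$matrix[perm, , drop = FALSE]
  peb_p <- fit_peb(posts[perm], design_p)
  expect_lt(max(abs(peb$beta_mean - peb_p$beta_mean)), 1e-8)
})

test_that("Bayesian model reduction matches conjugate-Gaussian refits", {
  # 1-D: prior N(0,1), likelihood equivalent N(1,1) -> posterior N(0.5,0.5)
  oracle <- function(mlik, vlik, v0, v0r) {
    C <- 1 / (1 / v0 + 1 / vlik); m <- C * mlik / vlik
    Cr <- 1 / (1 / v0r + 1 / vlik); mr <- Cr * mlik / vlik
    dF <- dnorm(mlik, 0, sqrt(v0r + vlik), log = TRUE) -
      dnorm(mlik, 0, sqrt(v0 + vlik), log = TRUE)
    list(m = m, C = C, mr = mr, Cr = Cr, dF = dF)
  }
  o <- oracle(1, 1, 1, 1e-8)
  red <- bayesian_model_reduction(
    list(mean = 0, var = 1),
    list(mean = o$m, cov = matrix(o$C)),
    list(mean = 0, var = 1e-8))
  expect_equal(red$mean, o$mr, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(red$cov[1, 1], o$Cr, tolerance = 1e-6)
  expect_equal(red$delta_log_evidence, o$dF, tolerance = 1e-6)

  # several random 1-D cases
  set.seed(9)
  for (i in 1:5) {
    mlik <- rnorm(1); vlik <- runif(1, 0.2, 2); v0r <- runif(1, 0.05, 0.5)
    o <- oracle(mlik, vlik, 1, v0r)
    red <- bayesian_model_reduction(
      list(mean = 0, var = 1),
      list(mean = o$m, cov = matrix(o$C)),
      list(mean = 0, var = v0r))
    expect_equal(red$delta_log_evidence, o$dF, tolerance = 1e-6)
    expect_equal(red$mean, o$mr, tolerance = 1e-6, ignore_attr = TRUE)
  }

  # no reduction: identical priors leave everything unchanged
  post <- list(mean = c(0.3, -0.2), cov = diag(c(0.5, 0.25)))
  same <- bayesian_model_reduction(list(mean = c(0, 0), var = c(1, 1)),
                                   post, list(mean = c(0, 0), var = c(1, 1)))
  expect_equal(same$delta_log_evidence, 0, tolerance = 1e-12)
  expect_equal(same$mean, post$mean, tolerance = 1e-12, ignore_attr = TRUE)

  # independence: pruning one parameter leaves the other marginal alone
  red2 <- bayesian_model_reduction(list(mean = c(0, 0), var = c(1, 1)),
                                   post,
                                   list(mean = c(0, 0), var = c(1, 1e-8)))
  expect_equal(red2$mean[1], post$mean[1], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(red2$cov[1, 1], post$cov[1, 1], tolerance = 1e-8)
})

toy_peb <- function(beta, se = 0.05, prior_var = 1 / 16) {
  # fabricate a peb_result with independent effects for search tests
  K <- nrow(beta); P <- ncol(beta)
  eff <- as.vector(outer(rownames(beta), colnames(beta), paste, sep = ":"))
  structure(list(
    beta_mean = beta, beta_cov = diag(se^2, K * P),
    beta_prior_mean = setNames(rep(0, K * P), eff),
    beta_prior_var = setNames(rep(prior_var, K * P), eff),
    lambda = 0, free_energy = 0, conn_names = rownames(beta),
    design = list(column_labels = colnames(beta)), K = K, P = P),
    class = "peb_result")
}

test_that("greedy and exhaustive searches agree on small model spaces", {
  beta <- matrix(c(0.2, 0.0, 0.15, 0.01), 2, 2,
                 dimnames = list(c("c1", "c2"), c("mean", "age")))
  peb <- toy_peb(beta)
  g <- bma_search(peb, "greedy", search_cols = 1:2)
  e <- bma_search(peb, "exhaustive", search_cols = 1:2)
  expect_lt(max(abs(g$posterior_prob - e$posterior_prob)), 0.02)
  expect_lt(max(abs(g$effect_mean - e$effect_mean)), 0.02)
  expect_equal(sum(e$weights), 1, tolerance = 1e-12)
})

test_that("null effects are pruned and true effects retained", {
  beta <- matrix(c(0.3, 0.25, 0.28, 0.003, -0.004, 0.002), 3, 2,
                 dimnames = list(c("c1", "c2", "c3"), c("mean", "age")))
  peb <- toy_peb(beta, se = 0.03)
  bma <- bma_search(peb)
  expect_true(all(bma$posterior_prob[, "mean"] > 0.99))
  expect_true(all(bma$posterior_prob[, "age"] < 0.5))
  expect_true(all(bma$ci90_low[, "age"] <= 0 & bma$ci90_high[, "age"] >= 0))
  # averaged means lie inside the convex hull [0, full estimate]
  expect_true(all(abs(bma$effect_mean[, "age"]) <= abs(beta[, "age"]) + 1e-12))
})

test_that("the 0.90 decision rule separates significant, trend and null", {
  d <- decision_rule(c(0.2, 0.1, 0.0), c(0.1, 0.1, 0.1),
                     c(0.95, 0.88, 0.50))
  expect_equal(as.character(d$decision), c("significant", "trend", "null"))
  expect_equal(d$ci90_low[1], 0.2 - qnorm(0.95) * 0.1)
  expect_equal(d$ci90_high[1], 0.2 + qnorm(0.95) * 0.1)
  expect_gt(d$ci90_low[1], 0)                     # CI excludes zero
  expect_equal(round(d$ci90_low[1], 4), 0.0355)
  expect_equal(round(d$ci90_high[1], 4), 0.3645)
  # exactly 0.90 is not significant (strict rule)
  expect_equal(as.character(decision_rule(0.1, 0.1, 0.90)$decision), "trend")
  expect_error(decision_rule(0.1, 0, 0.5))
})
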