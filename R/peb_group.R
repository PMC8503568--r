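# Second-level (between-subject) Bayesian GLM over first-level posteriors,
# Bayesian model reduction over nested effect structures, Bayesian model
# averaging and the 90% posterior-probability decision rule.

z_scale <- function(x) {
  s <- sd(x)
  if (s < 1e-12) return(x - mean(x))
  (x - mean(x)) / s
}

# successive orthogonalization: each column in `cols` is residualized on
# the span of `against` plus the previously processed columns, so the
# processed columns end up orthogonal to the age regressors and to each
# other while the overall column span is unchanged
orthogonalize_columns <- function(X, cols, against) {
  done <- against
  for (j in cols) {
    B <- X[, done, drop = FALSE]
    X[, j] <- X[, j] - B %*% qr.solve(B, X[, j])
    done <- c(done, j)
  }
  X
}

make_site_dummies <- function(site) {
  tab <- sort(table(site), decreasing = TRUE)
  ref <- names(tab)[1]             # reference = most populous site
  others <- setdiff(names(tab), ref)
  D <- sapply(others, function(s) as.numeric(site == s))
  D <- as.matrix(D)
  colnames(D) <- paste0("site_", others)
  sweep(D, 2, colMeans(D))         # centered dummies
}

finalize_design <- function(X, labels, site_mode, age_cols) {
  colnames(X) <- labels
  if (qr(X)$rank < ncol(X)) {
    cn <- ncol(X)
    stop("design matrix is rank deficient (", qr(X)$rank, " < ", cn,
         "); check for collinear or constant columns")
  }
  structure(list(matrix = X, column_labels = labels, site_mode = site_mode,
                 age_cols = age_cols),
            class = "peb_design")
}

#' @export
print.peb_design <- function(x, ...) {
  cat(sprintf("PEB design: %d subjects x %d covariates (site mode: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$site_mode))
  cat("  columns:", paste(x$column_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Build the main second-level design matrix
#'
#' Columns in order: mean (all ones), age (z-scored), group (ASD = +0.5,
#' TD = -0.5, so positive group effects read ASD > TD and the interaction
#' is the ASD-minus-TD difference in age slope), age-by-group interaction
#' (elementwise product of the coded columns), mean framewise displacement
#' (z-scored nuisance), and, depending on `site_mode`, centered site
#' indicator dummies (one fewer than the number of sites; reference = most
#' populous site). In `orthogonalized` mode each site dummy is
#' Gram-Schmidt-orthogonalized against the age regressors (age and
#' age-by-group) and then against the previously processed dummies, which
#' returns age-shared variance to the age columns without changing the
#' design's column span.
#'
#' @param records Participant data frame from [read_participants()] (or the
#'   synthetic generator).
#' @param site_mode One of `"none"`, `"dummies"`, `"orthogonalized"`.
#' @return A `peb_design` object.
#' @export
build_design <- function(records, site_mode = c("none", "dummies",
                                                "orthogonalized")) {
  site_mode <- match.arg(site_mode)
  n <- nrow(records)
  if (n < 2L) stop("need at least two subjects")
  age <- z_scale(records$age)
  grp <- ifelse(records$group == "ASD", 0.5, -0.5)
  fd <- z_scale(records$mean_fd)
  X <- cbind(mean = 1, age = age, group = grp, age_x_group = age * grp,
             fd = fd)
  age_cols <- c("age", "age_x_group")
  if (site_mode != "none") {
    if (length(unique(records$site)) < 2L)
      stop("site dummies requested but fewer than two sites present")
    D <- make_site_dummies(records$site)
    X <- cbind(X, D)
    if (site_mode == "orthogonalized")
      X <- orthogonalize_columns(X, colnames(D), age_cols)
  }
  finalize_design(X, colnames(X), site_mode, age_cols)
}

#' Build the within-group age design
#'
#' Models the effect of age separately in the two groups: columns
#' [mean, group, age_TD, age_ASD, fd, (site dummies...)], where `age_g` is
#' the within-group-centered age (scaled by the overall age SD) times the
#' group indicator. The two age columns sum to the group-wise centered age.
#'
#' @inheritParams build_design
#' @return A `peb_design` object.
#' @export
build_within_group_age_design <- function(records,
                                          site_mode = c("none", "dummies",
                                                        "orthogonalized")) {
  site_mode <- match.arg(site_mode)
  if (length(unique(records$group)) < 2L) stop("both groups must be present")
  s_age <- sd(records$age)
  if (s_age < 1e-12) stop("age has zero variance")
  age_in <- function(g) {
    ind <- records$group == g
    out <- numeric(nrow(records))
    out[ind] <- (records$age[ind] - mean(records$age[ind])) / s_age
    out
  }
  grp <- ifelse(records$group == "ASD", 0.5, -0.5)
  X <- cbind(mean = 1, group = grp, age_TD = age_in("TD"),
             age_ASD = age_in("ASD"), fd = z_scale(records$mean_fd))
  age_cols <- c("age_TD", "age_ASD")
  if (site_mode != "none") {
    if (length(unique(records$site)) < 2L)
      stop("site dummies requested but fewer than two sites present")
    D <- make_site_dummies(records$site)
    X <- cbind(X, D)
    if (site_mode == "orthogonalized")
      X <- orthogonalize_columns(X, colnames(D), age_cols)
  }
  finalize_design(X, colnames(X), site_mode, age_cols)
}

#' Second-level priors
#'
#' @param beta_var Prior variance of each second-level effect (default 1/16).
#' @param lambda_prior_var Prior variance of the between-subject
#'   log-precision (default 1).
#' @return List of prior settings.
#' @export
peb_priors <- function(beta_var = 1 / 16, lambda_prior_var = 1) {
  list(beta_var = beta_var, lambda_prior_var = lambda_prior_var)
}

#' Fit the parametric empirical Bayes model
#'
#' Hierarchical Gaussian model `theta_i = X_i beta + eps_i`: each subject's
#' first-level posterior (mean and covariance over the selected parameter
#' subset) is treated as a noisy observation of that subject's true
#' coupling vector, so first-level uncertainty propagates to the group
#' level. Between-subject residuals have isotropic precision `exp(lambda)`
#' with a N(0, 1) prior on `lambda`; `beta` has independent N(0, beta_var)
#' priors. `lambda` is estimated by maximizing the (beta-marginalized) free
#' energy in one dimension; `beta`'s Gaussian posterior is then exact.
#'
#' @param posteriors List of `dcm_posterior` objects sharing one layout.
#' @param design A `peb_design` with one row per posterior.
#' @param subset Character or integer vector of first-level parameters
#'   taken to the second level; default: all coupling + self parameters.
#' @param priors2 Second-level priors from [peb_priors()].
#' @return Object of class `peb_result`: `beta_mean` (K x P), `beta_cov`
#'   (KP x KP), `lambda`, `free_energy`, `conn_names`, `design`, and the
#'   second-level prior moments used (needed for reduction).
#' @export
fit_peb <- function(posteriors, design, subset = NULL,
                    priors2 = peb_priors()) {
  stopifnot(inherits(design, "peb_design"))
  N <- length(posteriors)
  if (nrow(design$matrix) != N)
    stop("design has ", nrow(design$matrix), " rows for ", N, " subjects")
  lay <- posteriors[[1]]$priors$layout
  if (is.null(subset)) subset <- lay$ix_coupling
  if (is.character(subset)) subset <- match(subset, names(posteriors[[1]]$mean))
  if (!length(subset)) stop("empty parameter subset")
  conn_names <- names(posteriors[[1]]$mean)[subset]
  K <- length(subset)
  P <- ncol(design$matrix)
  X <- design$matrix

  M <- t(vapply(posteriors, function(p) as.numeric(p$mean)[subset],
                numeric(K)))
  Cs <- lapply(seq_len(N), function(i) {
    Ci <- posteriors[[i]]$cov[subset, subset, drop = FALSE]
    Ci <- (Ci + t(Ci)) / 2
    if (inherits(tryCatch(chol(Ci), error = function(e) e), "error"))
      stop("first-level posterior covariance of subject ", i, " is not PD")
    Ci
  })

  prior_prec_b <- rep(1 / priors2$beta_var, K * P)

  peb_moments <- function(lambda) {
    Vb <- exp(-lambda)
    Lam <- diag(prior_prec_b, K * P)
    rhs <- numeric(K * P)
    quad <- 0
    logdetS <- 0
    for (i in seq_len(N)) {
      Si <- Cs[[i]] + diag(Vb, K)
      cS <- chol(Si)
      Si_inv <- chol2inv(cS)
      logdetS <- logdetS + 2 * sum(log(diag(cS)))
      Lam <- Lam + kronecker(tcrossprod(X[i, ]), Si_inv)
      smi <- Si_inv %*% M[i, ]
      rhs <- rhs + kronecker(X[i, ], smi)
      quad <- quad + sum(M[i, ] * smi)
    }
    cL <- chol(Lam)
    mb <- backsolve(cL, forwardsolve(t(cL), rhs))
    list(mb = mb, Lam = Lam, cL = cL, quad = quad, logdetS = logdetS,
         rhs = rhs)
  }
  free_energy_lambda <- function(lambda) {
    mo <- peb_moments(lambda)
    logdetLam <- 2 * sum(log(diag(mo$cL)))
    -0.5 * (mo$quad - sum(mo$mb * mo$rhs)) - 0.5 * mo$logdetS -
      0.5 * sum(log(1 / prior_prec_b)) - 0.5 * logdetLam -
      0.5 * N * K * log(2 * pi) -
      0.5 * lambda^2 / priors2$lambda_prior_var
  }
  opt <- optimise(free_energy_lambda, c(-4, 10), maximum = TRUE, tol = 1e-3)
  lambda <- opt$maximum
  mo <- peb_moments(lambda)
  beta_cov <- chol2inv(mo$cL)
  beta_cov <- (beta_cov + t(beta_cov)) / 2
  eff_names <- as.vector(outer(conn_names, design$column_labels,
                               function(a, b) paste(a, b, sep = ":")))
  dimnames(beta_cov) <- list(eff_names, eff_names)
  beta_mean <- matrix(mo$mb, K, P,
                      dimnames = list(conn_names, design$column_labels))
  structure(list(beta_mean = beta_mean, beta_cov = beta_cov,
                 beta_prior_mean = setNames(rep(0, K * P), eff_names),
                 beta_prior_var = setNames(rep(priors2$beta_var, K * P),
                                           eff_names),
                 lambda = lambda, free_energy = opt$objective,
                 conn_names = conn_names, design = design,
                 K = K, P = P),
            class = "peb_result")
}

#' @export
print.peb_result <- function(x, ...) {
  cat(sprintf("PEB result: %d connections x %d covariates, lambda = %.2f, F = %.2f\n",
              x$K, x$P, x$lambda, x$free_energy))
  print(round(x$beta_mean, 3))
  invisible(x)
}

#' Bayesian model reduction
#'
#' Computes the posterior and log-evidence change of a model whose prior is
#' a nested modification of the full model's prior, directly from the full
#' model's Gaussian posterior (no refit). With precisions `P = C^-1`:
#' `P_r = P + P0r - P0`, `m_r = P_r^-1 (P m + P0r m0r - P0 m0)`, and the
#' standard Gaussian evidence-ratio identity for the change in log
#' evidence. A parameter is "switched off" by a reduced prior with mean 0
#' and variance 1e-8.
#'
#' @param full_prior,full_posterior,reduced_prior Lists with `mean` and
#'   either `cov` (matrix) or `var` (diagonal vector).
#' @return List with `mean`, `cov` of the reduced posterior and
#'   `delta_log_evidence`; non-PD reductions yield
#'   `delta_log_evidence = -Inf`.
#' @export
bayesian_model_reduction <- function(full_prior, full_posterior,
                                     reduced_prior) {
  as_cov <- function(g, d) {
    if (!is.null(g$cov)) as.matrix(g$cov) else diag(g$var, d)
  }
  d <- length(full_posterior$mean)
  C <- as_cov(full_posterior, d)
  C0 <- as_cov(full_prior, d)
  C0r <- as_cov(reduced_prior, d)
  m <- as.numeric(full_posterior$mean)
  m0 <- as.numeric(full_prior$mean)
  m0r <- as.numeric(reduced_prior$mean)
  P <- chol2inv(chol(C))
  P0 <- chol2inv(chol(C0))
  P0r <- chol2inv(chol(C0r))
  Pr <- P + P0r - P0
  cPr <- tryCatch(chol((Pr + t(Pr)) / 2), error = function(e) NULL)
  if (is.null(cPr))
    return(list(mean = m, cov = C, delta_log_evidence = -Inf))
  Cr <- chol2inv(cPr)
  mr <- as.numeric(Cr %*% (P %*% m + P0r %*% m0r - P0 %*% m0))
  ld <- function(A) 2 * sum(log(diag(chol((A + t(A)) / 2)))) # log det
  dF <- 0.5 * (ld(P) + ld(P0r) - ld(P0) - ld(Pr)) +
    0.5 * (sum(mr * (Pr %*% mr)) - sum(m * (P %*% m))) -
    0.5 * (sum(m0r * (P0r %*% m0r)) - sum(m0 * (P0 %*% m0)))
  list(mean = setNames(mr, names(full_posterior$mean)),
       cov = Cr, delta_log_evidence = dF)
}

# evidence change and reduced posterior for a set of switched-off effects
reduce_peb <- function(peb, off, switch_var = 1e-8) {
  d <- peb$K * peb$P
  var_r <- as.numeric(peb$beta_prior_var)
  var_r[off] <- switch_var
  bayesian_model_reduction(
    full_prior = list(mean = peb$beta_prior_mean, var = as.numeric(peb$beta_prior_var)),
    full_posterior = list(mean = as.vector(peb$beta_mean), cov = peb$beta_cov),
    reduced_prior = list(mean = rep(0, d), var = var_r))
}

#' Search nested models and average (BMR + BMA)
#'
#' Candidate reduced models switch off subsets of the (connection x
#' covariate) second-level effects. `greedy` (default) iteratively removes
#' the effect whose removal most increases model evidence until no removal
#' helps, then averages over the `2^min(8, n)` neighbourhood of the most
#' evidence-ambiguous effects; `exhaustive` enumerates every subset (capped
#' at `max_models`). Averaging weights are the softmax of log evidences;
#' each effect's retention probability is the summed weight of models that
#' keep it; averaged moments (`effect_mean`, `effect_sd`) are those of the
#' spike-and-slab mixture (switched-off models contribute a point mass at
#' zero). The reported 90% credible interval is `mean +/- 1.6449 sd` of
#' the *conditional* average over the models that retain the effect — the
#' error bar of the estimated effect given that it exists, which is what
#' zero-crossing is read against. An effect is significant when its
#' retention probability exceeds 0.90.
#'
#' @param peb A `peb_result`.
#' @param search `"greedy"` or `"exhaustive"`.
#' @param max_models Cap on enumerable models (default 2^16).
#' @param search_cols Covariate columns whose effects enter the search;
#'   default all columns (commonalities included, so a genuinely zero
#'   baseline is pruned like any other null effect).
#' @return Object of class `bma_result` with K x P matrices `effect_mean`,
#'   `effect_sd`, `posterior_prob`, `ci90_low`, `ci90_high`, `significant`.
#' @export
bma_search <- function(peb, search = c("greedy", "exhaustive"),
                       max_models = 2^16, search_cols = NULL) {
  search <- match.arg(search)
  K <- peb$K; P <- peb$P
  if (is.null(search_cols)) search_cols <- seq_len(P)
  cells <- as.vector(outer(seq_len(K), (search_cols - 1L) * K, `+`))
  nc <- length(cells)

  model_evidence <- function(off) reduce_peb(peb, off)$delta_log_evidence

  if (search == "exhaustive") {
    if (2^nc > max_models)
      stop("exhaustive search over ", nc, " effects exceeds max_models")
    states <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), nc)))
  } else {
    # wave pruning: per sweep, evaluate the evidence change of switching
    # off each retained effect singly; switch off every effect whose
    # removal increases evidence (jointly, falling back to the single best
    # removal when the joint step does not help), until no removal helps
    on <- rep(TRUE, nc)
    repeat {
      idx_on <- which(on)
      if (!length(idx_on)) break
      base <- model_evidence(cells[!on])
      dFs <- vapply(idx_on, function(j) {
        trial <- on; trial[j] <- FALSE
        model_evidence(cells[!trial])
      }, numeric(1))
      cand <- idx_on[dFs > base]
      if (!length(cand)) break
      trial <- on; trial[cand] <- FALSE
      if (model_evidence(cells[!trial]) >= base) {
        on <- trial
      } else {
        on[idx_on[which.max(dFs)]] <- FALSE
      }
    }
    # ambiguity of each effect = |evidence change when toggled| from the
    # greedy optimum; enumerate the 8 most ambiguous
    base_F <- model_evidence(cells[!on])
    amb <- vapply(seq_len(nc), function(j) {
      trial <- on; trial[j] <- !trial[j]
      abs(model_evidence(cells[!trial]) - base_F)
    }, numeric(1))
    free <- order(amb)[seq_len(min(8L, nc))]
    states <- matrix(on, nrow = 2^length(free), ncol = nc, byrow = TRUE)
    grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(free))))
    states[, free] <- grid
    states <- unique(states)
  }

  fits <- apply(states, 1L, function(s) reduce_peb(peb, cells[!s]),
                simplify = FALSE)
  logZ <- vapply(fits, `[[`, numeric(1), "delta_log_evidence")
  keep <- is.finite(logZ)
  fits <- fits[keep]; states <- states[keep, , drop = FALSE]
  logZ <- logZ[keep]
  w <- exp(logZ - max(logZ))
  w <- w / sum(w)

  d <- K * P
  mix_m <- numeric(d); mix_m2 <- numeric(d); prob_on <- rep(1, d)
  on_m <- numeric(d); on_m2 <- numeric(d); on_w <- rep(1, d)
  prob_on_cells <- numeric(nc)
  on_w[cells] <- 0
  for (j in seq_along(fits)) {
    mu <- fits[[j]]$mean
    va <- diag(fits[[j]]$cov)
    mu_on <- mu; va_on <- va
    off_idx <- cells[!states[j, ]]
    mu[off_idx] <- 0; va[off_idx] <- 0       # spike component
    mix_m <- mix_m + w[j] * mu
    mix_m2 <- mix_m2 + w[j] * (va + mu^2)
    # retained-model (conditional) moments: basis of the reported CI
    keep_on <- rep(TRUE, d)
    keep_on[off_idx] <- FALSE
    on_m <- on_m + w[j] * mu_on * keep_on
    on_m2 <- on_m2 + w[j] * (va_on + mu_on^2) * keep_on
    on_w[cells] <- on_w[cells] + w[j] * as.numeric(states[j, ])
    prob_on_cells <- prob_on_cells + w[j] * as.numeric(states[j, ])
  }
  prob_on[cells] <- prob_on_cells
  mix_sd <- sqrt(pmax(mix_m2 - mix_m^2, 0))
  ok <- on_w > 1e-12
  cm <- ifelse(ok, on_m / pmax(on_w, 1e-12), 0)
  cs <- sqrt(pmax(ifelse(ok, on_m2 / pmax(on_w, 1e-12), 0) - cm^2, 0))
  shape <- function(v) matrix(v, K, P, dimnames = dimnames(peb$beta_mean))
  zq <- qnorm(0.95)
  em <- shape(mix_m); es <- shape(mix_sd); pp <- shape(prob_on)
  structure(list(effect_mean = em, effect_sd = es, posterior_prob = pp,
                 ci90_low = shape(cm - zq * cs),
                 ci90_high = shape(cm + zq * cs),
                 significant = pp > 0.90,
                 n_models = nrow(states), weights = w,
                 conn_names = peb$conn_names,
                 column_labels = peb$design$column_labels),
            class = "bma_result")
}

#' @export
print.bma_result <- function(x, ...) {
  cat(sprintf("BMA over %d reduced models\n", x$n_models))
  cat("posterior effect means (Hz per unit covariate):\n")
  print(round(x$effect_mean, 3))
  cat("retention probabilities:\n")
  print(round(x$posterior_prob, 2))
  invisible(x)
}

#' The 90% posterior-probability decision rule
#'
#' An effect is `significant` when its posterior probability exceeds 0.90
#' (equivalently its reported 90% credible interval `mean +/- 1.6449 sd`
#' excludes zero), a `trend` when the probability lies in (0.80, 0.90], and
#' `null` otherwise.
#'
#' @param effect_mean,effect_sd,posterior_prob Numeric vectors (recycled).
#' @return Data frame with the inputs, `ci90_low`, `ci90_high` and
#'   `decision` (factor significant/trend/null).
#' @export
decision_rule <- function(effect_mean, effect_sd, posterior_prob) {
  stopifnot(all(effect_sd > 0), all(posterior_prob >= 0 & posterior_prob <= 1))
  zq <- qnorm(0.95)
  decision <- ifelse(posterior_prob > 0.90, "significant",
                     ifelse(posterior_prob > 0.80, "trend", "null"))
  data.frame(effect_mean = effect_mean, effect_sd = effect_sd,
             posterior_prob = posterior_prob,
             ci90_low = effect_mean - zq * effect_sd,
             ci90_high = effect_mean + zq * effect_sd,
             decision = factor(decision,
                               levels = c("significant", "trend", "null")))
}

#' Tidy table of a BMA result
#'
#' @param bma A `bma_result`.
#' @return Data frame with one row per (connection, covariate): effect, sd,
#'   posterior probability, 90% CI, significance flag and decision.
#' @export
bma_table <- function(bma) {
  df <- expand.grid(connection = bma$conn_names,
                    covariate = bma$column_labels,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$effect <- as.vector(bma$effect_mean)
  df$sd <- as.vector(bma$effect_sd)
  df$posterior_prob <- as.vector(bma$posterior_prob)
  df$ci_low <- as.vector(bma$ci90_low)
  df$ci_high <- as.vector(bma$ci90_high)
  df$significant <- as.vector(bma$significant)
  df$decision <- ifelse(df$posterior_prob > 0.90, "significant",
                        ifelse(df$posterior_prob > 0.80, "trend", "null"))
  df
}
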