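# Symptom-association stage: site random-intercept linear mixed models on
# per-subject connection strengths, FDR correction, SRS stratification for
# presentation, and the PEB variant with SRS-by-age.

#' Random-intercept linear mixed model for one connection
#'
#' Fits `y = X beta + b_site + e` with `b_site ~ N(0, sigma_b^2)` and
#' `e ~ N(0, sigma^2)` by restricted maximum likelihood, profiling the
#' variance ratio `phi = sigma_b^2 / sigma^2` in one dimension (the
#' site-block structure gives closed-form determinants and inverses).
#' Fixed effects are tested with Wald t statistics using between-within
#' denominator degrees of freedom: subject-level covariates use
#' `n - n_sites - p + 1`, the intercept uses `n_sites - 1`.
#'
#' @param y Numeric response (one connection's posterior-mean strength per
#'   subject).
#' @param covariates Data frame of fixed-effect covariates (z-scoring is
#'   the caller's choice); an intercept is added automatically.
#' @param site Site labels (>= 2 distinct).
#' @param site_variance `"estimate"` (default) or `"zero"` (degenerate
#'   model, equals ordinary least squares).
#' @return Object of class `lmm_fit`: `coefficients` data frame (term,
#'   estimate, se, t, df, p), `sigma2`, `sigma2_site`, `phi`, `logLik_reml`.
#' @export
fit_lmm_random_intercept <- function(y, covariates, site,
                                     site_variance = c("estimate", "zero")) {
  site_variance <- match.arg(site_variance)
  site <- as.character(site)
  n <- length(y)
  stopifnot(nrow(covariates) == n, length(site) == n)
  if (length(unique(site)) < 2L)
    stop("all subjects share one site; random intercept not identifiable")
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  p <- ncol(X)
  if (qr(X)$rank < p) stop("fixed-effect design is singular")
  groups <- split(seq_len(n), site)
  ns <- lengths(groups)
  n_sites <- length(groups)

  # profiled REML criterion at variance ratio phi
  gls_parts <- function(phi) {
    XtVX <- matrix(0, p, p); XtVy <- numeric(p); yty <- 0; logdetV <- 0
    for (g in groups) {
      m <- length(g)
      Xg <- X[g, , drop = FALSE]; yg <- y[g]
      a <- phi / (1 + m * phi)
      sx <- colSums(Xg); sy <- sum(yg)
      XtVX <- XtVX + crossprod(Xg) - a * tcrossprod(sx)
      XtVy <- XtVy + crossprod(Xg, yg) - a * sx * sy
      yty <- yty + sum(yg^2) - a * sy^2
      logdetV <- logdetV + log(1 + m * phi)
    }
    beta <- solve(XtVX, XtVy)
    rss <- yty - sum(beta * XtVy)
    list(beta = as.numeric(beta), XtVX = XtVX, rss = rss,
         logdetV = logdetV)
  }
  reml_crit <- function(phi) {
    gp <- gls_parts(phi)
    sigma2 <- gp$rss / (n - p)
    -0.5 * ((n - p) * log(sigma2) + gp$logdetV +
            determinant(gp$XtVX, logarithm = TRUE)$modulus + (n - p))
  }
  if (n - p < 2L)
    stop("too few subjects (", n, ") for ", p, " fixed effects")
  if (site_variance == "zero") {
    phi <- 0
  } else {
    opt <- optimise(function(lp) reml_crit(exp(lp)), c(-12, 8),
                    maximum = TRUE, tol = 1e-6)
    phi <- exp(opt$maximum)
    crit0 <- reml_crit(0)
    if (is.finite(crit0) && crit0 >= opt$objective) phi <- 0  # boundary
  }
  gp <- gls_parts(phi)
  sigma2 <- gp$rss / (n - p)
  se <- sqrt(sigma2 * diag(solve(gp$XtVX)))
  est <- gp$beta
  tval <- est / se
  df <- c(n_sites - 1, rep(n - n_sites - p + 1, p - 1))
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = est, se = se,
                              t = tval, df = df, p = pval,
                              row.names = NULL),
    sigma2 = sigma2, sigma2_site = phi * sigma2, phi = phi,
    logLik_reml = reml_crit(phi), n = n, n_sites = n_sites),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM: n = %d, %d sites, sigma2_site = %.4g, sigma2 = %.4g\n",
              x$n, x$n_sites, x$sigma2_site, x$sigma2))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted q-values (order-preserving, capped at 1).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Stratify SRS scores for presentation
#'
#' Labels each subject `low` (total SRS < mean - 1 SD), `high`
#' (> mean + 1 SD) or `mid` (boundaries inclusive to mid), using the
#' moments of the analyzed (SRS-complete) subsample. Used for stratified
#' plotting/reporting, not for inference.
#'
#' @param srs Numeric SRS totals (NAs allowed; they get NA strata).
#' @return Factor with levels low/mid/high.
#' @export
stratify_srs <- function(srs) {
  ok <- !is.na(srs)
  if (sum(ok) < 3L) stop("need at least three subjects with SRS")
  m <- mean(srs[ok]); s <- sd(srs[ok])
  if (s < 1e-12) stop("SRS has zero variance")
  out <- rep(NA_character_, length(srs))
  out[ok] <- ifelse(srs[ok] < m - s, "low",
                    ifelse(srs[ok] > m + s, "high", "mid"))
  factor(out, levels = c("low", "mid", "high"))
}

#' Connection-wise LMM association with SRS
#'
#' For each connection, fits [fit_lmm_random_intercept()] of the subjects'
#' posterior-mean strengths on z-scored SRS, age, their interaction and
#' mean FD, with a site random intercept, over the SRS-complete subsample.
#' P-values of each tested term are FDR-adjusted across connections.
#'
#' @param strengths N x K matrix of posterior-mean connection strengths
#'   (columns named).
#' @param records Participant data frame (rows aligned with `strengths`).
#' @return Data frame: connection, term, estimate, se, df, p, q.
#' @export
srs_lmm_table <- function(strengths, records) {
  ok <- !is.na(records$srs_total)
  if (!any(ok)) stop("no subjects with SRS scores")
  rec <- records[ok, , drop = FALSE]
  Y <- strengths[ok, , drop = FALSE]
  covs <- data.frame(srs = z_scale(rec$srs_total), age = z_scale(rec$age))
  covs$srs_x_age <- covs$srs * covs$age
  covs$fd <- z_scale(rec$mean_fd)
  rows <- lapply(colnames(Y), function(cn) {
    fit <- fit_lmm_random_intercept(Y[, cn], covs, rec$site)
    cbind(connection = cn, fit$coefficients)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  tab$q <- NA_real_
  for (tm in unique(tab$term)) {
    sel <- tab$term == tm
    tab$q[sel] <- bh_fdr(tab$p[sel])
  }
  rownames(tab) <- NULL
  tab
}

#' PEB model with SRS, age and their interaction
#'
#' Delegates to the group PEB machinery over the SRS-complete subsample
#' with design columns [mean, srs, age, srs_x_age, fd, (site dummies...)],
#' continuous columns z-scored. This variant propagates first-level
#' uncertainty, complementing the two-step LMM.
#'
#' @param posteriors List of `dcm_posterior` (aligned with `records` rows).
#' @param records Participant data frame.
#' @param site_mode Site handling, as in [build_design()].
#' @param ... Passed to [bma_search()].
#' @return A `bma_result`.
#' @export
peb_srs_interaction <- function(posteriors, records,
                                site_mode = c("dummies", "none",
                                              "orthogonalized"), ...) {
  site_mode <- match.arg(site_mode)
  ok <- !is.na(records$srs_total)
  if (!any(ok)) stop("no subjects with SRS scores")
  rec <- records[ok, , drop = FALSE]
  srs <- z_scale(rec$srs_total)
  age <- z_scale(rec$age)
  X <- cbind(mean = 1, srs = srs, age = age, srs_x_age = srs * age,
             fd = z_scale(rec$mean_fd))
  age_cols <- c("srs", "age", "srs_x_age")
  if (site_mode != "none") {
    if (length(unique(rec$site)) < 2L)
      stop("site dummies requested but fewer than two sites present")
    D <- make_site_dummies(rec$site)
    X <- cbind(X, D)
    if (site_mode == "orthogonalized")
      X <- orthogonalize_columns(X, colnames(D), age_cols)
  }
  design <- finalize_design(X, colnames(X), site_mode, age_cols)
  peb <- fit_peb(posteriors[ok], design)
  bma_search(peb, ...)
}
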