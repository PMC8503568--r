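# Variational-Laplace inversion of the spectral DCM: Gauss-Newton ascent on
# the free energy with Levenberg-Marquardt damping and per-data-mode
# residual-precision hyperparameters.

#' Inversion settings
#'
#' @param max_iter Maximum outer iterations (default 128).
#' @param tol Free-energy convergence tolerance in nats (default 1e-2);
#'   convergence is declared after `n_converge` consecutive accepted steps
#'   with |dF| below it.
#' @param n_converge Consecutive small steps required (default 3).
#' @param damping Initial Levenberg-Marquardt damping (default 1/32);
#'   doubled on rejection, halved on acceptance.
#' @param fd_step Central finite-difference step for the Jacobian.
#' @param lambda_prior_var Prior variance of each log-precision
#'   hyperparameter (default 1).
#' @param alias_kmax Number of spectral alias images folded into the
#'   predicted spectrum when the data carry a sampling interval (default 2;
#'   0 disables folding). Sampled series observe the continuous spectrum
#'   folded at multiples of the sampling rate; ignoring this biases the
#'   fit near the Nyquist edge.
#' @return List of settings.
#' @export
invert_opts <- function(max_iter = 128L, tol = 1e-2, n_converge = 3L,
                        damping = 1 / 32, fd_step = 1e-4,
                        lambda_prior_var = 1, alias_kmax = 2L) {
  list(max_iter = as.integer(max_iter), tol = tol,
       n_converge = as.integer(n_converge), damping = damping,
       fd_step = fd_step, lambda_prior_var = lambda_prior_var,
       alias_kmax = as.integer(alias_kmax))
}

# free energy of (dtheta, lambda) given residuals e and Jacobian J
vl_free_energy <- function(e, J, lambda, modes, dtheta, prior_prec,
                           lambda_prior_var) {
  pi_d <- exp(lambda)[modes]
  n <- length(e)
  H <- crossprod(J * pi_d, J) + diag(prior_prec, nrow = length(prior_prec))
  cholH <- tryCatch(chol(H), error = function(err) NULL)
  if (is.null(cholH)) return(-Inf)
  logdetC <- -2 * sum(log(diag(cholH)))       # log det of posterior cov
  Ct <- chol2inv(cholH)
  acc <- -0.5 * sum(pi_d * e^2) + 0.5 * sum(log(pi_d)) - 0.5 * n * log(2 * pi)
  kl_t <- 0.5 * (sum(prior_prec * diag(Ct)) + sum(prior_prec * dtheta^2) -
                 length(dtheta) - sum(log(prior_prec)) - logdetC)
  # Gaussian treatment of the log-precisions; posterior curvature below
  S_i <- tapply(e^2 + rowSums((J %*% Ct) * J), modes, sum)
  h_i <- 0.5 * exp(lambda) * as.numeric(S_i) + 1 / lambda_prior_var
  kl_l <- 0.5 * (sum(lambda^2) / lambda_prior_var + sum(1 / (h_i * lambda_prior_var)) -
                 length(lambda) + sum(log(h_i * lambda_prior_var)))
  acc - kl_t - kl_l
}

# Newton updates of the log-precisions at fixed theta
vl_update_lambda <- function(e, J, lambda, modes, prior_prec,
                             lambda_prior_var, n_newton = 8L) {
  N_i <- as.numeric(table(modes))
  for (it in seq_len(n_newton)) {
    pi_d <- exp(lambda)[modes]
    H <- crossprod(J * pi_d, J) + diag(prior_prec, nrow = length(prior_prec))
    Ct <- tryCatch(chol2inv(chol(H)), error = function(err) NULL)
    if (is.null(Ct)) break
    q <- e^2 + rowSums((J %*% Ct) * J)
    S_i <- as.numeric(tapply(q, modes, sum))
    g <- 0.5 * (N_i - exp(lambda) * S_i) - lambda / lambda_prior_var
    h <- -0.5 * exp(lambda) * S_i - 1 / lambda_prior_var
    step <- -g / h
    step <- pmin(pmax(step, -2), 2)
    lambda <- pmin(pmax(lambda + step, -8), 12)
    if (max(abs(step)) < 1e-4) break
  }
  lambda
}

#' Invert a subject's spectral DCM
#'
#' Fits the generative model of [predict_csd()] to observed cross spectra by
#' variational Laplace: Gauss-Newton updates of the posterior mean under the
#' Gaussian prior, joint estimation of one residual log-precision per
#' region-pair data mode, and Levenberg-Marquardt damping so that accepted
#' steps do not decrease the free energy (accuracy minus KL complexity).
#' Candidate steps whose coupling matrix is unstable are rejected and the
#' damping increased. Non-convergence within the iteration budget yields a
#' warning and the best-so-far posterior flagged `converged = FALSE`;
#' subjects are never excluded for poor fit.
#'
#' @param data A `cross_spectra` object (the subject's spectral features).
#' @param mask A `conn_mask` matching the data's regions.
#' @param priors Priors from [dcm_priors()].
#' @param opts Settings from [invert_opts()].
#' @param scale_data Rescale the data spectra so their mean diagonal power
#'   matches the prior-mean model's (default TRUE). The tight log-amplitude
#'   priors assume this common scale; coupling parameters (Hz) are
#'   unaffected. The factor is returned as `data_scale`.
#' @return Object of class `dcm_posterior`: `mean` (named), `cov`,
#'   `free_energy`, `explained_variance`, `converged`, `lambda`,
#'   `f_trajectory`, plus the `mask`, `freqs`, `priors` used.
#' @export
invert_subject <- function(data, mask, priors = dcm_priors(mask),
                           opts = invert_opts(), scale_data = TRUE) {
  stopifnot(inherits(data, "cross_spectra"), inherits(mask, "conn_mask"))
  if (!identical(data$region_labels, mask$region_labels))
    stop("data regions do not match mask regions")
  freqs <- data$freqs
  R <- length(mask$region_labels)
  y <- csd_to_features(data)
  # alias-aware feature map when the data are spectra of a sampled series
  tr_fold <- if (!is.null(data$tr) && opts$alias_kmax > 0L) data$tr else 0
  predfun <- function(th, mi)
    cpp_predict_features_folded(th, mi, freqs, tr_fold, opts$alias_kmax)
  jacfun <- function(th, mi)
    cpp_jacobian_features_folded(th, mi, freqs, opts$fd_step, tr_fold,
                                 opts$alias_kmax)
  # bring the data onto the amplitude scale the (tight) log-amplitude
  # priors assume: match mean diagonal power of the prior-mean model
  data_scale <- 1
  if (scale_data) {
    diag_ix <- which(feature_is_diag(R, length(freqs)))
    mp <- predfun(as.numeric(priors$mean), mask_int(mask))
    data_scale <- mean(mp[diag_ix]) / mean(y[diag_ix])
    if (!is.finite(data_scale) || data_scale <= 0)
      stop("cannot scale data: non-positive mean diagonal power")
    y <- y * data_scale
  }
  modes <- feature_modes(R, length(freqs))
  mi <- mask_int(mask)
  lay <- priors$layout
  m0 <- as.numeric(priors$mean)
  prior_prec <- 1 / as.numeric(priors$var)
  theta <- m0
  lambda <- rep(0, max(modes))

  f0 <- predfun(theta, mi)
  J <- jacfun(theta, mi)
  e <- y - f0
  lambda <- vl_update_lambda(e, J, lambda, modes, prior_prec,
                             opts$lambda_prior_var)
  F_cur <- vl_free_energy(e, J, lambda, modes, theta - m0, prior_prec,
                          opts$lambda_prior_var)
  v <- opts$damping
  f_traj <- F_cur
  n_small <- 0L
  converged <- FALSE

  for (iter in seq_len(opts$max_iter)) {
    pi_d <- exp(lambda)[modes]
    H <- crossprod(J * pi_d, J) + diag(prior_prec, nrow = length(prior_prec))
    g <- crossprod(J, pi_d * e) - prior_prec * (theta - m0)
    accepted <- FALSE
    for (try in seq_len(10L)) {
      Hd <- H + diag(v * pmax(diag(H), 1e-8), nrow = nrow(H))
      step <- tryCatch(solve(Hd, g), error = function(err) NULL)
      if (is.null(step)) { v <- v * 4; next }
      th_new <- theta + as.numeric(step)
      if (!is_stable_A(assemble_A(th_new, mask))) { v <- v * 2; next }
      f_new <- predfun(th_new, mi)
      e_new <- y - f_new
      F_new <- vl_free_energy(e_new, J, lambda, modes, th_new - m0,
                              prior_prec, opts$lambda_prior_var)
      if (is.finite(F_new) && F_new >= F_cur - 1e-9) {
        theta <- th_new; e <- e_new
        v <- max(v / 2, 1e-7)
        dF <- F_new - F_cur
        F_cur <- F_new
        accepted <- TRUE
        break
      }
      v <- v * 2
    }
    if (!accepted) { converged <- TRUE; break }  # damping exhausted: optimum
    # refresh curvature and precisions at the accepted point
    J <- jacfun(theta, mi)
    lambda_new <- vl_update_lambda(e, J, lambda, modes, prior_prec,
                                   opts$lambda_prior_var)
    F_lam <- vl_free_energy(e, J, lambda_new, modes, theta - m0, prior_prec,
                            opts$lambda_prior_var)
    if (is.finite(F_lam) && F_lam >= F_cur - 1e-9) {
      lambda <- lambda_new
      F_cur <- F_lam
    }
    f_traj <- c(f_traj, F_cur)
    n_small <- if (abs(dF) < opts$tol) n_small + 1L else 0L
    if (n_small >= opts$n_converge) { converged <- TRUE; break }
  }
  if (!converged)
    warning("inversion did not converge within ", opts$max_iter,
            " iterations; returning best-so-far posterior")

  pi_d <- exp(lambda)[modes]
  H <- crossprod(J * pi_d, J) + diag(prior_prec, nrow = length(prior_prec))
  cov <- chol2inv(chol(H))
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(lay$names, lay$names)
  ev <- 1 - sum(e^2) / sum(y^2)
  structure(list(mean = setNames(theta, lay$names), cov = cov,
                 free_energy = F_cur, explained_variance = ev,
                 converged = converged, lambda = lambda,
                 f_trajectory = f_traj, data_scale = data_scale,
                 mask = mask, freqs = freqs, priors = priors),
            class = "dcm_posterior")
}

#' @export
print.dcm_posterior <- function(x, ...) {
  cat(sprintf("Spectral-DCM posterior: %d parameters, F = %.2f, expl. var = %.3f%s\n",
              length(x$mean), x$free_energy, x$explained_variance,
              if (x$converged) "" else " (non-converged)"))
  lay <- x$priors$layout
  cpl <- x$mean[lay$ix_coupling]
  cat("  coupling (Hz):\n")
  print(round(assemble_A(cpl, x$mask), 3))
  invisible(x)
}

#' Save / load a subject posterior
#'
#' Single-file JSON archive of a `dcm_posterior` (layout, moments, free
#' energy, diagnostics).
#'
#' @param post A `dcm_posterior`.
#' @param path File path (`.json`).
#' @return `write_posterior` returns the path; `read_posterior` the object.
#' @export
write_posterior <- function(post, path) {
  obj <- list(mean = as.numeric(post$mean), names = names(post$mean),
              cov = as.numeric(post$cov), dim = ncol(post$cov),
              free_energy = post$free_energy,
              explained_variance = post$explained_variance,
              converged = post$converged, lambda = post$lambda,
              freqs = post$freqs,
              region_labels = post$mask$region_labels,
              hub_index = post$mask$hub_index)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mask <- build_connectivity_mask(obj$region_labels, obj$hub_index)
  priors <- dcm_priors(mask)
  cov <- matrix(obj$cov, obj$dim, obj$dim,
                dimnames = list(obj$names, obj$names))
  structure(list(mean = setNames(obj$mean, obj$names), cov = cov,
                 free_energy = obj$free_energy,
                 explained_variance = obj$explained_variance,
                 converged = obj$converged, lambda = obj$lambda,
                 freqs = obj$freqs, mask = mask, priors = priors),
            class = "dcm_posterior")
}
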