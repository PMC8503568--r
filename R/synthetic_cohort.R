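# Synthetic multi-site two-group cohorts with known ground-truth coupling,
# the sampling counterpart of the generative model: every pipeline stage can
# be validated against a recoverable truth.

#' Default ground-truth effect table
#'
#' Qualitative shape of the study conditions, as generator defaults (not
#' estimates): with age (per SD) self-inhibition rises in every region and
#' bottom-up coupling falls, and both age effects are attenuated to 25% in
#' the ASD group (encoded through the age and age-by-group coefficients
#' under the +/-0.5 group coding: `beta_age` is the mid-group slope and
#' `beta_int = slope_ASD - slope_TD`).
#'
#' @param mask A `conn_mask`.
#' @param td_self_slope TD age slope on self-connections, per SD of age
#'   (default +0.10).
#' @param td_bu_slope TD age slope on bottom-up couplings, Hz per SD
#'   (default -0.08).
#' @param asd_attenuation Fraction of the TD slope retained in ASD
#'   (default 0.25).
#' @return Data frame with columns `param`, `covariate`, `value`.
#' @export
default_effect_table <- function(mask, td_self_slope = 0.10,
                                 td_bu_slope = -0.08,
                                 asd_attenuation = 0.25) {
  lay <- param_layout(mask)
  nm <- lay$names
  hub <- mask$region_labels[mask$hub_index]
  bu <- nm[lay$ix_a][startsWith(nm[lay$ix_a], paste0(hub, "->"))]
  selfs <- nm[lay$ix_self]
  mid <- (1 + asd_attenuation) / 2
  int <- asd_attenuation - 1
  rbind(
    data.frame(param = selfs, covariate = "age",
               value = mid * td_self_slope),
    data.frame(param = selfs, covariate = "age_x_group",
               value = int * td_self_slope),
    data.frame(param = bu, covariate = "age", value = mid * td_bu_slope),
    data.frame(param = bu, covariate = "age_x_group",
               value = int * td_bu_slope)
  )
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the study shape: 166 ASD + 193 TD male participants over
#' 8 acquisition sites, group age moments of 17.6 (7.6) years in [7, 50]
#' (ASD) and 16.9 (6.6) in [6.5, 39.4] (TD), site-dependent mean age
#' (evenly spaced offsets of -4..+4 years, which makes a one-way age-site
#' ANOVA strongly significant at this N), lognormal mean framewise
#' displacement that multiplies observation noise, and group-separated SRS
#' scores (ASD 89.4 (32.4), TD 22.2 (18.1)) observed for about 67% / 56% of
#' ASD / TD subjects.
#'
#' @param n_per_group Named counts, `c(ASD = ..., TD = ...)`.
#' @param region_labels Regions of the simulated network.
#' @param n_sites Number of sites.
#' @param tr Repetition time (s).
#' @param n_volumes Volumes per subject.
#' @param effect_table Ground-truth effect coefficients (Hz per SD / per
#'   group unit); default [default_effect_table()].
#' @param baseline Named baseline coupling values; defaults: bottom-up
#'   +0.20 Hz, top-down +0.10 Hz, self log-scales 0.
#' @param subject_sd Between-subject SD of each coupling parameter (Hz),
#'   default 0.05.
#' @param site_age_shift Per-site mean-age offsets in years.
#' @param age_mean,age_sd,age_range Per-group age moments.
#' @param fd_meanlog,fd_sdlog Lognormal FD parameters (mm).
#' @param fd_noise_coupling Observation-noise multiplier slope `c` in
#'   `(1 + c FD)`, default 0.5.
#' @param obs_noise_frac Observation-noise SD as a fraction of signal SD,
#'   default 0.25.
#' @param neural_exponent Power-law exponent of neuronal fluctuations,
#'   default 1.
#' @param srs_mean,srs_sd,srs_obs_rate Group-conditional SRS moments and
#'   observation rates.
#' @param seed Integer seed; same seed reproduces the cohort bit-identically.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(ASD = 166, TD = 193),
                        region_labels = canonical_regions(),
                        n_sites = 8L, tr = 2, n_volumes = 200L,
                        effect_table = NULL, baseline = NULL,
                        subject_sd = 0.05,
                        site_age_shift = NULL,
                        age_mean = c(ASD = 17.6, TD = 16.9),
                        age_sd = c(ASD = 7.6, TD = 6.6),
                        age_range = list(ASD = c(7, 50), TD = c(6.5, 39.4)),
                        fd_meanlog = log(0.12), fd_sdlog = 0.4,
                        fd_noise_coupling = 0.5,
                        obs_noise_frac = 0.25,
                        neural_exponent = 1,
                        srs_mean = c(ASD = 89.4, TD = 22.2),
                        srs_sd = c(ASD = 32.4, TD = 18.1),
                        srs_obs_rate = c(ASD = 0.67, TD = 0.56),
                        seed = 1L) {
  stopifnot(all(n_per_group > 0), n_sites >= 1L, tr > 0, n_volumes >= 64L)
  mask <- build_connectivity_mask(region_labels)
  if (is.null(effect_table)) effect_table <- default_effect_table(mask)
  lay <- param_layout(mask)
  cpl_names <- lay$names[lay$ix_coupling]
  bad <- !effect_table$param %in% cpl_names
  if (any(bad))
    stop("effect_table names unknown parameters: ",
         paste(unique(effect_table$param[bad]), collapse = ", "))
  ok_cov <- c("mean", "age", "group", "age_x_group", "srs", "srs_x_age")
  if (!all(effect_table$covariate %in% ok_cov))
    stop("effect_table covariates must be in: ", paste(ok_cov, collapse = ", "))
  if (is.null(baseline)) {
    baseline <- setNames(numeric(length(cpl_names)), cpl_names)
    hub <- region_labels[mask$hub_index]
    a_names <- lay$names[lay$ix_a]
    baseline[a_names[startsWith(a_names, paste0(hub, "->"))]] <- 0.20
    baseline[a_names[!startsWith(a_names, paste0(hub, "->"))]] <- 0.10
  }
  if (is.null(site_age_shift))
    site_age_shift <- if (n_sites > 1)
      seq(-4, 4, length.out = n_sites) else 0
  structure(list(
    n_per_group = n_per_group, region_labels = region_labels,
    mask = mask, n_sites = as.integer(n_sites), tr = tr,
    n_volumes = as.integer(n_volumes), effect_table = effect_table,
    baseline = baseline, subject_sd = subject_sd,
    site_age_shift = site_age_shift, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
    fd_noise_coupling = fd_noise_coupling,
    obs_noise_frac = obs_noise_frac, neural_exponent = neural_exponent,
    srs_mean = srs_mean, srs_sd = srs_sd, srs_obs_rate = srs_obs_rate,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Scale the age-site confound of a cohort spec
#'
#' Returns a spec whose per-site mean-age offsets are the canonical evenly
#' spaced unit offsets scaled by `severity`; severity 0 makes sites
#' exchangeable in age, severity 1 reproduces the default confounding (a
#' one-way age-on-site ANOVA is significant at the study's sample size).
#' Between-site age variance is monotone non-decreasing in `severity`.
#'
#' @param spec A `cohort_spec`.
#' @param severity Non-negative scale factor.
#' @return The modified `cohort_spec`.
#' @export
make_confounded_sites <- function(spec, severity) {
  stopifnot(inherits(spec, "cohort_spec"), severity >= 0,
            spec$n_sites >= 2L)
  spec$site_age_shift <- severity * seq(-4, 4, length.out = spec$n_sites)
  spec
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  for (k in seq_len(100)) {
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  pmin(pmax(out, lo), hi)
}

#' Sample a synthetic cohort
#'
#' Draws per-subject site, age (group moments plus the site's mean-age
#' offset), FD and SRS; builds each subject's true coupling vector as
#' baseline + sum(effect x coded covariate) + N(0, subject_sd^2) with the
#' same covariate coding the analysis design uses (z-scored age, group
#' +/-0.5, products for interactions); and enforces stability of the
#' assembled A matrix (resampling the subject noise up to 100 times).
#'
#' @param spec A `cohort_spec`.
#' @return List with `records` (participant data frame), `truth` (list:
#'   `theta` N x K matrix of true coupling parameters, `effect_table`,
#'   `design_covariates`, `spec`).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  N <- length(groups)
  site <- sample(rep_len(seq_len(spec$n_sites), N))
  age <- numeric(N)
  shift <- spec$site_age_shift[site]
  for (g in unique(groups)) {
    i <- groups == g
    within_sd <- sqrt(max(spec$age_sd[[g]]^2 - var(spec$site_age_shift) *
                            (spec$n_sites > 1), 1))
    age[i] <- rtrunc_norm(sum(i), spec$age_mean[[g]] + shift[i], within_sd,
                          spec$age_range[[g]][1], spec$age_range[[g]][2])
  }
  fd <- stats::rlnorm(N, spec$fd_meanlog, spec$fd_sdlog)
  srs <- numeric(N)
  for (g in unique(groups)) {
    i <- groups == g
    srs[i] <- pmax(rnorm(sum(i), spec$srs_mean[[g]], spec$srs_sd[[g]]), 0)
  }
  srs[runif(N) > spec$srs_obs_rate[groups]] <- NA

  records <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(N)),
    group = factor(groups, levels = c("ASD", "TD")),
    age = age, mean_fd = fd,
    site = sprintf("site%02d", site),
    srs_total = srs,
    excluded_motion = fd > 0.34,
    stringsAsFactors = FALSE)

  # coded covariates, identical to the analysis-side design conventions
  zage <- z_scale(age)
  gcode <- ifelse(groups == "ASD", 0.5, -0.5)
  zsrs <- rep(0, N)
  if (any(!is.na(srs))) zsrs[!is.na(srs)] <- z_scale(srs[!is.na(srs)])
  covs <- cbind(mean = 1, age = zage, group = gcode,
                age_x_group = zage * gcode, srs = zsrs,
                srs_x_age = zsrs * zage)

  lay <- param_layout(spec$mask)
  cpl_names <- lay$names[lay$ix_coupling]
  K <- length(cpl_names)
  fixed <- matrix(rep(spec$baseline[cpl_names], each = N), N, K,
                  dimnames = list(records$subject_id, cpl_names))
  for (r in seq_len(nrow(spec$effect_table))) {
    et <- spec$effect_table[r, ]
    fixed[, et$param] <- fixed[, et$param] + et$value * covs[, et$covariate]
  }
  theta <- fixed
  for (i in seq_len(N)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      cand <- fixed[i, ] + rnorm(K, 0, spec$subject_sd)
      if (is_stable_A(assemble_A(cand, spec$mask))) { ok <- TRUE; break }
    }
    if (!ok)
      stop("could not draw a stable coupling matrix for subject ", i,
           "; reduce effect sizes or subject noise")
    theta[i, ] <- cand
  }
  list(records = records,
       truth = list(theta = theta, effect_table = spec$effect_table,
                    design_covariates = covs, spec = spec))
}

#' Simulate one subject's BOLD time series
#'
#' Samples the generative model: neuronal fluctuations with power-law
#' spectrum `w^-beta` drive the linear dynamics `dx/dt = A x + v`
#' (Euler integration at `dt = tr/16`), each region's activity is convolved
#' with the two-pole hemodynamic kernel (`kappa = 0.64`, `gamma = 0.32` at
#' the prior mean), downsampled to the TR, and white observation noise is
#' added at `obs_noise_frac x (1 + c FD)` of the signal SD. The first 60 s
#' are discarded as burn-in.
#'
#' @param A Stable coupling matrix (Hz).
#' @param tr Repetition time (s).
#' @param n_volumes Number of output volumes.
#' @param seed Integer seed.
#' @param neural_exponent Spectral exponent beta of the neuronal input.
#' @param obs_noise_frac Observation-noise SD as a fraction of signal SD
#'   (0 disables it).
#' @param fd Subject mean FD (mm), multiplies observation noise via
#'   `1 + fd_noise_coupling * fd`.
#' @param fd_noise_coupling Slope of the FD-noise multiplier.
#' @param neural_sd Input amplitude scale (default 1; the analysis
#'   standardizes amplitudes away).
#' @param dt_factor Integration steps per TR (default 16).
#' @param burn_in Discarded initial span in seconds (default 60).
#' @param region_labels Labels for the output series.
#' @return An `roi_ts`.
#' @export
simulate_subject_bold <- function(A, tr, n_volumes, seed,
                                  neural_exponent = 1,
                                  obs_noise_frac = 0.25, fd = 0,
                                  fd_noise_coupling = 0.5,
                                  neural_sd = 1, dt_factor = 16L,
                                  burn_in = 60,
                                  region_labels = colnames(A)) {
  if (!is_stable_A(A)) stop("coupling matrix must be stable")
  if (is.null(region_labels))
    region_labels <- canonical_regions(nrow(A))
  set.seed(seed)
  R <- nrow(A)
  dt <- tr / dt_factor
  n_burn <- ceiling(burn_in / dt)
  n_steps <- n_burn + n_volumes * dt_factor
  if (neural_sd > 0) {
    v <- sapply(seq_len(R), function(r)
      powerlaw_noise(n_steps, dt, neural_exponent) * neural_sd)
  } else {
    v <- matrix(0, n_steps, R)
  }
  X <- cpp_simulate_lds(A, v, dt)
  # hemodynamic convolution with the prior-mean two-pole kernel
  kern_t <- seq(0, 32, by = dt)
  kap <- 0.64; gam <- 0.32
  h <- kap * (exp(-gam * kern_t) - exp(-kap * kern_t)) / (kap - gam)
  Y <- apply(X, 2, function(x) fft_convolve(x, h * dt))
  keep <- n_burn + seq_len(n_volumes) * dt_factor
  Y <- Y[keep, , drop = FALSE]
  if (obs_noise_frac > 0) {
    s <- apply(Y, 2, sd)
    s[s < 1e-12] <- 0
    noise_sd <- obs_noise_frac * (1 + fd_noise_coupling * fd) * s
    Y <- Y + sapply(seq_len(R), function(r) rnorm(n_volumes, 0, noise_sd[r]))
  }
  colnames(Y) <- region_labels
  roi_ts(Y, tr = tr, region_labels = region_labels,
         min_volumes = n_volumes)
}

# Gaussian noise with two-sided spectral density proportional to w^-beta,
# generated by FFT filtering of white noise; unit variance of the white
# seed per 1/dt bandwidth
powerlaw_noise <- function(n, dt, beta) {
  m <- stats::nextn(n, c(2, 3, 5))        # fast FFT length
  w <- rnorm(m, 0, 1 / sqrt(dt))
  if (beta == 0) return(w[seq_len(n)])
  W <- fft(w)
  f <- c(0, seq_len(m - 1)) / (m * dt)
  f <- pmin(f, 1 / dt - f)               # alias to [-Nyquist, Nyquist]
  g <- numeric(m)
  g[1] <- 0                               # drop DC
  g[-1] <- (2 * pi * f[-1])^(-beta / 2)
  ref <- (2 * pi * 0.03)^(-beta / 2)      # unit gain near 0.03 Hz
  (Re(fft(W * g / ref, inverse = TRUE)) / m)[seq_len(n)]
}

fft_convolve <- function(x, h) {
  n <- stats::nextn(length(x) + length(h) - 1L, c(2, 3, 5))
  X <- fft(c(x, rep(0, n - length(x))))
  H <- fft(c(h, rep(0, n - length(h))))
  Re(fft(X * H, inverse = TRUE) / n)[seq_along(x)]
}

#' Write a cohort to disk
#'
#' Emits the exact on-disk layout the reading stage consumes: a participant
#' CSV, one TSV per subject under `series/`, a JSON manifest, and the
#' ground truth as `truth.json`.
#'
#' @param cohort Result of [sample_cohort()].
#' @param dir Output directory (created).
#' @param simulate_bold If TRUE (default) per-subject BOLD series are
#'   simulated and written.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, simulate_bold = TRUE) {
  dir.create(file.path(dir, "series"), recursive = TRUE, showWarnings = FALSE)
  rec <- cohort$records
  write.csv(rec[, c("subject_id", "group", "age", "mean_fd", "site",
                    "srs_total")],
            file.path(dir, "participants.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  spec <- cohort$truth$spec
  if (simulate_bold) {
    for (i in seq_len(nrow(rec))) {
      A <- assemble_A(cohort$truth$theta[i, ], spec$mask)
      ts <- simulate_subject_bold(
        A, spec$tr, spec$n_volumes, seed = (spec$seed %% 1000000L) * 1000L + i,
        neural_exponent = spec$neural_exponent,
        obs_noise_frac = spec$obs_noise_frac, fd = rec$mean_fd[i],
        fd_noise_coupling = spec$fd_noise_coupling,
        region_labels = spec$region_labels)
      write_timeseries(ts, file.path(dir, "series",
                                     paste0(rec$subject_id[i], ".tsv")))
    }
  }
  jsonlite::write_json(list(participants = "participants.csv",
                            series_dir = "series", tr = spec$tr,
                            seed = spec$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(theta = as.data.frame(cohort$truth$theta),
                            effect_table = cohort$truth$effect_table),
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Draw synthetic first-level posteriors around the truth
#'
#' Fast path for validating the group stage in isolation: instead of
#' simulating and inverting BOLD data, each subject's first-level posterior
#' is drawn directly as N(theta_true + estimation noise, post_sd^2 I) over
#' the coupling block (nuisance parameters sit at their prior). Useful for
#' calibration studies of the design/BMA machinery where the first level's
#' behaviour is not under test.
#'
#' @param truth `truth` element of [sample_cohort()].
#' @param est_sd SD of the first-level estimation error (Hz), default 0.05.
#' @param post_sd Reported first-level posterior SD (Hz), default 0.05.
#' @return List of `dcm_posterior` objects.
#' @export
simulate_first_level_posteriors <- function(truth, est_sd = 0.05,
                                            post_sd = 0.05) {
  spec <- truth$spec
  mask <- spec$mask
  priors <- dcm_priors(mask)
  lay <- priors$layout
  N <- nrow(truth$theta)
  lapply(seq_len(N), function(i) {
    mean_full <- setNames(as.numeric(priors$mean), lay$names)
    mean_full[lay$ix_coupling] <- truth$theta[i, ] +
      rnorm(length(lay$ix_coupling), 0, est_sd)
    v <- as.numeric(priors$var)
    v[lay$ix_coupling] <- post_sd^2
    cov <- diag(v)
    dimnames(cov) <- list(lay$names, lay$names)
    structure(list(mean = mean_full, cov = cov, free_energy = NA_real_,
                   explained_variance = NA_real_, converged = TRUE,
                   lambda = NULL, mask = mask, freqs = NULL,
                   priors = priors),
              class = "dcm_posterior")
  })
}
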