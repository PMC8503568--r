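# Cross-spectral density features: MAR parameterization of each subject's
# spectrum plus a Welch estimator used as an independent oracle.

#' Build a frequency grid
#'
#' Linearly spaced analysis frequencies in Hz. The default band
#' (1/128 to 0.25 Hz, 32 points) covers resting-state BOLD fluctuations
#' while staying away from 0 Hz so that power-law spectral forms stay
#' finite. The grid is truncated to what a series of `n_volumes` at the
#' given TR can resolve: lowest frequency >= 1/(T*TR), highest <= Nyquist.
#'
#' @param tr Repetition time, seconds.
#' @param n_freq Number of grid points (default 32).
#' @param fmin,fmax Requested band edges in Hz.
#' @param n_volumes Optional series length used to enforce resolvability.
#' @return Numeric vector of strictly increasing frequencies (class
#'   `freq_grid`).
#' @export
frequency_grid <- function(tr, n_freq = 32L, fmin = 1 / 128, fmax = 0.25,
                           n_volumes = NULL) {
  stopifnot(tr > 0, n_freq >= 2L, fmin > 0, fmax > fmin)
  nyq <- 0.5 / tr
  hi <- min(fmax, nyq)
  lo <- fmin
  if (!is.null(n_volumes)) lo <- max(lo, 1 / (n_volumes * tr))
  if (lo >= hi) stop("no resolvable band: [", lo, ", ", hi, "] Hz")
  structure(seq(lo, hi, length.out = n_freq), class = "freq_grid", tr = tr)
}

#' Construct a cross-spectra object
#'
#' @param csd Complex array R x R x nf; each slice must be Hermitian with a
#'   real non-negative diagonal.
#' @param freqs Frequency grid (Hz), one per slice.
#' @param region_labels Region labels.
#' @param tr Sampling interval of the underlying series in seconds, or NULL
#'   for continuous-model spectra; lets consumers account for alias folding.
#' @return Object of class `cross_spectra`.
#' @export
cross_spectra <- function(csd, freqs, region_labels, tr = NULL) {
  stopifnot(length(dim(csd)) == 3L, dim(csd)[1] == dim(csd)[2],
            dim(csd)[3] == length(freqs),
            dim(csd)[1] == length(region_labels))
  for (f in seq_along(freqs)) {
    s <- csd[, , f]
    if (max(Mod(s - Conj(t(s)))) > 1e-8)
      stop("CSD not Hermitian at frequency ", freqs[f], " Hz")
    d <- diag(as.matrix(s))
    if (any(Re(d) < -1e-10))
      stop("negative spectral density on diagonal at ", freqs[f], " Hz")
  }
  structure(list(csd = csd, freqs = as.numeric(freqs),
                 region_labels = region_labels, tr = tr),
            class = "cross_spectra")
}

#' @export
print.cross_spectra <- function(x, ...) {
  cat(sprintf("Cross spectra: %d regions, %d frequencies [%.4g, %.4g] Hz\n",
              length(x$region_labels), length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Fit a multivariate autoregressive model
#'
#' Ridge-regularized least-squares MAR fit used to parameterize each
#' subject's cross spectrum. The innovation covariance is estimated from the
#' residuals; stability (companion-matrix spectral radius < 1) is enforced.
#'
#' @param ts A standardized `roi_ts`.
#' @param order MAR order p >= 1 (default 8).
#' @param ridge Ridge penalty on the stacked coefficients (default 1e-3).
#' @return Object of class `mar_model`: `order`, `coeff` (list of p R x R
#'   matrices, lag k maps x_{t-k} to x_t), `noise_cov`, `tr`,
#'   `region_labels`.
#' @export
fit_mar <- function(ts, order = 8L, ridge = 1e-3) {
  stopifnot(inherits(ts, "roi_ts"))
  if (order < 1L) stop("MAR order must be a positive integer")
  x <- ts$data
  R <- ncol(x)
  T_ <- nrow(x)
  if (T_ <= R * order + 10L)
    stop("series too short (T = ", T_, ") for MAR order ", order)
  y <- x[(order + 1):T_, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(k)
    x[(order + 1 - k):(T_ - k), , drop = FALSE]))
  XtX <- crossprod(X) + diag(ridge, ncol(X))
  B <- solve(XtX, crossprod(X, y))          # (R*p) x R
  resid <- y - X %*% B
  sigma <- crossprod(resid) / (nrow(y) - ncol(X))
  sigma <- (sigma + t(sigma)) / 2
  coeff <- lapply(seq_len(order), function(k)
    t(B[((k - 1) * R + 1):(k * R), , drop = FALSE]))
  m <- structure(list(order = order, coeff = coeff, noise_cov = sigma,
                      tr = ts$tr, region_labels = ts$region_labels),
                 class = "mar_model")
  rho <- mar_spectral_radius(m)
  if (rho >= 1)
    stop(sprintf("fitted MAR unstable (spectral radius %.3f); try a lower order",
                 rho))
  m
}

mar_spectral_radius <- function(mar) {
  R <- nrow(mar$noise_cov)
  p <- mar$order
  comp <- matrix(0, R * p, R * p)
  comp[seq_len(R), ] <- do.call(cbind, mar$coeff)
  if (p > 1)
    comp[(R + 1):(R * p), seq_len(R * (p - 1))] <- diag(R * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Cross-spectral density of a MAR model
#'
#' Evaluates `S(f) = TR * A(f)^{-1} Sigma A(f)^{-*}` with
#' `A(f) = I - sum_k C_k exp(-i 2 pi f k TR)`. The TR factor converts the
#' per-sample spectrum to density per Hz.
#'
#' @param mar A `mar_model`.
#' @param freqs Frequency grid in Hz (e.g. from [frequency_grid()]).
#' @return A `cross_spectra` object.
#' @export
mar_to_csd <- function(mar, freqs) {
  stopifnot(inherits(mar, "mar_model"))
  R <- nrow(mar$noise_cov)
  out <- array(complex(real = 0), dim = c(R, R, length(freqs)))
  I <- diag(R)
  for (f in seq_along(freqs)) {
    A <- I + 0i
    for (k in seq_len(mar$order))
      A <- A - mar$coeff[[k]] * exp(-1i * 2 * pi * freqs[f] * k * mar$tr)
    Ainv <- tryCatch(solve(A), error = function(e)
      stop("transfer matrix singular at ", freqs[f], " Hz"))
    S <- mar$tr * Ainv %*% mar$noise_cov %*% Conj(t(Ainv))
    out[, , f] <- (S + Conj(t(S))) / 2
  }
  cross_spectra(out, freqs, mar$region_labels, tr = mar$tr)
}

#' Subject cross-spectral features
#'
#' Convenience wrapper: standardize, fit the MAR model, evaluate its CSD on
#' the grid.
#'
#' @param ts An `roi_ts`.
#' @param freqs Frequency grid; default built from the series.
#' @param order,ridge Passed to [fit_mar()].
#' @param detrend_order Passed to [standardize_series()].
#' @return A `cross_spectra` object.
#' @export
csd_features <- function(ts, freqs = NULL, order = 8L, ridge = 1e-3,
                         detrend_order = 1L) {
  ts <- standardize_series(ts, detrend_order, scale = "global")
  if (is.null(freqs))
    freqs <- frequency_grid(ts$tr, n_volumes = nrow(ts$data))
  mar_to_csd(fit_mar(ts, order = order, ridge = ridge), freqs)
}

#' Welch cross-spectral estimate
#'
#' Segment-averaged Hann-tapered cross-periodogram, linearly interpolated
#' onto the requested grid. Used as an independent nonparametric check of
#' the MAR route (and of model-predicted spectra in simulations); not part
#' of the fitting path.
#'
#' @param ts An `roi_ts` (standardization is the caller's business).
#' @param freqs Target frequency grid in Hz.
#' @param seg_len Segment length in samples (default `min(256, T/4)`),
#'   50% overlap.
#' @return A `cross_spectra` object.
#' @export
csd_welch <- function(ts, freqs, seg_len = NULL) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- ts$data
  T_ <- nrow(x)
  R <- ncol(x)
  if (is.null(seg_len)) seg_len <- min(256L, floor(T_ / 4))
  if (seg_len < 8L || T_ < 2L * seg_len)
    stop("series too short for Welch segmentation")
  step <- max(1L, floor(seg_len / 2))
  starts <- seq(1L, T_ - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  U <- sum(w^2)
  fs <- 1 / ts$tr
  fgrid <- (seq_len(seg_len) - 1) * fs / seg_len
  keep <- fgrid > 0 & fgrid <= fs / 2
  if (min(freqs) < min(fgrid[keep]) - 1e-12 || max(freqs) > max(fgrid[keep]) + 1e-12)
    stop("requested grid outside the resolvable band [",
         signif(min(fgrid[keep]), 3), ", ", signif(max(fgrid[keep]), 3), "] Hz")
  acc <- array(0i, dim = c(R, R, sum(keep)))
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    Fm <- mvfft(seg * w)[keep, , drop = FALSE]
    for (i in seq_len(R)) for (j in seq_len(R))
      acc[i, j, ] <- acc[i, j, ] + Fm[, i] * Conj(Fm[, j])
  }
  # two-sided density per Hz (matches the MAR and model conventions)
  acc <- acc / (length(starts) * U * fs)
  out <- array(0i, dim = c(R, R, length(freqs)))
  fk <- fgrid[keep]
  for (i in seq_len(R)) for (j in seq_len(R)) {
    re <- stats::approx(fk, Re(acc[i, j, ]), xout = freqs, rule = 2)$y
    im <- stats::approx(fk, Im(acc[i, j, ]), xout = freqs, rule = 2)$y
    out[i, j, ] <- complex(real = re, imaginary = im)
  }
  for (f in seq_along(freqs)) {
    S <- out[, , f]
    out[, , f] <- (S + Conj(t(S))) / 2
  }
  cross_spectra(out, freqs, ts$region_labels, tr = ts$tr)
}
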