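# Generative spectral-DCM model: hub-and-spoke connectivity mask, parameter
# packing, priors, and the predicted cross-spectral density.

#' Build the hub-and-spoke connectivity mask
#'
#' Directed coupling is allowed only between the subcortical hub and each
#' cortical region (bottom-up: hub to cortex; top-down: cortex to hub) plus
#' the inhibitory self-connection of every region. Direct cortico-cortical
#' connections are anatomically implausible between primary sensory areas
#' and are not modelled, which also reduces the number of estimated
#' parameters: a network of R regions has 2(R-1) off-diagonal couplings and
#' R self-connections (13 free coupling parameters for the canonical 5-node
#' network).
#'
#' @param region_labels Character vector of region labels (R >= 2).
#' @param hub_index Index of the subcortical hub (default 1).
#' @return Object of class `conn_mask`: `offdiag` (R x R logical, entry
#'   (i, j) = influence of region j on region i allowed), `self` (length-R
#'   logical, all TRUE), `region_labels`, `hub_index`.
#' @export
build_connectivity_mask <- function(region_labels = canonical_regions(),
                                    hub_index = 1L) {
  R <- length(region_labels)
  if (R < 2L) stop("need at least two regions")
  if (hub_index < 1L || hub_index > R) stop("hub_index out of range")
  m <- matrix(FALSE, R, R, dimnames = list(region_labels, region_labels))
  m[, hub_index] <- TRUE   # bottom-up: hub drives every cortical region
  m[hub_index, ] <- TRUE   # top-down: every cortical region drives the hub
  diag(m) <- FALSE
  structure(list(offdiag = m, self = rep(TRUE, R),
                 region_labels = region_labels, hub_index = hub_index),
            class = "conn_mask")
}

#' @export
print.conn_mask <- function(x, ...) {
  cat(sprintf("Connectivity mask: %d regions, hub = %s; %d couplings + %d self = %d free parameters\n",
              length(x$region_labels), x$region_labels[x$hub_index],
              sum(x$offdiag), length(x$self), sum(x$offdiag) + length(x$self)))
  invisible(x)
}

# ---- parameter layout -------------------------------------------------
# theta = [a_offdiag (col-major over mask), self_log (R),
#          log_alpha_v, b_v, log_alpha_e, b_e,
#          decay_log (R), transit_log (R)]

#' Parameter layout for a connectivity mask
#'
#' Describes the packed parameter vector used by the model: off-diagonal
#' couplings in Hz, log-scaled self-connections, log-amplitude and
#' (logistic-mapped) exponent of the neuronal and observation power-law
#' spectra, and two hemodynamic log-scales per region.
#'
#' @param mask A `conn_mask`.
#' @return List with `n` (total length), `names`, index vectors `ix_a`,
#'   `ix_self`, `ix_neural`, `ix_obs`, `ix_hemo`, and `ix_coupling`
#'   (couplings + self, the parameters taken to the second level).
#' @export
param_layout <- function(mask) {
  R <- length(mask$region_labels)
  idx <- which(mask$offdiag)
  na <- length(idx)
  rc <- arrayInd(idx, dim(mask$offdiag))
  a_names <- sprintf("%s->%s", mask$region_labels[rc[, 2]],
                     mask$region_labels[rc[, 1]])
  nm <- c(a_names,
          sprintf("self_%s", mask$region_labels),
          "neural_logamp", "neural_exponent",
          "obs_logamp", "obs_exponent",
          sprintf("decay_%s", mask$region_labels),
          sprintf("transit_%s", mask$region_labels))
  list(n = na + R + 4L + 2L * R, names = nm,
       ix_a = seq_len(na),
       ix_self = na + seq_len(R),
       ix_neural = na + R + 1:2,
       ix_obs = na + R + 3:4,
       ix_hemo = na + R + 4L + seq_len(2L * R),
       ix_coupling = seq_len(na + R))
}

#' Default weakly informative priors
#'
#' Diagonal Gaussian priors centred at zero: couplings N(0, 1/16) Hz^2,
#' self-connection log-scales N(0, 1/64), hemodynamic log-scales
#' N(0, 1/256), noise parameters N(0, 1/64). Zero means keep the network
#' near its leak-dominated default A = -0.5 I a priori.
#'
#' @param mask A `conn_mask`.
#' @return List with `mean`, `var` (diagonal), and the `layout`.
#' @export
dcm_priors <- function(mask) {
  lay <- param_layout(mask)
  v <- numeric(lay$n)
  v[lay$ix_a] <- 1 / 16
  v[lay$ix_self] <- 1 / 64
  v[c(lay$ix_neural, lay$ix_obs)] <- 1 / 64
  v[lay$ix_hemo] <- 1 / 256
  list(mean = setNames(numeric(lay$n), lay$names),
       var = setNames(v, lay$names), layout = lay)
}

mask_int <- function(mask) {
  m <- mask$offdiag
  storage.mode(m) <- "integer"
  m
}

#' Assemble the coupling matrix A
#'
#' Off-diagonal entries are the packed coupling values (Hz) where the mask
#' allows them, zero elsewhere; diagonal entries are `-0.5 * exp(self_log)`
#' so that a positive self parameter means stronger self-inhibition (more
#' functional segregation of that region).
#'
#' @param theta Packed parameter vector (full layout, or just the
#'   couplings + self block).
#' @param mask A `conn_mask`.
#' @return R x R real matrix in Hz.
#' @export
assemble_A <- function(theta, mask) {
  R <- length(mask$region_labels)
  na <- sum(mask$offdiag)
  A <- matrix(0, R, R, dimnames = dimnames(mask$offdiag))
  A[which(mask$offdiag)] <- theta[seq_len(na)]
  diag(A) <- -0.5 * exp(theta[na + seq_len(R)])
  A
}

#' Is the coupling matrix stable?
#'
#' @param A Square real matrix.
#' @return TRUE when all eigenvalue real parts are negative.
#' @export
is_stable_A <- function(A) {
  all(Re(eigen(A, only.values = TRUE)$values) < 0)
}

#' Predicted cross-spectral density
#'
#' Evaluates the generative model: with `T(w) = (iwI - A)^{-1}` the neuronal
#' transfer function, `H(w)` the diagonal matrix of two-pole hemodynamic
#' kernels `h_r(w) = kappa_r / ((iw + kappa_r)(iw + gamma_r))`
#' (`kappa_r = 0.64 exp(decay_log_r)`, `gamma_r = 0.32 exp(transit_log_r)`),
#' and power-law neuronal fluctuations `G_v(w) = alpha_v w^{-beta_v}` shared
#' across regions, the predicted spectrum is
#' `S(f) = H T G_v T* H* + alpha_e w^{-beta_e} I`.
#' Exponents are constrained to (0, 2) by a logistic map of the free
#' parameter.
#'
#' @param theta Packed parameter vector.
#' @param mask A `conn_mask`.
#' @param freqs Frequency grid in Hz (all > 0).
#' @return A `cross_spectra` object.
#' @export
predict_csd <- function(theta, mask, freqs) {
  stopifnot(all(freqs > 0))
  A <- assemble_A(theta, mask)
  if (!is_stable_A(A)) stop("assembled coupling matrix is unstable")
  S <- cpp_predict_csd(theta, mask_int(mask), as.numeric(freqs))
  cross_spectra(S, freqs, mask$region_labels)
}

# feature stacking used by the inversion: per frequency, the real upper
# triangle (incl. diagonal) then the strictly-upper imaginary parts
csd_to_features <- function(cs) {
  as.numeric(cpp_csd_to_features(cs$csd))
}

# data-mode (region-pair) index for every feature element; real and
# imaginary parts of a pair share one residual-precision component
feature_modes <- function(R, nf) {
  pid <- matrix(0L, R, R)
  k <- 0L
  for (j in seq_len(R)) for (i in seq_len(j)) { k <- k + 1L; pid[i, j] <- k }
  re_ids <- integer(0)
  im_ids <- integer(0)
  for (j in seq_len(R)) for (i in seq_len(j)) re_ids <- c(re_ids, pid[i, j])
  for (j in seq_len(R)) for (i in seq_len(R)) if (i < j) im_ids <- c(im_ids, pid[i, j])
  rep(c(re_ids, im_ids), times = nf)
}

#' Predicted spectrum of the sampled process
#'
#' Like [predict_csd()], but folds spectral alias images at multiples of
#' the sampling rate: a series sampled at interval `tr` observes
#' `S_obs(f) = sum_k S(f + k/tr)` (with `S(-f) = conj(S(f))`). This is the
#' correct model-side counterpart when comparing against spectra estimated
#' from sampled data (Welch or MAR).
#'
#' @inheritParams predict_csd
#' @param tr Sampling interval (s).
#' @param kmax Number of alias images on each side (default 2).
#' @return A `cross_spectra` object (with `tr` recorded).
#' @export
predict_csd_sampled <- function(theta, mask, freqs, tr, kmax = 2L) {
  stopifnot(all(freqs > 0), tr > 0)
  A <- assemble_A(theta, mask)
  if (!is_stable_A(A)) stop("assembled coupling matrix is unstable")
  S <- cpp_predict_csd_folded(theta, mask_int(mask), as.numeric(freqs),
                              tr, as.integer(kmax))
  cross_spectra(S, freqs, mask$region_labels, tr = tr)
}

# TRUE for feature elements that are diagonal (auto-spectral) real parts
feature_is_diag <- function(R, nf) {
  re_diag <- logical(0)
  for (j in seq_len(R)) for (i in seq_len(j)) re_diag <- c(re_diag, i == j)
  rep(c(re_diag, rep(FALSE, R * (R - 1) / 2)), times = nf)
}

#' Explained variance of a spectral fit
#'
#' `1 - SS(residual) / SS(data)` over the stacked real and imaginary parts
#' of all upper-triangular entries (including the diagonal) across
#' frequencies.
#'
#' @param data,fitted `cross_spectra` objects on the same grid.
#' @return Fraction in (-Inf, 1].
#' @export
explained_variance <- function(data, fitted) {
  stopifnot(inherits(data, "cross_spectra"), inherits(fitted, "cross_spectra"),
            length(data$freqs) == length(fitted$freqs),
            max(abs(data$freqs - fitted$freqs)) < 1e-9)
  y <- csd_to_features(data)
  yh <- csd_to_features(fitted)
  ss <- sum(y^2)
  if (ss <= 0) stop("data sum of squares is zero")
  1 - sum((y - yh)^2) / ss
}
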