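# Orchestration: configuration plus the simulate / fit / group / srs
# stages operating on an on-disk cohort directory. A thin command-line
# wrapper around these functions ships in inst/cli/.

#' Pipeline run configuration
#'
#' Validated bag of settings shared by the pipeline stages. Unknown keys
#' are rejected. Every stage writes the configuration it ran with into its
#' output directory, making runs reproducible from the manifest alone.
#'
#' @param dir Cohort/output directory.
#' @param seed Root seed for all randomness.
#' @param region_labels Network regions.
#' @param n_per_group,n_sites,tr,n_volumes Cohort shape (see
#'   [cohort_spec()]).
#' @param n_freq Frequency-grid size.
#' @param mar_order MAR order for spectral features.
#' @param site_mode Site handling for the group stage.
#' @param fd_threshold Motion-exclusion threshold (mm).
#' @param invert Inversion settings from [invert_opts()].
#' @param ... Additional overrides passed to [cohort_spec()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(dir, seed = 1L,
                       region_labels = canonical_regions(),
                       n_per_group = c(ASD = 166, TD = 193),
                       n_sites = 8L, tr = 2, n_volumes = 200L,
                       n_freq = 32L, mar_order = 8L,
                       site_mode = c("none", "dummies", "orthogonalized"),
                       fd_threshold = 0.34,
                       invert = invert_opts(), ...) {
  site_mode <- match.arg(site_mode)
  extra <- list(...)
  allowed <- setdiff(names(formals(cohort_spec)),
                     c("n_per_group", "region_labels", "n_sites", "tr",
                       "n_volumes", "seed"))
  bad <- setdiff(names(extra), allowed)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  structure(list(dir = dir, seed = as.integer(seed),
                 region_labels = region_labels,
                 n_per_group = n_per_group, n_sites = as.integer(n_sites),
                 tr = tr, n_volumes = as.integer(n_volumes),
                 n_freq = as.integer(n_freq),
                 mar_order = as.integer(mar_order),
                 site_mode = site_mode, fd_threshold = fd_threshold,
                 invert = invert, extra = extra),
            class = "run_config")
}

config_json <- function(config) {
  obj <- unclass(config)
  obj$package_version <- as.character(utils::packageVersion("spdcmr"))
  obj
}

#' Simulate a cohort to disk
#'
#' Builds the [cohort_spec()] implied by the configuration, samples the
#' cohort and writes the participant table, per-subject BOLD series,
#' ground truth and manifest under `config$dir`.
#'
#' @param config A `run_config`.
#' @return The cohort directory, invisibly.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- do.call(cohort_spec, c(list(
    n_per_group = config$n_per_group,
    region_labels = config$region_labels, n_sites = config$n_sites,
    tr = config$tr, n_volumes = config$n_volumes, seed = config$seed),
    config$extra))
  cohort <- sample_cohort(spec)
  write_cohort(cohort, config$dir)
  jsonlite::write_json(config_json(config),
                       file.path(config$dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  message(sprintf("simulate: wrote %d subjects to %s",
                  nrow(cohort$records), config$dir))
  invisible(config$dir)
}

#' Fit every subject's spectral DCM
#'
#' Reads the cohort manifest, skips subjects flagged excluded-by-motion,
#' extracts cross-spectral features and inverts the model per subject.
#' Posteriors are written to `posteriors/<subject_id>.json` and a summary
#' table (free energy, explained variance, convergence, exclusion) to
#' `fit_summary.csv`.
#'
#' @param config A `run_config`.
#' @return The fit summary data frame, invisibly.
#' @export
cmd_fit <- function(config) {
  stopifnot(inherits(config, "run_config"))
  man <- read_manifest(file.path(config$dir, "manifest.json"))
  rec <- man$records
  rec$excluded_motion <- rec$mean_fd > config$fd_threshold
  mask <- build_connectivity_mask(config$region_labels)
  priors <- dcm_priors(mask)
  grid <- frequency_grid(man$tr, n_freq = config$n_freq,
                         n_volumes = config$n_volumes)
  post_dir <- file.path(config$dir, "posteriors")
  dir.create(post_dir, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(rec))) {
    id <- rec$subject_id[i]
    if (rec$excluded_motion[i]) {
      message(sprintf("fit: %s skipped (mean FD %.3f > %.2f mm)",
                      id, rec$mean_fd[i], config$fd_threshold))
      rows[[i]] <- data.frame(subject_id = id, excluded_motion = TRUE,
                              free_energy = NA, explained_variance = NA,
                              converged = NA)
      next
    }
    ts <- read_timeseries(man$series_paths[[id]], man$tr,
                          config$region_labels)
    cs <- csd_features(ts, freqs = grid, order = config$mar_order)
    post <- invert_subject(cs, mask, priors, config$invert)
    write_posterior(post, file.path(post_dir, paste0(id, ".json")))
    rows[[i]] <- data.frame(subject_id = id, excluded_motion = FALSE,
                            free_energy = post$free_energy,
                            explained_variance = post$explained_variance,
                            converged = post$converged)
  }
  summary <- do.call(rbind, rows)
  write.csv(summary, file.path(config$dir, "fit_summary.csv"),
            row.names = FALSE)
  invisible(summary)
}

#' Simulate and invert a cohort in memory
#'
#' The in-memory counterpart of [cmd_simulate()] + [cmd_fit()]: for every
#' subject of a sampled cohort, simulates the BOLD series from the true
#' coupling matrix, extracts cross-spectral features and inverts the model.
#' Used for validation studies where the on-disk layout is irrelevant.
#'
#' @param cohort Result of [sample_cohort()].
#' @param order MAR order (default 16; long simulated series support a
#'   richer spectral parameterization than the on-disk default).
#' @param n_freq Frequency-grid size.
#' @param opts Inversion settings.
#' @param dt_factor Integration steps per TR for the simulation.
#' @return List of `dcm_posterior`, one per subject (motion exclusion is
#'   ignored here; callers decide).
#' @export
fit_cohort <- function(cohort, order = 16L, n_freq = 32L,
                       opts = invert_opts(), dt_factor = 16L) {
  spec <- cohort$truth$spec
  mask <- spec$mask
  priors <- dcm_priors(mask)
  grid <- frequency_grid(spec$tr, n_freq = n_freq,
                         n_volumes = spec$n_volumes)
  lapply(seq_len(nrow(cohort$records)), function(i) {
    A <- assemble_A(cohort$truth$theta[i, ], mask)
    ts <- simulate_subject_bold(
      A, spec$tr, spec$n_volumes, seed = (spec$seed %% 1000000L) * 1000L + i,
      neural_exponent = spec$neural_exponent,
      obs_noise_frac = spec$obs_noise_frac,
      fd = cohort$records$mean_fd[i],
      fd_noise_coupling = spec$fd_noise_coupling,
      dt_factor = dt_factor, region_labels = spec$region_labels)
    invert_subject(csd_features(ts, freqs = grid, order = order),
                   mask, priors, opts)
  })
}

read_cohort_posteriors <- function(config) {
  man <- read_manifest(file.path(config$dir, "manifest.json"))
  rec <- man$records
  rec$excluded_motion <- rec$mean_fd > config$fd_threshold
  keep <- !rec$excluded_motion
  rec <- rec[keep, , drop = FALSE]
  paths <- file.path(config$dir, "posteriors",
                     paste0(rec$subject_id, ".json"))
  if (!any(file.exists(paths)))
    stop("no posterior files under ", file.path(config$dir, "posteriors"),
         "; run cmd_fit first")
  ok <- file.exists(paths)
  list(records = rec[ok, , drop = FALSE],
       posteriors = lapply(paths[ok], read_posterior))
}

#' Group-level PEB / BMA reports
#'
#' Runs the main between-subject model (mean, age, group, age-by-group,
#' FD, site per `config$site_mode`), the within-group age model, and a
#' site-mode comparison (none vs dummies vs orthogonalized), writing tidy
#' CSV tables to the cohort directory.
#'
#' @param config A `run_config`.
#' @return Named list of the three tables, invisibly.
#' @export
cmd_group <- function(config) {
  cp <- read_cohort_posteriors(config)
  main <- bma_table(bma_search(fit_peb(
    cp$posteriors, build_design(cp$records, config$site_mode))))
  within <- bma_table(bma_search(fit_peb(
    cp$posteriors, build_within_group_age_design(cp$records,
                                                 config$site_mode))))
  modes <- c("none", "dummies", "orthogonalized")
  cmp <- lapply(modes, function(m) {
    tb <- bma_table(bma_search(fit_peb(cp$posteriors,
                                       build_design(cp$records, m))))
    tb <- tb[, c("connection", "covariate", "effect", "posterior_prob",
                 "significant")]
    names(tb)[3:5] <- paste(names(tb)[3:5], m, sep = "_")
    tb
  })
  site_cmp <- Reduce(function(a, b)
    merge(a, b, by = c("connection", "covariate"), sort = FALSE), cmp)
  write.csv(main, file.path(config$dir, "group_main_model.csv"),
            row.names = FALSE)
  write.csv(within, file.path(config$dir, "group_within_group_age.csv"),
            row.names = FALSE)
  write.csv(site_cmp, file.path(config$dir, "group_site_mode_comparison.csv"),
            row.names = FALSE)
  invisible(list(main = main, within_group = within,
                 site_comparison = site_cmp))
}

#' Symptom-association reports
#'
#' On the SRS-complete subsample: the connection-wise site random-intercept
#' LMM table with FDR correction, the PEB variant with SRS, age and their
#' interaction, and the low/mid/high SRS strata used for stratified
#' presentation. CSV outputs land in the cohort directory.
#'
#' @param config A `run_config`.
#' @return Named list with `lmm`, `peb_srs`, `strata`, invisibly.
#' @export
cmd_srs <- function(config) {
  cp <- read_cohort_posteriors(config)
  if (all(is.na(cp$records$srs_total)))
    stop("cohort has no SRS scores; the symptom stage needs srs_total")
  lay <- cp$posteriors[[1]]$priors$layout
  strengths <- t(vapply(cp$posteriors,
                        function(p) as.numeric(p$mean)[lay$ix_coupling],
                        numeric(length(lay$ix_coupling))))
  colnames(strengths) <- names(cp$posteriors[[1]]$mean)[lay$ix_coupling]
  lmm <- srs_lmm_table(strengths, cp$records)
  srs_mode <- if (config$site_mode == "none") "none" else config$site_mode
  peb_srs <- bma_table(peb_srs_interaction(cp$posteriors, cp$records,
                                           srs_mode))
  strata <- stratify_srs(cp$records$srs_total)
  write.csv(lmm, file.path(config$dir, "srs_lmm.csv"), row.names = FALSE)
  write.csv(peb_srs, file.path(config$dir, "srs_peb.csv"),
            row.names = FALSE)
  strata_df <- data.frame(subject_id = cp$records$subject_id,
                          srs_total = cp$records$srs_total,
                          stratum = strata)
  write.csv(strata_df, file.path(config$dir, "srs_strata.csv"),
            row.names = FALSE)
  invisible(list(lmm = lmm, peb_srs = peb_srs, strata = strata))
}
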