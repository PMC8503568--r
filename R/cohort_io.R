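# Reading, validation and conditioning of participant tables and ROI series.

#' Read and validate a participant table
#'
#' Parses a CSV/TSV participant table into a validated data frame of
#' participant records. Required columns (renameable through `schema`):
#' `subject_id`, `group` (ASD/TD), `age` (years), `mean_fd` (mm, mean
#' framewise displacement), `site`; `srs_total` is optional and may be
#' missing per row (such subjects are only excluded from the symptom stage).
#' Subjects whose mean FD exceeds `fd_threshold` are flagged
#' `excluded_motion = TRUE`; the flag is informational — downstream stages
#' decide whether to drop them.
#'
#' @param path Path to a delimited text file (comma- or tab-separated,
#'   sniffed from the header line).
#' @param schema Named character vector mapping canonical names to file
#'   column names, e.g. `c(age = "AGE_AT_SCAN")`. Unmapped canonical names
#'   use their own name.
#' @param fd_threshold Motion-exclusion cutoff in mm (strict `>`), default
#'   0.34.
#' @param age_range Plausible age range in years; ages outside it are a
#'   validation error.
#' @return A `data.frame` with columns `subject_id`, `group` (factor
#'   ASD/TD), `age`, `mean_fd`, `site`, `srs_total` (NA allowed),
#'   `excluded_motion`.
#' @export
read_participants <- function(path, schema = character(),
                              fd_threshold = 0.34,
                              age_range = c(5, 60)) {
  if (!file.exists(path)) stop("participant table not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  canon <- c("subject_id", "group", "age", "mean_fd", "site", "srs_total")
  cols <- setNames(canon, canon)
  cols[names(schema)] <- schema
  required <- canon[canon != "srs_total"]
  missing_cols <- cols[required][!cols[required] %in% names(raw)]
  if (length(missing_cols))
    stop("participant table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  get_col <- function(nm) if (cols[[nm]] %in% names(raw)) raw[[cols[[nm]]]] else NULL

  n <- nrow(raw)
  rec <- data.frame(
    subject_id = as.character(get_col("subject_id")),
    group = as.character(get_col("group")),
    age = suppressWarnings(as.numeric(get_col("age"))),
    mean_fd = suppressWarnings(as.numeric(get_col("mean_fd"))),
    site = as.character(get_col("site")),
    stringsAsFactors = FALSE
  )
  srs <- get_col("srs_total")
  rec$srs_total <- if (is.null(srs)) NA_real_ else suppressWarnings(as.numeric(srs))

  problems <- character()
  bad_rows <- function(flag, what) {
    if (any(flag)) sprintf("row %d: %s", which(flag), what) else character()
  }
  problems <- c(problems,
    bad_rows(!rec$group %in% c("ASD", "TD"),
             "group must be ASD or TD"),
    bad_rows(is.na(rec$age) | rec$age < age_range[1] | rec$age > age_range[2],
             sprintf("age missing/unparseable or outside [%g, %g]",
                     age_range[1], age_range[2])),
    bad_rows(is.na(rec$mean_fd) | rec$mean_fd < 0,
             "mean_fd missing, unparseable or negative"),
    bad_rows(is.na(rec$site) | !nzchar(rec$site), "site label empty"),
    bad_rows(!is.na(rec$srs_total) & rec$srs_total < 0, "srs_total negative"))
  if (length(problems))
    stop("participant validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  if (anyDuplicated(rec$subject_id))
    stop("duplicate subject ids: ",
         paste(unique(rec$subject_id[duplicated(rec$subject_id)]),
               collapse = ", "))
  rec$group <- factor(rec$group, levels = c("ASD", "TD"))
  rec$excluded_motion <- rec$mean_fd > fd_threshold
  rec
}

#' Read an ROI time-series file
#'
#' Reads a tab-separated matrix (header row = region labels, one row per
#' volume) and reorders its columns to the expected canonical order.
#'
#' @param path Path to a TSV file.
#' @param tr Repetition time in seconds.
#' @param expected_labels Region labels defining the canonical column order;
#'   the file must contain exactly this set (any order).
#' @param min_volumes Minimum admissible number of volumes (default 64).
#' @return An object of class `roi_ts`: list with `data` (T x R matrix),
#'   `tr`, `region_labels`.
#' @export
read_timeseries <- function(path, tr, expected_labels = canonical_regions(),
                            min_volumes = 64L) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  raw <- read.csv(path, sep = "\t", check.names = FALSE)
  labels <- names(raw)
  if (!setequal(labels, expected_labels) || length(labels) != length(expected_labels))
    stop("region labels {", paste(labels, collapse = ", "),
         "} do not match expected {", paste(expected_labels, collapse = ", "), "}")
  x <- as.matrix(raw[, expected_labels, drop = FALSE])
  storage.mode(x) <- "double"
  roi_ts(x, tr = tr, region_labels = expected_labels,
         min_volumes = min_volumes)
}

#' Construct an ROI time-series object
#'
#' @param data Numeric T x R matrix of BOLD values.
#' @param tr Repetition time in seconds (> 0).
#' @param region_labels Unique labels, one per column.
#' @param min_volumes Minimum admissible T.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, tr, region_labels = colnames(data),
                   min_volumes = 64L) {
  data <- as.matrix(data)
  if (is.null(region_labels)) stop("region labels required")
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  if (length(region_labels) != ncol(data))
    stop("label count does not match column count")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  if (nrow(data) < min_volumes)
    stop("series too short: ", nrow(data), " volumes (need >= ", min_volumes, ")")
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value at (%d, %s)",
                 bad[1, 1], region_labels[bad[1, 2]]))
  colnames(data) <- region_labels
  structure(list(data = data, tr = tr, region_labels = region_labels),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %d volumes x %d regions (TR = %gs)\n",
              nrow(x$data), ncol(x$data), x$tr))
  cat("  regions:", paste(x$region_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Write an ROI time-series file
#'
#' Inverse of [read_timeseries()]: tab-separated, header = region labels,
#' full double precision.
#'
#' @param ts An `roi_ts` object.
#' @param path Output path.
#' @export
write_timeseries <- function(ts, path) {
  df <- as.data.frame(ts$data)
  names(df) <- ts$region_labels
  write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detrend and standardize an ROI time series
#'
#' Removes a polynomial trend of the given order from each region (order 0 =
#' mean only) and rescales to unit variance: per column (`scale =
#' "column"`, the default) or by one global factor (the geometric mean of
#' the column SDs, `scale = "global"`). Standardization puts subjects on a
#' common amplitude scale so that one set of priors on spectral amplitudes
#' is appropriate across a cohort. The model-fitting path uses the global
#' mode: rescaling region j by its own SD transforms the effective coupling
#' matrix as A -> D A D^-1 and would distort the couplings the spectra
#' reflect, whereas a shared factor leaves them untouched. Idempotent up to
#' numerical tolerance.
#'
#' @param ts An `roi_ts` object.
#' @param detrend_order Polynomial order 0, 1 or 2 (default 1).
#' @param scale `"column"` (unit variance per region) or `"global"` (one
#'   shared factor preserving relative region amplitudes).
#' @return A standardized `roi_ts`.
#' @export
standardize_series <- function(ts, detrend_order = 1L,
                               scale = c("column", "global")) {
  stopifnot(inherits(ts, "roi_ts"))
  scale <- match.arg(scale)
  if (!detrend_order %in% 0:2)
    stop("detrend_order must be 0, 1 or 2")
  x <- ts$data
  tt <- seq_len(nrow(x))
  basis <- outer(tt - mean(tt), 0:detrend_order, `^`)
  resid <- x - basis %*% qr.solve(basis, x)
  s <- apply(resid, 2, sd)
  zero <- s < 1e-12
  if (any(zero))
    stop("zero-variance region(s) after detrending: ",
         paste(ts$region_labels[zero], collapse = ", "))
  if (scale == "global") s <- rep(exp(mean(log(s))), length(s))
  out <- sweep(resid, 2, s, `/`)
  roi_ts(out, tr = ts$tr, region_labels = ts$region_labels,
         min_volumes = nrow(out))
}

#' Read a cohort manifest
#'
#' A manifest is a JSON (or YAML) file with fields `participants` (path to
#' the participant table), `series_dir` (directory of per-subject TSVs named
#' `<subject_id>.tsv`) and `tr` (seconds). Paths are resolved relative to the
#' manifest location.
#'
#' @param path Manifest file path.
#' @return List with `records` (validated participant data frame),
#'   `series_paths` (named character vector), `tr`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML manifests")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("participants", "series_dir", "tr")
  if (!all(need %in% names(m)))
    stop("manifest must declare: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  records <- read_participants(resolve(m$participants))
  paths <- setNames(file.path(resolve(m$series_dir),
                              paste0(records$subject_id, ".tsv")),
                    records$subject_id)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing series file(s) for subject(s): ",
         paste(records$subject_id[missing], collapse = ", "))
  list(records = records, series_paths = paths, tr = as.numeric(m$tr))
}
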