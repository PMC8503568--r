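# Shared fixtures: small participant tables and ROI series built in code.

write_participant_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

demo_participants <- function() {
  data.frame(
    subject_id = c("s1", "s2", "s3"),
    group = c("ASD", "TD", "TD"),
    age = c(12.5, 30, 22),
    mean_fd = c(0.10, 0.50, 0.20),
    site = c("siteA", "siteA", "siteB"),
    srs_total = c(90, NA, 15),
    stringsAsFactors = FALSE
  )
}

write_series_tsv <- function(mat, labels, path = tempfile(fileext = ".tsv")) {
  df <- as.data.frame(mat)
  names(df) <- labels
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

demo_ts <- function(T_ = 200L, R = 5L, seed = 1, tr = 2) {
  set.seed(seed)
  roi_ts(matrix(rnorm(T_ * R), T_, R), tr = tr,
         region_labels = canonical_regions(R))
}

# small 3-node ground-truth system used across DCM tests
demo_theta3 <- function() {
  mask <- build_connectivity_mask(canonical_regions(3))
  lay <- spdcmr:::param_layout(mask)
  theta <- numeric(lay$n)
  theta[lay$ix_a] <- c(0.3, -0.2, 0.15, 0.1)
  theta[lay$ix_self] <- c(0.1, -0.1, 0.05)
  list(mask = mask, lay = lay, theta = theta)
}
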