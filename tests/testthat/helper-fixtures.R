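# Shared fixture builders; all fixtures are generated in code.

# quick interval table on one chromosome
iv <- function(start, end, chrom = "1", patient = NULL) {
  data.frame(chrom = rep_len(chrom, length(start)), start = start,
             end = end,
             patient_id = if (is.null(patient))
               sprintf("P%d", seq_along(start)) else patient,
             stringsAsFactors = FALSE)
}

# quick segment table (already in internal convention)
seg_df <- function(patient, chrom, start, end, n_probes = 50,
                   cn_state = 3) {
  d <- data.frame(patient_id = patient, chrom = as.character(chrom),
                  start = start, end = end, n_probes = n_probes,
                  cn_state = cn_state, stringsAsFactors = FALSE)
  d$alteration_type <- alteration_type(d$cn_state)
  class(d) <- c("cna_segments", "data.frame")
  d
}

# random interval set for property tests
random_intervals <- function(n, max_coord = 100) {
  s <- sample.int(max_coord, n, replace = TRUE) - 1
  len <- sample.int(30, n, replace = TRUE)
  iv(s, s + len)
}

# write a SEG file in the default dialect
write_seg_fixture <- function(rows, path = tempfile(fileext = ".seg")) {
  header <- "ID\tchrom\tloc.start\tloc.end\tnum.mark\tcn.state"
  writeLines(c(header, rows), path)
  path
}

# clinical table file
write_clinical_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# one-row region in the caller's schema
region_row <- function(chrom, inner_start, inner_end, type = "gain",
                       outer_start = inner_start - 1000,
                       outer_end = inner_end + 1000,
                       n_patients = 5L,
                       patients = paste0("P", seq_len(n_patients))) {
  r <- data.frame(chrom = as.character(chrom), alteration_type = type,
                  inner_start = inner_start, inner_end = inner_end,
                  inner_size = inner_end - inner_start,
                  outer_start = outer_start, outer_end = outer_end,
                  outer_size = outer_end - outer_start,
                  n_patients = n_patients,
                  patients = paste(patients, collapse = ";"),
                  stringsAsFactors = FALSE)
  class(r) <- c("recurrent_regions", "data.frame")
  r
}

# small sim_config for fast end-to-end tests
small_sim_config <- function(seed = 42, ...) {
  sim_config(n_young = c(discovery = 40, validation = 40),
             n_old = c(discovery = 80, validation = 80),
             noise_mean = 2, seed = seed, ...)
}

# independent empirical survival oracle: no-censoring product-limit
empirical_survival <- function(times, t) {
  vapply(t, function(x) mean(times > x), 0)
}
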