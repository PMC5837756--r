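#' SEG dialect description
#'
#' Maps the columns of a tab-separated segment file (the SEG-like output of
#' circular binary segmentation) onto the fields this package needs, and
#' records the coordinate and copy-number conventions of the file.
#'
#' @param id,chrom,start,end,n_probes,cn Column names in the file header.
#' @param coords `"half_open"` (0-based half-open, size = end - start; the
#'   convention used internally and by all writers) or `"one_based"`
#'   (1-based inclusive array convention; starts are shifted by -1 on load
#'   and +1 on write).
#' @param cn_coding How the `cn` column encodes copy number:
#'   `"absolute"` (integer copies, 2 = neutral), `"delta"` (offsets from
#'   diploid in {-2,...,2}, 0 = neutral), or `"logratio"` (continuous log2
#'   ratios thresholded at `logratio_cutoff`).
#' @param logratio_cutoff Threshold for `cn_coding = "logratio"`: values
#'   above it are gains (state 3), below its negative losses (state 1).
#' @return A named list of class `seg_dialect`.
#' @export
seg_dialect <- function(id = "ID", chrom = "chrom", start = "loc.start",
                        end = "loc.end", n_probes = "num.mark",
                        cn = "cn.state",
                        coords = c("half_open", "one_based"),
                        cn_coding = c("absolute", "delta", "logratio"),
                        logratio_cutoff = 0.2) {
  out <- list(id = id, chrom = chrom, start = start, end = end,
              n_probes = n_probes, cn = cn,
              coords = match.arg(coords),
              cn_coding = match.arg(cn_coding),
              logratio_cutoff = logratio_cutoff)
  class(out) <- "seg_dialect"
  out
}

#' Alteration type implied by a copy-number state
#'
#' @param cn_state Integer absolute copy number (2 = neutral).
#' @return Character vector in `{"gain", "loss", "neutral"}`.
#' @export
alteration_type <- function(cn_state) {
  ifelse(cn_state > 2, "gain", ifelse(cn_state < 2, "loss", "neutral"))
}

# map a raw cn column to absolute integer states per the dialect
decode_cn <- function(x, dialect) {
  switch(dialect$cn_coding,
    absolute = as.numeric(x),
    delta = 2 + as.numeric(x),
    logratio = {
      v <- as.numeric(x)
      ifelse(v > dialect$logratio_cutoff, 3,
             ifelse(v < -dialect$logratio_cutoff, 1, 2))
    })
}

#' Read per-patient CNA segment calls
#'
#' Reads a tab-separated segment file, normalizes chromosome labels
#' (leading "chr" stripped), converts coordinates to the internal 0-based
#' half-open convention, and derives `alteration_type` from the
#' copy-number state.  Neutral segments are kept (and tagged) so the raw
#' data can be inspected; [filter_segments()] drops them.
#'
#' Segments of one patient on one chromosome are expected to be
#' non-overlapping (CBS output is); violations raise a warning, not an
#' error.
#'
#' @param path Path to the file.
#' @param dialect A [seg_dialect()].
#' @return A `data.frame` of class `cna_segments` with columns
#'   `patient_id`, `chrom`, `start`, `end`, `n_probes`, `cn_state`,
#'   `alteration_type`.
#' @export
read_segments <- function(path, dialect = seg_dialect()) {
  if (!file.exists(path)) stop("segment file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "#",
                           check.names = FALSE)
  needed <- c(id = dialect$id, chrom = dialect$chrom, start = dialect$start,
              end = dialect$end, n_probes = dialect$n_probes, cn = dialect$cn)
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols))
    stop("segment file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n <- nrow(raw)
  if (n == 0) return(empty_segments())
  line_no <- seq_len(n) + 1L  # header is line 1

  num_or_die <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | v != floor(v))
    if (length(bad))
      stop("non-integer ", what, " at line ",
           paste(line_no[bad], collapse = ", "), " of ", path, call. = FALSE)
    v
  }
  start <- num_or_die(dialect$start, "start coordinate")
  end <- num_or_die(dialect$end, "end coordinate")
  n_probes <- num_or_die(dialect$n_probes, "probe count")
  if (dialect$coords == "one_based") start <- start - 1
  bad <- which(end <= start)
  if (length(bad))
    stop("end <= start at line ", paste(line_no[bad], collapse = ", "),
         " of ", path, call. = FALSE)
  if (any(n_probes < 1))
    stop("probe count < 1 at line ",
         paste(line_no[n_probes < 1], collapse = ", "), " of ", path,
         call. = FALSE)

  cn_state <- decode_cn(raw[[dialect$cn]], dialect)
  seg <- data.frame(patient_id = as.character(raw[[dialect$id]]),
                    chrom = normalize_chrom(raw[[dialect$chrom]]),
                    start = start, end = end, n_probes = n_probes,
                    cn_state = cn_state,
                    alteration_type = alteration_type(cn_state),
                    stringsAsFactors = FALSE)
  warn_patient_overlaps(seg, path)
  class(seg) <- c("cna_segments", "data.frame")
  seg
}

empty_segments <- function() {
  seg <- data.frame(patient_id = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    n_probes = numeric(), cn_state = numeric(),
                    alteration_type = character(), stringsAsFactors = FALSE)
  class(seg) <- c("cna_segments", "data.frame")
  seg
}

# warn once if any patient has overlapping segments on one chromosome
warn_patient_overlaps <- function(seg, path) {
  key <- paste(seg$patient_id, seg$chrom, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    s <- seg[key == k, ]
    s <- s[order(s$start), ]
    if (any(s$start[-1] < s$end[-nrow(s)])) {
      warning("overlapping segments for patient ", s$patient_id[1],
              " on chromosome ", s$chrom[1],
              if (!is.null(path)) paste0(" in ", path), call. = FALSE)
      return(invisible(NULL))
    }
  }
  invisible(NULL)
}

#' Write segments in the SEG dialect
#'
#' Inverse of [read_segments()]: converts coordinates back to the dialect's
#' convention and records the convention in a header comment.
#'
#' @inheritParams read_segments
#' @param segments A `cna_segments` data.frame.
#' @export
write_segments <- function(segments, path, dialect = seg_dialect()) {
  out <- data.frame(segments$patient_id, segments$chrom,
                    if (dialect$coords == "one_based") segments$start + 1
                    else segments$start,
                    segments$end, segments$n_probes, segments$cn_state,
                    check.names = FALSE)
  names(out) <- c(dialect$id, dialect$chrom, dialect$start, dialect$end,
                  dialect$n_probes, dialect$cn)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# coords=", dialect$coords,
                    " cn_coding=", dialect$cn_coding), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter segments on probe support and size
#'
#' Retains segments generated by at least `min_probes` probes and spanning
#' at least `min_size` bp; neutral segments (copy number 2) are dropped
#' here since they carry no alteration.
#'
#' @param segments A `cna_segments` data.frame.
#' @param min_probes Minimum probe count (default 10).
#' @param min_size Minimum segment size in bp (default 1000, i.e. 1 kb).
#' @return The retained subset, same class.
#' @export
filter_segments <- function(segments, min_probes = 10, min_size = 1000) {
  stopifnot(min_probes >= 1, min_size >= 0)
  keep <- segments$n_probes >= min_probes &
    (segments$end - segments$start) >= min_size &
    segments$alteration_type != "neutral"
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a clinical table
#'
#' Tab-separated table with columns `patient_id`, `age`, `dss_time`
#' (disease-specific survival in years) and `dss_event` (1 = died of
#' disease, 0 = censored); extra columns are kept as covariates.  Derives
#' `age_group`: young iff `age < young_cutoff`, old otherwise (the
#' boundary age is old).
#'
#' @param path Path to the file.
#' @param young_cutoff Age cutoff in years (default 45).
#' @return A `data.frame` of class `patient_table`.
#' @export
read_clinical <- function(path, young_cutoff = 45) {
  if (!file.exists(path)) stop("clinical file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("patient_id", "age", "dss_time", "dss_event")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols))
    stop("clinical file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$patient_id <- as.character(tab$patient_id)
  if (any(tab$dss_time < 0)) stop("negative dss_time", call. = FALSE)
  if (!all(tab$dss_event %in% c(0, 1)))
    stop("dss_event must be 0 or 1", call. = FALSE)
  tab$age_group <- assign_age_group(tab$age, young_cutoff)
  class(tab) <- c("patient_table", "data.frame")
  tab
}

assign_age_group <- function(age, young_cutoff = 45) {
  ifelse(age < young_cutoff, "young", "old")
}

#' Partition segments by age group and alteration type
#'
#' Splits (already filtered, non-neutral) segments into the four analysis
#' buckets young-gain, young-loss, old-gain, old-loss according to each
#' patient's age group.
#'
#' @param segments Filtered `cna_segments`.
#' @param patients A `patient_table` (or data.frame with `patient_id` and
#'   `age`).
#' @param young_cutoff Age cutoff in years; patients with age strictly
#'   below it are young, at or above it old.
#' @return Named list of four `cna_segments` data.frames:
#'   `young_gain`, `young_loss`, `old_gain`, `old_loss`.
#' @export
partition_cohort <- function(segments, patients, young_cutoff = 45) {
  orphans <- setdiff(segments$patient_id, patients$patient_id)
  if (length(orphans))
    stop("segments reference unknown patient id(s): ",
         paste(sort(unique(orphans)), collapse = ", "), call. = FALSE)
  if (any(segments$alteration_type == "neutral"))
    stop("partition_cohort expects filtered (non-neutral) segments",
         call. = FALSE)
  grp <- assign_age_group(patients$age, young_cutoff)
  seg_grp <- grp[match(segments$patient_id, patients$patient_id)]
  pick <- function(g, t) {
    out <- segments[seg_grp == g & segments$alteration_type == t, ,
                    drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(young_gain = pick("young", "gain"),
       young_loss = pick("young", "loss"),
       old_gain = pick("old", "gain"),
       old_loss = pick("old", "loss"))
}
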