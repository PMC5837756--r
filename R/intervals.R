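#' Genomic intervals
#'
#' All coordinates in this package are 0-based, half-open: an interval
#' covers bases `start, start+1, ..., end-1` and its size is `end - start`.
#' Intervals that merely touch (`a$end == b$start`) do not overlap.
#'
#' @param chrom Character vector of chromosome labels ("1".."22", "X"); a
#'   leading "chr" prefix is stripped.
#' @param start,end Integer-valued base-pair coordinates, `start < end`.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and class
#'   `genomic_interval`.
#' @examples
#' gi <- genomic_interval("1", 222004315, 222004925)
#' region_size(gi)  # 610
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (any(is.na(start)) || any(is.na(end)) ||
      any(start != floor(start)) || any(end != floor(end)))
    stop("interval coordinates must be integers", call. = FALSE)
  if (any(start < 0)) stop("interval start must be non-negative", call. = FALSE)
  bad <- which(start >= end)
  if (length(bad))
    stop("empty or inverted interval (start >= end) at position ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(chrom = as.character(chrom),
                    start = as.numeric(start), end = as.numeric(end),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", "data.frame")
  out
}

#' Size of a genomic interval in base pairs
#'
#' Size follows the half-open convention, `end - start`.
#'
#' @param x A `genomic_interval` (or any data.frame with `start` and `end`
#'   columns).
#' @return Numeric vector of sizes.
#' @export
region_size <- function(x) {
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  x$end - x$start
}

#' Half-open overlap predicate
#'
#' Two intervals overlap iff `s1 < e2 && s2 < e1`.  Vectorized; chromosomes
#' are the caller's responsibility (intervals on different chromosomes never
#' overlap and should not be compared).
#'
#' @param s1,e1,s2,e2 Coordinate vectors.
#' @return Logical vector.
#' @export
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# bp of overlap between [s1,e1) and [s2,e2); 0 when disjoint
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Jaccard index of two half-open intervals on one chromosome
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- overlap_width(s1, e1, s2, e2)
  uni <- (e1 - s1) + (e2 - s2) - inter
  ifelse(uni > 0, inter / uni, 0)
}

normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

# karyotype sort order 1..22, X, Y, then anything else alphabetically
chrom_order <- function(chrom) {
  std <- c(as.character(1:22), "X", "Y")
  idx <- match(chrom, std)
  idx[is.na(idx)] <- length(std) + rank(chrom[is.na(idx)], ties.method = "min")
  idx
}
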