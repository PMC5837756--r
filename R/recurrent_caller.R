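#' Call recurrent CNA regions for one age group and alteration type
#'
#' Runs the maximal-clique sweep per chromosome over (already filtered)
#' segments of a single age group and alteration type, derives each
#' clique's minimal common region (inner) and outer span, and applies the
#' recurrence filters in order: clique size >= `min_clique`, distinct
#' patients >= `min_patients`, MCR size >= `min_mcr_size`.  Patient counts
#' deduplicate multiple segments of one patient inside a clique.
#'
#' @param segments Filtered `cna_segments` of one group and type (mixed
#'   alteration types are split internally and never merged).
#' @param min_clique Minimum clique size (default 2; singleton cliques are
#'   emitted by the sweep and removed here).
#' @param min_patients Minimum number of distinct patients per region
#'   (default 5).
#' @param min_mcr_size Minimum inner (MCR) size in bp (default 1000); the
#'   recurrence size filter applies to the inner region, the one reported.
#' @return A `data.frame` of class `recurrent_regions` with columns
#'   `chrom`, `alteration_type`, `inner_start`, `inner_end`, `inner_size`,
#'   `outer_start`, `outer_end`, `outer_size`, `n_patients`, `patients`
#'   (";"-joined sorted ids), sorted by karyotype order then inner start.
#' @export
call_recurrent_regions <- function(segments, min_clique = 2,
                                   min_patients = 5, min_mcr_size = 1000) {
  rows <- list()
  for (type in intersect(c("gain", "loss"), unique(segments$alteration_type))) {
    seg_t <- segments[segments$alteration_type == type, , drop = FALSE]
    for (chr in unique(seg_t$chrom)) {
      seg_c <- seg_t[seg_t$chrom == chr, , drop = FALSE]
      cliques <- sweep_maximal_cliques(seg_c)
      for (cl in cliques) {
        if (length(cl) < min_clique) next
        pats <- sort(unique(seg_c$patient_id[cl]))
        if (length(pats) < min_patients) next
        inner <- clique_mcr(seg_c, cl)
        if (region_size(inner) < min_mcr_size) next
        outer <- clique_outer(seg_c, cl)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chr, alteration_type = type,
          inner_start = inner$start, inner_end = inner$end,
          inner_size = region_size(inner),
          outer_start = outer$start, outer_end = outer$end,
          outer_size = region_size(outer),
          n_patients = length(pats),
          patients = paste(pats, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_regions()
  out <- out[order(chrom_order(out$chrom), out$inner_start, out$inner_end), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("recurrent_regions", "data.frame")
  out
}

empty_regions <- function() {
  data.frame(chrom = character(), alteration_type = character(),
             inner_start = numeric(), inner_end = numeric(),
             inner_size = numeric(), outer_start = numeric(),
             outer_end = numeric(), outer_size = numeric(),
             n_patients = integer(), patients = character(),
             stringsAsFactors = FALSE)
}

# TRUE for each target row whose inner MCR overlaps any other-collection
# inner MCR of the same type, under the given policy
inner_overlaps_any <- function(target, other,
                               policy = c("any_overlap", "reciprocal50")) {
  policy <- match.arg(policy)
  vapply(seq_len(nrow(target)), function(i) {
    cand <- other[other$chrom == target$chrom[i] &
                    other$alteration_type == target$alteration_type[i], ,
                  drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    w <- overlap_width(target$inner_start[i], target$inner_end[i],
                       cand$inner_start, cand$inner_end)
    if (policy == "any_overlap") return(any(w > 0))
    any(w >= 0.5 * target$inner_size[i] & w >= 0.5 * cand$inner_size)
  }, NA)
}

#' Age-group-specific recurrent regions
#'
#' Keeps the target-group regions whose inner MCR does not overlap the
#' inner MCR of any same-type region found in the other age group — the
#' strictest reading of "uniquely found" in one group.  A reciprocal-50%
#' policy (exclude only if the overlap covers half of both MCRs) is
#' available as a looser alternative.
#'
#' @param target_regions,other_regions `recurrent_regions` from the same
#'   cohort (e.g. young and old discovery regions).
#' @param policy `"any_overlap"` (default) or `"reciprocal50"`.
#' @return The retained subset of `target_regions`.
#' @export
group_specific_regions <- function(target_regions, other_regions,
                                   policy = c("any_overlap", "reciprocal50")) {
  policy <- match.arg(policy)
  if (!nrow(target_regions)) return(target_regions)
  keep <- !inner_overlaps_any(target_regions, other_regions, policy)
  out <- target_regions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match discovery regions against a validation cohort
#'
#' A discovery region is validated iff its inner MCR overlaps the inner
#' MCR of at least one same-type validation region.  The validated record
#' keeps the discovery coordinates; `size1` is the discovery patient count
#' and `size2` the patient count of the best-overlapping validation
#' partner (ties broken by larger overlap, then leftmost start).
#'
#' @param discovery_regions,validation_regions Group-specific
#'   `recurrent_regions` from the two cohorts.
#' @return Validated subset of `discovery_regions` with added `size1`,
#'   `size2` and `validation_patients` columns.
#' @export
match_discovery_validation <- function(discovery_regions,
                                       validation_regions) {
  disc <- discovery_regions
  if (!nrow(disc)) {
    disc$size1 <- integer(0); disc$size2 <- integer(0)
    disc$validation_patients <- character(0)
    return(disc)
  }
  size2 <- integer(nrow(disc))
  vpat <- character(nrow(disc))
  matched <- logical(nrow(disc))
  for (i in seq_len(nrow(disc))) {
    cand <- validation_regions[
      validation_regions$chrom == disc$chrom[i] &
        validation_regions$alteration_type == disc$alteration_type[i], ,
      drop = FALSE]
    if (!nrow(cand)) next
    w <- overlap_width(disc$inner_start[i], disc$inner_end[i],
                       cand$inner_start, cand$inner_end)
    if (all(w <= 0)) next
    best <- order(-w, cand$inner_start)[1]
    matched[i] <- TRUE
    size2[i] <- cand$n_patients[best]
    vpat[i] <- cand$patients[best]
  }
  out <- disc[matched, , drop = FALSE]
  out$size1 <- out$n_patients
  out$size2 <- size2[matched]
  out$validation_patients <- vpat[matched]
  rownames(out) <- NULL
  out
}

#' Write a region table
#'
#' Tab-separated table with the reporting schema
#' `Chr, InnerStart, InnerEnd, InnerSize, OuterStart, OuterEnd, OuterSize,
#' GeneSymbols, Size1, Size2`.  Coordinates are written in the internal
#' 0-based half-open convention (sizes are `End - Start`), noted in a
#' header comment.  Unannotated regions get empty gene symbols; unmatched
#' regions get `Size2 = NA`.
#'
#' @param regions A `recurrent_regions` data.frame, optionally annotated
#'   (`gene_symbols`) and matched (`size1`, `size2`).
#' @param path Output path.
#' @export
write_region_table <- function(regions, path) {
  out <- data.frame(
    Chr = regions$chrom,
    InnerStart = regions$inner_start, InnerEnd = regions$inner_end,
    InnerSize = regions$inner_size,
    OuterStart = regions$outer_start, OuterEnd = regions$outer_end,
    OuterSize = regions$outer_size,
    GeneSymbols = if ("gene_symbols" %in% names(regions))
      regions$gene_symbols else rep("", nrow(regions)),
    Size1 = if ("size1" %in% names(regions)) regions$size1
      else regions$n_patients,
    Size2 = if ("size2" %in% names(regions)) regions$size2
      else rep(NA, nrow(regions)),
    AlterationType = regions$alteration_type,
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coords=half_open (0-based; Size = End - Start)", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a region table written by [write_region_table()]
#'
#' @param path Path to the table.
#' @return A `recurrent_regions` data.frame.
#' @export
read_region_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  out <- data.frame(chrom = normalize_chrom(tab$Chr),
                    alteration_type = if ("AlterationType" %in% names(tab))
                      tab$AlterationType else NA_character_,
                    inner_start = tab$InnerStart, inner_end = tab$InnerEnd,
                    inner_size = tab$InnerSize,
                    outer_start = tab$OuterStart, outer_end = tab$OuterEnd,
                    outer_size = tab$OuterSize,
                    n_patients = tab$Size1, patients = NA_character_,
                    stringsAsFactors = FALSE)
  if ("GeneSymbols" %in% names(tab)) out$gene_symbols <- tab$GeneSymbols
  out$size1 <- tab$Size1
  out$size2 <- tab$Size2
  class(out) <- c("recurrent_regions", "data.frame")
  out
}

#' Export inner MCRs as BED
#'
#' BED is natively 0-based half-open, matching the internal convention.
#' The name field is `type:gene_symbols` (or `type:.` when unannotated).
#'
#' @inheritParams write_region_table
#' @export
regions_to_bed <- function(regions, path) {
  name <- paste0(regions$alteration_type, ":",
                 if ("gene_symbols" %in% names(regions))
                   ifelse(regions$gene_symbols == "", ".",
                          gsub("; ", ",", regions$gene_symbols))
                 else ".")
  bed <- data.frame(regions$chrom, format(regions$inner_start,
                                          scientific = FALSE, trim = TRUE),
                    format(regions$inner_end, scientific = FALSE,
                           trim = TRUE),
                    name, stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
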