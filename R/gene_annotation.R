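#' Load gene models from BED or GTF
#'
#' Parsed with `rtracklayer::import()` and normalized to the internal
#' 0-based half-open convention (BED already is; GTF is 1-based inclusive
#' and converted on load).  GTF `gene` features define spans and `exon`
#' features are aggregated under their gene; BED has no exon structure.
#' A gene is flagged protein-coding when a `gene_biotype`/`gene_type`
#' attribute says `protein_coding`, and by default otherwise (CNA gene
#' lists are typically coding genes).  Duplicate symbols on one chromosome
#' keep the widest span with a warning.
#'
#' @param path Path to a `.bed`, `.gtf` or `.gff` file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @return A `data.frame` of class `gene_models` with columns `symbol`,
#'   `chrom`, `start`, `end`, `strand`, `is_protein_coding` and a
#'   list-column `exons` (each element a data.frame of `start`, `end`, or
#'   NULL when the source has no exon features).
#' @export
load_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff", "gff2", "gff3")) "gtf" else "bed"
  }
  if (!file.exists(path)) stop("gene model file not found: ", path,
                               call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path, format = format),
                 error = function(e)
                   stop("failed to parse ", path, ": ", conditionMessage(e),
                        call. = FALSE))
  if (format == "bed") {
    models <- data.frame(
      symbol = as.character(gr$name),
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
      start = GenomicRanges::start(gr) - 1,  # back to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      is_protein_coding = TRUE,
      stringsAsFactors = FALSE)
    models$exons <- rep(list(NULL), nrow(models))
  } else {
    md <- as.data.frame(S4Vectors::mcols(gr))
    sym <- if ("gene_name" %in% names(md)) as.character(md$gene_name)
      else as.character(md$gene_id)
    feature <- as.character(md$type)
    chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(gr)))
    start0 <- GenomicRanges::start(gr) - 1
    end0 <- GenomicRanges::end(gr)
    strand <- as.character(GenomicRanges::strand(gr))
    biotype <- if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype)
      else if ("gene_type" %in% names(md)) as.character(md$gene_type)
      else rep(NA_character_, length(gr))
    is_gene <- feature == "gene"
    if (!any(is_gene))
      stop("GTF ", path, " contains no 'gene' features", call. = FALSE)
    models <- data.frame(symbol = sym[is_gene], chrom = chrom[is_gene],
                         start = start0[is_gene], end = end0[is_gene],
                         strand = strand[is_gene],
                         is_protein_coding =
                           is.na(biotype[is_gene]) |
                           biotype[is_gene] == "protein_coding",
                         stringsAsFactors = FALSE)
    is_exon <- feature == "exon"
    models$exons <- lapply(models$symbol, function(s) {
      sel <- is_exon & sym == s
      if (!any(sel)) return(NULL)
      ex <- data.frame(start = start0[sel], end = end0[sel])
      ex[order(ex$start), , drop = FALSE]
    })
  }
  # duplicate symbol on one chromosome: keep widest span
  key <- paste(models$symbol, models$chrom, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate gene symbol(s) on one chromosome in ", path,
            "; keeping widest span", call. = FALSE)
    width <- models$end - models$start
    keep <- unlist(lapply(split(seq_len(nrow(models)), key),
                          function(ix) ix[which.max(width[ix])]))
    models <- models[sort(keep), , drop = FALSE]
  }
  for (i in seq_len(nrow(models))) {
    ex <- models$exons[[i]]
    if (!is.null(ex) &&
        (any(ex$start < models$start[i]) || any(ex$end > models$end[i])))
      stop("exons outside gene span for ", models$symbol[i], call. = FALSE)
  }
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models
}

#' Annotate recurrent regions with overlapping genes
#'
#' Assigns to each region every gene whose span overlaps the region's
#' inner MCR (the region shared by all carriers; assignment against the
#' outer span is available as an option).  Classifies each region as
#' `"coding"` when it overlaps at least one protein-coding gene —
#' exon-level overlap when the model carries exons, span overlap otherwise
#' — else `"non-coding"`.  Strand is ignored (CNAs are strand-agnostic).
#'
#' @param regions A `recurrent_regions` data.frame.
#' @param genes A `gene_models` data.frame.
#' @param assign_by `"inner"` (default) or `"outer"`: which region span is
#'   used for gene assignment and classification.
#' @return `regions` with added columns `gene_symbols` ("; "-joined, empty
#'   when intergenic) and `region_class` in `{"coding", "non-coding"}`.
#' @export
annotate_regions <- function(regions, genes,
                             assign_by = c("inner", "outer")) {
  assign_by <- match.arg(assign_by)
  s_col <- paste0(assign_by, "_start")
  e_col <- paste0(assign_by, "_end")
  symbols <- character(nrow(regions))
  cls <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    hit <- intervals_overlap(regions[[s_col]][i], regions[[e_col]][i],
                             g$start, g$end)
    g <- g[hit, , drop = FALSE]
    symbols[i] <- paste(unique(g$symbol), collapse = "; ")
    coding <- FALSE
    for (j in seq_len(nrow(g))) {
      if (!g$is_protein_coding[j]) next
      ex <- g$exons[[j]]
      coding <- if (is.null(ex)) TRUE else
        any(intervals_overlap(regions[[s_col]][i], regions[[e_col]][i],
                              ex$start, ex$end))
      if (coding) break
    }
    cls[i] <- if (coding) "coding" else "non-coding"
  }
  regions$gene_symbols <- symbols
  regions$region_class <- cls
  regions
}

#' Per-patient CNA carrier status for a region
#'
#' A patient carries a region iff it has at least one filtered segment of
#' the region's alteration type overlapping the region's inner MCR.  This
#' definition is recomputable identically in any cohort, unlike clique
#' membership.
#'
#' @param region One-row `recurrent_regions` data.frame.
#' @param segments Filtered `cna_segments`.
#' @param patients Character vector of patient ids to report on.
#' @return Logical vector along `patients`.
#' @export
region_carriers <- function(region, segments, patients) {
  stopifnot(nrow(region) == 1)
  sel <- segments$chrom == region$chrom &
    segments$alteration_type == region$alteration_type &
    intervals_overlap(segments$start, segments$end,
                      region$inner_start, region$inner_end)
  patients %in% segments$patient_id[sel]
}

#' Build the gene-by-patient mutation matrix
#'
#' One row per gene attached to a validated region; the cell for
#' (gene, patient) is the region's alteration type when the patient
#' carries a same-type filtered segment overlapping the region's inner
#' MCR, else `"none"`.  A gene inherits the type of the region that
#' defined it, so genes from gain regions report only gains.  Rows are
#' ordered by descending mutation frequency, ties alphabetically.
#'
#' @param regions Annotated (and typically validated) `recurrent_regions`.
#' @param segments Filtered `cna_segments` of the cohort being displayed.
#' @param patients Character vector of patient ids (matrix columns).
#' @return A character matrix (genes x patients) with values in
#'   `{"gain", "loss", "none"}` and a `"mutation_matrix"` class attribute.
#' @export
build_mutation_matrix <- function(regions, segments, patients) {
  gene_rows <- list()
  for (i in seq_len(nrow(regions))) {
    syms <- strsplit(regions$gene_symbols[i], "; ", fixed = TRUE)[[1]]
    syms <- syms[nzchar(syms)]
    if (!length(syms)) next
    carriers <- region_carriers(regions[i, , drop = FALSE], segments,
                                patients)
    for (s in syms) {
      state <- ifelse(carriers, regions$alteration_type[i], "none")
      if (is.null(gene_rows[[s]])) {
        gene_rows[[s]] <- state
      } else {
        # a gene hit by several same-type regions: union of carriers;
        # the first (leftmost) region's type wins on conflict
        keep <- gene_rows[[s]]
        gene_rows[[s]] <- ifelse(keep != "none", keep, state)
      }
    }
  }
  if (!length(gene_rows)) {
    m <- matrix(character(0), nrow = 0, ncol = length(patients),
                dimnames = list(NULL, patients))
    class(m) <- c("mutation_matrix", class(m))
    return(m)
  }
  m <- do.call(rbind, gene_rows)
  colnames(m) <- patients
  freq <- rowMeans(m != "none")
  m <- m[order(-freq, rownames(m)), , drop = FALSE]
  class(m) <- c("mutation_matrix", class(m))
  m
}

#' Write a mutation matrix as a tab-separated oncoprint table
#'
#' States are encoded `G` (gain), `L` (loss), `.` (none): directly
#' loadable by oncoprint-style plotters.
#'
#' @param m A matrix from [build_mutation_matrix()].
#' @param path Output path.
#' @export
write_mutation_matrix <- function(m, path) {
  enc <- matrix(c(gain = "G", loss = "L", none = ".")[m], nrow = nrow(m),
                dimnames = dimnames(m))
  utils::write.table(data.frame(gene = rownames(enc), enc,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gene models as BED
#'
#' @param genes A `gene_models` data.frame.
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom,
                    format(genes$start, scientific = FALSE, trim = TRUE),
                    format(genes$end, scientific = FALSE, trim = TRUE),
                    genes$symbol, 0, genes$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
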