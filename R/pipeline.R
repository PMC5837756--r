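#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or a set of input paths;
#' exactly one must be given.  Thresholds default to the published
#' analysis settings: segments kept when supported by >= 10 probes and
#' >= 1 kb; recurrent regions from maximal cliques of size >= 2, with
#' >= 5 distinct patients and an MCR of >= 1 kb; age cutoff 45 years;
#' significance level 0.05.
#'
#' @param simulate Optional [sim_config()].
#' @param discovery_segments,validation_segments,clinical,expression,genes
#'   Input file paths (segment files in the SEG dialect; one clinical
#'   table covering both cohorts; expression TSV; gene models BED/GTF).
#' @param dialect [seg_dialect()] for the segment files.
#' @param min_probes,min_seg_size,min_clique,min_patients,min_mcr_size
#'   Filtering thresholds (see above).
#' @param young_cutoff Age cutoff in years.
#' @param alpha Significance level reported in the tables.
#' @param specificity_policy Overlap policy for [group_specific_regions()].
#' @param assign_by Gene-assignment span for [annotate_regions()].
#' @param out_dir Output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL,
                            discovery_segments = NULL,
                            validation_segments = NULL,
                            clinical = NULL, expression = NULL,
                            genes = NULL,
                            dialect = seg_dialect(),
                            min_probes = 10, min_seg_size = 1000,
                            min_clique = 2, min_patients = 5,
                            min_mcr_size = 1000, young_cutoff = 45,
                            alpha = 0.05,
                            specificity_policy = "any_overlap",
                            assign_by = "inner",
                            out_dir = tempfile("cnaclique_run_")) {
  has_paths <- !is.null(discovery_segments)
  if (is.null(simulate) == !has_paths)
    stop("give exactly one of a simulate block or input paths",
         call. = FALSE)
  if (has_paths) {
    paths <- c(discovery_segments, validation_segments, clinical)
    if (any(!file.exists(paths)))
      stop("missing input file(s): ",
           paste(paths[!file.exists(paths)], collapse = ", "),
           call. = FALSE)
  }
  stopifnot(min_probes >= 1, min_seg_size >= 0, min_clique >= 1,
            min_patients >= 1, min_mcr_size >= 0, young_cutoff > 0,
            alpha > 0, alpha < 1)
  structure(list(simulate = simulate,
                 discovery_segments = discovery_segments,
                 validation_segments = validation_segments,
                 clinical = clinical, expression = expression,
                 genes = genes, dialect = dialect,
                 min_probes = min_probes, min_seg_size = min_seg_size,
                 min_clique = min_clique, min_patients = min_patients,
                 min_mcr_size = min_mcr_size, young_cutoff = young_cutoff,
                 alpha = alpha, specificity_policy = specificity_policy,
                 assign_by = assign_by, out_dir = out_dir),
            class = "pipeline_config")
}

stage_count <- function(log, stage, detail, count) {
  rbind(log, data.frame(stage = stage, detail = detail, count = count,
                        stringsAsFactors = FALSE))
}

#' Run the full recurrent-CNA pipeline
#'
#' Stages, in order: load (or simulate) and filter segments; partition
#' each cohort by age group and alteration type; per-group per-type
#' maximal-clique recurrent-region calling; young-specific subtraction
#' (young regions overlapping no same-type old region); discovery vs
#' validation matching; gene annotation; mutation-matrix export; pooled
#' young-cohort eQTL; pooled young-cohort survival analysis.  A
#' machine-readable counts log records the records surviving every stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `validated` (annotated validated
#'   young-specific regions), `young_specific`, `eqtl`, `survival`,
#'   `mutation_matrix`, `counts` (the stage log) and `out_dir`.  Output
#'   tables are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- data.frame(stage = character(), detail = character(),
                    count = numeric(), stringsAsFactors = FALSE)

  # ---- load or simulate -------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- simulate_paired_experiment(config$simulate)
    seg_d <- sim$discovery$segments
    seg_v <- sim$validation$segments
    clinical <- rbind(sim$discovery$clinical, sim$validation$clinical)
    class(clinical) <- c("patient_table", "data.frame")
    expression <- cbind(sim$discovery$expression,
                        sim$validation$expression)
    genes <- sim$discovery$genes
    sim_dir <- file.path(config$out_dir, "simulated")
    write_cohort(sim$discovery, file.path(sim_dir, "discovery"))
    write_cohort(sim$validation, file.path(sim_dir, "validation"))
  } else {
    seg_d <- read_segments(config$discovery_segments, config$dialect)
    seg_v <- read_segments(config$validation_segments, config$dialect)
    clinical <- read_clinical(config$clinical, config$young_cutoff)
    expression <- if (!is.null(config$expression)) {
      if (!file.exists(config$expression))
        stop("stage eqtl: expression file not found: ", config$expression,
             call. = FALSE)
      read_expression(config$expression)
    } else NULL
    genes <- if (!is.null(config$genes)) load_gene_models(config$genes)
      else NULL
  }
  log <- stage_count(log, "load", "discovery_segments", nrow(seg_d))
  log <- stage_count(log, "load", "validation_segments", nrow(seg_v))
  log <- stage_count(log, "load", "patients", nrow(clinical))

  # ---- filter and partition --------------------------------------------
  fd <- filter_segments(seg_d, config$min_probes, config$min_seg_size)
  fv <- filter_segments(seg_v, config$min_probes, config$min_seg_size)
  log <- stage_count(log, "filter", "discovery_segments", nrow(fd))
  log <- stage_count(log, "filter", "validation_segments", nrow(fv))
  part_d <- partition_cohort(fd, clinical, config$young_cutoff)
  part_v <- partition_cohort(fv, clinical, config$young_cutoff)
  for (b in names(part_d)) {
    log <- stage_count(log, "partition", paste0("discovery_", b),
                       nrow(part_d[[b]]))
    log <- stage_count(log, "partition", paste0("validation_", b),
                       nrow(part_v[[b]]))
  }

  # ---- per-group per-type recurrent calling ----------------------------
  call_bucket <- function(seg)
    call_recurrent_regions(seg, config$min_clique, config$min_patients,
                           config$min_mcr_size)
  reg_d <- lapply(part_d, call_bucket)
  reg_v <- lapply(part_v, call_bucket)
  for (b in names(reg_d)) {
    log <- stage_count(log, "call", paste0("discovery_", b),
                       nrow(reg_d[[b]]))
    log <- stage_count(log, "call", paste0("validation_", b),
                       nrow(reg_v[[b]]))
  }

  # ---- young-specific subtraction --------------------------------------
  ys_d <- rbind(
    group_specific_regions(reg_d$young_gain, reg_d$old_gain,
                           config$specificity_policy),
    group_specific_regions(reg_d$young_loss, reg_d$old_loss,
                           config$specificity_policy))
  ys_v <- rbind(
    group_specific_regions(reg_v$young_gain, reg_v$old_gain,
                           config$specificity_policy),
    group_specific_regions(reg_v$young_loss, reg_v$old_loss,
                           config$specificity_policy))
  sort_regions <- function(r) {
    r <- r[order(chrom_order(r$chrom), r$inner_start, r$alteration_type), ,
           drop = FALSE]
    rownames(r) <- NULL
    class(r) <- c("recurrent_regions", "data.frame")
    r
  }
  ys_d <- sort_regions(ys_d)
  ys_v <- sort_regions(ys_v)
  log <- stage_count(log, "young_specific", "discovery", nrow(ys_d))
  log <- stage_count(log, "young_specific", "validation", nrow(ys_v))

  # ---- discovery/validation matching -----------------------------------
  validated <- match_discovery_validation(ys_d, ys_v)
  log <- stage_count(log, "validate", "validated_regions", nrow(validated))

  # ---- annotation -------------------------------------------------------
  if (!is.null(genes)) {
    validated <- annotate_regions(validated, genes, config$assign_by)
    log <- stage_count(log, "annotate", "regions_with_genes",
                       sum(nzchar(validated$gene_symbols)))
  } else {
    validated$gene_symbols <- ""
    validated$region_class <- NA_character_
  }

  # ---- pooled young cohort for association stages ----------------------
  young <- clinical$patient_id[clinical$age_group == "young"]
  pooled <- rbind(fd, fv)
  class(pooled) <- c("cna_segments", "data.frame")
  mut <- build_mutation_matrix(validated, pooled, young)
  eqtl <- NULL
  surv <- NULL
  if (!is.null(expression) && nrow(validated)) {
    young_expr <- intersect(young, colnames(expression))
    eqtl <- eqtl_table(validated, pooled, expression, young_expr)
    surv <- survival_table(validated, pooled, expression, clinical,
                           young_expr)
    log <- stage_count(log, "eqtl", "genes_tested", nrow(eqtl))
    log <- stage_count(log, "survival", "genes_tested", nrow(surv))
  }

  # ---- outputs ----------------------------------------------------------
  out <- config$out_dir
  write_region_table(ys_d, file.path(out, "young_specific_discovery.tsv"))
  write_region_table(validated, file.path(out, "validated_regions.tsv"))
  if (nrow(validated))
    regions_to_bed(validated, file.path(out, "validated_inner.bed"))
  if (nrow(mut))
    write_mutation_matrix(mut, file.path(out, "mutation_matrix.tsv"))
  if (!is.null(eqtl))
    utils::write.table(eqtl, file.path(out, "eqtl.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(surv))
    utils::write.table(surv, file.path(out, "survival.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(log, file.path(out, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(validated = validated, young_specific = ys_d,
                 young_specific_validation = ys_v,
                 regions_discovery = reg_d, regions_validation = reg_v,
                 eqtl = eqtl, survival = surv, mutation_matrix = mut,
                 counts = log, out_dir = out))
}
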