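#' Configuration of a synthetic paired-cohort experiment
#'
#' Describes a discovery/validation pair of tumor cohorts with the
#' statistical structure the recurrent-CNA analysis assumes: two age
#' groups per cohort, recurrent gain/loss regions planted at a configured
#' penetrance with outward breakpoint jitter, background noise segments,
#' one gene model inside every planted region, expression shifted in
#' carriers, and disease-specific survival with hazards coupled to
#' carrier status.
#'
#' Defaults emulate the scale of the motivating breast-cancer cohorts:
#' 130/125 young and 867/870 old patients in discovery/validation, a
#' young-age cutoff of 45 years, planted region penetrance 0.35 (the
#' frequency of the most recurrent gain reported in young patients),
#' ~100 kb planted regions, 300 bp breakpoint jitter, on average 2
#' background segments per patient with sizes log-uniform on [1 kb, 5 Mb],
#' SNP-array probe density 0.5/kb, a 1 SD expression shift in carriers,
#' and an exponential survival model (baseline median 12 years,
#' log-hazard 0.7 per carried deleterious region, administrative
#' censoring at 20 years).
#'
#' The background rate is derived from a false-positive budget, not from
#' array segment counts: with the given size distribution (mean segment
#' ~0.6 Mb) a mean of 2 segments per patient keeps the expected fraction
#' of the genome randomly covered by >= 5 same-type patients below 1e-3
#' even in the large (~870-patient) old group, so background noise stays
#' background — it does not by itself create recurrent regions that the
#' caller must report or subtract.
#'
#' @param chrom_lengths Named numeric vector, chromosome -> length in bp.
#' @param n_young,n_old Named integer vectors with entries `discovery`
#'   and `validation`.
#' @param young_cutoff Age cutoff in years.
#' @param planted_regions Data.frame with columns `name`, `chrom`,
#'   `start`, `end`, `type` ("gain"/"loss"), `target_group` ("young",
#'   "old" or "both"), `penetrance` in [0,1], `jitter_sd` (bp),
#'   `expr_beta` (carrier expression shift in SD units) and `log_hazard`
#'   (per-carrier log hazard ratio).
#' @param noise_mean Poisson mean of background segments per patient.
#' @param noise_size_range Length-2 bp range of background segment sizes
#'   (log-uniform).
#' @param probes_per_kb Probe density for the Poisson `n_probes` draw.
#' @param expr_baseline,expr_sd Baseline mean and residual SD of the
#'   per-gene expression model (log2-array-like scale).
#' @param base_hazard Baseline exponential hazard per year.
#' @param censor_years Administrative censoring window in years.
#' @param seed Master seed; per-cohort and per-patient streams are
#'   derived from it deterministically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = default_chrom_lengths(),
                       n_young = c(discovery = 130, validation = 125),
                       n_old = c(discovery = 867, validation = 870),
                       young_cutoff = 45,
                       planted_regions = default_planted_regions(),
                       noise_mean = 2,
                       noise_size_range = c(1e3, 5e6),
                       probes_per_kb = 0.5,
                       expr_baseline = 8, expr_sd = 1,
                       base_hazard = log(2) / 12,
                       censor_years = 20,
                       seed = 20180129) {
  cfg <- list(chrom_lengths = chrom_lengths, n_young = n_young,
              n_old = n_old, young_cutoff = young_cutoff,
              planted_regions = planted_regions, noise_mean = noise_mean,
              noise_size_range = noise_size_range,
              probes_per_kb = probes_per_kb, expr_baseline = expr_baseline,
              expr_sd = expr_sd, base_hazard = base_hazard,
              censor_years = censor_years, seed = as.integer(seed))
  pr <- cfg$planted_regions
  stopifnot(all(c("discovery", "validation") %in% names(n_young)),
            all(c("discovery", "validation") %in% names(n_old)),
            all(pr$penetrance >= 0 & pr$penetrance <= 1),
            all(pr$type %in% c("gain", "loss")),
            all(pr$target_group %in% c("young", "old", "both")),
            all(pr$start < pr$end))
  missing_chr <- setdiff(pr$chrom, names(chrom_lengths))
  if (length(missing_chr))
    stop("planted region chromosome(s) not in chrom_lengths: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  out_of_bounds <- pr$end > chrom_lengths[pr$chrom] | pr$start < 0
  if (any(out_of_bounds))
    stop("planted region(s) outside chromosome bounds: ",
         paste(pr$name[out_of_bounds], collapse = ", "), call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Default chromosome lengths for the simulator
#'
#' Approximate lengths (bp) of the human chromosomes the default planted
#' regions live on.
#' @return Named numeric vector.
#' @export
default_chrom_lengths <- function() {
  c("1" = 247e6, "8" = 146e6, "9" = 140e6, "10" = 135e6,
    "17" = 78e6, "20" = 62e6)
}

#' Default planted regions
#'
#' Five young-specific regions (three gains, two losses) plus one region
#' planted in both age groups (which must never surface as
#' young-specific).  Sizes around 100-150 kb, penetrance 0.35, outward
#' breakpoint jitter SD 300 bp.  Gene symbols are synthetic (`SIMG*` for
#' gains, `SIML*` for losses, `SIMB*` for the both-group control).
#' @return Data.frame accepted by [sim_config()].
#' @export
default_planted_regions <- function() {
  data.frame(
    name = c("SIMG1", "SIMG2", "SIMG3", "SIML1", "SIML2", "SIMB1"),
    chrom = c("1", "10", "17", "8", "10", "20"),
    start = c(222.00e6, 5.70e6, 45.10e6, 14.30e6, 89.65e6, 41.20e6),
    end = c(222.15e6, 5.82e6, 45.22e6, 14.45e6, 89.75e6, 41.32e6),
    type = c("gain", "gain", "gain", "loss", "loss", "gain"),
    target_group = c("young", "young", "young", "young", "young", "both"),
    penetrance = rep(0.35, 6),
    jitter_sd = rep(300, 6),
    expr_beta = rep(1, 6),
    log_hazard = c(0.7, 0.7, 0, 0.7, 0.7, 0),
    stringsAsFactors = FALSE)
}

# deterministic per-patient seed derivation; 10007 is coprime to the
# cohort-seed offsets used by simulate_paired_experiment
patient_seed <- function(cohort_seed, i) {
  (cohort_seed + i * 10007) %% .Machine$integer.max
}

#' Simulate one cohort
#'
#' Deterministic given `seed`: each patient is generated from its own
#' derived random stream, so any single patient can be regenerated in
#' isolation.  Carriers of a planted region receive a segment covering it
#' with endpoints jittered outward by |N(0, jitter_sd)|; background noise
#' segments are drawn independently of age group (and re-drawn if they
#' would overlap a same-patient segment, since segmentation output is
#' non-overlapping per patient); `n_probes` is Poisson in the segment
#' size; expression of each planted gene is baseline + beta * carrier +
#' N(0, sd); disease-specific survival is exponential with log-hazard
#' summed over carried regions, administratively censored.
#'
#' @param config A [sim_config()].
#' @param cohort_label `"discovery"` or `"validation"`.
#' @param seed Cohort seed; defaults to a label-specific offset of the
#'   config master seed.
#' @return A list of class `sim_cohort`: `segments` (`cna_segments`),
#'   `clinical` (`patient_table`), `expression` (genes x patients
#'   matrix), `genes` (`gene_models`), `carriers` (logical matrix regions
#'   x patients: the ground truth), `label`, `seed`.
#' @export
simulate_cohort <- function(config,
                            cohort_label = c("discovery", "validation"),
                            seed = NULL) {
  cohort_label <- match.arg(cohort_label)
  if (is.null(seed))
    seed <- (config$seed +
               if (cohort_label == "discovery") 1000000 else 2000000) %%
      .Machine$integer.max
  n_young <- config$n_young[[cohort_label]]
  n_old <- config$n_old[[cohort_label]]
  n <- n_young + n_old
  prefix <- if (cohort_label == "discovery") "D" else "V"
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  group <- rep(c("young", "old"), c(n_young, n_old))
  pr <- config$planted_regions
  chrlen <- config$chrom_lengths

  seg_list <- vector("list", n)
  clin_list <- vector("list", n)
  expr <- matrix(NA_real_, nrow = nrow(pr), ncol = n,
                 dimnames = list(pr$name, ids))
  carriers <- matrix(FALSE, nrow = nrow(pr), ncol = n,
                     dimnames = list(pr$name, ids))

  for (i in seq_len(n)) {
    set.seed(patient_seed(seed, i))
    g <- group[i]
    age <- if (g == "young") stats::runif(1, 28, config$young_cutoff - 0.01)
      else stats::runif(1, config$young_cutoff, 75)
    # planted carrier segments
    eligible <- pr$target_group == g | pr$target_group == "both"
    carry <- eligible & stats::runif(nrow(pr)) < pr$penetrance
    carriers[, i] <- carry
    segs <- list()
    for (r in which(carry)) {
      jit <- abs(stats::rnorm(2, 0, pr$jitter_sd[r]))
      s <- max(0, round(pr$start[r] - jit[1]))
      e <- min(chrlen[[pr$chrom[r]]], round(pr$end[r] + jit[2]))
      segs[[length(segs) + 1L]] <- data.frame(
        patient_id = ids[i], chrom = pr$chrom[r], start = s, end = e,
        n_probes = max(1, stats::rpois(1, (e - s) / 1000 *
                                         config$probes_per_kb)),
        cn_state = if (pr$type[r] == "gain") 3 else 1,
        stringsAsFactors = FALSE)
    }
    # background noise, independent of group; reject overlaps within patient
    n_noise <- stats::rpois(1, config$noise_mean)
    tries <- 0
    while (n_noise > 0 && tries < 50 * config$noise_mean + 100) {
      tries <- tries + 1
      chr <- sample(names(chrlen), 1, prob = chrlen / sum(chrlen))
      sz <- round(exp(stats::runif(1, log(config$noise_size_range[1]),
                                   log(config$noise_size_range[2]))))
      if (sz >= chrlen[[chr]]) next
      s <- floor(stats::runif(1, 0, chrlen[[chr]] - sz))
      e <- s + sz
      clash <- any(vapply(segs, function(x)
        x$chrom == chr && intervals_overlap(x$start, x$end, s, e), NA))
      if (isTRUE(clash)) next
      segs[[length(segs) + 1L]] <- data.frame(
        patient_id = ids[i], chrom = chr, start = s, end = e,
        n_probes = max(1, stats::rpois(1, sz / 1000 * config$probes_per_kb)),
        cn_state = sample(c(1, 3), 1), stringsAsFactors = FALSE)
      n_noise <- n_noise - 1
    }
    seg_list[[i]] <- if (length(segs)) do.call(rbind, segs) else NULL
    # expression of the planted genes
    expr[, i] <- config$expr_baseline +
      pr$expr_beta * carry + stats::rnorm(nrow(pr), 0, config$expr_sd)
    # disease-specific survival
    lambda <- config$base_hazard * exp(sum(pr$log_hazard[carry]))
    t_event <- stats::rexp(1, lambda)
    event <- as.integer(t_event <= config$censor_years)
    clin_list[[i]] <- data.frame(
      patient_id = ids[i], age = age,
      dss_time = min(t_event, config$censor_years), dss_event = event,
      stringsAsFactors = FALSE)
  }

  nonnull <- seg_list[!vapply(seg_list, is.null, NA)]
  if (length(nonnull)) {
    segments <- do.call(rbind, nonnull)
    segments$alteration_type <- alteration_type(segments$cn_state)
  } else {
    segments <- empty_segments()
  }
  rownames(segments) <- NULL
  class(segments) <- c("cna_segments", "data.frame")
  clinical <- do.call(rbind, clin_list)
  clinical$age_group <- assign_age_group(clinical$age, config$young_cutoff)
  class(clinical) <- c("patient_table", "data.frame")
  genes <- data.frame(symbol = pr$name, chrom = pr$chrom,
                      start = pr$start, end = pr$end, strand = "+",
                      is_protein_coding = TRUE, stringsAsFactors = FALSE)
  genes$exons <- rep(list(NULL), nrow(genes))
  class(genes) <- c("gene_models", "data.frame")
  structure(list(segments = segments, clinical = clinical,
                 expression = expr, genes = genes, carriers = carriers,
                 label = cohort_label, seed = seed),
            class = "sim_cohort")
}

#' Simulate a paired discovery/validation experiment
#'
#' Two independent cohorts from one configuration with distinct derived
#' seeds; planted regions are shared, so discovery/validation matching
#' succeeds by construction.
#'
#' @param config A [sim_config()].
#' @return List with elements `discovery` and `validation` (each a
#'   `sim_cohort`) and `config`.
#' @export
simulate_paired_experiment <- function(config) {
  list(discovery = simulate_cohort(config, "discovery"),
       validation = simulate_cohort(config, "validation"),
       config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits exactly the formats the loaders read: a SEG-dialect segment
#' file, clinical TSV, expression TSV, BED gene models, and a JSON
#' manifest recording the label and derived seed.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_segments(cohort$segments, file.path(dir, "segments.seg"))
  utils::write.table(cohort$clinical[, c("patient_id", "age", "dss_time",
                                         "dss_event")],
                     file.path(dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gene_bed(cohort$genes, file.path(dir, "genes.bed"))
  jsonlite::write_json(list(label = cohort$label, seed = cohort$seed),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
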