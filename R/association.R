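#' Binarize an expression vector at its mean
#'
#' The dichotomous response used by the eQTL logistic regression: 1 iff
#' the value exceeds the per-gene mean across the included samples
#' (strict inequality), else 0.  A constant vector gives all zeros with a
#' warning (degenerate response).
#'
#' @param values Numeric expression vector (length >= 2, no NAs).
#' @return Integer 0/1 vector.
#' @export
binarize_by_mean <- function(values) {
  stopifnot(length(values) >= 2, !anyNA(values))
  m <- mean(values)
  out <- as.integer(values > m)
  if (all(out == 0))
    warning("constant (or never above-mean) expression vector: degenerate ",
            "binarized response", call. = FALSE)
  out
}

#' Logistic eQTL test of binarized expression on CNA status
#'
#' Fits `binary expression ~ CNA status` by maximum likelihood and
#' reports exp(coefficient) as the odds ratio with a Wald 95% CI and
#' p-value, together with the underlying 2x2 table.  For a single binary
#' predictor the logistic MLE odds ratio equals the table's cross-product
#' ratio, which serves as an internal oracle.  A zero cell (separation)
#' yields the Haldane-Anscombe-corrected ratio (+0.5 to every cell) with
#' `separation = TRUE` and NA inference.
#'
#' @param expr_binary Integer 0/1 response (from [binarize_by_mean()]).
#' @param status Carrier status per patient, coercible to logical or a
#'   character vector in `{"mutated", "wildtype"}`; must contain both
#'   levels.
#' @return A list of class `eqtl_result`: `odds_ratio`, `ci95`
#'   (length-2), `p_value`, `n_mutated`, `n_wildtype`, `counts_2x2`
#'   (matrix, rows = wildtype/mutated, cols = low/high), `separation`.
#' @export
eqtl_test <- function(expr_binary, status) {
  if (is.character(status)) {
    bad <- setdiff(unique(status), c("mutated", "wildtype"))
    if (length(bad)) stop("unknown status value(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    status <- status == "mutated"
  }
  status <- as.logical(status)
  stopifnot(length(expr_binary) == length(status), !anyNA(status),
            all(expr_binary %in% c(0, 1)))
  if (all(status) || !any(status))
    stop("no contrast: all patients are ",
         if (all(status)) "mutated" else "wildtype", call. = FALSE)
  counts <- matrix(c(sum(!status & expr_binary == 0),
                     sum(!status & expr_binary == 1),
                     sum(status & expr_binary == 0),
                     sum(status & expr_binary == 1)),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("wildtype", "mutated"),
                                   c("low", "high")))
  res <- list(n_mutated = sum(status), n_wildtype = sum(!status),
              counts_2x2 = counts)
  if (any(counts == 0)) {
    cc <- counts + 0.5
    res$odds_ratio <- (cc["mutated", "high"] * cc["wildtype", "low"]) /
      (cc["mutated", "low"] * cc["wildtype", "high"])
    res$ci95 <- c(NA_real_, NA_real_)
    res$p_value <- NA_real_
    res$separation <- TRUE
  } else {
    fit <- stats::glm(expr_binary ~ status, family = stats::binomial())
    beta <- stats::coef(fit)[["statusTRUE"]]
    se <- sqrt(stats::vcov(fit)["statusTRUE", "statusTRUE"])
    res$odds_ratio <- exp(beta)
    res$ci95 <- exp(beta + c(-1, 1) * stats::qnorm(0.975) * se)
    res$p_value <- 2 * stats::pnorm(-abs(beta / se))
    res$separation <- FALSE
  }
  class(res) <- "eqtl_result"
  res
}

#' eQTL tests across the genes of validated regions
#'
#' Runs [eqtl_test()] per gene, defining carrier status from the gene's
#' defining region via [region_carriers()], and adjusts p-values across
#' all tested genes with Benjamini-Hochberg.
#'
#' @param regions Annotated validated `recurrent_regions` (their
#'   `gene_symbols` define the gene list).
#' @param segments Pooled filtered `cna_segments` (discovery + validation
#'   patients of the analysis group).
#' @param expression Numeric matrix, genes x patients (dimnames required).
#' @param patients Patient ids to include (must be columns of
#'   `expression`).
#' @return A data.frame with one row per (gene, region) pair: `gene`,
#'   `alteration_type`, `p_value`, `p_adjusted`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `n_mutated`, `n_wildtype`, `separation`.
#' @export
eqtl_table <- function(regions, segments, expression, patients) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    syms <- strsplit(regions$gene_symbols[i], "; ", fixed = TRUE)[[1]]
    syms <- intersect(syms[nzchar(syms)], rownames(expression))
    if (!length(syms)) next
    status <- region_carriers(regions[i, , drop = FALSE], segments, patients)
    if (all(status) || !any(status)) next
    for (s in syms) {
      eb <- suppressWarnings(binarize_by_mean(expression[s, patients]))
      r <- eqtl_test(eb, status)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = s, alteration_type = regions$alteration_type[i],
        p_value = r$p_value, odds_ratio = r$odds_ratio,
        ci_low = r$ci95[1], ci_high = r$ci95[2],
        n_mutated = r$n_mutated, n_wildtype = r$n_wildtype,
        separation = r$separation, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), alteration_type = character(),
               p_value = numeric(), odds_ratio = numeric(),
               ci_low = numeric(), ci_high = numeric(),
               n_mutated = integer(), n_wildtype = integer(),
               separation = logical(), stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier survival by CNA mutation status
#'
#' Product-limit curves per group with a log-rank test and per-group
#' median survival (first time the curve reaches 0.5 or below; NA when it
#' never does).
#'
#' @param times Survival times in years.
#' @param events Event indicator (1 = died of disease, 0 = censored).
#' @param groups Two-level factor/character vector (e.g. "mutated" /
#'   "wildtype").
#' @return A list of class `survival_result` with `analysis =
#'   "km_logrank_status"`, `logrank_p`, `medians` (named per group), `n`
#'   (named per group) and the `survival::survfit` object in `fit`.
#' @export
km_by_status <- function(times, events, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2 || any(table(groups) == 0))
    stop("km_by_status needs exactly two non-empty groups", call. = FALSE)
  if (sum(events) < 1) stop("no events", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  # median = first time the curve reaches 0.5 or below (NA if never);
  # this is deliberately not survfit's convention, which averages the
  # two adjacent times when the curve sits exactly at 0.5
  strata <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  med <- vapply(levels(groups), function(g) {
    t_g <- fit$time[strata == g]
    s_g <- fit$surv[strata == g]
    hit <- which(s_g <= 0.5)
    if (length(hit)) t_g[min(hit)] else NA_real_
  }, 0)
  n <- as.vector(table(groups))
  names(n) <- levels(groups)
  structure(list(analysis = "km_logrank_status", logrank_p = p,
                 medians = med, n = n, fit = fit),
            class = "survival_result")
}

#' Cox proportional-hazards regression on gene expression
#'
#' Partial-likelihood fit of survival on a single continuous covariate,
#' z-scored by default so the hazard ratio is per standard deviation of
#' expression (the native array scale being platform-specific).
#'
#' @param times Survival times in years.
#' @param events Event indicator (1/0).
#' @param expression Numeric covariate.
#' @param standardize Z-score the covariate first (default TRUE).
#' @return A list of class `survival_result` with `analysis =
#'   "cox_expression"`, `hazard_ratio`, `ci95`, `p_value`, `n` and the
#'   `coxph` fit in `fit`.
#' @export
cox_expression <- function(times, events, expression, standardize = TRUE) {
  if (sum(events) < 1) stop("no events", call. = FALSE)
  if (length(unique(expression)) < 2)
    stop("no contrast: constant covariate", call. = FALSE)
  x <- if (standardize) as.vector(scale(expression)) else expression
  fit <- survival::coxph(survival::Surv(times, events) ~ x)
  if (!is.null(fit$info) || any(is.na(stats::coef(fit))))
    stop("Cox fit did not converge", call. = FALSE)
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)[1, 1])
  structure(list(analysis = "cox_expression",
                 hazard_ratio = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(beta / se)),
                 n = length(times), fit = fit),
            class = "survival_result")
}

#' Survival analyses across the genes of validated regions
#'
#' For each annotated gene: a Kaplan-Meier / log-rank comparison of
#' disease-specific survival by CNA mutation status, and a Cox
#' proportional-hazards fit on the gene's (z-scored) expression.
#'
#' @inheritParams eqtl_table
#' @param clinical A `patient_table` covering `patients`.
#' @return A data.frame with one row per (gene, region) pair: log-rank p,
#'   per-group medians, Cox hazard ratio with CI and p, plus the region's
#'   inner coordinates.
#' @export
survival_table <- function(regions, segments, expression, clinical,
                           patients) {
  cl <- clinical[match(patients, clinical$patient_id), ]
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    syms <- strsplit(regions$gene_symbols[i], "; ", fixed = TRUE)[[1]]
    syms <- syms[nzchar(syms)]
    if (!length(syms)) next
    status <- region_carriers(regions[i, , drop = FALSE], segments, patients)
    grp <- ifelse(status, "mutated", "wildtype")
    km <- if (length(unique(grp)) == 2 && sum(cl$dss_event) >= 1)
      km_by_status(cl$dss_time, cl$dss_event, grp) else NULL
    for (s in syms) {
      cox <- if (s %in% rownames(expression))
        tryCatch(cox_expression(cl$dss_time, cl$dss_event,
                                expression[s, patients]),
                 error = function(e) NULL) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        gene = s, alteration_type = regions$alteration_type[i],
        chrom = regions$chrom[i],
        inner_start = regions$inner_start[i],
        inner_end = regions$inner_end[i],
        logrank_p = if (is.null(km)) NA_real_ else km$logrank_p,
        median_mutated = if (is.null(km)) NA_real_
          else unname(km$medians["mutated"]),
        median_wildtype = if (is.null(km)) NA_real_
          else unname(km$medians["wildtype"]),
        n_mutated = sum(status), n_wildtype = sum(!status),
        cox_p = if (is.null(cox)) NA_real_ else cox$p_value,
        hazard_ratio = if (is.null(cox)) NA_real_ else cox$hazard_ratio,
        hr_ci_low = if (is.null(cox)) NA_real_ else cox$ci95[1],
        hr_ci_high = if (is.null(cox)) NA_real_ else cox$ci95[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), alteration_type = character(),
               chrom = character(), inner_start = numeric(),
               inner_end = numeric(), logrank_p = numeric(),
               median_mutated = numeric(), median_wildtype = numeric(),
               n_mutated = integer(), n_wildtype = integer(),
               cox_p = numeric(), hazard_ratio = numeric(),
               hr_ci_low = numeric(), hr_ci_high = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read an expression matrix
#'
#' Tab-separated, genes as rows (first column `gene`), one column per
#' patient id.  Genes with missing values have those samples dropped at
#' test time; fully missing genes are removed with a message.
#'
#' @param path Path to the file.
#' @return Numeric matrix with gene rownames and patient colnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- tab[[1]]
  m
}

#' Write an expression matrix
#'
#' @param m Numeric matrix, genes x patients.
#' @param path Output path.
#' @export
write_expression <- function(m, path) {
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
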