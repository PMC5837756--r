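test_that("binarize_by_mean dichotomizes strictly above the mean", {
  expect_equal(binarize_by_mean(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_warning(b <- binarize_by_mean(c(5, 5, 5)), "degenerate")
  expect_equal(b, c(0L, 0L, 0L))
  set.seed(9)
  frac <- mean(binarize_by_mean(rnorm(100, 10, 2)))
  expect_lt(abs(frac - 0.5), 0.15)  # ~ binomial error at n = 100
})

test_that("eqtl_test odds ratio equals the 2x2 cross-product ratio", {
  # a=20 (mut, high), b=10 (mut, low), c=10 (wt, high), d=20 (wt, low)
  status <- rep(c(TRUE, FALSE), c(30, 30))
  expr <- c(rep(1L, 20), rep(0L, 10), rep(1L, 10), rep(0L, 20))
  r <- eqtl_test(expr, status)
  expect_equal(r$odds_ratio, 4.0, tolerance = 1e-6)
  expect_equal(r$n_mutated, 30)
  expect_equal(unname(r$counts_2x2["mutated", "high"]), 20)
  expect_true(r$ci95[1] <= r$odds_ratio && r$odds_ratio <= r$ci95[2])

  # balanced table: OR 1, p ~ 1
  status <- rep(c(TRUE, FALSE), each = 30)
  expr <- rep(c(1L, 0L, 1L, 0L), each = 15)
  r <- eqtl_test(expr, status)
  expect_equal(r$odds_ratio, 1.0, tolerance = 1e-6)
  expect_gt(r$p_value, 0.99)
})

test_that("eqtl identity holds on random non-degenerate tables", {
  set.seed(77)
  for (rep in 1:50) {
    a <- sample(1:30, 4, replace = TRUE)  # all cells positive
    status <- rep(c(TRUE, TRUE, FALSE, FALSE), a)
    expr <- rep(c(1L, 0L, 1L, 0L), a)
    r <- eqtl_test(expr, status)
    expect_equal(r$odds_ratio, (a[1] * a[4]) / (a[2] * a[3]),
                 tolerance = 1e-6)
  }
})

test_that("eqtl degenerate inputs: separation and no contrast", {
  status <- rep(c(TRUE, FALSE), c(10, 10))
  expr <- c(rep(1L, 10), rep(c(0L, 1L), 5))
  r <- eqtl_test(expr, status)  # zero cell: (mut, low) empty
  expect_true(r$separation)
  expect_true(is.finite(r$odds_ratio))  # Haldane-Anscombe corrected
  expect_error(eqtl_test(rep(0:1, 5), rep(TRUE, 10)), "no contrast")
})

test_that("eqtl detects a planted 1 SD expression shift at n = 200", {
  set.seed(123)
  status <- runif(200) < 0.3
  values <- rnorm(200) + 1 * status
  r <- eqtl_test(binarize_by_mean(values), status)
  expect_gt(r$odds_ratio, 1)
  expect_lt(r$p_value, 0.05)
})

test_that("KM equals the empirical survival function without censoring", {
  # group A: event times 1..10, no censoring; group B far-shifted
  times <- c(1:10, 101:110)
  events <- rep(1, 20)
  groups <- rep(c("mutated", "wildtype"), each = 10)
  r <- km_by_status(times, events, groups)
  expect_s3_class(r$fit, "survfit")
  sf <- summary(r$fit, times = 1:10)
  sA <- sf$surv[sf$strata == "groups=mutated"]
  expect_equal(sA, empirical_survival(1:10, 1:10))  # drops 0.1 per event
  expect_equal(unname(r$medians["mutated"]), 5)
  expect_equal(unname(r$n), c(10L, 10L))
})

test_that("log-rank: identical groups give p = 1, separated groups reject", {
  times <- rep(c(1, 2, 3, 4, 5), 2)
  events <- rep(1, 10)
  groups <- rep(c("a", "b"), each = 5)
  r <- km_by_status(times, events, groups)
  expect_equal(r$logrank_p, 1, tolerance = 1e-12)

  # exponential groups with hazard ratio 3, n = 300/arm: p < 0.001 in
  # (nearly) all seeded replicates
  set.seed(21)
  rejections <- vapply(1:20, function(i) {
    t1 <- rexp(300, 1); t2 <- rexp(300, 3)
    km_by_status(c(t1, t2), rep(1, 600),
                 rep(c("wt", "mut"), each = 300))$logrank_p < 0.001
  }, NA)
  expect_gte(mean(rejections), 0.95)
})

test_that("km_by_status rejects degenerate groupings", {
  expect_error(km_by_status(1:5, rep(1, 5), rep("a", 5)), "two")
  expect_error(km_by_status(1:4, rep(0, 4), rep(c("a", "b"), 2)),
               "no events")
})

test_that("Cox recovers a null and a true hazard ratio of 2", {
  set.seed(5)
  x <- rnorm(300)
  t0 <- rexp(300, 0.2)
  r <- cox_expression(t0, rep(1, 300), x)
  expect_true(r$ci95[1] <= 1 && 1 <= r$ci95[2])  # CI covers the null

  covered <- 0; in_band <- 0
  for (i in 1:30) {
    x <- rnorm(500)
    t1 <- rexp(500, 0.1 * exp(log(2) * x))
    cens <- pmin(t1, 15)
    r <- cox_expression(cens, as.numeric(t1 <= 15), x,
                        standardize = FALSE)
    covered <- covered + (r$ci95[1] <= 2 && 2 <= r$ci95[2])
    in_band <- in_band + (r$hazard_ratio >= 1.6 && r$hazard_ratio <= 2.5)
  }
  expect_gte(covered / 30, 0.9)
  expect_gte(in_band / 30, 0.9)
})

test_that("Cox rejects degenerate inputs", {
  expect_error(cox_expression(1:5, rep(0, 5), rnorm(5)), "no events")
  expect_error(cox_expression(1:5, rep(1, 5), rep(2, 5)), "no contrast")
})

test_that("direction consistency on a tiny planted world", {
  # carriers: higher expression (OR > 1) and worse survival
  set.seed(99)
  n <- 120
  status <- runif(n) < 0.4
  expr_v <- rnorm(n) + 1.2 * status
  r <- eqtl_test(binarize_by_mean(expr_v), status)
  expect_gt(r$odds_ratio, 1)
  t1 <- rexp(n, 0.08 * exp(1 * status))
  km <- km_by_status(pmin(t1, 25), as.numeric(t1 <= 25),
                     ifelse(status, "mutated", "wildtype"))
  expect_lt(unname(km$medians["mutated"]),
            unname(km$medians["wildtype"]))
})

test_that("eqtl_table and survival_table wire genes to regions", {
  reg <- region_row("1", 1e6, 1.1e6)
  reg$gene_symbols <- "GENEA"
  patients <- paste0("P", 1:60)
  seg <- seg_df(paste0("P", 1:25), "1", 0.95e6, 1.2e6, cn_state = 3)
  set.seed(4)
  carrier <- patients %in% paste0("P", 1:25)
  expr_m <- matrix(rnorm(60) + 1.5 * carrier, nrow = 1,
                   dimnames = list("GENEA", patients))
  clin <- data.frame(patient_id = patients, age = 40,
                     dss_time = rexp(60, 0.1 * exp(0.8 * carrier)),
                     dss_event = 1, age_group = "young")
  et <- eqtl_table(reg, seg, expr_m, patients)
  expect_equal(nrow(et), 1)
  expect_equal(et$n_mutated, 25)
  expect_gt(et$odds_ratio, 1)
  expect_equal(et$p_adjusted, et$p_value)  # single test: BH is identity
  st <- survival_table(reg, seg, expr_m, clin, patients)
  expect_equal(st$gene, "GENEA")
  expect_equal(st$n_mutated, 25)
  expect_true(is.finite(st$logrank_p) && is.finite(st$hazard_ratio))
  expect_equal(st$inner_start, 1e6)
})
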