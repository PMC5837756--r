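test_that("genomic_interval validates and region_size is end - start", {
  gi <- genomic_interval("chr1", 222004315, 222004925)
  expect_equal(gi$chrom, "1")  # chr prefix stripped
  expect_equal(region_size(gi), 610)
  expect_equal(region_size(genomic_interval("1", 191359529, 191405183)),
               45654)
  expect_error(genomic_interval("X", 100, 100), "start >= end")
  expect_error(genomic_interval("X", 200, 100), "start >= end")
  expect_error(genomic_interval("1", 0.5, 10), "integer")
})

test_that("read_segments parses, normalizes and derives alteration type", {
  path <- write_seg_fixture(c(
    "P1\tchr1\t1000\t5000\t25\t3",
    "P2\t2\t2000\t9000\t40\t4",
    "P3\t1\t1500\t4500\t30\t1"))
  seg <- read_segments(path)
  expect_s3_class(seg, "cna_segments")
  expect_equal(nrow(seg), 3)
  expect_equal(seg$patient_id, c("P1", "P2", "P3"))
  expect_equal(seg$chrom, c("1", "2", "1"))
  expect_equal(seg$start, c(1000, 2000, 1500))
  expect_equal(seg$end, c(5000, 9000, 4500))
  expect_equal(seg$alteration_type, c("gain", "gain", "loss"))

  # empty file with valid header -> empty collection
  empty <- read_segments(write_seg_fixture(character(0)))
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "cna_segments")
})

test_that("read_segments reports row- and column-level errors", {
  expect_error(read_segments(write_seg_fixture("P1\t1\t500\t400\t20\t3")),
               "end <= start at line 2")
  expect_error(read_segments(write_seg_fixture("P1\t1\t10.5\t400\t20\t3")),
               "non-integer start")
  bad_header <- tempfile(fileext = ".seg")
  writeLines(c("ID\tchrom\tloc.start\tloc.end\tnum.mark",
               "P1\t1\t1\t2\t3"), bad_header)
  expect_error(read_segments(bad_header), "cn.state")
  expect_error(read_segments(tempfile()), "not found")
})

test_that("dialect options: 1-based coordinates and cn encodings", {
  path <- write_seg_fixture("P1\t1\t1001\t5000\t25\t3")
  seg1 <- read_segments(path, seg_dialect(coords = "one_based"))
  expect_equal(seg1$start, 1000)  # shifted to 0-based
  expect_equal(seg1$end, 5000)

  path <- write_seg_fixture(c("P1\t1\t100\t9000\t25\t-1",
                              "P2\t1\t100\t9000\t25\t0"))
  segd <- read_segments(path, seg_dialect(cn_coding = "delta"))
  expect_equal(segd$cn_state, c(1, 2))
  expect_equal(segd$alteration_type, c("loss", "neutral"))

  path <- write_seg_fixture(c("P1\t1\t100\t9000\t25\t0.8",
                              "P2\t1\t100\t9000\t25\t-0.5",
                              "P3\t1\t100\t9000\t25\t0.05"))
  segl <- read_segments(path, seg_dialect(cn_coding = "logratio"))
  expect_equal(segl$alteration_type, c("gain", "loss", "neutral"))
})

test_that("overlapping same-patient segments warn but load", {
  path <- write_seg_fixture(c("P1\t1\t1000\t5000\t25\t3",
                              "P1\t1\t4000\t8000\t25\t3"))
  expect_warning(seg <- read_segments(path), "overlapping segments")
  expect_equal(nrow(seg), 2)
})

test_that("write/read round-trip is the identity on field values", {
  seg <- seg_df(c("P1", "P2", "P3"), c("1", "2", "X"),
                c(100, 5000, 7e6), c(2100, 9000, 7.5e6),
                n_probes = c(12, 40, 99), cn_state = c(3, 1, 4))
  for (coords in c("half_open", "one_based")) {
    d <- seg_dialect(coords = coords)
    path <- tempfile(fileext = ".seg")
    write_segments(seg, path, d)
    back <- read_segments(path, d)
    expect_equal(as.data.frame(back), as.data.frame(seg))
  }
})

test_that("filter_segments enforces probe, size and neutrality rules", {
  seg <- seg_df("P1", "1",
                start = c(0, 0, 0, 0),
                end = c(5000, 999, 1000, 5000),
                n_probes = c(9, 10, 10, 10),
                cn_state = c(3, 3, 3, 2))
  out <- filter_segments(seg)
  # 9 probes fails; 999 bp fails; 1000 bp boundary passes; neutral dropped
  expect_equal(nrow(out), 1)
  expect_equal(out$end, 1000)

  # 20-segment fixture with exactly 7 passing both rules
  set.seed(1)
  n_probes <- c(rep(10, 7), rep(9, 6), rep(15, 7))
  sizes <- c(rep(2000, 7), rep(2000, 6), rep(500, 7))
  seg20 <- seg_df(paste0("P", 1:20), "1", start = (0:19) * 1e6,
                  end = (0:19) * 1e6 + sizes, n_probes = n_probes)
  expect_equal(nrow(filter_segments(seg20)), 7)
})

test_that("filter_segments is monotone in both thresholds", {
  set.seed(7)
  seg <- seg_df(paste0("P", 1:50), "1", start = (0:49) * 1e6,
                end = (0:49) * 1e6 +
                  sample(c(500, 1000, 5000, 5e4), 50, replace = TRUE),
                n_probes = sample(5:40, 50, replace = TRUE))
  counts_p <- vapply(c(1, 5, 10, 20, 40),
                     function(p) nrow(filter_segments(seg, min_probes = p)),
                     0)
  counts_s <- vapply(c(0, 500, 1000, 5000, 1e5),
                     function(s) nrow(filter_segments(seg, min_size = s)),
                     0)
  expect_true(all(diff(counts_p) <= 0))
  expect_true(all(diff(counts_s) <= 0))
})

test_that("partition_cohort splits by strict age cutoff and type", {
  patients <- data.frame(patient_id = paste0("P", 1:6),
                         age = c(44.9, 45.0, 30, 60, 44.999, 45.001),
                         stringsAsFactors = FALSE)
  seg <- seg_df(paste0("P", c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4)), "1",
                start = (0:9) * 1e5, end = (0:9) * 1e5 + 5e4,
                cn_state = c(3, 3, 1, 1, 3, 1, 1, 3, 3, 1))
  part <- partition_cohort(seg, patients)
  # hand partition: young = P1,P3,P5; old = P2,P4,P6
  expect_equal(nrow(part$young_gain), 3)  # P1 gain, P5 gain, P3 gain
  expect_equal(nrow(part$young_loss), 2)  # P3 loss, P1 loss
  expect_equal(nrow(part$old_gain), 2)    # P2 gain x2
  expect_equal(nrow(part$old_loss), 3)    # P4 x2, P6
  # completeness
  expect_equal(sum(vapply(part, nrow, 0L)), nrow(seg))
  # orphan patient -> error listing ids
  seg_bad <- seg_df("GHOST", "1", 0, 1e4)
  expect_error(partition_cohort(seg_bad, patients), "GHOST")
})
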