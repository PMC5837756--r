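write_bed_fixture <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

write_gtf_fixture <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, feature, start1, end1, gene, strand = "+",
                     biotype = "protein_coding") {
  sprintf(paste0("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; ",
                 "gene_name \"%s\"; gene_biotype \"%s\";"),
          chrom, feature, start1, end1, strand, gene, gene, biotype)
}

test_that("BED gene models load with strands and 0-based coordinates", {
  path <- write_bed_fixture(c("chr1\t1000\t5000\tGENEA\t0\t+",
                              "2\t7000\t9000\tGENEB\t0\t-"))
  g <- load_gene_models(path)
  expect_s3_class(g, "gene_models")
  expect_equal(g$symbol, c("GENEA", "GENEB"))
  expect_equal(g$chrom, c("1", "2"))
  expect_equal(g$start, c(1000, 7000))
  expect_equal(g$end, c(5000, 9000))
  expect_equal(g$strand, c("+", "-"))
  expect_true(all(vapply(g$exons, is.null, NA)))
})

test_that("GTF exons aggregate under their gene, converted to half-open", {
  path <- write_gtf_fixture(c(
    gtf_line("1", "gene", 1001, 5000, "GENEA"),
    gtf_line("1", "exon", 1001, 1200, "GENEA"),
    gtf_line("1", "exon", 2001, 2300, "GENEA"),
    gtf_line("1", "exon", 4501, 5000, "GENEA")))
  g <- load_gene_models(path)
  expect_equal(nrow(g), 1)
  expect_equal(g$start, 1000)  # 1-based inclusive -> 0-based half-open
  expect_equal(g$end, 5000)
  ex <- g$exons[[1]]
  expect_equal(nrow(ex), 3)
  expect_equal(ex$start, c(1000, 2000, 4500))
  expect_equal(ex$end, c(1200, 2300, 5000))
  expect_true(all(ex$start >= g$start & ex$end <= g$end))
})

test_that("BED and GTF encodings of the same genes agree after loading", {
  genes <- data.frame(chrom = c("1", "1", "2", "3", "X"),
                      start0 = c(100, 5000, 200, 1e6, 5e5),
                      end0 = c(900, 7500, 4200, 2e6, 6e5),
                      symbol = paste0("G", 1:5),
                      strand = c("+", "-", "+", "-", "+"))
  bed <- write_bed_fixture(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom,
                                   genes$start0, genes$end0, genes$symbol,
                                   genes$strand))
  gtf <- write_gtf_fixture(mapply(gtf_line, genes$chrom, "gene",
                                  genes$start0 + 1, genes$end0,
                                  genes$symbol, genes$strand))
  gb <- load_gene_models(bed)
  gg <- load_gene_models(gtf)
  ord <- order(gb$symbol)
  for (col in c("symbol", "chrom", "start", "end", "strand"))
    expect_equal(gb[[col]][ord], gg[[col]][order(gg$symbol)])
})

test_that("duplicate symbols keep the widest span with a warning", {
  path <- write_bed_fixture(c("1\t1000\t2000\tDUP\t0\t+",
                              "1\t500\t9000\tDUP\t0\t+"))
  expect_warning(g <- load_gene_models(path), "duplicate")
  expect_equal(nrow(g), 1)
  expect_equal(g$end - g$start, 8500)
})

test_that("annotate_regions assigns overlapping genes and classifies", {
  genes <- load_gene_models(write_bed_fixture(c(
    "1\t1000\t5000\tGENEA\t0\t+",
    "1\t5200\t8000\tGENEB\t0\t-",
    "2\t0\t1000\tGENEC\t0\t+")))
  # intergenic desert
  desert <- region_row("1", 20e3, 30e3)
  a <- annotate_regions(desert, genes)
  expect_equal(a$gene_symbols, "")
  expect_equal(a$region_class, "non-coding")
  # spanning two adjacent genes: multi-gene "; " join
  span2 <- region_row("1", 4000, 6000)
  a <- annotate_regions(span2, genes)
  expect_equal(a$gene_symbols, "GENEA; GENEB")
  expect_equal(a$region_class, "coding")
  # assignment is against the inner MCR by default, outer optionally
  outer_only <- region_row("1", 20e3, 30e3, outer_start = 4500,
                           outer_end = 40e3)
  expect_equal(annotate_regions(outer_only, genes)$gene_symbols, "")
  expect_equal(annotate_regions(outer_only, genes,
                                assign_by = "outer")$gene_symbols,
               "GENEA; GENEB")
})

test_that("exon-level refinement: intron-only overlap is non-coding", {
  gtf <- write_gtf_fixture(c(
    gtf_line("1", "gene", 1001, 9000, "GENEA"),
    gtf_line("1", "exon", 1001, 1500, "GENEA"),
    gtf_line("1", "exon", 8001, 9000, "GENEA")))
  genes <- load_gene_models(gtf)
  intronic <- region_row("1", 3000, 6000)
  a <- annotate_regions(intronic, genes)
  expect_equal(a$gene_symbols, "GENEA")  # span overlap still assigns
  expect_equal(a$region_class, "non-coding")  # but no exon overlap
  exonic <- region_row("1", 1200, 2000)
  expect_equal(annotate_regions(exonic, genes)$region_class, "coding")
})

test_that("coding fraction of a constructed region set is exact", {
  genes <- load_gene_models(write_bed_fixture(
    sprintf("1\t%d\t%d\tCG%d\t0\t+", (0:11) * 1e6 + 1e5,
            (0:11) * 1e6 + 2e5, 1:12)))
  # 50 regions at 1 Mb spacing; the first 12 overlap a coding gene
  regs <- do.call(rbind, lapply(0:49, function(i)
    region_row("1", i * 1e6 + 1.5e5, i * 1e6 + 2.5e5)))
  class(regs) <- c("recurrent_regions", "data.frame")
  a <- annotate_regions(regs, genes)
  expect_equal(mean(a$region_class == "coding"), 0.24)
  expect_equal(mean(a$region_class == "non-coding"), 0.76)
})

test_that("mutation matrix states, frequencies and ordering", {
  reg <- region_row("1", 1e6, 1.1e6, type = "gain")
  reg$gene_symbols <- "GENEA"
  reg2 <- region_row("1", 5e6, 5.1e6, type = "loss")
  reg2$gene_symbols <- "GENEB"
  regions <- rbind(reg, reg2)
  class(regions) <- c("recurrent_regions", "data.frame")
  patients <- paste0("P", 1:10)
  seg <- rbind(
    seg_df(paste0("P", 1:5), "1", 0.95e6, 1.2e6, cn_state = 3),
    seg_df(paste0("P", 1:6), "1", 4.9e6, 5.2e6, cn_state = 1))
  m <- build_mutation_matrix(regions, seg, patients)
  expect_equal(rownames(m), c("GENEB", "GENEA"))  # 0.6 before 0.5
  expect_equal(mean(m["GENEA", ] != "none"), 0.5)
  expect_equal(unname(m["GENEA", "P1"]), "gain")
  expect_equal(unname(m["GENEB", "P2"]), "loss")
  # patient with no segments: all-none column
  expect_true(all(m[, "P10"] == "none"))
  # writer encodes G/L/.
  path <- tempfile(fileext = ".tsv")
  write_mutation_matrix(m, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(tab$gene, c("GENEB", "GENEA"))
  expect_equal(tab[tab$gene == "GENEA", "P1"], "G")
  expect_equal(tab[tab$gene == "GENEB", "P8"], ".")
})
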