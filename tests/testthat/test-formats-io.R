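# Readers and writers: round trips, validation, exact error locations.

mk_table <- function() {
  counts <- matrix(c(5L, 0L, 7L, 2L, 3L, 9L, 1L, 4L), nrow = 2,
                   dimnames = list(c("gA", "gB"),
                                   c("mRNA_t0_r1", "mRNA_t30_r1",
                                     "RPF_t0_r1", "RPF_t30_r1")))
  samples <- data.frame(
    sample_id = colnames(counts),
    assay = rep(c("mRNA", "RPF"), each = 2),
    condition = rep(c("t0", "t30"), 2),
    replicate = 1L, stringsAsFactors = FALSE)
  count_table(counts, samples)
}

test_that("count tables round-trip exactly through TSV", {
  t1 <- mk_table()
  cp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  write_counts(t1, cp, mp)
  t2 <- read_counts(cp, mp)
  expect_identical(t2$counts, t1$counts)
  expect_identical(t2$samples, t1$samples)
})

test_that("a hand-written counts file is read back verbatim", {
  cp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t5\t7\t1\t2",
               "g2\t0\t2\t3\t4"), cp)
  writeLines(c("sample_id\tassay\tcondition\treplicate",
               "s1\tmRNA\tt0\t1", "s2\tmRNA\tt30\t1",
               "s3\tRPF\tt0\t1", "s4\tRPF\tt30\t1"), mp)
  tab <- read_counts(cp, mp)
  expect_identical(tab$counts[, 1:2],
                   matrix(c(5L, 0L, 7L, 2L), 2,
                          dimnames = list(c("g1", "g2"), c("s1", "s2"))))
})

test_that("malformed counts are rejected with their location", {
  cp <- withr::local_tempfile(); mp <- withr::local_tempfile()
  writeLines(c("sample_id\tassay\tcondition\treplicate",
               "s1\tmRNA\tt0\t1", "s2\tmRNA\tt30\t1",
               "s3\tRPF\tt0\t1", "s4\tRPF\tt30\t1"), mp)
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t5\t-3\t1\t1"), cp)
  expect_error(read_counts(cp, mp), "-3.*g1.*s2.*line 2")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t1\t1\t1", "g1\t2\t2\t2\t2"), cp)
  expect_error(read_counts(cp, mp), "duplicate gene id 'g1' at line 3")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4\ts5",
               "g1\t1\t1\t1\t1\t1"), cp)
  expect_error(read_counts(cp, mp), "s5.*absent from metadata")
})

test_that("GFF3 gene models yield summed region lengths", {
  gp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t90\t260\t.\t+\t.\tID=g1",
    "chr1\t.\tmRNA\t90\t260\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\t.\tfive_prime_UTR\t90\t100\t.\t+\t.\tParent=g1.t1",
    "chr1\t.\tCDS\t101\t160\t.\t+\t.\tParent=g1.t1",
    "chr1\t.\tthree_prime_UTR\t161\t180\t.\t+\t.\tParent=g1.t1",
    "chr1\t.\tgene\t300\t560\t.\t+\t.\tID=g2",
    "chr1\t.\tmRNA\t300\t560\t.\t+\t.\tID=g2.t1;Parent=g2",
    "chr1\t.\tCDS\t301\t330\t.\t+\t.\tParent=g2.t1",
    "chr1\t.\tCDS\t401\t430\t.\t+\t.\tParent=g2.t1"), gp)
  ann <- read_gene_models(gp, "gff3")
  expect_equal(ann$cds_length[ann$gene_id == "g1"], 60L)
  expect_equal(ann$utr5_length[ann$gene_id == "g1"], 11L)
  # gene without a 5'UTR feature gets length 0; multi-exon CDS spans sum
  expect_equal(ann$utr5_length[ann$gene_id == "g2"], 0L)
  expect_equal(ann$cds_length[ann$gene_id == "g2"], 60L)
})

test_that("gene models survive a GFF3 write/read round trip", {
  ann <- mk_ann(4, utr5 = c(0L, 10L, 25L, 3L), cds = c(30L, 60L, 300L, 9L),
                utr3 = c(12L, 0L, 40L, 5L),
                is_membrane = c(TRUE, FALSE, TRUE, FALSE))
  gp <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(ann, gp, "gff3")
  back <- read_gene_models(gp, "gff3")
  expect_equal(as.data.frame(back), as.data.frame(ann))
  tp <- withr::local_tempfile()
  write_gene_models(ann, tp, "tsv")
  expect_equal(as.data.frame(read_gene_models(tp, "tsv")),
               as.data.frame(ann))
})

test_that("a CDS length that is not a multiple of 3 is rejected", {
  gp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\t.\tmRNA\t1\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
               "chr1\t.\tCDS\t1\t50\t.\t+\t.\tParent=g1.t1"), gp)
  expect_error(read_gene_models(gp, "gff3"), "multiple of 3")
})

test_that("PARS score files parse, reject malformation, and round-trip", {
  pp <- withr::local_tempfile()
  writeLines("YAL001C\t0.1;0.2;NA;0.4", pp)
  prof <- read_pars_scores(pp)
  expect_equal(prof$YAL001C, c(0.1, 0.2, NA, 0.4))

  writeLines("YAL001C 0.1;0.2", pp)   # no TAB
  expect_error(read_pars_scores(pp), "line 1")
  writeLines(c("g1\t0.1", "g1\t0.2"), pp)
  expect_error(read_pars_scores(pp), "duplicate gene line")
  writeLines("g1\t0.1;x;0.2", pp)
  expect_error(read_pars_scores(pp), "non-numeric score 'x'")
  writeLines("g1\t", pp)
  expect_error(read_pars_scores(pp), "empty score list")

  prof <- list(gA = c(-0.5, 1.25, NA, 3), gB = c(0.125))
  write_pars_scores(prof, pp)
  expect_equal(read_pars_scores(pp), prof)
})

test_that("codon coverage round-trips", {
  cov <- list(RPF_t0_r1 = list(gA = c(3L, 0L, 5L), gB = c(1L, 1L)),
              RPF_t30_r1 = list(gA = c(0L, 0L, 2L), gB = c(4L, 0L)))
  cp <- withr::local_tempfile()
  write_codon_coverage(cov, cp)
  expect_equal(read_codon_coverage(cp), cov)
})

test_that("result writer is deterministic and keeps empty tables", {
  df <- data.frame(gene_id = c("a", "b"), value = c(1 / 3, 2e-7),
                   class_label = c("activated_buffered", "not_regulated"),
                   stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_results(df, p1); write_results(df, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_results(p1)
  expect_identical(back$class_label, df$class_label)

  write_results(df[0, ], p1)
  expect_identical(readLines(p1), "gene_id\tvalue\tclass_label")
})
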