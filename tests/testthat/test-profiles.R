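# Positional analyses: masking, metagenes, region means, group features.

one_sample_meta <- function(ids, condition = "t0") {
  data.frame(sample_id = ids, assay = "RPF", condition = condition,
             replicate = seq_along(ids), stringsAsFactors = FALSE)
}

test_that("start-region masking slices and excludes correctly", {
  expect_equal(mask_start_region(rep(1L, 100)), rep(1L, 85))
  expect_equal(sum(mask_start_region(rep(1L, 100))), 85)
  expect_length(mask_start_region(rep(3L, 15)), 0)          # boundary
  v <- sample.int(20, 50, replace = TRUE)
  expect_identical(mask_start_region(v, 15), v[16:50])      # slicing identity
})

test_that("uniform coverage normalizes to a flat unit metagene", {
  cov <- list(s1 = list(g1 = rep(5L, 100)))
  prof <- rpf_metagene(cov, one_sample_meta("s1"), c(g1 = 1), "g1")
  expect_equal(prof$value, rep(1, 100))
  expect_equal(unique(prof$n_genes), 1L)
  expect_identical(prof$position, 1:100)
})

test_that("metagene is invariant to library scaling and gene order", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:12)
  mk_cov <- function(scale = 1L) lapply(setNames(genes, genes), function(g)
    as.integer(scale * rpois(80, 6)))
  cov <- list(s1 = mk_cov(), s2 = mk_cov())
  meta <- one_sample_meta(c("s1", "s2"))
  fc <- setNames(rep(1, 12), genes)
  base <- rpf_metagene(cov, meta, fc, genes)

  cov10 <- cov
  cov10$s2 <- lapply(cov$s2, function(v) v * 10L)
  scaled <- rpf_metagene(cov10, meta, fc, genes)
  expect_equal(scaled$value, base$value)

  shuffled <- rpf_metagene(cov, meta, fc, rev(genes))
  expect_equal(shuffled$value, base$value)
})

test_that("a halved t30 gene drops by exactly the library-adjusted factor", {
  # deterministic construction: the profiled gene halves at t30 while a
  # background gene is flat, so each t30 bin equals 0.5 x (lib0/lib30)
  cov <- list(
    RPF_t0_r1 = list(g1 = rep(4L, 100), g2 = rep(4L, 100)),
    RPF_t30_r1 = list(g1 = rep(2L, 100), g2 = rep(4L, 100)))
  meta <- rbind(one_sample_meta("RPF_t0_r1", "t0"),
                one_sample_meta("RPF_t30_r1", "t30"))
  prof <- rpf_metagene(cov, meta, c(g1 = 1, g2 = 1), "g1")
  v0 <- prof$value[prof$condition == "t0"]
  v30 <- prof$value[prof$condition == "t30"]
  lib_ratio <- (4 * 85 + 4 * 85) / (2 * 85 + 4 * 85)
  expect_equal(v30 / v0, rep(0.5 * lib_ratio, 100))
  # the per-gene mRNA fold-change correction rescales t30 values only
  prof_fc <- rpf_metagene(cov, meta, c(g1 = 2, g2 = 1), "g1")
  expect_equal(prof_fc$value[prof_fc$condition == "t30"], v30 / 2)
  expect_equal(prof_fc$value[prof_fc$condition == "t0"], v0)
})

test_that("metagene validates inputs and filters short genes", {
  cov <- list(s1 = list(g1 = rep(2L, 100), g2 = rep(2L, 30)))
  meta <- one_sample_meta("s1")
  prof <- rpf_metagene(cov, meta, c(g1 = 1, g2 = 1), c("g1", "g2"))
  expect_equal(attr(prof, "n_excluded"), 1L)       # g2 < min_codons
  expect_error(rpf_metagene(cov, meta, c(g1 = 1, g2 = 1), c("g1", "gX")),
               "without coverage")
  expect_error(rpf_metagene(cov, meta, c(g1 = -1, g2 = 1), c("g1", "g2")),
               "positive")
})

test_that("TIS profile aligns, truncates and skips missing values", {
  ann <- mk_ann(2, utr5 = c(50L, 30L), cds = c(300L, 300L))
  prof_all <- list()
  prof_all[[ann$gene_id[1]]] <- rep(0.5, 50 + 300 + 60)
  prof_all[[ann$gene_id[2]]] <- rep(0.1, 30 + 300 + 60)

  one <- pars_tis_profile(prof_all[1], ann[1, ], ann$gene_id[1])
  expect_equal(one$n_genes[one$position < -50], rep(0L, 50))
  expect_equal(one$n_genes[one$position >= -50], rep(1L, 350))
  expect_equal(one$value[one$position >= -50], rep(0.5, 350))

  both <- pars_tis_profile(prof_all, ann, ann$gene_id)
  expect_equal(both$value[both$position == -20], 0.3)   # mean of 0.5, 0.1
  expect_equal(both$value[both$position == -45], 0.5)   # only gene 1 reaches
  # n_genes never increases moving upstream from the TIS
  up <- both[both$position < 0, ]
  expect_true(all(diff(up$n_genes[order(up$position)]) >= 0))

  # missing values are skipped position-wise
  prof_all[[ann$gene_id[1]]][50 + 1] <- NA    # TIS position of gene 1
  both2 <- pars_tis_profile(prof_all, ann, ann$gene_id)
  expect_equal(both2$value[both2$position == 0], 0.1)
  expect_equal(both2$n_genes[both2$position == 0], 2L)
})

test_that("region means skip missing values and flag empty regions", {
  ann1 <- mk_ann(1, utr5 = 3L, cds = 6L, utr3 = 2L)[1, ]
  prof <- c(0.1, 0.3, NA, 1, 1, 1, 1, 1, 1, 0.2, 0.4)
  expect_equal(pars_region_means(prof, ann1),
               c(mean_utr5 = 0.2, mean_cds = 1, mean_utr3 = 0.3))
  expect_equal(pars_region_means(rep(0.7, 11), ann1),
               c(mean_utr5 = 0.7, mean_cds = 0.7, mean_utr3 = 0.7))

  ann0 <- mk_ann(1, utr5 = 0L, cds = 6L, utr3 = 0L)[1, ]
  out <- pars_region_means(rep(0.5, 6), ann0)
  expect_true(is.na(out[["mean_utr5"]]) && is.na(out[["mean_utr3"]]))
  expect_error(pars_region_means(rep(0.5, 5), ann0), "does not match")
})

test_that("group feature comparison detects length shifts", {
  set.seed(33)
  bg <- rlnorm(400, log(52), 0.6)
  act <- rlnorm(400, log(80), 0.6)
  out <- compare_group_feature(list(activated = act, same = bg), bg)
  expect_lt(out$p[out$group == "activated"], 1e-6)
  expect_gt(out$p[out$group == "same"], 0.5)
  expect_gt(out$median[out$group == "activated"],
            out$median[out$group == "same"])

  tied <- compare_group_feature(list(g = rep(3, 4)), rep(3, 6))
  expect_equal(tied$U, 12)                     # n1*n2/2 under complete ties
  expect_error(compare_group_feature(list(g = numeric(0)), bg), "empty")
})
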