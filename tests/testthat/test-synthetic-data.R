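# Synthetic-data generators: determinism, ground-truth contracts, and
# agreement with the generative model's moment structure.

test_that("generators are deterministic given the master seed", {
  s1 <- simulate_annotation(80, seed = 7)
  s2 <- simulate_annotation(80, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_annotation(80, seed = 8)
  expect_false(identical(s1$annotation, s3$annotation))

  c1 <- simulate_counts(s1$annotation, s1$truth, seed = 7)
  c2 <- simulate_counts(s1$annotation, s1$truth, seed = 7)
  expect_identical(c1, c2)

  g1 <- simulate_gro(s1$annotation, s1$truth, seed = 7)
  expect_identical(g1, simulate_gro(s1$annotation, s1$truth, seed = 7))
})

test_that("annotation honors class proportions, lengths and invariants", {
  sim <- simulate_annotation(5000, seed = 3)
  ann <- sim$annotation; truth <- sim$truth

  expect_equal(nrow(ann), 5000)
  expect_identical(ann$gene_id, truth$gene_id)     # one truth row per gene
  expect_true(all(ann$cds_length %% 3 == 0 & ann$cds_length > 0))
  expect_identical(vapply(sim$pars, length, integer(1)),
                   setNames(ann$utr5_length + ann$cds_length + ann$utr3_length,
                            ann$gene_id))

  # multinomial convergence of class fractions (3 sd tolerance)
  pr <- default_class_proportions()
  obs <- table(factor(truth$true_class, names(pr))) / 5000
  tol <- 3 * sqrt(pr * (1 - pr) / 5000)
  expect_true(all(abs(obs - pr) <= pmax(tol, 1e-12)))

  # activated genes draw long 5'UTRs: sample median near the 80 nt target
  act <- ann$utr5_length[truth$true_class == "activated_buffered"]
  expect_gt(median(act), 72); expect_lt(median(act), 88)

  # effect-sign contract: TE drops for activated, rises for repressed
  expect_true(all(truth$true_log2fc_te[startsWith(truth$true_class, "activated")] < 0))
  expect_true(all(truth$true_log2fc_te[startsWith(truth$true_class, "repressed")] > 0))
  expect_true(all((truth$true_log2fc_te != 0) ==
                    (truth$true_class != "not_regulated")))
  expect_true(all(truth$base_mean > 0 & truth$dispersion > 0))
})

test_that("degenerate length scale collapses to the location", {
  lp <- default_length_params(sdlog = 0)
  for (cl in names(lp)) lp[[cl]]$utr5 <- c(90, 0)
  sim <- simulate_annotation(50, seed = 1, length_params = lp)
  expect_true(all(sim$annotation$utr5_length == 90L))
})

test_that("invalid generator arguments are rejected", {
  pr <- default_class_proportions()
  expect_error(simulate_annotation(10, class_proportions = pr * 0.9),
               "sum to 1")
  lp <- default_length_params()
  lp$not_regulated$cds <- c(-5, 0.5)
  expect_error(simulate_annotation(10, length_params = lp),
               "negative length parameter")
  ann <- mk_ann(3)
  truth <- mk_truth(ann)
  truth$gene_id[1] <- "other"
  expect_error(simulate_counts(ann, truth), "do not match")
})

test_that("counts follow the generative moment structure", {
  # null effects, (near-)zero dispersion, large base mean: condition means equal
  ann <- mk_ann(40)
  truth <- mk_truth(ann, base_mean = 5000, dispersion = 1e-9)
  cnt <- simulate_counts(ann, truth, n_reps = 30, seed = 2)
  m <- cnt$counts$counts
  cond <- cnt$counts$samples$condition
  for (g in seq_len(5)) {
    m0 <- mean(m[g, cond == "t0"]); m30 <- mean(m[g, cond == "t30"])
    se <- sqrt(5000 / sum(cond == "t0") + 5000 / sum(cond == "t30"))
    expect_lt(abs(m0 - m30), 3 * se)
  }
  expect_true(is_integer_matrix <- all(m >= 0 & m == round(m)))

  # a unit TE effect doubles the RPF ratio relative to the mRNA ratio
  ann1 <- mk_ann(1)
  truth1 <- mk_truth(ann1, class = "repressed_buffered", fc_te = 1,
                     base_mean = 2000, dispersion = 1e-3)
  cnt1 <- simulate_counts(ann1, truth1, n_reps = 150, seed = 3)
  s <- cnt1$counts$samples
  mm <- cnt1$counts$counts[1, ]
  ratio <- function(assay) mean(mm[s$assay == assay & s$condition == "t30"]) /
    mean(mm[s$assay == assay & s$condition == "t0"])
  expect_equal(ratio("RPF") / ratio("mRNA"), 2, tolerance = 0.05)
})

test_that("codon coverage partitions each gene's RPF count", {
  sim <- simulate_annotation(30, seed = 5)
  cnt <- simulate_counts(sim$annotation, sim$truth, seed = 5)
  s <- cnt$counts$samples
  for (sid in names(cnt$coverage)) {
    expect_equal(s$assay[s$sample_id == sid], "RPF")
    sums <- vapply(cnt$coverage[[sid]], sum, numeric(1))
    expect_equal(unname(sums), unname(cnt$counts$counts[names(sums), sid]))
  }
  # geometric 5' ramp concentrates footprints toward the start
  cnt_r <- simulate_counts(sim$annotation, sim$truth, seed = 5, ramp = 0.1)
  cov <- cnt_r$coverage[[1]]
  long <- names(cov)[vapply(cov, length, integer(1)) >= 60 &
                       vapply(cov, sum, numeric(1)) >= 50]
  frac_first <- vapply(cov[long], function(v)
    sum(v[1:20]) / sum(v), numeric(1))
  expect_gt(mean(frac_first), 0.5)
})

test_that("GRO records satisfy the rate identities and class effects", {
  sim <- simulate_annotation(2000, seed = 9)
  rec <- simulate_gro(sim$annotation, sim$truth, seed = 9)
  expect_equal(rec$RA, rec$SR * rec$HL)            # RA = SR x HL exactly
  expect_equal(rec$SR, rec$nTR / rec$cell_volume)

  # noise-free: every activated gene's SR ratio is exactly the multiplier
  rec0 <- simulate_gro(sim$annotation, sim$truth, noise_sd = 0, seed = 9)
  act <- sim$truth$gene_id[startsWith(sim$truth$true_class, "activated")]
  r0 <- rec0[rec0$condition == "t0", ]; r30 <- rec0[rec0$condition == "t30", ]
  i <- match(act, r0$gene_id)
  expect_equal(r30$SR[match(act, r30$gene_id)] / r0$SR[i], rep(0.5, length(act)))
  expect_equal(r30$HL[match(act, r30$gene_id)] / r0$HL[i], rep(2, length(act)))

  # with noise, the activated class still gains half-life (rank test)
  i0 <- match(sim$truth$gene_id, rec$gene_id[rec$condition == "t0"])
  hl0 <- rec$HL[rec$condition == "t0"][i0]
  hl30 <- rec$HL[rec$condition == "t30"][match(sim$truth$gene_id,
                                               rec$gene_id[rec$condition == "t30"])]
  act_sel <- startsWith(sim$truth$true_class, "activated")
  expect_gt(median(hl30[act_sel]), median(hl0[act_sel]))
  p <- mann_whitney(log2(hl30[act_sel] / hl0[act_sel]),
                    log2(hl30[!act_sel] / hl0[!act_sel]),
                    alternative = "greater")$p
  expect_lt(p, 0.01)

  expect_error(simulate_gro(sim$annotation, sim$truth, noise_sd = -1),
               ">= 0")
  bad <- list(not_regulated = c(sr = 0, hl = 1))
  expect_error(simulate_gro(sim$annotation, sim$truth,
                            effect_params = bad), "positive")
})
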