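## Pipeline orchestration: simulate -> analyze -> report, driven by one
## config object (or YAML file), fully deterministic given the seed.

#' Build a pipeline configuration
#'
#' Returns the default configuration, optionally overridden by a YAML
#' file (`key: value` form, nested sections allowed) and/or a list of
#' overrides; overrides win over the file, the file over the defaults.
#'
#' @param path optional YAML config file.
#' @param overrides optional named list of overrides (possibly nested).
#' @return validated configuration list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    simulation = list(n_genes = 1500, n_reps = 2,
                      class_proportions = as.list(default_class_proportions()),
                      te_magnitude = 1, dispersion = 0.1,
                      gro_noise_sd = 0.2, ramp = 0),
    te = list(fdr_cut = 0.05, buffer_threshold = 0.433, min_mean_count = 0,
              dispersion_prior_df = 20),
    metagene = list(n_bins = 100, mask_codons = 15, min_codons = 40,
                    min_group = 10),
    pars = list(up = 100, down = 300))
  if (!is.null(path)) cfg <- modifyList(cfg, yaml::read_yaml(path))
  cfg <- modifyList(cfg, overrides)
  stopifnot(cfg$te$fdr_cut > 0, cfg$te$fdr_cut < 1,
            cfg$te$buffer_threshold > 0,
            cfg$simulation$n_genes >= 1, cfg$simulation$n_reps >= 1)
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

bundle_paths <- function(dir) {
  list(counts = file.path(dir, "counts.tsv"),
       samples = file.path(dir, "samples.tsv"),
       gff3 = file.path(dir, "gene_models.gff3"),
       annotation = file.path(dir, "gene_models.tsv"),
       pars = file.path(dir, "pars_scores.tab"),
       coverage = file.path(dir, "codon_coverage.tsv"),
       gro = file.path(dir, "gro_records.tsv"),
       truth = file.path(dir, "truth.tsv"),
       manifest = file.path(dir, "manifest.txt"))
}

#' Simulate a complete dataset bundle to disk
#'
#' Generates annotation, structure profiles, counts, codon coverage, GRO
#' records and the ground-truth table, and writes them plus a manifest
#' (seed and parameter hash) to `outdir`. Identical configurations yield
#' byte-identical bundles.
#'
#' @param config configuration from [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
pipeline_simulate <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- bundle_paths(outdir)
  sim <- config$simulation
  ann <- simulate_annotation(
    n_genes = sim$n_genes,
    class_proportions = unlist(sim$class_proportions),
    seed = config$seed,
    effect_params = list(te_magnitude = sim$te_magnitude,
                         dispersion = sim$dispersion))
  cnt <- simulate_counts(ann$annotation, ann$truth, n_reps = sim$n_reps,
                         seed = config$seed, ramp = sim$ramp)
  gro <- simulate_gro(ann$annotation, ann$truth,
                      noise_sd = sim$gro_noise_sd, seed = config$seed)
  write_counts(cnt$counts, p$counts, p$samples)
  write_gene_models(ann$annotation, p$gff3, "gff3")
  write_gene_models(ann$annotation, p$annotation, "tsv")
  write_pars_scores(ann$pars, p$pars)
  write_codon_coverage(cnt$coverage, p$coverage)
  write_results(gro, p$gro)
  write_results(ann$truth, p$truth)
  writeLines(c(sprintf("seed: %d", as.integer(config$seed)),
               sprintf("param_hash: %s", config_hash(config))),
             p$manifest)
  invisible(p)
}

#' Analyze a dataset bundle
#'
#' Runs the full analysis on a simulated (or equivalently formatted)
#' bundle: TE interaction test and classification, codon-level RPF
#' metagenes and TIS-anchored structure metagenes per recovered class,
#' gene-architecture and structure feature comparisons against the
#' unregulated background, GRO rate comparisons, membrane enrichment,
#' and -- when a truth table is present -- class-recovery and overlap
#' statistics. All outputs are written as TSV; the analysis itself is
#' deterministic (no random stage), so reruns are byte-identical.
#'
#' @param config configuration from [pipeline_config()].
#' @param indir bundle directory from [pipeline_simulate()].
#' @param outdir results directory (created if needed).
#' @return invisibly, the results directory.
#' @export
pipeline_analyze <- function(config = pipeline_config(), indir, outdir) {
  p <- bundle_paths(indir)
  for (f in c(p$counts, p$samples, p$annotation, p$pars, p$coverage, p$gro))
    if (!file.exists(f)) fail("missing bundle artifact: %s", f)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  tab <- read_counts(p$counts, p$samples)
  annotation <- read_gene_models(p$annotation, "tsv")
  pars <- read_pars_scores(p$pars)
  coverage <- read_codon_coverage(p$coverage)
  gro <- read_results(p$gro)
  if (!setequal(rownames(tab$counts), annotation$gene_id))
    fail("gene ids of counts and annotation are inconsistent")

  note("te-test: %d genes, %d samples", nrow(tab$counts), ncol(tab$counts))
  te <- run_te_test(tab, min_mean_count = config$te$min_mean_count,
                    dispersion_prior_df = config$te$dispersion_prior_df)
  te <- classify_genes(te, fdr_cut = config$te$fdr_cut,
                       buffer_threshold = config$te$buffer_threshold)
  note("te-test: %d untested, %d failed fits, %d significant",
       attr(te, "n_untested"), attr(te, "n_failed"),
       sum(te$class_label != "not_regulated"))
  write_results(te, file.path(outdir, "te_results.tsv"))

  groups <- split(te$gene_id, te$class_label)
  big <- names(groups)[vapply(groups, length, integer(1)) >=
                         config$metagene$min_group]

  ## codon-level RPF metagenes per class
  mrna_fc <- setNames(2^ifelse(is.na(te$log2fc_mrna), 0, te$log2fc_mrna),
                      te$gene_id)
  meta_rows <- list()
  for (g in big) {
    prof <- rpf_metagene(coverage, tab$samples, mrna_fc, groups[[g]],
                         n_bins = config$metagene$n_bins,
                         min_codons = config$metagene$min_codons,
                         mask_codons = config$metagene$mask_codons)
    if (attr(prof, "n_excluded") > 0)
      note("metagene %s: %d gene(s) below min_codons", g,
           attr(prof, "n_excluded"))
    prof$group <- g
    meta_rows[[g]] <- prof
  }
  write_results(do.call(rbind, meta_rows), file.path(outdir, "metagene.tsv"))

  ## TIS-anchored structure metagenes per class
  tis_rows <- list()
  for (g in big) {
    prof <- pars_tis_profile(pars, annotation, groups[[g]],
                             up = config$pars$up, down = config$pars$down)
    if (attr(prof, "n_skipped") > 0)
      note("pars %s: %d gene(s) without profile", g, attr(prof, "n_skipped"))
    prof$group <- g
    tis_rows[[g]] <- prof
  }
  write_results(do.call(rbind, tis_rows), file.path(outdir, "pars_tis.tsv"))

  ## per-gene features and group comparisons vs background
  idx <- match(te$gene_id, annotation$gene_id)
  rmeans <- t(vapply(te$gene_id, function(g)
    pars_region_means(pars[[g]], annotation[match(g, annotation$gene_id), ]),
    numeric(3)))
  features <- data.frame(gene_id = te$gene_id,
                         utr5_length = annotation$utr5_length[idx],
                         cds_length = annotation$cds_length[idx],
                         utr3_length = annotation$utr3_length[idx],
                         rmeans, stringsAsFactors = FALSE)
  bg_genes <- groups[["not_regulated"]] %||% character(0)
  if (length(bg_genes) == 0) fail("no unregulated background genes")
  feat_rows <- list()
  for (feat in setdiff(names(features), "gene_id")) {
    v <- setNames(features[[feat]], features$gene_id)
    by_group <- lapply(groups[setdiff(big, "not_regulated")], function(ids) {
      x <- v[ids]; x[!is.na(x)]
    })
    cmp <- compare_group_feature(by_group, v[bg_genes][!is.na(v[bg_genes])])
    cmp$feature <- feat
    feat_rows[[feat]] <- cmp
  }
  write_results(do.call(rbind, feat_rows),
                file.path(outdir, "feature_stats.tsv"))

  ## GRO rate comparisons
  classes <- setNames(te$class_label, te$gene_id)
  rates_cmp <- group_rate_comparison(gro, classes)
  if (attr(rates_cmp, "n_incomplete") > 0)
    note("rates: %d gene(s) missing one condition", attr(rates_cmp, "n_incomplete"))
  write_results(rates_cmp, file.path(outdir, "rates_comparison.tsv"))

  ## membrane enrichment + optional truth-based recovery
  stats <- list()
  enr <- tryCatch(membrane_enrichment(te, annotation), error = function(e) NULL)
  if (!is.null(enr)) {
    stats[["membrane_enrichment_ratio"]] <- enr$ratio
  } else note("membrane enrichment not computable")
  if (file.exists(p$truth)) {
    truth <- read_results(p$truth)
    truth <- truth[match(te$gene_id, truth$gene_id), ]
    est_act <- te$gene_id[startsWith(te$class_label, "activated")]
    true_act <- te$gene_id[startsWith(truth$true_class, "activated")]
    if (length(est_act) && length(true_act)) {
      ov <- overlap_significance(est_act, true_act, te$gene_id)
      stats[["activated_overlap_k"]] <- ov$k
      stats[["activated_overlap_expected"]] <- ov$expected
      stats[["activated_overlap_p"]] <- ov$p
    }
    reg <- truth$true_class != "not_regulated"
    detected <- te$class_label != "not_regulated"
    stats[["regulated_detected_fraction"]] <-
      if (any(reg)) mean(detected[reg]) else NA_real_
    stats[["detected_correct_class_fraction"]] <-
      if (any(detected & reg))
        mean(te$class_label[detected & reg] == truth$true_class[detected & reg])
      else NA_real_
    stats[["false_positive_fraction"]] <-
      if (any(!reg)) mean(detected[!reg]) else NA_real_
  }
  write_results(data.frame(statistic = names(stats),
                           value = unname(unlist(stats)),
                           stringsAsFactors = FALSE),
                file.path(outdir, "summary_stats.tsv"))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Summarize a results bundle
#'
#' A pure function of the results directory: class counts (empty classes
#' reported as 0), per-class median effect sizes, and the headline
#' statistics, as a TSV plus a human-readable text report.
#'
#' @param resdir results directory from [pipeline_analyze()].
#' @param outdir where to write `report.tsv` / `report.txt` (default:
#'   `resdir`).
#' @return invisibly, the report table.
#' @export
pipeline_report <- function(resdir, outdir = resdir) {
  te_path <- file.path(resdir, "te_results.tsv")
  if (!file.exists(te_path)) fail("incomplete results bundle: missing %s", te_path)
  te <- read_results(te_path)
  counts <- vapply(TE_CLASSES, function(cl) sum(te$class_label == cl),
                   integer(1))
  med <- vapply(TE_CLASSES, function(cl) {
    v <- te$delta_te[te$class_label == cl]
    if (length(v)) median(v, na.rm = TRUE) else NA_real_
  }, numeric(1))
  report <- data.frame(class_label = TE_CLASSES, n_genes = unname(counts),
                       median_delta_te = unname(med),
                       stringsAsFactors = FALSE)
  write_results(report, file.path(outdir, "report.tsv"))
  lines <- c(sprintf("genes tested: %d", nrow(te)),
             sprintf("significant: %d", sum(te$class_label != "not_regulated")),
             sprintf("%-22s %6d  (median delta-TE %s)", report$class_label,
                     report$n_genes, fmt_num(report$median_delta_te)))
  sstats <- file.path(resdir, "summary_stats.tsv")
  if (file.exists(sstats)) {
    ss <- read_results(sstats)
    lines <- c(lines, sprintf("%-32s %s", ss$statistic, fmt_num(ss$value)))
  }
  writeLines(lines, file.path(outdir, "report.txt"))
  invisible(report)
}
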