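## Synthetic-data generators. The defaults encode the study conditions:
## two conditions (t0 = untreated, t30 = 30 min of regulator depletion),
## two replicates, NB-distributed mRNA/RPF counts with per-gene mRNA and
## TE effects, class-dependent gene architecture and 5'UTR structure, and
## GRO-style synthesis-rate/half-life records.

#' Default behavioral class proportions
#'
#' Five regulated subgroups plus the unregulated background. The overall
#' activated:repressed balance (6.5% vs 8.5% of genes) mirrors the ratio
#' of activated to repressed genes typically recovered at genome scale;
#' the split among subgroups is a free modeling choice.
#'
#' @return named numeric vector summing to 1.
#' @export
default_class_proportions <- function() {
  c(activated_buffered = 0.040, activated_decreased = 0.025,
    activated_increased = 0.000, repressed_buffered = 0.035,
    repressed_decreased = 0.035, repressed_increased = 0.015,
    not_regulated = 0.850)
}

#' Default per-class gene architecture parameters
#'
#' Region lengths are log-normal per class, parameterized by the median
#' (nt) and a log-scale spread. Medians follow the characteristic
#' contrasts between regulatory classes: translationally activated genes
#' have long 5'UTRs (80 nt) and CDSs (1555.5 nt) versus the background
#' (52 and 1113 nt); repressed genes are shorter (44/753 and 35.5/600 nt
#' for buffered and mRNA-decreased subgroups), and only the
#' repressed-buffered subgroup has an extended 3'UTR (128 vs 105 nt).
#'
#' @param sdlog common log-scale spread of all regions (default 0.6).
#' @return named list: per class, a list with `utr5`, `cds`, `utr3`, each
#'   `c(median, sdlog)`.
#' @export
default_length_params <- function(sdlog = 0.6) {
  spec <- list(
    activated_buffered  = c(80, 1555.5, 105),
    activated_decreased = c(80, 1555.5, 105),
    activated_increased = c(80, 1555.5, 105),
    repressed_buffered  = c(44, 753, 128),
    repressed_decreased = c(35.5, 600, 105),
    repressed_increased = c(44, 753, 105),
    not_regulated       = c(52, 1113, 105))
  lapply(spec, function(v)
    list(utr5 = c(v[1], sdlog), cds = c(v[2], sdlog), utr3 = c(v[3], sdlog)))
}

#' Default per-class PARS structure parameters
#'
#' Each transcript's structure profile is a per-region baseline plus a
#' per-gene offset, a class-specific additive level in the TIS window
#' `[-100, +50]` nt, i.i.d. Gaussian noise, and -- for every class except
#' the activated ones -- a "dip" (score reduction) in `[-20, 0]` that
#' mimics the unstructured window ribosomes need at genuine start sites.
#' Activated transcripts keep their structure right through the TIS.
#' Region baselines follow the class contrasts: 5'UTR 0.16 (activated)
#' vs 0.06 (background) vs 0.03 (repressed, mRNA down); CDS 0.32--0.35
#' (regulated) vs 0.25 (background).
#'
#' @return named list of per-class parameter lists.
#' @export
default_structure_params <- function() {
  mk <- function(utr5, cds, utr3, tis, dip) {
    list(utr5_level = utr5, cds_level = cds, utr3_level = utr3,
         tis_level = tis, tis_window = c(-100, 50),
         dip_depth = dip, dip_window = c(-20, 0),
         gene_sd = 0.1, noise_sd = 0.5, missing_rate = 0.02)
  }
  list(
    activated_buffered  = mk(0.16, 0.35, 0.10, 0.05, 0.00),
    activated_decreased = mk(0.16, 0.35, 0.10, 0.05, 0.00),
    activated_increased = mk(0.16, 0.35, 0.10, 0.05, 0.00),
    repressed_buffered  = mk(0.06, 0.32, 0.10, 0.00, 0.30),
    repressed_decreased = mk(0.03, 0.32, 0.10, 0.00, 0.30),
    repressed_increased = mk(0.06, 0.32, 0.10, 0.00, 0.30),
    not_regulated       = mk(0.06, 0.25, 0.10, 0.00, 0.30))
}

## Truncated-normal draw via inverse CDF (deterministic given RNG state).
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate gene annotation, structure profiles and ground truth
#'
#' Draws a behavioral class per gene, then class-conditional region
#' lengths (log-normal), membrane/SRP labels, per-nucleotide structure
#' scores, and the true mRNA and TE log2 fold changes that the count
#' generator will impose. Activated classes carry negative TE effects
#' (translational efficiency falls when the activator is depleted),
#' repressed classes positive ones.
#'
#' @param n_genes number of genes (>= 1).
#' @param class_proportions named class fractions summing to 1.
#' @param seed master seed; all draws derive from it.
#' @param length_params per-class region length parameters, see
#'   [default_length_params()].
#' @param structure_params per-class structure parameters, see
#'   [default_structure_params()].
#' @param effect_params list with `te_magnitude` (|log2 TE change| of
#'   regulated genes, default 1), `mrna_buffered_sd`, `mrna_shift_range`,
#'   `base_mean_meanlog`, `base_mean_sdlog`, `dispersion`.
#' @param membrane_probs per-class probability of encoding a membrane
#'   protein (defaults: 0.5 for activated classes, 0.25 otherwise).
#' @return list with `annotation` ([gene_annotation]), `pars` (named list
#'   of score vectors) and `truth` (data frame: `gene_id`, `true_class`,
#'   `true_log2fc_mrna`, `true_log2fc_te`, `base_mean`, `dispersion`).
#' @export
simulate_annotation <- function(n_genes,
                                class_proportions = default_class_proportions(),
                                seed = 1,
                                length_params = default_length_params(),
                                structure_params = default_structure_params(),
                                effect_params = list(),
                                membrane_probs = NULL) {
  stopifnot(n_genes >= 1)
  pr <- class_proportions
  if (is.null(names(pr)) || !all(names(pr) %in% TE_CLASSES))
    fail("class_proportions must be named by behavioral class")
  if (any(pr < 0)) fail("class proportions must be non-negative")
  if (abs(sum(pr) - 1) > 1e-9) fail("class proportions must sum to 1")
  for (cl in names(length_params))
    for (reg in c("utr5", "cds", "utr3")) {
      pars <- length_params[[cl]][[reg]]
      if (any(pars < 0)) fail("negative length parameter for %s/%s", cl, reg)
    }
  ep <- modifyList(list(te_magnitude = 1, mrna_buffered_sd = 0.15,
                        mrna_shift_range = c(0.55, 1.6),
                        base_mean_meanlog = log(200), base_mean_sdlog = 0.8,
                        dispersion = 0.1), effect_params)
  if (is.null(membrane_probs)) {
    membrane_probs <- setNames(rep(0.25, length(TE_CLASSES)), TE_CLASSES)
    membrane_probs[startsWith(TE_CLASSES, "activated")] <- 0.5
  }

  set.seed(derive_seed(seed, "annotation"))
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  classes <- sample(names(pr), n_genes, replace = TRUE, prob = pr)

  draw_len <- function(cl, reg, n) {
    p <- length_params[[cl]][[reg]]
    round(rlnorm(n, meanlog = log(max(p[1], 1e-12)), sdlog = p[2]))
  }
  utr5 <- integer(n_genes); cds <- integer(n_genes); utr3 <- integer(n_genes)
  for (cl in unique(classes)) {
    i <- which(classes == cl)
    utr5[i] <- as.integer(draw_len(cl, "utr5", length(i)))
    raw_cds <- draw_len(cl, "cds", length(i))
    cds[i] <- pmax(3L, as.integer(3 * round(raw_cds / 3)))
    utr3[i] <- as.integer(draw_len(cl, "utr3", length(i)))
  }
  is_membrane <- runif(n_genes) < membrane_probs[classes]
  srp_class <- ifelse(is_membrane,
                      ifelse(runif(n_genes) < 0.5, "dependent", "independent"),
                      "unknown")
  annotation <- gene_annotation(data.frame(
    gene_id = gene_id, utr5_length = utr5, cds_length = cds,
    utr3_length = utr3, is_membrane = is_membrane, srp_class = srp_class,
    stringsAsFactors = FALSE))

  ## ground-truth effects
  set.seed(derive_seed(seed, "effects"))
  fc_mrna <- numeric(n_genes)
  fc_te <- numeric(n_genes)
  buffered <- grepl("buffered", classes)
  decreased <- grepl("decreased", classes)
  increased <- grepl("increased", classes)
  background <- classes == "not_regulated"
  fc_mrna[buffered] <- rtnorm(sum(buffered), 0, ep$mrna_buffered_sd, -0.4, 0.4)
  fc_mrna[decreased] <- -runif(sum(decreased), ep$mrna_shift_range[1],
                               ep$mrna_shift_range[2])
  fc_mrna[increased] <- runif(sum(increased), ep$mrna_shift_range[1],
                              ep$mrna_shift_range[2])
  fc_mrna[background] <- rnorm(sum(background), 0, 0.1)
  fc_te[startsWith(classes, "activated")] <- -ep$te_magnitude
  fc_te[startsWith(classes, "repressed")] <- ep$te_magnitude
  base_mean <- rlnorm(n_genes, ep$base_mean_meanlog, ep$base_mean_sdlog)
  truth <- data.frame(gene_id = gene_id, true_class = classes,
                      true_log2fc_mrna = fc_mrna, true_log2fc_te = fc_te,
                      base_mean = base_mean,
                      dispersion = rep(ep$dispersion, n_genes),
                      stringsAsFactors = FALSE)

  ## per-nucleotide structure profiles
  set.seed(derive_seed(seed, "pars"))
  pars <- vector("list", n_genes)
  names(pars) <- gene_id
  for (g in seq_len(n_genes)) {
    sp <- structure_params[[classes[g]]]
    len <- utr5[g] + cds[g] + utr3[g]
    region <- rep(c(sp$utr5_level, sp$cds_level, sp$utr3_level),
                  times = c(utr5[g], cds[g], utr3[g]))
    pos <- seq_len(len) - utr5[g] - 1L   # 0 = first CDS nucleotide
    tis <- pos >= sp$tis_window[1] & pos <= sp$tis_window[2]
    dip <- pos >= sp$dip_window[1] & pos <= sp$dip_window[2]
    scores <- region + rnorm(1, 0, sp$gene_sd) +
      sp$tis_level * tis - sp$dip_depth * dip +
      rnorm(len, 0, sp$noise_sd)
    if (sp$missing_rate > 0)
      scores[runif(len) < sp$missing_rate] <- NA_real_
    pars[[g]] <- scores
  }
  list(annotation = annotation, pars = pars, truth = truth)
}

#' Simulate mRNA/RPF counts and codon-level coverage
#'
#' Counts are drawn NB(mu, alpha) per gene and sample with
#' \eqn{\log_2 \mu} shifted by the true mRNA log2 fold change at t30 and,
#' for RPF samples, additionally by the true TE log2 fold change. Codon
#' coverage for each gene and RPF sample is multinomial over its codons
#' conditioned on the gene's RPF count, uniform by default or with a
#' geometric 5' ramp.
#'
#' @param annotation [gene_annotation] (supplies codon counts).
#' @param truth truth table from [simulate_annotation()].
#' @param n_reps replicates per assay and condition (default 2).
#' @param library_sizes optional named per-sample relative depths;
#'   normalized internally to geometric mean 1.
#' @param seed master seed.
#' @param ramp geometric 5' ramp parameter in `[0, 1)`; 0 = uniform codon
#'   usage.
#' @return list with `counts` ([count_table]) and `coverage` (nested list
#'   `coverage[[sample_id]][[gene_id]]` of per-codon counts for RPF
#'   samples).
#' @export
simulate_counts <- function(annotation, truth, n_reps = 2,
                            library_sizes = NULL, seed = 1, ramp = 0) {
  stopifnot(n_reps >= 1, ramp >= 0, ramp < 1)
  if (!identical(annotation$gene_id, truth$gene_id))
    fail("annotation and truth gene ids do not match")
  samples <- expand.grid(replicate = seq_len(n_reps),
                         condition = CONDITIONS, assay = ASSAYS,
                         stringsAsFactors = FALSE)[, 3:1]
  samples$sample_id <- sprintf("%s_%s_r%d", samples$assay,
                               samples$condition, samples$replicate)
  samples <- samples[, c("sample_id", "assay", "condition", "replicate")]
  if (is.null(library_sizes)) library_sizes <- setNames(
    rep(1, nrow(samples)), samples$sample_id)
  if (any(library_sizes <= 0)) fail("library sizes must be positive")
  if (!all(samples$sample_id %in% names(library_sizes)))
    fail("library_sizes must name every sample")
  s <- library_sizes[samples$sample_id]
  s <- s / exp(mean(log(s)))

  a <- as.numeric(samples$assay == "RPF")
  cnd <- as.numeric(samples$condition == "t30")
  lfc <- outer(truth$true_log2fc_mrna, cnd) +
    outer(truth$true_log2fc_te, cnd * a)
  mu <- truth$base_mean * 2^lfc
  mu <- sweep(mu, 2, s, `*`)

  set.seed(derive_seed(seed, "counts"))
  n <- length(mu)
  disp <- rep(truth$dispersion, times = ncol(mu))
  counts <- integer(n)
  pois <- disp <= 1e-8
  counts[pois] <- rpois(sum(pois), as.vector(mu)[pois])
  counts[!pois] <- rnbinom(sum(!pois), mu = as.vector(mu)[!pois],
                           size = 1 / disp[!pois])
  counts <- matrix(counts, nrow = nrow(mu),
                   dimnames = list(truth$gene_id, samples$sample_id))
  tab <- count_table(counts, samples)

  ## codon coverage, RPF samples only
  set.seed(derive_seed(seed, "coverage"))
  n_codons <- annotation$cds_length %/% 3L
  coverage <- list()
  for (j in which(samples$assay == "RPF")) {
    sid <- samples$sample_id[j]
    per_gene <- vector("list", nrow(annotation))
    names(per_gene) <- annotation$gene_id
    for (g in seq_len(nrow(annotation))) {
      k <- n_codons[g]
      prob <- if (ramp > 0) (1 - ramp)^(seq_len(k) - 1) else rep(1, k)
      per_gene[[g]] <- as.integer(rmultinom(1, counts[g, j], prob))
    }
    coverage[[sid]] <- per_gene
  }
  list(counts = tab, coverage = coverage)
}

#' Simulate genomic run-on rate records
#'
#' Baseline synthesis rates (SR) and half-lives (HL) are log-normal per
#' gene; at t30 each class's SR and HL are scaled by class multipliers
#' with log-normal noise. Abundance is RA = SR x HL by construction and
#' the nascent transcription rate is nTR = SR x cell volume, so the rate
#' identities hold exactly on every record. Default multipliers encode
#' the signature of the translationally activated class: synthesis drops
#' (x0.5) while half-life rises (x2) upon depletion of the regulator;
#' all other classes are unchanged.
#'
#' @param annotation [gene_annotation].
#' @param truth truth table (supplies classes).
#' @param effect_params named list per class: `c(sr = ..., hl = ...)`
#'   multipliers applied at t30 (must be positive).
#' @param noise_sd log-scale SD of multiplicative noise at t30 (>= 0;
#'   exactly 0 gives the noise-free construction).
#' @param seed master seed.
#' @param cell_volume named vector `c(t0 = ..., t30 = ...)` of average
#'   cell volumes (a.u.).
#' @return data frame of rate records: `gene_id`, `condition`, `nTR`,
#'   `cell_volume`, `SR`, `RA`, `HL`.
#' @export
simulate_gro <- function(annotation, truth, effect_params = NULL,
                         noise_sd = 0.2, seed = 1,
                         cell_volume = c(t0 = 1, t30 = 1)) {
  if (!identical(annotation$gene_id, truth$gene_id))
    fail("annotation and truth gene ids do not match")
  if (noise_sd < 0) fail("noise_sd must be >= 0")
  if (is.null(effect_params)) {
    effect_params <- setNames(rep(list(c(sr = 1, hl = 1)), length(TE_CLASSES)),
                              TE_CLASSES)
    for (cl in TE_CLASSES[startsWith(TE_CLASSES, "activated")])
      effect_params[[cl]] <- c(sr = 0.5, hl = 2)
  }
  mult <- vapply(effect_params, function(x) c(x[["sr"]], x[["hl"]]),
                 numeric(2))
  if (any(mult <= 0)) fail("effect multipliers must be positive")

  set.seed(derive_seed(seed, "gro"))
  n <- nrow(truth)
  sr0 <- rlnorm(n, 0, 0.7)
  hl0 <- rlnorm(n, 0, 0.7)
  noise <- function() if (noise_sd == 0) rep(1, n) else rlnorm(n, 0, noise_sd)
  sr30 <- sr0 * mult[1, truth$true_class] * noise()
  hl30 <- hl0 * mult[2, truth$true_class] * noise()
  rec <- function(cond, sr, hl) {
    v <- cell_volume[[cond]]
    data.frame(gene_id = truth$gene_id, condition = cond, nTR = sr * v,
               cell_volume = v, SR = sr, RA = sr * hl, HL = hl,
               stringsAsFactors = FALSE)
  }
  out <- rbind(rec("t0", sr0, hl0), rec("t30", sr30, hl30))
  rownames(out) <- NULL
  out
}
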