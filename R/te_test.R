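## Differential translation-efficiency testing and behavioral
## classification: the package's headline computation.

#' Per-gene differential translation-efficiency test
#'
#' Fits, for every gene, the negative-binomial GLM
#' \deqn{\log \mu_j = \log s_j + \beta_0 + \beta_A A_j + \beta_C C_j +
#'   \beta_I A_j C_j}
#' (A = 1 for RPF samples, C = 1 for the perturbed condition t30) with
#' median-of-ratios size factors \eqn{s_j} computed once on the combined
#' mRNA+RPF matrix, and tests the interaction coefficient \eqn{\beta_I}
#' -- the log change of translational efficiency -- with a Wald test.
#' P-values are adjusted by Benjamini-Hochberg across all tested genes.
#'
#' Dispersion is estimated per gene by method of moments
#' ([estimate_dispersion()]) and moderated toward the across-gene mean
#' with weight `residual df / (residual df + dispersion_prior_df)`; with
#' few replicates the raw per-gene estimator is too noisy for a
#' calibrated Wald test, and this moderation restores nominal type-I
#' error without a full empirical-Bayes dispersion machinery.
#'
#' Genes whose mean raw count does not exceed `min_mean_count`, and genes
#' whose fit fails or does not converge, receive missing statistics
#' (never aborting the run) and are labelled `not_regulated`.
#'
#' @param table a [count_table] containing both assays and conditions.
#' @param min_mean_count genes with mean raw count <= this are not tested
#'   (default 0, which drops all-zero genes only).
#' @param dispersion_prior_df prior degrees of freedom of the dispersion
#'   moderation (default 20; 0 disables moderation).
#' @return data frame of class `te_result`: `gene_id`, `log2fc_mrna`,
#'   `log2fc_rpf`, `delta_te` (= `log2fc_rpf - log2fc_mrna`), `wald_z`,
#'   `p`, `fdr`, `class_label` (all `not_regulated` until
#'   [classify_genes()] is applied -- which this function calls with
#'   default thresholds).
#' @export
run_te_test <- function(table, min_mean_count = 0, dispersion_prior_df = 20) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  s <- table$samples
  a <- as.numeric(s$assay == "RPF")
  cnd <- as.numeric(s$condition == "t30")
  design <- cbind(intercept = 1, assay = a, condition = cnd,
                  interaction = a * cnd)
  sf <- size_factors(m)
  offsets <- log(sf)
  cells <- factor(paste(s$assay, s$condition))
  resid_df <- ncol(m) - nlevels(cells)

  tested <- rowMeans(m) > min_mean_count
  alpha_raw <- rep(NA_real_, nrow(m))
  for (g in which(tested))
    alpha_raw[g] <- estimate_dispersion(m[g, ], cells, sf)
  alpha0 <- mean(alpha_raw[tested])
  w <- resid_df / (resid_df + dispersion_prior_df)
  alpha_mod <- w * alpha_raw + (1 - w) * alpha0

  n <- nrow(m)
  out <- data.frame(gene_id = rownames(m),
                    log2fc_mrna = NA_real_, log2fc_rpf = NA_real_,
                    delta_te = NA_real_, wald_z = NA_real_,
                    p = NA_real_, fdr = NA_real_,
                    class_label = rep("not_regulated", n),
                    stringsAsFactors = FALSE)
  n_failed <- 0L
  for (g in which(tested)) {
    fit <- tryCatch(nb_glm_fit(m[g, ], design, offsets, alpha_mod[g]),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
    b <- fit$coefficients
    out$log2fc_mrna[g] <- b[["condition"]] / log(2)
    out$log2fc_rpf[g] <- (b[["condition"]] + b[["interaction"]]) / log(2)
    out$delta_te[g] <- b[["interaction"]] / log(2)
    wt <- wald_test(fit, "interaction")
    out$wald_z[g] <- wt$z
    out$p[g] <- wt$p
  }
  out$fdr <- bh_fdr(out$p)
  attr(out, "n_untested") <- sum(!tested)
  attr(out, "n_failed") <- n_failed
  class(out) <- c("te_result", "data.frame")
  classify_genes(out)
}

#' Classify genes into behavioral subgroups
#'
#' A gene is significant when `fdr < fdr_cut` (strictly). Direction:
#' `activated_*` when `delta_te < 0` (translational efficiency falls when
#' the activator is depleted), `repressed_*` when `delta_te > 0`. mRNA
#' status: `buffered` when `|log2fc_mrna| < buffer_threshold` (strictly),
#' `decreased` when `log2fc_mrna <= -buffer_threshold`, `increased` when
#' `>= +buffer_threshold`. Everything else -- non-significant genes and
#' genes with missing statistics -- is `not_regulated`. The default
#' buffering boundary 0.433 log2 units corresponds to a +/-35% mRNA
#' change ([buffering_threshold()]).
#'
#' @param results a `te_result` data frame from [run_te_test()].
#' @param fdr_cut significance cutoff on the adjusted p-value (default
#'   0.05).
#' @param buffer_threshold buffering boundary in log2 units (default
#'   0.433).
#' @return `results` with `class_label` filled in.
#' @export
classify_genes <- function(results, fdr_cut = 0.05, buffer_threshold = 0.433) {
  stopifnot(fdr_cut > 0, fdr_cut < 1, buffer_threshold > 0)
  sig <- !is.na(results$fdr) & results$fdr < fdr_cut &
    !is.na(results$delta_te) & results$delta_te != 0 &
    !is.na(results$log2fc_mrna)
  direction <- ifelse(results$delta_te < 0, "activated", "repressed")
  status <- ifelse(abs(results$log2fc_mrna) < buffer_threshold, "buffered",
                   ifelse(results$log2fc_mrna <= -buffer_threshold,
                          "decreased", "increased"))
  results$class_label <- ifelse(sig, paste(direction, status, sep = "_"),
                                "not_regulated")
  results
}

#' Log2 buffering threshold for a fold-change boundary
#'
#' mRNA levels are called buffered when their fold change stays within a
#' boundary; a +/-35% change corresponds to `log2(1.35) = 0.433` log2
#' units, the default classification threshold.
#'
#' @param fold_change linear fold-change boundary (default 1.35).
#' @return threshold in log2 units.
#' @export
#' @examples
#' buffering_threshold()        # 0.433 (to 3 decimals)
buffering_threshold <- function(fold_change = 1.35) {
  stopifnot(fold_change > 0)
  abs(log2(fold_change))
}

#' Hypergeometric significance of a gene-set overlap
#'
#' @param setA,setB gene id vectors, both subsets of `universe`.
#' @param universe gene id vector.
#' @return list with `k` (observed overlap), `expected`
#'   (`|A||B|/|U|`) and upper-tail hypergeometric `p`.
#' @export
overlap_significance <- function(setA, setB, universe) {
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  out <- setdiff(c(setA, setB), universe)
  if (length(out))
    fail("set element(s) outside universe: %s",
         paste(head(out, 3), collapse = ", "))
  k <- length(intersect(setA, setB))
  list(k = k,
       expected = length(setA) * length(setB) / length(universe),
       p = hypergeom_overlap_p(k, length(setA), length(setB),
                               length(universe)))
}

#' Membrane enrichment of translationally activated genes
#'
#' Builds the 2x2 table membrane-vs-not by activated-vs-not-dependent
#' (genes classified `not_regulated`) and reports how much more likely
#' activated transcripts are to encode membrane proteins.
#'
#' @param results a `te_result` data frame with class labels.
#' @param annotation a [gene_annotation] carrying `is_membrane`.
#' @return list with `ratio` and the 2x2 `table` (a, b, c, d as counts
#'   membrane/non-membrane x activated/not-dependent).
#' @export
membrane_enrichment <- function(results, annotation) {
  i <- match(results$gene_id, annotation$gene_id)
  if (anyNA(i)) fail("results contain genes absent from the annotation")
  memb <- annotation$is_membrane[i]
  if (all(is.na(memb))) fail("annotation carries no membrane labels")
  activated <- startsWith(results$class_label, "activated")
  notdep <- results$class_label == "not_regulated"
  ok <- !is.na(memb)
  a <- sum(activated & memb & ok); b <- sum(activated & !memb & ok)
  cc <- sum(notdep & memb & ok); d <- sum(notdep & !memb & ok)
  if (a + b == 0) fail("no translationally activated genes")
  if (cc + d == 0) fail("no unregulated background genes")
  list(ratio = relative_enrichment(a, b, cc, d),
       table = matrix(c(a, b, cc, d), 2, 2,
                      dimnames = list(c("membrane", "non_membrane"),
                                      c("activated", "not_dependent"))))
}
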