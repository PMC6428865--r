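## Positional analyses: codon-level RPF metagenes, TIS-anchored PARS
## metagenes, region-average structure scores, and group feature
## comparisons.

#' Mask the start-proximal codons of a coverage vector
#'
#' The first codons after the start site carry elongation-inhibitor
#' artefacts and are discarded before any footprint-density analysis.
#' Genes with no codons left are excluded (empty coverage), not an
#' error.
#'
#' @param cov per-codon counts of one gene (integer vector).
#' @param n_codons number of leading codons to drop (default 15).
#' @return the retained tail of `cov` (possibly empty).
#' @export
mask_start_region <- function(cov, n_codons = 15) {
  stopifnot(n_codons >= 0)
  if (length(cov) <= n_codons) return(cov[0])
  cov[(n_codons + 1):length(cov)]
}

## Average a per-codon step function over n equal-width relative bins.
## Each codon is the interval [(i-1)/L, i/L); the bin value is the
## overlap-weighted mean, so every bin is defined for any gene length
## and a constant vector maps to a constant profile.
bin_relative <- function(x, n_bins) {
  len <- length(x)
  cum <- c(0, cumsum(x)) / len          # integral of the step function
  S <- function(t) {
    tl <- t * len
    k <- pmin(floor(tl), len - 1)
    cum[k + 1] + (tl - k) * x[k + 1] / len
  }
  edges <- seq(0, 1, length.out = n_bins + 1)
  diff(S(edges)) * n_bins
}

#' Codon-level RPF metagene profile of a gene group
#'
#' Per gene and RPF sample, start-proximal codons are masked and each
#' retained codon count is normalized observed/expected, where the
#' expected count is uniform usage of the sample's library total over
#' all retained codons of the analysis set -- every gene with coverage,
#' not only the profiled group
#' (`expected = library_total_j / total retained codons`); this keeps
#' profiles comparable across samples and genes while preserving level
#' differences between genes, groups and conditions. Normalized values are
#' averaged over replicates per condition, the t30 values of each gene
#' are divided by that gene's linear mRNA fold change, codon positions
#' are mapped to `n_bins` equal-width relative bins along the CDS, and
#' bins are averaged over genes.
#'
#' @param coverages nested list `coverages[[sample_id]][[gene_id]]` of
#'   per-codon counts (RPF samples).
#' @param meta sample metadata (data frame with `sample_id`, `assay`,
#'   `condition`, `replicate`) covering every coverage sample.
#' @param mrna_fc named per-gene linear mRNA fold change t30/t0 (> 0).
#' @param group gene ids to profile.
#' @param n_bins number of relative-position bins (default 100).
#' @param min_codons genes with fewer retained codons are excluded, with
#'   the count recorded in attribute `n_excluded` (default 40).
#' @param mask_codons leading codons masked per gene (default 15).
#' @return data frame (`metagene_profile`): `axis`, `position` (bin),
#'   `value`, `n_genes`, `condition`.
#' @export
rpf_metagene <- function(coverages, meta, mrna_fc, group, n_bins = 100,
                         min_codons = 40, mask_codons = 15) {
  meta <- as.data.frame(meta)
  samp <- names(coverages)
  mi <- match(samp, meta$sample_id)
  if (anyNA(mi)) fail("coverage sample(s) missing from metadata: %s",
                      paste(samp[is.na(mi)], collapse = ", "))
  cond <- setNames(as.character(meta$condition)[mi], samp)

  for (sid in samp) {
    missing <- setdiff(group, names(coverages[[sid]]))
    if (length(missing))
      fail("group gene(s) without coverage in %s: %s", sid,
           paste(head(missing, 3), collapse = ", "))
  }
  if (!all(group %in% names(mrna_fc)))
    fail("mrna_fc must name every group gene")
  if (any(!is.finite(mrna_fc[group]) | mrna_fc[group] <= 0))
    fail("mrna_fc must be positive for all group genes")

  ## retained (masked) coverage per sample x gene; the expectation is
  ## computed over the whole analysis set (every gene with coverage), so
  ## a group-wide footprint change is preserved, not normalized away
  retained <- lapply(coverages, function(per)
    lapply(per, mask_start_region, n_codons = mask_codons))
  keep <- vapply(retained[[1]][group], length, integer(1)) >= min_codons
  n_excluded <- sum(!keep)
  genes <- group[keep]
  if (length(genes) == 0) fail("no gene passes the min_codons filter")

  total_codons <- sum(vapply(retained[[1]], length, integer(1)))
  lib_total <- vapply(samp, function(sid)
    sum(unlist(retained[[sid]], use.names = FALSE)), numeric(1))
  if (any(lib_total <= 0)) fail("zero library total in sample %s",
                                samp[which(lib_total <= 0)[1]])

  out <- list()
  for (cn in unique(cond)) {
    sids <- samp[cond == cn]
    acc <- matrix(0, length(genes), n_bins)
    for (g in seq_along(genes)) {
      gene <- genes[g]
      len <- length(retained[[sids[1]]][[gene]])
      norm <- rep(0, len)
      for (sid in sids) {
        expected <- lib_total[[sid]] / total_codons
        norm <- norm + retained[[sid]][[gene]] / expected
      }
      norm <- norm / length(sids)
      if (cn == "t30") norm <- norm / mrna_fc[[gene]]
      acc[g, ] <- bin_relative(norm, n_bins)
    }
    out[[cn]] <- data.frame(axis = "codon_bins", position = 1:n_bins,
                            value = colMeans(acc),
                            n_genes = length(genes), condition = cn,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  class(res) <- c("metagene_profile", "data.frame")
  res
}

#' TIS-anchored structure-score metagene
#'
#' Aligns the structure profiles of a gene group at the translation
#' initiation site (position 0 = first CDS nucleotide) and averages the
#' available scores per position, skipping missing values. Genes
#' contribute upstream positions only as far as their 5'UTR extends and
#' downstream positions only as far as their CDS extends; `n_genes`
#' counts the genes covering each position.
#'
#' @param profiles named list of per-nucleotide score vectors.
#' @param annotation a [gene_annotation] matching the profiles.
#' @param group gene ids to profile.
#' @param up nucleotides of 5'UTR upstream of the TIS (default 100).
#' @param down nucleotides of CDS downstream of the TIS (default 300).
#' @return data frame (`metagene_profile`): `axis`, `position`
#'   (`-up .. down - 1`), `value`, `n_genes`.
#' @export
pars_tis_profile <- function(profiles, annotation, group, up = 100,
                             down = 300) {
  idx <- match(group, annotation$gene_id)
  if (anyNA(idx)) fail("group gene(s) missing from annotation: %s",
                       paste(head(group[is.na(idx)], 3), collapse = ", "))
  have <- group %in% names(profiles)
  n_skipped <- sum(!have)
  group <- group[have]; idx <- idx[have]
  if (length(group) == 0) fail("no group gene has a structure profile")
  validate_pars_profiles(profiles[group], annotation)

  positions <- seq(-up, down - 1)
  sums <- numeric(length(positions))
  n_obs <- integer(length(positions))   # non-missing scores
  n_cov <- integer(length(positions))   # genes covering the position
  for (g in seq_along(group)) {
    u5 <- annotation$utr5_length[idx[g]]
    cd <- annotation$cds_length[idx[g]]
    p <- profiles[[group[g]]]
    ci <- which(positions >= -min(u5, up) & positions < min(cd, down))
    vals <- p[u5 + positions[ci] + 1L]
    ok <- !is.na(vals)
    sums[ci[ok]] <- sums[ci[ok]] + vals[ok]
    n_obs[ci[ok]] <- n_obs[ci[ok]] + 1L
    n_cov[ci] <- n_cov[ci] + 1L
  }
  value <- ifelse(n_obs > 0, sums / n_obs, NA_real_)
  res <- data.frame(axis = "nt_relative_to_TIS", position = positions,
                    value = value, n_genes = n_cov,
                    stringsAsFactors = FALSE)
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("metagene_profile", "data.frame")
  res
}

#' Region-average structure scores of one transcript
#'
#' Arithmetic mean of the profile over the 5'UTR, CDS and 3'UTR, with
#' missing values skipped; a region of length zero yields `NA`.
#'
#' @param profile per-nucleotide score vector of one gene.
#' @param annotation_row one-row [gene_annotation] (or a row of one).
#' @return named numeric vector `c(mean_utr5, mean_cds, mean_utr3)`.
#' @export
pars_region_means <- function(profile, annotation_row) {
  u5 <- annotation_row$utr5_length[1]
  cd <- annotation_row$cds_length[1]
  u3 <- annotation_row$utr3_length[1]
  if (length(profile) != u5 + cd + u3)
    fail("profile length %d does not match annotation (%d)",
         length(profile), u5 + cd + u3)
  reg_mean <- function(from, len) {
    if (len == 0) return(NA_real_)
    mean(profile[from:(from + len - 1)], na.rm = TRUE)
  }
  out <- c(mean_utr5 = reg_mean(1, u5),
           mean_cds = reg_mean(u5 + 1, cd),
           mean_utr3 = reg_mean(u5 + cd + 1, u3))
  out[is.nan(out)] <- NA_real_
  out
}

#' Compare a per-gene feature between groups and a background
#'
#' Reports mean and median per group plus a two-sided Wilcoxon-Mann-
#' Whitney p-value of each group against the background vector.
#'
#' @param values_by_group named list of numeric vectors (one per group).
#' @param background numeric vector of background values.
#' @return data frame: `group`, `n`, `mean`, `median`, `U`, `p`.
#' @export
compare_group_feature <- function(values_by_group, background) {
  if (length(background) == 0) fail("background must be non-empty")
  rows <- lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    if (length(v) == 0) fail("group '%s' is empty", g)
    mw <- mann_whitney(v, background, alternative = "two.sided")
    data.frame(group = g, n = length(v), mean = mean(v),
               median = median(v), U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
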