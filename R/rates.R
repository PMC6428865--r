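## Synthesis-rate / half-life calculus from genomic run-on style records,
## translatability arithmetic, shut-off decay fitting, and polysome
## fraction grouping.

#' Synthesis rate from nascent transcription rate
#'
#' `SR = nTR / cell_volume` (arbitrary units).
#'
#' @param nTR nascent transcription rate.
#' @param cell_volume average cell volume (> 0).
#' @return synthesis rate.
#' @export
synthesis_rate <- function(nTR, cell_volume) {
  if (any(cell_volume <= 0)) fail("cell volume must be positive")
  nTR / cell_volume
}

#' mRNA half-life from abundance and synthesis rate
#'
#' `HL = RA / SR` in arbitrary units; non-positive synthesis rates yield
#' `NA`.
#'
#' @param RA mRNA abundance (>= 0).
#' @param SR synthesis rate.
#' @return half-life (same length as inputs), `NA` where `SR <= 0`.
#' @export
half_life <- function(RA, SR) {
  if (any(RA < 0)) fail("abundance must be non-negative")
  out <- RA / SR
  out[SR <= 0] <- NA_real_
  out
}

#' Compare synthesis-rate and half-life changes across gene groups
#'
#' Computes per-gene `log2(t30/t0)` for SR and HL and compares each
#' group's distribution to the `not_regulated` background with two-sided
#' Wilcoxon-Mann-Whitney tests. Genes missing one condition are excluded
#' (count in attribute `n_incomplete`).
#'
#' @param records rate-record data frame (as from [simulate_gro()]),
#'   both conditions per gene.
#' @param classes named character vector gene_id -> class label (e.g.
#'   from a `te_result` table).
#' @return data frame: `group`, `n`, `median_sr_lfc`, `median_hl_lfc`,
#'   `p_sr`, `p_hl` (groups vs background; background row has `NA` p).
#' @export
group_rate_comparison <- function(records, classes) {
  t0 <- records[records$condition == "t0", ]
  t30 <- records[records$condition == "t30", ]
  shared <- intersect(t0$gene_id, t30$gene_id)
  n_incomplete <- length(unique(records$gene_id)) - length(shared)
  i0 <- match(shared, t0$gene_id); i30 <- match(shared, t30$gene_id)
  ok <- t0$SR[i0] > 0 & t30$SR[i30] > 0 & t0$HL[i0] > 0 & t30$HL[i30] > 0
  shared <- shared[ok]; i0 <- i0[ok]; i30 <- i30[ok]
  sr_lfc <- log2(t30$SR[i30] / t0$SR[i0])
  hl_lfc <- log2(t30$HL[i30] / t0$HL[i0])
  cl <- classes[shared]
  if (anyNA(cl)) fail("class label missing for %d gene(s)", sum(is.na(cl)))
  bg <- cl == "not_regulated"
  if (!any(bg)) fail("no background (not_regulated) genes in records")
  groups <- setdiff(unique(cl), "not_regulated")
  rows <- lapply(groups, function(g) {
    sel <- cl == g
    if (!any(sel)) fail("group '%s' is empty", g)
    data.frame(group = g, n = sum(sel),
               median_sr_lfc = median(sr_lfc[sel]),
               median_hl_lfc = median(hl_lfc[sel]),
               p_sr = mann_whitney(sr_lfc[sel], sr_lfc[bg])$p,
               p_hl = mann_whitney(hl_lfc[sel], hl_lfc[bg])$p,
               stringsAsFactors = FALSE)
  })
  rows <- c(rows, list(data.frame(group = "not_regulated", n = sum(bg),
                                  median_sr_lfc = median(sr_lfc[bg]),
                                  median_hl_lfc = median(hl_lfc[bg]),
                                  p_sr = NA_real_, p_hl = NA_real_,
                                  stringsAsFactors = FALSE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_incomplete") <- n_incomplete
  out
}

#' Translatability ratio
#'
#' Change in protein level divided by change in mRNA level, both
#' relative to the reference strain.
#'
#' @param protein_rel protein level as a fraction of the reference.
#' @param rna_rel mRNA level as a fraction of the reference (> 0).
#' @return translatability ratio.
#' @export
translatability <- function(protein_rel, rna_rel) {
  if (any(rna_rel <= 0)) fail("relative RNA level must be positive")
  protein_rel / rna_rel
}

#' Cap-corrected translatability
#'
#' Restricting the mRNA denominator to capped molecules rescales a
#' translatability estimate by the ratio of capped fractions:
#' `adjusted = t * capped_fraction_wt / capped_fraction_mut`. With the
#' reference fully capped, a mutant capped fraction of 0.77 turns a
#' 0.4% translatability into 0.52% (0.5% at one decimal).
#'
#' @param t translatability (any scale).
#' @param capped_fraction_mut capped fraction in the mutant, in (0, 1].
#' @param capped_fraction_wt capped fraction in the reference, in
#'   (0, 1] (default 1).
#' @return adjusted translatability.
#' @export
capped_adjusted_translatability <- function(t, capped_fraction_mut,
                                            capped_fraction_wt = 1.0) {
  for (f in c(capped_fraction_mut, capped_fraction_wt))
    if (f <= 0 || f > 1) fail("capped fractions must lie in (0, 1]")
  t * capped_fraction_wt / capped_fraction_mut
}

#' Half-life from a transcription shut-off time course
#'
#' Ordinary least squares of `ln(level)` on time;
#' `t_half = ln 2 / |slope|`. A non-negative slope (no decay) is flagged
#' as an infinite half-life.
#'
#' @param times sampling times (minutes), at least 3.
#' @param levels positive signal levels.
#' @return list with `t_half` (minutes, possibly `Inf`), `slope` and
#'   `decaying` (logical).
#' @export
decay_half_life_fit <- function(times, levels) {
  if (length(times) < 3 || length(levels) != length(times))
    fail("need at least 3 matched time points")
  if (any(levels <= 0)) fail("levels must be positive")
  slope <- unname(coef(lm(log(levels) ~ times))[2])
  if (slope >= 0) return(list(t_half = Inf, slope = slope, decaying = FALSE))
  list(t_half = log(2) / abs(slope), slope = slope, decaying = TRUE)
}

#' Normalized polysome-gradient distribution and fraction groups
#'
#' Normalizes a 26-fraction sucrose-gradient signal to sum 1 and sums
#' the five canonical groups: free (1-5), ribosomal subunits (6-11),
#' monosomes (12-15), light polysomes (16-21), heavy polysomes (22-26).
#'
#' @param fraction_signal non-negative signal over fractions 1..26.
#' @return list with `distribution` (length 26, sums to 1) and `groups`
#'   (named length-5 vector, sums to 1).
#' @export
polysome_distribution <- function(fraction_signal) {
  if (length(fraction_signal) != 26) fail("expected 26 fractions")
  if (any(fraction_signal < 0)) fail("signal must be non-negative")
  total <- sum(fraction_signal)
  if (total <= 0) fail("all-zero polysome profile")
  d <- fraction_signal / total
  ranges <- list(free = 1:5, subunits = 6:11, monosomes = 12:15,
                 light_polysomes = 16:21, heavy_polysomes = 22:26)
  groups <- vapply(ranges, function(r) sum(d[r]), numeric(1))
  list(distribution = d, groups = groups)
}
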