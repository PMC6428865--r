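# Independent oracles and small fixture builders used across tests.
# Oracles never share code with the implementation paths they check.

# NB log-likelihood at fixed dispersion (direct density sum).
nb_loglik <- function(beta, y, design, alpha, off = 0) {
  mu <- exp(drop(design %*% beta) + off)
  sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
}

# Brute-force likelihood maximization by iterative grid refinement:
# a 5-point grid per dimension around the current center, halving the
# width each level. The NB log-likelihood is concave in beta, so the
# refinement converges to the global maximum.
nb_grid_fit <- function(y, design, alpha, off = 0, center = NULL,
                        width = 4, levels = 16) {
  k <- ncol(design)
  if (is.null(center)) center <- rep(0, k)
  for (lev in seq_len(levels)) {
    grids <- lapply(center, function(c0) c0 + seq(-width, width, length.out = 5))
    pts <- as.matrix(expand.grid(grids))
    ll <- vapply(seq_len(nrow(pts)), function(r)
      nb_loglik(pts[r, ], y, design, alpha, off), numeric(1))
    center <- pts[which.max(ll), ]
    width <- width / 2
  }
  unname(center)
}

# Exhaustive-enumeration Mann-Whitney p (two-sided), valid under ties.
mw_enum <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  ustat <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  u <- ustat(x, y)
  mid <- n1 * (n - n1) / 2
  idx <- combn(n, n1)
  us <- apply(idx, 2, function(i) ustat(pooled[i], pooled[-i]))
  mean(abs(us - mid) >= abs(u - mid) - 1e-12)
}

# Exhaustive-enumeration hypergeometric upper tail: draw every subset of
# size nB from 1..N and count overlaps with the fixed set 1..nA.
hyper_enum <- function(k, nA, nB, N) {
  if (nB == 0) return(as.numeric(k == 0))
  sets <- combn(N, nB)
  overlaps <- colSums(sets <= nA)
  mean(overlaps >= k)
}

# Minimal annotation with constant region lengths.
mk_ann <- function(n, utr5 = 50L, cds = 300L, utr3 = 60L,
                   is_membrane = FALSE) {
  gene_annotation(data.frame(
    gene_id = sprintf("G%04d", seq_len(n)),
    utr5_length = utr5, cds_length = cds, utr3_length = utr3,
    is_membrane = is_membrane, srp_class = "unknown",
    stringsAsFactors = FALSE))
}

# Truth table with explicit effects; defaults give pure null genes.
mk_truth <- function(ann, class = "not_regulated", fc_mrna = 0, fc_te = 0,
                     base_mean = 200, dispersion = 0.1) {
  data.frame(gene_id = ann$gene_id, true_class = class,
             true_log2fc_mrna = fc_mrna, true_log2fc_te = fc_te,
             base_mean = base_mean, dispersion = dispersion,
             stringsAsFactors = FALSE)
}

# te_result-shaped frame for classifier unit tests.
mk_te <- function(gene_id, log2fc_mrna, delta_te, fdr) {
  data.frame(gene_id = gene_id, log2fc_mrna = log2fc_mrna,
             log2fc_rpf = log2fc_mrna + delta_te, delta_te = delta_te,
             wald_z = NA_real_, p = fdr, fdr = fdr,
             class_label = "not_regulated", stringsAsFactors = FALSE)
}
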