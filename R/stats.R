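## Statistical primitives: normalization, NB regression, Wald tests,
## rank tests, FDR, and set-overlap statistics.

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median, over reference genes,
#' of the ratio between a sample's count and the gene's geometric mean
#' across samples. Genes containing any zero are excluded from the
#' reference set, so adding such a gene never changes the factors.
#'
#' @param counts a [count_table] or a gene-by-sample count matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  ref <- rowSums(m == 0) == 0
  if (!any(ref))
    fail("no reference gene: every gene contains a zero count")
  lg <- log(m[ref, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- apply(lg, 2, function(col) exp(median(col - loggeo)))
  names(sf) <- colnames(m)
  sf
}

#' Method-of-moments negative-binomial dispersion
#'
#' Estimates the NB dispersion \eqn{\alpha} (variance \eqn{\mu + \alpha
#' \mu^2}) of one gene from its size-factor-normalized counts. The
#' variance is pooled within design cells (deviations from each cell's
#' mean, denominator `n - k`), so condition/assay mean differences do not
#' inflate the estimate:
#' \eqn{\hat\alpha = \max(10^{-8}, (s^2 - \bar m)/\bar m^2)}.
#'
#' @param y counts for one gene across samples.
#' @param groups factor of design cells (e.g. assay:condition), same
#'   length as `y`.
#' @param sf per-sample size factors.
#' @return dispersion estimate (>= 1e-8).
#' @export
estimate_dispersion <- function(y, groups, sf = rep(1, length(y))) {
  stopifnot(length(y) == length(groups), length(y) == length(sf))
  groups <- droplevels(as.factor(groups))
  if (max(table(groups)) < 2)
    fail("dispersion needs at least 2 samples in one design cell")
  x <- y / sf
  cell_means <- ave(x, groups)
  df <- length(x) - nlevels(groups)
  s2 <- sum((x - cell_means)^2) / df
  m <- mean(x)
  if (!is.finite(m) || m <= 0) return(1e-8)
  max(1e-8, (s2 - m) / m^2)
}

#' Fit a negative-binomial GLM with fixed dispersion
#'
#' Maximizes the NB log-likelihood with a log link by iteratively
#' reweighted least squares at a fixed dispersion \eqn{\alpha}.
#' Convergence when the largest coefficient change drops below 1e-8, or
#' after 100 iterations (flagged, never silent). Standard errors come
#' from the observed Fisher information at the optimum.
#'
#' @param y non-negative integer response vector.
#' @param design full-rank model matrix.
#' @param offsets per-observation log offsets (log size factors).
#' @param alpha NB dispersion (> 0; variance \eqn{\mu + \alpha\mu^2}).
#' @return list of class `nb_glm_fit` with `coefficients` (natural-log
#'   scale), `standard_errors`, `converged`, `iterations`,
#'   `dispersion_used`.
#' @export
nb_glm_fit <- function(y, design, offsets = rep(0, length(y)), alpha) {
  design <- as.matrix(design)
  if (!is_count_vector(y)) fail("y must be non-negative integers")
  if (nrow(design) != length(y)) fail("design rows must match length(y)")
  if (qr(design)$rank < ncol(design)) fail("design matrix is rank deficient")
  stopifnot(alpha > 0)
  bad_fit <- function(iter) {
    structure(list(coefficients = rep(NA_real_, ncol(design)),
                   standard_errors = rep(NA_real_, ncol(design)),
                   converged = FALSE, iterations = iter,
                   dispersion_used = alpha),
              class = "nb_glm_fit")
  }
  if (all(y == 0)) return(bad_fit(0L))

  beta <- qr.solve(design, log(pmax(y, 0.5)) - offsets)
  converged <- FALSE
  iter <- 0L
  while (iter < 100L) {
    iter <- iter + 1L
    eta <- drop(design %*% beta) + offsets
    mu <- pmin(exp(eta), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offsets) + (y - mu) / mu
    xtw <- t(design * w)
    beta_new <- tryCatch(drop(solve(xtw %*% design, xtw %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) return(bad_fit(iter))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  mu <- pmin(exp(drop(design %*% beta) + offsets), 1e12)
  w_obs <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  info <- t(design * w_obs) %*% design
  covm <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(covm) || any(diag(covm) <= 0)) return(bad_fit(iter))
  structure(list(coefficients = setNames(beta, colnames(design)),
                 standard_errors = setNames(sqrt(diag(covm)), colnames(design)),
                 converged = converged, iterations = iter,
                 dispersion_used = alpha),
            class = "nb_glm_fit")
}

#' Wald test on one GLM coefficient
#'
#' @param fit an [nb_glm_fit] result.
#' @param index coefficient index (or name).
#' @return list with `z` and two-sided `p`; both `NA` when the fit did
#'   not converge.
#' @export
wald_test <- function(fit, index) {
  stopifnot(inherits(fit, "nb_glm_fit"))
  if (!isTRUE(fit$converged)) return(list(z = NA_real_, p = NA_real_))
  se <- fit$standard_errors[[index]]
  if (!is.finite(se) || se <= 0) fail("standard error at index is not positive")
  z <- fit$coefficients[[index]] / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across the non-missing p-values; missing values
#' propagate to missing q-values and do not count toward the number of
#' tests.
#'
#' @param p vector of p-values in `[0, 1]`, `NA` allowed.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) fail("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

## U statistic: number of (x, y) pairs with x > y, ties counted 1/2.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Exact p-values by enumeration of all label assignments (valid under
#' ties) when `n1 + n2 <= 12` in `auto`/`exact` mode; otherwise a normal
#' approximation with tie correction and a 0.5 continuity correction.
#'
#' @param x,y non-empty numeric samples.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `U` (for the first sample) and `p`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) fail("both samples must be non-empty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) fail("missing values not allowed in rank test")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u <- u_statistic(x, y)
  use_exact <- (mode == "exact") || (mode == "auto" && n <= 12)
  if (use_exact) {
    if (n > 12 && mode == "exact")
      fail("exact mode limited to n1 + n2 <= 12")
    pooled <- c(x, y)
    idx <- combn(n, n1)
    us <- apply(idx, 2, function(i) u_statistic(pooled[i], pooled[-i]))
    mid <- n1 * n2 / 2
    p <- switch(alternative,
                two.sided = mean(abs(us - mid) >= abs(u - mid) - 1e-12),
                greater = mean(us >= u - 1e-12),
                less = mean(us <= u + 1e-12))
  } else {
    mid <- n1 * n2 / 2
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u, p = 1))
    sd_u <- sqrt(sigma2)
    p <- switch(alternative,
                two.sided = 2 * pnorm((abs(u - mid) - 0.5) / sd_u,
                                      lower.tail = FALSE),
                greater = pnorm((u - mid - 0.5) / sd_u, lower.tail = FALSE),
                less = pnorm((u - mid + 0.5) / sd_u))
    p <- min(1, max(0, p))
  }
  list(U = u, p = p)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' \eqn{P(X \ge k)} for the overlap of a set of size `nA` with a set of
#' size `nB` drawn from a universe of size `N`. Computed in log space via
#' the exact hypergeometric tail, so values down to ~1e-300 do not
#' underflow.
#'
#' @param k observed overlap.
#' @param nA,nB set sizes.
#' @param N universe size.
#' @return p-value.
#' @export
hypergeom_overlap_p <- function(k, nA, nB, N) {
  vals <- c(k, nA, nB, N)
  if (!is_count_vector(vals)) fail("arguments must be non-negative integers")
  if (nA > N || nB > N) fail("set larger than universe")
  if (k > min(nA, nB)) fail("overlap k exceeds min(nA, nB)")
  if (k == 0) return(1)
  lp <- phyper(k - 1, nA, N - nA, nB, lower.tail = FALSE, log.p = TRUE)
  exp(lp)
}

#' Relative enrichment ratio from a 2x2 table
#'
#' `(a/(a+b)) / (c/(c+d))`: how much more likely the feature (a, c
#' counts) is in the first group than in the second.
#'
#' @param a,b feature-positive / feature-negative counts in group 1.
#' @param c,d feature-positive / feature-negative counts in group 2.
#' @return enrichment ratio.
#' @export
relative_enrichment <- function(a, b, c, d) {
  if (!is_count_vector(c(a, b, c, d))) fail("cell counts must be non-negative integers")
  if (a + b == 0 || c + d == 0) fail("empty comparison group")
  if (c == 0) fail("reference group has no feature-positive members")
  (a / (a + b)) / (c / (c + d))
}
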