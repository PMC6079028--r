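#' Minimal LD-score regression for SNP heritability
#'
#' Regresses per-SNP chi-square statistics `(beta/se)^2` on
#' `N * ld_score / M`. The slope estimates the SNP heritability `h2` on
#' the analysis scale and the intercept estimates `1 + N a`, the
#' confounding/overlap term. Weights `1 / (2 * E[chi2]^2)` are iterated
#' twice from an OLS start ("lite" weighting; adequate for synthetic
#' calibration, not a replica of the reference implementation's scheme).
#'
#' @param stats a `sumstat_table`.
#' @param ld an `ldscore_table` covering (at least) the table's SNPs.
#' @param m number of SNPs in the LD-score universe; defaults to the size
#'   of `ld`.
#' @param n_blocks_jackknife if > 0, a delete-one block jackknife over
#'   contiguous SNP blocks supplies slope/intercept standard errors.
#' @param chisq_max optional cap: SNPs with chi-square above it are
#'   excluded before fitting.
#' @return An `ldsc_fit`: list `(h2, intercept, m_snps, n_mean, n_snps_fit,
#'   h2_se, intercept_se)`.
#' @export
fit_h2 <- function(stats, ld, m = NULL, n_blocks_jackknife = 0,
                   chisq_max = Inf) {
  st <- as.data.table(stats)
  dt <- merge(st[, c("snp_id", "beta", "se", "n_eff"), with = FALSE],
              as.data.table(ld)[, c("snp_id", "ld_score"), with = FALSE],
              by = "snp_id")
  if (is.null(m)) m <- nrow(ld)
  dt[, "chisq" := (beta / se)^2]
  dt <- dt[is.finite(chisq) & chisq <= chisq_max]
  if (nrow(dt) < 50L) stop("need at least 50 SNPs with chi-square and LD score")
  if (var(dt$ld_score) == 0) stop("degenerate design: constant LD scores")
  x <- dt$n_eff * dt$ld_score / m
  y <- dt$chisq
  co <- .wls_iter(x, y)
  out <- list(h2 = co[2], intercept = co[1], m_snps = m,
              n_mean = mean(dt$n_eff), n_snps_fit = nrow(dt),
              h2_se = NA_real_, intercept_se = NA_real_)
  if (n_blocks_jackknife > 0) {
    jk <- .block_jackknife(x, y, n_blocks_jackknife)
    out$intercept_se <- jk[1]
    out$h2_se <- jk[2]
  }
  structure(out, class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("ldsc_fit: h2 = %.4f, intercept = %.4f (M = %d, %d SNPs fit)\n",
              x$h2, x$intercept, x$m_snps, x$n_snps_fit))
  invisible(x)
}

# two-step reweighted least squares: OLS start, then 1/(2 E[chi2]^2) twice
.wls_iter <- function(x, y, iters = 2L) {
  co <- stats::coef(stats::lm.fit(cbind(1, x), y))
  for (i in seq_len(iters)) {
    ey <- pmax(co[1] + co[2] * x, 0.1)
    w <- 1 / (2 * ey^2)
    co <- stats::coef(stats::lm.wfit(cbind(1, x), y, w))
  }
  unname(co)
}

.block_jackknife <- function(x, y, n_blocks) {
  n <- length(x)
  blk <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  ests <- vapply(seq_len(n_blocks), function(b) {
    keep <- blk != b
    .wls_iter(x[keep], y[keep])
  }, numeric(2))
  apply(ests, 1, sd) * (n_blocks - 1) / sqrt(n_blocks)
}

#' Cross-trait LD-score regression
#'
#' Regresses the per-SNP z-score product of two traits on
#' `sqrt(N_a * N_b) * ld_score / M`. The slope estimates the genetic
#' covariance `cov_g` on the analysis scale; the intercept captures
#' phenotypic correlation in overlapping samples and is ~0 for
#' non-overlapping cohorts. The genetic correlation
#' `rg = cov_g / sqrt(h2_a * h2_b)` is derived from per-trait [fit_h2()]
#' fits (flagged undefined if either h2 is non-positive).
#'
#' @param stats_a,stats_b aligned `sumstat_table`s (same allele coding).
#' @param ld an `ldscore_table`.
#' @param m LD-score universe size; defaults to `nrow(ld)`.
#' @return A `cross_trait_fit`: list `(cov_g, cross_intercept, rg,
#'   rg_defined, h2_a, h2_b, n_snps_fit)`.
#' @export
fit_cross <- function(stats_a, stats_b, ld, m = NULL) {
  sa <- as.data.table(stats_a)
  sb <- as.data.table(stats_b)
  ldt <- as.data.table(ld)
  if (is.null(m)) m <- nrow(ldt)
  dt <- merge(sa[, list(snp_id, za = beta / se, na = n_eff)],
              sb[, list(snp_id, zb = beta / se, nb = n_eff)],
              by = "snp_id")
  dt <- merge(dt, ldt[, c("snp_id", "ld_score"), with = FALSE], by = "snp_id")
  if (nrow(dt) < 50L) stop("need at least 50 aligned SNPs")
  x <- sqrt(dt$na * dt$nb) * dt$ld_score / m
  y <- dt$za * dt$zb
  co <- stats::coef(stats::lm.fit(cbind(1, x), y))
  for (i in 1:2) {
    # heteroskedastic weights from the product-normal variance approximation
    ey2 <- pmax(1 + abs(co[1] + co[2] * x), 0.5)
    w <- 1 / ey2^2
    co <- stats::coef(stats::lm.wfit(cbind(1, x), y, w))
  }
  co <- unname(co)
  ha <- fit_h2(stats_a, ld, m = m)
  hb <- fit_h2(stats_b, ld, m = m)
  defined <- ha$h2 > 0 && hb$h2 > 0
  structure(list(cov_g = co[2], cross_intercept = co[1],
                 rg = if (defined) co[2] / sqrt(ha$h2 * hb$h2) else NA_real_,
                 rg_defined = defined, h2_a = ha$h2, h2_b = hb$h2,
                 n_snps_fit = nrow(dt)),
            class = "cross_trait_fit")
}

#' @export
print.cross_trait_fit <- function(x, ...) {
  cat(sprintf(
    "cross_trait_fit: cov_g = %.4f, intercept = %.4f, rg = %s\n",
    x$cov_g, x$cross_intercept,
    if (x$rg_defined) sprintf("%.3f", x$rg) else "undefined"))
  invisible(x)
}
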