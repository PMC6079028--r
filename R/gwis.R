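#' Projection coefficient for trait purging
#'
#' The genome-wide regression coefficient of trait a's genetic values on
#' trait b's: `beta = cov_g(a, b) / var_g(b)`, with both terms estimated
#' by LD-score regression on a common analysis scale.
#'
#' @param cross a `cross_trait_fit` from [fit_cross()] of (a, b).
#' @param fit_b an `ldsc_fit` for trait b on the same scale.
#' @return scalar projection coefficient.
#' @export
projection_beta <- function(cross, fit_b) {
  if (fit_b$h2 <= 0) stop("var_g of trait b is non-positive; beta undefined")
  cross$cov_g / fit_b$h2
}

#' Estimation-error correlation from the cross-trait intercept
#'
#' With overlapping GWAS samples the estimation errors of the two traits'
#' per-SNP effects are correlated; the cross-trait LD-score intercept
#' estimates that correlation. Values outside `[-1, 1]` are clamped with a
#' warning.
#'
#' @param cross a `cross_trait_fit`.
#' @return scalar in `[-1, 1]`.
#' @export
overlap_rho_from_intercept <- function(cross) {
  rho <- cross$cross_intercept
  if (abs(rho) > 1) {
    warning("cross-trait intercept ", signif(rho, 3), " clamped to [-1, 1]")
    rho <- sign(rho)
  }
  rho
}

#' Purge one trait's effects of their overlap with another
#'
#' Genome-wide inferred statistics for the residual trait `a - beta * b`:
#' per SNP, `effect_e = beta_a - beta_proj * beta_b` with delta-method
#' standard error
#' `sqrt(se_a^2 + beta_proj^2 * se_b^2 - 2 * beta_proj * rho * se_a * se_b)`,
#' where `rho` is the estimation-error correlation induced by sample
#' overlap. `beta_proj` is treated as fixed (its sampling variance
#' ignored); `beta_var` adds a first-order `beta_b^2 * beta_var` term for
#' sensitivity analysis.
#'
#' @param merged a merged table from [align_and_merge()] (allele-aligned;
#'   run with `drop_strand_ambiguous = TRUE` for purging). Effects must be
#'   on a common (standardized) scale.
#' @param beta_proj the projection coefficient (see [projection_beta()]).
#' @param overlap_rho estimation-error correlation (default 0).
#' @param beta_var optional sampling variance of `beta_proj`.
#' @return A `gwis_result`: list with `beta_proj`, `overlap_rho` and
#'   `table` — data.table `(snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, effect_e, se_e, z_e, pvalue_e)`.
#' @export
purge_effects <- function(merged, beta_proj, overlap_rho = 0,
                          beta_var = 0) {
  stopifnot(abs(overlap_rho) <= 1)
  m <- as.data.table(merged)
  eff <- m$beta_a - beta_proj * m$beta_b
  var_e <- m$se_a^2 + beta_proj^2 * m$se_b^2 -
    2 * beta_proj * overlap_rho * m$se_a * m$se_b +
    beta_var * m$beta_b^2
  bad <- var_e < -1e-12
  if (any(bad)) {
    stop("negative purged variance (extreme overlap_rho?) at SNP(s): ",
         paste(utils::head(m$snp_id[bad], 5), collapse = ", "))
  }
  # variance exactly zero arises only in complete annihilation (a trait
  # purged of itself at beta = rho = 1); the effect is then exactly zero
  se_e <- sqrt(pmax(var_e, 0))
  z <- ifelse(se_e > 0, eff / se_e, 0)
  tab <- data.table(snp_id = m$snp_id, chrom = m$chrom, pos = m$pos,
                    effect_allele = m$effect_allele,
                    other_allele = m$other_allele, eaf = m$eaf_a,
                    n_eff = m$n_a,
                    effect_e = eff, se_e = se_e, z_e = z,
                    pvalue_e = 2 * pnorm(-abs(z)))
  structure(list(beta_proj = beta_proj, overlap_rho = overlap_rho,
                 table = tab),
            class = "gwis_result")
}

#' Purged results as a summary-statistics table
#'
#' Re-expresses a [purge_effects()] result in the standard
#' summary-statistics schema so every other stage (clumping, enrichment,
#' scoring, LD-score regression) can consume it unchanged.
#'
#' @param x a `gwis_result`.
#' @param trait_label label for the derived trait.
#' @return A `sumstat_table`.
#' @export
gwis_as_sumstats <- function(x, trait_label = "purged") {
  t <- x$table
  sumstat_table(data.table(snp_id = t$snp_id, chrom = t$chrom, pos = t$pos,
                           effect_allele = t$effect_allele,
                           other_allele = t$other_allele, eaf = t$eaf,
                           beta = t$effect_e, se = t$se_e,
                           pvalue = pmax(t$pvalue_e, 1e-320),
                           n_eff = t$n_eff),
                trait_label = trait_label)
}

#' One-call GWIS purge from two summary-statistics tables
#'
#' Aligns the two tables (dropping strand-ambiguous SNPs), converts both
#' to standardized z-derived betas `z / sqrt(n)` so the LD-score scale and
#' the per-SNP scale agree, estimates the projection coefficient and
#' overlap correlation by LD-score regression, and purges.
#'
#' @param stats_a,stats_b `sumstat_table`s (a is purged of b).
#' @param ld an `ldscore_table`.
#' @param m LD-score universe size passed to the fits.
#' @param overlap_rho `NULL` to estimate from the cross-trait intercept.
#' @return list `(result, beta_proj, overlap_rho, cross, fit_b, sumstats)`
#'   where `sumstats` is the purged `sumstat_table`.
#' @export
gwis <- function(stats_a, stats_b, ld, m = NULL, overlap_rho = NULL) {
  std <- function(s) {
    d <- as.data.table(s)
    z <- d$beta / d$se
    d$beta <- z / sqrt(d$n_eff)
    d$se <- 1 / sqrt(d$n_eff)
    out <- sumstat_table(d, trait_label = attr(s, "trait_label"))
    out
  }
  a <- std(stats_a)
  b <- std(stats_b)
  cross <- fit_cross(a, b, ld, m = m)
  # var_g(b) from the self-cross regression: same design and weighting as
  # the covariance fit, so the purge cancels the shared component exactly
  # up to weight differences rather than up to independent fit noise
  fb_cross <- fit_cross(b, b, ld, m = m)
  fb <- structure(list(h2 = fb_cross$cov_g,
                       intercept = fb_cross$cross_intercept,
                       m_snps = if (is.null(m)) nrow(ld) else m,
                       n_mean = mean(as.data.table(b)$n_eff),
                       n_snps_fit = fb_cross$n_snps_fit,
                       h2_se = NA_real_, intercept_se = NA_real_),
                  class = "ldsc_fit")
  bp <- projection_beta(cross, fb)
  if (is.null(overlap_rho)) overlap_rho <- overlap_rho_from_intercept(cross)
  mg <- align_and_merge(a, b, drop_strand_ambiguous = TRUE)$table
  res <- purge_effects(mg, bp, overlap_rho)
  lab <- paste0(attr(stats_a, "trait_label"), "_min_",
                attr(stats_b, "trait_label"))
  list(result = res, beta_proj = bp, overlap_rho = overlap_rho,
       cross = cross, fit_b = fb,
       sumstats = gwis_as_sumstats(res, trait_label = lab))
}
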