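#' Expected chi-square of a SNP under a polygenic model
#'
#' `E[chi2_i] = N * h2 * ld_score_i / M + intercept`: the infinitesimal
#' expectation that the LD-aware enrichment test uses as its null
#' variance. The intercept is the LD-score-regression intercept
#' `1 + N a`, capturing confounding and overlap.
#'
#' @param n GWAS sample size.
#' @param h2 SNP heritability of the trait.
#' @param ld_score LD score(s) of the SNP(s).
#' @param m number of SNPs in the LD-score universe.
#' @param intercept LD-score regression intercept.
#' @return expected chi-square, vectorized.
#' @export
expected_chisq <- function(n, h2, ld_score, m, intercept = 1) {
  stopifnot(m > 0, all(ld_score >= 0))
  (n * h2 * ld_score / m) + intercept
}

#' Per-SNP LD-aware enrichment test
#'
#' Tests an observed z statistic against a normal null with the
#' polygenic variance from [expected_chisq()]: the enrichment ratio is
#' `z^2 / variance` and the two-sided P value is
#' `2 * (1 - Phi(|z| / sqrt(variance)))`.
#'
#' @param z_obs observed z statistic(s).
#' @param variance expected chi-square under the polygenic null (> 0).
#' @return list `(ratio, pvalue)`, vectorized.
#' @export
per_snp_test <- function(z_obs, variance) {
  if (any(variance <= 0)) stop("variance must be positive")
  ratio <- z_obs^2 / variance
  pvalue <- 2 * pnorm(-abs(z_obs) / sqrt(variance))
  list(ratio = ratio, pvalue = pvalue)
}

#' Fisher's method for combining independent P values
#'
#' `X = -2 * sum(log(p))` compared against chi-square with `2k` degrees of
#' freedom. Zero P values are clamped to `p_floor` with a warning (log of
#' zero is undefined).
#'
#' @param pvalues P values in `(0, 1]`, assumed independent.
#' @param p_floor clamp for zero P values (default `1e-300`).
#' @return list `(statistic, df, pvalue)`.
#' @export
fisher_combine <- function(pvalues, p_floor = 1e-300) {
  stopifnot(length(pvalues) > 0, all(pvalues >= 0 & pvalues <= 1))
  if (any(pvalues == 0)) {
    warning("zero P value(s) clamped to ", p_floor)
    pvalues[pvalues == 0] <- p_floor
  }
  x <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = x, df = df,
       pvalue = pchisq(x, df = df, lower.tail = FALSE))
}

#' LD-aware enrichment of a SNP set across traits
#'
#' For each trait, looks up the candidate SNPs in its summary statistics
#' (substituting the best LD proxy within `proxy_window_kb` at
#' `r2 > proxy_min_r2` for SNPs missing from the trait's LD-score
#' universe, when a panel is supplied), computes the per-SNP enrichment
#' test against the trait's polygenic expectation, and combines the
#' per-SNP P values with Fisher's method. SNPs with no direct or proxy
#' match are dropped and counted. A warning is issued when two combined
#' SNPs lie within 1 Mb of each other, since Fisher's method assumes
#' independence.
#'
#' @param snps character vector of candidate SNP ids (pre-clumped).
#' @param traits named list; each element is a list with `stats` (a
#'   `sumstat_table`) and either `fit` (an `ldsc_fit`) or scalars `h2` and
#'   `intercept` (and optionally `n`, defaulting to the trait's mean
#'   `n_eff`).
#' @param ld an `ldscore_table` defining the SNP universe.
#' @param panel optional [genotype_panel()] enabling proxy substitution.
#' @param proxy_min_r2,proxy_window_kb proxy-search parameters.
#' @return named list of `ld_aware_result` objects: per-SNP table
#'   `(snp_id, source_snp, status, observed_chisq, expected_chisq, ratio,
#'   pvalue)` plus `combined_statistic`, `combined_df`, `combined_pvalue`,
#'   and direct/proxy/dropped counts.
#' @export
run_trait_panel <- function(snps, traits, ld, panel = NULL,
                            proxy_min_r2 = 0.8, proxy_window_kb = 500) {
  ldt <- as.data.table(ld)
  m <- nrow(ldt)
  out <- list()
  for (lab in names(traits)) {
    tr <- traits[[lab]]
    st <- as.data.table(tr$stats)
    h2 <- if (!is.null(tr$fit)) tr$fit$h2 else tr$h2
    intercept <- if (!is.null(tr$fit)) tr$fit$intercept else
      if (!is.null(tr$intercept)) tr$intercept else 1
    n <- if (!is.null(tr$n)) tr$n else mean(st$n_eff)
    usable <- intersect(st$snp_id, ldt$snp_id)
    target <- character(0)
    source_snp <- character(0)
    status <- character(0)
    for (s in snps) {
      if (s %in% usable) {
        target <- c(target, s); source_snp <- c(source_snp, s)
        status <- c(status, "direct")
      } else if (!is.null(panel) && s %in% panel$map$snp_id) {
        px <- find_proxy(panel, s, setdiff(usable, target),
                         min_r2 = proxy_min_r2, window_kb = proxy_window_kb)
        if (!is.na(px)) {
          target <- c(target, px); source_snp <- c(source_snp, s)
          status <- c(status, "proxy")
        } else {
          status <- c(status, "dropped"); target <- c(target, NA_character_)
          source_snp <- c(source_snp, s)
        }
      } else {
        status <- c(status, "dropped"); target <- c(target, NA_character_)
        source_snp <- c(source_snp, s)
      }
    }
    keep <- !is.na(target)
    if (!any(keep)) {
      warning("trait '", lab, "' has no usable candidate SNPs; skipped")
      out[[lab]] <- structure(
        list(per_snp = data.table(), combined_statistic = NA_real_,
             combined_df = NA_integer_, combined_pvalue = NA_real_,
             trait_label = lab, no_usable_snps = TRUE,
             n_direct = 0L, n_proxy = 0L, n_dropped = sum(!keep)),
        class = "ld_aware_result")
      next
    }
    ti <- match(target[keep], st$snp_id)
    li <- match(target[keep], ldt$snp_id)
    z <- st$beta[ti] / st$se[ti]
    v <- expected_chisq(n, h2, ldt$ld_score[li], m, intercept)
    tst <- per_snp_test(z, v)
    per_snp <- data.table(snp_id = target[keep],
                          source_snp = source_snp[keep],
                          status = status[keep],
                          chrom = ldt$chrom[li], pos = ldt$pos[li],
                          observed_chisq = z^2, expected_chisq = v,
                          ratio = tst$ratio, pvalue = tst$pvalue)
    setorderv(per_snp, c("chrom", "pos"))
    close_pairs <- per_snp[, any(diff(pos) <= 1e6), by = "chrom"]$V1
    if (any(close_pairs)) {
      warning("trait '", lab, "': combined SNPs within 1 Mb of each other; ",
              "Fisher independence may be violated")
    }
    fc <- fisher_combine(per_snp$pvalue)
    out[[lab]] <- structure(
      list(per_snp = per_snp, combined_statistic = fc$statistic,
           combined_df = fc$df, combined_pvalue = fc$pvalue,
           trait_label = lab, no_usable_snps = FALSE,
           n_direct = sum(status == "direct"),
           n_proxy = sum(status == "proxy"),
           n_dropped = sum(status == "dropped")),
      class = "ld_aware_result")
  }
  out
}

#' @export
print.ld_aware_result <- function(x, ...) {
  if (isTRUE(x$no_usable_snps)) {
    cat(sprintf("ld_aware_result [%s]: no usable SNPs\n", x$trait_label))
    return(invisible(x))
  }
  cat(sprintf(
    "ld_aware_result [%s]: %d SNPs (%d direct, %d proxy, %d dropped), combined P = %.3g\n",
    x$trait_label, nrow(x$per_snp), x$n_direct, x$n_proxy, x$n_dropped,
    x$combined_pvalue))
  invisible(x)
}
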