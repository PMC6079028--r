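#' First-stage lead-SNP selection on the proxy trait
#'
#' Clumps the proxy-trait summary statistics at the preregistered P-value
#' threshold, returning approximately independent lead SNPs together with
#' their proxy-trait P values.
#'
#' @param proxy_stats `sumstat_table` for the proxy trait.
#' @param panel a [genotype_panel()].
#' @param p_threshold lead-selection threshold (default `1e-5`).
#' @param r2_threshold,window_kb clumping parameters.
#' @return A `clump_result` (see [ld_clump()]).
#' @export
select_leads <- function(proxy_stats, panel, p_threshold = 1e-5,
                         r2_threshold = 0.1, window_kb = 1000) {
  ld_clump(proxy_stats, panel, p_threshold = p_threshold,
           r2_threshold = r2_threshold, window_kb = window_kb)
}

#' Second-stage lookup of proxy-trait leads in the target trait
#'
#' Looks up each lead SNP in the target-trait summary statistics and flags
#' nominal (`pvalue < alpha`) and Bonferroni
#' (`pvalue < alpha / n_leads`) significance. The Bonferroni denominator is
#' the preregistered number of selected leads; leads absent from the target
#' table are reported with a `missing` flag, never silently dropped.
#'
#' @param leads a `clump_result` from [select_leads()].
#' @param target_stats `sumstat_table` for the target trait.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.table `(snp_id, pvalue_proxy, beta_target, se_target,
#'   pvalue_target, eaf_target, missing, nominal, bonferroni)` with the
#'   Bonferroni threshold as attribute `bonferroni_threshold`.
#' @export
second_stage_lookup <- function(leads, target_stats, alpha = 0.05) {
  n_leads <- length(leads$lead_snps)
  thr <- alpha / n_leads
  tt <- as.data.table(target_stats)
  i <- match(leads$lead_snps, tt$snp_id)
  out <- data.table(snp_id = leads$lead_snps,
                    pvalue_proxy = unname(leads$lead_pvalues),
                    beta_target = tt$beta[i],
                    se_target = tt$se[i],
                    pvalue_target = tt$pvalue[i],
                    eaf_target = tt$eaf[i],
                    missing = is.na(i))
  out[, `:=`(nominal = !missing & pvalue_target < alpha,
             bonferroni = !missing & pvalue_target < thr)]
  setattr(out, "bonferroni_threshold", thr)
  setattr(out, "n_leads", n_leads)
  out
}

#' Exact two-sided binomial test at p = 1/2 by tail doubling
#' @keywords internal
.binom_p_half <- function(k, n) {
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Sign-concordance test between proxy and target effects
#'
#' Counts leads whose proxy-trait and target-trait betas share a sign and
#' tests the count against Binomial(n, 1/2) with an exact two-sided P value
#' obtained by doubling the smaller tail (capped at 1). Exact zero betas
#' carry no sign information and are excluded with a message.
#'
#' @param lookup a lookup table from [second_stage_lookup()] that also
#'   carries a `beta_proxy` column, or any data.frame with `beta_proxy` and
#'   `beta_target`.
#' @param beta_proxy,beta_target alternatively, two bare numeric vectors.
#' @param subset one of `"all"`, `"nominal"`, `"bonferroni"`: restrict to
#'   leads with the corresponding lookup flag.
#' @return list `(k, n, share, pvalue)`.
#' @export
sign_concordance_test <- function(lookup = NULL, beta_proxy = NULL,
                                  beta_target = NULL, subset = "all") {
  if (!is.null(lookup)) {
    lk <- as.data.table(lookup)
    if (subset != "all") lk <- lk[lk[[subset]] == TRUE]
    lk <- lk[!lk$missing]
    beta_proxy <- lk$beta_proxy
    beta_target <- lk$beta_target
  }
  zero <- beta_proxy == 0 | beta_target == 0
  if (any(zero)) {
    message(sum(zero), " lead(s) with an exactly zero beta excluded from ",
            "the sign test")
    beta_proxy <- beta_proxy[!zero]
    beta_target <- beta_target[!zero]
  }
  n <- length(beta_proxy)
  if (n < 1L) stop("no usable leads for the sign-concordance test")
  k <- sum(sign(beta_proxy) == sign(beta_target))
  list(k = k, n = n, share = k / n, pvalue = .binom_p_half(k, n))
}

#' Raw enrichment of joint association
#'
#' Under the null of no genetic overlap, the expected number of proxy-trait
#' lead SNPs that also pass the target-trait threshold is
#' `N_T * tau_proxy * tau_target`, where `N_T` is the total number of
#' independent lead SNPs (clumped with no P filter) and the `tau` are the
#' shares of those leads below the proxy and target thresholds. The raw
#' enrichment factor is observed / expected.
#'
#' @param n_total_leads `N_T`, total independent leads.
#' @param n_proxy_leads leads below the proxy-trait threshold.
#' @param n_target_leads leads below the target-trait threshold.
#' @param n_observed leads passing both thresholds.
#' @return An `enrichment_counts` list with `tau_proxy`, `tau_target`,
#'   `expected`, `factor` (`NA` with `factor_undefined = TRUE` when the
#'   expectation is zero).
#' @export
raw_enrichment <- function(n_total_leads, n_proxy_leads, n_target_leads,
                           n_observed) {
  stopifnot(n_total_leads > 0, n_proxy_leads >= 0, n_target_leads >= 0,
            n_observed >= 0)
  tau_p <- n_proxy_leads / n_total_leads
  tau_t <- n_target_leads / n_total_leads
  expected <- n_total_leads * tau_p * tau_t
  undef <- expected == 0
  structure(list(n_total_leads = n_total_leads,
                 tau_proxy = tau_p, tau_target = tau_t,
                 n_observed = n_observed, expected = expected,
                 factor = if (undef) NA_real_ else n_observed / expected,
                 factor_undefined = undef),
            class = "enrichment_counts")
}

#' @export
print.enrichment_counts <- function(x, ...) {
  cat(sprintf(
    "raw enrichment: expected %.3f, observed %d, factor %s\n",
    x$expected, x$n_observed,
    if (x$factor_undefined) "undefined" else sprintf("%.2f", x$factor)))
  invisible(x)
}

#' Draw MAF-matched null SNP sets for the enrichment rank test
#'
#' For each lead SNP, draws `k_per_lead` distinct SNPs uniformly without
#' replacement from the pool, restricted to pool SNPs whose folded minor
#' allele frequency lies within `maf_tolerance` of the lead's. Sampling is
#' without replacement across the whole draw (no SNP reused between leads)
#' and the pool must exclude the leads themselves.
#'
#' @param leads_maf named numeric vector: folded MAF per lead SNP id.
#' @param pool a `sumstat_table` of approximately independent SNPs
#'   (pre-clumped), excluding the leads.
#' @param k_per_lead matched SNPs per lead.
#' @param maf_tolerance absolute MAF tolerance (frequency units).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return A `matched_null_draw`: list with `matches` (named list lead ->
#'   ids), `k_per_lead`, `maf_tolerance`, `seed`.
#' @export
draw_matched_null <- function(leads_maf, pool, k_per_lead = 10,
                              maf_tolerance = 0.01, seed = 1L) {
  pl <- as.data.table(pool)
  if (any(names(leads_maf) %in% pl$snp_id)) {
    stop("pool must exclude the lead SNPs themselves")
  }
  pool_maf <- pmin(pl$eaf, 1 - pl$eaf)
  used <- logical(nrow(pl))
  matches <- vector("list", length(leads_maf))
  names(matches) <- names(leads_maf)
  rng <- .with_seed(seed)
  on.exit(rng(), add = TRUE)
  for (i in seq_along(leads_maf)) {
    elig <- which(!used & abs(pool_maf - leads_maf[i]) <= maf_tolerance)
    if (length(elig) < k_per_lead) {
      stop(sprintf(
        "insufficient MAF-matched pool for lead %s: need %d, have %d",
        names(leads_maf)[i], k_per_lead, length(elig)))
    }
    take <- if (length(elig) == 1L) elig else sample(elig, k_per_lead)
    used[take] <- TRUE
    matches[[i]] <- pl$snp_id[take]
  }
  structure(list(matches = matches, k_per_lead = k_per_lead,
                 maf_tolerance = maf_tolerance, seed = seed),
            class = "matched_null_draw")
}

#' Mann-Whitney rank-sum enrichment test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test that the lead P values
#' are drawn from the same distribution as the matched-null P values, using
#' the normal approximation with tie correction. Returns the standardized
#' statistic so the direction and magnitude of the shift are visible.
#'
#' @param lead_pvalues,null_pvalues numeric vectors of P values.
#' @return list `(z, pvalue)`; negative `z` means the leads rank lower
#'   (smaller P values) than the null SNPs.
#' @export
mannwhitney_enrichment <- function(lead_pvalues, null_pvalues) {
  stopifnot(length(lead_pvalues) > 0, length(null_pvalues) > 0)
  n1 <- length(lead_pvalues)
  n2 <- length(null_pvalues)
  r <- rank(c(lead_pvalues, null_pvalues))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U for leads
  mu <- n1 * n2 / 2
  nties <- table(r)
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(z = 0, pvalue = 1))
  z <- (w - mu) / sqrt(sigma2)
  list(z = z, pvalue = 2 * pnorm(-abs(z)))
}

#' Fisher's exact test on two proportions of novel loci
#'
#' Two-sided Fisher's exact test (minimum-likelihood convention) on the
#' 2x2 table `(k1, n1 - k1; k2, n2 - k2)`, used to ask whether
#' proxy-informed candidate SNPs are enriched for loci later confirmed in a
#' larger target-trait GWAS.
#'
#' @param k1,n1 novel hits and set size in the proxy-informed group.
#' @param k2,n2 novel hits and set size in the reference group.
#' @return two-sided P value.
#' @export
novelty_proportions_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2,
                            byrow = TRUE))$p.value
}

# Run fn under a local RNG state seeded with `seed`; returns a restorer.
.with_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
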