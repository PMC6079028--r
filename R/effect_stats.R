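#' @importFrom stats pbinom dnorm rnorm rbinom runif sd cor var pchisq
#'   qchisq pf lm anova fisher.test setNames
NULL

#' Winner's-curse correction of a selected effect size
#'
#' Effect estimates at loci selected for significance are biased away from
#' zero. Given that a SNP was selected because `|beta_hat| / se` exceeded
#' the two-sided critical value for `alpha`, the corrected estimate is the
#' conditional maximum-likelihood value: the `beta` maximizing the density
#' of `beta_hat` under Normal(beta, se^2) truncated to the selection
#' region. It is solved by monotone bisection of the conditional score on
#' the bracket `[0, beta_hat]` (sign-symmetric), so the corrected value is
#' always shrunk toward zero and never changes sign.
#'
#' `method = "mean_inversion"` instead solves
#' `E[beta_hat | beta, selection] = beta_hat` for `beta` (a
#' conditional-mean inversion), provided for sensitivity analysis.
#'
#' @param beta_hat observed effect(s) (log OR for case-control traits).
#' @param se standard error(s), positive.
#' @param alpha two-sided selection threshold on the P value.
#' @param method `"cmle"` (default) or `"mean_inversion"`.
#' @return corrected beta(s), vectorized over inputs.
#' @export
winners_curse_correct <- function(beta_hat, se, alpha,
                                  method = c("cmle", "mean_inversion")) {
  method <- match.arg(method)
  stopifnot(all(se > 0), alpha > 0, alpha < 1)
  c0 <- qnorm(1 - alpha / 2)
  z <- abs(beta_hat) / se
  if (any(z < c0 - 1e-8)) {
    stop("SNP not significant at alpha: |beta_hat|/se below the critical value")
  }
  # work on the z scale; answer scales back by se and sign
  surv <- function(u) pnorm(u - c0) + pnorm(-u - c0)
  score <- if (method == "cmle") {
    # d/du log{ dnorm(z - u) / S(u) }
    function(u, zz) (zz - u) - (dnorm(u - c0) - dnorm(u + c0)) / surv(u)
  } else {
    # E[Z | selection] - z  (decreasing in u gap); root of z - E[Z|u]
    function(u, zz) zz - (u + (dnorm(c0 - u) - dnorm(-c0 - u)) / surv(u))
  }
  lo <- rep(0, length(z))
  hi <- z
  f_lo <- score(lo, z)
  # score at 0 is z >= 0; at z it is <= 0: bisect
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    f_mid <- score(mid, z)
    pos <- f_mid > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  u <- (lo + hi) / 2
  u[f_lo <= 0] <- 0  # selection so strong the corrected effect is 0
  sign(beta_hat) * u * se
}

#' Two-sided power of a Wald test
#'
#' `Phi(-c + beta/se) + Phi(-c - beta/se)` with `c` the two-sided critical
#' value at `alpha`. With `beta = 0` this equals `alpha` (size = level).
#'
#' @param beta true effect(s).
#' @param se standard error(s).
#' @param alpha two-sided significance threshold in (0,1).
#' @return power in `[0, 1]`, vectorized.
#' @export
power_two_sided <- function(beta, se, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  stopifnot(all(se > 0))
  c0 <- qnorm(1 - alpha / 2)
  pnorm(-c0 + beta / se) + pnorm(-c0 - beta / se)
}

#' Log-odds-ratio standard error from a case-control design
#'
#' `sqrt( 1 / (2 * maf * (1 - maf)) * (1 / n_cases + 1 / n_controls) )`
#' with `maf = min(eaf, 1 - eaf)`: the large-sample SE of an allele-based
#' log OR when the per-SNP SE is not reported.
#'
#' @param design a [case_control_design()].
#' @param eaf effect-allele frequency in (0,1).
#' @return standard error(s), vectorized over `eaf`.
#' @export
logor_se <- function(design, eaf) {
  stopifnot(inherits(design, "case_control_design"))
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must be strictly inside (0,1)")
  maf <- pmin(eaf, 1 - eaf)
  sqrt((1 / (2 * maf * (1 - maf))) *
         (1 / design$n_cases + 1 / design$n_controls))
}

#' Convert an odds ratio to variance explained
#'
#' Cohen's `d = ln(OR) * sqrt(3) / pi`, MAF correction factor
#' `a = 1 / (maf * (1 - maf))` (the `(n1+n2)^2 / (n1 n2)` group-imbalance
#' factor with group sizes proportional to allele frequencies), and
#' `R^2 = d^2 / (d^2 + a)`, returned as a fraction.
#'
#' @param or_value odds ratio(s), positive.
#' @param eaf effect-allele frequency in (0,1); folded internally.
#' @return R^2 as a fraction (multiply by 100 for percent), vectorized.
#' @export
or_to_r2 <- function(or_value, eaf) {
  stopifnot(all(or_value > 0))
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must be strictly inside (0,1)")
  maf <- pmin(eaf, 1 - eaf)
  d <- log(or_value) * sqrt(3) / pi
  a <- 1 / (maf * (1 - maf))
  d^2 / (d^2 + a)
}

#' Posterior probability that a significant association is true
#'
#' Bayes' rule on the significance event:
#' `(power * prior) / (power * prior + alpha * (1 - prior))`.
#'
#' @param power two-sided power at the selection threshold, in (0,1).
#' @param alpha the selection threshold, in (0,1).
#' @param prior prior probability of true association, in (0,1).
#' @return posterior probability, vectorized.
#' @export
bayesian_posterior <- function(power, alpha, prior) {
  stopifnot(all(power > 0 & power < 1), all(alpha > 0 & alpha < 1),
            all(prior > 0 & prior < 1))
  (power * prior) / (power * prior + alpha * (1 - prior))
}

#' Implied lower bound on the number of causal loci
#'
#' If every truly causal locus had the largest observed per-SNP effect
#' `r2_max`, the trait's SNP heritability `h2` would require at least
#' `h2 / r2_max` such loci — a conservative floor used to anchor prior
#' beliefs.
#'
#' @param h2 SNP heritability in (0,1].
#' @param r2_max largest observed per-SNP variance explained (fraction).
#' @return implied count (real).
#' @export
implied_causal_count <- function(h2, r2_max) {
  if (!(r2_max > 0 && r2_max <= h2 && h2 <= 1)) {
    stop("need 0 < r2_max <= h2 <= 1")
  }
  h2 / r2_max
}

#' Per-SNP credibility report
#'
#' For each SNP selected at `alpha`, computes the winner's-curse-corrected
#' beta and odds ratio, the two-sided power at the corrected effect (SE
#' reconstructed from the design and allele frequency when not supplied),
#' the variance explained by the corrected OR, and the Bayesian posterior
#' probability of true association over a grid of priors.
#'
#' @param snp_id,beta,eaf per-SNP identifier, observed log OR, and
#'   effect-allele frequency.
#' @param se per-SNP standard errors; if `NULL`, reconstructed via
#'   [logor_se()] from `design`.
#' @param alpha the selection threshold the SNPs passed.
#' @param design a [case_control_design()].
#' @param priors prior grid (default 0.1%, 1%, 5%, 10%).
#' @param power optional externally supplied power values (overrides the
#'   internal reconstruction, e.g. when reproducing published posteriors
#'   whose power calculation is not recoverable).
#' @return data.table with one row per SNP: corrected beta/OR, power,
#'   `r2_pct` (percent units) and one `posterior_<prior>` column per prior.
#' @export
credibility_table <- function(snp_id, beta, eaf, se = NULL, alpha,
                              design = NULL,
                              priors = c(0.001, 0.01, 0.05, 0.10),
                              power = NULL) {
  if (is.null(se)) {
    if (is.null(design)) stop("supply per-SNP se or a case_control_design")
    se <- logor_se(design, eaf)
  }
  corrected <- winners_curse_correct(beta, se, alpha)
  if (is.null(power)) power <- power_two_sided(corrected, se, alpha)
  out <- data.table(snp_id = snp_id, observed_beta = beta, se = se,
                    corrected_beta = corrected,
                    corrected_or = exp(corrected),
                    power = power,
                    r2_pct = 100 * or_to_r2(exp(corrected), eaf))
  for (p in priors) {
    out[, (sprintf("posterior_%g", p)) := bayesian_posterior(power, alpha, p)]
  }
  setattr(out, "alpha", alpha)
  setattr(out, "priors", priors)
  out
}
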