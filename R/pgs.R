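#' Build a polygenic score definition
#'
#' MAF-filters the summary statistics (dropping SNPs with effect-allele
#' frequency `<= maf_floor` or `>= 1 - maf_floor`), LD-clumps them, and
#' extracts one weight per surviving lead SNP. Weights are the table's
#' betas (natural-log odds ratios for case-control source traits).
#'
#' @param stats a harmonized `sumstat_table`.
#' @param panel a [genotype_panel()] for clumping.
#' @param p_threshold clumping P threshold (1 keeps every clump).
#' @param maf_floor allele-frequency floor (0 disables the filter).
#' @param r2_threshold,window_kb clumping parameters.
#' @param name score name recorded in the provenance.
#' @return A `score_definition`: data.table `(snp_id, effect_allele,
#'   weight)` with a `provenance` attribute.
#' @export
build_score <- function(stats, panel, p_threshold = 1, maf_floor = 0,
                        r2_threshold = 0.1, window_kb = 1000,
                        name = "score") {
  st <- as.data.table(stats)
  if (maf_floor > 0) {
    st <- st[st$eaf > maf_floor & st$eaf < 1 - maf_floor]
  }
  if (nrow(st) == 0L) stop("no SNPs left after the MAF filter")
  st2 <- sumstat_table(st, trait_label = attr(stats, "trait_label"))
  cl <- ld_clump(st2, panel, p_threshold = p_threshold,
                 r2_threshold = r2_threshold, window_kb = window_kb)
  keep <- st2[match(cl$lead_snps, st2$snp_id)]
  if (nrow(keep) == 0L) stop("empty score: no lead SNPs survived")
  def <- data.table(snp_id = keep$snp_id, effect_allele = keep$effect_allele,
                    weight = keep$beta)
  setattr(def, "class", c("score_definition", class(def)))
  setattr(def, "provenance",
          list(name = name, source_trait = attr(stats, "trait_label"),
               p_threshold = p_threshold, maf_floor = maf_floor,
               r2_threshold = r2_threshold, window_kb = window_kb))
  def
}

#' Split a score by cross-trait sign concordance
#'
#' Partitions a score's SNPs into a concordant set (the SNP's weight and
#' its beta in `other` share a sign) and a discordant set (opposite
#' signs). Two strategies:
#' * `"prune_then_split"` partitions the already-clumped parent score, so
#'   the two halves are LD-pruned both within and across sets and their
#'   union is exactly the parent (conservative).
#' * `"split_then_prune"` partitions the full harmonized SNP set
#'   (`stats`) by sign first and clumps within each half, yielding more
#'   SNPs in total because cross-set LD is not pruned.
#'
#' SNPs with no sign available in `other` (missing or zero beta) are
#' excluded with a count.
#'
#' @param score a `score_definition` (the parent).
#' @param other a `sumstat_table` providing the comparison signs, aligned
#'   to the same allele coding as the score's source.
#' @param strategy `"prune_then_split"` or `"split_then_prune"`.
#' @param stats full harmonized `sumstat_table` of the source trait
#'   (required for `"split_then_prune"`).
#' @param panel,r2_threshold,window_kb clumping parameters for
#'   `"split_then_prune"`.
#' @return list `(concordant, discordant, n_no_sign)` of two
#'   `score_definition`s.
#' @export
split_by_concordance <- function(score, other,
                                 strategy = c("prune_then_split",
                                              "split_then_prune"),
                                 stats = NULL, panel = NULL,
                                 r2_threshold = 0.1, window_kb = 1000) {
  strategy <- match.arg(strategy)
  ot <- as.data.table(other)
  prov <- attr(score, "provenance")
  mk <- function(def, suffix) {
    setattr(def, "class", c("score_definition", class(def)))
    p <- prov
    p$name <- paste0(prov$name, "_", suffix)
    p$split_rule <- paste0("sign_", strategy)
    setattr(def, "provenance", p)
    def
  }
  if (strategy == "prune_then_split") {
    i <- match(score$snp_id, ot$snp_id)
    sign_other <- sign(ot$beta[i])
    no_sign <- is.na(sign_other) | sign_other == 0 | score$weight == 0
    sc <- score[!no_sign]
    sign_other <- sign_other[!no_sign]
    conc <- sign(sc$weight) == sign_other
    list(concordant = mk(sc[conc], "concordant"),
         discordant = mk(sc[!conc], "discordant"),
         n_no_sign = sum(no_sign))
  } else {
    if (is.null(stats) || is.null(panel)) {
      stop("split_then_prune needs the full `stats` table and a panel")
    }
    st <- as.data.table(stats)
    i <- match(st$snp_id, ot$snp_id)
    sign_other <- sign(ot$beta[i])
    no_sign <- is.na(sign_other) | sign_other == 0 | st$beta == 0
    st <- st[!no_sign]
    sign_other <- sign_other[!no_sign]
    conc <- sign(st$beta) == sign_other
    clump_half <- function(half) {
      tb <- sumstat_table(half, trait_label = attr(stats, "trait_label"))
      cl <- ld_clump(tb, panel, p_threshold = 1,
                     r2_threshold = r2_threshold, window_kb = window_kb)
      keep <- tb[match(cl$lead_snps, tb$snp_id)]
      data.table(snp_id = keep$snp_id, effect_allele = keep$effect_allele,
                 weight = keep$beta)
    }
    list(concordant = mk(clump_half(st[conc]), "concordant"),
         discordant = mk(clump_half(st[!conc]), "discordant"),
         n_no_sign = sum(no_sign))
  }
}

#' Compute per-individual polygenic scores
#'
#' For each score definition, sums `weight * dosage` over the score's SNPs
#' present in the cohort genotypes (flipping the weight sign when the
#' cohort counts the other allele). Under the `"sum"` convention missing
#' dosages contribute zero; under `"average_per_allele"` the sum is
#' divided by twice the per-individual count of non-missing score SNPs.
#' The sum convention makes a parent score exactly the sum of its
#' concordant and discordant halves.
#'
#' @param defs a `score_definition` or list of them.
#' @param cohort a [genotype_panel()] (or `cohort_data`) holding the
#'   target-cohort genotypes.
#' @param convention `"sum"` (default) or `"average_per_allele"`.
#' @return data.table with `id` and one column per score.
#' @export
compute_scores <- function(defs, cohort,
                           convention = c("sum", "average_per_allele")) {
  convention <- match.arg(convention)
  if (inherits(defs, "score_definition")) defs <- list(defs)
  panel <- if (inherits(cohort, "cohort_data")) cohort$panel else cohort
  G <- panel$dosages
  ids <- rownames(G)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(G)))
  out <- data.table(id = ids)
  for (d in defs) {
    nm <- attr(d, "provenance")$name
    if (is.null(nm)) nm <- "score"
    i <- match(d$snp_id, panel$map$snp_id)
    ok <- !is.na(i)
    if (!any(ok)) stop("score '", nm, "' shares no SNPs with the cohort")
    w <- d$weight[ok]
    pi <- i[ok]
    # flip weights coded on the cohort's other allele
    flip <- panel$map$a1[pi] != d$effect_allele[ok]
    w[flip] <- -w[flip]
    X <- G[, pi, drop = FALSE]
    na <- is.na(X)
    X[na] <- 0
    s <- as.numeric(X %*% w)
    # allele flips shift the score by 2*sum(w_flipped); keep the raw sum —
    # a constant offset is irrelevant for standardized regression use
    if (convention == "average_per_allele") {
      denom <- 2 * rowSums(!na)
      s <- ifelse(denom > 0, s / denom, NA_real_)
    }
    out[, (nm) := s]
  }
  out
}

#' Nested-model F test for polygenic heterogeneity
#'
#' Compares a baseline ordinary-least-squares model of an outcome on the
#' parent score (plus a companion proxy-trait score and covariates)
#' against a split model in which the parent score is replaced by its
#' concordant and discordant halves. With sum-convention scores the
#' baseline is exactly nested in the split model, and the F test on the
#' one-parameter difference asks whether splitting by cross-trait sign
#' concordance improves prediction — evidence of genetic heterogeneity.
#' All scores are standardized to unit variance within the complete-case
#' analysis sample; coefficients are reported per standard deviation.
#'
#' @param data data.frame holding the outcome, score columns, and
#'   covariates (complete cases are selected internally).
#' @param outcome outcome column name.
#' @param parent,conc,disc column names of the parent score and its two
#'   halves.
#' @param ea optional column name of the companion (proxy-trait) score
#'   included in both models.
#' @param covariates character vector of covariate column names.
#' @return A `het_test_result`: list with `baseline` and `split`
#'   (coefficients, standardized betas, `r2`, `adj_r2`), `delta_r2`,
#'   `delta_adj_r2`, `f_statistic`, `df1`, `df2`, `pvalue`, `n`.
#' @export
heterogeneity_f_test <- function(data, outcome, parent, conc, disc,
                                 ea = NULL, covariates = character()) {
  cols <- c(outcome, parent, conc, disc, ea, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(data)[, cols]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  for (sc in c(parent, conc, disc, ea)) {
    s <- stats::sd(df[[sc]])
    if (s == 0) stop("score '", sc, "' is constant in the analysis sample")
    df[[sc]] <- (df[[sc]] - mean(df[[sc]])) / s
  }
  rhs_base <- paste(sprintf("`%s`", c(parent, ea, covariates)),
                    collapse = " + ")
  rhs_split <- paste(sprintf("`%s`", c(conc, disc, ea, covariates)),
                     collapse = " + ")
  f_base <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs_base))
  f_split <- stats::as.formula(paste(sprintf("`%s`", outcome), "~", rhs_split))
  m_base <- lm(f_base, data = df)
  m_split <- lm(f_split, data = df)
  if (any(is.na(stats::coef(m_split)))) {
    bad <- names(stats::coef(m_split))[is.na(stats::coef(m_split))]
    stop("rank-deficient split design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  ssr_base <- sum(stats::resid(m_base)^2)
  ssr_split <- sum(stats::resid(m_split)^2)
  df1 <- length(stats::coef(m_split)) - length(stats::coef(m_base))
  df2 <- n - length(stats::coef(m_split))
  f_stat <- ((ssr_base - ssr_split) / df1) / (ssr_split / df2)
  pval <- pf(f_stat, df1, df2, lower.tail = FALSE)
  summ <- function(m) {
    sm <- summary(m)
    list(coefficients = stats::coef(sm), r2 = sm$r.squared,
         adj_r2 = sm$adj.r.squared)
  }
  b <- summ(m_base); s <- summ(m_split)
  structure(list(baseline = b, split = s,
                 delta_r2 = s$r2 - b$r2,
                 delta_adj_r2 = s$adj_r2 - b$adj_r2,
                 f_statistic = f_stat, df1 = df1, df2 = df2,
                 pvalue = pval, n = n),
            class = "het_test_result")
}

#' @export
print.het_test_result <- function(x, ...) {
  cat(sprintf(
    "heterogeneity F test: F(%d, %d) = %.3f, P = %.4g (n = %d)\n",
    x$df1, x$df2, x$f_statistic, x$pvalue, x$n))
  cat(sprintf("  baseline adj R2 = %.4f, split adj R2 = %.4f, delta = %.4f\n",
              x$baseline$adj_r2, x$split$adj_r2, x$delta_adj_r2))
  invisible(x)
}

#' Random-split permutation control for the heterogeneity test
#'
#' Repeats the heterogeneity F test with uniformly random partitions of
#' the parent score's SNPs into sets of the same sizes as the observed
#' concordant/discordant split. If the sign-based split captures real
#' heterogeneity, its F statistic should exceed most random splits.
#'
#' @param parent a `score_definition`.
#' @param cohort a [genotype_panel()] (or `cohort_data`) with the target
#'   cohort's genotypes.
#' @param data data.frame with outcome and covariates, rows aligned to the
#'   cohort's samples.
#' @param outcome,ea,covariates passed to [heterogeneity_f_test()]; `ea`
#'   names a column already present in `data` (or `NULL`).
#' @param n_conc,n_disc sizes of the observed split (preserved in every
#'   permutation).
#' @param observed_f the observed sign-based split's F statistic.
#' @param n_permutations at least 100.
#' @param seed integer seed.
#' @return list `(pvalues, f_statistics, observed_f, rank, exceed_share)`:
#'   `rank` is the empirical rank of `observed_f` among the permuted F's,
#'   `exceed_share` the share of permutations it exceeds.
#' @export
random_split_control <- function(parent, cohort, data, outcome, ea = NULL,
                                 covariates = character(),
                                 n_conc, n_disc, observed_f = NA_real_,
                                 n_permutations = 100, seed = 1L) {
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  stopifnot(n_conc + n_disc <= nrow(parent))
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  fs <- numeric(n_permutations)
  ps <- numeric(n_permutations)
  m <- nrow(parent)
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(m, n_conc + n_disc)
    c_def <- parent[idx[seq_len(n_conc)]]
    d_def <- parent[idx[(n_conc + 1):(n_conc + n_disc)]]
    setattr(c_def, "class", class(parent))
    setattr(d_def, "class", class(parent))
    setattr(c_def, "provenance", list(name = ".perm_conc"))
    setattr(d_def, "provenance", list(name = ".perm_disc"))
    sc <- compute_scores(list(c_def, d_def, .named_parent(parent)), cohort)
    dd <- cbind(as.data.frame(data), as.data.frame(sc[, -1]))
    ht <- heterogeneity_f_test(dd, outcome, parent = ".perm_parent",
                               conc = ".perm_conc", disc = ".perm_disc",
                               ea = ea, covariates = covariates)
    fs[b] <- ht$f_statistic
    ps[b] <- ht$pvalue
  }
  exceed <- mean(observed_f > fs)
  list(pvalues = ps, f_statistics = fs, observed_f = observed_f,
       rank = sum(observed_f > fs) + 1L, exceed_share = exceed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.named_parent <- function(parent) {
  p <- copy(parent)
  setattr(p, "class", class(parent))
  setattr(p, "provenance", list(name = ".perm_parent"))
  p
}
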