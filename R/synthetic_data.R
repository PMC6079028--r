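#' Mixture genetic architecture for two dependent traits
#'
#' Describes the generator's study design: LD-blocked genotypes and two
#' traits whose causal SNPs fall into five classes — concordant (same-sign
#' effects on both traits), discordant (opposite-sign), specific to either
#' trait, and null. With equal concordant and discordant shares the true
#' per-SNP effect correlation cancels to ~0 while the shared causal
#' fraction stays large: genetic dependence without genetic correlation,
#' the pattern the proxy-phenotype and split-score analyses are designed
#' to detect.
#'
#' Defaults: 20,000 SNPs in 2,000 blocks (10 SNPs each), per-block latent
#' correlation uniform on (0.3, 0.9), MAF uniform on (0.05, 0.5), class
#' fractions 0.25/0.25/0.10/0.10/0.30 (the hypothesized architecture is
#' dominated by shared loci of mixed sign), heritabilities 0.25
#' (quantitative trait a) and 0.21 (liability of case-control trait b),
#' prevalence 0.10, and one symptom measure loading +0.6 on the
#' concordant genic component and -0.6 on the discordant one. The
#' vignette discusses these choices.
#'
#' @param m_snps,n_blocks total SNPs and LD blocks (`m_snps` divisible by
#'   `n_blocks`).
#' @param within_block_r latent within-block correlation in `[0, 1)`; a
#'   length-2 vector draws each block's correlation uniformly from that
#'   range, giving variable LD (and hence a spread of LD scores) across
#'   the genome.
#' @param maf_range MAF sampling range.
#' @param f_concordant,f_discordant,f_specific_a,f_specific_b,f_null
#'   class fractions; must sum to 1.
#' @param h2_a,h2_b heritabilities (trait b on the liability scale).
#' @param h2_c heritability of the auxiliary shared-component trait (the
#'   second psychiatric trait used by the purging analysis).
#' @param c_share share of trait c's genic variance drawn from trait b's
#'   concordant component (the planted overlap that purging removes).
#' @param prevalence_k population prevalence of the case-control trait.
#' @param symptom_loadings named list: symptom -> numeric
#'   `c(loading_on_concordant, loading_on_discordant, noise_sd)`.
#' @param maf_effect_coupling if nonzero, per-SNP effect standard
#'   deviations are scaled by `(2 maf (1-maf))^(-coupling/2)` so that
#'   rarer alleles get larger effects — a mode that demonstrates the
#'   allele-frequency assumption of LD-score-based tests.
#' @return An `architecture_spec` list; the implied true effect-size
#'   correlation is available via [implied_rg()].
#' @export
architecture_spec <- function(m_snps = 20000L, n_blocks = 2000L,
                              within_block_r = c(0.3, 0.9),
                              maf_range = c(0.05, 0.5),
                              f_concordant = 0.25, f_discordant = 0.25,
                              f_specific_a = 0.10, f_specific_b = 0.10,
                              f_null = 0.30,
                              h2_a = 0.25, h2_b = 0.21,
                              h2_c = 0.21, c_share = 0.6,
                              prevalence_k = 0.10,
                              symptom_loadings = list(
                                severity = c(0.6, -0.6, 0.53)),
                              maf_effect_coupling = 0) {
  fr <- c(f_concordant, f_discordant, f_specific_a, f_specific_b, f_null)
  if (abs(sum(fr) - 1) > 1e-12) stop("class fractions must sum to 1")
  stopifnot(m_snps %% n_blocks == 0,
            all(within_block_r >= 0), all(within_block_r < 1),
            length(within_block_r) %in% 1:2,
            h2_a >= 0, h2_a <= 1, h2_b >= 0, h2_b <= 1,
            prevalence_k > 0, prevalence_k < 1)
  structure(list(m_snps = as.integer(m_snps), n_blocks = as.integer(n_blocks),
                 within_block_r = within_block_r, maf_range = maf_range,
                 f_concordant = f_concordant, f_discordant = f_discordant,
                 f_specific_a = f_specific_a, f_specific_b = f_specific_b,
                 f_null = f_null, h2_a = h2_a, h2_b = h2_b,
                 h2_c = h2_c, c_share = c_share,
                 prevalence_k = prevalence_k,
                 symptom_loadings = symptom_loadings,
                 maf_effect_coupling = maf_effect_coupling),
            class = "architecture_spec")
}

#' Closed-form implied effect-size correlation
#'
#' The correlation of the true per-SNP effects of traits a and b implied
#' by the mixture: concordant pairs contribute `+ (2/pi) sd_a sd_b` per
#' SNP (sign-matched folded normals), discordant pairs the negative, and
#' specific/null SNPs contribute variance to one or neither trait.
#'
#' @param spec an [architecture_spec()].
#' @return implied correlation of true effect sizes.
#' @export
implied_rg <- function(spec) {
  va <- spec$h2_a / (spec$f_concordant + spec$f_discordant + spec$f_specific_a)
  vb <- spec$h2_b / (spec$f_concordant + spec$f_discordant + spec$f_specific_b)
  cov_term <- (2 / pi) * sqrt(va * vb) *
    (spec$f_concordant - spec$f_discordant)
  cov_term / sqrt(spec$h2_a * spec$h2_b)
}

# variant map shared by every cohort drawn from one spec
.sim_variant_map <- function(spec) {
  m <- spec$m_snps
  per_block <- m %/% spec$n_blocks
  block <- rep(seq_len(spec$n_blocks), each = per_block)
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  within <- sequence(rep(per_block, spec$n_blocks))
  block_on_chrom <- ((block - 1L) %/% 22L)
  # blocks 5 Mb apart, SNPs 1 kb apart within a block: clumping windows of
  # up to 1 Mb never bridge blocks
  pos <- 1e6L + block_on_chrom * 5000000L + within * 1000L
  r <- spec$within_block_r
  block_r <- if (length(r) == 2L) runif(spec$n_blocks, r[1], r[2]) else
    rep(r, spec$n_blocks)
  maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
  alleles <- matrix(sample(VALID_ALLELES, 2 * m, replace = TRUE), ncol = 2)
  swap <- alleles[, 1] == alleles[, 2]
  while (any(swap)) {
    alleles[swap, 2] <- sample(VALID_ALLELES, sum(swap), replace = TRUE)
    swap <- alleles[, 1] == alleles[, 2]
  }
  data.table(snp_id = sprintf("rs%06d", seq_len(m)), chrom = chrom,
             pos = as.integer(pos), a1 = alleles[, 1], a2 = alleles[, 2],
             maf = maf, block = block, block_r = block_r[block])
}

#' Simulate LD-blocked genotypes
#'
#' Gaussian-copula genotypes: each gamete's latent value within a block is
#' `sqrt(r) * u_block + sqrt(1 - r) * e`, thresholded at the SNP's MAF
#' quantile, and the dosage is the sum of two independent gametes — so
#' every SNP is in Hardy-Weinberg equilibrium at its MAF and SNPs within a
#' block are exchangeably correlated while blocks are independent.
#'
#' @param spec an [architecture_spec()].
#' @param n_individuals samples to draw.
#' @param seed integer seed.
#' @param map optional precomputed variant map (internal use: shares one
#'   map across cohorts).
#' @return A [genotype_panel()]; the map (with per-SNP `maf` and `block`)
#'   is carried in `$map`.
#' @export
simulate_genotypes <- function(spec, n_individuals, seed = 1L, map = NULL) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  if (is.null(map)) map <- .sim_variant_map(spec)
  n <- n_individuals
  m <- nrow(map)
  r_col <- if ("block_r" %in% names(map)) map$block_r else
    rep(spec$within_block_r[1], m)
  thr <- qnorm(1 - map$maf)
  G <- matrix(0L, nrow = n, ncol = m)
  per_block <- m %/% spec$n_blocks
  # chunk over blocks to bound peak memory at large n * m
  chunk_blocks <- max(1L, min(spec$n_blocks, ceiling(4e6 / n / per_block)))
  starts <- seq(1L, spec$n_blocks, by = chunk_blocks)
  for (gamete in 1:2) {
    for (s in starts) {
      bl <- s:min(s + chunk_blocks - 1L, spec$n_blocks)
      cols <- ((bl[1] - 1L) * per_block + 1L):(bl[length(bl)] * per_block)
      u <- matrix(rnorm(n * length(bl)), n, length(bl))
      u <- u[, rep(seq_along(bl), each = per_block), drop = FALSE]
      rc <- r_col[cols]
      z <- sweep(u, 2, sqrt(rc), "*") +
        sweep(matrix(rnorm(n * length(cols)), n, length(cols)), 2,
              sqrt(1 - rc), "*")
      G[, cols] <- G[, cols] +
        (z > matrix(thr[cols], n, length(cols), byrow = TRUE))
    }
  }
  storage.mode(G) <- "integer"
  colnames(G) <- map$snp_id
  genotype_panel(G, map[, c("snp_id", "chrom", "pos", "a1", "a2"),
                        with = FALSE]) -> p
  p$map <- copy(map)
  p
}

#' Draw true per-SNP effects under the mixture architecture
#'
#' Assigns each SNP a class by the spec's fractions, then draws effects on
#' the standardized-genotype scale with per-class variance scaled so that
#' the total genic variance of each trait equals its `h2`. Concordant
#' SNPs get sign-matched effect pairs, discordant SNPs opposite-signed
#' pairs, specific SNPs affect one trait only. Trait c (the auxiliary
#' psychiatric trait) shares trait b's concordant component.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed.
#' @param map variant map (from [simulate_genotypes()]'s panel or
#'   internal).
#' @return A `truth_table`: data.table `(snp_id, class, beta_a, beta_b,
#'   beta_c)` with the realized effect correlation as an attribute.
#' @export
draw_effects <- function(spec, seed = 1L, map = NULL) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  if (is.null(map)) map <- .sim_variant_map(spec)
  m <- nrow(map)
  classes <- sample(c("concordant", "discordant", "specific_a",
                      "specific_b", "null"), m, replace = TRUE,
                    prob = c(spec$f_concordant, spec$f_discordant,
                             spec$f_specific_a, spec$f_specific_b,
                             spec$f_null))
  # per-SNP variance so that expected total genic variance hits h2
  va <- spec$h2_a /
    (m * (spec$f_concordant + spec$f_discordant + spec$f_specific_a))
  vb <- spec$h2_b /
    (m * (spec$f_concordant + spec$f_discordant + spec$f_specific_b))
  beta_a <- numeric(m)
  beta_b <- numeric(m)
  scl <- if (spec$maf_effect_coupling != 0) {
    het <- 2 * map$maf * (1 - map$maf)
    (het / mean(het))^(-spec$maf_effect_coupling / 2)
  } else rep(1, m)
  shared <- classes %in% c("concordant", "discordant")
  s <- sample(c(-1, 1), m, replace = TRUE)
  beta_a[shared] <- s[shared] * abs(rnorm(sum(shared), 0, sqrt(va)))
  bsign <- ifelse(classes == "concordant", s, -s)
  beta_b[shared] <- bsign[shared] * abs(rnorm(sum(shared), 0, sqrt(vb)))
  ia <- classes == "specific_a"
  ib <- classes == "specific_b"
  beta_a[ia] <- rnorm(sum(ia), 0, sqrt(va))
  beta_b[ib] <- rnorm(sum(ib), 0, sqrt(vb))
  beta_a <- beta_a * scl
  beta_b <- beta_b * scl
  # trait c: c_share of genic variance from b's concordant component,
  # remainder from its own SNPs drawn among the null class
  conc <- classes == "concordant"
  beta_c <- numeric(m)
  vb_conc <- sum(beta_b[conc]^2)
  if (vb_conc > 0) {
    beta_c[conc] <- beta_b[conc] * sqrt(spec$h2_c * spec$c_share / vb_conc)
  }
  own <- which(classes == "null")
  own <- own[seq_len(min(length(own), floor(m * spec$f_specific_b)))]
  if (length(own)) {
    raw <- rnorm(length(own))
    beta_c[own] <- raw * sqrt(spec$h2_c * (1 - spec$c_share) / sum(raw^2))
  }
  out <- data.table(snp_id = map$snp_id, class = classes,
                    beta_a = beta_a, beta_b = beta_b, beta_c = beta_c)
  setattr(out, "class", c("truth_table", class(out)))
  setattr(out, "realized_effect_cor",
          suppressWarnings(cor(beta_a, beta_b)))
  out
}

.standardize_dosages <- function(panel) {
  maf <- panel$map$maf
  if (is.null(maf)) {
    maf <- colMeans(panel$dosages, na.rm = TRUE) / 2
  }
  sweep(sweep(panel$dosages, 2, 2 * maf), 2, sqrt(2 * maf * (1 - maf)), "/")
}

#' Simulate phenotypes from genotypes and true effects
#'
#' Quantitative trait a is genic value plus normal noise scaled to unit
#' total variance. Trait b follows the liability-threshold model: a unit
#' liability whose upper `prevalence_k` tail is labelled case. Trait c is
#' a second liability trait. For cases, each symptom in the spec is the
#' stated loadings applied to the individual's standardized concordant-
#' and discordant-component genic values plus noise.
#'
#' @param panel a [genotype_panel()] from [simulate_genotypes()].
#' @param truth a `truth_table` from [draw_effects()].
#' @param spec the [architecture_spec()].
#' @param seed integer seed.
#' @return data.table with `id`, `trait_a`, `liability_b`, `case_b`,
#'   `liability_c`, `case_c`, genic components `genic_conc`, `genic_disc`,
#'   and one column per symptom (`NA` for non-cases).
#' @export
simulate_phenotypes <- function(panel, truth, spec, seed = 1L) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  X <- .standardize_dosages(panel)
  n <- nrow(X)
  ga <- as.numeric(X %*% truth$beta_a)
  gb <- as.numeric(X %*% truth$beta_b)
  gc_ <- as.numeric(X %*% truth$beta_c)
  ya <- ga + rnorm(n, 0, sqrt(max(1 - spec$h2_a, 0)))
  lb <- gb + rnorm(n, 0, sqrt(max(1 - spec$h2_b, 0)))
  lc <- gc_ + rnorm(n, 0, sqrt(max(1 - spec$h2_c, 0)))
  thr <- qnorm(1 - spec$prevalence_k)
  conc <- truth$class == "concordant"
  disc <- truth$class == "discordant"
  gcn <- as.numeric(X[, conc, drop = FALSE] %*% truth$beta_b[conc])
  gds <- as.numeric(X[, disc, drop = FALSE] %*% truth$beta_b[disc])
  zs <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v
  out <- data.table(id = rownames(panel$dosages) %||%
                      as.character(seq_len(n)),
                    trait_a = ya, liability_b = lb,
                    case_b = as.integer(lb > thr),
                    liability_c = lc, case_c = as.integer(lc > thr),
                    genic_conc = zs(gcn), genic_disc = zs(gds))
  for (sym in names(spec$symptom_loadings)) {
    ld <- spec$symptom_loadings[[sym]]
    v <- ld[1] * out$genic_conc + ld[2] * out$genic_disc +
      rnorm(n, 0, ld[3])
    v[out$case_b == 0L] <- NA_real_
    out[, (sym) := v]
  }
  out
}

#' Per-SNP GWAS on a simulated cohort
#'
#' Quantitative traits: simple per-SNP ordinary least squares (exact
#' closed form, vectorized). Case-control: one-step logistic score
#' statistics — `U = g'(y - ybar)`, `V = ybar (1 - ybar) * SS_g`,
#' `beta = U / V` (a log-OR-scale estimate), `se = 1 / sqrt(V)` — the
#' standard large-sample approximation to per-SNP logistic regression.
#' Monomorphic SNPs are emitted with missing statistics and flagged.
#'
#' @param panel cohort genotypes (a [genotype_panel()]).
#' @param phenotype numeric vector (0/1 for case-control).
#' @param type `"linear"` or `"case_control"`.
#' @param trait_label label for the output table.
#' @return A `sumstat_table` (monomorphic SNPs dropped by validation are
#'   counted in its `qc` attribute).
#' @export
run_gwas <- function(panel, phenotype, type = c("linear", "case_control"),
                     trait_label = "simtrait") {
  type <- match.arg(type)
  G <- panel$dosages
  n <- nrow(G)
  stopifnot(length(phenotype) == n)
  eaf <- colMeans(G) / 2
  gc_ <- sweep(G, 2, 2 * eaf)  # centered dosages
  ssg <- colSums(gc_^2)
  mono <- ssg == 0
  if (type == "linear") {
    y <- phenotype - mean(phenotype)
    xy <- as.numeric(crossprod(gc_, y))
    beta <- xy / ssg
    # residual variance of simple OLS, exact
    rss <- sum(y^2) - beta * xy
    se <- sqrt(pmax(rss, 0) / (n - 2) / ssg)
  } else {
    y <- phenotype
    pbar <- mean(y)
    u <- as.numeric(crossprod(gc_, y - pbar))
    v <- pbar * (1 - pbar) * ssg
    beta <- u / v
    se <- 1 / sqrt(v)
  }
  z <- beta / se
  pv <- 2 * pnorm(-abs(z))
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) emitted with missing statistics")
  }
  dt <- data.table(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                   pos = panel$map$pos, effect_allele = panel$map$a1,
                   other_allele = panel$map$a2, eaf = eaf,
                   beta = beta, se = se, pvalue = pmax(pv, 1e-320),
                   n_eff = n)
  sumstat_table(dt, trait_label = trait_label,
                design = if (type == "case_control") {
                  case_control_design(sum(y == 1), sum(y == 0))
                } else NULL)
}

#' Assortative-mating forward simulation
#'
#' Each generation, individuals are split into two mating pools and
#' rank-matched on a noisy copy of the phenotype, with the noise sized so
#' that the expected spousal phenotype correlation approximates
#' `spouse_corr`; each couple produces two offspring by per-SNP Mendelian
#' transmission (binomial draws from parental dosages), and phenotypes are
#' regenerated from the truth table. Assortment on a heritable trait
#' builds gametic-phase disequilibrium, inflating that trait's genic
#' variance across generations.
#'
#' @param panel founder genotypes.
#' @param truth a `truth_table`.
#' @param spec the [architecture_spec()].
#' @param spouse_corr target spousal phenotype correlation in `[0, 1)`.
#' @param generations number of generations (>= 1).
#' @param mate_on which phenotype drives assortment: `"trait_a"` or
#'   `"liability_b"`.
#' @param seed integer seed.
#' @return list `(panel, phenotypes)` for the final generation.
#' @export
assortative_mating <- function(panel, truth, spec, spouse_corr = 0.4,
                               generations = 1L, mate_on = "trait_a",
                               seed = 1L) {
  stopifnot(spouse_corr >= 0, spouse_corr < 1, generations >= 1)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  G <- panel$dosages
  map <- panel$map
  phen <- simulate_phenotypes(panel, truth, spec,
                              seed = sample.int(.Machine$integer.max, 1))
  for (g in seq_len(generations)) {
    n <- nrow(G)
    if (n %% 2L == 1L) {
      warning("odd cohort size: last individual unmatched and dropped")
      G <- G[-n, , drop = FALSE]
      phen <- phen[-n]
      n <- n - 1L
    }
    y <- phen[[mate_on]]
    half <- sample.int(n, n / 2)
    a_idx <- half
    b_idx <- setdiff(seq_len(n), half)
    # rank-match pool B on a noisy copy of its phenotype: spouse
    # correlation ~ spouse_corr for large n
    if (spouse_corr > 0) {
      noise_sd <- sqrt(1 / spouse_corr^2 - 1) * sd(y)
      a_ord <- a_idx[order(y[a_idx])]
      b_ord <- b_idx[order(y[b_idx] + rnorm(n / 2, 0, noise_sd))]
    } else {
      a_ord <- a_idx[sample.int(n / 2)]
      b_ord <- b_idx
    }
    m <- ncol(G)
    kids <- matrix(0L, n, m)
    for (k in 1:2) {
      off <- matrix(
        rbinom(length(a_ord) * m, 1L, as.numeric(G[a_ord, ]) / 2) +
          rbinom(length(b_ord) * m, 1L, as.numeric(G[b_ord, ]) / 2),
        nrow = length(a_ord))
      kids[seq((k - 1) * n / 2 + 1, k * n / 2), ] <- off
    }
    storage.mode(kids) <- "integer"
    colnames(kids) <- map$snp_id
    G <- kids
    newp <- genotype_panel(G, map[, c("snp_id", "chrom", "pos", "a1", "a2"),
                                  with = FALSE])
    newp$map <- copy(map)
    phen <- simulate_phenotypes(newp, truth, spec,
                                seed = sample.int(.Machine$integer.max, 1))
  }
  list(panel = newp, phenotypes = phen)
}

#' Simulate the full cross-trait study
#'
#' Generates everything the analysis pipeline consumes, from one spec and
#' one seed: a reference panel; a quantitative-trait GWAS cohort (trait
#' a, the schooling-like proxy trait); a case-control GWAS cohort (trait
#' b, the disease target) ascertained under the liability-threshold model
#' with a balanced case-control design (all cases plus an equal number of
#' controls, `n_eff` = total included); a second case-control GWAS for the
#' auxiliary shared-component trait c; and a deeply phenotyped patient
#' cohort (cases and screened controls with symptom measures and genetic
#' principal components) disjoint from every GWAS cohort by construction.
#'
#' @param spec an [architecture_spec()].
#' @param seed master seed; per-stage seeds are derived as
#'   `seed * 1000 + stage` (documented counter scheme).
#' @param n_gwas_a,n_gwas_b,n_gwas_c GWAS cohort sizes (pool size for the
#'   case-control traits, pre-ascertainment).
#' @param n_panel reference-panel samples.
#' @param n_patients patient-cohort target size (half cases, half
#'   controls).
#' @param n_pcs genetic principal components computed for the patient
#'   cohort.
#' @return A `sim_output` list: `spec`, `seed`, `map`, `truth`, `panel`,
#'   `sumstats_a`, `sumstats_b`, `sumstats_c`, and `patients` (a
#'   `cohort_data`: `panel`, `data` with case status, symptoms, PCs).
#' @export
simulate_study <- function(spec, seed = 1L,
                           n_gwas_a = 20000L, n_gwas_b = 20000L,
                           n_gwas_c = 20000L, n_panel = 2000L,
                           n_patients = 1000L, n_pcs = 10L) {
  st_seed <- function(k) (seed * 1000L + k) %% .Machine$integer.max
  restore <- .with_seed(st_seed(0L))
  on.exit(restore(), add = TRUE)
  map <- .sim_variant_map(spec)
  truth <- draw_effects(spec, seed = st_seed(1L), map = map)

  panel <- simulate_genotypes(spec, n_panel, seed = st_seed(2L), map = map)

  # cohort A: quantitative proxy trait
  pa <- simulate_genotypes(spec, n_gwas_a, seed = st_seed(3L), map = map)
  fa <- simulate_phenotypes(pa, truth, spec, seed = st_seed(4L))
  sumstats_a <- run_gwas(pa, fa$trait_a, "linear", trait_label = "trait_a")
  rm(pa)

  # cohort B: case-control target trait, balanced ascertainment
  pb <- simulate_genotypes(spec, n_gwas_b, seed = st_seed(5L), map = map)
  fb <- simulate_phenotypes(pb, truth, spec, seed = st_seed(6L))
  sel_b <- .ascertain_balanced(fb$case_b, st_seed(7L))
  pb_sub <- .subset_panel(pb, sel_b)
  sumstats_b <- run_gwas(pb_sub, fb$case_b[sel_b], "case_control",
                         trait_label = "trait_b")
  rm(pb, pb_sub)

  # cohort C: auxiliary shared-component case-control trait
  pc <- simulate_genotypes(spec, n_gwas_c, seed = st_seed(8L), map = map)
  fc <- simulate_phenotypes(pc, truth, spec, seed = st_seed(9L))
  sel_c <- .ascertain_balanced(fc$case_c, st_seed(10L))
  pc_sub <- .subset_panel(pc, sel_c)
  sumstats_c <- run_gwas(pc_sub, fc$case_c[sel_c], "case_control",
                         trait_label = "trait_c")
  rm(pc, pc_sub)

  # patient cohort: half cases, half screened controls, with symptoms
  pool_n <- max(ceiling(n_patients / (2 * spec$prevalence_k) * 1.3),
                2L * n_patients)
  pp <- simulate_genotypes(spec, pool_n, seed = st_seed(11L), map = map)
  fp <- simulate_phenotypes(pp, truth, spec, seed = st_seed(12L))
  ncase <- min(sum(fp$case_b == 1L), n_patients %/% 2L)
  restore2 <- .with_seed(st_seed(13L))
  cases <- sample(which(fp$case_b == 1L), ncase)
  ctrls <- sample(which(fp$case_b == 0L), n_patients - ncase)
  restore2()
  sel_p <- sort(c(cases, ctrls))
  patients_panel <- .subset_panel(pp, sel_p)
  pdata <- fp[sel_p]
  rm(pp)
  pcs <- .genetic_pcs(patients_panel, n_pcs)
  pdata <- cbind(pdata, pcs)
  patients <- structure(list(panel = patients_panel, data = pdata),
                        class = "cohort_data")

  structure(list(spec = spec, seed = seed, map = map, truth = truth,
                 panel = panel, sumstats_a = sumstats_a,
                 sumstats_b = sumstats_b, sumstats_c = sumstats_c,
                 patients = patients),
            class = "sim_output")
}

.ascertain_balanced <- function(case, seed) {
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  cases <- which(case == 1L)
  ctrls <- which(case == 0L)
  k <- min(length(cases), length(ctrls))
  sort(c(cases[seq_len(min(length(cases), k))], sample(ctrls, k)))
}

.subset_panel <- function(panel, rows) {
  p <- genotype_panel(panel$dosages[rows, , drop = FALSE],
                      panel$map[, c("snp_id", "chrom", "pos", "a1", "a2"),
                                with = FALSE])
  p$map <- copy(panel$map)
  p
}

.genetic_pcs <- function(panel, n_pcs) {
  X <- .standardize_dosages(panel)
  # PCs from a thinned SNP set keep this cheap at any m
  keep <- seq(1, ncol(X), by = max(1L, ncol(X) %/% 2000L))
  pr <- stats::prcomp(X[, keep, drop = FALSE], center = FALSE,
                      scale. = FALSE, rank. = n_pcs)
  pcs <- pr$x
  colnames(pcs) <- paste0("PC", seq_len(ncol(pcs)))
  as.data.table(pcs)
}
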