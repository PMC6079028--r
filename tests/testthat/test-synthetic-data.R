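test_that("architecture_spec validates fractions and exposes implied rg", {
  expect_error(architecture_spec(f_null = 0.9), "sum to 1")
  spec <- architecture_spec(m_snps = 1000L, n_blocks = 100L)
  # balanced concordant/discordant shares cancel: dependence without
  # correlation, the central data pattern
  expect_equal(implied_rg(spec), 0)
  spec1 <- architecture_spec(m_snps = 1000L, n_blocks = 100L,
                             f_concordant = 0.3, f_discordant = 0,
                             f_specific_a = 0.1, f_specific_b = 0.1,
                             f_null = 0.5)
  expect_gt(implied_rg(spec1), 0)
})

test_that("simulated genotypes are Hardy-Weinberg at the spec MAF with
           block-local LD only", {
  spec <- architecture_spec(m_snps = 200L, n_blocks = 40L,
                            within_block_r = 0.8)
  p <- simulate_genotypes(spec, 2500, seed = 3)
  eaf <- colMeans(p$dosages) / 2
  se <- sqrt(p$map$maf * (1 - p$map$maf) / (2 * 2500))
  expect_true(all(abs(eaf - p$map$maf) < 4 * se))
  # same seed reproduces bit-identically; another seed differs
  p2 <- simulate_genotypes(spec, 2500, seed = 3)
  expect_identical(p$dosages, p2$dosages)
  p3 <- simulate_genotypes(spec, 2500, seed = 4)
  expect_false(identical(p$dosages, p3$dosages))
  # within-block correlation present, across-block absent
  within <- pairwise_r2(p, p$map$snp_id[1], p$map$snp_id[2])
  across <- pairwise_r2(p, p$map$snp_id[1], p$map$snp_id[6])
  expect_gt(within, 0.1)
  expect_lt(across, 0.01)
  # r = 0 gives unlinked SNPs even inside a block
  spec0 <- architecture_spec(m_snps = 40L, n_blocks = 4L,
                             within_block_r = 0)
  p0 <- simulate_genotypes(spec0, 5000, seed = 5)
  expect_lt(pairwise_r2(p0, p0$map$snp_id[1], p0$map$snp_id[2]), 0.01)
})

test_that("draw_effects realizes the mixture architecture and its implied
           effect correlation", {
  spec <- architecture_spec(m_snps = 50000L, n_blocks = 5000L)
  tr <- draw_effects(spec, seed = 8)
  expect_equal(nrow(tr), 50000L)
  frac <- table(tr$class) / 50000
  expect_equal(as.numeric(frac[c("concordant", "discordant", "null")]),
               c(0.25, 0.25, 0.30), tolerance = 0.03)
  # concordant SNPs share signs, discordant oppose
  conc <- tr[tr$class == "concordant"]
  expect_true(all(sign(conc$beta_a) == sign(conc$beta_b)))
  disc <- tr[tr$class == "discordant"]
  expect_true(all(sign(disc$beta_a) == -sign(disc$beta_b)))
  # symmetric mixture: realized effect correlation ~ closed form (0)
  expect_lt(abs(attr(tr, "realized_effect_cor") - implied_rg(spec)), 0.05)
  # genic variances hit the spec heritabilities in expectation
  expect_equal(sum(tr$beta_a^2), spec$h2_a, tolerance = 0.02)
  expect_equal(sum(tr$beta_b^2), spec$h2_b, tolerance = 0.02)
  # one-sided mixture has positive realized correlation
  spec1 <- architecture_spec(m_snps = 20000L, n_blocks = 2000L,
                             f_concordant = 0.3, f_discordant = 0,
                             f_specific_a = 0.1, f_specific_b = 0.1,
                             f_null = 0.5)
  tr1 <- draw_effects(spec1, seed = 9)
  expect_lt(abs(attr(tr1, "realized_effect_cor") - implied_rg(spec1)), 0.05)
  expect_gt(attr(tr1, "realized_effect_cor"), 0.3)
})

test_that("phenotypes follow the liability-threshold and loading model", {
  spec <- architecture_spec(m_snps = 400L, n_blocks = 80L)
  p <- simulate_genotypes(spec, 6000, seed = 12)
  tr <- draw_effects(spec, seed = 12, map = p$map)
  ph <- simulate_phenotypes(p, tr, spec, seed = 13)
  # case fraction ~ prevalence
  expect_lt(abs(mean(ph$case_b) - spec$prevalence_k), 0.015)
  # regression of the quantitative trait on the true genic value ~ 1
  X <- crosstrait:::.standardize_dosages(p)
  g <- as.numeric(X %*% tr$beta_a)
  expect_equal(unname(coef(lm(ph$trait_a ~ g))[2]), 1, tolerance = 0.1)
  # symptoms only for cases
  expect_true(all(is.na(ph$severity[ph$case_b == 0])))
  expect_true(all(!is.na(ph$severity[ph$case_b == 1])))
  # zero heritability: no genotype-phenotype association
  spec0 <- architecture_spec(m_snps = 400L, n_blocks = 80L, h2_a = 0,
                             h2_b = 0, h2_c = 0)
  tr0 <- draw_effects(spec0, seed = 14, map = p$map)
  ph0 <- simulate_phenotypes(p, tr0, spec0, seed = 15)
  expect_equal(unname(coef(lm(ph0$trait_a ~ p$dosages[, 1]))[2]), 0,
               tolerance = 0.05)
})

test_that("run_gwas is calibrated at null SNPs and powered at causal ones", {
  sim <- shared_sim()
  st <- data.table::as.data.table(sim$sumstats_a)
  # a fully null phenotype gives uniform P at every SNP (null-class SNPs
  # inside mixed LD blocks tag causal neighbours, so the clean null needs
  # an unassociated outcome)
  set.seed(321)
  y0 <- rnorm(nrow(sim$panel$dosages))
  s0 <- run_gwas(sim$panel, y0, "linear", "null")
  expect_gt(ks.test(s0$pvalue, "punif")$p.value, 0.01)
  nulls <- sim$truth$snp_id[sim$truth$class %in% c("null", "specific_b")]
  causal <- sim$truth$snp_id[sim$truth$class %in%
                               c("concordant", "discordant", "specific_a")]
  chi_c <- (st$beta / st$se)[match(intersect(causal, st$snp_id), st$snp_id)]^2
  chi_n <- (st$beta / st$se)[match(intersect(nulls, st$snp_id), st$snp_id)]^2
  expect_gt(mean(chi_c), mean(chi_n))
  # case-control path returns a design and log-OR-scale effects
  expect_s3_class(attr(sim$sumstats_b, "design"), "case_control_design")
  # effect estimates replicate across disjoint cohorts at causal SNPs
  spec <- sim$spec
  p2 <- simulate_genotypes(spec, 4000, seed = 900, map = sim$panel$map)
  f2 <- simulate_phenotypes(p2, sim$truth, spec, seed = 901)
  s2 <- run_gwas(p2, f2$trait_a, "linear", "a2")
  ci <- match(intersect(causal, st$snp_id), st$snp_id)
  expect_gt(cor(st$beta[ci], s2$beta[ci]), 0.2)
})

test_that("assortative mating piles up genic variance only when assortment
           is on", {
  spec <- architecture_spec(m_snps = 300L, n_blocks = 60L, h2_a = 0.5)
  p <- simulate_genotypes(spec, 2000, seed = 20)
  tr <- draw_effects(spec, seed = 20, map = p$map)
  gvar <- function(panel) {
    X <- crosstrait:::.standardize_dosages(panel)
    var(as.numeric(X %*% tr$beta_a))
  }
  base <- gvar(p)
  am <- assortative_mating(p, tr, spec, spouse_corr = 0.6, generations = 2,
                           mate_on = "trait_a", seed = 21)
  rm0 <- assortative_mating(p, tr, spec, spouse_corr = 0, generations = 2,
                            mate_on = "trait_a", seed = 21)
  expect_gt(gvar(am$panel), gvar(rm0$panel))
  # random mating leaves the genic variance roughly unchanged (drift and
  # Mendelian sampling allowed for)
  expect_lt(abs(gvar(rm0$panel) - base), 0.35 * base)
  # reproducible under the seed
  am2 <- assortative_mating(p, tr, spec, spouse_corr = 0.6, generations = 2,
                            mate_on = "trait_a", seed = 21)
  expect_identical(am$panel$dosages, am2$panel$dosages)
  # odd cohort size: drop with warning
  podd <- crosstrait:::.subset_panel(p, 1:101)
  expect_warning(assortative_mating(podd, tr, spec, 0.3, 1, seed = 3),
                 "odd")
})

test_that("simulate_study is reproducible and its cohorts are disjoint by
           construction", {
  spec <- architecture_spec(m_snps = 300L, n_blocks = 60L)
  s1 <- suppressWarnings(simulate_study(spec, seed = 5, n_gwas_a = 800L,
                                        n_gwas_b = 800L, n_gwas_c = 500L,
                                        n_panel = 300L, n_patients = 120L))
  s2 <- suppressWarnings(simulate_study(spec, seed = 5, n_gwas_a = 800L,
                                        n_gwas_b = 800L, n_gwas_c = 500L,
                                        n_panel = 300L, n_patients = 120L))
  expect_equal(data.table::as.data.table(s1$sumstats_a),
               data.table::as.data.table(s2$sumstats_a))
  expect_identical(s1$patients$panel$dosages, s2$patients$panel$dosages)
  s3 <- suppressWarnings(simulate_study(spec, seed = 6, n_gwas_a = 800L,
                                        n_gwas_b = 800L, n_gwas_c = 500L,
                                        n_panel = 300L, n_patients = 120L))
  expect_false(identical(data.table::as.data.table(s1$sumstats_a),
                         data.table::as.data.table(s3$sumstats_a)))
  # patient data carries genetic PCs, case status, and symptom columns
  expect_true(all(c("case_b", "severity", "PC1", "PC10") %in%
                    names(s1$patients$data)))
})
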