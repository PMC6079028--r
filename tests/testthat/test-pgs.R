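test_that("build_score applies the MAF floor, clumps, and keeps zero weights", {
  panel <- make_block_panel(blocks = 10, per_block = 1, n = 300, seed = 4)
  df <- make_sumstat_df(10, pos = panel$map$pos, seed = 13)
  df$snp_id <- panel$map$snp_id
  df$eaf <- c(0.005, 0.002, 0.995, 0.999, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  df$beta[5] <- 0  # an OR = 1 SNP carries weight zero, harmlessly
  ss <- sumstat_table(df)
  def <- build_score(ss, panel, p_threshold = 1, maf_floor = 0.01)
  expect_equal(nrow(def), 6L)   # 4 below the floor dropped
  expect_equal(def$weight[def$snp_id == "snp005"], 0)
  # no filtering: one weight per LD clump (blocks are singletons here)
  def_all <- build_score(ss, panel, p_threshold = 1, maf_floor = 0)
  expect_equal(nrow(def_all), 10L)
  # nothing survives an extreme floor on an all-rare table
  rare <- df[df$eaf < 0.01 | df$eaf > 0.99, ]
  expect_error(build_score(sumstat_table(rare), panel, maf_floor = 0.05),
               "MAF filter")
})

test_that("split_by_concordance partitions the pruned parent exactly", {
  panel <- make_block_panel(blocks = 10, per_block = 1, n = 300, seed = 4)
  df <- make_sumstat_df(10, pos = panel$map$pos, seed = 14)
  df$snp_id <- panel$map$snp_id
  df$beta <- c(1, 1, 1, 1, 1, 1, -1, -1, -1, -1) * 0.1
  ss <- sumstat_table(df, "b")
  other <- df; other$beta <- abs(other$beta)      # all positive in `other`
  parent <- build_score(ss, panel, p_threshold = 1)
  halves <- split_by_concordance(parent, sumstat_table(other, "a"))
  expect_equal(nrow(halves$concordant), 6L)
  expect_equal(nrow(halves$discordant), 4L)
  # disjoint, and union equals the parent
  expect_length(intersect(halves$concordant$snp_id,
                          halves$discordant$snp_id), 0L)
  expect_setequal(c(halves$concordant$snp_id, halves$discordant$snp_id),
                  parent$snp_id)
  # self-comparison: everything concordant
  self <- split_by_concordance(parent, ss)
  expect_equal(nrow(self$concordant), nrow(parent))
  expect_equal(nrow(self$discordant), 0L)
  # missing signs are excluded and counted
  other2 <- other[-1, ]
  h2 <- split_by_concordance(parent, sumstat_table(other2, "a"))
  expect_equal(h2$n_no_sign, 1L)
})

test_that("split_then_prune retains more SNPs than prune_then_split on
           LD-blocked data", {
  sim <- shared_sim()
  parent <- suppressWarnings(build_score(sim$sumstats_b, sim$panel,
                                         name = "parent"))
  s1 <- suppressWarnings(split_by_concordance(parent, sim$sumstats_a))
  s2 <- suppressWarnings(split_by_concordance(
    parent, sim$sumstats_a, strategy = "split_then_prune",
    stats = sim$sumstats_b, panel = sim$panel))
  n1 <- nrow(s1$concordant) + nrow(s1$discordant)
  n2 <- nrow(s2$concordant) + nrow(s2$discordant)
  expect_gt(n2, n1)
})

test_that("compute_scores sums weighted dosages with allele flips and both
           conventions", {
  dos <- rbind(c(2L, 0L, 1L), c(0L, 2L, NA))
  colnames(dos) <- c("x", "y", "z")
  rownames(dos) <- c("i1", "i2")
  panel <- genotype_panel(dos, data.frame(
    snp_id = c("x", "y", "z"), chrom = "1", pos = c(1e6, 2e6, 3e6),
    a1 = c("A", "C", "G"), a2 = c("G", "T", "A")))
  def <- data.table::data.table(snp_id = c("x", "y", "z"),
                                effect_allele = c("A", "T", "G"),
                                weight = c(0.2, 0.1, 0.3))
  data.table::setattr(def, "class", c("score_definition", class(def)))
  data.table::setattr(def, "provenance", list(name = "s"))
  got <- compute_scores(def, panel)
  # i1: 0.2*2 + (-0.1)*0 + 0.3*1 = 0.7 ; y flipped (other-allele coding)
  expect_equal(got$s, c(0.2 * 2 + 0.3 * 1, -0.1 * 2 + 0))
  avg <- compute_scores(def, panel, convention = "average_per_allele")
  expect_equal(avg$s[1], 0.7 / (2 * 3))
  expect_equal(avg$s[2], -0.2 / (2 * 2))  # missing SNP out of denominator
  # all-zero dosages give score zero
  zero <- genotype_panel(matrix(0L, 2, 1, dimnames = list(NULL, "x")),
                         data.frame(snp_id = "x", chrom = "1", pos = 1e6,
                                    a1 = "A", a2 = "G"))
  expect_warning(z0 <- compute_scores(def[1], zero), NA)
  expect_equal(z0[[2]], c(0, 0))
  # no overlap errors
  expect_error(compute_scores(def[2], zero), "no SNPs")
})

test_that("sum-convention scores are exactly partition-additive", {
  sim <- shared_sim()
  parent <- suppressWarnings(build_score(sim$sumstats_b, sim$panel,
                                         name = "parent"))
  halves <- split_by_concordance(parent, sim$sumstats_a)
  sc <- compute_scores(list(parent, halves$concordant, halves$discordant),
                       sim$patients)
  # parent = concordant + discordant, to floating tolerance 1e-12
  expect_equal(sc$parent,
               sc$parent_concordant + sc$parent_discordant,
               tolerance = 1e-12)
})

test_that("heterogeneity_f_test enforces nesting and standardization
           invariances", {
  set.seed(66)
  n <- 300
  d <- data.frame(conc = rnorm(n), disc = rnorm(n), cov1 = rnorm(n))
  d$parent <- d$conc + d$disc
  d$ea <- rnorm(n)
  d$y <- 0.3 * d$conc - 0.3 * d$disc + rnorm(n)
  ht <- heterogeneity_f_test(d, "y", "parent", "conc", "disc", ea = "ea",
                             covariates = "cov1")
  expect_equal(ht$df1, 1L)
  expect_gte(ht$f_statistic, 0)
  expect_gte(ht$split$r2, ht$baseline$r2)   # nesting: SSR_base >= SSR_split
  expect_equal(ht$delta_r2, ht$split$r2 - ht$baseline$r2)
  expect_lt(ht$pvalue, 0.01)                 # planted opposite effects
  # rescaling a score changes nothing after standardization
  d2 <- d; d2$conc <- 100 * d2$conc
  ht2 <- heterogeneity_f_test(d2, "y", "parent", "conc", "disc", ea = "ea",
                              covariates = "cov1")
  expect_equal(ht2$f_statistic, ht$f_statistic, tolerance = 1e-10)
  expect_equal(ht2$split$adj_r2, ht$split$adj_r2, tolerance = 1e-10)
  # duplicated split column is a rank-deficiency error
  d3 <- d; d3$disc <- d3$conc
  expect_error(heterogeneity_f_test(d3, "y", "parent", "conc", "disc"),
               "rank-deficient|constant")
  # F statistic agrees with anova() on the same nested models
  m1 <- lm(y ~ scale(parent) + scale(ea) + cov1, d)
  m2 <- lm(y ~ scale(conc) + scale(disc) + scale(ea) + cov1, d)
  expect_equal(ht$f_statistic, anova(m1, m2)$F[2], tolerance = 1e-10)
})

test_that("pure-noise covariates leave the adjusted-R2 gain unchanged", {
  set.seed(99)
  n <- 500
  base <- data.frame(conc = rnorm(n), disc = rnorm(n))
  base$parent <- base$conc + base$disc
  base$y <- 0.25 * base$conc - 0.25 * base$disc + rnorm(n)
  ht0 <- heterogeneity_f_test(base, "y", "parent", "conc", "disc")
  noise <- base
  for (k in 1:5) noise[[paste0("nz", k)]] <- rnorm(n)
  ht1 <- heterogeneity_f_test(noise, "y", "parent", "conc", "disc",
                              covariates = paste0("nz", 1:5))
  expect_lt(abs(ht1$delta_adj_r2 - ht0$delta_adj_r2), 0.01)
})

test_that("random_split_control preserves split sizes and reproduces
           bit-identically under a seed", {
  sim <- shared_sim()
  parent <- suppressWarnings(build_score(sim$sumstats_b, sim$panel,
                                         name = "parent"))
  pd <- as.data.frame(sim$patients$data)
  cases_idx <- which(pd$case_b == 1L)
  dat <- pd[cases_idx, c("severity", paste0("PC", 1:3))]
  cp <- crosstrait:::.subset_panel(sim$patients$panel, cases_idx)
  nc <- floor(nrow(parent) / 2); nd <- nrow(parent) - nc
  c1 <- random_split_control(parent, cp, dat, outcome = "severity",
                             covariates = paste0("PC", 1:3),
                             n_conc = nc, n_disc = nd, observed_f = 2,
                             n_permutations = 100, seed = 5)
  c2 <- random_split_control(parent, cp, dat, outcome = "severity",
                             covariates = paste0("PC", 1:3),
                             n_conc = nc, n_disc = nd, observed_f = 2,
                             n_permutations = 100, seed = 5)
  expect_identical(c1$f_statistics, c2$f_statistics)
  expect_length(c1$pvalues, 100L)
  expect_error(random_split_control(parent, cp, dat, outcome = "severity",
                                    n_conc = nc, n_disc = nd,
                                    n_permutations = 10, seed = 1),
               "at least 100")
})
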