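test_that("pairwise_r2 matches a direct correlation computation", {
  panel <- make_block_panel(blocks = 2, per_block = 3, n = 300)
  r2 <- pairwise_r2(panel, "snp001", "snp002")
  oracle <- cor(panel$dosages[, 1], panel$dosages[, 2])^2
  expect_equal(r2, oracle)
  expect_equal(pairwise_r2(panel, "snp001", "snp001"), 1.0)
  # independent blocks at large n have near-zero r2
  set.seed(5)
  big <- genotype_panel(
    cbind(a = rbinom(10000, 2, 0.3), b = rbinom(10000, 2, 0.3)),
    data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(1e6, 2e6),
               a1 = "A", a2 = "G"))
  expect_lt(pairwise_r2(big, "a", "b"), 0.01)
  # monomorphic SNP is an error
  mono <- genotype_panel(
    cbind(a = rep(0L, 10), b = rbinom(10, 2, 0.5)),
    data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(1, 2),
               a1 = "A", a2 = "G"))
  expect_error(pairwise_r2(mono, "a", "b"), "monomorphic|undefined")
})

test_that("ld_clump keeps one lead per tight block and respects the window", {
  panel <- make_block_panel(blocks = 3, per_block = 4, n = 500,
                            flip_prob = 0.02)
  df <- make_sumstat_df(12, pos = panel$map$pos)
  df$snp_id <- panel$map$snp_id
  df$pvalue <- seq(1e-8, 1e-3, length.out = 12)
  ss <- sumstat_table(df)
  cl <- ld_clump(ss, panel, p_threshold = 1, r2_threshold = 0.1,
                 window_kb = 1000)
  expect_equal(length(cl$lead_snps), 3L)
  # the smallest-P SNP of each block leads it
  expect_true("snp001" %in% cl$lead_snps)
  # leads ordered by ascending P
  expect_equal(cl$lead_pvalues, sort(cl$lead_pvalues))
  # membership covers all SNPs and each lead is its own member
  expect_equal(length(cl$membership), 12L)
  expect_true(all(cl$membership[cl$lead_snps] == cl$lead_snps))
  # a window smaller than the within-block span splits blocks by distance
  cl2 <- ld_clump(ss, panel, p_threshold = 1, r2_threshold = 0.1,
                  window_kb = 1)  # 1 kb: only adjacent SNPs merge
  expect_gt(length(cl2$lead_snps), 3L)
  # no SNP below the threshold: empty result
  expect_length(ld_clump(ss, panel, p_threshold = 1e-12)$lead_snps, 0L)
})

test_that("ld_clump equals the brute-force oracle over random P assignments", {
  panel <- make_block_panel(blocks = 5, per_block = 5, n = 300, seed = 8,
                            flip_prob = 0.15)
  m <- nrow(panel$map)
  r2mat <- cor(panel$dosages)^2
  for (s in 1:60) {
    set.seed(1000 + s)
    pv <- runif(m)^3
    df <- make_sumstat_df(m, pos = panel$map$pos)
    df$snp_id <- panel$map$snp_id
    df$pvalue <- pv
    thr <- sample(c(1, 0.5, 0.05), 1)
    win <- sample(c(3, 50, 1000), 1)
    cl <- ld_clump(sumstat_table(df), panel, p_threshold = thr,
                   r2_threshold = 0.1, window_kb = win)
    oracle <- brute_clump(df$snp_id, df$chrom, df$pos, df$pvalue, r2mat,
                          p_threshold = thr, r2_threshold = 0.1,
                          window_bp = win * 1000)
    expect_equal(cl$lead_snps, oracle, info = paste("seed", s))
  }
})

test_that("clump leads are mutually quasi-independent within the window", {
  panel <- make_block_panel(blocks = 4, per_block = 5, n = 400, seed = 3,
                            flip_prob = 0.3)
  df <- make_sumstat_df(20, pos = panel$map$pos, seed = 12)
  df$snp_id <- panel$map$snp_id
  cl <- ld_clump(sumstat_table(df), panel, p_threshold = 1,
                 r2_threshold = 0.2, window_kb = 1e6)
  leads <- cl$lead_snps
  if (length(leads) > 1) {
    combs <- combn(leads, 2)
    r2s <- apply(combs, 2, function(p) pairwise_r2(panel, p[1], p[2]))
    expect_true(all(r2s <= 0.2))
  }
})

test_that("find_proxy returns the best in-window candidate and is idempotent", {
  panel <- make_block_panel(blocks = 1, per_block = 6, n = 600, seed = 10,
                            flip_prob = 0.10)
  ids <- panel$map$snp_id
  # target in candidates returns itself
  expect_equal(find_proxy(panel, ids[1], ids), ids[1])
  # otherwise the highest-r2 candidate wins
  cand <- ids[-1]
  best <- find_proxy(panel, ids[1], cand, min_r2 = 0.1)
  r2s <- sapply(cand, function(s) pairwise_r2(panel, ids[1], s))
  expect_equal(best, cand[which.max(r2s)])
  # no candidate above the threshold: NA
  expect_true(is.na(find_proxy(panel, ids[1], cand, min_r2 = 0.999)))
  # proxy of a proxy within the same candidates returns itself
  again <- find_proxy(panel, best, cand, min_r2 = 0.1)
  expect_equal(again, best)
})

test_that("ld_partners matches a brute-force scan and honors the window", {
  panel <- make_block_panel(blocks = 2, per_block = 5, n = 500, seed = 6,
                            flip_prob = 0.1)
  ids <- panel$map$snp_id
  got <- ld_partners(panel, ids[2], min_r2 = 0.5, window_kb = 100)
  oracle <- ids[sapply(ids, function(s) {
    same_chr <- TRUE
    d <- abs(panel$map$pos[match(s, ids)] - panel$map$pos[2])
    s == ids[2] || (d <= 1e5 && cor(panel$dosages[, s],
                                    panel$dosages[, ids[2]])^2 > 0.5)
  })]
  expect_equal(got, sort(oracle))
  # min_r2 = 0 returns everything in the window (block 1 here)
  expect_equal(ld_partners(panel, ids[2], 0, 100), sort(ids[1:5]))
  expect_error(ld_partners(panel, "nope", 0.5, 100), "not in panel")
})

test_that("ld_scores: self term, monotonicity in window, and adjustment", {
  # independent SNPs: unadjusted scores ~ 1 + sampling noise, adjusted ~ 1
  set.seed(21)
  n <- 800; m <- 40
  dos <- matrix(rbinom(n * m, 2, 0.4), n, m)
  colnames(dos) <- sprintf("s%02d", 1:m)
  panel <- genotype_panel(dos, data.frame(
    snp_id = colnames(dos), chrom = "1", pos = seq_len(m) * 1000L,
    a1 = "A", a2 = "G"))
  un <- ld_scores(panel, window_kb = 100)
  ad <- ld_scores(panel, window_kb = 100, adjusted = TRUE)
  expect_true(all(un$ld_score >= 1))
  expect_equal(mean(un$ld_score), 1 + (m - 1) / n, tolerance = 0.25)
  # flooring the adjusted r2 at zero leaves a small positive residual
  expect_equal(mean(ad$ld_score), 1, tolerance = 0.04)
  # singleton universe: exactly 1
  one <- ld_scores(panel, universe = "s01", window_kb = 100)
  expect_equal(one$ld_score, 1)
  # widening the window never decreases the unadjusted score
  narrow <- ld_scores(panel, window_kb = 5)
  expect_true(all(un$ld_score - narrow$ld_score >= -1e-12))
})

test_that("panels round-trip through plain text and load from VCF", {
  panel <- make_block_panel(blocks = 2, per_block = 2, n = 30)
  f <- withr::local_tempfile(fileext = ".tsv")
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_panel_matrix(panel, f, fm)
  back <- read_panel_matrix(f, fm)
  expect_equal(unname(back$dosages), unname(panel$dosages))
  expect_equal(back$map$snp_id, panel$map$snp_id)
  skip_if_not_installed("vcfR")
  # minimal VCF with two samples, two variants
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trsA\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t0/0\t0|1"), vcf)
  pv <- read_panel_vcf(vcf)
  expect_equal(unname(pv$dosages[, "rsA"]), c(1, 2))
  expect_equal(unname(pv$dosages[, "rsB"]), c(0, 1))
  expect_equal(pv$map$a1, c("A", "T"))
})
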