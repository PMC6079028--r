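# Shared in-code fixtures. Everything is generated programmatically; the
# larger simulation objects are built once per test run and cached.

make_sumstat_df <- function(n = 10, seed = 1, chrom = "1",
                            pos = NULL, beta = NULL, se = NULL,
                            eaf = NULL, n_eff = 1000) {
  set.seed(seed)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(beta)) beta <- rnorm(n, 0, 0.05)
  if (is.null(se)) se <- rep(0.02, n)
  if (is.null(eaf)) eaf <- runif(n, 0.05, 0.95)
  z <- beta / se
  data.frame(snp_id = sprintf("snp%03d", seq_len(n)), chrom = chrom,
             pos = pos, effect_allele = "A", other_allele = "G",
             eaf = eaf, beta = beta, se = se,
             pvalue = 2 * pnorm(-abs(z)), n_eff = n_eff,
             stringsAsFactors = FALSE)
}

# tiny hand-built panel: `blocks` LD blocks of `per_block` SNPs each,
# constructed by duplicating a base dosage vector with per-SNP noise flips
make_block_panel <- function(blocks = 3, per_block = 4, n = 400, seed = 42,
                             flip_prob = 0.05, maf = 0.3, gap_bp = 2e6) {
  set.seed(seed)
  m <- blocks * per_block
  dos <- matrix(0L, n, m)
  pos <- integer(m)
  k <- 0L
  for (b in seq_len(blocks)) {
    base <- rbinom(n, 2L, maf)
    for (j in seq_len(per_block)) {
      k <- k + 1L
      flip <- runif(n) < flip_prob
      col <- base
      col[flip] <- rbinom(sum(flip), 2L, maf)
      dos[, k] <- col
      pos[k] <- b * gap_bp + j * 1000L
    }
  }
  ids <- sprintf("snp%03d", seq_len(m))
  colnames(dos) <- ids
  genotype_panel(dos, data.frame(snp_id = ids, chrom = "1", pos = pos,
                                 a1 = "A", a2 = "G"))
}

# brute-force oracle for greedy clumping (direct transcription of the rule)
brute_clump <- function(ids, chrom, pos, pvalue, r2mat, p_threshold,
                        r2_threshold, window_bp) {
  ord <- order(pvalue, ids)
  assigned <- setNames(rep(FALSE, length(ids)), ids)
  leads <- character(0)
  for (i in ord) {
    if (assigned[ids[i]] || pvalue[i] >= p_threshold) next
    leads <- c(leads, ids[i])
    assigned[ids[i]] <- TRUE
    for (j in seq_along(ids)) {
      if (assigned[ids[j]]) next
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window_bp &&
          r2mat[i, j] > r2_threshold) {
        assigned[ids[j]] <- TRUE
      }
    }
  }
  leads
}

# one moderately sized simulated study, shared across expensive tests
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- architecture_spec(m_snps = 1200L, n_blocks = 240L)
      cache <<- suppressWarnings(
        simulate_study(spec, seed = 7, n_gwas_a = 4000L, n_gwas_b = 4000L,
                       n_gwas_c = 4000L, n_panel = 800L, n_patients = 400L))
    }
    cache
  }
})
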