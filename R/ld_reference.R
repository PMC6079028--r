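#' Genotype reference panel
#'
#' Wraps a samples-by-variants dosage matrix (integers 0/1/2, `NA` allowed)
#' together with a variant map. All LD computations (pairwise r2, clumping,
#' proxy search, LD scores) run against this object. Dosage-based
#' (unphased) r2 is used throughout, matching common reference-panel
#' practice.
#'
#' @param dosages numeric matrix, one row per sample, one column per
#'   variant; column names must be variant ids.
#' @param map data.frame with columns `snp_id, chrom, pos, a1, a2` aligned
#'   to the dosage columns.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, map) {
  map <- as.data.table(map)
  stopifnot(ncol(dosages) == nrow(map))
  if (is.null(colnames(dosages))) colnames(dosages) <- map$snp_id
  stopifnot(identical(colnames(dosages), map$snp_id),
            !anyDuplicated(map$snp_id))
  if (any(colMeans(is.na(dosages)) >= 1)) {
    stop("panel contains fully missing variants")
  }
  map[, `:=`(chrom = as.character(chrom), pos = as.integer(pos))]
  structure(list(dosages = dosages, map = map,
                 sample_count = nrow(dosages)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (%d chromosome(s))\n",
              x$sample_count, nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

.panel_idx <- function(panel, snp_id, what = "SNP") {
  i <- match(snp_id, panel$map$snp_id)
  if (anyNA(i)) {
    stop(what, " not in panel: ", paste(snp_id[is.na(i)], collapse = ", "))
  }
  i
}

#' Read a plain-text genotype matrix panel
#'
#' Expects a delimited samples-by-variants dosage table whose header row
#' holds the variant ids, plus a side-car variant map file with columns
#' `snp_id, chrom, pos, a1, a2`.
#'
#' @param path dosage matrix file.
#' @param map_path variant map file.
#' @return A [genotype_panel()].
#' @export
read_panel_matrix <- function(path, map_path) {
  g <- as.matrix(fread(path, header = TRUE))
  map <- fread(map_path, header = TRUE)
  genotype_panel(g, map)
}

#' Write a genotype panel as plain text
#' @param panel a [genotype_panel()].
#' @param path,map_path output files for dosages and variant map.
#' @return `path`, invisibly.
#' @export
write_panel_matrix <- function(panel, path, map_path) {
  fwrite(as.data.table(panel$dosages), path, sep = "\t")
  fwrite(panel$map, map_path, sep = "\t")
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Parses GT fields into dosages of the ALT allele. Requires the `vcfR`
#' package. Multi-allelic records are dropped.
#'
#' @param path VCF file (optionally gzipped).
#' @return A [genotype_panel()] with `a1` = ALT (dosage-counted allele),
#'   `a2` = REF.
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_panel_vcf requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(a, function(al) {
      if (any(al == ".")) return(NA_real_)
      sum(al == "1")
    }, numeric(1))
  }
  dos <- t(apply(gt, 1, count_alt))
  dos <- t(dos)  # samples x variants
  colnames(dos) <- fix$ID
  map <- data.table(snp_id = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF)
  genotype_panel(dos, map)
}

.r2_one_vs_many <- function(panel, i, js) {
  x <- panel$dosages[, i]
  out <- numeric(length(js))
  for (k in seq_along(js)) {
    y <- panel$dosages[, js[k]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) { out[k] <- NA_real_; next }
    sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
    if (sx == 0 || sy == 0) { out[k] <- NA_real_; next }
    out[k] <- stats::cor(x[ok], y[ok])^2
  }
  out
}

#' Pairwise r2 between two panel variants
#'
#' Squared sample correlation of dosages over pairwise-complete samples.
#'
#' @param panel a [genotype_panel()].
#' @param snp_a,snp_b variant ids.
#' @return r2 in `[0, 1]`.
#' @export
pairwise_r2 <- function(panel, snp_a, snp_b) {
  i <- .panel_idx(panel, snp_a)
  j <- .panel_idx(panel, snp_b)
  r2 <- .r2_one_vs_many(panel, i, j)
  if (is.na(r2)) {
    stop("LD undefined for (", snp_a, ", ", snp_b,
         "): monomorphic variant or fewer than 3 complete pairs")
  }
  r2
}

#' Greedy LD clumping
#'
#' Reduces a summary-statistics table to approximately independent lead
#' SNPs: repeatedly take the smallest-P unassigned SNP with
#' `pvalue < p_threshold` as a lead, assign to its clump every unassigned
#' SNP within `window_kb` of it whose r2 with the lead exceeds
#' `r2_threshold`, and iterate until no unassigned SNP remains below the
#' threshold. Setting `p_threshold = 1` clumps the whole table. A window
#' larger than any chromosome makes clumping effectively chromosome-wide.
#'
#' SNPs absent from the panel are treated as independent singletons: they
#' become their own leads (when below the threshold) with a warning.
#'
#' @param sumstats a `sumstat_table`.
#' @param panel a [genotype_panel()].
#' @param p_threshold lead-eligibility P-value threshold.
#' @param r2_threshold clump membership requires r2 strictly above this.
#' @param window_kb maximum lead-to-member distance in kilobases
#'   (inclusive).
#' @return An object of class `clump_result`: `lead_snps` (ordered by
#'   ascending P), `membership` (named vector SNP -> lead), `lead_pvalues`.
#' @export
ld_clump <- function(sumstats, panel, p_threshold, r2_threshold = 0.1,
                     window_kb = 1000) {
  dt <- as.data.table(sumstats)[, c("snp_id", "chrom", "pos", "pvalue"),
                                with = FALSE]
  in_panel <- dt$snp_id %in% panel$map$snp_id
  if (any(!in_panel)) {
    warning(sum(!in_panel),
            " SNP(s) absent from the panel kept as independent singletons")
  }
  ord <- order(dt$pvalue, dt$snp_id)
  dt <- dt[ord]
  in_panel <- in_panel[ord]
  n <- nrow(dt)
  assigned <- rep(FALSE, n)
  lead_of <- rep(NA_character_, n)
  leads <- character(0)
  lead_p <- numeric(0)
  window_bp <- window_kb * 1000
  pidx <- match(dt$snp_id, panel$map$snp_id)
  for (i in seq_len(n)) {
    if (assigned[i] || dt$pvalue[i] >= p_threshold) next
    lead <- dt$snp_id[i]
    assigned[i] <- TRUE
    lead_of[i] <- lead
    leads <- c(leads, lead)
    lead_p <- c(lead_p, dt$pvalue[i])
    if (in_panel[i]) {
      cand <- which(!assigned & in_panel & dt$chrom == dt$chrom[i] &
                      abs(dt$pos - dt$pos[i]) <= window_bp)
      if (length(cand)) {
        r2 <- .r2_one_vs_many(panel, pidx[i], pidx[cand])
        hit <- cand[!is.na(r2) & r2 > r2_threshold]
        assigned[hit] <- TRUE
        lead_of[hit] <- lead
      }
    }
  }
  membership <- lead_of[assigned]
  names(membership) <- dt$snp_id[assigned]
  structure(list(lead_snps = leads, membership = membership,
                 lead_pvalues = stats::setNames(lead_p, leads)),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("clump_result: %d lead SNP(s), %d assigned SNP(s)\n",
              length(x$lead_snps), length(x$membership)))
  invisible(x)
}

#' Find the best LD proxy for a variant
#'
#' Among `candidates` within `window_kb` of the target whose r2 with the
#' target exceeds `min_r2`, returns the one with the highest r2; ties are
#' broken by smaller distance, then lexicographic id. Returns `NA` when no
#' candidate qualifies.
#'
#' @param panel a [genotype_panel()].
#' @param target variant id (must be in the panel).
#' @param candidates character vector of candidate variant ids.
#' @param min_r2 minimum r2 (strict).
#' @param window_kb maximum distance in kilobases (inclusive).
#' @return A variant id or `NA_character_`.
#' @export
find_proxy <- function(panel, target, candidates, min_r2 = 0.8,
                       window_kb = 500) {
  ti <- .panel_idx(panel, target, "target")
  cand <- intersect(candidates, panel$map$snp_id)
  if (!length(cand)) return(NA_character_)
  ci <- match(cand, panel$map$snp_id)
  tmap <- panel$map[ti]
  dist <- abs(panel$map$pos[ci] - tmap$pos)
  ok <- panel$map$chrom[ci] == tmap$chrom & dist <= window_kb * 1000
  cand <- cand[ok]; ci <- ci[ok]; dist <- dist[ok]
  if (!length(cand)) return(NA_character_)
  r2 <- .r2_one_vs_many(panel, ti, ci)
  ok <- !is.na(r2) & r2 > min_r2
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok]; r2 <- r2[ok]; dist <- dist[ok]
  o <- order(-r2, dist, cand)
  cand[o[1]]
}

#' All LD partners of a variant
#'
#' Every panel variant within `window_kb` of the target with r2 strictly
#' above `min_r2`, always including the target itself.
#'
#' @inheritParams find_proxy
#' @return Character vector of variant ids.
#' @export
ld_partners <- function(panel, target, min_r2, window_kb) {
  ti <- .panel_idx(panel, target, "target")
  tmap <- panel$map[ti]
  cand <- which(panel$map$chrom == tmap$chrom &
                  abs(panel$map$pos - tmap$pos) <= window_kb * 1000)
  cand <- setdiff(cand, ti)
  out <- panel$map$snp_id[ti]
  if (length(cand)) {
    r2 <- .r2_one_vs_many(panel, ti, cand)
    out <- c(out, panel$map$snp_id[cand[!is.na(r2) & r2 > min_r2]])
  }
  sort(out)
}

#' LD scores from a reference panel
#'
#' For each variant i in `universe`, `ld_score_i = sum_k r2_ik` over
#' universe variants within `window_kb` (the self term r2 = 1 included).
#' With `adjusted = TRUE` each r2 is replaced by the bias-adjusted
#' `r2 - (1 - r2) / (n - 2)`, floored at 0, which removes the upward
#' finite-sample bias of the sample r2.
#'
#' @param panel a [genotype_panel()].
#' @param universe variant ids to score over; default: all panel variants.
#' @param window_kb window in kilobases (inclusive).
#' @param adjusted apply the finite-sample bias adjustment.
#' @return An `ldscore_table`: data.table `(snp_id, chrom, pos, ld_score)`
#'   with the window parameters as attributes.
#' @export
ld_scores <- function(panel, universe = NULL, window_kb = 1000,
                      adjusted = FALSE) {
  if (is.null(universe)) universe <- panel$map$snp_id
  idx <- .panel_idx(panel, universe, "universe SNP")
  map <- panel$map[idx]
  n <- panel$sample_count
  # standardized dosages once; mean-impute missing so crossprod is defined
  X <- panel$dosages[, idx, drop = FALSE]
  X <- scale(X)
  X[is.na(X)] <- 0
  window_bp <- window_kb * 1000
  m <- length(idx)
  score <- numeric(m)
  o <- order(map$chrom, map$pos)
  for (ch in unique(map$chrom)) {
    sel <- o[map$chrom[o] == ch]
    pos <- map$pos[sel]
    lo <- findInterval(pos - window_bp - 0.5, pos) + 1L
    hi <- findInterval(pos + window_bp + 0.5, pos)
    for (k in seq_along(sel)) {
      win <- sel[lo[k]:hi[k]]
      r <- crossprod(X[, win, drop = FALSE], X[, sel[k]]) / (n - 1)
      r2 <- as.numeric(r)^2
      if (adjusted) r2 <- pmax(r2 - (1 - r2) / (n - 2), 0)
      self <- which(win == sel[k])
      r2[self] <- 1  # exact self term
      score[sel[k]] <- sum(r2)
    }
  }
  out <- data.table(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                    ld_score = score)
  setattr(out, "class", c("ldscore_table", class(out)))
  setattr(out, "window_kb", window_kb)
  setattr(out, "adjusted", adjusted)
  out
}

#' Write LD scores as tab-delimited text
#' @param x an `ldscore_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_scores <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}
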