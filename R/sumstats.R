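#' @importFrom data.table data.table as.data.table setkeyv setorderv fread fwrite := .SD setnames copy setattr
#' @importFrom stats pnorm qnorm quantile
NULL

VALID_ALLELES <- c("A", "C", "G", "T")

#' Case-control study design
#'
#' Small container for the numbers of cases and controls behind a set of
#' case-control GWAS summary statistics. Used to reconstruct per-SNP
#' log-odds-ratio standard errors and statistical power.
#'
#' @param n_cases,n_controls positive integer counts.
#' @return An object of class `case_control_design`.
#' @export
case_control_design <- function(n_cases, n_controls) {
  stopifnot(length(n_cases) == 1L, length(n_controls) == 1L,
            n_cases > 0, n_controls > 0)
  structure(list(n_cases = as.numeric(n_cases),
                 n_controls = as.numeric(n_controls)),
            class = "case_control_design")
}

#' QC report constructor
#'
#' Accounting object for row-level filters: every dropped SNP is attributed
#' to exactly one (first-failing) rule, so drops always sum to
#' `n_input - n_output`.
#'
#' @param n_input rows seen.
#' @param drops named integer vector, one entry per rule.
#' @return An object of class `qc_report`.
#' @export
qc_report <- function(n_input, drops = integer()) {
  drops <- vapply(drops, as.integer, integer(1))
  out <- list(n_input = as.integer(n_input),
              n_dropped_by_rule = drops,
              n_output = as.integer(n_input - sum(drops)))
  structure(out, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d in, %d out\n", x$n_input, x$n_output))
  if (length(x$n_dropped_by_rule)) {
    for (r in names(x$n_dropped_by_rule)) {
      cat(sprintf("  dropped by %-18s %d\n", paste0(r, ":"), x$n_dropped_by_rule[[r]]))
    }
  }
  invisible(x)
}

#' Write a QC report as machine-readable key-value text
#'
#' @param report a `qc_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  lines <- c(sprintf("n_input\t%d", report$n_input),
             sprintf("dropped.%s\t%d", names(report$n_dropped_by_rule),
                     unlist(report$n_dropped_by_rule)),
             sprintf("n_output\t%d", report$n_output))
  writeLines(lines, path)
  invisible(path)
}

.new_sumstat_table <- function(dt, trait_label, design = NULL) {
  setorderv(dt, c("chrom_num", "pos"))
  dt[, "chrom_num" := NULL]
  setattr(dt, "class", c("sumstat_table", class(dt)))
  setattr(dt, "trait_label", trait_label)
  setattr(dt, "design", design)
  dt
}

#' Build a validated summary-statistics table
#'
#' Validates per-SNP association records (autosomal chromosome, 1-based
#' position, A/C/G/T alleles, effect-allele frequency strictly inside (0,1),
#' positive standard error, P value in (0,1], positive per-SNP sample size),
#' drops failing rows with a count, de-duplicates SNP ids, and sorts by
#' (chromosome, position). Effect sizes are betas; for case-control traits
#' they are log odds ratios.
#'
#' @param df data.frame with columns `snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta, se, pvalue, n_eff`.
#' @param trait_label character scalar naming the trait.
#' @param design optional [case_control_design()].
#' @return A `sumstat_table` (a keyed `data.table`) with a `qc` attribute
#'   holding the validation [qc_report()].
#' @export
sumstat_table <- function(df, trait_label = "trait", design = NULL) {
  dt <- as.data.table(df)
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n_eff")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  dt <- dt[, need, with = FALSE]
  n_in <- nrow(dt)
  dt[, `:=`(snp_id = as.character(snp_id),
            chrom = as.character(chrom),
            pos = suppressWarnings(as.integer(pos)),
            effect_allele = toupper(as.character(effect_allele)),
            other_allele = toupper(as.character(other_allele)),
            eaf = suppressWarnings(as.numeric(eaf)),
            beta = suppressWarnings(as.numeric(beta)),
            se = suppressWarnings(as.numeric(se)),
            pvalue = suppressWarnings(as.numeric(pvalue)),
            n_eff = suppressWarnings(as.numeric(n_eff)))]
  ok_type <- !is.na(dt$pos) & !is.na(dt$eaf) & !is.na(dt$beta) &
    !is.na(dt$se) & !is.na(dt$pvalue) & !is.na(dt$n_eff)
  dt1 <- dt[ok_type]
  ok_range <- dt1$chrom %in% as.character(1:22) & dt1$pos >= 1L &
    dt1$effect_allele %in% VALID_ALLELES & dt1$other_allele %in% VALID_ALLELES &
    dt1$effect_allele != dt1$other_allele &
    dt1$eaf > 0 & dt1$eaf < 1 & dt1$se > 0 &
    dt1$pvalue > 0 & dt1$pvalue <= 1 & dt1$n_eff > 0
  dt2 <- dt1[ok_range]
  dup <- duplicated(dt2$snp_id)
  dt3 <- dt2[!dup]
  rep <- qc_report(n_in, c(type = n_in - nrow(dt1),
                           range = nrow(dt1) - nrow(dt2),
                           duplicate = sum(dup)))
  dt3[, "chrom_num" := as.integer(chrom)]
  out <- .new_sumstat_table(dt3, trait_label, design)
  setattr(out, "qc", rep)
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or whitespace-delimited file with a header (gzip handled
#' transparently), renames physical columns to the canonical schema through
#' `column_map`, optionally converts odds ratios to betas by natural log,
#' and validates via [sumstat_table()].
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta` or `or`, `se`, `pvalue`, `n_eff`) to column names in the file.
#'   `NULL` assumes the file already uses canonical names.
#' @param trait_label trait name stored on the table.
#' @param design optional [case_control_design()].
#' @return A `sumstat_table`; validation drops are recorded in its `qc`
#'   attribute.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_label = "trait",
                          design = NULL) {
  raw <- fread(path, header = TRUE)
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(raw))
    if (length(miss)) {
      stop("column_map names columns absent from file: ",
           paste(miss, collapse = ", "))
    }
    setnames(raw, unname(column_map), names(column_map))
  }
  if ("or" %in% names(raw) && !("beta" %in% names(raw))) {
    raw[, "beta" := log(as.numeric(raw[["or"]]))]
  }
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "pvalue", "n_eff")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  sumstat_table(raw, trait_label = trait_label, design = design)
}

#' Write a summary-statistics table as tab-delimited text
#'
#' @param x a `sumstat_table` (or merged table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t")
  invisible(path)
}

#' Coverage (sample-size) filter
#'
#' Keeps records whose per-SNP sample size (or any monotone surrogate such
#' as a cohort count) is at least `min_n`.
#'
#' @param table a `sumstat_table`.
#' @param min_n positive threshold, same units as the table's `n_eff`.
#' @return `list(table = filtered table, report = qc_report)`.
#' @export
coverage_filter <- function(table, min_n) {
  if (!is.numeric(min_n) || length(min_n) != 1L || min_n <= 0) {
    stop("min_n must be a single positive number")
  }
  keep <- table$n_eff >= min_n
  out <- table[keep]
  setattr(out, "class", class(table))
  setattr(out, "trait_label", attr(table, "trait_label"))
  setattr(out, "design", attr(table, "design"))
  list(table = out,
       report = qc_report(nrow(table), c(coverage = sum(!keep))))
}

.is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Align two summary-statistics tables on a shared SNP universe
#'
#' Intersects on SNP id and harmonizes trait b to trait a's allele coding:
#' where b's effect allele equals a's other allele, b's beta sign is flipped
#' and its effect-allele frequency is replaced by `1 - eaf`. Records whose
#' allele pairs cannot be reconciled are dropped, as are (optionally)
#' strand-ambiguous A/T and C/G SNPs.
#'
#' @param a,b `sumstat_table`s.
#' @param drop_strand_ambiguous drop A/T and C/G SNPs before merging.
#' @return `list(table = merged_table, report = qc_report)`. The merged
#'   table carries `beta_a, se_a, pvalue_a, eaf_a, n_a` and the `_b`
#'   counterparts side by side, on trait a's allele coding.
#' @export
align_and_merge <- function(a, b, drop_strand_ambiguous = FALSE) {
  da <- as.data.table(a)
  db <- as.data.table(b)
  n_in <- nrow(da)
  common <- intersect(da$snp_id, db$snp_id)
  if (length(common) == 0L) {
    stop("zero SNP intersection between '", attr(a, "trait_label"), "' and '",
         attr(b, "trait_label"), "'")
  }
  m <- merge(da[da$snp_id %in% common],
             db[db$snp_id %in% common,
                c("snp_id", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pvalue", "n_eff"),
                with = FALSE],
             by = "snp_id", suffixes = c("", ".b"))
  n_isect <- nrow(m)
  same <- m$effect_allele == m$effect_allele.b &
    m$other_allele == m$other_allele.b
  swap <- m$effect_allele == m$other_allele.b &
    m$other_allele == m$effect_allele.b
  m <- m[same | swap]
  n_allele_drop <- n_isect - nrow(m)
  sw <- m$effect_allele == m$other_allele.b  # recompute on kept rows
  m[sw, `:=`(beta.b = -beta.b, eaf.b = 1 - eaf.b)]
  n_amb <- 0L
  if (drop_strand_ambiguous) {
    amb <- .is_strand_ambiguous(m$effect_allele, m$other_allele)
    n_amb <- sum(amb)
    m <- m[!amb]
  }
  out <- m[, list(snp_id = snp_id, chrom = chrom, pos = pos,
                  effect_allele = effect_allele, other_allele = other_allele,
                  eaf_a = eaf, beta_a = beta, se_a = se, pvalue_a = pvalue,
                  n_a = n_eff,
                  eaf_b = eaf.b, beta_b = beta.b, se_b = se.b,
                  pvalue_b = pvalue.b, n_b = n_eff.b)]
  out[, "chrom_num" := as.integer(chrom)]
  setorderv(out, c("chrom_num", "pos"))
  out[, "chrom_num" := NULL]
  setattr(out, "class", c("merged_table", class(out)))
  setattr(out, "trait_a", attr(a, "trait_label"))
  setattr(out, "trait_b", attr(b, "trait_label"))
  drops <- c(not_in_both = n_in - n_isect, allele_mismatch = n_allele_drop)
  if (drop_strand_ambiguous) drops <- c(drops, strand_ambiguous = n_amb)
  list(table = out, report = qc_report(n_in, drops))
}

#' Allele-frequency divergence filter
#'
#' Computes the signed difference of the two aligned effect-allele
#' frequencies and drops records strictly below the `lower_pct` percentile
#' or strictly above the `upper_pct` percentile of that distribution
#' (percentiles by linear interpolation on the sorted values, symmetric in
#' the two tails). Flags SNPs likely affected by coding errors, strand flips
#' or real frequency divergence between the two GWAS samples.
#'
#' @param merged a merged table from [align_and_merge()].
#' @param lower_pct,upper_pct percentile bounds in `[0, 100]`.
#' @return `list(table, report)`.
#' @export
maf_divergence_filter <- function(merged, lower_pct = 1, upper_pct = 99) {
  if (lower_pct >= upper_pct) stop("lower_pct must be < upper_pct")
  d <- merged$eaf_a - merged$eaf_b
  qs <- quantile(d, probs = c(lower_pct, upper_pct) / 100,
                 type = 6, names = FALSE)
  keep <- d >= qs[1] & d <= qs[2]
  out <- merged[keep]
  setattr(out, "class", class(merged))
  setattr(out, "trait_a", attr(merged, "trait_a"))
  setattr(out, "trait_b", attr(merged, "trait_b"))
  list(table = out,
       report = qc_report(nrow(merged), c(maf_divergence = sum(!keep))))
}

#' Standardized beta from a z-score
#'
#' Approximates the per-allele effect on a standardized phenotype as
#' `z / sqrt(n * 2 * maf * (1 - maf))`, with `maf = min(eaf, 1 - eaf)`.
#' Useful when a GWAS reports z-scores (or betas on an unknown scale) and a
#' weight on a common scale is needed.
#'
#' @param z z-score(s).
#' @param n sample size(s), positive.
#' @param eaf effect-allele frequency in (0,1).
#' @return numeric vector of approximated betas.
#' @export
beta_from_z <- function(z, n, eaf) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(eaf <= 0 | eaf >= 1)) stop("eaf must be strictly inside (0,1)")
  maf <- pmin(eaf, 1 - eaf)
  z / sqrt(n * 2 * maf * (1 - maf))
}

#' Inverse of [beta_from_z()]
#' @param beta standardized beta.
#' @inheritParams beta_from_z
#' @return z-score(s).
#' @export
z_from_beta <- function(beta, n, eaf) {
  maf <- pmin(eaf, 1 - eaf)
  beta * sqrt(n * 2 * maf * (1 - maf))
}
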