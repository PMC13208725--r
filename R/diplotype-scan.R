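#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR q-values, order-preserving against the input.
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values (`q >= p` elementwise, monotone in rank order).
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

geno_label <- function(dosage, maj, mnr) {
  c(paste0(maj, "/", maj), paste0(maj, "/", mnr),
    paste0(mnr, "/", mnr))[dosage + 1L]
}

#' Pairwise genotype-combination (diplotype) scan
#'
#' For every unordered pair of SNPs and every observed two-locus
#' genotype combination, tests carriers of the combination against all
#' other individuals in a case-control 2x2 table. Odds ratios use the
#' Haldane-Anscombe +0.5 correction on all four cells whenever the
#' smallest cell is `haldane_min` or less; two-sided p is chi-square
#' without continuity correction (Fisher exact when an expected cell is
#' below 5). BH-FDR is applied within the stratum over all tested
#' rows; a `screened` flag marks rows with raw p < 0.05 (the two-step
#' presentation), while q-values are computed over the full set to
#' avoid selection bias.
#'
#' @param gm a [genotype_matrix()].
#' @param ct cohort table.
#' @param stratum `"entire"`, `"male"` or `"female"`.
#' @param pairs optional 2-column character matrix of SNP id pairs
#'   (default: all pairs).
#' @param haldane_min apply the +0.5 rule when `min(cell) <= haldane_min`.
#' @param alpha CI level for the odds ratio.
#' @return Data frame of `diplotype_result` rows.
#' @export
diplotype_scan <- function(gm, ct, stratum = "entire", pairs = NULL,
                           haldane_min = 5, alpha = 0.05) {
  if (ncol(gm) < 2) stop("need at least two SNPs")
  sel <- stratum_selector(ct, stratum)
  ids <- ct$id[sel]; st <- ct$status[sel]
  dos <- unclass(gm)[ids, , drop = FALSE]
  info <- snps_of(gm)
  n_case <- sum(st == 1); n_ctrl <- sum(st == 0)
  if (is.null(pairs)) {
    cmb <- utils::combn(colnames(gm), 2)
    pairs <- t(cmb)
  }
  rows <- list()
  for (r in seq_len(nrow(pairs))) {
    sA <- pairs[r, 1]; sB <- pairs[r, 2]
    iA <- match(sA, info$snp_id); iB <- match(sB, info$snp_id)
    for (gA in 0:2) for (gB in 0:2) {
      carrier <- dos[, sA] == gA & dos[, sB] == gB
      a <- sum(carrier & st == 1); c <- sum(carrier & st == 0)
      if (a + c == 0) next  # combination absent in both groups
      b <- n_case - a; d <- n_ctrl - c
      use_h <- min(a, b, c, d) <= haldane_min
      orci <- crude_or_ci(a, b, c, d, haldane = use_h, alpha = alpha)
      p <- asym_p_2x2(c(a, b, c, d))
      rows[[length(rows) + 1]] <- data.frame(
        snpA = sA, genoA = geno_label(gA, info$allele_major[iA],
                                      info$allele_minor[iA]),
        snpB = sB, genoB = geno_label(gB, info$allele_major[iB],
                                      info$allele_minor[iB]),
        n_case = a, n_control = c,
        pct_case = round(100 * a / n_case, 1),
        pct_control = round(100 * c / n_ctrl, 1),
        or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
        haldane = use_h, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p) & out$p < 1
  out$q <- NA_real_
  out$q[ok] <- bh_fdr(out$p[ok])
  out$screened <- !is.na(out$p) & out$p < 0.05
  out$stratum <- stratum
  out
}
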