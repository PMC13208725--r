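# EM haplotype machinery for 2-3 SNP blocks. Genotype patterns are
# grouped (at most 3^k distinct patterns), so one EM iteration is O(3^k)
# regardless of sample size; this is what makes permutation re-estimation
# affordable.

hap_strings <- function(k, labels_major, labels_minor) {
  grid <- expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE]
  apply(grid, 1, function(row)
    paste0(ifelse(row == 1, labels_minor, labels_major), collapse = ""))
}

hap_alleles <- function(k) {
  as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
}

# compatible ordered haplotype pairs for each genotype pattern
hap_pairs_for_patterns <- function(k) {
  H <- hap_alleles(k)
  nh <- nrow(H)
  pats <- as.matrix(expand.grid(rep(list(0:2), k))[, k:1, drop = FALSE])
  key <- apply(pats, 1, paste, collapse = "")
  pairs <- vector("list", nrow(pats))
  names(pairs) <- key
  for (i in seq_len(nh)) for (j in seq_len(nh)) {
    g <- paste(H[i, ] + H[j, ], collapse = "")
    pairs[[g]] <- rbind(pairs[[g]], c(i, j))
  }
  list(pairs = pairs, n_hap = nh, pattern_key = key)
}

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for a block of 2 or 3 SNPs
#' by expectation-maximization over phase-ambiguous multi-heterozygotes:
#' the E-step distributes each genotype over its compatible haplotype
#' pairs in proportion to current haplotype-product probabilities, the
#' M-step renormalizes expected haplotype counts. Initialization is the
#' linkage-equilibrium product of allele frequencies (deterministic).
#'
#' @param gm a [genotype_matrix()] (complete genotypes).
#' @param snp_ids the 2 or 3 SNPs of the block (default: all columns).
#' @param tol stop when the largest frequency change falls below this.
#' @param max_iter iteration cap.
#' @return List with `snp_ids`, `haplotype` labels (major/minor allele
#'   characters), `freq`, `loglik` at convergence, `iterations`, and
#'   the per-iteration `loglik_trace` (non-decreasing).
#' @export
em_haplotypes <- function(gm, snp_ids = colnames(gm), tol = 1e-8,
                          max_iter = 1000) {
  k <- length(snp_ids)
  if (!k %in% 2:3) stop("blocks of ", k, " SNPs unsupported (need 2 or 3)")
  dos <- unclass(gm)[, snp_ids, drop = FALSE]
  if (nrow(dos) == 0) stop("no individuals")
  if (anyNA(dos)) stop("complete genotypes required")
  info <- snps_of(gm)
  info <- info[match(snp_ids, info$snp_id), ]
  pat_idx <- apply(dos, 1, paste, collapse = "")
  setup <- hap_pairs_for_patterns(k)
  counts <- table(factor(pat_idx, levels = setup$pattern_key))
  fit <- em_haplotypes_counts(as.numeric(counts), setup, tol, max_iter)
  labs <- hap_strings(k, info$allele_major, info$allele_minor)
  list(snp_ids = snp_ids, haplotype = labs, freq = fit$freq,
       loglik = fit$loglik, iterations = fit$iterations,
       loglik_trace = fit$trace)
}

# EM on pattern counts; freq over the 2^k haplotypes
em_haplotypes_counts <- function(counts, setup, tol = 1e-8, max_iter = 1000,
                                 init = NULL) {
  nh <- setup$n_hap
  k <- log2(nh)
  H <- hap_alleles(k)
  n2 <- 2 * sum(counts)
  # equilibrium init: product of allele frequencies
  if (is.null(init)) {
    pats <- do.call(rbind, strsplit(setup$pattern_key, ""))
    storage.mode(pats) <- "numeric"
    af <- colSums(pats * counts) / n2  # minor-allele freq per SNP
    freq <- apply(H, 1, function(h) prod(ifelse(h == 1, af, 1 - af)))
  } else freq <- init
  freq <- pmax(freq, 1e-12); freq <- freq / sum(freq)
  trace <- numeric(0)
  nonzero <- which(counts > 0)
  for (it in seq_len(max_iter)) {
    newc <- numeric(nh)
    ll <- 0
    for (g in nonzero) {
      pr <- setup$pairs[[g]]
      w <- freq[pr[, 1]] * freq[pr[, 2]]
      tot <- sum(w)
      ll <- ll + counts[g] * log(tot)
      w <- w / tot
      for (r in seq_len(nrow(pr))) {
        newc[pr[r, 1]] <- newc[pr[r, 1]] + counts[g] * w[r]
        newc[pr[r, 2]] <- newc[pr[r, 2]] + counts[g] * w[r]
      }
    }
    trace <- c(trace, ll)
    newf <- newc / n2
    delta <- max(abs(newf - freq))
    freq <- newf
    if (delta < tol) break
  }
  list(freq = freq, loglik = trace[length(trace)], iterations = length(trace),
       trace = trace)
}

#' Pairwise linkage disequilibrium from haplotype frequencies
#'
#' For two biallelic SNPs with haplotype frequencies ordered
#' (AB, Ab, aB, ab) - capital = first allele of each SNP:
#' `D = pAB - pA*pB`; `D' = |D| / Dmax` with
#' `Dmax = min(pA*pb, pa*pB)` when `D > 0`, else `min(pA*pB, pa*pb)`;
#' `r2 = D^2 / (pA*pa*pB*pb)`. D carries the sign; D' is reported as a
#' magnitude.
#'
#' @param freq numeric length-4 vector `(pAB, pAb, paB, pab)`.
#' @return List with `D`, `Dprime`, `r2`.
#' @export
ld_from_freqs <- function(freq) {
  stopifnot(length(freq) == 4, all(freq >= -1e-12))
  freq <- pmax(freq, 0); freq <- freq / sum(freq)
  pA <- freq[1] + freq[2]; pB <- freq[1] + freq[3]
  pa <- 1 - pA; pb <- 1 - pB
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("fixed allele: LD undefined")
  D <- freq[1] - pA * pB
  Dmax <- if (D > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  Dprime <- if (D == 0) 0 else abs(D) / Dmax
  list(D = D, Dprime = Dprime, r2 = D^2 / (pA * pa * pB * pb))
}

#' Haplotype case-control association with permutation p-values
#'
#' Estimates haplotype frequencies separately in cases and controls by
#' EM, forms per-haplotype 2x2 tables of expected chromosome counts
#' (freq x 2N per group, this haplotype vs all others), and computes a
#' chi-square statistic per haplotype. The permutation p shuffles case
#' labels and re-runs the EM within each permuted group. Haplotypes
#' below `min_freq` in both groups are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param status 0/1 case vector aligned with the rows of `gm`.
#' @param snp_ids the block's SNPs (2 or 3).
#' @param B permutations.
#' @param seed RNG seed.
#' @param min_freq rare-haplotype exclusion threshold (default 1%).
#' @return Data frame with `haplotype`, `freq_case`, `freq_control`,
#'   `chi2`, `p_perm`.
#' @export
haplotype_assoc <- function(gm, status, snp_ids = colnames(gm), B = 1000,
                            seed = 1, min_freq = 0.01) {
  k <- length(snp_ids)
  dos <- unclass(gm)[, snp_ids, drop = FALSE]
  if (anyNA(dos)) stop("complete genotypes required")
  stopifnot(length(status) == nrow(dos), all(status %in% 0:1))
  setup <- hap_pairs_for_patterns(k)
  pat <- factor(apply(dos, 1, paste, collapse = ""),
                levels = setup$pattern_key)
  chi2_by_group <- function(st) {
    fc <- em_haplotypes_counts(as.numeric(table(pat[st == 1])), setup)$freq
    f0 <- em_haplotypes_counts(as.numeric(table(pat[st == 0])), setup)$freq
    n1 <- 2 * sum(st == 1); n0 <- 2 * sum(st == 0)
    a <- fc * n1; b <- n1 - a; c <- f0 * n0; d <- n0 - c
    num <- (a * d - b * c)^2 * (n1 + n0)
    den <- (a + c) * (b + d) * n1 * n0
    chi <- ifelse(den > 0, num / den, 0)
    list(chi2 = chi, fc = fc, f0 = f0)
  }
  obs <- chi2_by_group(status)
  keep <- obs$fc >= min_freq | obs$f0 >= min_freq
  set.seed(as.integer(seed))
  exceed <- numeric(setup$n_hap)
  if (B >= 1) {
    for (b in seq_len(B)) {
      perm <- chi2_by_group(sample(status))
      exceed <- exceed + (perm$chi2 >= obs$chi2)
    }
  }
  info <- snps_of(gm); info <- info[match(snp_ids, info$snp_id), ]
  out <- data.frame(
    haplotype = hap_strings(k, info$allele_major, info$allele_minor),
    freq_case = obs$fc, freq_control = obs$f0, chi2 = obs$chi2,
    p_perm = (exceed + 1) / (B + 1), stringsAsFactors = FALSE)
  out[keep, , drop = FALSE]
}
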