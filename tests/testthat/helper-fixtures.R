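# Shared fixtures: tiny genotype matrices built in code, and
# independent oracles used across test files.

# genotype_matrix from a plain dosage matrix with default metadata
gm_from_dosage <- function(dos, snp_ids = paste0("s", seq_len(ncol(dos))),
                           gene = "G",
                           ids = sprintf("ind%05d", seq_len(nrow(dos)))) {
  info <- snp_info(snp_ids, gene = rep_len(gene, ncol(dos)),
                   allele_major = rep_len("A", ncol(dos)),
                   allele_minor = rep_len("G", ncol(dos)))
  genotype_matrix(as.matrix(dos), info, ids)
}

# cohort table wrapper
ct_from <- function(status, sex = rep(c("M", "F"), length.out = length(status)),
                    age = rep(60, length(status)),
                    smoking = rep(0L, length(status)),
                    alcohol = rep(0L, length(status)),
                    id = sprintf("ind%05d", seq_along(status))) {
  data.frame(id = id, status = status, sex = sex, age = age,
             smoking = smoking, alcohol = alcohol, stringsAsFactors = FALSE)
}

# Exhaustive-enumeration oracle for the Hardy-Weinberg exact test:
# enumerates every genotype table with the same allele margin and sums
# multinomial probabilities (with the 2^het phase factor) of tables no
# more probable than the observed one.
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  if (nA == 0 || nA == 2 * n) return(1)
  tabs <- list()
  for (het in 0:n) {
    homA2 <- nA - het
    if (homA2 < 0 || homA2 %% 2 != 0) next
    homA <- homA2 / 2
    homa <- n - homA - het
    if (homa < 0) next
    tabs[[length(tabs) + 1]] <- c(homA, het, homa)
  }
  logp <- vapply(tabs, function(t)
    lfactorial(n) - sum(lfactorial(t)) + t[2] * log(2), 0)
  prob <- exp(logp - max(logp)); prob <- prob / sum(prob)
  obs <- which(vapply(tabs, function(t) t[2] == nAa, TRUE))
  sum(prob[prob <= prob[obs] + 1e-12])
}

# Brute-force maximizer of the multinomial phase likelihood for a
# 2-SNP block over a frequency grid (independent EM oracle).
hap_grid_oracle <- function(dos, step = 0.005) {
  pats <- apply(dos, 1, paste, collapse = "")
  cnt <- table(pats)
  # haplotypes in order (00, 01, 10, 11) = (AB, Ab, aB, ab) minor coding
  lik <- function(f) {
    p <- c("00" = f[1] * f[1], "01" = 2 * f[1] * f[2], "02" = f[2] * f[2],
           "10" = 2 * f[1] * f[3], "11" = 2 * (f[1] * f[4] + f[2] * f[3]),
           "12" = 2 * f[2] * f[4], "20" = f[3] * f[3],
           "21" = 2 * f[3] * f[4], "22" = f[4] * f[4])
    sum(cnt * log(p[names(cnt)]))
  }
  best <- NULL; best_ll <- -Inf
  for (f1 in seq(step, 1 - step, step)) for (f2 in seq(0, 1 - f1, step)) {
    for (f3 in seq(0, 1 - f1 - f2, step)) {
      f <- c(f1, f2, f3, 1 - f1 - f2 - f3)
      if (any(f < 0)) next
      ll <- lik(pmax(f, 1e-12))
      if (is.finite(ll) && ll > best_ll) { best_ll <- ll; best <- f }
    }
  }
  list(freq = best, loglik = best_ll)
}

# write a minimal ped/map pair for reader tests
write_ped_map <- function(dir, ids, alleles, snp_ids) {
  ped <- file.path(dir, "toy.ped"); map <- file.path(dir, "toy.map")
  rows <- vapply(seq_along(ids), function(i)
    paste(c("FAM", ids[i], "0", "0", "1", "1", alleles[[i]]),
          collapse = " "), "")
  writeLines(rows, ped)
  writeLines(sprintf("1 %s 0 %d", snp_ids, seq_along(snp_ids)), map)
  list(ped = ped, map = map)
}
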