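#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts:
#' enumerates every heterozygote count compatible with the allele
#' margin and sums the probabilities of all genotype configurations no
#' more probable than the observed one.
#'
#' @param nAA,nAa,naa genotype counts.
#' @return Exact p-value in (0, 1]; monomorphic samples return 1 by
#'   convention.
#' @export
hwe_exact <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n == 0) stop("empty sample")
  n_a <- 2L * naa + nAa      # minor-ish allele count (either works)
  n_A <- 2L * nAA + nAa
  if (n_a == 0L || n_A == 0L) return(1)
  rare <- min(n_a, n_A)
  # heterozygote counts share the parity of the rare-allele count
  het <- seq(rare %% 2L, rare, by = 2L)
  # log P(nAa = h | allele margin): n! 2^h / (hom1! h! hom2!) * C
  logp <- lgamma(n + 1) + het * log(2) -
    lgamma((rare - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((2L * n - rare - het) / 2 + 1)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(nAa, het)]
  min(1, sum(prob[prob <= obs + 1e-12]))
}

#' Collapse dosages under a genetic model
#'
#' @param dosage integer vector in \{0, 1, 2\}.
#' @param model `"additive"` (identity), `"dominant"` (carrier
#'   indicator) or `"recessive"` (homozygote indicator).
#' @return Integer vector.
#' @export
collapse_model <- function(dosage, model = c("additive", "dominant",
                                             "recessive")) {
  model <- match.arg(model)
  switch(model,
         additive = as.integer(dosage),
         dominant = as.integer(dosage > 0),
         recessive = as.integer(dosage == 2))
}

#' Crude odds ratio with Woolf confidence interval
#'
#' OR = ad/bc for the 2x2 table `(a, b; c, d)` with a Woolf
#' (log-normal) interval. With `haldane = TRUE`, 0.5 is added to all
#' four cells before any ratio (Haldane-Anscombe continuity
#' correction), keeping the estimate finite for sparse tables.
#'
#' @param a,b,c,d cell counts (a = exposed cases, b = unexposed cases,
#'   c = exposed controls, d = unexposed controls).
#' @param haldane apply the +0.5 correction to every cell.
#' @param alpha two-sided interval level (default 95% CI).
#' @return List with `or`, `ci_low`, `ci_high`, and `defined` (FALSE
#'   when a zero cell makes the uncorrected OR undefined).
#' @export
crude_or_ci <- function(a, b, c, d, haldane = FALSE, alpha = 0.05) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  } else if (min(a, b, c, d) == 0) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                defined = FALSE))
  }
  z <- qnorm(1 - alpha / 2)
  lo <- unname(log(a) + log(d) - log(b) - log(c))
  se <- unname(sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  list(or = exp(lo), ci_low = exp(lo - z * se), ci_high = exp(lo + z * se),
       defined = TRUE)
}

#' Permutation p-value for an arbitrary statistic
#'
#' `p_hat = (R + 1) / (B_done + 1)` where `R` counts permuted
#' statistics at least as large as the observed one. In adaptive mode
#' permutation stops early (after a floor of 100 draws) once the 99%
#' binomial interval around `p_hat` excludes `alpha`.
#'
#' @param stat_fn function of a status vector returning a scalar
#'   statistic (larger = more extreme).
#' @param status 0/1 vector to permute.
#' @param B maximum number of permutations.
#' @param adaptive stop early by the binomial-interval rule.
#' @param alpha significance level targeted by the adaptive rule.
#' @param seed RNG seed.
#' @return List with `p_hat`, `B_done`, and the observed statistic.
#' @export
permutation_pvalue <- function(stat_fn, status, B = 1000, adaptive = FALSE,
                               alpha = 0.05, seed = 1) {
  stopifnot(B >= 1)
  set.seed(as.integer(seed))
  obs <- stat_fn(status)
  if (!is.finite(obs)) return(list(p_hat = 1, B_done = 0L, observed = obs))
  R <- 0L; done <- 0L
  floor_b <- min(B, 100L)
  for (b in seq_len(B)) {
    perm <- stat_fn(sample(status))
    if (is.finite(perm) && perm >= obs) R <- R + 1L
    done <- b
    if (adaptive && b >= floor_b) {
      p <- (R + 1) / (b + 1)
      half <- qnorm(0.995) * sqrt(p * (1 - p) / b)
      if (p - half > alpha || p + half < alpha) break
    }
  }
  list(p_hat = (R + 1) / (done + 1), B_done = done, observed = obs)
}

#' Genotype counts for a case-control stratum
#'
#' @param case,control length-3 vectors `(nAA, nAa, naa)` ordered as
#'   0, 1, 2 copies of the minor allele.
#' @return Object of class `genotype_counts`.
#' @export
genotype_counts <- function(case, control) {
  stopifnot(length(case) == 3, length(control) == 3,
            all(case >= 0), all(control >= 0))
  structure(list(case = as.numeric(case), control = as.numeric(control)),
            class = "genotype_counts")
}

model_2x2 <- function(counts, model) {
  # a = exposed cases, b = unexposed cases, c = exposed ctrls, d = unexposed
  if (model == "dominant") {
    c(a = counts$case[2] + counts$case[3], b = counts$case[1],
      c = counts$control[2] + counts$control[3], d = counts$control[1])
  } else {  # recessive
    c(a = counts$case[3], b = counts$case[1] + counts$case[2],
      c = counts$control[3], d = counts$control[1] + counts$control[2])
  }
}

asym_p_2x2 <- function(tab) {
  m <- matrix(tab, 2, 2, byrow = TRUE)
  if (any(m < 0) || sum(m) == 0) return(NA_real_)
  expd <- outer(rowSums(m), colSums(m)) / sum(m)
  if (min(expd) < 5) return(fisher.test(round(m))$p.value)
  suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
}

#' Best-genetic-model association for one SNP
#'
#' Evaluates the dominant and recessive collapses (chi-square, Fisher
#' when an expected cell is below 5) and the additive model
#' (Cochran-Armitage trend), selects the model with the smallest
#' asymptotic p, and reports its crude OR/Woolf CI together with a
#' permutation p-value of the selected model's statistic.
#'
#' @param counts a [genotype_counts()].
#' @param B permutations (0 skips the permutation p).
#' @param seed RNG seed for the permutation stream.
#' @param haldane passed to [crude_or_ci()].
#' @return A one-row data frame (`model`, `or`, `ci_low`, `ci_high`,
#'   `p_asymptotic`, `p_perm`, `n_permutations`, plus the 2x2 cells),
#'   or `NULL` when every model is degenerate.
#' @export
best_model_assoc <- function(counts, B = 0, seed = 1, haldane = FALSE) {
  stopifnot(inherits(counts, "genotype_counts"))
  models <- c("dominant", "recessive", "additive")
  ps <- setNames(rep(NA_real_, 3), models)
  for (mdl in c("dominant", "recessive")) {
    tab <- model_2x2(counts, mdl)
    if (sum(tab[c("a", "c")]) > 0 && sum(tab[c("b", "d")]) > 0)
      ps[mdl] <- asym_p_2x2(tab)
  }
  tot <- counts$case + counts$control
  if (sum(tot[2:3]) > 0 && sum(tot[1:2]) > 0)
    ps["additive"] <- suppressWarnings(
      prop.trend.test(counts$case, tot, score = 0:2)$p.value)
  if (all(is.na(ps))) return(NULL)
  best <- models[which.min(ps)]
  tab <- if (best == "additive") {
    # allelic 2x2: minor-allele chromosomes vs major-allele chromosomes
    c(a = counts$case[2] + 2 * counts$case[3],
      b = 2 * counts$case[1] + counts$case[2],
      c = counts$control[2] + 2 * counts$control[3],
      d = 2 * counts$control[1] + counts$control[2])
  } else model_2x2(counts, best)
  orci <- crude_or_ci(tab["a"], tab["b"], tab["c"], tab["d"],
                      haldane = haldane)
  p_perm <- NA_real_; b_done <- 0L
  if (B > 0) {
    status <- rep(c(1L, 0L), c(sum(counts$case), sum(counts$control)))
    dosage <- c(rep(0:2, counts$case), rep(0:2, counts$control))
    x <- collapse_model(dosage,
                        if (best == "additive") "additive" else best)
    stat_fn <- function(st) {
      tb <- table(factor(st, levels = 0:1), factor(x, levels = sort(unique(x))))
      suppressWarnings(chisq.test(tb, correct = FALSE)$statistic)
    }
    pp <- permutation_pvalue(stat_fn, status, B = B, seed = seed)
    p_perm <- pp$p_hat; b_done <- pp$B_done
  }
  data.frame(model = best, or = orci$or, ci_low = orci$ci_low,
             ci_high = orci$ci_high, p_asymptotic = ps[best],
             p_perm = p_perm, n_permutations = b_done,
             a = unname(tab["a"]), b = unname(tab["b"]),
             c = unname(tab["c"]), d = unname(tab["d"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

counts_from_data <- function(dosage, status) {
  genotype_counts(
    case = tabulate(factor(dosage[status == 1], levels = 0:2), 3),
    control = tabulate(factor(dosage[status == 0], levels = 0:2), 3))
}

#' Single-variant association table for a stratum
#'
#' Runs [best_model_assoc()] for every SNP within a sex stratum.
#'
#' @param gm a [genotype_matrix()].
#' @param ct cohort table.
#' @param stratum `"entire"`, `"male"` or `"female"`.
#' @param B permutations per SNP.
#' @param seed RNG seed.
#' @return Data frame with one row per SNP.
#' @export
assoc_table <- function(gm, ct, stratum = "entire", B = 1000, seed = 1) {
  sel <- stratum_selector(ct, stratum)
  ids <- ct$id[sel]
  st <- ct$status[sel]
  rows <- lapply(seq_len(ncol(gm)), function(j) {
    res <- best_model_assoc(counts_from_data(unclass(gm)[ids, j], st),
                            B = B, seed = seed + j)
    if (is.null(res)) return(NULL)
    cbind(snp_id = colnames(gm)[j], stratum = stratum, res,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Predictor-by-sex interaction scan
#'
#' One logistic fit per predictor x genetic-model combination:
#' `status ~ predictor + sex + predictor:sex + age`, reporting the Wald
#' p of the interaction term with BH-FDR across all scanned rows.
#' Exposure predictors (`smoking`, `alcohol`) are scanned once without
#' a genetic model.
#'
#' @param gm a [genotype_matrix()].
#' @param ct cohort table (both sexes required).
#' @param predictors SNP ids and/or `"smoking"`, `"alcohol"`.
#' @param models genetic models applied to each SNP predictor.
#' @return Data frame with `predictor`, `model`, `beta_int`, `p`, `q`,
#'   and a `flagged` column for non-finite (separated) fits; flagged
#'   rows are excluded from the FDR family.
#' @export
sex_interaction_scan <- function(gm, ct,
                                 predictors = c(colnames(gm), "smoking",
                                                "alcohol"),
                                 models = c("additive", "dominant",
                                            "recessive")) {
  if (length(unique(ct$sex)) < 2) stop("both sexes required")
  sexm <- as.integer(ct$sex == "M")
  rows <- list()
  for (pr in predictors) {
    is_snp <- pr %in% colnames(gm)
    mdls <- if (is_snp) models else NA_character_
    for (mdl in mdls) {
      x <- if (is_snp) collapse_model(unclass(gm)[ct$id, pr], mdl)
           else ct[[pr]]
      keep <- complete.cases(x, ct$age)
      fit <- tryCatch(
        glm(ct$status[keep] ~ x[keep] * sexm[keep] + ct$age[keep],
            family = binomial()), warning = function(w) NULL,
        error = function(e) NULL)
      beta <- p <- NA_real_; flagged <- TRUE
      if (!is.null(fit)) {
        cf <- summary(fit)$coefficients
        idx <- grep(":", rownames(cf))
        if (length(idx) == 1 && is.finite(cf[idx, 4])) {
          beta <- cf[idx, 1]; p <- cf[idx, 4]; flagged <- FALSE
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pr, model = mdl, beta_int = beta, p = p,
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !out$flagged
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}

#' Exposure-stratified association for one SNP
#'
#' Within each level of a binary exposure: selects the best genetic
#' model by crude asymptotic p, then estimates the OR adjusted for sex
#' and age by logistic regression, with a permutation p-value that
#' permutes status within the stratum. Rows with missing exposure are
#' dropped (count reported); strata under 10 individuals are flagged.
#'
#' @param gm a [genotype_matrix()].
#' @param ct cohort table.
#' @param snp SNP id.
#' @param exposure `"smoking"` or `"alcohol"`.
#' @param B permutations per stratum.
#' @param seed RNG seed.
#' @return Data frame with one row per exposure level (exposed,
#'   unexposed).
#' @export
exposure_stratified_assoc <- function(gm, ct, snp, exposure, B = 200,
                                      seed = 1) {
  ex <- ct[[exposure]]
  keep <- !is.na(ex)
  n_dropped <- sum(!keep)
  ct <- ct[keep, , drop = FALSE]
  ex <- ex[keep]
  if (length(unique(ex)) < 2) stop("exposure is constant after dropping NAs")
  dosage <- unclass(gm)[ct$id, snp]
  rows <- lapply(c(1, 0), function(lev) {
    sel <- ex == lev
    st <- ct$status[sel]
    low_n <- sum(sel) < 10
    cnt <- counts_from_data(dosage[sel], st)
    crude <- best_model_assoc(cnt)
    if (is.null(crude))
      return(data.frame(snp_id = snp, exposure = exposure, exposed = lev,
                        n = sum(sel), model = NA, or_adj = NA, ci_low = NA,
                        ci_high = NA, p_perm = NA, low_n = low_n,
                        n_dropped = n_dropped))
    mdl <- if (crude$model == "additive") "additive" else crude$model
    x <- collapse_model(dosage[sel], mdl)
    sexm <- as.integer(ct$sex[sel] == "M")
    X <- cbind(1, x, sexm, ct$age[sel])
    fit <- logistic_fit_cpp(X, as.numeric(st))
    or_adj <- ci_lo <- ci_hi <- p_perm <- NA_real_
    if (isTRUE(fit$converged)) {
      b <- fit$beta[2]; se <- fit$se[2]
      or_adj <- exp(b); ci_lo <- exp(b - 1.96 * se); ci_hi <- exp(b + 1.96 * se)
      if (B > 0) {
        set.seed(as.integer(seed) + lev)
        obs <- abs(b / se)
        perm <- perm_wald_cpp(X, as.numeric(st), 1L, as.integer(B))
        p_perm <- (sum(perm >= obs, na.rm = TRUE) + 1) / (B + 1)
      }
    }
    data.frame(snp_id = snp, exposure = exposure, exposed = lev, n = sum(sel),
               model = mdl, or_adj = or_adj, ci_low = ci_lo, ci_high = ci_hi,
               p_perm = p_perm, low_n = low_n, n_dropped = n_dropped,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
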