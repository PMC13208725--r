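test_that("HWE exact test matches the enumeration oracle and conventions", {
  expect_equal(hwe_exact(50, 0, 0), 1)           # monomorphic
  expect_lt(hwe_exact(0, 100, 0), 1e-6)          # all heterozygotes
  expect_equal(hwe_exact(3, 5, 2), hwe_oracle(3, 5, 2))
})

test_that("HWE exact test equals the oracle for all tables with n <= 50", {
  # property sweep over a deterministic grid of genotype tables
  for (n in c(5, 12, 23, 50)) {
    for (nAA in seq(0, n, by = max(1, n %/% 5))) {
      for (nAa in seq(0, n - nAA, by = max(1, (n - nAA) %/% 4 + 1))) {
        naa <- n - nAA - nAa
        expect_equal(hwe_exact(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                     tolerance = 1e-10,
                     info = sprintf("table %d/%d/%d", nAA, nAa, naa))
      }
    }
  }
})

test_that("genetic-model collapse follows the dominant/recessive rules", {
  expect_equal(collapse_model(c(0, 1, 2), "recessive"), c(0L, 0L, 1L))
  expect_equal(collapse_model(c(0, 1, 2), "dominant"), c(0L, 1L, 1L))
  expect_equal(collapse_model(c(0, 1, 2), "additive"), c(0L, 1L, 2L))
})

test_that("crude OR and Woolf interval reproduce case-control tables", {
  r <- crude_or_ci(53, 547, 40, 648)
  expect_equal(round(c(r$or, r$ci_low, r$ci_high), 2), c(1.57, 1.03, 2.40))
  r <- crude_or_ci(23, 247, 11, 311)
  expect_equal(round(c(r$or, r$ci_low, r$ci_high), 2), c(2.63, 1.26, 5.51))
  expect_equal(crude_or_ci(1, 1, 1, 1)$or, 1)
  r <- crude_or_ci(16, 254, 3, 319, haldane = TRUE)
  expect_equal(round(c(r$or, r$ci_low, r$ci_high), 2), c(5.92, 1.85, 18.98))
  # zero cell without continuity correction is an undefined-OR signal
  expect_false(crude_or_ci(0, 10, 5, 5)$defined)
})

test_that("crude OR is exactly reciprocal under column swap and the CI
           contains the point estimate", {
  set.seed(2)
  for (i in 1:25) {
    cells <- sample(1:40, 4, TRUE)
    r1 <- crude_or_ci(cells[1], cells[2], cells[3], cells[4])
    r2 <- crude_or_ci(cells[2], cells[1], cells[4], cells[3])
    expect_equal(log(r1$or), -log(r2$or), tolerance = 1e-12)
    expect_lte(r1$ci_low, r1$or); expect_gte(r1$ci_high, r1$or)
  }
})

test_that("permutation p-values carry the +1 correction and are seeded", {
  # observed statistic above every permuted value: p = (0+1)/(99+1)
  x <- c(rep(1, 5), rep(0, 45))
  stat_fn <- function(st) if (identical(st, x)) 100 else runif(1)
  p <- permutation_pvalue(stat_fn, x, B = 99, seed = 1)
  expect_equal(p$p_hat, 0.01)
  s1 <- permutation_pvalue(function(st) sum(st[1:10]), x, B = 200, seed = 9)
  s2 <- permutation_pvalue(function(st) sum(st[1:10]), x, B = 200, seed = 9)
  expect_identical(s1, s2)
  expect_gte(s1$p_hat, 1 / (s1$B_done + 1))
})

test_that("permutation test holds its type-I error on null data", {
  set.seed(100)
  rej <- replicate(400, {
    g <- rbinom(60, 2, 0.3)
    st <- rbinom(60, 1, 0.5)
    stat_fn <- function(s) abs(mean(g[s == 1]) - mean(g[s == 0]))
    permutation_pvalue(stat_fn, st, B = 60, seed = sample.int(1e6, 1))$p_hat <= 0.05
  })
  expect_gt(mean(rej), 0.02); expect_lt(mean(rej), 0.08)
})

test_that("adaptive permutation stops early for clearly null statistics", {
  x <- rep(0:1, 50)
  stat_fn <- function(st) sum(st * seq_along(st)) %% 7  # arbitrary, exchangeable
  p <- permutation_pvalue(stat_fn, x, B = 5000, adaptive = TRUE, seed = 2)
  expect_lt(p$B_done, 5000)
  expect_gte(p$B_done, 100)
})

test_that("best-model selection reproduces sex-stratified genotype tables", {
  # women: recessive collapse is the strongest signal, protective OR
  res <- best_model_assoc(genotype_counts(c(87, 155, 28), c(91, 169, 62)))
  expect_equal(res$model, "recessive")
  expect_equal(round(res$or, 2), 0.49)
  expect_equal(round(c(res$ci_low, res$ci_high), 2), c(0.30, 0.78))
  # men, same SNP: dominant collapse wins with a null-ish OR
  res <- best_model_assoc(genotype_counts(c(87, 180, 63), c(112, 181, 73)))
  expect_equal(res$model, "dominant")
  expect_equal(round(res$or, 2), 1.23)
  # perfectly balanced counts: OR 1 under every model
  for (m in c("dominant", "recessive")) {
    cnt <- genotype_counts(c(50, 30, 20), c(50, 30, 20))
    tab <- epistab:::model_2x2(cnt, m)
    expect_equal(crude_or_ci(tab[1], tab[2], tab[3], tab[4])$or, 1)
  }
  # no minor alleles anywhere: no result
  expect_null(best_model_assoc(genotype_counts(c(50, 0, 0), c(60, 0, 0))))
})

test_that("sex-interaction scan recovers a planted female-only effect", {
  spec <- default_sim_spec(seed = 61, interaction_or = 2.0)
  spec$model$interactions <- list(
    list(exposure = "smoking", snp = "rs8140505", sex = "F", log_or = log(2)))
  spec$n_cases <- 2000; spec$n_controls <- 2000
  spec$smoking_prev <- c(M = 0.4, F = 0.4)
  coh <- simulate_cohort(spec)
  # scan the smoking-stratified carrier product as a derived predictor:
  # the planted effect makes the smoking x sex interaction detectable
  # through the genotype x sex term among smokers
  sm <- coh$ct$smoking == 1
  scan <- sex_interaction_scan(coh$gm[coh$ct$id[sm], "rs8140505",
                                      drop = FALSE],
                               coh$ct[sm, ], predictors = "rs8140505",
                               models = "additive")
  expect_lt(scan$q[1], 0.05)
  # interaction log-OR has the right sign (female = reference here,
  # male indicator reduces the slope)
  expect_lt(scan$beta_int[1], 0)
})

test_that("sex-interaction scan is calibrated near the null and q = p for
           a single predictor", {
  spec <- default_sim_spec(seed = 71)
  spec$model <- disease_model(intercept = 0)
  spec$n_cases <- 400; spec$n_controls <- 400
  coh <- simulate_cohort(spec)
  scan <- sex_interaction_scan(coh$gm, coh$ct)
  ok <- !scan$flagged
  expect_gt(mean(scan$p[ok] > 0.05), 0.7)
  one <- sex_interaction_scan(coh$gm, coh$ct, predictors = "rs8140505",
                              models = "additive")
  expect_equal(one$q, one$p)
})

test_that("exposure-stratified association flags degenerate strata and
           matches the crude OR absent confounding", {
  gm <- gm_from_dosage(matrix(rbinom(400, 2, 0.3), 200, 2),
                       snp_ids = c("rs1", "rs2"))
  ct <- ct_from(rep(0:1, 100))
  ct$smoking <- 0L
  expect_error(exposure_stratified_assoc(gm, ct, "rs1", "smoking"),
               "constant")
  # null confounding: adjusted OR within 5% of crude
  spec <- default_sim_spec(seed = 81)
  spec$model <- disease_model(intercept = -0.2,
                              snp_effects = c(rs4820599 = log(1.8)))
  spec$n_cases <- 2000; spec$n_controls <- 2000
  coh <- simulate_cohort(spec)
  res <- exposure_stratified_assoc(coh$gm, coh$ct, "rs4820599", "smoking",
                                   B = 0)
  cr <- best_model_assoc(epistab:::counts_from_data(
    unclass(coh$gm)[coh$ct$id[coh$ct$smoking == 1], "rs4820599"],
    coh$ct$status[coh$ct$smoking == 1]))
  adj <- res$or_adj[res$exposed == 1]
  expect_lt(abs(log(adj) - log(cr$or)), log(1.05) + 0.02)
})
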