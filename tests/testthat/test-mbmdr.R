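make_stratum <- function(n = 400, seed = 1, maf = c(0.3, 0.25)) {
  set.seed(seed)
  dos <- vapply(maf, function(q) rbinom(n, 2, q), integer(n))
  gm <- gm_from_dosage(dos, snp_ids = c("rsA", "rsB"))
  ct <- ct_from(rbinom(n, 1, 0.5), sex = "F", age = round(rnorm(n, 60, 8)),
                smoking = rbinom(n, 1, 0.4))
  list(gm = gm, ct = ct)
}

test_that("cell partitions are deterministic and exhaustive", {
  d <- make_stratum(300, seed = 5)
  part <- build_cells(d$gm, d$ct, c("rsA", "rsB"))
  expect_lte(part$K, 9)
  expect_equal(sum(part$n), 300)          # cells partition the stratum
  part2 <- build_cells(d$gm, d$ct, c("rsA", "smoking"))
  expect_lte(part2$K, 6)
  expect_error(build_cells(d$gm, d$ct, c("rsA", "rsA")), "duplicate")
})

test_that("cell classification agrees with a direct glm oracle", {
  set.seed(9)
  # one cell of 30 cases / 5 controls against a balanced background
  status <- c(rep(1, 30), rep(0, 5), rep(1, 100), rep(0, 100))
  age <- round(rnorm(235, 60, 8))
  part <- structure(list(cell = c(rep(1L, 35), rep(2L, 200)), K = 2L,
                         key = c("0:0", "1:0"), n = c(35L, 200L),
                         factors = c("a", "b"), keep = rep(TRUE, 235)),
                    class = "cell_partition")
  labs <- classify_cells(part, status, age)
  expect_equal(labs[1], "H")
  oracle <- glm(status ~ I(part$cell == 1) + age, family = binomial())
  expect_lt(summary(oracle)$coefficients[2, 4], 0.05)
  expect_gt(coef(oracle)[2], 0)
  # threshold 0: nothing can be significant, everything O
  expect_equal(classify_cells(part, status, age, risk_threshold = 0),
               c("O", "O"))
  # a cell with the background case fraction is O
  status2 <- c(rep(c(1, 0), 17), 1, rep(c(1, 0), 100))
  expect_equal(classify_cells(part, status2, age)[1], "O")
})

test_that("cells below min_cell are never pooled", {
  set.seed(13)
  status <- c(rep(1, 8), rbinom(200, 1, 0.5))
  part <- structure(list(cell = c(rep(1L, 8), rep(2L, 200)), K = 2L,
                         key = c("x", "y"), n = c(8L, 200L),
                         factors = c("a", "b"), keep = rep(TRUE, 208)),
                    class = "cell_partition")
  labs <- classify_cells(part, status, NULL, min_cell = 10)
  expect_equal(labs[1], "O")  # 8 pure cases, but below the size floor
})

test_that("pooled Wald tests match glm and keep OR = exp(beta)", {
  d <- make_stratum(500, seed = 17)
  part <- build_cells(d$gm, d$ct, c("rsA", "rsB"))
  fit <- pooled_tests(part, d$ct$status, d$ct$age, risk_threshold = 0.5)
  labs <- classify_cells(part, d$ct$status, d$ct$age, risk_threshold = 0.5)
  if (!is.null(fit) && fit[["NH"]] > 0) {
    pooled <- labs[part$cell] == "H"
    oracle <- glm(d$ct$status ~ pooled + d$ct$age, family = binomial())
    expect_equal(unname(fit[["beta_H"]]), unname(coef(oracle)[2]),
                 tolerance = 1e-6)
    z <- summary(oracle)$coefficients[2, 3]
    expect_equal(unname(fit[["W_H"]]), z^2, tolerance = 1e-6)
  }
  # all-O labelling is a skipped model
  expect_null(pooled_tests(part, d$ct$status, d$ct$age, risk_threshold = 0))
})

test_that("Wmax is invariant to factor order within a set", {
  d <- make_stratum(400, seed = 21)
  s1 <- mbmdr_scan(d$gm, d$ct, "entire", orders = 2, exposures = "smoking",
                   B_by_order = c("2" = 0), risk_threshold = 0.3)
  p12 <- build_cells(d$gm, d$ct, c("rsA", "rsB"))
  p21 <- build_cells(d$gm, d$ct, c("rsB", "rsA"))
  f12 <- pooled_tests(p12, d$ct$status, d$ct$age, 0.3)
  f21 <- pooled_tests(p21, d$ct$status, d$ct$age, 0.3)
  if (!is.null(f12) && !is.null(f21)) {
    expect_equal(max(f12[["W_H"]], f12[["W_L"]]),
                 max(f21[["W_H"]], f21[["W_L"]]), tolerance = 1e-9)
  }
  if (nrow(s1)) expect_equal(s1$OR_H, exp(s1$beta_H), tolerance = 1e-12)
})

test_that("permutation p-values are seeded, tie-conservative, and admit 0", {
  d <- make_stratum(300, seed = 23)
  s1 <- mbmdr_scan(d$gm, d$ct, "entire", orders = 2, exposures = character(),
                   B_by_order = c("2" = 50), risk_threshold = 0.4, seed = 3)
  s2 <- mbmdr_scan(d$gm, d$ct, "entire", orders = 2, exposures = character(),
                   B_by_order = c("2" = 50), risk_threshold = 0.4, seed = 3)
  expect_identical(s1, s2)
  if (nrow(s1)) {
    expect_true(all(s1$p_perm >= 0 & s1$p_perm <= 1))
    expect_true(all(s1$B_done == 50))
  }
})

test_that("a planted interaction dominates its permutation null", {
  spec <- default_sim_spec(seed = 101, interaction_or = 2.5)
  spec$model$interactions <- spec$model$interactions[1]  # smoking x rs8140505 in F
  spec$n_cases <- 1000; spec$n_controls <- 1000
  coh <- simulate_cohort(spec)
  sel <- coh$ct$sex == "F"
  ct_f <- coh$ct[sel, ]
  part <- build_cells(coh$gm, ct_f, c("rs8140505", "smoking"))
  fit <- pooled_tests(part, ct_f$status, ct_f$age)
  wmax <- max(fit[["W_H"]], fit[["W_L"]])
  set.seed(7)
  wnull <- epistab:::mbmdr_perm_cpp(
    as.integer(part$cell), part$K, as.numeric(ct_f$status),
    as.matrix(as.numeric(ct_f$age)), 200L, 0.05, 10L)
  expect_gt(wmax, quantile(wnull, 0.95))
})
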