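test_that("permutation-p confidence intervals reproduce closed forms", {
  ci <- perm_ci(0.02, 1000)
  expect_equal(ci$high, 0.02 + qnorm(0.975) * sqrt(0.02 * 0.98 / 1000),
               tolerance = 1e-12)
  expect_lt(ci$high, 0.05)                      # retained
  ci2 <- perm_ci(0.04, 100)
  expect_equal(round(ci2$high, 4), 0.0784)
  expect_gt(ci2$high, 0.05)                     # rejected
  ci3 <- perm_ci(0, 100)
  expect_false(ci3$estimable)                   # retained by the 0-rule
  expect_true(perm_ci(0.5, 50)$low <= 0.5 && perm_ci(0.5, 50)$high >= 0.5)
})

fake_models <- function(p, order = 2, stratum = "female",
                        wmax = seq_along(p) + 10, B = 1000,
                        model = paste0("smoking x rs", seq_along(p))) {
  data.frame(model = model, order = order, NH = 1, NL = 1,
             beta_H = 0.4, beta_L = -0.2, W_H = wmax, W_L = 1, Wmax = wmax,
             OR_H = exp(0.4), OR_L = exp(-0.2), p_perm = p, B_done = B,
             stratum = stratum, stringsAsFactors = FALSE)
}

test_that("reliability filter applies the CI rule then grouped FDR", {
  # all p_perm = 0: every model reliable
  m <- reliability_filter(fake_models(rep(0, 4)))
  expect_true(all(m$reliable))
  # single model with p = 0.2 at B = 1000: CI high ~ 0.225, not reliable
  m2 <- reliability_filter(fake_models(0.2))
  expect_false(m2$reliable)
  expect_equal(m2$ci_high_p, 0.2 + qnorm(0.975) * sqrt(0.2 * 0.8 / 1000),
               tolerance = 1e-12)
  # identical p-values in different orders are corrected independently
  m3 <- reliability_filter(rbind(fake_models(c(0.001, 0.002), order = 2),
                                 fake_models(c(0.001, 0.002), order = 3)))
  expect_equal(m3$q[1:2], m3$q[3:4])
  # a reliable model can never carry q >= 0.05
  expect_true(all(m3$q[m3$reliable] < 0.05))
})

test_that("factor recurrence counts reliable models", {
  m <- reliability_filter(fake_models(
    rep(0, 4), model = c("smoking x rs1", "smoking x rs2",
                         "smoking x rs3", "rs2 x rs3")))
  rec <- factor_recurrence(m, "female")
  expect_equal(rec$recurrence[rec$factor == "smoking"], 75)  # 3 of 4
  expect_equal(rec$recurrence[rec$factor == "rs1"], 25)
  expect_false("alcohol" %in% rec$factor)                    # absent = absent
})

test_that("composite scores, priority bands and ties follow the rules", {
  expect_equal(composite_score(54.4, 100), 68.08, tolerance = 1e-9)
  expect_equal(composite_score(0, 0), 0)
  expect_equal(as.character(priority_class(c(86.35, 68.1, 45, 12))),
               c("Highest", "High", "Medium", "Low"))
  # band edges are closed on the left
  expect_equal(as.character(priority_class(c(80, 60, 40))),
               c("Highest", "High", "Medium"))
})

test_that("score_models normalizes Wmax within (stratum, order) and handles
           degenerate groups", {
  m <- reliability_filter(rbind(
    fake_models(rep(0, 3), order = 2, wmax = c(10, 20, 30)),
    fake_models(0, order = 3, wmax = 50,
                model = "smoking x rs9 x rs8")))
  sc <- score_models(m)
  o2 <- sc[sc$order == 2, ]
  expect_equal(sort(o2$Wmax_norm), c(0, 50, 100))
  # single-model order-3 group: degenerate normalization gives 100
  expect_equal(sc$Wmax_norm[sc$order == 3], 100)
  expect_equal(sc$Score, 0.7 * sc$MFS + 0.3 * sc$Wmax_norm, tolerance = 1e-9)
  # Score monotone in Wmax within the group (same MFS)
  same_mfs <- o2[abs(o2$MFS - o2$MFS[1]) < 1e-9, ]
  if (nrow(same_mfs) > 1)
    expect_true(all(diff(same_mfs$Score[order(same_mfs$Wmax)]) > 0))
})

test_that("sensitivity sweep counts are monotone and bounded", {
  m <- reliability_filter(fake_models(rep(0, 5), wmax = c(5, 15, 30, 45, 70)))
  sc <- score_models(m)
  sw <- sensitivity_sweep(sc)
  for (crit in unique(sw$criterion)) {
    cnt <- sw$n_models[sw$criterion == crit]
    expect_true(all(diff(cnt) <= 0))
    expect_lte(max(cnt), nrow(sc))
  }
  # threshold below/above every value
  expect_equal(sum(sc$Score >= 0), nrow(sc))
  expect_equal(sum(sc$Score >= 1000), 0)
})

test_that("the worked-example model table is internally consistent", {
  tab <- example_prioritized_models()
  # pooled log-OR / OR consistency at the printed precision
  expect_equal(round(exp(tab$beta_H), 2), tab$OR_H)
  expect_equal(round(exp(tab$beta_L), 2), tab$OR_L)
  # the composite score reproduces: for the top women's order-2 model
  # (maximal Wmax in its group) Wmax_norm = 100 exactly
  w2 <- tab[tab$stratum == "female" & tab$order == 2, ]
  top <- w2[which.max(w2$Wmax), ]
  expect_equal(round(composite_score(top$MFS, 100), 1), top$Score)
})

test_that("printed women order-2 scores are cross-row consistent once
           min_Wmax is solved from the highest-leverage row", {
  w2 <- example_prioritized_models()
  w2 <- w2[w2$stratum == "female" & w2$order == 2, ]
  mx <- max(w2$Wmax)
  # solve min_Wmax from the row farthest from the max (best leverage)
  i <- which.min(w2$Wmax)
  wn_i <- (w2$Score[i] - 0.7 * w2$MFS[i]) / 0.3
  mn <- (w2$Wmax[i] - wn_i / 100 * mx) / (1 - wn_i / 100)
  pred <- composite_score(w2$MFS, 100 * (w2$Wmax - mn) / (mx - mn))
  expect_lt(max(abs(pred - w2$Score)), 0.15)
})
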