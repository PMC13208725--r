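# Closed-form and Monte-Carlo power for case-control single-variant
# tests and second-order gene-environment interaction tests. The
# analytic forms and the simulation oracle apply the same test, so the
# pair cross-validates itself.

#' Power calculation specification
#'
#' @param n_cases,n_controls group sizes.
#' @param maf minor allele frequency in the population (0, 0.5].
#' @param or_g genotype relative risk per allele (multiplicative
#'   model).
#' @param prevalence disease prevalence K.
#' @param alpha two-sided significance level (after any multiplicity
#'   correction).
#' @param p_exposure exposure prevalence (gene-environment power only).
#' @param or_int interaction odds ratio (gene-environment power only).
#' @param or_e exposure main-effect odds ratio.
#' @return Object of class `power_spec`.
#' @export
power_spec <- function(n_cases, n_controls, maf, or_g = 1,
                       prevalence = 0.01, alpha = 0.05,
                       p_exposure = NULL, or_int = NULL, or_e = 1) {
  stopifnot(maf > 0, maf <= 0.5, prevalence > 0, prevalence < 1,
            alpha > 0, alpha < 1, n_cases > 0, n_controls > 0)
  if (or_g <= 0) stop("odds ratios must be positive")
  structure(list(n_cases = n_cases, n_controls = n_controls, maf = maf,
                 or_g = or_g, prevalence = prevalence, alpha = alpha,
                 p_exposure = p_exposure, or_int = or_int, or_e = or_e),
            class = "power_spec")
}

# expected case/control allele frequencies under a multiplicative model
expected_allele_freqs <- function(maf, or_g, K) {
  q <- maf
  pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  f0 <- K / sum(pg * or_g^(0:2))
  fg <- pmin(f0 * or_g^(0:2), 1)
  p_case <- pg * fg / sum(pg * fg)
  p_ctrl <- pg * (1 - fg) / sum(pg * (1 - fg))
  c(case = (p_case[2] + 2 * p_case[3]) / 2,
    control = (p_ctrl[2] + 2 * p_ctrl[3]) / 2)
}

#' Analytic power for a single-variant allelic test
#'
#' Derives the expected case and control allele frequencies from the
#' per-allele odds ratio and disease prevalence under a multiplicative
#' model, then computes the power of the two-sided Wald test on the
#' allelic log odds ratio using the variance of the expected 2x2
#' allele-count table.
#'
#' @param spec a [power_spec()].
#' @return Power in [alpha, 1]; equals `alpha` at `or_g = 1`.
#' @export
power_single <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  q <- expected_allele_freqs(spec$maf, spec$or_g, spec$prevalence)
  m1 <- 2 * spec$n_cases; m0 <- 2 * spec$n_controls
  lo <- log(q["case"] / (1 - q["case"])) - log(q["control"] / (1 - q["control"]))
  se <- sqrt(1 / (m1 * q["case"]) + 1 / (m1 * (1 - q["case"])) +
             1 / (m0 * q["control"]) + 1 / (m0 * (1 - q["control"])))
  z <- qnorm(1 - spec$alpha / 2)
  unname(pnorm(abs(lo) / se - z) + pnorm(-abs(lo) / se - z))
}

#' Monte-Carlo power oracle for the single-variant allelic test
#'
#' Simulates allele-count tables from the same expected case/control
#' allele frequencies and applies the same Wald test (Haldane +0.5 on
#' zero cells) at level `alpha`.
#'
#' @param spec a [power_spec()].
#' @param n_reps simulation replicates.
#' @param seed RNG seed.
#' @return Empirical rejection rate.
#' @export
power_single_mc <- function(spec, n_reps = 10000, seed = 1) {
  q <- expected_allele_freqs(spec$maf, spec$or_g, spec$prevalence)
  m1 <- 2 * spec$n_cases; m0 <- 2 * spec$n_controls
  set.seed(as.integer(seed))
  a <- rbinom(n_reps, m1, q["case"]);  b <- m1 - a
  c <- rbinom(n_reps, m0, q["control"]); d <- m0 - c
  zero <- pmin(a, b, c, d) == 0
  a <- a + 0.5 * zero; b <- b + 0.5 * zero
  c <- c + 0.5 * zero; d <- d + 0.5 * zero
  lo <- log(a) - log(b) - log(c) + log(d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  mean(abs(lo / se) > qnorm(1 - spec$alpha / 2))
}

# weighted logistic fit over expected/observed cell counts: X (rows =
# cells), events y and trials n per cell. Returns beta and se.
weighted_logit <- function(X, events, trials) {
  beta <- rep(0, ncol(X))
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- trials * mu * (1 - mu)
    w <- pmax(w, 1e-10)
    grad <- drop(t(X) %*% (events - trials * mu))
    H <- t(X) %*% (X * w)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    beta <- beta + step
    if (max(abs(beta)) > 30) return(NULL)
    if (max(abs(step)) < 1e-10) {
      se <- sqrt(diag(solve(H)))
      return(list(beta = beta, se = se))
    }
  }
  NULL
}

# joint (genotype, exposure) distributions in cases and controls under
# a logistic model with allele-dosage G, binary E, and interaction
gxe_cell_probs <- function(spec) {
  q <- spec$maf
  pg <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  pe <- c(1 - spec$p_exposure, spec$p_exposure)
  grid <- expand.grid(g = 0:2, e = 0:1)
  pjoint <- pg[grid$g + 1] * pe[grid$e + 1]
  eta_no_b0 <- log(spec$or_g) * grid$g + log(spec$or_e) * grid$e +
    log(spec$or_int) * grid$g * grid$e
  # solve the intercept so population prevalence matches K
  f <- function(b0) sum(pjoint * stats::plogis(b0 + eta_no_b0)) -
    spec$prevalence
  b0 <- stats::uniroot(f, c(-30, 10))$root
  pen <- stats::plogis(b0 + eta_no_b0)
  list(grid = grid,
       p_case = pjoint * pen / sum(pjoint * pen),
       p_ctrl = pjoint * (1 - pen) / sum(pjoint * (1 - pen)))
}

#' Analytic power for a gene-environment interaction test
#'
#' Wald power for the interaction coefficient in the logistic model
#' `status ~ G + E + G:E` (G = allele dosage, E binary), using the
#' asymptotic information of the expected case/control cell counts
#' under case-control sampling.
#'
#' @param spec a [power_spec()] with `p_exposure` and `or_int` set.
#' @return Power in [alpha, 1].
#' @export
power_gxe <- function(spec) {
  stopifnot(inherits(spec, "power_spec"), !is.null(spec$p_exposure),
            !is.null(spec$or_int), spec$p_exposure > 0, spec$p_exposure < 1)
  pr <- gxe_cell_probs(spec)
  events <- spec$n_cases * pr$p_case
  trials <- events + spec$n_controls * pr$p_ctrl
  X <- cbind(1, pr$grid$g, pr$grid$e, pr$grid$g * pr$grid$e)
  fit <- weighted_logit(X, events, trials)
  if (is.null(fit)) stop("expected-information fit failed")
  z <- qnorm(1 - spec$alpha / 2)
  ncp <- abs(fit$beta[4]) / fit$se[4]
  pnorm(ncp - z) + pnorm(-ncp - z)
}

#' Monte-Carlo power oracle for the gene-environment interaction test
#'
#' Simulates fixed-margin case-control cohorts from the exact joint
#' (genotype, exposure) distributions implied by the logistic disease
#' model, fits `status ~ G + E + G:E` on each, and counts two-sided
#' Wald rejections of the interaction term at level `alpha`.
#'
#' @param spec a [power_spec()] with `p_exposure` and `or_int` set.
#' @param n_reps simulation replicates.
#' @param seed RNG seed.
#' @return Empirical rejection rate (non-converged fits count as
#'   non-rejections).
#' @export
power_gxe_mc <- function(spec, n_reps = 10000, seed = 1) {
  pr <- gxe_cell_probs(spec)
  X <- cbind(1, pr$grid$g, pr$grid$e, pr$grid$g * pr$grid$e)
  z <- qnorm(1 - spec$alpha / 2)
  set.seed(as.integer(seed))
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    ev <- drop(stats::rmultinom(1, spec$n_cases, pr$p_case))
    ct <- drop(stats::rmultinom(1, spec$n_controls, pr$p_ctrl))
    fit <- weighted_logit(X, ev, ev + ct)
    rej[r] <- !is.null(fit) && abs(fit$beta[4] / fit$se[4]) > z
  }
  mean(rej)
}
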