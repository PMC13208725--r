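#' Haplotype pool for one LD block
#'
#' A block is described by its SNPs and the population frequencies of
#' the haplotypes spanning them. Individuals are simulated as two
#' independent haplotype draws, so within-block LD is induced purely by
#' the pool frequencies while genotypes obey Hardy-Weinberg proportions
#' at the implied allele frequencies.
#'
#' @param snp_ids SNP identifiers, in block order.
#' @param haplotypes character vector of allele strings (one character
#'   per SNP, e.g. `"ATT"`).
#' @param freq haplotype frequencies; must be non-negative and are
#'   renormalized to sum to one (an error if they are off by more than
#'   0.01).
#' @param gene gene label for the block.
#' @return An object of class `haplotype_pool` carrying the implied
#'   per-SNP major/minor alleles (minor = lower implied frequency).
#' @export
haplotype_pool <- function(snp_ids, haplotypes, freq, gene = "") {
  stopifnot(length(haplotypes) == length(freq), length(haplotypes) > 0,
            all(nchar(haplotypes) == length(snp_ids)))
  if (any(freq < 0)) stop("haplotype frequencies must be >= 0")
  s <- sum(freq)
  if (abs(s - 1) > 0.01) stop("haplotype frequencies must sum to ~1")
  freq <- freq / s
  alleles <- do.call(rbind, strsplit(haplotypes, ""))
  maj <- min_ <- character(length(snp_ids))
  for (j in seq_along(snp_ids)) {
    af <- tapply(freq, alleles[, j], sum)
    if (length(af) == 1L) {
      # monomorphic in the pool: minor allele is a placeholder
      maj[j] <- names(af); min_[j] <- "."
    } else {
      ord <- order(af, names(af), decreasing = TRUE)
      maj[j] <- names(af)[ord[1]]; min_[j] <- names(af)[ord[2]]
    }
  }
  structure(list(snp_ids = as.character(snp_ids), haplotypes = haplotypes,
                 freq = freq, gene = gene,
                 allele_major = maj, allele_minor = min_),
            class = "haplotype_pool")
}

#' Logistic disease model with planted interaction effects
#'
#' Case status is drawn from
#' `logit P(case) = b0 + sum(dosage * beta_snp) + sum(exposure * beta_env)
#'  + age_coef * (age - 60) + sum(interactions)`,
#' where each interaction term is `log_or * exposure * dosage` (per
#' minor allele), active only in the stated sex (`"M"`, `"F"`, or `NA`
#' for both sexes).
#'
#' @param intercept baseline log-odds of disease in the sampling pool.
#' @param snp_effects named numeric vector of per-allele log odds ratios.
#' @param exposure_effects named numeric vector (`smoking`, `alcohol`).
#' @param age_coef log-OR per year of age (centred at 60).
#' @param interactions list of `list(exposure=, snp=, sex=, log_or=)`.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(intercept = 0, snp_effects = numeric(),
                          exposure_effects = numeric(), age_coef = 0,
                          interactions = list()) {
  co <- c(intercept, snp_effects, exposure_effects, age_coef,
          vapply(interactions, function(x) x$log_or, 0))
  if (!all(is.finite(co))) stop("all coefficients must be finite")
  structure(list(intercept = intercept, snp_effects = snp_effects,
                 exposure_effects = exposure_effects, age_coef = age_coef,
                 interactions = interactions),
            class = "disease_model")
}

#' Simulation specification for a case-control cohort
#'
#' @param n_cases,n_controls target group sizes.
#' @param sex_ratio_cases,sex_ratio_controls probability that an
#'   individual destined for the group is male.
#' @param smoking_prev,alcohol_prev named vectors `c(M=, F=)` of
#'   exposure prevalence by sex.
#' @param pools list of [haplotype_pool()] objects (blocks are
#'   independent of each other).
#' @param model a [disease_model()].
#' @param seed master RNG seed; component streams (genotypes,
#'   exposures, ages, status) are seeded at fixed offsets from it so
#'   adding a component never perturbs the others.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(n_cases, n_controls,
                     sex_ratio_cases = 0.5, sex_ratio_controls = sex_ratio_cases,
                     smoking_prev = c(M = 0.5, F = 0.25),
                     alcohol_prev = c(M = 0.25, F = 0.08),
                     pools, model = disease_model(), seed = 1) {
  stopifnot(n_cases > 0, n_controls > 0,
            all(smoking_prev >= 0 & smoking_prev <= 1),
            all(alcohol_prev >= 0 & alcohol_prev <= 1))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 sex_ratio_cases = sex_ratio_cases,
                 sex_ratio_controls = sex_ratio_controls,
                 smoking_prev = smoking_prev, alcohol_prev = alcohol_prev,
                 pools = pools, model = model, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Default cohort specification
#'
#' Mirrors the structure of a candidate-gene ischemic-stroke panel:
#' 600 cases (330 M / 270 F) and 688 controls (366 M / 322 F); a
#' three-SNP GGT5 block and a two-SNP GGT6 block with common-haplotype
#' frequencies taken from control-group estimates, plus four unlinked
#' GGT1/GGT7 SNPs; sex-specific smoking/alcohol prevalences averaging
#' to 0.38 and 0.17; and two planted sex-specific interactions of
#' odds ratio 2.0 (smoking x rs8140505 in women, regular alcohol x
#' rs5751909 in men).
#'
#' @param seed master RNG seed.
#' @param interaction_or odds ratio of the two planted interactions.
#' @return A [sim_spec()].
#' @export
default_sim_spec <- function(seed = 1, interaction_or = 2.0) {
  pools <- list(
    haplotype_pool(c("rs8140505", "rs2275984", "rs2267073"),
                   c("ATT", "ATC", "ACC", "GTC", "GCC", "ACT", "GTT"),
                   c(0.402, 0.167, 0.135, 0.136, 0.111, 0.033, 0.010),
                   gene = "GGT5"),
    haplotype_pool(c("rs11657054", "rs2100986"),
                   c("AT", "GC", "GT", "AC"),
                   c(0.808, 0.132, 0.047, 0.013), gene = "GGT6"),
    haplotype_pool("rs4820599", c("A", "G"), c(0.80, 0.20), gene = "GGT1"),
    haplotype_pool("rs5760489", c("A", "G"), c(0.70, 0.30), gene = "GGT1"),
    haplotype_pool("rs5751909", c("A", "G"), c(0.83, 0.17), gene = "GGT1"),
    haplotype_pool("rs11546155", c("G", "A"), c(0.80, 0.20), gene = "GGT7"))
  model <- disease_model(
    intercept = -0.25,
    interactions = list(
      list(exposure = "smoking", snp = "rs8140505", sex = "F",
           log_or = log(interaction_or)),
      list(exposure = "alcohol", snp = "rs5751909", sex = "M",
           log_or = log(interaction_or))))
  sim_spec(n_cases = 600, n_controls = 688,
           sex_ratio_cases = 330 / 600, sex_ratio_controls = 366 / 688,
           smoking_prev = c(M = 0.55, F = 0.20),
           alcohol_prev = c(M = 0.26, F = 0.08),
           pools = pools, model = model, seed = seed)
}

pool_snp_info <- function(pools) {
  do.call(rbind, lapply(pools, function(p)
    snp_info(p$snp_ids, gene = rep_len(p$gene, length(p$snp_ids)),
             allele_major = p$allele_major, allele_minor = p$allele_minor)))
}

# dosage draws for one pool: two independent haplotypes per individual
draw_pool_dosages <- function(pool, n) {
  k <- length(pool$snp_ids)
  al <- do.call(rbind, strsplit(pool$haplotypes, ""))
  minor <- matrix(0L, length(pool$haplotypes), k)
  for (j in seq_len(k)) minor[, j] <- as.integer(al[, j] == pool$allele_minor[j])
  h1 <- sample.int(length(pool$freq), n, replace = TRUE, prob = pool$freq)
  h2 <- sample.int(length(pool$freq), n, replace = TRUE, prob = pool$freq)
  minor[h1, , drop = FALSE] + minor[h2, , drop = FALSE]
}

#' Simulate genotypes from a haplotype pool
#'
#' Each individual receives two independent haplotype draws; dosages
#' count copies of the pool's minor allele.
#'
#' @param pool a [haplotype_pool()] (or list of pools for a multi-block
#'   panel).
#' @param n number of individuals.
#' @param seed RNG seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(pool, n, seed = 1) {
  pools <- if (inherits(pool, "haplotype_pool")) list(pool) else pool
  if (!length(pools)) stop("empty pool list")
  set.seed(as.integer(seed))
  dos <- do.call(cbind, lapply(pools, draw_pool_dosages, n = n))
  genotype_matrix(dos, pool_snp_info(pools),
                  individuals = sprintf("ind%05d", seq_len(n)))
}

#' Simulate a case-control cohort with planted effects
#'
#' Generates candidate individuals (genotypes from the haplotype pools,
#' sex and exposures from the sex-specific prevalences, age from
#' Normal(61, 9) truncated to 40-90), draws case status from the
#' logistic disease model, and fills the case and control groups by
#' rejection sampling until both reach their target sizes (fixed-margin
#' case-control design). Each component uses its own RNG stream seeded
#' at a fixed offset from the master seed.
#'
#' @param spec a [sim_spec()].
#' @param max_batches bound on rejection-sampling rounds before
#'   declaring the case fraction unreachable.
#' @return A list with `gm` ([genotype_matrix()]), `ct` (cohort table),
#'   and `truth` (data frame of planted effects for recovery tests).
#' @export
simulate_cohort <- function(spec, max_batches = 200) {
  stopifnot(inherits(spec, "sim_spec"))
  info <- pool_snp_info(spec$pools)
  m <- spec$model
  batch <- max(1000L, spec$n_cases + spec$n_controls)
  cases_gm <- controls_gm <- NULL
  cases_ct <- controls_ct <- NULL
  n_done <- 0L
  for (b in seq_len(max_batches)) {
    need_cases <- spec$n_cases - (if (is.null(cases_ct)) 0L else nrow(cases_ct))
    need_controls <- spec$n_controls -
      (if (is.null(controls_ct)) 0L else nrow(controls_ct))
    if (need_cases <= 0L && need_controls <= 0L) break
    # the sampling pool is a mixture of the two sex compositions
    p_male <- mean(c(spec$sex_ratio_cases, spec$sex_ratio_controls))
    set.seed(spec$seed + 7L * b + 1L)
    dos <- do.call(cbind, lapply(spec$pools, draw_pool_dosages, n = batch))
    colnames(dos) <- info$snp_id
    set.seed(spec$seed + 7L * b + 2L)
    sex <- ifelse(runif(batch) < p_male, "M", "F")
    smoking <- rbinom(batch, 1L, spec$smoking_prev[sex])
    alcohol <- rbinom(batch, 1L, spec$alcohol_prev[sex])
    set.seed(spec$seed + 7L * b + 3L)
    age <- round(pmin(pmax(rnorm(batch, 61, 9), 40), 90), 1)
    eta <- rep(m$intercept, batch)
    for (s in names(m$snp_effects)) eta <- eta + m$snp_effects[[s]] * dos[, s]
    env <- cbind(smoking = smoking, alcohol = alcohol)
    for (e in names(m$exposure_effects))
      eta <- eta + m$exposure_effects[[e]] * env[, e]
    eta <- eta + m$age_coef * (age - 60)
    for (ia in m$interactions) {
      sel <- if (is.null(ia$sex) || is.na(ia$sex)) rep(TRUE, batch)
             else sex == ia$sex
      eta <- eta + ia$log_or * env[, ia$exposure] * dos[, ia$snp] * sel
    }
    set.seed(spec$seed + 7L * b + 4L)
    status <- rbinom(batch, 1L, stats::plogis(eta))
    take_case <- which(status == 1L)[seq_len(min(need_cases, sum(status == 1L)))]
    take_ctrl <- which(status == 0L)[seq_len(min(need_controls,
                                                 sum(status == 0L)))]
    add <- function(store, idx) rbind(store, cbind(dos[idx, , drop = FALSE]))
    cases_gm <- add(cases_gm, take_case)
    controls_gm <- add(controls_gm, take_ctrl)
    mk_ct <- function(idx, st) data.frame(
      status = rep(st, length(idx)), sex = sex[idx], age = age[idx],
      smoking = smoking[idx], alcohol = alcohol[idx],
      stringsAsFactors = FALSE)
    cases_ct <- rbind(cases_ct, mk_ct(take_case, 1L))
    controls_ct <- rbind(controls_ct, mk_ct(take_ctrl, 0L))
    n_done <- b
  }
  if (nrow(cases_ct) < spec$n_cases || nrow(controls_ct) < spec$n_controls)
    stop("target case/control counts unreachable after ", n_done,
         " batches; check the disease-model intercept")
  dos <- rbind(cases_gm, controls_gm)
  ct <- rbind(cases_ct, controls_ct)
  ids <- sprintf("ind%05d", seq_len(nrow(ct)))
  ct <- cbind(id = ids, ct, stringsAsFactors = FALSE)
  rownames(ct) <- NULL
  truth <- do.call(rbind, lapply(m$interactions, function(ia)
    data.frame(term = paste(ia$exposure, ia$snp, sep = ":"),
               type = "interaction",
               sex = if (is.null(ia$sex)) NA_character_ else ia$sex,
               log_or = ia$log_or, or = exp(ia$log_or),
               stringsAsFactors = FALSE)))
  if (is.null(truth))
    truth <- data.frame(term = character(), type = character(),
                        sex = character(), log_or = numeric(), or = numeric())
  list(gm = genotype_matrix(dos, info, ids), ct = ct, truth = truth)
}

#' Read a simulation specification from a YAML config
#'
#' The config mirrors the [sim_spec()] fields; blocks are given as
#' `pools: [{snp_ids: [...], haplotypes: [...], freq: [...], gene: x}]`
#' and interactions as `{exposure:, snp:, sex:, or:}`.
#'
#' @param path YAML file path.
#' @return A [sim_spec()].
#' @export
read_sim_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  pools <- lapply(cfg$pools, function(p)
    haplotype_pool(unlist(p$snp_ids), unlist(p$haplotypes),
                   as.numeric(unlist(p$freq)),
                   gene = if (is.null(p$gene)) "" else p$gene))
  inter <- lapply(cfg$model$interactions, function(ia)
    list(exposure = ia$exposure, snp = ia$snp,
         sex = if (is.null(ia$sex)) NA_character_ else ia$sex,
         log_or = log(ia$or)))
  model <- disease_model(
    intercept = cfg$model$intercept %||% 0,
    snp_effects = unlist(cfg$model$snp_effects) %||% numeric(),
    exposure_effects = unlist(cfg$model$exposure_effects) %||% numeric(),
    age_coef = cfg$model$age_coef %||% 0,
    interactions = inter)
  sim_spec(n_cases = cfg$n_cases, n_controls = cfg$n_controls,
           sex_ratio_cases = cfg$sex_ratio_cases %||% 0.5,
           sex_ratio_controls = cfg$sex_ratio_controls %||%
             (cfg$sex_ratio_cases %||% 0.5),
           smoking_prev = unlist(cfg$smoking_prev) %||% c(M = 0.5, F = 0.25),
           alcohol_prev = unlist(cfg$alcohol_prev) %||% c(M = 0.25, F = 0.08),
           pools = pools, model = model, seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
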