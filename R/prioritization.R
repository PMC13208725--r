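# Stability-and-prioritization layer over MB-MDR output: permutation
# confidence-interval filtering, per-(stratum, order) FDR, factor
# recurrence, Mean Factor Stability, normalized Wmax, weighted
# composite score, priority classes, and sensitivity sweeps.

#' Normal-approximation confidence interval for a permutation p-value
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / B)`, clipped to [0, 1]. The
#' interval is non-estimable when `p_hat` is exactly 0 or 1 (zero
#' variance).
#'
#' @param p_hat empirical permutation p-value.
#' @param B number of permutations behind it.
#' @param level interval level.
#' @return List with `low`, `high`, `estimable`.
#' @export
perm_ci <- function(p_hat, B, level = 0.95) {
  stopifnot(p_hat >= 0, p_hat <= 1, B >= 1)
  if (p_hat %in% c(0, 1))
    return(list(low = NA_real_, high = NA_real_, estimable = FALSE))
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p_hat * (1 - p_hat) / B)
  list(low = max(0, p_hat - half), high = min(1, p_hat + half),
       estimable = TRUE)
}

#' Reliability filter: permutation-CI rule plus grouped FDR
#'
#' A model passes the CI rule when the upper confidence bound of its
#' permutation p-value is below `alpha`, or when `p_perm = 0` with a
#' non-estimable interval. BH-FDR is then applied separately within
#' each (stratum, interaction order) group over the CI-passing models;
#' a model is reliable when it passes the CI rule and has `q < alpha`.
#'
#' @param models data frame from [mbmdr_scan()] (needs `p_perm`,
#'   `B_done`, `stratum`, `order`).
#' @param level CI level.
#' @param alpha retention / FDR threshold.
#' @return The input with `ci_low_p`, `ci_high_p`, `ci_pass`, `q`,
#'   `reliable` columns appended.
#' @export
reliability_filter <- function(models, level = 0.95, alpha = 0.05) {
  n <- nrow(models)
  ci_lo <- ci_hi <- rep(NA_real_, n)
  pass <- logical(n)
  for (i in seq_len(n)) {
    ci <- perm_ci(models$p_perm[i], models$B_done[i], level)
    ci_lo[i] <- ci$low; ci_hi[i] <- ci$high
    pass[i] <- if (ci$estimable) ci$high < alpha else models$p_perm[i] == 0
  }
  models$ci_low_p <- ci_lo
  models$ci_high_p <- ci_hi
  models$ci_pass <- pass
  models$q <- NA_real_
  grp <- interaction(models$stratum, models$order, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g & pass)
    if (length(idx))
      models$q[idx] <- bh_fdr(pmax(models$p_perm[idx],
                                   1 / (models$B_done[idx] + 1)))
  }
  models$reliable <- pass & !is.na(models$q) & models$q < alpha
  models
}

model_factors <- function(model) strsplit(model, " x ", fixed = TRUE)

#' Factor recurrence across reliable models
#'
#' Percentage of a stratum's reliable models (pooled across interaction
#' orders) that contain each factor.
#'
#' @param models output of [reliability_filter()].
#' @param stratum stratum label to summarize.
#' @return Data frame `factor`, `recurrence` (percent).
#' @export
factor_recurrence <- function(models, stratum = unique(models$stratum)) {
  rel <- models[models$reliable & models$stratum %in% stratum, , drop = FALSE]
  if (!nrow(rel)) stop("no reliable models in stratum")
  fl <- model_factors(rel$model)
  all_f <- sort(unique(unlist(fl)))
  rec <- vapply(all_f, function(f)
    100 * mean(vapply(fl, function(s) f %in% s, TRUE)), 0)
  data.frame(factor = all_f, recurrence = unname(rec),
             stringsAsFactors = FALSE)
}

#' Weighted composite score
#'
#' `Score = w_mfs * MFS + w_wmax * Wmax_norm` on the 0-100 scale.
#'
#' @param mfs Mean Factor Stability (percent).
#' @param wmax_norm min-max normalized Wmax (0-100).
#' @param w_mfs,w_wmax weights (must sum to 1).
#' @return Numeric score.
#' @export
composite_score <- function(mfs, wmax_norm, w_mfs = 0.7, w_wmax = 0.3) {
  stopifnot(abs(w_mfs + w_wmax - 1) < 1e-9)
  w_mfs * mfs + w_wmax * wmax_norm
}

#' Priority class from a composite score
#'
#' Bands closed on the left: Highest `[80, Inf)`, High `[60, 80)`,
#' Medium `[40, 60)`, Low `(-Inf, 40)`.
#'
#' @param score numeric scores.
#' @return Factor with levels Highest > High > Medium > Low.
#' @export
priority_class <- function(score) {
  cut(score, breaks = c(-Inf, 40, 60, 80, Inf), right = FALSE,
      labels = c("Low", "Medium", "High", "Highest"))
}

#' Score and prioritize reliable models
#'
#' For each reliable model: MFS = mean recurrence of its constituent
#' factors (recurrence computed per stratum across all reliable
#' models); `Wmax_norm = 100 (Wmax - min) / (max - min)` with the
#' min/max taken within the model's (stratum, order) normalization
#' group (a degenerate group with max = min gets 100 for all members);
#' `Score = 0.7 MFS + 0.3 Wmax_norm`; priority by [priority_class()].
#' Rows are ordered by (stratum, Score desc, Wmax desc, model id).
#'
#' @param models output of [reliability_filter()] (only reliable rows
#'   are scored).
#' @param recurrence optional precomputed recurrence table per stratum
#'   (list keyed by stratum) overriding the internal computation.
#' @param w_mfs,w_wmax composite-score weights.
#' @return Data frame of reliable models with `MFS`, `Wmax_norm`,
#'   `Score`, `priority` appended.
#' @export
score_models <- function(models, recurrence = NULL, w_mfs = 0.7,
                         w_wmax = 0.3) {
  rel <- models[models$reliable, , drop = FALSE]
  if (!nrow(rel)) stop("no reliable models to score")
  rel$MFS <- NA_real_
  for (s in unique(rel$stratum)) {
    rec <- if (!is.null(recurrence)) recurrence[[s]]
           else factor_recurrence(models, s)
    idx <- which(rel$stratum == s)
    fl <- model_factors(rel$model[idx])
    rel$MFS[idx] <- vapply(fl, function(f)
      mean(rec$recurrence[match(f, rec$factor)]), 0)
  }
  rel$Wmax_norm <- NA_real_
  grp <- interaction(rel$stratum, rel$order, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    w <- rel$Wmax[idx]
    rng <- range(w)
    rel$Wmax_norm[idx] <- if (diff(rng) < 1e-12) 100
      else 100 * (w - rng[1]) / (rng[2] - rng[1])
  }
  rel$Score <- composite_score(rel$MFS, rel$Wmax_norm, w_mfs, w_wmax)
  rel$priority <- priority_class(rel$Score)
  rel[order(rel$stratum, -rel$Score, -rel$Wmax, rel$model), , drop = FALSE]
}

#' Sensitivity sweep over stability thresholds
#'
#' Counts how many scored models survive increasingly stringent
#' thresholds on MFS, Wmax and the composite score. Counts are
#' non-increasing along each sweep.
#'
#' @param scored output of [score_models()].
#' @param mfs_thresholds,wmax_thresholds,score_thresholds sweep grids.
#' @return Data frame `criterion`, `threshold`, `n_models`.
#' @export
sensitivity_sweep <- function(scored,
                              mfs_thresholds = seq(30, 70, 10),
                              wmax_thresholds = seq(20, 60, 10),
                              score_thresholds = seq(20, 80, 10)) {
  sweep1 <- function(crit, thresholds, values)
    data.frame(criterion = crit, threshold = thresholds,
               n_models = vapply(thresholds,
                                 function(t) sum(values >= t), 0L),
               stringsAsFactors = FALSE)
  rbind(sweep1("MFS", mfs_thresholds, scored$MFS),
        sweep1("Wmax", wmax_thresholds, scored$Wmax),
        sweep1("Score", score_thresholds, scored$Score))
}

#' Worked-example table of prioritized interaction models
#'
#' Loads the packaged worked example: the top prioritized MB-MDR
#' models (men and women strata) from a sex-stratified case-control
#' ischemic-stroke study of GGT-family variants, with their pooled
#' coefficients, Wald statistics, MFS and composite scores. Used by
#' examples and internal-consistency checks.
#'
#' @return Data frame mirroring the columns of [score_models()] output.
#' @export
example_prioritized_models <- function() {
  path <- system.file("extdata", "prioritized_models_example.tsv",
                      package = "epistab")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
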