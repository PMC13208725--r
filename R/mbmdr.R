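# Model-Based Multifactor Dimensionality Reduction for binary traits.
# Cells are multilocus genotype / exposure combinations; each cell is
# tested against the rest of the stratum by covariate-adjusted logistic
# regression and labelled high-risk (H), low-risk (L) or no-evidence
# (O); the pooled H and L groups are then tested with Wald statistics,
# and Wmax = max(W_H, W_L) is permuted to obtain an empirical p-value.

#' Build the cell partition for a factor set
#'
#' @param gm a [genotype_matrix()].
#' @param ct cohort table (rows = the analysis stratum).
#' @param factors character vector of 2-4 distinct SNP ids and/or
#'   exposure names (`"smoking"`, `"alcohol"`).
#' @return List of class `cell_partition`: `cell` (1-based cell index
#'   per individual, empty cells dropped), `K`, `key` (factor-level
#'   combination per cell), `n` (per-cell sizes), `factors`.
#' @export
build_cells <- function(gm, ct, factors) {
  if (anyDuplicated(factors)) stop("duplicate factors")
  if (!length(factors) %in% 2:4) stop("interaction order must be 2-4")
  cols <- lapply(factors, function(f) {
    if (f %in% colnames(gm)) unclass(gm)[ct$id, f]
    else if (f %in% names(ct)) ct[[f]]
    else stop("unknown factor: ", f)
  })
  if (any(vapply(cols, anyNA, TRUE))) {
    keep <- complete.cases(do.call(cbind, cols))
  } else keep <- rep(TRUE, nrow(ct))
  key_str <- do.call(paste, c(lapply(cols, function(x) x[keep]), sep = ":"))
  lev <- sort(unique(key_str))
  cell <- match(key_str, lev)
  structure(list(cell = cell, K = length(lev), key = lev,
                 n = tabulate(cell, length(lev)), factors = factors,
                 keep = keep),
            class = "cell_partition")
}

#' Classify cells as high-risk, low-risk, or no evidence
#'
#' Per cell `j` a logistic model `status ~ 1{cell == j} + covariates`
#' is fitted on the whole stratum; the cell is H when the indicator's
#' Wald p is below `risk_threshold` with a positive coefficient, L when
#' below the threshold with a negative coefficient, otherwise O. Cells
#' smaller than `min_cell`, and cells whose fit fails to converge
#' (separation), are O.
#'
#' @param part a [build_cells()] partition.
#' @param status 0/1 vector for the stratum.
#' @param age numeric covariate (or `NULL` for no adjustment).
#' @param risk_threshold per-cell significance level.
#' @param min_cell minimum cell size eligible for H/L.
#' @return Character vector of labels (`"H"`, `"L"`, `"O"`) per cell.
#' @export
classify_cells <- function(part, status, age = NULL, risk_threshold = 0.05,
                           min_cell = 10) {
  fit <- mbmdr_fit_core(part, status, age, risk_threshold, min_cell)
  c("L", "O", "H")[attr(fit, "labels") + 2L]
}

#' Pooled high/low-risk Wald tests
#'
#' Fits `status ~ 1{H-pooled} + covariates` (and the analogous L fit)
#' and reports the pooled coefficients and Wald statistics
#' `W = (beta/se)^2`. A missing category (NH = 0 or NL = 0) gives
#' W = 0 with an undefined beta.
#'
#' @inheritParams classify_cells
#' @return Named vector `(beta_H, W_H, beta_L, W_L, NH, NL)` with a
#'   `labels` attribute; `NULL` (skipped model) when NH = NL = 0.
#' @export
pooled_tests <- function(part, status, age = NULL, risk_threshold = 0.05,
                         min_cell = 10) {
  fit <- mbmdr_fit_core(part, status, age, risk_threshold, min_cell)
  if (fit[["NH"]] == 0 && fit[["NL"]] == 0) return(NULL)
  fit
}

mbmdr_fit_core <- function(part, status, age, risk_threshold, min_cell) {
  stopifnot(inherits(part, "cell_partition"))
  y <- as.numeric(status[part$keep])
  covar <- if (is.null(age)) matrix(0, length(y), 0)
           else as.matrix(as.numeric(age[part$keep]))
  mbmdr_fit_cpp(as.integer(part$cell), part$K, y, covar,
                risk_threshold, as.integer(min_cell))
}

enumerate_factor_sets <- function(snps, exposures, order,
                                  include_env_only = FALSE) {
  all_f <- c(snps, exposures)
  if (order > length(all_f)) return(list())
  sets <- utils::combn(all_f, order, simplify = FALSE)
  if (!include_env_only && length(exposures))
    sets <- Filter(function(s) any(s %in% snps), sets)
  sets
}

#' MB-MDR interaction scan over a stratum
#'
#' Enumerates all factor sets of the requested orders drawn from the
#' SNP panel and the binary exposures (mixed gene-environment sets
#' allowed; purely environmental sets excluded by default), evaluates
#' each with [build_cells()] + pooled Wald tests, and attaches an
#' empirical permutation p-value `p_perm = R/B`, where `R` counts
#' permutations whose Wmax is at least the observed one (ties counted;
#' 0 is an admissible value). Permutations shuffle the status vector
#' only, keeping the factor-covariate pairing intact. Age enters every
#' fit as a linear covariate.
#'
#' @param gm a [genotype_matrix()].
#' @param ct cohort table.
#' @param stratum `"entire"`, `"male"` or `"female"`.
#' @param orders interaction orders to scan (subset of 2:4).
#' @param exposures exposure columns of `ct` to include as factors.
#' @param B_by_order named permutation budgets, e.g.
#'   `c("2" = 1000, "3" = 500, "4" = 100)`.
#' @param risk_threshold per-cell significance level for H/L calls.
#' @param min_cell minimum cell size eligible for H/L.
#' @param seed RNG seed (per-model streams derived deterministically).
#' @param adjust_age adjust all fits for age.
#' @param include_env_only allow purely environmental factor sets.
#' @return Data frame with one row per evaluated model: `model`
#'   (factor ids joined by " x "), `order`, `NH`, `NL`, `beta_H`,
#'   `beta_L`, `W_H`, `W_L`, `Wmax`, `OR_H`, `OR_L`, `p_perm`,
#'   `B_done`, `stratum`. Models with no H and no L cell are skipped.
#' @export
mbmdr_scan <- function(gm, ct, stratum = "entire", orders = 2:4,
                       exposures = c("smoking", "alcohol"),
                       B_by_order = c("2" = 1000, "3" = 500, "4" = 100),
                       risk_threshold = 0.05, min_cell = 10, seed = 1,
                       adjust_age = TRUE, include_env_only = FALSE) {
  sel <- stratum_selector(ct, stratum)
  cts <- ct[sel, , drop = FALSE]
  if (!nrow(cts)) stop("empty stratum")
  exposures <- intersect(exposures, names(cts))
  age <- if (adjust_age) cts$age else NULL
  rows <- list()
  midx <- 0L
  for (ord in sort(orders)) {
    sets <- enumerate_factor_sets(colnames(gm), exposures, ord,
                                  include_env_only)
    B <- unname(B_by_order[as.character(ord)])
    if (is.na(B)) B <- 100
    for (fs in sets) {
      midx <- midx + 1L
      part <- build_cells(gm, cts, fs)
      fit <- tryCatch(
        pooled_tests(part, cts$status, age, risk_threshold, min_cell),
        error = function(e) NULL)
      if (is.null(fit)) next
      wmax <- max(fit[["W_H"]], fit[["W_L"]])
      p_perm <- NA_real_; b_done <- 0L
      if (B > 0) {
        y <- as.numeric(cts$status[part$keep])
        covar <- if (is.null(age)) matrix(0, length(y), 0)
                 else as.matrix(as.numeric(age[part$keep]))
        set.seed(as.integer(seed) + 131L * midx)
        wperm <- mbmdr_perm_cpp(as.integer(part$cell), part$K, y, covar,
                                as.integer(B), risk_threshold,
                                as.integer(min_cell))
        p_perm <- sum(wperm >= wmax) / B
        b_done <- B
      }
      rows[[length(rows) + 1]] <- data.frame(
        model = paste(fs, collapse = " x "), order = ord,
        NH = fit[["NH"]], NL = fit[["NL"]],
        beta_H = fit[["beta_H"]], beta_L = fit[["beta_L"]],
        W_H = fit[["W_H"]], W_L = fit[["W_L"]], Wmax = wmax,
        OR_H = exp(fit[["beta_H"]]), OR_L = exp(fit[["beta_L"]]),
        p_perm = p_perm, B_done = b_done, stratum = stratum,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out
}
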