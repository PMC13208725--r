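# Nine-stage analysis pipeline: power calculation; single-variant,
# haplotype and diplotype analyses; formal predictor x sex interaction;
# replication (placeholder, external data); MB-MDR; reliability
# filtering with factor recurrence and prioritization; annotation
# (placeholder, external databases); and a summary manifest. Stages
# write tab-separated tables into the output directory and the run is
# idempotent given an identical config and seed.

pipeline_stage_names <- c("power", "single_variant", "haplotype",
                          "diplotype", "sex_interaction", "replication",
                          "mbmdr", "prioritization", "annotation")

#' Assemble a pipeline configuration
#'
#' @param out_dir output directory (created if missing).
#' @param sim a [sim_spec()] for a self-contained synthetic run, or
#'   `NULL` when `genotypes`/`phenotypes` paths are given.
#' @param genotypes,phenotypes input file paths (delimited formats of
#'   the core readers); ignored when `sim` is given.
#' @param strata strata to analyse.
#' @param stages stage subset to run (dependencies are checked).
#' @param blocks named list of SNP-id vectors defining haplotype
#'   blocks (2-3 SNPs each).
#' @param perms permutations for single-variant and haplotype tests.
#' @param mbmdr_B_by_order permutation budgets per interaction order.
#' @param orders MB-MDR interaction orders.
#' @param risk_threshold MB-MDR per-cell significance level.
#' @param fdr_alpha reliability threshold.
#' @param score_weights `c(mfs, wmax)` composite-score weights
#'   (must sum to 1).
#' @param seed master seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, genotypes = NULL,
                            phenotypes = NULL,
                            strata = c("entire", "male", "female"),
                            stages = pipeline_stage_names,
                            blocks = NULL, perms = 200,
                            mbmdr_B_by_order = c("2" = 200, "3" = 100,
                                                 "4" = 50),
                            orders = 2:3, risk_threshold = 0.05,
                            fdr_alpha = 0.05, score_weights = c(0.7, 0.3),
                            seed = 1) {
  if (abs(sum(score_weights) - 1) > 1e-9)
    stop("score weights must sum to 1")
  if (is.null(sim) && (is.null(genotypes) || is.null(phenotypes)))
    stop("either a sim spec or genotype+phenotype paths are required")
  if (!is.null(genotypes) && !file.exists(genotypes))
    stop("genotype file not found: ", genotypes)
  if (!is.null(sim) && !inherits(sim, "sim_spec"))
    stop("sim must be a sim_spec")
  unknown <- setdiff(stages, pipeline_stage_names)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ","))
  structure(list(out_dir = out_dir, sim = sim, genotypes = genotypes,
                 phenotypes = phenotypes, strata = strata, stages = stages,
                 blocks = blocks, perms = perms,
                 mbmdr_B_by_order = mbmdr_B_by_order, orders = orders,
                 risk_threshold = risk_threshold, fdr_alpha = fdr_alpha,
                 score_weights = score_weights, seed = as.integer(seed)),
            class = "pipeline_config")
}

stratum_seed <- function(seed, stratum, offset = 0L) {
  seed + offset + 1000L * match(stratum, c("entire", "male", "female"))
}

#' Run the nine-stage pipeline
#'
#' Executes the configured stages in order, writing one TSV per stage
#' and a `manifest.yaml` recording the package version, seed,
#' thresholds and stage status. The replication and annotation stages
#' are explicit no-op placeholders (they require external cohorts and
#' databases) so the manifest mirrors the full nine-stage flow. A
#' stage failure aborts with the stage name; running `prioritization`
#' without `mbmdr` is a dependency error.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the per-stage result tables and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if ("prioritization" %in% config$stages && !"mbmdr" %in% config$stages)
    stop("stage dependency error: prioritization requires mbmdr")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  status <- setNames(rep("skipped", length(pipeline_stage_names)),
                     pipeline_stage_names)

  # inputs
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    gm <- cohort$gm; ct <- cohort$ct
    write_result_table(cohort$truth, file.path(config$out_dir, "truth.tsv"))
  } else {
    gm <- read_genotypes(config$genotypes, format = "delimited")
    ct <- read_phenotypes(config$phenotypes)
    fc <- filter_complete_cases(gm, ct)
    gm <- fc$gm; ct <- fc$ct
  }

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    status[[name]] <<- "ok"
    results[[name]] <<- res
    invisible(res)
  }

  run_stage("power", function() {
    mafs <- colMeans(unclass(gm)[ct$id[ct$status == 0], , drop = FALSE]) / 2
    tab <- do.call(rbind, lapply(seq_along(mafs), function(j)
      data.frame(snp_id = colnames(gm)[j], maf = round(mafs[j], 3),
                 or = 1.5,
                 power = power_single(power_spec(
                   sum(ct$status == 1), sum(ct$status == 0),
                   maf = max(min(mafs[j], 0.5), 0.01), or_g = 1.5,
                   alpha = 0.05 / ncol(gm))))))
    write_result_table(tab, file.path(config$out_dir, "power.tsv"))
    tab
  })

  run_stage("single_variant", function() {
    tab <- do.call(rbind, lapply(config$strata, function(s)
      assoc_table(gm, ct, s, B = config$perms,
                  seed = stratum_seed(config$seed, s, 10L))))
    write_result_table(tab, file.path(config$out_dir, "single_variant.tsv"))
    tab
  })

  run_stage("haplotype", function() {
    blocks <- config$blocks
    if (is.null(blocks)) {
      info <- snps_of(gm)
      blocks <- split(info$snp_id, info$gene)
      blocks <- Filter(function(b) length(b) %in% 2:3, blocks)
    }
    if (!length(blocks)) return(data.frame())
    tab <- do.call(rbind, lapply(names(blocks), function(bn) {
      do.call(rbind, lapply(config$strata, function(s) {
        sel <- stratum_selector(ct, s)
        res <- haplotype_assoc(gm[ct$id[sel], , drop = FALSE],
                               ct$status[sel], blocks[[bn]],
                               B = config$perms,
                               seed = stratum_seed(config$seed, s, 20L))
        cbind(block = bn, stratum = s, res, stringsAsFactors = FALSE)
      }))
    }))
    write_result_table(tab, file.path(config$out_dir, "haplotype.tsv"))
    tab
  })

  run_stage("diplotype", function() {
    tab <- do.call(rbind, lapply(config$strata, function(s)
      diplotype_scan(gm, ct, s)))
    write_result_table(tab, file.path(config$out_dir, "diplotype.tsv"))
    tab
  })

  run_stage("sex_interaction", function() {
    tab <- sex_interaction_scan(gm, ct)
    write_result_table(tab, file.path(config$out_dir, "sex_interaction.tsv"))
    tab
  })

  run_stage("replication", function() {
    # placeholder: replication requires external cohort summary data
    data.frame(stage = "replication", note = "external data; not run")
  })

  run_stage("mbmdr", function() {
    tab <- do.call(rbind, lapply(config$strata, function(s)
      mbmdr_scan(gm, ct, s, orders = config$orders,
                 B_by_order = config$mbmdr_B_by_order,
                 risk_threshold = config$risk_threshold,
                 seed = stratum_seed(config$seed, s, 30L))))
    write_result_table(tab, file.path(config$out_dir, "mbmdr.tsv"))
    tab
  })

  run_stage("prioritization", function() {
    rel <- reliability_filter(results$mbmdr, alpha = config$fdr_alpha)
    write_result_table(rel, file.path(config$out_dir, "reliability.tsv"))
    if (!any(rel$reliable)) return(rel)
    scored <- score_models(rel, w_mfs = config$score_weights[1],
                           w_wmax = config$score_weights[2])
    write_result_table(scored, file.path(config$out_dir, "prioritized.tsv"))
    sweep <- sensitivity_sweep(scored)
    write_result_table(sweep, file.path(config$out_dir, "sensitivity.tsv"))
    rec <- do.call(rbind, lapply(unique(scored$stratum), function(s)
      cbind(stratum = s, factor_recurrence(rel, s),
            stringsAsFactors = FALSE)))
    write_result_table(rec, file.path(config$out_dir, "recurrence.tsv"))
    scored
  })

  run_stage("annotation", function() {
    # placeholder: functional annotation requires external databases
    data.frame(stage = "annotation", note = "external data; not run")
  })

  manifest <- list(
    package = "epistab",
    version = as.character(utils::packageVersion("epistab")),
    seed = config$seed, strata = config$strata,
    stages = as.list(status[config$stages]),
    thresholds = list(risk_threshold = config$risk_threshold,
                      fdr_alpha = config$fdr_alpha,
                      score_weights = config$score_weights),
    n_individuals = nrow(ct), n_snps = ncol(gm))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(list(results = results, manifest = manifest))
}
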