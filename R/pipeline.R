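#' Pipeline configuration
#'
#' Settings for [run_pipeline()]: where the cohort comes from (an in-memory
#' cohort, a file, or synthetic generation), which SNPs and covariates are
#' analysed, multiple-testing control, optional subset-ensemble settings, and
#' output location.
#'
#' @param cohort Optional `oag_cohort` data frame (takes precedence).
#' @param cohort_path Optional cohort file path.
#' @param dialect Cohort file dialect, `"tsv"` or `"plink_raw"`.
#' @param params [cohort_params()] used when the cohort is generated (and for
#'   SNP metadata in reports).
#' @param mode Generation mode when simulating (see [generate_cohort()]).
#' @param snp_ids SNPs to test (default: all in the panel).
#' @param joint_snp_ids SNPs entering the joint multivariate model (default:
#'   the three modelled loci).
#' @param covariates Adjustment covariates.
#' @param family_alpha Family-wise error rate for Bonferroni control.
#' @param n_snps_tested Number of tests the Bonferroni correction accounts
#'   for.
#' @param run_nn Run the subset-ensemble ranking stage?
#' @param nn Named list of [run_ensemble()] settings (`reps`, `age_matched`,
#'   `tolerance_years`, `subset_cap`, `panel`, training knobs).
#' @param seed Seed used for cohort generation and the ensemble master seed.
#' @param output_dir Directory for report files (created if needed); `NULL`
#'   skips writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = NULL, cohort_path = NULL,
                            dialect = "tsv", params = cohort_params(),
                            mode = "prospective",
                            snp_ids = NULL,
                            joint_snp_ids = c("rs4656461", "rs1412829",
                                              "rs10483727"),
                            covariates = oag_clinical_covariates(),
                            family_alpha = 0.05, n_snps_tested = 7,
                            run_nn = FALSE, nn = list(),
                            seed = 1, output_dir = NULL) {
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("`family_alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(cohort = cohort, cohort_path = cohort_path,
                 dialect = dialect, params = params, mode = mode,
                 snp_ids = snp_ids, joint_snp_ids = joint_snp_ids,
                 covariates = covariates, family_alpha = family_alpha,
                 n_snps_tested = n_snps_tested, run_nn = run_nn, nn = nn,
                 seed = seed, output_dir = output_dir),
            class = "pipeline_config")
}

fmt_num <- function(x, digits) formatC(x, digits = digits, format = "f")

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (load or simulate), baseline
#' characteristics comparison, per-SNP univariate allelic and
#' covariate-adjusted additive tests with Bonferroni flagging, the joint
#' multivariate model with collinearity diagnostics, and (optionally) the
#' exhaustive-subset ensemble ranking. When `output_dir` is set, each stage
#' writes a report table (rounded display precision: odds ratios 2 dp,
#' frequencies 3 dp, p-values 3 dp), a full-precision machine-readable JSON
#' results file, and a manifest recording seeds and settings. A stage error
#' aborts the run naming the stage; reports already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `cohort`, `baseline`,
#'   `snp_association`, `joint`, `vif`, `bonferroni_alpha`, `importance`
#'   (or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  files <- character(0)
  emit <- function(df, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    files[[length(files) + 1]] <<- name
  }

  cohort <- run_stage("cohort", {
    if (!is.null(config$cohort)) {
      config$cohort
    } else if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path, config$dialect,
                  config$params$snp_info)
    } else {
      generate_cohort(config$params, seed = config$seed, mode = config$mode)
    }
  })

  baseline <- run_stage("baseline_comparison", baseline_comparison(cohort))
  emit(data.frame(variable = baseline$variable,
                  cases = baseline$case_summary,
                  controls = baseline$control_summary,
                  p_value = format_pvalue(baseline$p_value)),
       "baseline_characteristics.tsv")

  snp_ids <- config$snp_ids %||%
    intersect(config$params$snp_info$snp_id, names(cohort))
  alpha_bonf <- bonferroni_threshold(config$family_alpha,
                                     config$n_snps_tested)
  is_case <- cohort$status == "case"
  assoc <- run_stage("snp_association", {
    rows <- lapply(snp_ids, function(s) {
      info <- config$params$snp_info[config$params$snp_info$snp_id == s, ,
                                     drop = FALSE]
      tab <- allele_count_table(cohort[[s]][is_case],
                                cohort[[s]][!is_case], snp_id = s)
      uni <- allelic_test(tab)
      adj <- additive_logistic(cohort, s, config$covariates)
      data.frame(
        locus = if (nrow(info)) info$locus else NA_character_,
        chromosome = if (nrow(info)) info$chromosome else NA_character_,
        snp_id = s,
        position_bp = if (nrow(info)) info$position_bp else NA_integer_,
        alleles = if (nrow(info))
          paste0(info$risk_allele, "/", info$other_allele) else NA_character_,
        case_freq = tab$case_risk / (tab$case_risk + tab$case_other),
        control_freq = tab$control_risk /
          (tab$control_risk + tab$control_other),
        univ_p = uni$p_value, univ_or = uni$odds_ratio,
        univ_ci_low = uni$ci_low, univ_ci_high = uni$ci_high,
        adj_p = adj$p_value, adj_or = adj$odds_ratio,
        adj_ci_low = adj$ci_low, adj_ci_high = adj$ci_high,
        significant_bonferroni = adj$p_value < alpha_bonf,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  emit(data.frame(
    locus = assoc$locus, chromosome = assoc$chromosome,
    snp_id = assoc$snp_id, position_bp = assoc$position_bp,
    alleles = assoc$alleles,
    case_freq = fmt_num(assoc$case_freq, 3),
    control_freq = fmt_num(assoc$control_freq, 3),
    univ_p = format_pvalue(assoc$univ_p),
    univ_or_ci = sprintf("%s (%s-%s)", fmt_num(assoc$univ_or, 2),
                         fmt_num(assoc$univ_ci_low, 2),
                         fmt_num(assoc$univ_ci_high, 2)),
    adj_p = format_pvalue(assoc$adj_p),
    adj_or_ci = sprintf("%s (%s-%s)", fmt_num(assoc$adj_or, 2),
                        fmt_num(assoc$adj_ci_low, 2),
                        fmt_num(assoc$adj_ci_high, 2)),
    significant = assoc$significant_bonferroni),
    "snp_association.tsv")

  joint <- run_stage("joint_model",
                     joint_multivariate_model(cohort, config$joint_snp_ids,
                                              config$covariates))
  emit(data.frame(variable = joint$terms$snp_id,
                  B = fmt_num(joint$terms$beta, 3),
                  SE = fmt_num(joint$terms$se, 3),
                  p_value = format_pvalue(joint$terms$p_value),
                  or_ci = sprintf("%s (%s-%s)",
                                  fmt_num(joint$terms$odds_ratio, 2),
                                  fmt_num(joint$terms$ci_low, 2),
                                  fmt_num(joint$terms$ci_high, 2))),
       "joint_model.tsv")

  vif_res <- run_stage("collinearity", {
    preds <- c(config$covariates, config$joint_snp_ids)
    vif(cohort, preds)
  })
  emit(data.frame(variable = vif_res$variable,
                  tolerance = fmt_num(vif_res$tolerance, 3),
                  vif = fmt_num(vif_res$vif, 2)),
       "collinearity.tsv")

  importance <- NULL
  if (isTRUE(config$run_nn)) {
    importance <- run_stage("subset_ensemble", {
      nn <- config$nn
      panel <- nn$panel %||% variable_panel()
      runs <- run_ensemble(cohort[is_case, , drop = FALSE],
                           cohort[!is_case, , drop = FALSE],
                           panel,
                           reps = nn$reps %||% 20,
                           age_matched = nn$age_matched %||% FALSE,
                           tolerance_years = nn$tolerance_years %||% 2,
                           master_seed = config$seed,
                           subset_cap = nn$subset_cap,
                           checkpoint = nn$checkpoint)
      rank_variables(runs, panel,
                     age_matched = nn$age_matched %||% FALSE)
    })
    emit(data.frame(rank = importance$rank, variable = importance$variable,
                    contribution = fmt_num(importance$contribution, 6),
                    age_matched = importance$age_matched),
         "variable_importance.tsv")
  }

  manifest <- list(
    package = "oagrisk",
    version = as.character(utils::packageVersion("oagrisk")),
    seed = config$seed,
    n_participants = nrow(cohort),
    n_cases = sum(is_case),
    snps_tested = snp_ids,
    n_snps_tested = config$n_snps_tested,
    family_alpha = config$family_alpha,
    bonferroni_alpha = alpha_bonf,
    bonferroni_alpha_display = format_pvalue(alpha_bonf),
    covariates = config$covariates,
    joint_snp_ids = config$joint_snp_ids,
    nn_stage = isTRUE(config$run_nn),
    files = files
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    machine <- list(baseline = baseline, snp_association = assoc,
                    joint_terms = joint$terms,
                    joint_intercept = joint$intercept,
                    vif = vif_res, importance = importance)
    jsonlite::write_json(machine, file.path(out_dir, "results.json"),
                         digits = NA, dataframe = "rows", na = "null")
  }
  invisible(list(cohort = cohort, baseline = baseline,
                 snp_association = assoc, joint = joint, vif = vif_res,
                 bonferroni_alpha = alpha_bonf, importance = importance,
                 manifest = manifest))
}
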