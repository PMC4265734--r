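#' Reported open-angle glaucoma risk SNP panel
#'
#' The seven genome-wide significant OAG risk SNPs analysed by the package,
#' with hg18 positions, risk (A1) and other (A2) alleles, locus labels, and the
#' published risk-allele frequencies in incident cases and in controls. All
#' genotype coding in the package counts copies of the risk allele.
#'
#' @return A data frame with one row per SNP and columns `snp_id`,
#'   `chromosome`, `position_bp`, `risk_allele`, `other_allele`, `locus`,
#'   `case_freq`, `control_freq`.
#' @examples
#' oag_snp_panel()
#' @export
oag_snp_panel <- function() {
  data.frame(
    snp_id = c("rs4656461", "rs4236601", "rs1521774", "rs1063192",
               "rs1412829", "rs4977756", "rs10483727"),
    chromosome = c("1", "7", "8", "9", "9", "9", "14"),
    position_bp = c(163953829L, 115949965L, 106048166L, 21993367L,
                    22033926L, 22058652L, 60142628L),
    risk_allele = c("G", "A", "G", "A", "A", "A", "A"),
    other_allele = c("A", "G", "A", "G", "G", "G", "G"),
    locus = c("TMCO1", "CAV1/CAV2", "8q22", "9p21", "9p21", "9p21",
              "SIX1/SIX6"),
    case_freq = c(0.187, 0.313, 0.366, 0.642, 0.687, 0.687, 0.508),
    control_freq = c(0.116, 0.268, 0.324, 0.549, 0.568, 0.591, 0.384),
    stringsAsFactors = FALSE
  )
}

#' Baseline clinical covariate distributions by incident glaucoma status
#'
#' Group-specific means and standard deviations of the continuous baseline
#' covariates (age in years, mean intraocular pressure in mm Hg, mean vertical
#' cup-to-disc ratio, mean disc diameter in mm, systolic and diastolic blood
#' pressure in mm Hg), together with the physical bounds used when sampling
#' truncated normal values.
#'
#' @return A data frame with columns `name`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`, `lower`, `upper`.
#' @export
oag_covariate_table <- function() {
  data.frame(
    name = c("age", "iop", "vcdr", "dd", "sbp", "dbp"),
    case_mean = c(68.9, 17.6, 0.53, 1.52, 151.6, 85.7),
    case_sd = c(7.9, 2.8, 0.11, 0.18, 21.2, 9.5),
    control_mean = c(63.8, 15.9, 0.42, 1.51, 144.0, 83.4),
    control_sd = c(8.3, 2.6, 0.12, 0.17, 20.4, 9.6),
    lower = c(0, 0, 0, 0, 0, 0),
    upper = c(Inf, Inf, 1, Inf, Inf, Inf),
    stringsAsFactors = FALSE
  )
}

#' Multivariate logistic risk model coefficients
#'
#' Maximum-likelihood log-odds coefficients of the joint incident-OAG risk
#' model: female sex, age (per year), mean IOP (per mm Hg), mean VCDR (per 0.1
#' unit of cup-to-disc ratio), mean disc diameter (per mm), systolic and
#' diastolic blood pressure (per mm Hg), and per-risk-allele effects at the
#' three associated loci. `oag_model_intercept()` returns the fitted constant;
#' for synthetic cohorts the constant is usually recalibrated to a target
#' incidence with [calibrate_intercept()].
#'
#' @return Named numeric vector of log-odds coefficients.
#' @seealso [cohort_params()], [case_probability()]
#' @export
oag_model_betas <- function() {
  c(sex = 0.930, age = 0.064, iop = 0.217, vcdr = 0.827, dd = -1.803,
    sbp = -0.005, dbp = 0.021,
    rs4656461 = 0.608, rs1412829 = 0.439, rs10483727 = 0.525)
}

#' @rdname oag_model_betas
#' @export
oag_model_intercept <- function() -16.221

#' Standard errors of the multivariate risk model coefficients
#'
#' Companion to [oag_model_betas()]; used for parameter-recovery checks on
#' simulated cohorts.
#'
#' @return Named numeric vector of standard errors.
#' @export
oag_model_ses <- function() {
  c(sex = 0.305, age = 0.017, iop = 0.048, vcdr = 0.135, dd = 0.838,
    sbp = 0.008, dbp = 0.018,
    rs4656461 = 0.258, rs1412829 = 0.205, rs10483727 = 0.200)
}

#' Clinical covariates entering adjusted association models
#'
#' @return Character vector of the seven baseline clinical adjustment
#'   variables (sex plus the six continuous covariates).
#' @export
oag_clinical_covariates <- function() {
  c("sex", "age", "iop", "vcdr", "dd", "sbp", "dbp")
}

#' Cohort generation parameters
#'
#' Bundles everything needed to generate a synthetic incident-OAG cohort:
#' sample size, group-specific covariate distributions, female fractions,
#' SNP panel with group risk-allele frequencies, and the logistic risk model
#' (coefficients plus intercept) that drives case status in prospective mode.
#'
#' The default parameter set reproduces the published baseline
#' characteristics, risk-allele frequencies, and multivariate model of the
#' incident-glaucoma cohort (1986 participants, 67 incident cases). The VCDR
#' coefficient is on a per-0.1 scale; `vcdr_scale` records the multiplier
#' applied to raw cup-to-disc ratios before they meet the coefficient.
#'
#' @param n_total Number of participants to generate.
#' @param covariates Data frame as returned by [oag_covariate_table()].
#' @param female_frac_case,female_frac_control Proportion female by group.
#' @param snp_info Data frame as returned by [oag_snp_panel()].
#' @param logistic_betas Named log-odds coefficients; names must be `"sex"`,
#'   continuous covariate names, or SNP ids present in `snp_info`.
#' @param intercept Log-odds constant of the risk model.
#' @param target_incidence Proportion of incident cases the cohort should
#'   average; used by [calibrate_intercept()] and by retrospective generation.
#' @param vcdr_scale Multiplier applied to raw VCDR before the model
#'   coefficient (default 10: coefficient per 0.1 VCDR).
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @return An object of class `cohort_params`.
#' @examples
#' p <- cohort_params(n_total = 500)
#' p$snp_info$snp_id
#' @export
cohort_params <- function(n_total = 1986,
                          covariates = oag_covariate_table(),
                          female_frac_case = 0.73,
                          female_frac_control = 0.57,
                          snp_info = oag_snp_panel(),
                          logistic_betas = oag_model_betas(),
                          intercept = oag_model_intercept(),
                          target_incidence = 67 / 1986,
                          vcdr_scale = 10,
                          missing_rate = 0) {
  if (!is.numeric(n_total) || length(n_total) != 1 || n_total < 1) {
    stop("`n_total` must be a positive integer", call. = FALSE)
  }
  req <- c("name", "case_mean", "case_sd", "control_mean", "control_sd",
           "lower", "upper")
  if (!all(req %in% names(covariates))) {
    stop("`covariates` must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(covariates$case_sd <= 0) || any(covariates$control_sd <= 0)) {
    stop("covariate standard deviations must be strictly positive",
         call. = FALSE)
  }
  for (fr in c(female_frac_case, female_frac_control)) {
    if (fr < 0 || fr > 1) stop("female fractions must lie in [0, 1]",
                               call. = FALSE)
  }
  validate_snp_info(snp_info)
  if (is.null(names(logistic_betas)) || any(names(logistic_betas) == "")) {
    stop("`logistic_betas` must be a fully named numeric vector",
         call. = FALSE)
  }
  known <- c("sex", covariates$name, snp_info$snp_id)
  unknown <- setdiff(names(logistic_betas), known)
  if (length(unknown)) {
    stop("unknown modelled variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate > 1) {
    stop("`missing_rate` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_total = as.integer(n_total), covariates = covariates,
         female_frac_case = female_frac_case,
         female_frac_control = female_frac_control,
         snp_info = snp_info, logistic_betas = logistic_betas,
         intercept = intercept, target_incidence = target_incidence,
         vcdr_scale = vcdr_scale, missing_rate = missing_rate),
    class = "cohort_params"
  )
}

validate_snp_info <- function(snp_info) {
  req <- c("snp_id", "risk_allele", "other_allele", "case_freq",
           "control_freq")
  if (!all(req %in% names(snp_info))) {
    stop("`snp_info` must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(snp_info$snp_id)) {
    stop("duplicated snp_id in `snp_info`", call. = FALSE)
  }
  if (any(snp_info$risk_allele == snp_info$other_allele)) {
    stop("risk and other allele must differ", call. = FALSE)
  }
  for (col in c("case_freq", "control_freq")) {
    f <- snp_info[[col]]
    if (any(f < 0 | f > 1)) stop(col, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(snp_info)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Cohort generation parameters\n")
  cat(sprintf("  n_total: %d  (target incidence %.4f)\n",
              x$n_total, x$target_incidence))
  cat(sprintf("  SNPs: %d  covariates: %d  modelled terms: %d\n",
              nrow(x$snp_info), nrow(x$covariates),
              length(x$logistic_betas)))
  cat(sprintf("  intercept: %.3f  (vcdr scale x%g)\n",
              x$intercept, x$vcdr_scale))
  invisible(x)
}
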