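#' Sample Hardy-Weinberg genotypes
#'
#' Draws additive-coded genotypes (risk-allele counts 0/1/2) as the sum of two
#' independent Bernoulli allele draws at the given risk-allele frequency, i.e.
#' under Hardy-Weinberg equilibrium.
#'
#' @param n Number of individuals.
#' @param freq Risk-allele frequency in \[0, 1\].
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (so callers that have already seeded get reproducible streams).
#' @return Integer vector of length `n` with values in \{0, 1, 2\}.
#' @examples
#' genotypes_hwe(10, 0.3, seed = 1)
#' @export
genotypes_hwe <- function(n, freq, seed = NULL) {
  if (!is.numeric(freq) || length(freq) != 1 || is.na(freq) ||
      freq < 0 || freq > 1) {
    stop("`freq` must be a single value in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0) {
    stop("`n` must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, freq)
}

# Truncated-normal sampling by resampling out-of-bound draws (no point mass
# at the bounds, unlike clipping).
rnorm_truncated <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) stop("standard deviation must be strictly positive",
                    call. = FALSE)
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Generate baseline clinical covariates for one status group
#'
#' Continuous covariates are drawn from independent truncated normal
#' distributions with the group's means and SDs (VCDR restricted to \[0, 1\],
#' the others to positive values); sex is drawn Bernoulli at the group's
#' female fraction. Covariates are generated independently of each other:
#' between-covariate correlation is not emulated.
#'
#' @param n Number of participants.
#' @param group `"case"` or `"control"`.
#' @param params A [cohort_params()] object.
#' @param seed Optional integer seed (see [genotypes_hwe()]).
#' @return Data frame with columns `sex` (factor male/female) and one column
#'   per continuous covariate.
#' @export
generate_covariates <- function(n, group = c("case", "control"), params,
                                seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  cv <- params$covariates
  mean_col <- paste0(group, "_mean")
  sd_col <- paste0(group, "_sd")
  out <- data.frame(row.names = seq_len(max(n, 0)))
  ffrac <- if (group == "case") params$female_frac_case else
    params$female_frac_control
  out$sex <- factor(ifelse(stats::rbinom(n, 1L, ffrac) == 1L,
                           "female", "male"),
                    levels = c("male", "female"))
  for (i in seq_len(nrow(cv))) {
    out[[cv$name[i]]] <- rnorm_truncated(n, cv[[mean_col]][i], cv[[sd_col]][i],
                                         cv$lower[i], cv$upper[i])
  }
  out
}

# Linear predictor of the logistic risk model; `data` must carry every
# modelled variable. VCDR meets its coefficient on the per-(1/vcdr_scale)
# scale.
linear_predictor <- function(data, params, include_intercept = TRUE) {
  b <- params$logistic_betas
  lp <- rep(if (include_intercept) params$intercept else 0, nrow(data))
  for (v in names(b)) {
    x <- data[[v]]
    if (is.null(x)) stop("modelled variable missing from data: ", v,
                         call. = FALSE)
    if (v == "sex") x <- as.numeric(x == "female")
    if (v == "vcdr") x <- x * params$vcdr_scale
    if (anyNA(x)) stop("missing values in modelled variable: ", v,
                       call. = FALSE)
    lp <- lp + b[[v]] * x
  }
  lp
}

#' Incident-case probability under the logistic risk model
#'
#' Evaluates the inverse-logit of `intercept + sum(beta_v * x_v)` for each row
#' of `data`, with genotypes entered as risk-allele counts and covariates on
#' the model's reporting scale (VCDR per 0.1 unit by default).
#'
#' @param data Data frame (or single-row list) holding every modelled
#'   variable: `sex`, continuous covariates, and genotype columns named by
#'   SNP id.
#' @param params A [cohort_params()] object.
#' @return Numeric vector of case probabilities.
#' @examples
#' p <- cohort_params()
#' row <- data.frame(sex = factor("female", c("male", "female")), age = 64,
#'                   iop = 16, vcdr = 0.42, dd = 1.5, sbp = 144, dbp = 83,
#'                   rs4656461 = 0L, rs1412829 = 1L, rs10483727 = 2L)
#' case_probability(row, p)
#' @export
case_probability <- function(data, params) {
  data <- as.data.frame(data)
  stats::plogis(linear_predictor(data, params))
}

#' Calibrate the risk-model intercept to a target incidence
#'
#' The published model constant was fitted on the real cohort; synthetic
#' marginals (independent covariates, Hardy-Weinberg genotypes at population
#' frequencies) need a recalibrated constant for the simulated incidence to
#' land on target. The mean case probability over a large Monte-Carlo
#' population sample is strictly increasing in the intercept, so the root is
#' found by bisection ([stats::uniroot()]).
#'
#' @param params A [cohort_params()] object.
#' @param target_incidence Desired mean incidence in (0, 1); defaults to the
#'   value stored in `params`.
#' @param seed Integer seed for the Monte-Carlo population sample.
#' @param n_mc Monte-Carlo sample size (default 200 000).
#' @param tol Tolerance on the achieved mean incidence (default 1e-4).
#' @return The calibrated intercept (numeric scalar).
#' @export
calibrate_intercept <- function(params, target_incidence =
                                  params$target_incidence,
                                seed = 1, n_mc = 200000, tol = 1e-4) {
  if (!is.numeric(target_incidence) || length(target_incidence) != 1 ||
      is.na(target_incidence) || target_incidence <= 0 ||
      target_incidence >= 1) {
    stop("`target_incidence` must lie strictly inside (0, 1)", call. = FALSE)
  }
  set.seed(seed)
  pop <- draw_population(n_mc, params)
  lp0 <- linear_predictor(pop, params, include_intercept = FALSE)
  f <- function(c0) mean(stats::plogis(c0 + lp0)) - target_incidence
  # mean probability is monotone in c0 and spans (0, 1) over this bracket
  root <- stats::uniroot(f, lower = -60, upper = 60, tol = tol / 10)$root
  if (abs(f(root)) > tol) {
    stop("intercept calibration did not reach tolerance ", tol, call. = FALSE)
  }
  root
}

# Population sample for prospective generation: control-group covariate
# distributions (controls are 96.6% of the cohort, the closest available
# proxy for population marginals) and Hardy-Weinberg genotypes at control
# risk-allele frequencies.
draw_population <- function(n, params) {
  pop <- generate_covariates(n, "control", params)
  for (i in seq_len(nrow(params$snp_info))) {
    pop[[params$snp_info$snp_id[i]]] <-
      genotypes_hwe(n, params$snp_info$control_freq[i])
  }
  pop
}

#' Generate a synthetic incident-glaucoma cohort
#'
#' Two generation modes are supported. In `"prospective"` mode, population
#' covariates and Hardy-Weinberg genotypes are drawn first and incident case
#' status is then sampled from the logistic risk model -- use this when the
#' downstream analysis should be able to recover the generating model. In
#' `"retrospective"` mode, case status is drawn first (Bernoulli at the
#' target incidence) and covariates/genotypes are then drawn from the
#' group-specific distributions -- use this when the case/control marginals
#' (group means, group risk-allele frequencies) should match their published
#' values directly.
#'
#' @param params A [cohort_params()] object. For prospective mode the
#'   intercept should be calibrated (see [calibrate_intercept()]) if a
#'   particular incidence is wanted.
#' @param seed Integer seed; identical `(params, seed)` give identical
#'   cohorts.
#' @param mode `"prospective"` or `"retrospective"`.
#' @return A data frame of class `oag_cohort`: `pid`, `status`
#'   (factor control/case), `sex`, the continuous covariates, then one
#'   genotype column per SNP.
#' @examples
#' coh <- generate_cohort(cohort_params(n_total = 200), seed = 7,
#'                        mode = "retrospective")
#' table(coh$status)
#' @export
generate_cohort <- function(params, seed,
                            mode = c("prospective", "retrospective")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "cohort_params"))
  set.seed(seed)
  n <- params$n_total
  if (mode == "prospective") {
    dat <- draw_population(n, params)
    p <- stats::plogis(linear_predictor(dat, params))
    status <- stats::rbinom(n, 1L, p)
  } else {
    status <- stats::rbinom(n, 1L, params$target_incidence)
    dat <- NULL
    for (g in c("control", "case")) {
      idx <- which(status == (g == "case"))
      if (!length(idx)) next
      block <- generate_covariates(length(idx), g, params)
      freq_col <- paste0(g, "_freq")
      for (i in seq_len(nrow(params$snp_info))) {
        block[[params$snp_info$snp_id[i]]] <-
          genotypes_hwe(length(idx), params$snp_info[[freq_col]][i])
      }
      block$.row <- idx
      dat <- rbind(dat, block)
    }
    dat <- dat[order(dat$.row), ]
    dat$.row <- NULL
    rownames(dat) <- NULL
  }
  if (params$missing_rate > 0) {
    for (s in params$snp_info$snp_id) {
      miss <- stats::runif(n) < params$missing_rate
      dat[[s]][miss] <- NA_integer_
    }
  }
  out <- cbind(
    data.frame(pid = sprintf("P%05d", seq_len(n)),
               status = factor(ifelse(status == 1L, "case", "control"),
                               levels = c("control", "case")),
               stringsAsFactors = FALSE),
    dat
  )
  class(out) <- c("oag_cohort", "data.frame")
  out
}
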