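assoc_result <- function(snp_id, model, beta, se, p_value,
                         conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(snp_id = snp_id, model = model, beta = beta, se = se,
             odds_ratio = exp(beta),
             ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
             p_value = p_value, stringsAsFactors = FALSE)
}

#' Allele count table for a univariate allelic test
#'
#' Collapses additive-coded genotypes into the 2x2 table of risk/other allele
#' counts by case status (two alleles per subject; missing genotypes are
#' excluded).
#'
#' @param case_genotypes,control_genotypes Vectors of genotypes in
#'   \{0, 1, 2, NA\}.
#' @param snp_id Optional SNP label carried through to results.
#' @return An object of class `allelic2x2` with fields `case_risk`,
#'   `case_other`, `control_risk`, `control_other`.
#' @examples
#' allele_count_table(c(1, 1, NA), c(0, 2))
#' @export
allele_count_table <- function(case_genotypes, control_genotypes,
                               snp_id = NA_character_) {
  check <- function(g, what) {
    if (any(!is.na(g) & !(g %in% c(0, 1, 2)))) {
      stop("invalid genotype code in ", what,
           " (must be 0, 1, 2 or missing)", call. = FALSE)
    }
  }
  check(case_genotypes, "case genotypes")
  check(control_genotypes, "control genotypes")
  ca <- case_genotypes[!is.na(case_genotypes)]
  co <- control_genotypes[!is.na(control_genotypes)]
  structure(list(case_risk = sum(ca), case_other = 2 * length(ca) - sum(ca),
                 control_risk = sum(co),
                 control_other = 2 * length(co) - sum(co),
                 snp_id = snp_id),
            class = "allelic2x2")
}

#' @export
print.allelic2x2 <- function(x, ...) {
  m <- matrix(c(x$case_risk, x$case_other, x$control_risk, x$control_other),
              2, 2, byrow = TRUE,
              dimnames = list(c("case", "control"), c("risk", "other")))
  print(m)
  invisible(x)
}

#' Univariate allelic association test
#'
#' Odds ratio on allele counts with a Woolf (log-OR) 95% confidence interval,
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`, and a two-sided p-value
#' from the 1-df Pearson chi-square on the 2x2 allele table without
#' continuity correction. Tables with a zero cell are rejected; callers
#' wanting a continuity correction must add 0.5 to the counts explicitly.
#'
#' @param table An [allele_count_table()] result (or a list with the same
#'   fields).
#' @return One-row data frame: `snp_id`, `model = "allelic"`, `beta`, `se`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @examples
#' allelic_test(allele_count_table(c(2, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
allelic_test <- function(table) {
  a <- table$case_risk; b <- table$case_other
  c_ <- table$control_risk; d <- table$control_other
  if (min(a, b, c_, d) <= 0) {
    stop("degenerate allele table (zero cell); add 0.5 to all cells ",
         "explicitly if a corrected estimate is wanted", call. = FALSE)
  }
  or <- (a / b) / (c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  m <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
  # asymptotic Pearson p by design; silence the small-count approximation note
  p <- withCallingHandlers(
    stats::chisq.test(m, correct = FALSE)$p.value,
    warning = function(w) {
      if (grepl("approximation may be incorrect", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  assoc_result(table$snp_id %||% NA_character_, "allelic", log(or), se, p)
}

#' Allelic odds ratio from case/control risk-allele frequencies
#'
#' `OR = [p_case (1 - p_control)] / [p_control (1 - p_case)]` -- reproduces a
#' univariate allelic odds ratio directly from reported frequency columns.
#'
#' @param p_case,p_control Risk-allele frequencies strictly inside (0, 1).
#' @return The allelic odds ratio.
#' @examples
#' or_from_freqs(0.508, 0.384)
#' @export
or_from_freqs <- function(p_case, p_control) {
  if (any(p_case <= 0 | p_case >= 1) || any(p_control <= 0 | p_control >= 1)) {
    stop("frequencies must lie strictly inside (0, 1)", call. = FALSE)
  }
  (p_case * (1 - p_control)) / (p_control * (1 - p_case))
}

# Model frame for logistic fits: response, dosage columns, covariates with
# sex coded female = 1 and VCDR on the reporting scale. Complete cases only.
logistic_frame <- function(cohort, snp_ids, covariates, vcdr_scale = 10) {
  df <- data.frame(y = as.numeric(cohort$status == "case"))
  for (s in snp_ids) {
    if (is.null(cohort[[s]])) stop("SNP column not found: ", s, call. = FALSE)
    df[[s]] <- as.numeric(cohort[[s]])
  }
  for (v in covariates) {
    x <- cohort[[v]]
    if (is.null(x)) stop("covariate column not found: ", v, call. = FALSE)
    if (v == "sex") x <- as.numeric(x == "female")
    if (v == "vcdr") x <- as.numeric(x) * vcdr_scale
    df[[v]] <- as.numeric(x)
  }
  df[stats::complete.cases(df), , drop = FALSE]
}

fit_logistic <- function(df) {
  if (length(unique(df$y)) < 2) {
    stop("need at least one case and one control with complete data",
         call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation || !fit$converged) {
    stop("logistic fit did not converge (possible perfect separation); ",
         "cases = ", sum(df$y), ", controls = ", sum(1 - df$y), call. = FALSE)
  }
  fit
}

#' Covariate-adjusted additive logistic association for one SNP
#'
#' Maximum-likelihood logistic regression of incident case status on the
#' risk-allele count plus the listed baseline covariates (complete-case).
#' Returns the SNP term with Wald standard error, 95% CI and p-value.
#'
#' @param cohort An `oag_cohort` data frame.
#' @param snp_id Genotype column to test.
#' @param covariates Adjustment variables (default the seven baseline
#'   clinical variables).
#' @param vcdr_scale VCDR multiplier matching the reporting scale (default
#'   10).
#' @return One-row data frame as in [allelic_test()], `model =
#'   "additive_adjusted"`.
#' @export
additive_logistic <- function(cohort, snp_id,
                              covariates = oag_clinical_covariates(),
                              vcdr_scale = 10) {
  df <- logistic_frame(cohort, snp_id, covariates, vcdr_scale)
  if (stats::var(df[[snp_id]]) == 0) {
    stop("genotype is constant for ", snp_id, "; no association estimable",
         call. = FALSE)
  }
  fit <- fit_logistic(df)
  cf <- summary(fit)$coefficients
  assoc_result(snp_id, "additive_adjusted", cf[snp_id, 1], cf[snp_id, 2],
               cf[snp_id, 4])
}

#' Joint multivariate logistic model over SNPs and covariates
#'
#' Fits one logistic model containing every listed SNP (additive risk-allele
#' counts) and covariate, returning one result row per term plus the fitted
#' constant.
#'
#' @inheritParams additive_logistic
#' @param snp_ids Genotype columns entering the model jointly.
#' @return An object of class `joint_model`: list with `terms` (data frame of
#'   per-term results, `model = "joint_multivariate"`), `intercept`,
#'   `intercept_se`, and `n` (complete-case rows used).
#' @export
joint_multivariate_model <- function(cohort, snp_ids,
                                     covariates = oag_clinical_covariates(),
                                     vcdr_scale = 10) {
  df <- logistic_frame(cohort, snp_ids, covariates, vcdr_scale)
  fit <- fit_logistic(df)
  cf <- summary(fit)$coefficients
  terms <- setdiff(rownames(cf), "(Intercept)")
  res <- do.call(rbind, lapply(terms, function(t)
    assoc_result(t, "joint_multivariate", cf[t, 1], cf[t, 2], cf[t, 4])))
  structure(list(terms = res, intercept = cf["(Intercept)", 1],
                 intercept_se = cf["(Intercept)", 2], n = nrow(df)),
            class = "joint_model")
}

#' @export
print.joint_model <- function(x, digits = 3, ...) {
  cat(sprintf("Joint multivariate logistic model (n = %d)\n", x$n))
  print(cbind(x$terms[, c("snp_id", "beta", "se")],
              OR = round(x$terms$odds_ratio, 2),
              p = round(x$terms$p_value, digits)), row.names = FALSE)
  cat(sprintf("Constant: %.3f (SE %.3f)\n", x$intercept, x$intercept_se))
  invisible(x)
}

#' Collinearity diagnostics: tolerance and variance inflation factor
#'
#' For each predictor, the squared multiple correlation from an ordinary
#' least-squares regression of it on the remaining predictors gives
#' `tolerance = 1 - R^2` and `VIF = 1 / tolerance`. Exact linear dependence
#' is reported as infinite VIF rather than an error.
#'
#' @param cohort Data frame holding the predictors (sex coded female = 1,
#'   genotypes as numeric counts).
#' @param predictors Character vector of predictor columns.
#' @return Data frame with columns `variable`, `tolerance`, `vif`.
#' @export
vif <- function(cohort, predictors) {
  df <- data.frame(row.names = seq_len(nrow(cohort)))
  for (v in predictors) {
    x <- cohort[[v]]
    if (is.null(x)) stop("predictor column not found: ", v, call. = FALSE)
    if (is.factor(x) || is.character(x)) x <- as.numeric(x == "female")
    df[[v]] <- as.numeric(x)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < length(predictors) + 2) {
    stop("need at least ", length(predictors) + 2, " complete rows",
         call. = FALSE)
  }
  res <- lapply(predictors, function(v) {
    fit <- stats::lm(stats::reformulate(setdiff(predictors, v),
                                        response = v), data = df)
    # exact dependence gives a perfect fit; that is a reportable outcome here
    r2 <- withCallingHandlers(
      summary(fit)$r.squared,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    tol <- 1 - r2
    data.frame(variable = v, tolerance = tol,
               vif = if (tol < 1e-12) Inf else 1 / tol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `family_alpha / m`. Reports conventionally display this at three
#'   decimals (see [format_pvalue()]).
#' @examples
#' bonferroni_threshold(0.05, 7)
#' @export
bonferroni_threshold <- function(family_alpha, m) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 1) {
    stop("`m` must be a positive count", call. = FALSE)
  }
  if (family_alpha <= 0 || family_alpha >= 1) {
    stop("`family_alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  family_alpha / m
}

#' Format a p-value or threshold in report style
#'
#' Three decimals with the leading zero dropped (`.007`), the convention used
#' in the package's table outputs.
#'
#' @param p Numeric vector of p-values.
#' @param digits Decimals to keep (default 3).
#' @return Character vector.
#' @export
format_pvalue <- function(p, digits = 3) {
  out <- sub("^0", "", formatC(p, digits = digits, format = "f"))
  out[is.na(p)] <- NA_character_
  out
}

#' Baseline characteristics comparison by case status
#'
#' Welch two-sample t-tests for continuous covariates and a Pearson
#' chi-square (no continuity correction) for sex, case versus control.
#' Zero-variance variables get a missing p-value.
#'
#' @param cohort An `oag_cohort` data frame.
#' @param variables Variables to compare (default sex plus the continuous
#'   covariates present).
#' @return Data frame with `variable`, formatted `case_summary` /
#'   `control_summary`, numeric group means and SDs, and `p_value`.
#' @export
baseline_comparison <- function(cohort, variables = NULL) {
  if (is.null(variables)) {
    variables <- intersect(c("sex", "age", "iop", "vcdr", "dd", "sbp", "dbp"),
                           names(cohort))
  }
  is_case <- cohort$status == "case"
  if (!any(is_case) || !any(!is_case)) {
    stop("both status groups must be non-empty", call. = FALSE)
  }
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    if (v == "sex" || is.factor(x)) {
      pf_case <- mean(x[is_case] == "female")
      pf_ctrl <- mean(x[!is_case] == "female")
      tab <- table(cohort$status, x)
      p <- if (any(dim(tab) < 2)) NA_real_ else
        stats::chisq.test(tab, correct = FALSE)$p.value
      data.frame(variable = "sex_female",
                 case_summary = sprintf("%.0f%%", 100 * pf_case),
                 control_summary = sprintf("%.0f%%", 100 * pf_ctrl),
                 case_mean = pf_case, case_sd = NA_real_,
                 control_mean = pf_ctrl, control_sd = NA_real_,
                 p_value = p, stringsAsFactors = FALSE)
    } else {
      xc <- x[is_case]; xo <- x[!is_case]
      p <- if (stats::var(xc) == 0 && stats::var(xo) == 0) NA_real_ else
        stats::t.test(xc, xo)$p.value
      data.frame(variable = v,
                 case_summary = sprintf("%.1f ± %.1f", mean(xc),
                                        stats::sd(xc)),
                 control_summary = sprintf("%.1f ± %.1f", mean(xo),
                                           stats::sd(xo)),
                 case_mean = mean(xc), case_sd = stats::sd(xc),
                 control_mean = mean(xo), control_sd = stats::sd(xo),
                 p_value = p, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
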