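#' Case-control genetic power specification
#'
#' Design parameters for an additive (trend-test) case-control power
#' computation: sample sizes, risk-allele frequency, genotype odds ratios,
#' population prevalence and test size. When `or_hom` is not given it is
#' derived from `or_het` by the chosen additive convention:
#' `"odds-multiplicative"` uses `or_het^2` (log-additive allele effect on the
#' odds scale) and `"risk-additive"` uses `2 * or_het - 1`.
#'
#' @param n_cases,n_controls Numbers of cases and controls.
#' @param risk_allele_freq Population risk-allele frequency in (0, 1).
#' @param or_het Heterozygote odds ratio (Aa vs aa).
#' @param or_hom Homozygote odds ratio (AA vs aa); default per `model`.
#' @param prevalence Population disease prevalence K in (0, 1).
#' @param alpha Two-sided test size in (0, 1).
#' @param model Additive convention used to fill in `or_hom`.
#' @return An object of class `power_spec`.
#' @examples
#' power_spec(67, 1919, 0.30, 1.6, prevalence = 0.0567, alpha = 0.007)
#' @export
power_spec <- function(n_cases, n_controls, risk_allele_freq, or_het,
                       or_hom = NULL, prevalence, alpha = 0.05,
                       model = c("odds-multiplicative", "risk-additive")) {
  model <- match.arg(model)
  if (is.null(or_hom)) {
    or_hom <- if (model == "odds-multiplicative") or_het^2 else 2 * or_het - 1
  }
  if (risk_allele_freq <= 0 || risk_allele_freq >= 1) {
    stop("`risk_allele_freq` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (or_het <= 0 || or_hom <= 0) {
    stop("odds ratios must be strictly positive", call. = FALSE)
  }
  if (n_cases < 1 || n_controls < 1) {
    stop("sample sizes must be positive", call. = FALSE)
  }
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 risk_allele_freq = risk_allele_freq, or_het = or_het,
                 or_hom = or_hom, prevalence = prevalence, alpha = alpha,
                 model = model),
            class = "power_spec")
}

hwe_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

#' Genotype penetrances from odds ratios and prevalence
#'
#' Solves for penetrances `(f0, f1, f2)` such that the heterozygote and
#' homozygote disease odds are `or_het` and `or_hom` times the baseline odds
#' `f0 / (1 - f0)`, and the Hardy-Weinberg-weighted mean penetrance equals
#' the population prevalence. The prevalence constraint is strictly
#' increasing in `f0`, so the root is found by 1-d bisection
#' ([stats::uniroot()]).
#'
#' @param spec A [power_spec()] object.
#' @return Named numeric vector `c(f0, f1, f2)` of penetrances.
#' @export
penetrances_from_ors <- function(spec) {
  stopifnot(inherits(spec, "power_spec"))
  hw <- hwe_probs(spec$risk_allele_freq)
  pen <- function(f0) {
    o0 <- f0 / (1 - f0)
    c(f0,
      spec$or_het * o0 / (1 + spec$or_het * o0),
      spec$or_hom * o0 / (1 + spec$or_hom * o0))
  }
  f <- function(f0) sum(hw * pen(f0)) - spec$prevalence
  eps <- 1e-12
  if (f(eps) > 0 || f(1 - eps) < 0) {
    stop("infeasible specification: no baseline penetrance in (0, 1) ",
         "satisfies the prevalence constraint", call. = FALSE)
  }
  f0 <- stats::uniroot(f, c(eps, 1 - eps), tol = 1e-14)$root
  stats::setNames(pen(f0), c("f0", "f1", "f2"))
}

#' Genotype distributions in cases and controls
#'
#' Bayes inversion of the penetrance model: `P(G | case)` is proportional to
#' `HWE(G) * f_G` and, for disease-free (screened) controls,
#' `P(G | control)` to `HWE(G) * (1 - f_G)`. With `screened = FALSE`
#' controls are unselected population members with genotype distribution
#' equal to Hardy-Weinberg.
#'
#' @param penetrances Numeric vector `(f0, f1, f2)`.
#' @param risk_allele_freq Population risk-allele frequency.
#' @param screened Are controls screened disease-free? (default `TRUE`).
#' @return List with numeric length-3 elements `case` and `control`, each
#'   summing to one.
#' @export
case_control_genotype_freqs <- function(penetrances, risk_allele_freq,
                                        screened = TRUE) {
  hw <- hwe_probs(risk_allele_freq)
  case <- hw * penetrances / sum(hw * penetrances)
  control <- if (screened) {
    hw * (1 - penetrances) / sum(hw * (1 - penetrances))
  } else {
    hw
  }
  list(case = case, control = control)
}

#' Analytic power of the Cochran-Armitage trend test
#'
#' Power of the 1-df additive-score (0, 1, 2) trend test for a case-control
#' design. Penetrances are solved from the prevalence and odds ratios
#' ([penetrances_from_ors()]), case/control genotype distributions follow by
#' Bayes inversion, the noncentrality parameter is the trend statistic
#' evaluated at the expected genotype counts, and power is the upper tail of
#' the noncentral chi-square beyond the central critical value at `alpha`.
#'
#' @param spec A [power_spec()] object.
#' @param screened Are controls screened disease-free? (default `TRUE`).
#' @return An object of class `power_result`: list with `power`, `ncp`,
#'   `penetrances`, `geno_case`, `geno_control`, and the `spec`.
#' @examples
#' trend_test_power(power_spec(67, 1919, 0.30, 1.6,
#'                             prevalence = 0.0567, alpha = 0.007))
#' @export
trend_test_power <- function(spec, screened = TRUE) {
  stopifnot(inherits(spec, "power_spec"))
  pen <- penetrances_from_ors(spec)
  gf <- case_control_genotype_freqs(pen, spec$risk_allele_freq, screened)
  ncp <- trend_ncp(gf$case, gf$control, spec$n_cases, spec$n_controls)
  crit <- stats::qchisq(1 - spec$alpha, df = 1)
  power <- stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  structure(list(power = power, ncp = ncp, penetrances = pen,
                 geno_case = gf$case, geno_control = gf$control,
                 spec = spec),
            class = "power_result")
}

# Trend chi-square evaluated at expected genotype counts = noncentrality.
trend_ncp <- function(p_case, p_control, n_cases, n_controls) {
  x <- 0:2
  n <- n_cases + n_controls
  r <- n_cases * p_case
  s <- n_controls * p_control
  tot <- r + s
  u <- sum(x * (n_controls * r - n_cases * s)) / n
  v <- (n_cases * n_controls / n) *
    (sum(x^2 * tot) / n - (sum(x * tot) / n)^2)
  u^2 / v
}

#' @export
print.power_result <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Trend-test power: %.1f%% (%d cases / %d controls, freq %.3g, OR %.3g/%.3g, K %.4g, alpha %.4g, %s)\n",
    100 * x$power, s$n_cases, s$n_controls, s$risk_allele_freq, s$or_het,
    s$or_hom, s$prevalence, s$alpha, s$model))
  invisible(x)
}
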