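test_that("allele counting matches hand counts and a per-subject oracle", {
  t1 <- allele_count_table(c(2, 2), c(0, 0))
  expect_identical(c(t1$case_risk, t1$case_other, t1$control_risk,
                     t1$control_other), c(4, 0, 0, 4))
  t2 <- allele_count_table(c(1, 1, NA), c(0, 2))
  expect_identical(c(t2$case_risk, t2$case_other, t2$control_risk,
                     t2$control_other), c(2, 2, 2, 2))
  expect_error(allele_count_table(c(0, 3), c(1)), "invalid genotype")

  set.seed(10)
  g_case <- sample(c(0:2, NA), 500, replace = TRUE)
  g_ctrl <- sample(c(0:2, NA), 500, replace = TRUE)
  # brute-force per-subject recount
  risk <- other <- 0
  for (g in g_case[!is.na(g_case)]) {
    risk <- risk + g
    other <- other + (2 - g)
  }
  t3 <- allele_count_table(g_case, g_ctrl)
  expect_equal(t3$case_risk, risk)
  expect_equal(t3$case_other, other)
  expect_equal(t3$case_risk + t3$case_other, 2 * sum(!is.na(g_case)))
})

test_that("allelic test matches direct ratio arithmetic and an independent Pearson oracle", {
  bal <- allelic_test(list(case_risk = 10, case_other = 10,
                           control_risk = 10, control_other = 10))
  expect_equal(bal$odds_ratio, 1)
  expect_equal(bal$p_value, 1)

  tab <- list(case_risk = 68, case_other = 66, control_risk = 1474,
              control_other = 2364, snp_id = "x")
  res <- allelic_test(tab)
  expect_equal(res$odds_ratio, (68 / 66) / (1474 / 2364), tolerance = 1e-12)
  expect_equal(res$p_value, pearson_2x2_p(68, 66, 1474, 2364),
               tolerance = 1e-10)
  # Woolf CI from the explicit formula
  se <- sqrt(1 / 68 + 1 / 66 + 1 / 1474 + 1 / 2364)
  expect_equal(res$ci_low, exp(log(res$odds_ratio) - qnorm(0.975) * se))

  set.seed(3)
  for (i in 1:20) {
    cts <- rmultinom(1, 400, c(0.2, 0.3, 0.25, 0.25))[, 1] + 1
    r <- allelic_test(list(case_risk = cts[1], case_other = cts[2],
                           control_risk = cts[3], control_other = cts[4]))
    expect_equal(r$p_value, pearson_2x2_p(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-10)
  }

  expect_error(allelic_test(list(case_risk = 0, case_other = 5,
                                 control_risk = 5, control_other = 5)),
               "degenerate")
})

test_that("relabelling risk and other alleles inverts the OR and preserves the p-value", {
  tab <- list(case_risk = 68, case_other = 66, control_risk = 1474,
              control_other = 2364)
  fwd <- allelic_test(tab)
  rev <- allelic_test(list(case_risk = tab$case_other,
                           case_other = tab$case_risk,
                           control_risk = tab$control_other,
                           control_other = tab$control_risk))
  expect_equal(rev$odds_ratio, 1 / fwd$odds_ratio, tolerance = 1e-12)
  expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
})

test_that("OR/CI duality holds and Wald p agrees with CI coverage of 1", {
  set.seed(8)
  for (i in 1:50) {
    cts <- rmultinom(1, 300, runif(4, 0.1, 0.4))[, 1] + 1
    r <- allelic_test(list(case_risk = cts[1], case_other = cts[2],
                           control_risk = cts[3], control_other = cts[4]))
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    wald_p <- 2 * pnorm(-abs(r$beta / r$se))
    excludes_1 <- r$ci_low > 1 || r$ci_high < 1
    expect_identical(wald_p < 0.05, excludes_1)
  }
})

test_that("frequency-based OR reproduces published univariate odds ratios", {
  expect_equal(or_from_freqs(0.5, 0.5), 1)
  expect_equal(round(or_from_freqs(0.687, 0.568), 2), 1.67)
  expect_equal(round(or_from_freqs(0.642, 0.549), 2), 1.47)
  expect_error(or_from_freqs(0, 0.5), "strictly inside")
  expect_error(or_from_freqs(0.5, 1), "strictly inside")
  # allelic_test OR equals or_from_freqs applied to the table frequencies
  tab <- allele_count_table(c(2, 1, 1, 0, 0), c(0, 0, 1, 2, 1, 1))
  r <- allelic_test(tab)
  fc <- tab$case_risk / (tab$case_risk + tab$case_other)
  fo <- tab$control_risk / (tab$control_risk + tab$control_other)
  expect_equal(r$odds_ratio, or_from_freqs(fc, fo), tolerance = 1e-12)
})

test_that("adjusted additive regression reduces to the joint model with one SNP", {
  p <- cohort_params(n_total = 3000)
  p$intercept <- -13
  coh <- generate_cohort(p, seed = 61)
  single <- additive_logistic(coh, "rs10483727")
  joint <- joint_multivariate_model(coh, "rs10483727")
  jrow <- joint$terms[joint$terms$snp_id == "rs10483727", ]
  expect_equal(single$beta, jrow$beta, tolerance = 1e-12)
  expect_equal(single$se, jrow$se, tolerance = 1e-12)
  expect_equal(single$p_value, jrow$p_value, tolerance = 1e-12)
})

test_that("adjusted regression rejects constant genotypes and missing columns", {
  p <- cohort_params(n_total = 300)
  p$intercept <- -12
  coh <- generate_cohort(p, seed = 62)
  coh$rs4656461 <- 0L
  expect_error(additive_logistic(coh, "rs4656461"), "constant")
  expect_error(additive_logistic(coh, "rs99"), "not found")
})

test_that("joint model recovers a generating coefficient on a moderate cohort", {
  p <- cohort_params(n_total = 20000)
  p$intercept <- calibrate_intercept(p, seed = 71, n_mc = 50000)
  coh <- generate_cohort(p, seed = 73)
  fit <- joint_multivariate_model(coh, c("rs4656461", "rs1412829",
                                         "rs10483727"))
  row <- fit$terms[fit$terms$snp_id == "rs10483727", ]
  expect_lt(abs(row$beta - 0.525), 2 * 0.200)
  expect_true(all(fit$terms$ci_low <= fit$terms$odds_ratio &
                    fit$terms$odds_ratio <= fit$terms$ci_high))
})

test_that("VIF matches the OLS definition, flags exact collinearity, and agrees with car", {
  set.seed(12)
  n <- 2000
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v <- vif(d, c("a", "b", "c"))
  expect_true(all(abs(v$vif - 1) < 0.05))
  expect_equal(v$vif, 1 / v$tolerance)

  d$a2 <- d$a
  v2 <- vif(d, c("a", "a2", "b"))
  expect_true(all(is.infinite(v2$vif[v2$variable %in% c("a", "a2")])))

  skip_if_not_installed("car")
  d$y <- rnorm(n)
  d$ab <- d$a + 0.6 * d$b + 0.2 * rnorm(n)
  ref <- car::vif(lm(y ~ a + b + ab, data = d))
  v3 <- vif(d, c("a", "b", "ab"))
  expect_equal(unname(ref[v3$variable]), v3$vif, tolerance = 1e-10)
})

test_that("default synthetic cohort shows no collinearity above the VIF 2 screen", {
  p <- cohort_params(n_total = 4000)
  p$intercept <- -13
  coh <- generate_cohort(p, seed = 81)
  v <- vif(coh, c(oag_clinical_covariates(),
                  c("rs4656461", "rs1412829", "rs10483727")))
  expect_true(all(v$vif < 2))
})

test_that("Bonferroni threshold divides the family alpha and prints at 3 decimals", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_identical(format_pvalue(bonferroni_threshold(0.05, 7)), ".007")
  expect_error(bonferroni_threshold(0.05, 0), "positive count")
  expect_error(bonferroni_threshold(1.5, 7), "strictly inside")
})

test_that("baseline comparison uses Welch t (oracle-checked) and detects group differences", {
  p <- cohort_params(n_total = 5000)
  coh <- generate_cohort(p, seed = 91, mode = "retrospective")
  bl <- baseline_comparison(coh)
  is_case <- coh$status == "case"
  for (v in c("age", "iop", "vcdr")) {
    expect_equal(bl$p_value[bl$variable == v],
                 welch_p(coh[[v]][is_case], coh[[v]][!is_case]),
                 tolerance = 1e-10)
  }
  # cases are older by construction
  age <- bl[bl$variable == "age", ]
  expect_gt(age$case_mean, age$control_mean)

  # identical groups: t = 0, p = 1
  cases <- coh[is_case, ][1:30, ]
  clone <- cases
  clone$status <- factor("control", levels = c("control", "case"))
  clone$pid <- paste0(clone$pid, "c")
  bl2 <- baseline_comparison(rbind(cases, clone))
  cont <- bl2[bl2$variable != "sex_female", ]
  expect_true(all(abs(cont$p_value - 1) < 1e-12))
})
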