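# Shared fixtures, all generated in code.

# Small case/control frames with one planted signal variable ("sig") and
# pure-noise companions; used by the ensemble tests.
make_planted_groups <- function(n_cases = 50, n_controls = 150,
                                n_noise = 2, signal_shift = 2, seed = 1) {
  set.seed(seed)
  mk <- function(n, status) {
    d <- data.frame(status = factor(rep(status, n),
                                    levels = c("control", "case")))
    d$sig <- stats::rnorm(n, mean = if (status == "case") signal_shift else 0)
    for (j in seq_len(n_noise)) d[[paste0("noise", j)]] <- stats::rnorm(n)
    d
  }
  list(cases = mk(n_cases, "case"), controls = mk(n_controls, "control"))
}

# Independent Pearson chi-square on a 2x2 table, coded from the textbook
# formula (row/column margins -> expected counts).
pearson_2x2_p <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

# Welch t statistic / p coded directly from the formula.
welch_p <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * stats::pt(-abs(t), df)
}

# Default params shrunk to a quick cohort.
quick_params <- function(n_total = 400) cohort_params(n_total = n_total)
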