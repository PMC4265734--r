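test_that("subset enumeration is exhaustive, ordered, and guarded", {
  expect_length(enumerate_subsets(variable_panel()), 16383)
  p1 <- variable_panel(clinical = "a", snps = character(0))
  expect_identical(enumerate_subsets(p1), 1L)
  p3 <- variable_panel(clinical = c("a", "b", "c"), snps = character(0))
  expect_identical(enumerate_subsets(p3), 1:7)
  for (k in c(2, 5, 9, 16)) {
    pk <- variable_panel(clinical = paste0("v", seq_len(k)),
                         snps = character(0))
    expect_length(enumerate_subsets(pk), 2^k - 1)
  }
  expect_error(variable_panel(clinical = paste0("v", 1:21),
                              snps = character(0)), "between 1 and 20")
  expect_error(variable_panel(clinical = c("a", "a"), snps = character(0)),
               "unique")
})

test_that("subset bitmasks decode to the panel variables they index", {
  p <- variable_panel(clinical = c("a", "b", "c"), snps = "s1")
  expect_identical(subset_variables(1L, p), "a")
  expect_identical(subset_variables(8L, p), "s1")
  expect_identical(subset_variables(11L, p), c("a", "b", "s1"))
  expect_identical(subset_variables(15L, p), p$variables)
})

test_that("per-run seed derivation is deterministic, in range, and spreads", {
  s1 <- derive_seed(42, 100, 3)
  expect_identical(s1, derive_seed(42, 100, 3))
  grid <- expand.grid(subset = 1:50, rep = 1:20)
  seeds <- mapply(derive_seed, 7, grid$subset, grid$rep)
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_identical(anyDuplicated(seeds), 0L)
})

test_that("balanced sampling returns equal groups; matching respects the age tolerance", {
  set.seed(2)
  cases <- data.frame(status = factor(rep("case", 67), c("control", "case")),
                      age = rnorm(67, 69, 8))
  controls <- data.frame(status = factor(rep("control", 1919),
                                         c("control", "case")),
                         age = rnorm(1919, 64, 8))
  bal <- sample_balanced_cohort(cases, controls, seed = 5)
  expect_equal(nrow(bal), 134)
  expect_equal(as.vector(table(bal$status)), c(67L, 67L))

  mat <- sample_balanced_cohort(cases, controls, age_matched = TRUE,
                                tolerance_years = 2, seed = 5)
  expect_equal(nrow(mat), 134)
  diffs <- abs(mat$age[1:67] - mat$age[68:134])
  expect_lte(max(diffs), 2)
  # controls are sampled without replacement
  expect_identical(anyDuplicated(rownames(mat[68:134, ])), 0L)

  old_cases <- transform(cases, age = 70)
  young_controls <- transform(controls, age = 30)
  expect_error(sample_balanced_cohort(old_cases, young_controls,
                                      age_matched = TRUE, seed = 1),
               "infeasible.*70")
  expect_error(sample_balanced_cohort(controls, cases), "at least as many")
})

test_that("stratified splitting gives 94/20/20 from 134 rows and partitions exactly", {
  set.seed(3)
  rows <- data.frame(status = factor(rep(c("case", "control"), each = 67),
                                     c("control", "case")),
                     x = rnorm(134), id = 1:134)
  sp <- split_train_val_test(rows, seed = 9)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 94L, validation = 20L, test = 20L))
  ids <- sort(c(sp$train$id, sp$validation$id, sp$test$id))
  expect_identical(ids, rows$id)
  for (part in sp) {
    frac_case <- mean(part$status == "case")
    expect_lte(abs(frac_case - 0.5), 1 / nrow(part))
  }
  expect_error(split_train_val_test(rows, fractions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  tiny <- rows[1:3, ]
  expect_error(split_train_val_test(tiny, seed = 1), "empty or single-class")
})

test_that("classifier training separates separable data, is seeded, and chance-level on noise", {
  set.seed(11)
  mk <- function(n) data.frame(
    status = factor(rep(c("case", "control"), each = n / 2),
                    c("control", "case")),
    x = c(rnorm(n / 2, 3), rnorm(n / 2, -3)), z = rnorm(n))
  train <- mk(80); val <- mk(30); test <- mk(30)
  net <- train_classifier(train, val, c("x", "z"), seed = 1)
  expect_equal(error_score(net, val), 0)
  expect_equal(error_score(net, test), 0)

  net2 <- train_classifier(train, val, c("x", "z"), seed = 1)
  expect_identical(predict(net, test), predict(net2, test))

  # permuted labels: held-out error near one half
  errs <- vapply(1:12, function(i) {
    set.seed(100 + i)
    tr <- train; tr$status <- sample(tr$status)
    va <- val; va$status <- sample(va$status)
    te <- test; te$status <- sample(te$status)
    error_score(train_classifier(tr, va, c("x", "z"), seed = i), te)
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.15)
})

test_that("error score is the misclassified fraction", {
  set.seed(13)
  d <- data.frame(status = factor(rep(c("case", "control"), 10),
                                  c("control", "case")),
                  x = rnorm(20))
  net <- train_classifier(d, d, "x", seed = 2, max_iterations = 25)
  pred <- predict(net, d, type = "class")
  expect_equal(error_score(net, d),
               sum(pred != (d$status == "case")) / 20)
  expect_error(error_score(net, d[0, ]), "non-empty")
})

test_that("ensemble runs cover every subset x rep, reproduce under the master seed, and resume", {
  g <- make_planted_groups(n_cases = 30, n_controls = 90, seed = 21)
  panel <- variable_panel(clinical = c("sig", "noise1", "noise2"),
                          snps = character(0))
  runs <- run_ensemble(g$cases, g$controls, panel, reps = 2, master_seed = 7)
  expect_equal(nrow(runs), 14)
  expect_true(all(runs$error_score >= 0 & runs$error_score <= 1))
  expect_identical(runs,
                   run_ensemble(g$cases, g$controls, panel, reps = 2,
                                master_seed = 7))

  ckpt <- tempfile(fileext = ".tsv")
  partial <- run_ensemble(g$cases, g$controls, panel, reps = 2,
                          master_seed = 7, subset_cap = 3, checkpoint = ckpt)
  expect_equal(nrow(utils::read.delim(ckpt)), 6)
  resumed <- run_ensemble(g$cases, g$controls, panel, reps = 2,
                          master_seed = 7, checkpoint = ckpt)
  expect_equal(as.data.frame(resumed), as.data.frame(runs))
  unlink(ckpt)
})

test_that("variable contributions: constant errors give zero; pairing count matches the oracle", {
  panel <- variable_panel(clinical = c("a", "b", "c"), snps = character(0))
  flat <- data.frame(subset = rep(1:7, each = 2), rep = rep(1:2, 7),
                     seed = 0L, error_score = 0.25)
  for (v in c("a", "b", "c")) {
    expect_equal(variable_contribution(flat, v, panel), 0)
    expect_equal(variable_contribution(flat, v, panel,
                                       estimator = "marginal"), 0)
  }
  expect_error(variable_contribution(flat, "zz", panel), "not in panel")

  # pairing completeness: 2^(k-1) - 1 pairs per variable, by enumeration
  for (k in 2:5) {
    pk <- variable_panel(clinical = paste0("v", seq_len(k)),
                         snps = character(0))
    masks <- enumerate_subsets(pk)
    for (vi in seq_len(k)) {
      bit <- bitwShiftL(1L, vi - 1L)
      n_pairs <- sum(vapply(masks, function(m)
        bitwAnd(m, bit) == 0 && (m + bit) %in% masks, logical(1)))
      expect_equal(n_pairs, 2^(k - 1) - 1)
    }
  }
})

test_that("a planted signal variable earns the top rank and ties break by panel order", {
  g <- make_planted_groups(n_cases = 40, n_controls = 120, seed = 31)
  panel <- variable_panel(clinical = c("noise1", "sig", "noise2"),
                          snps = character(0))
  runs <- run_ensemble(g$cases, g$controls, panel, reps = 3, master_seed = 11)
  tab <- rank_variables(runs, panel)
  expect_s3_class(tab, "importance_table")
  expect_identical(tab$variable[1], "sig")
  expect_gt(tab$contribution[1], 0)
  expect_identical(sort(tab$rank), 1:3)

  # identical contributions fall back to panel order
  flat <- data.frame(subset = 1:7, rep = 1L, seed = 0L, error_score = 0.3)
  tied <- rank_variables(flat, panel)
  expect_identical(tied$variable, panel$variables)
})
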