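#' Variable panel for the exhaustive-subset ensemble
#'
#' Ordered lists of clinical variables and SNPs whose non-empty subsets the
#' ensemble enumerates. The default is the incident-glaucoma panel: seven
#' clinical variables and seven risk SNPs (k = 14, hence 16 383 subsets).
#'
#' @param clinical Character vector of clinical variable names.
#' @param snps Character vector of SNP ids.
#' @return Object of class `variable_panel` with elements `clinical`, `snps`,
#'   `variables` (their concatenation, the bit order of subset masks) and
#'   `k`.
#' @examples
#' variable_panel()$k
#' @export
variable_panel <- function(clinical = c("age", "sex", "dbp", "sbp", "vcdr",
                                        "iop", "dd"),
                           snps = oag_snp_panel()$snp_id) {
  vars <- c(clinical, snps)
  if (anyDuplicated(vars)) stop("panel variable names must be unique",
                                call. = FALSE)
  if (length(vars) < 1 || length(vars) > 20) {
    stop("panel must hold between 1 and 20 variables", call. = FALSE)
  }
  structure(list(clinical = clinical, snps = snps, variables = vars,
                 k = length(vars)),
            class = "variable_panel")
}

#' Enumerate all non-empty variable subsets
#'
#' @param panel A [variable_panel()].
#' @return Integer vector of the `2^k - 1` non-empty subset bitmasks in
#'   ascending order; bit `i` corresponds to `panel$variables[i]`.
#' @examples
#' length(enumerate_subsets(variable_panel(c("a", "b", "c"), character(0))))
#' @export
enumerate_subsets <- function(panel) {
  stopifnot(inherits(panel, "variable_panel"))
  if (panel$k > 20) stop("refusing to enumerate more than 2^20 subsets",
                         call. = FALSE)
  seq_len(2^panel$k - 1)
}

#' Decode a subset bitmask to variable names
#'
#' @param mask Subset bitmask (non-empty).
#' @param panel A [variable_panel()].
#' @return Character vector of the variables in the subset.
#' @export
subset_variables <- function(mask, panel) {
  bits <- bitwAnd(as.integer(mask), bitwShiftL(1L, 0:(panel$k - 1))) > 0
  panel$variables[bits]
}

#' Deterministic per-run seed derivation
#'
#' Folds `(master_seed, subset, rep)` through a Lehmer-style multiplicative
#' congruential step modulo 2^31 - 1, so every ensemble run gets its own
#' reproducible seed.
#'
#' @param master_seed Non-negative integer master seed.
#' @param subset,rep Run coordinates.
#' @return Integer seed in \[0, 2^31 - 1).
#' @export
derive_seed <- function(master_seed, subset, rep) {
  m <- 2147483647
  s <- master_seed %% m
  for (v in c(subset, rep)) {
    s <- ((s + v) * 48271) %% m
  }
  as.integer(s)
}

#' Balanced case-control sample, optionally age-matched
#'
#' Returns all cases plus exactly as many controls. Unmatched mode draws a
#' simple random sample of controls without replacement. Matched mode visits
#' the cases in random order and greedily assigns each the unused control
#' with the nearest age (ties broken toward the younger control); every
#' matched pair must satisfy `|case age - control age| <= tolerance_years`.
#'
#' @param cases,controls Data frames of case and control rows (matched mode
#'   requires an `age` column).
#' @param age_matched Use greedy nearest-age matching? (default `FALSE`).
#' @param tolerance_years Maximum allowed age difference for a matched pair.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Data frame of `2 * nrow(cases)` rows (cases first).
#' @export
sample_balanced_cohort <- function(cases, controls, age_matched = FALSE,
                                   tolerance_years = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cases)
  if (nrow(controls) < n) {
    stop("need at least as many controls as cases", call. = FALSE)
  }
  if (!age_matched) {
    sel <- controls[sample.int(nrow(controls), n), , drop = FALSE]
  } else {
    avail <- rep(TRUE, nrow(controls))
    pick <- integer(n)
    unmatched <- numeric(0)
    for (i in sample.int(n)) {
      d <- abs(controls$age - cases$age[i])
      d[!avail] <- Inf
      j <- which(d == min(d))
      if (length(j) > 1) j <- j[which.min(controls$age[j])]
      if (d[j] > tolerance_years) {
        unmatched <- c(unmatched, cases$age[i])
      } else {
        pick[i] <- j
        avail[j] <- FALSE
      }
    }
    if (length(unmatched)) {
      stop("age matching infeasible within ", tolerance_years,
           " years for case ages: ",
           paste(sort(unmatched), collapse = ", "), call. = FALSE)
    }
    sel <- controls[pick, , drop = FALSE]
  }
  out <- rbind(cases, sel)
  rownames(out) <- NULL
  out
}

#' Stratified train/validation/test split
#'
#' Random partition stratified by case status: within each status group the
#' part sizes are the floored fractions with the remainder handed out
#' train-first, so the parts are disjoint, exhaustive, and each holds both
#' classes (an empty or single-class part is an error).
#'
#' @param rows Data frame with a `status` column.
#' @param fractions Length-3 proportions summing to one
#'   (train, validation, test).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return List with data frames `train`, `validation`, `test`.
#' @export
split_train_val_test <- function(rows, fractions = c(0.70, 0.15, 0.15),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be three proportions summing to 1", call. = FALSE)
  }
  parts <- list(integer(0), integer(0), integer(0))
  for (cl in levels(factor(rows$status))) {
    ids <- sample(which(rows$status == cl))
    sizes <- floor(fractions * length(ids))
    rem <- length(ids) - sum(sizes)
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
    stops <- cumsum(sizes)
    starts <- c(1, head(stops, -1) + 1)
    for (p in 1:3) {
      if (sizes[p] > 0) parts[[p]] <- c(parts[[p]], ids[starts[p]:stops[p]])
    }
  }
  out <- lapply(parts, function(idx) rows[sort(idx), , drop = FALSE])
  names(out) <- c("train", "validation", "test")
  for (nm in names(out)) {
    if (nrow(out[[nm]]) == 0 ||
        length(unique(as.character(out[[nm]]$status))) < 2) {
      stop("split part '", nm, "' would be empty or single-class",
           call. = FALSE)
    }
  }
  out
}

# Design matrix for the network: factors (sex) -> 0/1, additive genotype
# columns (integral values within 0..2) kept raw, other continuous columns
# standardized with training-set statistics.
nn_design <- function(data, vars, centers = NULL, scales = NULL) {
  x <- matrix(0, nrow(data), length(vars),
              dimnames = list(NULL, vars))
  fit_stats <- is.null(centers)
  if (fit_stats) {
    centers <- stats::setNames(rep(0, length(vars)), vars)
    scales <- stats::setNames(rep(1, length(vars)), vars)
  }
  for (v in vars) {
    col <- data[[v]]
    if (is.null(col)) stop("input variable not found: ", v, call. = FALSE)
    if (is.factor(col) || is.character(col)) {
      x[, v] <- as.numeric(col == "female")
    } else {
      col <- as.numeric(col)
      genotype_like <- all(!is.na(col)) && all(col %in% c(0, 1, 2))
      if (genotype_like) {
        x[, v] <- col
      } else {
        if (fit_stats) {
          centers[v] <- mean(col)
          s <- stats::sd(col)
          scales[v] <- if (is.na(s) || s == 0) 1 else s
        }
        x[, v] <- (col - centers[v]) / scales[v]
      }
    }
  }
  list(x = x, centers = centers, scales = scales)
}

nn_forward <- function(net, x) {
  h <- stats::plogis(cbind(1, x) %*% net$w1)
  as.vector(stats::plogis(cbind(1, h) %*% net$w2))
}

#' Train the binary classifier used by the ensemble
#'
#' A feed-forward network with one hidden layer of logistic units and a
#' logistic output, fitted by [nnet::nnet()] (cross-entropy loss) in short
#' optimisation chunks. After each chunk the validation loss is evaluated;
#' the best weights are kept and training stops once the loss has failed to
#' improve for `patience` consecutive evaluations (or at `max_iterations`).
#' Continuous inputs are standardized with training-set statistics;
#' genotypes enter as raw 0/1/2 counts. Deterministic given the seed.
#'
#' @param train,validation Data frames with a `status` column and the input
#'   variables.
#' @param input_variables Character vector of input columns.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param hidden_units Hidden layer width (default 5).
#' @param decay Weight decay passed to [nnet::nnet()].
#' @param chunk_iterations Optimiser iterations per evaluation chunk.
#' @param patience Evaluations without improvement before stopping.
#' @param max_iterations Upper bound on total optimiser iterations.
#' @return Object of class `oag_net` (weights, standardization statistics,
#'   input variables, validation loss trace).
#' @export
train_classifier <- function(train, validation, input_variables, seed = NULL,
                             hidden_units = 5, decay = 1e-3,
                             chunk_iterations = 25, patience = 10,
                             max_iterations = 500) {
  if (!nrow(train) || !nrow(validation)) {
    stop("train and validation sets must be non-empty", call. = FALSE)
  }
  y <- as.numeric(train$status == "case")
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  des <- nn_design(train, input_variables)
  vdes <- nn_design(validation, input_variables, des$centers, des$scales)
  yval <- as.numeric(validation$status == "case")
  n_in <- length(input_variables)
  wts <- stats::runif((n_in + 1) * hidden_units + hidden_units + 1,
                      -0.5, 0.5)
  unpack <- function(w) {
    w1 <- matrix(w[seq_len((n_in + 1) * hidden_units)], n_in + 1,
                 hidden_units)
    w2 <- w[(n_in + 1) * hidden_units + seq_len(hidden_units + 1)]
    list(w1 = w1, w2 = w2)
  }
  val_loss <- function(w) {
    net <- unpack(w)
    p <- nn_forward(net, vdes$x)
    mean((p - yval)^2)
  }
  best_w <- wts
  best_loss <- val_loss(wts)
  trace <- best_loss
  stall <- 0
  iter <- 0
  while (iter < max_iterations && stall < patience) {
    fit <- nnet::nnet(des$x, y, size = hidden_units, Wts = wts,
                      maxit = chunk_iterations, decay = decay,
                      entropy = TRUE, trace = FALSE)
    wts <- fit$wts
    iter <- iter + chunk_iterations
    loss <- val_loss(wts)
    trace <- c(trace, loss)
    if (loss < best_loss - 1e-8) {
      best_loss <- loss
      best_w <- wts
      stall <- 0
    } else {
      stall <- stall + 1
    }
  }
  structure(c(unpack(best_w),
              list(variables = input_variables, centers = des$centers,
                   scales = des$scales, validation_loss = best_loss,
                   loss_trace = trace, iterations = iter)),
            class = "oag_net")
}

#' @export
predict.oag_net <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  des <- nn_design(newdata, object$variables, object$centers, object$scales)
  p <- nn_forward(object, des$x)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' Classification error score on a test set
#'
#' Proportion of test subjects misclassified (threshold 0.5 on the predicted
#' case probability).
#'
#' @param model A trained `oag_net`.
#' @param test Data frame with a `status` column and the model's inputs.
#' @return Error score in \[0, 1\].
#' @export
error_score <- function(model, test) {
  if (!nrow(test)) stop("test set must be non-empty", call. = FALSE)
  pred <- predict(model, test, type = "class")
  mean(pred != as.numeric(test$status == "case"))
}

#' Run the exhaustive-subset ensemble
#'
#' For every enumerated variable subset and repetition: draw a fresh balanced
#' (optionally age-matched) case-control sample, split it 70/15/15 into
#' train/validation/test, train the classifier on the subset's variables, and
#' score it on the held-out test part. Per-run seeds derive deterministically
#' from `(master_seed, subset, rep)`, so results are reproducible and
#' resumable: with `checkpoint` set, finished runs are appended to a TSV and
#' skipped on re-invocation.
#'
#' The full panel (k = 14, 16 383 subsets) at 20 repetitions is a
#' long-running mode (hours on one CPU); `subset_cap` and small `reps` give
#' a reduced mode for interactive use and testing.
#'
#' @param cases,controls Data frames of case and control rows.
#' @param panel A [variable_panel()].
#' @param reps Repetitions per subset (default 20).
#' @param age_matched,tolerance_years Passed to [sample_balanced_cohort()].
#' @param master_seed Master seed for per-run seed derivation.
#' @param subset_cap Optional limit on the number of subsets (ascending
#'   bitmask order) for reduced-scale runs.
#' @param checkpoint Optional path of an append-only runs TSV enabling
#'   resume.
#' @param fractions Train/validation/test fractions.
#' @param verbose Print progress about every 1000 runs?
#' @param ... Training knobs passed to [train_classifier()].
#' @return Data frame of class `subset_runs`: `subset`, `rep`, `seed`,
#'   `error_score`.
#' @export
run_ensemble <- function(cases, controls, panel, reps = 20,
                         age_matched = FALSE, tolerance_years = 2,
                         master_seed = 1, subset_cap = NULL,
                         checkpoint = NULL, fractions = c(0.70, 0.15, 0.15),
                         verbose = FALSE, ...) {
  subsets <- enumerate_subsets(panel)
  if (!is.null(subset_cap)) {
    subsets <- subsets[seq_len(min(subset_cap, length(subsets)))]
  }
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.delim(checkpoint)
  }
  rows <- vector("list", length(subsets) * reps)
  i <- 0
  n_run <- 0
  for (s in subsets) {
    vars <- subset_variables(s, panel)
    for (r in seq_len(reps)) {
      i <- i + 1
      if (!is.null(done) && any(done$subset == s & done$rep == r)) {
        j <- which(done$subset == s & done$rep == r)[1]
        rows[[i]] <- done[j, c("subset", "rep", "seed", "error_score")]
        next
      }
      run_seed <- derive_seed(master_seed, s, r)
      set.seed(run_seed)
      bal <- sample_balanced_cohort(cases, controls, age_matched,
                                    tolerance_years)
      parts <- split_train_val_test(bal, fractions)
      net <- train_classifier(parts$train, parts$validation, vars, ...)
      err <- error_score(net, parts$test)
      row <- data.frame(subset = s, rep = r, seed = run_seed,
                        error_score = err)
      rows[[i]] <- row
      if (!is.null(checkpoint)) {
        utils::write.table(row, checkpoint, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names =
                             !file.exists(checkpoint), append =
                             file.exists(checkpoint))
      }
      n_run <- n_run + 1
      if (verbose && n_run %% 1000 == 0) {
        message(sprintf("[ensemble] %d runs complete (subset %d of %d)",
                        n_run, match(s, subsets), length(subsets)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subset_runs", "data.frame")
  out
}

#' Contribution of a variable to ensemble prediction
#'
#' Error scores are first averaged over repetitions within each subset. The
#' default paired estimator then averages `error(S) - error(S + v)` over all
#' subset pairs that differ only by the variable; the marginal estimator
#' instead takes the difference of mean error between subsets excluding and
#' including the variable. Positive contributions mean the variable reduces
#' prediction error.
#'
#' @param runs A `subset_runs` data frame from [run_ensemble()].
#' @param variable Panel variable name.
#' @param panel The [variable_panel()] the runs were produced with.
#' @param estimator `"paired"` (default) or `"marginal"`.
#' @return Numeric contribution (mean reduction in error score).
#' @export
variable_contribution <- function(runs, variable, panel,
                                  estimator = c("paired", "marginal")) {
  estimator <- match.arg(estimator)
  vi <- match(variable, panel$variables)
  if (is.na(vi)) stop("variable not in panel: ", variable, call. = FALSE)
  bit <- bitwShiftL(1L, vi - 1L)
  per <- stats::aggregate(error_score ~ subset, data = runs, FUN = mean)
  has <- bitwAnd(per$subset, bit) > 0
  if (!any(has) || !any(!has)) {
    stop("runs must cover subsets both with and without ", variable,
         call. = FALSE)
  }
  if (estimator == "marginal") {
    return(mean(per$error_score[!has]) - mean(per$error_score[has]))
  }
  without <- per[!has, , drop = FALSE]
  partner <- match(without$subset + bit, per$subset)
  ok <- !is.na(partner)
  if (!any(ok)) {
    stop("no paired subsets available for ", variable, call. = FALSE)
  }
  mean(without$error_score[ok] - per$error_score[partner[ok]])
}

#' Rank panel variables by ensemble contribution
#'
#' Sorts contributions in descending order; ties are broken by panel order.
#'
#' @inheritParams variable_contribution
#' @param age_matched Flag recorded in the output (purely descriptive).
#' @return Data frame of class `importance_table`: `rank`, `variable`,
#'   `contribution`, `age_matched`.
#' @export
rank_variables <- function(runs, panel, estimator = c("paired", "marginal"),
                           age_matched = NA) {
  estimator <- match.arg(estimator)
  contrib <- vapply(panel$variables, function(v)
    variable_contribution(runs, v, panel, estimator), numeric(1))
  ord <- order(-contrib, seq_along(contrib))
  out <- data.frame(rank = seq_along(ord),
                    variable = panel$variables[ord],
                    contribution = unname(contrib[ord]),
                    age_matched = age_matched,
                    stringsAsFactors = FALSE)
  class(out) <- c("importance_table", "data.frame")
  out
}
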