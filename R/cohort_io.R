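#' Write a cohort as tab-separated text
#'
#' Fixed header `pid status sex age iop vcdr dd sbp dbp` followed by one
#' column per SNP holding risk-allele counts 0/1/2 (`NA` for missing).
#'
#' @param cohort An `oag_cohort` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  base <- intersect(c("pid", "status", "sex", "age", "iop", "vcdr", "dd",
                      "sbp", "dbp"), names(cohort))
  snps <- setdiff(names(cohort), c("pid", "status", "sex", "age", "iop",
                                   "vcdr", "dd", "sbp", "dbp"))
  utils::write.table(cohort[, c(base, snps), drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a cohort in PLINK-style additive-coded ".raw" layout
#'
#' Columns `FID IID PAT MAT SEX PHENOTYPE` then one dosage column per SNP,
#' named `<snp_id>_<risk_allele>` (the counted allele is the reported risk
#' allele). `SEX` is 1 = male, 2 = female; `PHENOTYPE` is 1 = control,
#' 2 = case. Output is space-separated.
#'
#' @param cohort An `oag_cohort` data frame.
#' @param path Output file path.
#' @param snp_info SNP panel providing the counted (risk) allele per SNP.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(cohort, path, snp_info = oag_snp_panel()) {
  snps <- intersect(snp_info$snp_id, names(cohort))
  out <- data.frame(
    FID = cohort$pid, IID = cohort$pid, PAT = 0L, MAT = 0L,
    SEX = ifelse(cohort$sex == "female", 2L, 1L),
    PHENOTYPE = ifelse(cohort$status == "case", 2L, 1L),
    stringsAsFactors = FALSE
  )
  for (s in snps) {
    allele <- snp_info$risk_allele[snp_info$snp_id == s]
    out[[paste0(s, "_", allele)]] <- cohort[[s]]
  }
  utils::write.table(out, path, sep = " ", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a cohort file
#'
#' Supports the package's TSV dialect (see [write_cohort()]) and the
#' PLINK-style additive ".raw" dialect (see [write_plink_raw()]). Genotypes
#' are validated to \{0, 1, 2, NA\}; in the `.raw` dialect, dosages are
#' accepted only when within 1e-6 of an integer. Dosage columns whose counted
#' allele is the *other* allele for a known SNP are flipped so that all
#' genotypes count the reported risk allele.
#'
#' @param path Input file path.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @param snp_info SNP panel used for risk-allele orientation of `.raw`
#'   dosage columns.
#' @return An `oag_cohort` data frame.
#' @export
read_cohort <- function(path, dialect = c("tsv", "plink_raw"),
                        snp_info = oag_snp_panel()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    dat <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(pid = "character"))
    req <- c("pid", "status", "sex")
    if (!all(req %in% names(dat))) {
      stop("malformed header: expected at least columns ",
           paste(req, collapse = ", "), call. = FALSE)
    }
    snps <- setdiff(names(dat), c("pid", "status", "sex", "age", "iop",
                                  "vcdr", "dd", "sbp", "dbp"))
    bad_status <- setdiff(unique(dat$status), c("case", "control"))
    if (length(bad_status)) {
      stop("invalid status value(s): ", paste(bad_status, collapse = ", "),
           call. = FALSE)
    }
    dat$status <- factor(dat$status, levels = c("control", "case"))
    dat$sex <- factor(dat$sex, levels = c("male", "female"))
  } else {
    dat0 <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                              colClasses = c(FID = "character",
                                             IID = "character"))
    req <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!identical(names(dat0)[seq_len(6)], req)) {
      stop("malformed header: expected PLINK .raw columns ",
           paste(req, collapse = " "), call. = FALSE)
    }
    snp_cols <- setdiff(names(dat0), req)
    dat <- data.frame(
      pid = dat0$IID,
      status = factor(ifelse(dat0$PHENOTYPE == 2L, "case", "control"),
                      levels = c("control", "case")),
      sex = factor(ifelse(dat0$SEX == 2L, "female", "male"),
                   levels = c("male", "female")),
      stringsAsFactors = FALSE
    )
    for (col in snp_cols) {
      us <- regexpr("_[^_]*$", col)
      snp <- substr(col, 1, us - 1)
      counted <- substr(col, us + 1, nchar(col))
      x <- dat0[[col]]
      off <- which(!is.na(x) & abs(x - round(x)) > 1e-6)
      if (length(off)) {
        stop(sprintf("non-integer dosage %.6g in column '%s', row %d",
                     x[off[1]], col, off[1]), call. = FALSE)
      }
      x <- as.integer(round(x))
      info <- snp_info[snp_info$snp_id == snp, , drop = FALSE]
      if (nrow(info) == 1 && counted == info$other_allele) {
        x <- 2L - x  # orient to the risk allele
      }
      dat[[snp]] <- x
    }
    snps <- setdiff(names(dat), c("pid", "status", "sex"))
  }
  if (anyDuplicated(dat$pid)) {
    stop("duplicated pid: ",
         paste(unique(dat$pid[duplicated(dat$pid)]), collapse = ", "),
         call. = FALSE)
  }
  for (s in snps) {
    g <- dat[[s]]
    bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)))
    if (length(bad)) {
      stop(sprintf("genotype value %s out of range in column '%s', row %d",
                   g[bad[1]], s, bad[1]), call. = FALSE)
    }
    dat[[s]] <- as.integer(g)
  }
  class(dat) <- c("oag_cohort", "data.frame")
  dat
}

#' Write cohort generation parameters to a YAML file
#'
#' Sections `cohort`, `covariates`, `snps`, `model` mirror the
#' [cohort_params()] structure. The file shipped at
#' `system.file("extdata", "incident_oag_params.yaml", package = "oagrisk")` holds the
#' package defaults.
#'
#' @param params A [cohort_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_params <- function(params, path) {
  stopifnot(inherits(params, "cohort_params"))
  obj <- list(
    cohort = list(n_total = params$n_total,
                  target_incidence = params$target_incidence,
                  female_frac_case = params$female_frac_case,
                  female_frac_control = params$female_frac_control,
                  missing_rate = params$missing_rate),
    covariates = lapply(seq_len(nrow(params$covariates)), function(i)
      as.list(params$covariates[i, , drop = FALSE])),
    snps = lapply(seq_len(nrow(params$snp_info)), function(i)
      as.list(params$snp_info[i, , drop = FALSE])),
    model = list(intercept = params$intercept,
                 vcdr_scale = params$vcdr_scale,
                 betas = as.list(params$logistic_betas))
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read cohort generation parameters from a YAML file
#'
#' @param path YAML file written by [write_cohort_params()].
#' @return A [cohort_params()] object.
#' @export
read_cohort_params <- function(path) {
  obj <- yaml::read_yaml(path)
  covs <- do.call(rbind, lapply(obj$covariates, as.data.frame))
  snps <- do.call(rbind, lapply(obj$snps, as.data.frame))
  covs$upper[is.na(covs$upper) | covs$upper == ".inf"] <- Inf
  cohort_params(
    n_total = obj$cohort$n_total,
    covariates = covs,
    female_frac_case = obj$cohort$female_frac_case,
    female_frac_control = obj$cohort$female_frac_control,
    snp_info = snps,
    logistic_betas = unlist(obj$model$betas),
    intercept = obj$model$intercept,
    target_incidence = obj$cohort$target_incidence,
    vcdr_scale = obj$model$vcdr_scale,
    missing_rate = obj$cohort$missing_rate
  )
}
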