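#' Remove samples with short or missing follow-up
#'
#' Drops samples whose overall-survival time is missing or shorter than
#' `min_days`. The boundary is kept: a sample followed for exactly
#' `min_days` days survives the filter ("less than 30 days" removed).
#'
#' @param surv A [survival_table()].
#' @param min_days Minimum follow-up in days (default 30).
#' @return The filtered `surv_table`, original row order preserved.
#' @export
filter_samples <- function(surv, min_days = 30) {
  stopifnot(inherits(surv, "surv_table"))
  keep <- !is.na(surv$os_days) & surv$os_days >= min_days
  out <- surv[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("empty cohort: no sample has os_days >= ", min_days)
  rownames(out) <- NULL
  out
}

#' Transcripts-per-million normalisation
#'
#' Converts raw counts to TPM: per sample, each transcript's count is
#' divided by its effective length (kb) and the resulting rates are scaled
#' to sum to 1e6.
#'
#' @param expr An `expr_matrix` with `scale = "counts"` and `lengths` set.
#' @return An `expr_matrix` with `scale = "TPM"`; every column sums to 1e6.
#' @export
tpm_normalize <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$scale != "counts")
    stop("tpm_normalize() requires scale = \"counts\", got \"", expr$scale, "\"")
  if (is.null(expr$lengths)) {
    stop("effective lengths missing for transcript(s): ",
         paste(utils::head(rownames(expr$values), 3), collapse = ", "),
         if (nrow(expr$values) > 3) ", ...")
  }
  rates <- expr$values / expr$lengths
  totals <- colSums(rates)
  if (any(totals == 0)) {
    stop("zero total length-normalised count in sample(s): ",
         paste(colnames(expr$values)[totals == 0], collapse = ", "))
  }
  tpm <- sweep(rates, 2, totals, "/") * 1e6
  expression_matrix(tpm, biotype = expr$biotype, scale = "TPM")
}

#' log2(TPM + 1) transform
#'
#' @param expr An `expr_matrix` with `scale = "TPM"` (or `"RPM"`).
#' @return An `expr_matrix` with `scale = "log2p1"`.
#' @export
log2_tpm <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$scale %in% c("TPM", "RPM"))
    stop("log2_tpm() expects TPM or RPM input, got \"", expr$scale, "\"")
  expression_matrix(log2(expr$values + 1), biotype = expr$biotype,
                    scale = "log2p1")
}

#' Low-expression transcript filter
#'
#' An mRNA is excluded iff its count is below `mrna_min` in every sample;
#' a lncRNA iff below `lnc_min` in every sample. A single sample above the
#' threshold rescues the transcript. Other biotypes are always retained.
#'
#' @param expr_counts An `expr_matrix` with `scale = "counts"`.
#' @param mrna_min,lnc_min Count thresholds (defaults 1 and 0.5).
#' @return Character vector of retained transcript ids, input order.
#' @export
filter_low_expression <- function(expr_counts, mrna_min = 1, lnc_min = 0.5) {
  stopifnot(inherits(expr_counts, "expr_matrix"))
  if (expr_counts$scale != "counts")
    stop("filter_low_expression() requires scale = \"counts\"")
  v <- expr_counts$values
  bt <- expr_counts$biotype
  rmax <- apply(v, 1, max)
  drop <- (bt == "mRNA" & rmax < mrna_min) |
          (bt == "lncRNA" & rmax < lnc_min)
  rownames(v)[!drop]
}

#' miRNA zero-fraction filter and reads-per-million normalisation
#'
#' Drops miRNAs with a zero count in more than half of the samples
#' (strictly more: zero in exactly 50% is retained), then normalises the
#' remaining counts to RPM per sample.
#'
#' @param mirna_counts An `expr_matrix` with `scale = "counts"` and
#'   miRNA rows.
#' @param max_zero_frac Maximum tolerated zero fraction (default 0.5).
#' @return An `expr_matrix` with `scale = "RPM"`; columns sum to 1e6.
#' @export
preprocess_mirna <- function(mirna_counts, max_zero_frac = 0.5) {
  stopifnot(inherits(mirna_counts, "expr_matrix"))
  if (mirna_counts$scale != "counts")
    stop("preprocess_mirna() requires scale = \"counts\"")
  v <- mirna_counts$values
  zero_frac <- rowMeans(v == 0)
  keep <- zero_frac <= max_zero_frac
  if (!any(keep))
    stop("all miRNAs removed by the zero-fraction filter")
  v <- v[keep, , drop = FALSE]
  totals <- colSums(v)
  if (any(totals == 0))
    stop("zero total count in sample(s): ",
         paste(colnames(v)[totals == 0], collapse = ", "))
  rpm <- sweep(v, 2, totals, "/") * 1e6
  expression_matrix(rpm, biotype = mirna_counts$biotype[keep], scale = "RPM")
}

#' Random train/validation split with a covariate-balance report
#'
#' Partitions the cohort at random (seeded, reproducible) and reports, for
#' every clinical covariate present, a between-arm test p-value: Wilcoxon
#' rank-sum for numeric covariates, chi-square for categorical ones.
#' Degenerate covariates (constant, or all-missing) are flagged rather
#' than tested.
#'
#' @param surv A `surv_table` (already survival-filtered).
#' @param train_fraction Fraction of samples assigned to the training arm.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list of class `cohort_split`: `train_ids`, `validation_ids`,
#'   `seed`, and `balance` (data.frame: variable, test, p, note).
#' @export
split_cohort <- function(surv, train_fraction, seed) {
  stopifnot(inherits(surv, "surv_table"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must lie in (0, 1)")
  n <- nrow(surv)
  n_train <- round(n * train_fraction)
  n_train <- max(1L, min(n - 1L, n_train))
  ids <- surv$sample_id
  train_ids <- with_local_seed(seed, sort(sample(ids, n_train)))
  validation_ids <- setdiff(ids, train_ids)
  arm <- ifelse(ids %in% train_ids, "train", "validation")

  balance <- lapply(c("os_days", "age", "gender", "stage", "grade"), function(v) {
    if (!v %in% names(surv)) return(NULL)
    x <- surv[[v]]
    ok <- !is.na(x)
    if (sum(ok) == 0L || length(unique(x[ok])) < 2L)
      return(data.frame(variable = v, test = NA_character_, p = NA_real_,
                        note = "degenerate", stringsAsFactors = FALSE))
    if (is.numeric(x)) {
      p <- stats::wilcox.test(x[ok] ~ factor(arm[ok]))$p.value
      data.frame(variable = v, test = "wilcoxon", p = p, note = "",
                 stringsAsFactors = FALSE)
    } else {
      tab <- table(x[ok], arm[ok])
      p <- suppressWarnings(stats::chisq.test(tab)$p.value)
      data.frame(variable = v, test = "chisq", p = p, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  balance <- do.call(rbind, balance)
  structure(list(train_ids = train_ids, validation_ids = validation_ids,
                 seed = seed, balance = balance),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("cohort_split: %d train / %d validation (seed %d)\n",
              length(x$train_ids), length(x$validation_ids), x$seed))
  if (!is.null(x$balance)) {
    cat("covariate balance (between-arm p-values):\n")
    print(x$balance, row.names = FALSE)
  }
  invisible(x)
}
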