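#' Expression matrix with biotype annotation and scale flag
#'
#' Light-weight container for a transcripts x samples abundance table.
#' Rows carry a biotype label (`lncRNA`, `mRNA`, `miRNA` or `other`) and
#' the whole matrix carries a scale flag so downstream steps can refuse
#' inputs on the wrong scale (e.g. TPM normalisation requires raw counts).
#'
#' @param values Numeric matrix, transcripts in rows (rownames = transcript
#'   ids), samples in columns (colnames = sample ids). Values must be finite
#'   and non-negative.
#' @param biotype Character vector of per-transcript biotypes, recycled if
#'   length 1. Allowed values: `"lncRNA"`, `"mRNA"`, `"miRNA"`, `"other"`.
#' @param scale One of `"counts"`, `"TPM"`, `"RPM"`, `"log2p1"`.
#' @param lengths Optional per-transcript effective length in kilobases;
#'   required by [tpm_normalize()] when `scale = "counts"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `biotype`, `scale` and `lengths`.
#' @export
expression_matrix <- function(values, biotype = "other",
                              scale = c("counts", "TPM", "RPM", "log2p1"),
                              lengths = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("`values` must have rownames (transcript ids)")
  if (is.null(colnames(values)))
    stop("`values` must have colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicated transcript ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in `values`")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0))
    stop("expression values must be non-negative")
  if (length(biotype) == 1L) biotype <- rep(biotype, nrow(values))
  if (length(biotype) != nrow(values))
    stop("`biotype` must have one entry per transcript")
  bad <- setdiff(unique(biotype), c("lncRNA", "mRNA", "miRNA", "other"))
  if (length(bad))
    stop("unknown biotype(s): ", paste(bad, collapse = ", "))
  names(biotype) <- rownames(values)
  if (!is.null(lengths)) {
    if (length(lengths) != nrow(values))
      stop("`lengths` must have one entry per transcript")
    if (any(!is.finite(lengths)) || any(lengths <= 0))
      stop("effective lengths must be positive and finite")
    names(lengths) <- rownames(values)
  }
  structure(list(values = values, biotype = biotype, scale = scale,
                 lengths = lengths),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  tab <- table(x$biotype)
  cat("biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by transcripts and/or samples
#'
#' @param x An `expr_matrix`.
#' @param transcripts,samples Character vectors of row/column ids to keep
#'   (order preserved as given); `NULL` keeps everything.
#' @return An `expr_matrix` restricted to the requested rows and columns.
#' @export
subset_expression <- function(x, transcripts = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(transcripts)) transcripts <- rownames(x$values)
  if (is.null(samples)) samples <- colnames(x$values)
  missing_t <- setdiff(transcripts, rownames(x$values))
  if (length(missing_t))
    stop("transcripts not found: ", paste(utils::head(missing_t, 5), collapse = ", "))
  missing_s <- setdiff(samples, colnames(x$values))
  if (length(missing_s))
    stop("samples not found: ", paste(utils::head(missing_s, 5), collapse = ", "))
  expression_matrix(x$values[transcripts, samples, drop = FALSE],
                    biotype = x$biotype[transcripts],
                    scale = x$scale,
                    lengths = if (!is.null(x$lengths)) x$lengths[transcripts])
}

#' Per-sample survival table with clinical covariates
#'
#' @param sample_id Character vector of unique sample ids.
#' @param os_days Overall-survival time in days (non-negative; `NA` allowed
#'   and removed by [filter_samples()]).
#' @param event Event indicator, 0 = censored, 1 = death. Must be 0/1
#'   wherever `os_days` is present.
#' @param age,gender,stage,grade Optional clinical covariates; `gender`
#'   should use levels `male`/`female`, `stage` and `grade` are kept as
#'   given and recoded only inside [multivariate_cox()].
#'
#' @return A `data.frame` of class `surv_table`.
#' @export
survival_table <- function(sample_id, os_days, event,
                           age = NA_real_, gender = NA_character_,
                           stage = NA_character_, grade = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample ids")
  if (any(os_days < 0, na.rm = TRUE))
    stop("`os_days` must be non-negative")
  ok <- !is.na(os_days)
  if (any(!(event[ok] %in% c(0, 1))))
    stop("`event` must be 0 or 1 wherever `os_days` is present")
  out <- data.frame(sample_id = sample_id,
                    os_days = as.numeric(os_days),
                    event = as.numeric(event),
                    age = age, gender = gender,
                    stage = stage, grade = grade,
                    stringsAsFactors = FALSE)
  class(out) <- c("surv_table", "data.frame")
  out
}

as_surv_table <- function(df) {
  need <- c("sample_id", "os_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  survival_table(df$sample_id, df$os_days, df$event,
                 age = if ("age" %in% names(df)) df$age else NA_real_,
                 gender = if ("gender" %in% names(df)) df$gender else NA_character_,
                 stage = if ("stage" %in% names(df)) df$stage else NA_character_,
                 grade = if ("grade" %in% names(df)) df$grade else NA_character_)
}

surv_object <- function(surv) {
  stopifnot(inherits(surv, "surv_table"))
  if (anyNA(surv$os_days))
    stop("survival table contains missing times; run filter_samples() first")
  survival::Surv(surv$os_days, surv$event)
}

#' Read an expression table from TSV/CSV
#'
#' Expects a header row of sample ids and transcript ids in the first
#' column. Biotypes arrive either via a `biotype` column in the file or a
#' two-column mapping file (`transcript_id`, `biotype`), replacing GTF
#' annotation.
#'
#' @param path Path to the expression table (TSV or CSV, by extension).
#' @param biotype_map Optional path to a two-column TSV mapping transcript
#'   id to biotype; unmapped transcripts get biotype `"other"`.
#' @param scale Scale flag of the stored values (see [expression_matrix()]).
#' @param lengths_col Optional name of a column holding effective lengths
#'   in kb.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, biotype_map = NULL, scale = "counts",
                            lengths_col = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  biotype <- "other"
  if ("biotype" %in% names(df)) {
    biotype <- df$biotype
    df$biotype <- NULL
  }
  lengths <- NULL
  if (!is.null(lengths_col) && lengths_col %in% names(df)) {
    lengths <- df[[lengths_col]]
    df[[lengths_col]] <- NULL
  }
  if (!is.null(biotype_map)) {
    map <- utils::read.table(biotype_map, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             col.names = c("transcript_id", "biotype"))
    biotype <- map$biotype[match(rownames(df), map$transcript_id)]
    biotype[is.na(biotype)] <- "other"
  }
  expression_matrix(as.matrix(df), biotype = biotype, scale = scale,
                    lengths = lengths)
}

#' Read a clinical table from TSV/CSV
#'
#' Requires columns `sample_id`, `os_days`, `event`; picks up `age`,
#' `gender`, `stage`, `grade` when present.
#'
#' @param path Path to the clinical table.
#' @return A `surv_table`.
#' @export
read_clinical <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as_surv_table(df)
}

#' Write an expression matrix / clinical table to TSV
#'
#' @param x An `expr_matrix` or `surv_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  if (inherits(x, "expr_matrix")) {
    df <- data.frame(transcript_id = rownames(x$values),
                     biotype = unname(x$biotype),
                     x$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
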