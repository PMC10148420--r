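#' Enumerate all unordered lncRNA pairs
#'
#' Forms every unordered pair from `k` ids, in canonical orientation
#' (first member lexicographically smaller) and deterministic
#' lexicographic order. The count is k(k-1)/2.
#'
#' @param lnc_ids Character vector of at least two distinct ids.
#' @return A data.frame with columns `a`, `b` (a < b lexicographically).
#' @export
enumerate_pairs <- function(lnc_ids) {
  lnc_ids <- unique(as.character(lnc_ids))
  if (length(lnc_ids) < 2) stop("need at least 2 lncRNA ids to form pairs")
  ids <- sort(lnc_ids)
  idx <- utils::combn(length(ids), 2)
  data.frame(a = ids[idx[1, ]], b = ids[idx[2, ]], stringsAsFactors = FALSE)
}

pair_keys <- function(pairs) paste(pairs$a, pairs$b, sep = "|")

#' Build the binary within-sample REO matrix
#'
#' For pair i = (a, b) and sample j, `X[i, j] = 1` iff expr(a) < expr(b)
#' in that sample, and 0 otherwise — ties fall into the `>=` state. The
#' matrix is rank-based: any strictly monotone per-sample transform of the
#' expression values leaves it unchanged.
#'
#' @param expr An `expr_matrix` (any scale).
#' @param pairs A data.frame with columns `a`, `b` (e.g. from
#'   [enumerate_pairs()], or a risk model's `terms` in stored orientation).
#' @return A list of class `reo_matrix`: `pairs`, `X` (pairs x samples 0/1
#'   integer matrix, rownames `"a|b"`), `sample_ids`.
#' @export
build_reo_matrix <- function(expr, pairs) {
  stopifnot(inherits(expr, "expr_matrix"))
  stopifnot(is.data.frame(pairs), all(c("a", "b") %in% names(pairs)))
  members <- unique(c(pairs$a, pairs$b))
  missing <- setdiff(members, rownames(expr$values))
  if (length(missing))
    stop("lncRNA(s) missing from expression: ",
         paste(missing, collapse = ", "))
  v <- expr$values
  X <- (v[pairs$a, , drop = FALSE] < v[pairs$b, , drop = FALSE]) * 1L
  storage.mode(X) <- "integer"
  rownames(X) <- pair_keys(pairs)
  structure(list(pairs = pairs[, c("a", "b")], X = X,
                 sample_ids = colnames(v)),
            class = "reo_matrix")
}

#' @export
print.reo_matrix <- function(x, ...) {
  cat(sprintf("reo_matrix: %d pairs x %d samples\n",
              nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' REO prevalence of each pair
#'
#' @param reo A `reo_matrix`.
#' @return Numeric vector: per pair, the fraction of samples in state 1.
#' @export
reo_prevalence <- function(reo) {
  stopifnot(inherits(reo, "reo_matrix"))
  rowMeans(reo$X)
}

#' Prevalence filter on REO pairs
#'
#' Removes pairs whose REO-1 prevalence is strictly below `low` or
#' strictly above `high`; the boundaries are retained. Near-constant pairs
#' carry no within-cohort reversal information.
#'
#' @param reo A `reo_matrix`.
#' @param low,high Prevalence bounds (defaults 0.20 and 0.80).
#' @return The filtered `reo_matrix`.
#' @export
prevalence_filter <- function(reo, low = 0.20, high = 0.80) {
  stopifnot(inherits(reo, "reo_matrix"))
  if (!(low >= 0 && low < high && high <= 1))
    stop("need 0 <= low < high <= 1")
  prev <- reo_prevalence(reo)
  keep <- prev >= low & prev <= high
  if (!any(keep))
    warning("no pair survives the prevalence filter")
  structure(list(pairs = reo$pairs[keep, , drop = FALSE],
                 X = reo$X[keep, , drop = FALSE],
                 sample_ids = reo$sample_ids),
            class = "reo_matrix")
}

# Univariate Cox fit of survival on a single binary covariate.
# Returns c(beta, se, z, p) or NULL on failure.
cox_single <- function(x, y, ties = "breslow") {
  if (length(unique(x)) < 2) return(NULL)
  fit <- tryCatch(
    survival::coxph(y ~ x, ties = ties),
    error = function(e) NULL, warning = function(w) {
      # refit, keeping the result but noting possible non-convergence /
      # separation; infinite coefficients are rejected below
      suppressWarnings(survival::coxph(y ~ x, ties = ties))
    })
  if (is.null(fit)) return(NULL)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15) return(NULL)
  z <- beta / se
  c(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Univariate Cox screening of REO pairs
#'
#' Fits, for every pair, a Cox proportional-hazards model with the pair's
#' binary REO state as the single covariate (Breslow tie handling by
#' default) and keeps pairs whose Wald p-value is below `alpha`.
#' Non-convergent or degenerate pairs are flagged not-kept with a reason
#' and the screen continues.
#'
#' @param reo A `reo_matrix` (typically prevalence-filtered).
#' @param surv A `surv_table` covering the REO samples.
#' @param alpha Wald p-value threshold (default 0.005, strict `<`).
#' @param ties Tie handling for the partial likelihood, `"breslow"`
#'   (default) or `"efron"`.
#' @return A data.frame of class `pair_screen`: per pair `a`, `b`,
#'   `prevalence`, `beta`, `hr`, `z`, `p`, `kept_after_prevalence`
#'   (always TRUE for pairs present), `kept_after_cox`, `reason`.
#' @export
univariate_cox_screen <- function(reo, surv, alpha = 0.005,
                                  ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(inherits(reo, "reo_matrix"), inherits(surv, "surv_table"))
  missing <- setdiff(reo$sample_ids, surv$sample_id)
  if (length(missing))
    stop("survival table does not cover sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  surv <- surv[match(reo$sample_ids, surv$sample_id), , drop = FALSE]
  if (sum(surv$event, na.rm = TRUE) < 1)
    stop("no events in the cohort; Cox screening impossible")
  y <- surv_object(surv)
  prev <- reo_prevalence(reo)
  res <- matrix(NA_real_, nrow(reo$X), 4,
                dimnames = list(NULL, c("beta", "se", "z", "p")))
  reason <- rep("", nrow(reo$X))
  for (i in seq_len(nrow(reo$X))) {
    fit <- cox_single(reo$X[i, ], y, ties = ties)
    if (is.null(fit)) {
      reason[i] <- if (length(unique(reo$X[i, ])) < 2)
        "constant covariate" else "non-convergent or separated"
    } else {
      res[i, ] <- fit
    }
  }
  out <- data.frame(reo$pairs,
                    prevalence = unname(prev),
                    beta = res[, "beta"],
                    hr = exp(res[, "beta"]),
                    z = res[, "z"],
                    p = res[, "p"],
                    kept_after_prevalence = TRUE,
                    kept_after_cox = !is.na(res[, "p"]) & res[, "p"] < alpha,
                    reason = reason,
                    stringsAsFactors = FALSE)
  rownames(out) <- rownames(reo$X)
  class(out) <- c("pair_screen", "data.frame")
  out
}

#' Subset a REO matrix to a set of pairs
#'
#' @param reo A `reo_matrix`.
#' @param keys Character vector of `"a|b"` pair keys (row names), e.g.
#'   `rownames(screen)[screen$kept_after_cox]`.
#' @return The restricted `reo_matrix`.
#' @export
subset_pairs <- function(reo, keys) {
  stopifnot(inherits(reo, "reo_matrix"))
  missing <- setdiff(keys, rownames(reo$X))
  if (length(missing))
    stop("pair(s) not in REO matrix: ", paste(missing, collapse = ", "))
  idx <- match(keys, rownames(reo$X))
  structure(list(pairs = reo$pairs[idx, , drop = FALSE],
                 X = reo$X[idx, , drop = FALSE],
                 sample_ids = reo$sample_ids),
            class = "reo_matrix")
}
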