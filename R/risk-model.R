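#' Construct a pair-based Cox risk model
#'
#' A risk model is an ordered list of lncRNA pairs with Cox coefficients
#' and a classification threshold on the linear risk score
#' `score = sum_i beta_i * X_i`, where `X_i` is the pair's binary REO
#' state in the model's stored orientation (`X = 1` means the first-listed
#' member is expressed below the second).
#'
#' @param terms A data.frame with columns `a`, `b`, `beta`. Orientation is
#'   stored as given — it is not canonicalised, so published signatures
#'   keep their printed pair order.
#' @param threshold Risk-score cutoff; samples at or above it are
#'   classified high-risk. May be `NA` until set by [youden_threshold()].
#' @param horizon_years ROC horizon (years) used for thresholding.
#' @param provenance `"fitted"` or `"published"`.
#' @return A list of class `risk_model`.
#' @export
risk_model <- function(terms, threshold = NA_real_, horizon_years = 5,
                       provenance = c("fitted", "published")) {
  provenance <- match.arg(provenance)
  stopifnot(is.data.frame(terms), all(c("a", "b", "beta") %in% names(terms)))
  if (nrow(terms) < 1) stop("a risk model needs at least one pair term")
  if (any(terms$a == terms$b)) stop("pair members must differ")
  if (anyDuplicated(pair_keys(terms)))
    stop("duplicated pairs in `terms`")
  if (!all(is.finite(terms$beta))) stop("coefficients must be finite")
  if (!is.na(threshold) && !is.finite(threshold))
    stop("`threshold` must be finite or NA")
  terms <- terms[, c("a", "b", "beta")]
  rownames(terms) <- NULL
  structure(list(terms = terms, threshold = threshold,
                 horizon_years = horizon_years, provenance = provenance),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("risk_model (%s): %d pair terms, threshold %s, horizon %g y\n",
              x$provenance, nrow(x$terms),
              if (is.na(x$threshold)) "unset" else format(x$threshold),
              x$horizon_years))
  eq <- paste(sprintf("%+.4f x %s|%s", x$terms$beta, x$terms$a, x$terms$b),
              collapse = " ")
  cat("risk score =", sub("^\\+", "", eq), "\n")
  invisible(x)
}

#' Serialize / read a risk model as JSON
#'
#' @param model A `risk_model`.
#' @param path File path.
#' @return `path` invisibly / a `risk_model`.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  jsonlite::write_json(
    list(terms = model$terms, threshold = model$threshold,
         horizon_years = model$horizon_years, provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(as.data.frame(x$terms),
             threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
             horizon_years = x$horizon_years,
             provenance = x$provenance)
}

#' The published 11-pair hepatocellular carcinoma model
#'
#' Loads the published 11-pair lncRNA REO signature for hepatocellular
#' carcinoma (22 distinct lncRNAs) with its risk-score threshold of 0.025
#' on the 5-year ROC. Pair orientation follows the published names: the
#' first-listed lncRNA is the `a` member and `X = 1` means a < b within
#' the sample.
#'
#' @return A `risk_model` with `provenance = "published"`.
#' @export
published_model <- function() {
  path <- system.file("extdata", "published_model_hcc.json",
                      package = "reopair", mustWork = TRUE)
  read_risk_model(path)
}

#' LASSO-Cox selection of candidate pairs
#'
#' Fits an L1-penalised Cox path on the binary REO covariates and picks
#' the penalty with the smallest cross-validated partial-likelihood
#' deviance (tenfold by default). Covariates are standardized internally
#' during fitting; coefficients are reported on the original 0/1 scale.
#'
#' @param reo A `reo_matrix` restricted to the screened pairs.
#' @param surv A `surv_table` covering the REO samples.
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return A list of class `lasso_path`: `lambda`, `cvm`, `cvsd`, `nzero`
#'   (active-set size along the path), `lambda_min`, `selected` (pair
#'   keys with nonzero coefficients), `coef` (named, nonzero only),
#'   `seed`, `foldid`.
#' @export
lasso_cox_select <- function(reo, surv, n_folds = 10, seed = 1L) {
  stopifnot(inherits(reo, "reo_matrix"), inherits(surv, "surv_table"))
  surv <- surv[match(reo$sample_ids, surv$sample_id), , drop = FALSE]
  if (anyNA(surv$sample_id))
    stop("survival table does not cover all REO samples")
  y <- surv_object(surv)
  if (sum(surv$event) < n_folds)
    stop("need at least `n_folds` events for cross-validation")
  x <- t(reo$X)
  colnames(x) <- rownames(reo$X)
  n <- nrow(x)
  foldid <- with_local_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", type.measure = "deviance",
                          foldid = foldid, standardize = TRUE)
  lambda_min <- cv$lambda.min
  cf <- as.matrix(stats::coef(cv, s = lambda_min))[, 1]
  if (all(cf == 0)) {
    nz <- cv$nzero
    ok <- which(nz >= 1)
    if (length(ok) == 0) stop("no lambda on the grid yields a nonzero coefficient")
    warning("all coefficients zero at the CV-optimal lambda; ",
            "falling back to the closest lambda with a nonzero coefficient")
    lambda_min <- max(cv$lambda[ok])
    cf <- as.matrix(stats::coef(cv, s = lambda_min))[, 1]
  }
  sel <- names(cf)[cf != 0]
  structure(list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 nzero = cv$nzero, lambda_min = lambda_min, selected = sel,
                 coef = cf[cf != 0], seed = seed, foldid = foldid),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf(
    "lasso_path: %d lambdas, lambda* = %.4g, %d pair(s) selected (seed %d)\n",
    length(x$lambda), x$lambda_min, length(x$selected), x$seed))
  invisible(x)
}

# Cox AIC on the partial likelihood: -2 logPL + 2 * n_terms
cox_aic <- function(fit) stats::extractAIC(fit)[2]

#' Stepwise AIC refinement of a candidate pair set
#'
#' Bidirectional stepwise search over the candidate pairs, starting from
#' the full model: at each step the single-term addition or deletion with
#' the largest AIC decrease is accepted, stopping at a local minimum
#' (AIC = -2 logPL + 2 |terms|). The final unpenalised Cox fit supplies
#' the coefficients; the classification threshold is left unset (see
#' [youden_threshold()]). If the full starting fit fails, the search
#' falls back to forward selection from the empty model with a warning.
#'
#' @param reo A `reo_matrix` containing the candidate pairs.
#' @param surv A `surv_table` covering the REO samples.
#' @param candidate_pairs Character vector of `"a|b"` pair keys (e.g.
#'   `lasso_path$selected`); defaults to every pair in `reo`.
#' @param horizon_years Stored on the returned model (default 5).
#' @return A `risk_model` (`provenance = "fitted"`, threshold `NA`), with
#'   attributes `aic` (final) and `aic_start` (full/empty starting model).
#' @export
stepwise_aic_cox <- function(reo, surv, candidate_pairs = NULL,
                             horizon_years = 5) {
  stopifnot(inherits(reo, "reo_matrix"), inherits(surv, "surv_table"))
  if (is.null(candidate_pairs)) candidate_pairs <- rownames(reo$X)
  if (length(candidate_pairs) < 1) stop("candidate set is empty")
  reo <- subset_pairs(reo, candidate_pairs)
  surv <- surv[match(reo$sample_ids, surv$sample_id), , drop = FALSE]
  y <- surv_object(surv)
  dat <- as.data.frame(t(reo$X))
  vars <- sprintf("P%03d", seq_len(ncol(dat)))
  key_of <- stats::setNames(rownames(reo$X), vars)
  names(dat) <- vars
  dat$.y <- y
  env <- new.env(parent = environment())
  assign("dat", dat, envir = env)
  full_fml <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")),
                                env = env)
  null_fml <- stats::as.formula(".y ~ 1", env = env)
  full_fit <- tryCatch(survival::coxph(full_fml, data = dat),
                       error = function(e) NULL)
  scope <- list(lower = null_fml, upper = full_fml)
  if (!is.null(full_fit)) {
    start <- full_fit
  } else {
    warning("full candidate model failed to converge; ",
            "falling back to forward selection from the empty model")
    start <- survival::coxph(null_fml, data = dat)
  }
  aic_start <- cox_aic(start)
  step_fit <- suppressWarnings(
    MASS::stepAIC(start, scope = scope, direction = "both", trace = 0))
  kept_vars <- names(stats::coef(step_fit))
  if (length(kept_vars) == 0) {
    # stepwise emptied the model: keep the single best candidate instead,
    # so the pipeline always yields a scorable model
    warning("stepwise search removed every term; keeping the single best pair")
    aics <- vapply(vars, function(v) {
      cox_aic(survival::coxph(stats::as.formula(paste(".y ~", v)), data = dat))
    }, numeric(1))
    kept_vars <- vars[which.min(aics)]
    step_fit <- survival::coxph(
      stats::as.formula(paste(".y ~", kept_vars)), data = dat)
  }
  keys <- unname(key_of[kept_vars])
  idx <- match(keys, rownames(reo$X))
  terms <- data.frame(a = reo$pairs$a[idx], b = reo$pairs$b[idx],
                      beta = unname(stats::coef(step_fit)),
                      stringsAsFactors = FALSE)
  out <- risk_model(terms, horizon_years = horizon_years,
                    provenance = "fitted")
  attr(out, "aic") <- cox_aic(step_fit)
  attr(out, "aic_start") <- aic_start
  out
}

#' Compute linear REO risk scores
#'
#' `score_j = sum_i beta_i * X_ij`, with `X` evaluated in the model's
#' stored pair orientation. Accepts either a prebuilt `reo_matrix` (whose
#' rows may be stored in either orientation — reversed rows are flipped)
#' or a raw expression matrix, in which case the REO states are computed
#' on the fly. Being rank-based, scores are invariant to strictly
#' monotone per-sample transforms of expression.
#'
#' @param model A `risk_model`.
#' @param input An `expr_matrix` or `reo_matrix`.
#' @return Named numeric vector of risk scores (one per sample).
#' @export
compute_risk_scores <- function(model, input) {
  stopifnot(inherits(model, "risk_model"))
  if (inherits(input, "expr_matrix")) {
    missing <- setdiff(unique(c(model$terms$a, model$terms$b)),
                       rownames(input$values))
    if (length(missing))
      stop("lncRNA(s) required by the model are missing: ",
           paste(missing, collapse = ", "))
    reo <- build_reo_matrix(input, model$terms)
    X <- reo$X
  } else if (inherits(input, "reo_matrix")) {
    keys <- pair_keys(model$terms)
    rev_keys <- paste(model$terms$b, model$terms$a, sep = "|")
    have <- keys %in% rownames(input$X)
    have_rev <- rev_keys %in% rownames(input$X)
    if (!all(have | have_rev))
      stop("pair(s) required by the model are missing from the REO matrix: ",
           paste(keys[!(have | have_rev)], collapse = ", "))
    X <- matrix(0L, length(keys), length(input$sample_ids),
                dimnames = list(keys, input$sample_ids))
    X[have, ] <- input$X[keys[have], , drop = FALSE]
    # a reversed row stores 1{b < a}; the model's orientation needs 1{a < b}
    X[!have, ] <- 1L - input$X[rev_keys[!have], , drop = FALSE]
  } else {
    stop("`input` must be an expr_matrix or a reo_matrix")
  }
  scores <- as.numeric(crossprod(X, model$terms$beta))
  names(scores) <- colnames(X)
  scores
}

#' Youden-optimal risk threshold on the time-dependent ROC
#'
#' Builds the cumulative/dynamic time-dependent ROC at the horizon and
#' returns the score cutoff maximizing the Youden index
#' `J(c) = sensitivity(c) + specificity(c) - 1` over all observed score
#' cutoffs; ties are broken toward the smaller (more sensitive) cutoff.
#'
#' @param scores Named risk scores (from [compute_risk_scores()]).
#' @param surv A `surv_table` covering the scored samples.
#' @param horizon_years ROC horizon in years (default 5).
#' @param estimator ROC estimator, `"KM"` (default) or `"NNE"` (see
#'   [time_dependent_roc()]).
#' @return The threshold (numeric), with attribute `youden` (the maximal
#'   J) and `roc` (the `timed_roc` object).
#' @export
youden_threshold <- function(scores, surv, horizon_years = 5,
                             estimator = c("KM", "NNE")) {
  estimator <- match.arg(estimator)
  roc <- time_dependent_roc(scores, surv, horizon_years,
                            estimator = estimator)
  J <- roc$sens_raw + roc$spec_raw - 1
  best <- which(J == max(J))
  thr <- min(roc$cutoffs[best])
  attr(thr, "youden") <- max(J)
  attr(thr, "roc") <- roc
  thr
}

#' Classify samples by risk score
#'
#' @param scores Named numeric risk scores.
#' @param threshold Score cutoff; samples with `score >= threshold` are
#'   high-risk (the boundary is high-risk).
#' @return A data.frame of class `risk_assignment`: `sample_id`,
#'   `risk_score`, `group` (factor low/high).
#' @export
classify <- function(scores, threshold) {
  if (is.na(threshold)) stop("`threshold` is not set")
  out <- data.frame(sample_id = names(scores),
                    risk_score = as.numeric(scores),
                    group = factor(ifelse(scores >= threshold,
                                          "high", "low"),
                                   levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("risk_assignment", "data.frame")
  out
}

#' End-to-end signature fit: LASSO, stepwise AIC, Youden threshold
#'
#' Convenience wrapper chaining [lasso_cox_select()],
#' [stepwise_aic_cox()] and [youden_threshold()] on a screened REO
#' matrix.
#'
#' @inheritParams lasso_cox_select
#' @param horizon_years ROC horizon for thresholding (default 5).
#' @return A `risk_model` with the threshold set; attribute `lasso` holds
#'   the `lasso_path`.
#' @export
fit_risk_model <- function(reo, surv, n_folds = 10, seed = 1L,
                           horizon_years = 5) {
  path <- lasso_cox_select(reo, surv, n_folds = n_folds, seed = seed)
  model <- stepwise_aic_cox(reo, surv, candidate_pairs = path$selected,
                            horizon_years = horizon_years)
  scores <- compute_risk_scores(model, reo)
  thr <- youden_threshold(scores, surv, horizon_years = horizon_years)
  model$threshold <- as.numeric(thr)
  attr(model, "lasso") <- path
  model
}
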