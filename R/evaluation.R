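#' Kaplan-Meier curves and log-rank test for risk groups
#'
#' @param assignment A `risk_assignment` from [classify()].
#' @param surv A `surv_table` covering the assigned samples.
#' @return A list: `fit` (a `survfit` object with one stratum per risk
#'   group), `chisq`, `p` (two-group log-rank).
#' @export
km_logrank <- function(assignment, surv) {
  stopifnot(inherits(assignment, "risk_assignment"),
            inherits(surv, "surv_table"))
  surv <- surv[match(assignment$sample_id, surv$sample_id), , drop = FALSE]
  if (anyNA(surv$sample_id))
    stop("survival table does not cover all assigned samples")
  group <- assignment$group
  if (any(table(group) == 0) || nlevels(droplevels(group)) < 2)
    stop("both risk groups must be nonempty")
  y <- surv_object(surv)
  fit <- survival::survfit(y ~ group)
  sd <- survival::survdiff(y ~ group)
  list(fit = fit, chisq = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

# Kaplan-Meier survival probability at time t, optionally weighted
# (weights enter the risk set and event counts).
km_at <- function(time, event, t, w = NULL) {
  if (is.null(w)) w <- rep(1, length(time))
  keep <- w > 0
  time <- time[keep]; event <- event[keep]; w <- w[keep]
  if (!length(time)) return(NA_real_)
  ut <- sort(unique(time[event == 1 & time <= t]))
  s <- 1
  for (tt in ut) {
    atrisk <- sum(w[time >= tt])
    d <- sum(w[time == tt & event == 1])
    if (atrisk > 0) s <- s * (1 - d / atrisk)
  }
  s
}

#' Time-dependent (cumulative/dynamic) ROC at a fixed horizon
#'
#' Cases are samples with an event by the horizon, controls are samples
#' surviving past it; censoring before the horizon is handled through the
#' Kaplan-Meier estimator of survival within marker strata (`"KM"`,
#' default) or through nearest-neighbour smoothing of the joint
#' marker-survival distribution (`"NNE"`, span `0.25 * n^(-0.20)` on the
#' marker percentile scale). At each observed score cutoff `c`, a sample
#' is test-positive iff its score is `>= c`; sensitivity and specificity
#' follow Bayes' rule from the estimated joint distribution. The AUC is
#' the trapezoidal integral over the raw (1-specificity, sensitivity)
#' points. With no censoring before the horizon, the KM estimator reduces
#' exactly to the empirical (Mann-Whitney) ROC.
#'
#' The raw KM-estimated curve need not be monotone; an isotonic cleanup
#' is applied for curve reporting only (`sensitivity`/`specificity`),
#' while the AUC and the Youden search use the raw values
#' (`sens_raw`/`spec_raw`).
#'
#' @param scores Named numeric risk scores (names = sample ids).
#' @param surv A `surv_table` covering the scored samples.
#' @param horizon_years Horizon in years (365.25 days/year).
#' @param estimator `"KM"` or `"NNE"`.
#' @param span NNE span; default `0.25 * n^(-0.20)`.
#' @return A list of class `timed_roc`: `horizon` (years), `cutoffs`
#'   (sorted observed scores), `sens_raw`, `spec_raw`, `sensitivity`,
#'   `specificity` (isotonic-cleaned), `auc`, `estimator`.
#' @export
time_dependent_roc <- function(scores, surv, horizon_years,
                               estimator = c("KM", "NNE"), span = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(surv, "surv_table"))
  if (is.null(names(scores)))
    stop("`scores` must be named by sample id")
  surv <- surv[match(names(scores), surv$sample_id), , drop = FALSE]
  if (anyNA(surv$sample_id))
    stop("survival table does not cover all scored samples")
  t_h <- horizon_years * DAYS_PER_YEAR
  time <- surv$os_days; event <- surv$event
  n <- length(scores)
  if (sum(event == 1 & time <= t_h) < 1)
    stop("no event before the horizon; ROC is degenerate (no cases)")
  if (sum(time > t_h) < 1)
    stop("no subject at risk past the horizon; ROC is degenerate (no controls)")
  cutoffs <- sort(unique(as.numeric(scores)))

  if (estimator == "KM") {
    s_all <- km_at(time, event, t_h)
    if (s_all <= 0 || s_all >= 1)
      stop("degenerate overall survival at the horizon (S = ", s_all, ")")
    sens <- spec <- numeric(length(cutoffs))
    for (i in seq_along(cutoffs)) {
      pos <- scores >= cutoffs[i]
      p_c <- mean(pos)
      s_c <- km_at(time[pos], event[pos], t_h)
      tp <- (1 - s_c) * p_c / (1 - s_all)
      fp <- s_c * p_c / s_all
      sens[i] <- min(max(tp, 0), 1)
      spec[i] <- min(max(1 - fp, 0), 1)
    }
  } else {
    if (is.null(span)) span <- 0.25 * n^(-0.20)
    pct <- rank(scores, ties.method = "average") / n
    # Akritas nearest-neighbour estimator: per-subject weighted KM over a
    # symmetric neighbourhood on the marker percentile scale
    s_i <- vapply(seq_len(n), function(i) {
      w <- as.numeric(abs(pct - pct[i]) <= span)
      km_at(time, event, t_h, w = w)
    }, numeric(1))
    s_marg <- mean(s_i)
    if (s_marg <= 0 || s_marg >= 1)
      stop("degenerate smoothed survival at the horizon")
    sens <- spec <- numeric(length(cutoffs))
    for (i in seq_along(cutoffs)) {
      pos <- scores >= cutoffs[i]
      s_joint <- sum(s_i[pos]) / n          # P(M >= c, T > t)
      p_c <- mean(pos)
      tp <- (p_c - s_joint) / (1 - s_marg)
      fp <- s_joint / s_marg
      sens[i] <- min(max(tp, 0), 1)
      spec[i] <- min(max(1 - fp, 0), 1)
    }
  }

  # signed trapezoid along the cutoff-ordered ROC path: cutoffs descend
  # from (0,0) towards (1,1); anchors close the curve at both ends
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  # isotonic cleanup for reporting: sensitivity non-increasing and
  # specificity non-decreasing in the cutoff
  k <- length(cutoffs)
  sens_iso <- rev(stats::isoreg(seq_len(k), rev(sens))$yf)
  spec_iso <- stats::isoreg(seq_len(k), spec)$yf
  structure(list(horizon = horizon_years, cutoffs = cutoffs,
                 sens_raw = sens, spec_raw = spec,
                 sensitivity = pmin(pmax(sens_iso, 0), 1),
                 specificity = pmin(pmax(spec_iso, 0), 1),
                 auc = auc, estimator = estimator),
            class = "timed_roc")
}

#' @export
print.timed_roc <- function(x, ...) {
  cat(sprintf("timed_roc (%s): horizon %g y, AUC = %.3f (%d cutoffs)\n",
              x$estimator, x$horizon, x$auc, length(x$cutoffs)))
  invisible(x)
}

#' @export
plot.timed_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 main = sprintf("%g-year ROC (AUC = %.3f)", x$horizon, x$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Multivariate Cox test of risk-score independence
#'
#' Fits a multivariable Cox model (Breslow ties) of overall survival on
#' the risk score (continuous, or the high/low group when a
#' `risk_assignment` is supplied) together with the clinical covariates
#' present in the survival table: age (continuous, years), gender
#' (reference `female`), stage and grade (each collapsed to an early
#' vs. late binary by default: stage I-II vs III-IV, grade G1-G2 vs
#' G3-G4). Collinear covariates are dropped with a warning.
#'
#' @param risk Named numeric scores or a `risk_assignment`.
#' @param surv A `surv_table` with clinical covariates.
#' @param collapse_stage Collapse stage/grade to binaries (default TRUE);
#'   set FALSE to keep the original levels as factors.
#' @return A data.frame of class `independence_report`: `term`, `hr`,
#'   `lower`, `upper` (95% Wald CI), `p`.
#' @export
multivariate_cox <- function(risk, surv, collapse_stage = TRUE) {
  stopifnot(inherits(surv, "surv_table"))
  if (inherits(risk, "risk_assignment")) {
    ids <- risk$sample_id
    risk_var <- stats::setNames(as.numeric(risk$group == "high"), ids)
    risk_name <- "risk_group_high"
  } else {
    if (is.null(names(risk))) stop("`risk` scores must be named by sample id")
    ids <- names(risk)
    risk_var <- risk
    risk_name <- "risk_score"
  }
  surv <- surv[match(ids, surv$sample_id), , drop = FALSE]
  if (anyNA(surv$sample_id))
    stop("survival table does not cover all risk samples")
  dat <- data.frame(risk = as.numeric(risk_var))
  names(dat) <- risk_name
  if (!all(is.na(surv$age))) dat$age <- surv$age
  if (!all(is.na(surv$gender)))
    dat$gender <- factor(surv$gender, levels = c("female", "male"))
  if (!all(is.na(surv$stage))) {
    dat$stage <- if (collapse_stage)
      factor(ifelse(grepl("III|IV", surv$stage), "III-IV", "I-II"),
             levels = c("I-II", "III-IV"))
    else factor(surv$stage)
  }
  if (!all(is.na(surv$grade))) {
    dat$grade <- if (collapse_stage)
      factor(ifelse(grepl("3|4", surv$grade), "G3-G4", "G1-G2"),
             levels = c("G1-G2", "G3-G4"))
    else factor(surv$grade)
  }
  constant <- vapply(dat, function(x) length(unique(x[!is.na(x)])) < 2,
                     logical(1))
  if (any(constant)) {
    warning("constant covariate(s) dropped: ",
            paste(names(dat)[constant], collapse = ", "))
    dat <- dat[, !constant, drop = FALSE]
  }
  n_events <- sum(surv$event)
  if (n_events < ncol(dat))
    warning("fewer events (", n_events, ") than covariates (", ncol(dat), ")")
  y <- surv_object(surv)
  fit <- survival::coxph(y ~ ., data = dat, ties = "breslow")
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    dropped <- names(cf)[is.na(cf)]
    warning("collinear covariate(s) dropped: ", paste(dropped, collapse = ", "))
  }
  keep <- !is.na(cf)
  se <- sqrt(diag(stats::vcov(fit)))[keep]
  cf <- cf[keep]
  z <- cf / se
  out <- data.frame(term = names(cf),
                    hr = exp(cf),
                    lower = exp(cf - 1.959964 * se),
                    upper = exp(cf + 1.959964 * se),
                    p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("independence_report", "data.frame")
  out
}
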