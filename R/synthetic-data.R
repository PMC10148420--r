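#' Configuration for a synthetic HCC-like cohort
#'
#' Defines the statistical structure the pipeline assumes: two latent
#' sample subtypes with distinct panel-gene profiles, subtype-differential
#' lncRNAs, planted prognostic lncRNA pairs whose binary within-sample
#' ordering (REO) drives the hazard under a proportional-hazards model,
#' independent right-censoring, and clinical covariates. Defaults mirror a
#' TCGA-LIHC-sized cohort: 343 usable samples, a 40-gene pyroptosis panel,
#' 104 subtype-differential lncRNAs, a minority subtype of about 15%, and
#' roughly 60% censoring.
#'
#' @param n_samples Number of samples drawn (before the short-follow-up
#'   filter; see `early_frac`).
#' @param n_lnc Number of lncRNAs.
#' @param n_prg Number of panel (pyroptosis-related) genes.
#' @param n_de_lnc Number of lncRNAs differentially expressed between the
#'   two subtypes (absolute log2 mean difference > 1). Planted-pair
#'   members are drawn from this set so that recovery is testable through
#'   the differential-expression funnel.
#' @param n_planted_pairs Number of prognostic REO pairs planted.
#' @param beta_true Log-hazard coefficient per planted pair (length
#'   `n_planted_pairs`).
#' @param prevalence_range Interval within (0,1) from which each planted
#'   pair's REO prevalence is drawn.
#' @param baseline_hazard Baseline event rate in events/day.
#' @param censor_rate Target fraction of censored samples.
#' @param subtype_prob Probability of the minority subtype (subtype 1).
#' @param noise_sd Per-gene noise SD on the log2 abundance scale.
#' @param early_frac Fraction of samples given follow-up under 30 days or
#'   missing survival, to exercise [filter_samples()].
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 343,
                       n_lnc = 300,
                       n_prg = 40,
                       n_de_lnc = 104,
                       n_planted_pairs = 5,
                       beta_true = c(1.2, -1.2, 1.0, -1.0, 1.5),
                       prevalence_range = c(0.3, 0.7),
                       baseline_hazard = 1e-4,
                       censor_rate = 0.6,
                       subtype_prob = 35 / 240,
                       noise_sd = 1,
                       early_frac = 0.075,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_lnc = as.integer(n_lnc),
              n_prg = as.integer(n_prg), n_de_lnc = as.integer(n_de_lnc),
              n_planted_pairs = as.integer(n_planted_pairs),
              beta_true = as.numeric(beta_true),
              prevalence_range = as.numeric(prevalence_range),
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              subtype_prob = subtype_prob, noise_sd = noise_sd,
              early_frac = early_frac, seed = as.integer(seed))
  with(cfg, {
    if (n_samples < 1 || n_lnc < 2 || n_prg < 1)
      stop("all counts must be positive")
    if (n_de_lnc < 0 || n_de_lnc > n_lnc)
      stop("`n_de_lnc` must lie in [0, n_lnc]")
    if (n_planted_pairs > n_lnc / 2)
      stop("`n_planted_pairs` must not exceed n_lnc/2")
    if (length(beta_true) != n_planted_pairs)
      stop("`beta_true` must have length n_planted_pairs")
    if (length(prevalence_range) != 2 ||
        !(prevalence_range[1] < prevalence_range[2]) ||
        prevalence_range[1] <= 0 || prevalence_range[2] >= 1)
      stop("`prevalence_range` must be a non-empty interval within (0, 1)")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("`censor_rate` must lie in [0, 1)")
    if (subtype_prob <= 0 || subtype_prob >= 1)
      stop("`subtype_prob` must lie in (0, 1)")
    if (baseline_hazard <= 0) stop("`baseline_hazard` must be positive")
    if (noise_sd <= 0) stop("`noise_sd` must be positive")
    if (early_frac < 0 || early_frac >= 1)
      stop("`early_frac` must lie in [0, 1)")
  })
  structure(cfg, class = "sim_config")
}

# Solve for the upper limit of Uniform(0, cmax) censoring so that the
# expected censored fraction over the cohort's hazards equals `target`.
censor_upper_limit <- function(lambda, target) {
  if (target <= 0) return(Inf)
  pcens <- function(cmax) mean((1 - exp(-lambda * cmax)) / (lambda * cmax)) - target
  # P(censored) decreases from 1 (cmax -> 0) to 0 (cmax -> Inf)
  lo <- 1e-6; hi <- 1 / min(lambda)
  while (pcens(hi) > 0) hi <- hi * 10
  stats::uniroot(pcens, c(lo, hi), tol = 1e-8)$root
}

#' Generate a synthetic cohort with planted prognostic REO pairs
#'
#' Draws subtype labels, panel-gene and lncRNA abundances on the log2
#' scale, exponential event times under a proportional-hazards model whose
#' linear predictor is the sum of `beta_true` over the planted pairs'
#' binary REO states, and uniform censoring calibrated to the requested
#' censor rate. Planted-pair expression is constructed with a guaranteed
#' margin of at least `3 * noise_sd` between the two members, so that
#' recomputing the REO state from the expression values reproduces the
#' recorded truth exactly (and no ties occur).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`:
#'   \describe{
#'     \item{expression}{`expr_matrix`, scale `log2p1`, lncRNA + panel rows.}
#'     \item{survival}{[survival_table()] with age/gender/stage/grade.}
#'     \item{truth}{list: `pairs` (data.frame a, b, beta), `Z` (pairs x
#'       samples planted REO states), `subtype` (per-sample 1/2), `de_ids`,
#'       `panel_ids`.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    n <- cfg$n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    subtype <- ifelse(stats::runif(n) < cfg$subtype_prob, 1L, 2L)

    lnc_ids <- sprintf("lnc%04d", seq_len(cfg$n_lnc))
    prg_ids <- sprintf("PRG%02d", seq_len(cfg$n_prg))

    # gene-specific baselines: log-normal across genes for realistic
    # between-gene ordering on the log2 scale
    base_lnc <- stats::rnorm(cfg$n_lnc, mean = 4, sd = 1.5)
    base_prg <- stats::rnorm(cfg$n_prg, mean = 6, sd = 1.5)

    # panel genes: subtype-specific means separated by >= 2 * noise_sd
    prg_shift <- sample(c(-1, 1), cfg$n_prg, replace = TRUE) *
      stats::runif(cfg$n_prg, 2.5 * cfg$noise_sd, 3.5 * cfg$noise_sd)
    prg <- matrix(stats::rnorm(cfg$n_prg * n, sd = cfg$noise_sd),
                  cfg$n_prg, n) + base_prg
    prg <- prg + outer(prg_shift, as.numeric(subtype == 1L))

    # DE lncRNAs: between-subtype log2 mean difference > 1
    de_ids <- lnc_ids[seq_len(cfg$n_de_lnc)]
    de_shift <- numeric(cfg$n_lnc)
    if (cfg$n_de_lnc > 0) {
      de_shift[seq_len(cfg$n_de_lnc)] <-
        sample(c(-1, 1), cfg$n_de_lnc, replace = TRUE) *
        stats::runif(cfg$n_de_lnc, 1.3, 2.5)
    }
    lnc <- matrix(stats::rnorm(cfg$n_lnc * n, sd = cfg$noise_sd),
                  cfg$n_lnc, n) + base_lnc
    lnc <- lnc + outer(de_shift, as.numeric(subtype == 1L))

    # planted pairs: members taken from the DE set first so that pairs
    # survive the differential-expression funnel in end-to-end runs
    m <- cfg$n_planted_pairs
    Z <- matrix(0L, 0, n)
    pairs_truth <- data.frame(a = character(0), b = character(0),
                              beta = numeric(0), stringsAsFactors = FALSE)
    if (m > 0) {
      member_idx <- seq_len(2 * m)   # within lnc_ids; DE slots come first
      prevalence <- stats::runif(m, cfg$prevalence_range[1],
                                 cfg$prevalence_range[2])
      Z <- matrix(0L, m, n)
      for (i in seq_len(m)) {
        ia <- member_idx[2 * i - 1]; ib <- member_idx[2 * i]
        # both members of a planted pair share one subtype shift (a pair
        # member that fell in the DE block keeps a DE effect > 1 without
        # the two members' shifts cancelling)
        if (ia <= cfg$n_de_lnc || ib <= cfg$n_de_lnc) {
          shared <- if (ia <= cfg$n_de_lnc) de_shift[ia] else de_shift[ib]
          de_shift[c(ia, ib)] <- shared
        }
        Z[i, ] <- as.integer(stats::runif(n) < prevalence[i])
        # shared centre carries the subtype shift for both members; the
        # pair state sets the ordering with a margin >= 3 * noise_sd, so
        # the REO recomputed from expression equals Z with no ties
        centre <- (base_lnc[ia] + base_lnc[ib]) / 2 +
          de_shift[ia] * as.numeric(subtype == 1L) +
          stats::rnorm(n, sd = cfg$noise_sd)
        half_gap <- (3 * cfg$noise_sd +
                       abs(stats::rnorm(n, sd = cfg$noise_sd))) / 2
        sgn <- ifelse(Z[i, ] == 1L, 1, -1)   # Z=1  <=>  a < b
        lnc[ia, ] <- centre - sgn * half_gap
        lnc[ib, ] <- centre + sgn * half_gap
      }
      pairs_truth <- data.frame(a = lnc_ids[member_idx[seq(1, 2 * m, 2)]],
                                b = lnc_ids[member_idx[seq(2, 2 * m, 2)]],
                                beta = cfg$beta_true,
                                stringsAsFactors = FALSE)
      rownames(Z) <- paste(pairs_truth$a, pairs_truth$b, sep = "|")
      colnames(Z) <- sample_ids
    }

    # survival: exponential PH with linear predictor sum(beta * Z)
    lp <- if (m > 0) as.numeric(crossprod(Z, cfg$beta_true)) else numeric(n)
    lambda <- cfg$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = lambda)
    if (cfg$censor_rate > 0) {
      cmax <- censor_upper_limit(lambda, cfg$censor_rate)
      t_cens <- stats::runif(n, 0, cmax)
    } else {
      t_cens <- rep(Inf, n)
    }
    os_days <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    # exponential times are continuous; keep a strictly positive floor
    os_days <- pmax(os_days, 1e-3)

    # a small fraction of early / missing follow-up for the 30-day filter
    n_early <- round(cfg$early_frac * n)
    if (n_early > 0) {
      idx <- sample(n, n_early)
      half <- idx[seq_len(floor(n_early / 2))]
      os_days[half] <- NA_real_
      event[half] <- NA_integer_
      late <- setdiff(idx, half)
      os_days[late] <- stats::runif(length(late), 1, 29)
      event[late] <- as.integer(stats::runif(length(late)) < 0.5)
    }

    age <- round(stats::rnorm(n, 60, 10))
    gender <- sample(c("male", "female"), n, replace = TRUE,
                     prob = c(0.68, 0.32))
    stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                    prob = c(0.5, 0.25, 0.2, 0.05))
    grade <- sample(c("G1", "G2", "G3", "G4"), n, replace = TRUE,
                    prob = c(0.15, 0.5, 0.3, 0.05))

    values <- rbind(lnc, prg)
    rownames(values) <- c(lnc_ids, prg_ids)
    colnames(values) <- sample_ids
    # log2-scale abundances; a global shift (order-preserving, so REO and
    # log2 differences are untouched) keeps the matrix non-negative
    if (min(values) < 0) values <- values - min(values)

    expression <- expression_matrix(values,
                                    biotype = c(rep("lncRNA", cfg$n_lnc),
                                                rep("mRNA", cfg$n_prg)),
                                    scale = "log2p1")
    survival <- survival_table(sample_ids, os_days, event, age = age,
                               gender = gender, stage = stage, grade = grade)
    structure(list(expression = expression, survival = survival,
                   truth = list(pairs = pairs_truth, Z = Z,
                                subtype = stats::setNames(subtype, sample_ids),
                                de_ids = de_ids, panel_ids = prg_ids),
                   config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d samples, %d lncRNAs + %d panel genes, %d planted pair(s)\n",
    ncol(x$expression$values), x$config$n_lnc, x$config$n_prg,
    nrow(x$truth$pairs)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the three standard input tables: expression TSV, clinical TSV
#' and truth JSON.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  write_table_tsv(cohort$survival, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$Z <- if (nrow(truth$Z)) apply(truth$Z, 1, as.integer, simplify = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
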