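# expression matrix in which every model pair is in a chosen state
expr_for_states <- function(model, state) {
  ids <- unique(c(model$terms$a, model$terms$b))
  v <- matrix(0, length(ids), length(state),
              dimnames = list(ids, names(state)))
  for (j in seq_along(state)) {
    for (i in seq_len(nrow(model$terms))) {
      lo <- if (state[j] == 1) model$terms$a[i] else model$terms$b[i]
      hi <- if (state[j] == 1) model$terms$b[i] else model$terms$a[i]
      v[lo, j] <- 1; v[hi, j] <- 2
    }
  }
  expression_matrix(v, biotype = "lncRNA", scale = "TPM")
}

test_that("the published signature carries 11 pairs over 22 lncRNAs and scores by coefficient sums", {
  m <- published_model()
  expect_identical(nrow(m$terms), 11L)
  expect_length(unique(c(m$terms$a, m$terms$b)), 22L)
  expect_identical(m$provenance, "published")
  expect_equal(m$threshold, 0.025)

  e <- expr_for_states(m, c(all1 = 1, all0 = 0))
  s <- compute_risk_scores(m, e)
  expect_equal(unname(s["all1"]), sum(m$terms$beta), tolerance = 1e-12)
  expect_equal(unname(s["all1"]), 2.1542, tolerance = 1e-12)
  expect_equal(unname(s["all0"]), 0)

  # linearity: negating every coefficient negates the scores
  m_neg <- risk_model(transform(m$terms, beta = -beta), threshold = 0,
                      provenance = "fitted")
  expect_equal(unname(compute_risk_scores(m_neg, e)), -unname(s))
})

test_that("classification puts the threshold boundary in the high-risk group", {
  s <- c(a = 0.025, b = 0.0249, c = -1)
  asg <- classify(s, 0.025)
  expect_identical(as.character(asg$group), c("high", "low", "low"))
  expect_true(all(classify(s, -Inf)$group == "high"))
  expect_error(classify(s, NA_real_), "not set")
})

test_that("scores from a REO matrix honour stored orientation, including reversed rows", {
  m <- published_model()
  e <- expr_for_states(m, c(s1 = 1, s2 = 0))
  direct <- compute_risk_scores(m, e)
  # canonical enumeration stores many pairs in the opposite orientation
  canon <- enumerate_pairs(unique(c(m$terms$a, m$terms$b)))
  reo <- build_reo_matrix(e, canon)
  via_reo <- compute_risk_scores(m, reo)
  expect_equal(via_reo[names(direct)], direct, tolerance = 1e-12)
  expect_error(compute_risk_scores(m, subset_pairs(reo, "AC005083.1|CASC9")),
               "missing")
})

test_that("risk scores are invariant under monotone per-sample transforms", {
  co <- generate_cohort(quick_config(seed = 55, n_samples = 60))
  m <- risk_model(co$truth$pairs, threshold = 0)
  e <- co$expression
  s0 <- compute_risk_scores(m, e)
  e_exp <- expression_matrix(2^e$values - 1 + 5, biotype = e$biotype,
                             scale = "TPM")
  e_rank <- expression_matrix(apply(e$values, 2, rank),
                              biotype = e$biotype, scale = "TPM")
  expect_equal(compute_risk_scores(m, e_exp), s0)
  expect_equal(compute_risk_scores(m, e_rank), s0)
})

test_that("LASSO-Cox selects planted pairs among null decoys and is seeded", {
  contains_all <- vapply(1:5, function(s) {
    co <- generate_cohort(sim_config(n_samples = 400, n_lnc = 110,
                                     n_de_lnc = 10, n_prg = 8,
                                     beta_true = c(1, -1, 1, -1, 1),
                                     early_frac = 0, seed = 8100 + s))
    members <- unique(c(co$truth$pairs$a, co$truth$pairs$b))
    others <- setdiff(rownames(co$expression$values)[
      co$expression$biotype == "lncRNA"], members)
    nullp <- enumerate_pairs(others[1:30])[1:45, ]
    pairs <- rbind(co$truth$pairs[, c("a", "b")], nullp)
    reo <- build_reo_matrix(co$expression, pairs)
    path <- lasso_cox_select(reo, co$survival, seed = s)
    path2 <- lasso_cox_select(reo, co$survival, seed = s)
    expect_identical(path$selected, path2$selected)
    all(rownames(co$truth$Z) %in% path$selected)
  }, logical(1))
  expect_gte(mean(contains_all), 0.8)
})

test_that("the heaviest LASSO penalty empties the active set", {
  co <- generate_cohort(quick_config(seed = 66, n_samples = 150, n_lnc = 30))
  reo <- build_reo_matrix(co$expression,
                          enumerate_pairs(co$truth$de_ids))
  path <- lasso_cox_select(reo, co$survival, seed = 2)
  expect_identical(unname(path$nzero[1]), 0L)
  expect_equal(path$cvm[match(path$lambda_min, path$lambda)], min(path$cvm))
})

test_that("duplicated covariates do not change the selected risk scores", {
  co <- generate_cohort(quick_config(seed = 67, n_samples = 250, n_lnc = 30))
  reo <- build_reo_matrix(co$expression, co$truth$pairs)
  # duplicate pair rows under shadow ids pointing to identical expression
  shadow <- reo$pairs
  shadow$a <- paste0(shadow$a, "_dup")
  e2v <- co$expression$values
  dup_rows <- e2v[reo$pairs$a, , drop = FALSE]
  rownames(dup_rows) <- paste0(reo$pairs$a, "_dup")
  e2 <- expression_matrix(rbind(e2v, dup_rows),
                          biotype = c(co$expression$biotype,
                                      rep("lncRNA", nrow(dup_rows))),
                          scale = "log2p1")
  reo_dup <- build_reo_matrix(e2, rbind(reo$pairs, shadow))
  p1 <- lasso_cox_select(reo, co$survival, seed = 5)
  p2 <- lasso_cox_select(reo_dup, co$survival, seed = 5)
  score1 <- as.numeric(crossprod(reo$X[names(p1$coef), , drop = FALSE],
                                 p1$coef))
  score2 <- as.numeric(crossprod(reo_dup$X[names(p2$coef), , drop = FALSE],
                                 p2$coef))
  expect_gt(stats::cor(score1, score2), 0.99)
})

test_that("stepwise AIC drops pure-noise candidates and keeps prognostic ones", {
  # AIC retains a pure-noise term whenever its chi-square exceeds 2
  # (probability ~0.16), so the expected drop rate is ~0.84
  set.seed(91)
  drops <- replicate(20, {
    n <- 400
    z <- rbinom(n, 1, 0.5)
    noise <- rbinom(n, 1, 0.5)
    surv <- sim_surv_binary(z, beta = 1.3, base = 1e-3, cmax = 2500,
                            ids = sprintf("s%03d", 1:n))
    v <- rbind(a = ifelse(z == 1, 1, 3), b = rep(2, n),
               c = ifelse(noise == 1, 1, 3), d = rep(2, n))
    colnames(v) <- surv$sample_id
    e <- expression_matrix(v, biotype = "lncRNA", scale = "TPM")
    reo <- build_reo_matrix(e, data.frame(a = c("a", "c"), b = c("b", "d")))
    m <- stepwise_aic_cox(reo, surv)
    keys <- paste(m$terms$a, m$terms$b, sep = "|")
    ("a|b" %in% keys) && !("c|d" %in% keys)
  })
  expect_gte(mean(drops), 0.7)
})

test_that("a single prognostic candidate is retained", {
  set.seed(92)
  n <- 300
  z <- rbinom(n, 1, 0.5)
  surv <- sim_surv_binary(z, beta = 1.5, base = 1e-3, cmax = 2500,
                          ids = sprintf("s%03d", 1:n))
  v <- rbind(a = ifelse(z == 1, 1, 3), b = rep(2, n))
  colnames(v) <- surv$sample_id
  e <- expression_matrix(v, biotype = "lncRNA", scale = "TPM")
  reo <- build_reo_matrix(e, data.frame(a = "a", b = "b"))
  m <- stepwise_aic_cox(reo, surv)
  expect_identical(nrow(m$terms), 1L)
  expect_lte(attr(m, "aic"), attr(m, "aic_start"))
})

test_that("stepwise AIC matches an exhaustive subset-search oracle on small instances", {
  # oracle: minimal AIC over all 2^m subsets, fitted independently
  subset_oracle_aic <- function(X, y) {
    m <- nrow(X)
    dat <- as.data.frame(t(X))
    names(dat) <- sprintf("V%d", seq_len(m))
    dat$.y <- y
    best <- Inf
    for (mask in 0:(2^m - 1)) {
      vars <- names(dat)[seq_len(m)][bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      fml <- if (length(vars))
        stats::as.formula(paste(".y ~", paste(vars, collapse = "+")))
      else stats::as.formula(".y ~ 1")
      fit <- survival::coxph(fml, data = dat)
      best <- min(best, stats::extractAIC(fit)[2])
    }
    best
  }
  set.seed(93)
  equal <- logical(10)
  for (r in 1:10) {
    n <- 120; m <- 6
    X <- matrix(rbinom(m * n, 1, 0.5), m, n)
    lp <- 1.2 * X[1, ] - 1.0 * X[2, ]
    t_ev <- rexp(n, 1e-3 * exp(lp))
    surv <- make_surv(pmin(t_ev, 2000), as.integer(t_ev <= 2000),
                      ids = sprintf("s%03d", 1:n))
    v <- matrix(0, 2 * m, n,
                dimnames = list(sprintf("g%02d", 1:(2 * m)), surv$sample_id))
    odd <- seq(1, 2 * m, 2)
    v[odd, ] <- ifelse(X == 1, 1, 3); v[odd + 1, ] <- 2
    e <- expression_matrix(v, biotype = "lncRNA", scale = "TPM")
    pairs <- data.frame(a = rownames(v)[odd], b = rownames(v)[odd + 1])
    reo <- build_reo_matrix(e, pairs)
    model <- stepwise_aic_cox(reo, surv)
    oracle <- subset_oracle_aic(X, survival::Surv(surv$os_days, surv$event))
    expect_gte(attr(model, "aic"), oracle - 1e-6)
    expect_lte(attr(model, "aic"), attr(model, "aic_start") + 1e-9)
    equal[r] <- abs(attr(model, "aic") - oracle) < 1e-6
  }
  expect_gte(mean(equal), 0.7)
})

test_that("the Youden threshold equals an exhaustive cutoff scan", {
  set.seed(94)
  n <- 20
  scores <- stats::setNames(round(runif(n), 2), sprintf("s%02d", 1:n))
  t_ev <- rexp(n, 1e-3 * exp(1.5 * scores))
  surv <- make_surv(pmin(t_ev, 3000), as.integer(t_ev <= 3000),
                    ids = names(scores))
  thr <- youden_threshold(scores, surv, horizon_years = 5)
  # oracle: no censoring before the horizon, so sensitivity/specificity are
  # empirical fractions over cases (event by t) and controls (past t)
  t_h <- 5 * 365.25
  case <- surv$os_days <= t_h & surv$event == 1
  ctrl <- surv$os_days > t_h
  Js <- vapply(sort(unique(scores)), function(c) {
    mean(scores[case] >= c) + mean(scores[ctrl] < c) - 1
  }, numeric(1))
  expect_equal(attr(thr, "youden"), max(Js), tolerance = 1e-10)
  cand <- sort(unique(scores))[Js == max(Js)]
  expect_equal(as.numeric(thr), min(cand))
})

test_that("a perfect marker attains Youden index 1 and a null marker stays low", {
  n <- 60
  t_h_days <- 5 * 365.25
  time <- c(rep(400, 30), rep(2500, 30))
  event <- c(rep(1, 30), rep(0, 30))
  scores <- stats::setNames(c(rep(2, 30), rep(1, 30)), sprintf("s%02d", 1:n))
  surv <- make_surv(time, event, ids = names(scores))
  thr <- youden_threshold(scores, surv)
  expect_equal(attr(thr, "youden"), 1)
  expect_true(as.numeric(thr) > 1 && as.numeric(thr) <= 2)

  set.seed(95)
  low <- vapply(1:10, function(s) {
    n <- 300
    scores <- stats::setNames(runif(n), sprintf("s%03d", 1:n))
    t_ev <- rexp(n, 5e-4)
    cens <- runif(n, 0, 4000)
    surv <- make_surv(pmin(t_ev, cens), as.integer(t_ev <= cens),
                      ids = names(scores))
    attr(youden_threshold(scores, surv), "youden") < 0.3
  }, logical(1))
  expect_gte(mean(low), 0.9)
})

test_that("risk model constructor and JSON round trip preserve structure", {
  terms <- data.frame(a = c("x", "y"), b = c("y2", "z"), beta = c(1.5, -2))
  m <- risk_model(terms, threshold = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(m, path)
  m2 <- read_risk_model(path)
  expect_equal(m2$terms, m$terms)
  expect_equal(m2$threshold, 0.3)
  expect_identical(m2$provenance, "fitted")
  expect_error(risk_model(data.frame(a = "x", b = "x", beta = 1)), "differ")
  expect_error(risk_model(terms[0, ]), "at least one")
  expect_error(risk_model(transform(terms, beta = c(Inf, 1))), "finite")
})

test_that("the fitted pipeline recovers planted pairs and separates validation survival", {
  res <- vapply(1:10, function(s) {
    co <- generate_cohort(sim_config(n_samples = 400, n_lnc = 110,
                                     n_de_lnc = 10, n_prg = 8,
                                     early_frac = 0, seed = 40000 + s))
    members <- unique(c(co$truth$pairs$a, co$truth$pairs$b))
    others <- setdiff(rownames(co$expression$values)[
      co$expression$biotype == "lncRNA"], members)
    pairs <- rbind(co$truth$pairs[, c("a", "b")],
                   enumerate_pairs(others[1:30])[1:45, ])
    reo <- prevalence_filter(build_reo_matrix(co$expression, pairs))
    scr <- univariate_cox_screen(reo, co$survival)
    kept <- rownames(scr)[scr$kept_after_cox]
    model <- fit_risk_model(subset_pairs(reo, kept), co$survival, seed = s)
    mk <- canon_key(model$terms$a, model$terms$b)
    tk <- canon_key(co$truth$pairs$a, co$truth$pairs$b)
    co2 <- generate_cohort(sim_config(n_samples = 400, n_lnc = 110,
                                      n_de_lnc = 10, n_prg = 8,
                                      early_frac = 0, seed = 50000 + s))
    sc2 <- compute_risk_scores(model, co2$expression)
    p_val <- km_logrank(classify(sc2, model$threshold), co2$survival)$p
    sum(tk %in% mk) >= 4 && p_val < 0.01
  }, logical(1))
  expect_gte(mean(res), 0.8)
})
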