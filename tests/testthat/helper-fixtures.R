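# shared fixture builders: everything is generated in code at test time

canon_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# small expression matrix from a plain numeric matrix
make_expr <- function(v, biotype = "lncRNA", scale = "TPM") {
  if (is.null(rownames(v))) rownames(v) <- sprintf("g%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  expression_matrix(v, biotype = biotype, scale = scale)
}

# survival table without clinical covariates
make_surv <- function(time, event, ids = sprintf("s%02d", seq_along(time))) {
  survival_table(ids, time, event)
}

# exponential survival with a binary covariate effect and uniform censoring
sim_surv_binary <- function(x, beta, base = 1e-3, cmax = 1500,
                            ids = sprintf("s%02d", seq_along(x))) {
  lambda <- base * exp(beta * x)
  t_ev <- stats::rexp(length(x), lambda)
  t_c <- stats::runif(length(x), 0, cmax)
  survival_table(ids, pmin(t_ev, t_c), as.integer(t_ev <= t_c))
}

# a small cohort configuration that keeps test runtime down
quick_config <- function(seed, n_samples = 200, n_lnc = 40, n_prg = 12,
                         n_de_lnc = 20, early_frac = 0, ...) {
  sim_config(n_samples = n_samples, n_lnc = n_lnc, n_prg = n_prg,
             n_de_lnc = n_de_lnc, early_frac = early_frac, seed = seed, ...)
}
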