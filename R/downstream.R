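#' Exact hypergeometric overlap (enrichment) test
#'
#' Upper-tail probability that two sets of sizes `K` and `n`, drawn from a
#' population of `N`, overlap by at least `k` elements: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. One-sided (enrichment) by construction.
#'
#' @param N Population size.
#' @param K Size of set A.
#' @param n Size of set B.
#' @param k Observed overlap; must satisfy
#'   `max(0, n + K - N) <= k <= min(n, K)`.
#' @return A list of class `overlap_test`: `N`, `K`, `n`, `k`, `p_upper`.
#' @export
hypergeometric_overlap <- function(N, K, n, k) {
  if (any(c(N, K, n, k) %% 1 != 0) || N < 0)
    stop("all arguments must be non-negative integers")
  if (K > N || n > N)
    stop("set sizes cannot exceed the population size")
  lo <- max(0, n + K - N); hi <- min(n, K)
  if (k < lo || k > hi)
    stop("infeasible overlap: k must lie in [", lo, ", ", hi, "]")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, p_upper = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "hypergeometric overlap: k = %d of sets %d & %d in N = %d, P(X >= k) = %.3g\n",
    x$k, x$K, x$n, x$N, x$p_upper))
  invisible(x)
}

# first two columns of an edge table, as character
edge_cols <- function(edges, what) {
  if (!is.data.frame(edges) || ncol(edges) < 2)
    stop(what, " must be a data.frame with at least two columns (source, target)")
  if (nrow(edges) == 0) stop(what, " is empty")
  data.frame(source = as.character(edges[[1]]),
             target = as.character(edges[[2]]), stringsAsFactors = FALSE)
}

# univariate Cox p-value for a continuous log2 expression covariate
node_cox_p <- function(id, expr, y) {
  if (!id %in% rownames(expr$values)) return(NA_real_)
  v <- expr$values[id, ]
  if (!expr$scale %in% "log2p1") v <- log2(v + 1)
  fit <- cox_single(as.numeric(v), y)
  if (is.null(fit)) NA_real_ else unname(fit["p"])
}

#' Assemble prognostic lncRNA-miRNA-mRNA (ceRNA) axes
#'
#' Builds competing-endogenous-RNA axes from user-supplied interaction
#' tables (e.g. miRNet and TargetScan exports): (1) lncRNAs are
#' restricted to the risk model's members; (2) candidate miRNAs are
#' targets of those lncRNAs that also target at least one supplied mRNA
#' (PRG); (3) each candidate miRNA and mRNA is tested by univariate Cox
#' regression on its continuous log2 expression and kept at `p < alpha`;
#' (4) every lncRNA-miRNA-mRNA path whose two edges exist and whose
#' miRNA and mRNA both survive is emitted. Nodes without expression are
#' skipped with a warning.
#'
#' @param model A `risk_model`; its pair members define the lncRNA set.
#' @param lnc_mir_edges Data.frame, first column lncRNA id, second miRNA id.
#' @param mir_prg_edges Data.frame, first column miRNA id, second mRNA
#'   (PRG) id.
#' @param expr An `expr_matrix` holding the mRNA (PRG) expression.
#' @param mirna_expr An `expr_matrix` holding the miRNA expression.
#' @param surv A `surv_table`; samples are taken as the intersection of
#'   the two expression matrices' columns.
#' @param alpha Node-level significance threshold (default 0.05).
#' @return A data.frame of class `cerna_axes`: `lncRNA`, `miRNA`, `mRNA`,
#'   `p_miRNA`, `p_mRNA` (zero rows if no axis survives).
#' @export
build_cerna_axes <- function(model, lnc_mir_edges, mir_prg_edges,
                             expr, mirna_expr, surv, alpha = 0.05) {
  stopifnot(inherits(model, "risk_model"),
            inherits(expr, "expr_matrix"),
            inherits(mirna_expr, "expr_matrix"),
            inherits(surv, "surv_table"))
  lm_edges <- edge_cols(lnc_mir_edges, "`lnc_mir_edges`")
  mp_edges <- edge_cols(mir_prg_edges, "`mir_prg_edges`")
  model_lnc <- unique(c(model$terms$a, model$terms$b))
  lm_edges <- lm_edges[lm_edges$source %in% model_lnc, , drop = FALSE]
  cand_mir <- unique(lm_edges$target)
  cand_mir <- cand_mir[cand_mir %in% mp_edges$source]
  mp_edges <- mp_edges[mp_edges$source %in% cand_mir, , drop = FALSE]
  cand_prg <- unique(mp_edges$target)

  empty <- data.frame(lncRNA = character(0), miRNA = character(0),
                      mRNA = character(0), p_miRNA = numeric(0),
                      p_mRNA = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("cerna_axes", "data.frame")
  if (length(cand_mir) == 0 || length(cand_prg) == 0) return(empty)

  samples <- intersect(colnames(expr$values), colnames(mirna_expr$values))
  samples <- intersect(samples, surv$sample_id)
  if (length(samples) < 2) stop("too few samples shared by the inputs")
  surv <- surv[match(samples, surv$sample_id), , drop = FALSE]
  y <- surv_object(surv)
  expr <- subset_expression(expr,
                            transcripts = intersect(cand_prg,
                                                    rownames(expr$values)),
                            samples = samples)
  mirna_expr <- subset_expression(
    mirna_expr,
    transcripts = intersect(cand_mir, rownames(mirna_expr$values)),
    samples = samples)

  p_mir <- vapply(cand_mir, node_cox_p, numeric(1), expr = mirna_expr, y = y)
  p_prg <- vapply(cand_prg, node_cox_p, numeric(1), expr = expr, y = y)
  no_expr <- c(cand_mir[is.na(p_mir)], cand_prg[is.na(p_prg)])
  if (length(no_expr))
    warning("node(s) without usable expression skipped: ",
            paste(no_expr, collapse = ", "))
  keep_mir <- cand_mir[!is.na(p_mir) & p_mir < alpha]
  keep_prg <- cand_prg[!is.na(p_prg) & p_prg < alpha]
  if (length(keep_mir) == 0 || length(keep_prg) == 0) return(empty)

  lm_keep <- data.frame(lncRNA = lm_edges$source, miRNA = lm_edges$target,
                        stringsAsFactors = FALSE)
  lm_keep <- lm_keep[lm_keep$miRNA %in% keep_mir, , drop = FALSE]
  mp_keep <- data.frame(miRNA = mp_edges$source, mRNA = mp_edges$target,
                        stringsAsFactors = FALSE)
  mp_keep <- mp_keep[mp_keep$mRNA %in% keep_prg &
                       mp_keep$miRNA %in% keep_mir, , drop = FALSE]
  axes <- merge(lm_keep, mp_keep, by = "miRNA")
  if (nrow(axes) == 0) return(empty)
  out <- data.frame(lncRNA = axes$lncRNA,
                    miRNA = axes$miRNA,
                    mRNA = axes$mRNA,
                    p_miRNA = unname(p_mir[match(axes$miRNA, cand_mir)]),
                    p_mRNA = unname(p_prg[match(axes$mRNA, cand_prg)]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncRNA, out$miRNA, out$mRNA), , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("cerna_axes", "data.frame")
  out
}
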