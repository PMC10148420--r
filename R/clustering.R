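#' Ward clustering of samples on a gene panel
#'
#' Agglomerative clustering of samples with Ward's minimum-variance
#' linkage on Euclidean distance over per-gene z-scored log2 abundances of
#' the panel rows — the conventional heatmap-clustering setup. The
#' dendrogram is cut into `k` groups; cluster 1 is relabelled to be the
#' larger cluster so labels are deterministic and comparable across runs.
#'
#' @param expr An `expr_matrix` on the log2 scale (`log2p1`); TPM input is
#'   log-transformed internally.
#' @param panel_ids Character vector of panel gene ids. Ids absent from
#'   `expr` are reported and dropped with a warning.
#' @param k Number of clusters (default 2).
#' @return A list of class `panel_clustering`: `panel_ids` (used),
#'   `labels` (named integer vector, 1..k, 1 = largest), `linkage`
#'   (the `hclust` object), `dropped` (missing panel ids).
#' @export
ward_cluster <- function(expr, panel_ids, k = 2) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (k < 2) stop("`k` must be at least 2")
  if (ncol(expr$values) < k)
    stop("fewer samples (", ncol(expr$values), ") than clusters (", k, ")")
  dropped <- setdiff(panel_ids, rownames(expr$values))
  if (length(dropped)) {
    warning("panel ids missing from expression and dropped: ",
            paste(dropped, collapse = ", "))
    panel_ids <- setdiff(panel_ids, dropped)
  }
  if (length(panel_ids) < 1) stop("no panel gene present in the expression matrix")
  v <- expr$values[panel_ids, , drop = FALSE]
  if (expr$scale %in% c("TPM", "RPM")) v <- log2(v + 1)
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance panel gene(s) excluded from z-scoring: ",
            paste(panel_ids[sds == 0], collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
    if (nrow(v) == 0) stop("all panel genes have zero variance")
  }
  z <- t(scale(t(v)))
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  # deterministic labels: rank clusters by decreasing size (ties broken by
  # the original cutree label)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  labels <- relabel[as.character(raw)]
  names(labels) <- colnames(expr$values)
  structure(list(panel_ids = rownames(v), labels = labels, linkage = hc,
                 dropped = dropped, k = k),
            class = "panel_clustering")
}

#' @export
print.panel_clustering <- function(x, ...) {
  cat(sprintf("panel_clustering: %d samples on %d panel genes, k = %d\n",
              length(x$labels), length(x$panel_ids), x$k))
  print(table(cluster = x$labels))
  invisible(x)
}

#' Log-rank test for survival separation between clusters
#'
#' Two-sample log-rank test (chi-square, k-1 df) comparing overall
#' survival between the panel clusters.
#'
#' @param clustering A `panel_clustering`, or a named vector of cluster
#'   labels.
#' @param surv A `surv_table` covering the clustered samples.
#' @return A list: `chisq`, `df`, `p`.
#' @export
cluster_logrank <- function(clustering, surv) {
  labels <- if (inherits(clustering, "panel_clustering"))
    clustering$labels else clustering
  stopifnot(inherits(surv, "surv_table"))
  labels <- labels[surv$sample_id]
  if (anyNA(labels))
    stop("cluster labels do not cover all survival samples")
  groups <- factor(labels)
  if (nlevels(groups) < 2) stop("need at least two clusters")
  events_per_group <- tapply(surv$event, groups, sum)
  if (any(events_per_group == 0))
    warning("cluster(s) with zero events: ",
            paste(names(events_per_group)[events_per_group == 0],
                  collapse = ", "))
  sd <- survival::survdiff(surv_object(surv) ~ groups)
  df <- length(sd$n) - 1
  list(chisq = sd$chisq, df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}
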