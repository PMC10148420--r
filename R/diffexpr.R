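#' Moderated two-group differential expression of lncRNAs
#'
#' Fits a per-gene two-group linear model on log2 abundances and applies
#' empirical-Bayes variance shrinkage (limma's moderated t). The contrast
#' is cluster 1 minus cluster 2, where cluster 1 is the larger panel
#' cluster by the [ward_cluster()] labelling convention. P-values are
#' adjusted by Benjamini-Hochberg.
#'
#' @param expr An `expr_matrix` on the log2 scale (TPM is transformed
#'   internally). Only rows with biotype `lncRNA` are tested unless
#'   `biotypes` says otherwise.
#' @param labels Named cluster labels (values 1/2) covering the samples of
#'   `expr`, e.g. from [ward_cluster()].
#' @param biotypes Biotypes to test (default `"lncRNA"`).
#' @return A data.frame of class `de_table` with columns `id`, `log2FC`
#'   (cluster 1 - cluster 2), `t` (moderated), `p`, `FDR`.
#' @export
moderated_de <- function(expr, labels, biotypes = "lncRNA") {
  stopifnot(inherits(expr, "expr_matrix"))
  if (inherits(labels, "panel_clustering")) labels <- labels$labels
  labels <- labels[colnames(expr$values)]
  if (anyNA(labels)) stop("`labels` must cover every sample in `expr`")
  groups <- factor(labels, levels = sort(unique(labels)))
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  keep <- expr$biotype %in% biotypes
  if (!any(keep)) stop("no transcript with biotype in: ",
                       paste(biotypes, collapse = ", "))
  v <- expr$values[keep, , drop = FALSE]
  if (expr$scale %in% c("TPM", "RPM")) v <- log2(v + 1)
  design <- stats::model.matrix(~ 0 + groups)
  colnames(design) <- c("g1", "g2")
  fit <- limma::lmFit(v, design)
  fit <- limma::contrasts.fit(fit, limma::makeContrasts(g1 - g2,
                                                        levels = design))
  fit <- limma::eBayes(fit)
  out <- data.frame(id = rownames(v),
                    log2FC = as.numeric(fit$coefficients),
                    t = as.numeric(fit$t),
                    p = as.numeric(fit$p.value),
                    FDR = stats::p.adjust(as.numeric(fit$p.value),
                                          method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Select differential lncRNAs at effect-size and FDR thresholds
#'
#' Both thresholds are strict: a gene is selected iff |log2FC| > `lfc_min`
#' and FDR < `fdr_max`.
#'
#' @param de A `de_table` from [moderated_de()].
#' @param lfc_min Minimum absolute log2 fold-change (exclusive, default 1).
#' @param fdr_max Maximum FDR (exclusive, default 0.05).
#' @return Character vector of selected ids (possibly empty, with a
#'   warning).
#' @export
select_prlncrnas <- function(de, lfc_min = 1, fdr_max = 0.05) {
  stopifnot(is.data.frame(de), all(c("id", "log2FC", "FDR") %in% names(de)))
  sel <- de$id[abs(de$log2FC) > lfc_min & de$FDR < fdr_max]
  if (length(sel) == 0)
    warning("no lncRNA passes |log2FC| > ", lfc_min, " and FDR < ", fdr_max)
  sel
}
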