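check_labels <- function(labels, n, need_both = TRUE) {
  if (length(labels) != n) stop("labels length must match the number of samples")
  if (anyNA(labels)) stop("labels must not contain NA")
  labels <- as.logical(labels)
  if (need_both && (!any(labels) || all(labels))) {
    stop("both label classes must be nonempty")
  }
  labels
}

#' Rank features by AUC between two sample groups
#'
#' For each feature (gene or pathway) computes the area under the ROC
#' curve with the positive class (by convention the recurrent-like group)
#' as reference: the tie-corrected Mann-Whitney pair statistic
#' `(#{pos > neg} + 0.5 #{pos = neg}) / (n_pos * n_neg)`, evaluated via
#' midranks. Significance is two-sided: `max(auc, 1 - auc) >= threshold`,
#' with the direction (`"up"`/`"down"` in the positive class) reported by
#' comparing group medians. No multiplicity correction is applied to the
#' AUC threshold rule; this mirrors threshold-based pathway ranking
#' practice and is noted in the output attribute `"note"`.
#'
#' @param values feature-by-sample numeric matrix.
#' @param labels logical (or 0/1) per-sample vector; `TRUE` = positive
#'   class.
#' @param threshold two-sided significance threshold on the AUC
#'   (default 0.7).
#' @return data.frame with columns `feature_id`, `auc`, `direction`,
#'   `median_pos`, `median_neg`, `significant`.
#' @export
rank_auc <- function(values, labels, threshold = 0.7) {
  if (!is.matrix(values)) values <- as.matrix(values)
  labels <- check_labels(labels, ncol(values))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  ranks <- t(apply(values, 1L, rank))
  if (ncol(values) == 1L) ranks <- t(ranks)
  u <- rowSums(ranks[, labels, drop = FALSE]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  med_pos <- apply(values[, labels, drop = FALSE], 1L, stats::median)
  med_neg <- apply(values[, !labels, drop = FALSE], 1L, stats::median)
  res <- data.frame(
    feature_id = rownames(values) %||% as.character(seq_len(nrow(values))),
    auc = auc,
    direction = ifelse(med_pos > med_neg, "up", "down"),
    median_pos = med_pos,
    median_neg = med_neg,
    significant = pmax(auc, 1 - auc) >= threshold,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "note") <- "AUC threshold rule applied without multiplicity correction"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect differentially expressed genes between two groups
#'
#' Per-gene two-sided Mann-Whitney (Wilcoxon rank-sum) test with
#' Benjamini-Hochberg FDR control across tested genes, plus a natural-log
#' fold-change filter computed on pseudocounted group means. A gene is
#' called significant when `fdr <= fdr_threshold` and
#' `|lfc| >= lfc_threshold`.
#'
#' @param expr normalized `expr_matrix`.
#' @param labels logical per-sample vector (`TRUE` = positive class);
#'   each class needs >= 2 samples.
#' @param fdr_threshold BH FDR cutoff (default 0.05).
#' @param lfc_threshold minimum absolute natural-log fold change
#'   (default `log(1.5)`).
#' @param pseudocount added to group means before the ratio (default 1).
#' @return data.frame with columns `gene_id`, `log_fold_change`,
#'   `p_value`, `fdr`, `significant`.
#' @export
detect_degs <- function(expr, labels, fdr_threshold = 0.05,
                        lfc_threshold = log(1.5), pseudocount = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$is_normalized) stop("expression must be normalized before DEG detection")
  labels <- check_labels(labels, ncol(expr$values))
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    stop("each class needs at least 2 samples")
  }
  v <- expr$values
  pos <- v[, labels, drop = FALSE]
  neg <- v[, !labels, drop = FALSE]
  p <- vapply(seq_len(nrow(v)), function(g) {
    suppressWarnings(stats::wilcox.test(pos[g, ], neg[g, ], exact = FALSE,
                                        correct = TRUE)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # constant genes: no evidence either way
  lfc <- log((rowMeans(pos) + pseudocount) / (rowMeans(neg) + pseudocount))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(v), log_fold_change = lfc, p_value = p,
             fdr = fdr,
             significant = fdr <= fdr_threshold & abs(lfc) >= lfc_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Features differentially active in two comparisons with matching direction
#'
#' Intersects two AUC result sets (e.g. the tissue-based and the stem-cell-
#' culture-based stage comparison): a feature is concordant when it is
#' significant in both and changes in the same direction. Venn counts of
#' the two significant sets are reported alongside.
#'
#' @param set_a,set_b data.frames from [rank_auc()].
#' @return list with `shared` (concordant feature ids), `a_only`,
#'   `b_only` (significant in one set but not concordant), and
#'   `venn_counts` (named integer vector `a_only`, `b_only`, `shared`).
#' @export
concordant_features <- function(set_a, set_b) {
  sig_a <- set_a[set_a$significant, c("feature_id", "direction")]
  sig_b <- set_b[set_b$significant, c("feature_id", "direction")]
  m <- merge(sig_a, sig_b, by = "feature_id", suffixes = c("_a", "_b"))
  shared <- sort(m$feature_id[m$direction_a == m$direction_b])
  a_only <- sort(setdiff(sig_a$feature_id, shared))
  b_only <- sort(setdiff(sig_b$feature_id, shared))
  list(shared = shared, a_only = a_only, b_only = b_only,
       venn_counts = c(a_only = length(a_only), b_only = length(b_only),
                       shared = length(shared)))
}

#' Genes significant in two DEG comparisons with matching fold-change sign
#'
#' @param degs_a,degs_b data.frames from [detect_degs()].
#' @return sorted character vector of concordant gene ids.
#' @export
overlap_genes <- function(degs_a, degs_b) {
  sig_a <- degs_a[degs_a$significant, c("gene_id", "log_fold_change")]
  sig_b <- degs_b[degs_b$significant, c("gene_id", "log_fold_change")]
  m <- merge(sig_a, sig_b, by = "gene_id", suffixes = c("_a", "_b"))
  sort(m$gene_id[sign(m$log_fold_change_a) == sign(m$log_fold_change_b)])
}

#' Assign molecular subtype labels by nearest centroid
#'
#' Each sample's expression vector, restricted to the union of signature
#' genes present in the matrix, is compared to every subtype centroid by
#' Spearman correlation; the sample is labelled with the best-correlated
#' subtype, or `"unclassified"` on a tie. Signatures without a stored
#' centroid use an indicator centroid (1 on their own signature genes,
#' 0 elsewhere in the union).
#'
#' @param expr an `expr_matrix` (normalized values recommended; Spearman
#'   correlation makes the call scale-free).
#' @param signatures list of >= 2 [subtype_signature()] objects; each must
#'   overlap the matrix by >= 10 genes.
#' @return named character vector of subtype labels, one per sample.
#' @export
assign_subtype <- function(expr, signatures) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(signatures) < 2L) stop("need at least 2 subtype signatures")
  genes <- rownames(expr$values)
  for (s in signatures) {
    stopifnot(inherits(s, "subtype_signature"))
    if (length(intersect(s$signature_genes, genes)) < 10L) {
      stop("signature '", s$subtype_name,
           "' overlaps the expression matrix by fewer than 10 genes")
    }
  }
  union_genes <- sort(unique(unlist(lapply(signatures, `[[`, "signature_genes"))))
  union_genes <- intersect(union_genes, genes)
  centroids <- vapply(signatures, function(s) {
    if (!is.null(s$centroid)) {
      if (!all(union_genes %in% names(s$centroid))) {
        stop("centroid of '", s$subtype_name,
             "' does not cover the union of signature genes")
      }
      s$centroid[union_genes]
    } else {
      as.numeric(union_genes %in% s$signature_genes)
    }
  }, numeric(length(union_genes)))
  colnames(centroids) <- vapply(signatures, `[[`, character(1), "subtype_name")
  sub <- expr$values[union_genes, , drop = FALSE]
  # a constant sample vector has no rank order: cor is NA -> unclassified
  cors <- suppressWarnings(stats::cor(sub, centroids, method = "spearman"))
  labels <- apply(cors, 1L, function(r) {
    if (all(is.na(r))) return("unclassified")  # e.g. a constant sample vector
    r[is.na(r)] <- -Inf
    o <- order(r, decreasing = TRUE)
    if (length(r) > 1L && abs(r[o[1L]] - r[o[2L]]) < 1e-12) "unclassified"
    else colnames(centroids)[o[1L]]
  })
  stats::setNames(labels, colnames(expr$values))
}

#' Hierarchical clustering and principal-component projection of samples
#'
#' Ward-linkage (`ward.D2`) hierarchical clustering of samples on Euclidean
#' distances between their feature vectors, plus a centered (unscaled) PCA
#' reporting the first two component scores and the percent variance of
#' every component, as used for cohort-structure overview plots.
#'
#' @param values feature-by-sample numeric matrix (expression or pathway
#'   activation).
#' @return list with `hclust` (the tree), `order` (sample ids in dendrogram
#'   order), `scores` (samples x 2 matrix of PC1/PC2 scores) and
#'   `var_pct` (percent variance per component; sums to 100).
#' @export
cluster_and_project <- function(values) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (ncol(values) < 2L) stop("need at least 2 samples")
  x <- t(values)
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  list(hclust = hc, order = rownames(x)[hc$order], scores = scores,
       var_pct = var_pct)
}
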