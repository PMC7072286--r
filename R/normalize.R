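#' Library-size normalization by median-of-ratios size factors
#'
#' Divides each sample column by its median-of-ratios size factor: the
#' median, over genes with all-positive counts (nonzero geometric mean
#' across samples), of that sample's count divided by the gene's
#' geometric mean. This is the standard size-factor procedure for bulk
#' RNA-seq counts (identical to DESeq2's estimator on the genes both
#' retain). Size factors are defined only up to a common constant, so
#' multiplying all counts of one sample by k rescales the whole
#' normalized matrix by `k^(1/n)` while leaving every relative
#' expression value -- and every case-to-normal ratio built with
#' pseudocount 0 -- unchanged.
#'
#' @param expr an `expr_matrix` of raw counts (`is_normalized = FALSE`)
#'   with at least 2 samples.
#' @return a normalized `expr_matrix`; the estimated size factors are
#'   attached as attribute `"size_factors"`.
#' @export
normalize_counts <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$is_normalized) stop("matrix is already normalized")
  v <- expr$values
  if (ncol(v) < 2L) stop("normalization needs at least 2 samples")
  all_pos <- rowSums(v > 0) == ncol(v)
  if (!any(all_pos)) {
    stop("cannot estimate size factors: no gene has all-positive counts")
  }
  logv <- log(v[all_pos, , drop = FALSE])
  loggeo <- rowMeans(logv)
  sf <- exp(apply(logv - loggeo, 2L, stats::median))
  out <- expression_matrix(sweep(v, 2L, sf, "/"), is_normalized = TRUE)
  attr(out, "size_factors") <- sf
  out
}

#' Build a normal-reference profile from control samples
#'
#' Averages normalized expression over a normal control group, per gene;
#' this is the denominator of every case-to-normal ratio. The default is
#' the geometric mean of (value + pseudocount), which centers log CNR at 0
#' for genes with no case/control difference; the arithmetic mean is
#' selectable.
#'
#' @param normals an `expr_matrix` of >= 2 normalized control samples.
#' @param pseudocount nonnegative regularizer added before averaging
#'   (default 1). With `pseudocount = 0` and zero counts in the controls
#'   the mean can be 0, which [compute_cnr()] then rejects.
#' @param mean_type `"geometric"` (default) or `"arithmetic"`.
#' @return a [normal_reference()].
#' @export
build_normal_reference <- function(normals, pseudocount = 1,
                                   mean_type = c("geometric", "arithmetic")) {
  stopifnot(inherits(normals, "expr_matrix"))
  mean_type <- match.arg(mean_type)
  if (!normals$is_normalized) stop("control samples must be normalized first")
  if (ncol(normals$values) < 2L) stop("a normal reference needs at least 2 control samples")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  v <- normals$values + pseudocount
  cm <- if (mean_type == "geometric") {
    exp(rowMeans(log(v)))
  } else {
    rowMeans(v)
  }
  names(cm) <- rownames(normals$values)
  normal_reference(cm, n_controls = ncol(normals$values))
}

#' Compute per-gene case-to-normal ratios
#'
#' For every gene shared between the sample matrix and the reference,
#' `CNR = (value + pseudocount) / control_mean`. Genes absent from either
#' side are dropped with a logged message -- never zero-filled, which
#' would fabricate extreme ratios.
#'
#' @param expr normalized `expr_matrix` of case samples.
#' @param ref a [normal_reference()] built with the same pseudocount so
#'   that null genes center at CNR = 1.
#' @param pseudocount nonnegative regularizer added to the numerator
#'   (default 1).
#' @return a [cnr_matrix()] of strictly positive ratios.
#' @export
compute_cnr <- function(expr, ref, pseudocount = 1) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(ref, "normal_reference"))
  if (!expr$is_normalized) stop("case samples must be normalized first")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  common <- intersect(rownames(expr$values), ref$gene_ids)
  if (!length(common)) stop("no genes shared between sample matrix and normal reference")
  n_drop <- (nrow(expr$values) - length(common)) + (length(ref$gene_ids) - length(common))
  if (n_drop > 0L) {
    message("dropped ", n_drop, " gene(s) absent from one side of the CNR computation")
  }
  cm <- ref$control_mean[common]
  if (any(cm <= 0)) {
    stop("control mean is nonpositive for ", sum(cm <= 0),
         " shared gene(s); rebuild the reference with a positive pseudocount")
  }
  ratios <- (expr$values[common, , drop = FALSE] + pseudocount) / cm
  cnr_matrix(ratios)
}
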