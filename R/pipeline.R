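#' Run the scoring chain from raw counts to pathway activation
#'
#' Convenience wrapper over the individual stages: normalize the full count
#' matrix (cases and controls together), build the normal reference from
#' the `stage == "normal"` samples, compute case-to-normal ratios for the
#' remaining samples, and score every pathway.
#'
#' @param expr raw-count `expr_matrix` containing both case and normal
#'   samples.
#' @param meta [sample_metadata()] covering all samples in `expr`.
#' @param db a [pathway_db()].
#' @param pseudocount regularizer for the reference and the ratios
#'   (default 1).
#' @param min_coverage minimum measured nonzero-ARR members per scored
#'   pathway (default 1).
#' @param mean_type control averaging, `"geometric"` (default) or
#'   `"arithmetic"`.
#' @return list with `normalized` (full normalized matrix), `reference`,
#'   `cnr` (case samples only), `pal`, and `case_meta` (metadata rows of
#'   the scored samples, in matrix column order).
#' @export
score_cohort <- function(expr, meta, db, pseudocount = 1, min_coverage = 1L,
                         mean_type = "geometric") {
  stopifnot(inherits(expr, "expr_matrix"), inherits(meta, "sample_metadata"))
  if (!setequal(meta$sample_id, colnames(expr$values))) {
    stop("metadata and expression matrix must cover the same samples")
  }
  meta <- meta[match(colnames(expr$values), meta$sample_id), ]
  norm <- if (expr$is_normalized) expr else normalize_counts(expr)
  normal_ids <- meta$sample_id[meta$stage == "normal"]
  if (length(normal_ids) < 2L) stop("need at least 2 normal samples in the cohort")
  case_ids <- setdiff(colnames(norm$values), normal_ids)
  if (!length(case_ids)) stop("no case samples in the cohort")
  normals <- expression_matrix(norm$values[, normal_ids, drop = FALSE],
                               is_normalized = TRUE)
  cases <- expression_matrix(norm$values[, case_ids, drop = FALSE],
                             is_normalized = TRUE)
  ref <- build_normal_reference(normals, pseudocount = pseudocount,
                                mean_type = mean_type)
  cnr <- compute_cnr(cases, ref, pseudocount = pseudocount)
  pal <- compute_pal(cnr, db, min_coverage = min_coverage)
  list(normalized = norm, reference = ref, cnr = cnr, pal = pal,
       case_meta = meta[match(case_ids, meta$sample_id), ])
}
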