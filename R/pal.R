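#' Pathway activation levels from case-to-normal ratios
#'
#' Scores every pathway in every sample with the signed, normalized sum of
#' log-ratios over pathway members:
#' \deqn{PAL_{pj} = \frac{\sum_n ARR_{np} \, \ln CNR_{nj}}{\sum_n |ARR_{np}|}}
#' where the sums run over the member genes of pathway *p* that are present
#' in the CNR matrix, and ARR is the discrete activator/repressor role in
#' \{-1, -0.5, 0, 0.5, 1\}. A positive PAL means the pathway's activators
#' are up and/or its repressors are down relative to the normal reference;
#' all-null ratios (CNR = 1 everywhere) give PAL = 0.
#'
#' Member genes absent from the CNR matrix are excluded from both the
#' numerator and the denominator. Pathways retaining fewer than
#' `min_coverage` measured members with nonzero ARR (neutral ARR = 0
#' members carry no weight in either sum) are dropped with a logged
#' message; if every pathway is dropped, an error is raised.
#'
#' @param cnr a [cnr_matrix()].
#' @param db a [pathway_db()].
#' @param min_coverage minimum number of measured nonzero-ARR members for
#'   a pathway to be scored (default 1).
#' @return an object of class `pal_matrix`: list with `pal` (pathways x
#'   samples matrix), `coverage` (measured members per retained pathway,
#'   including neutral ones) and `n_informative` (measured nonzero-ARR
#'   members).
#' @export
compute_pal <- function(cnr, db, min_coverage = 1L) {
  stopifnot(inherits(cnr, "cnr_matrix"), inherits(db, "pathway_db"))
  if (min_coverage < 1L) stop("min_coverage must be >= 1")
  measured <- rownames(cnr$ratios)
  logcnr <- log(cnr$ratios)

  ids <- names(db$pathways)
  member_lists <- lapply(db$pathways, function(p) {
    m <- p$members[names(p$members) %in% measured]
    m
  })
  coverage <- vapply(member_lists, length, integer(1))
  n_informative <- vapply(member_lists, function(m) sum(m != 0), integer(1))
  keep <- n_informative >= min_coverage
  if (!any(keep)) stop("no scorable pathways: every pathway fell below coverage")
  if (any(!keep)) {
    message("dropped ", sum(!keep), " pathway(s) below min_coverage = ", min_coverage)
  }

  kept <- member_lists[keep]
  # sparse pathway-by-gene ARR weight matrix over measured genes
  i <- rep.int(seq_along(kept), lengths(kept))
  j <- match(unlist(lapply(kept, names), use.names = FALSE), measured)
  w <- unlist(kept, use.names = FALSE)
  A <- Matrix::sparseMatrix(i = i, j = j, x = w,
                            dims = c(length(kept), length(measured)))
  num <- as.matrix(A %*% logcnr)
  den <- Matrix::rowSums(abs(A))
  pal <- num / den
  dimnames(pal) <- list(ids[keep], colnames(cnr$ratios))
  structure(list(pal = pal,
                 coverage = stats::setNames(coverage[keep], ids[keep]),
                 n_informative = stats::setNames(n_informative[keep], ids[keep])),
            class = "pal_matrix")
}

#' @export
print.pal_matrix <- function(x, ...) {
  cat(sprintf("pal_matrix: %d pathways x %d samples\n", nrow(x$pal), ncol(x$pal)))
  invisible(x)
}
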