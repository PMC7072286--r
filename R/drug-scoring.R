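#' Balanced efficiency scores for a drug panel
#'
#' Scores each drug in each sample from the two transcriptomic information
#' sources that define target-drug response modelling: expression of the
#' drug's target genes and activation of the pathways containing them.
#'
#' Per drug *d* and sample *j*:
#' \itemize{
#'   \item Gene component `G = mean over measured targets t of w_t * ln(CNR_t)`,
#'     with target weights `w` in \{+1, -1\} (-1 encodes resistance factors
#'     such as MGMT for temozolomide, so their overexpression lowers the
#'     score).
#'   \item Pathway component `P = mean over Q of s_dp * PAL_p`, where Q is
#'     the set of scored pathways containing at least one target of *d*
#'     with nonzero ARR, and `s_dp = sign(sum of w_t * ARR_tp over d's
#'     targets in p)`; pathways with `s_dp = 0` are excluded.
#'   \item Balancing: within each sample, G and P are z-standardized across
#'     the drug panel (a component with zero panel standard deviation is
#'     set to 0), and `BES = (z(G) + z(P)) / 2`; when Q is empty the score
#'     is `z(G)` alone.
#' }
#'
#' The balancing rule makes the two components commensurate but also makes
#' BES values panel-relative: scores are only comparable between runs using
#' the same drug panel (recorded in the returned object). This scoring rule
#' is the package's own reconstruction of balanced efficiency scoring from
#' its two published ingredients and is isolated here so an alternative
#' rule can be swapped in.
#'
#' @param cnr a [cnr_matrix()].
#' @param pal a `pal_matrix` computed from the same samples.
#' @param drugs list of >= 2 [drug_definition()] objects (after dropping
#'   drugs with no measured target, which are logged).
#' @param db the [pathway_db()] used for `pal` (supplies ARR values for
#'   the pathway component).
#' @return object of class `bes_matrix`: list with `bes`, `G`, `P`
#'   (drugs x samples; `P` is `NA` where undefined), `zG`, `zP`, and
#'   `panel` (drug names).
#' @export
compute_bes <- function(cnr, pal, drugs, db) {
  stopifnot(inherits(cnr, "cnr_matrix"), inherits(pal, "pal_matrix"),
            inherits(db, "pathway_db"))
  if (any(colnames(cnr$ratios) != colnames(pal$pal))) {
    stop("CNR and PAL matrices must cover the same samples in the same order")
  }
  measured <- rownames(cnr$ratios)
  keep <- vapply(drugs, function(d) any(names(d$targets) %in% measured), logical(1))
  if (any(!keep)) {
    message("dropped ", sum(!keep), " drug(s) with no measured target")
  }
  drugs <- drugs[keep]
  if (length(drugs) < 2L) {
    stop("drug panel has fewer than 2 scorable drugs; balancing undefined")
  }
  dnames <- vapply(drugs, `[[`, character(1), "drug_name")
  logcnr <- log(cnr$ratios)
  nsamp <- ncol(logcnr)
  scored_pw <- rownames(pal$pal)

  G <- t(matrix(vapply(drugs, function(d) {
    t_meas <- d$targets[names(d$targets) %in% measured]
    colMeans(t_meas * logcnr[names(t_meas), , drop = FALSE])
  }, numeric(nsamp)), nrow = nsamp))

  P <- t(matrix(vapply(drugs, function(d) {
    s <- vapply(scored_pw, function(pid) {
      arr <- db$pathways[[pid]]$members
      t_in <- intersect(names(d$targets), names(arr)[arr != 0])
      if (!length(t_in)) return(NA_real_)
      sign(sum(d$targets[t_in] * arr[t_in]))
    }, numeric(1))
    s <- s[!is.na(s) & s != 0]
    if (!length(s)) return(rep(NA_real_, nsamp))
    colMeans(s * pal$pal[names(s), , drop = FALSE])
  }, numeric(nsamp)), nrow = nsamp))
  dimnames(G) <- dimnames(P) <- list(dnames, colnames(cnr$ratios))

  z_cols <- function(m) {
    apply(m, 2L, function(col) {
      ok <- !is.na(col)
      out <- rep(NA_real_, length(col))
      mu <- mean(col[ok])
      sdv <- stats::sd(col[ok])
      out[ok] <- if (is.na(sdv) || sdv == 0) 0 else (col[ok] - mu) / sdv
      out
    })
  }
  zG <- z_cols(G)
  zP <- z_cols(P)
  bes <- ifelse(is.na(zP), zG, (zG + zP) / 2)
  dimnames(bes) <- dimnames(zG) <- dimnames(zP) <- dimnames(G)
  structure(list(bes = bes, G = G, P = P, zG = zG, zP = zP, panel = dnames),
            class = "bes_matrix")
}

#' @export
print.bes_matrix <- function(x, ...) {
  cat(sprintf("bes_matrix: %d drugs x %d samples (panel-relative scores)\n",
              nrow(x$bes), ncol(x$bes)))
  invisible(x)
}

#' Compare balanced efficiency scores between two sample groups
#'
#' Per drug: group medians, a two-sided Mann-Whitney test, and the AUC
#' (positive class = `TRUE` labels), as for pathway ranking.
#'
#' @param bes a `bes_matrix`.
#' @param labels logical per-sample vector; both classes nonempty.
#' @param auc_threshold threshold passed through to [rank_auc()]
#'   (default 0.7).
#' @return data.frame with columns `drug_name`, `median_pos`,
#'   `median_neg`, `wilcoxon_p`, `auc`, `direction`, `significant`.
#' @export
compare_bes_groups <- function(bes, labels, auc_threshold = 0.7) {
  stopifnot(inherits(bes, "bes_matrix"))
  labels <- check_labels(labels, ncol(bes$bes))
  aucres <- rank_auc(bes$bes, labels, threshold = auc_threshold)
  p <- vapply(seq_len(nrow(bes$bes)), function(i) {
    suppressWarnings(stats::wilcox.test(bes$bes[i, labels],
                                        bes$bes[i, !labels])$p.value)
  }, numeric(1))
  data.frame(drug_name = rownames(bes$bes), median_pos = aucres$median_pos,
             median_neg = aucres$median_neg, wilcoxon_p = p,
             auc = aucres$auc, direction = aucres$direction,
             significant = aucres$significant,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Drugs differentially scored in both tissue and stem-cell comparisons
#'
#' A drug is reported when its BES AUC passes the two-sided threshold in
#' BOTH the tissue-based and the culture-based stage comparison; the output
#' mirrors a drug-ranking table with group medians per sample set.
#'
#' @param bes_tissue,bes_gsc `bes_matrix` objects for the two sample sets.
#' @param labels_tissue,labels_gsc logical per-sample group labels.
#' @param threshold AUC significance threshold (default 0.7).
#' @return data.frame with one row per differential drug: `drug_name`,
#'   medians and AUC per set.
#' @export
rank_differential_drugs <- function(bes_tissue, bes_gsc, labels_tissue,
                                    labels_gsc, threshold = 0.7) {
  rt <- compare_bes_groups(bes_tissue, labels_tissue, auc_threshold = threshold)
  rg <- compare_bes_groups(bes_gsc, labels_gsc, auc_threshold = threshold)
  m <- merge(rt, rg, by = "drug_name", suffixes = c("_tissue", "_gsc"))
  out <- m[m$significant_tissue & m$significant_gsc,
           c("drug_name", "median_neg_tissue", "median_pos_tissue",
             "auc_tissue", "median_neg_gsc", "median_pos_gsc", "auc_gsc")]
  out <- out[order(out$drug_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratify patients by the sign of a drug's balanced efficiency score
#'
#' Patient-level label from sample-level scores: majority vote over the
#' patient's samples of `BES > cutoff`; on a tie the sign of the mean BES
#' decides, with mean exactly at the cutoff falling in the negative
#' stratum. Patients with no scored samples are excluded with a logged
#' message.
#'
#' @param bes a `bes_matrix`.
#' @param meta a [sample_metadata()] mapping samples to patients.
#' @param drug drug name present in the panel.
#' @param cutoff score cutoff (default 0).
#' @return data.frame with columns `patient_id`, `stratum`
#'   (`"positive"`/`"negative"`), `n_samples`, `mean_bes`.
#' @export
stratify_by_bes <- function(bes, meta, drug, cutoff = 0) {
  stopifnot(inherits(bes, "bes_matrix"), inherits(meta, "sample_metadata"))
  if (!drug %in% rownames(bes$bes)) stop("drug '", drug, "' not in the scored panel")
  scores <- bes$bes[drug, ]
  pts <- unique(meta$patient_id)
  rows <- lapply(pts, function(p) {
    samp <- intersect(meta$sample_id[meta$patient_id == p], names(scores))
    if (!length(samp)) return(NULL)
    s <- scores[samp]
    above <- sum(s > cutoff)
    below <- length(s) - above
    stratum <- if (above > below) "positive"
      else if (above < below) "negative"
      else if (mean(s) > cutoff) "positive" else "negative"
    data.frame(patient_id = p, stratum = stratum, n_samples = length(s),
               mean_bes = mean(s), stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0L) message("excluded ", dropped, " patient(s) with no scored samples")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
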