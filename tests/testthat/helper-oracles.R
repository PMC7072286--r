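# Independent oracles, coded as direct transliterations of the definitions
# they check; deliberately loop-based and kept free of package internals.

# pathway activation by direct summation over members
pal_oracle <- function(cnr_values, arr) {
  num <- 0
  den <- 0
  for (g in names(arr)) {
    if (!g %in% names(cnr_values)) next
    num <- num + arr[[g]] * log(cnr_values[[g]])
    den <- den + abs(arr[[g]])
  }
  if (den == 0) return(NA_real_)
  num / den
}

# AUC by brute-force counting over all (positive, negative) pairs,
# half-credit for ties
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

expr_from <- function(m, normalized = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  expression_matrix(m, is_normalized = normalized)
}

cnr_from <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  cnr_matrix(m)
}
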