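# internal helpers shared across modules

ARR_LEVELS <- c(-1, -0.5, 0, 0.5, 1)

STAGE_LEVELS <- c("ndGB", "recGB", "secondary-recGB", "normal")
MATERIAL_LEVELS <- c("tissue", "GSC")

geomean <- function(x) exp(mean(log(x)))

# %.17g round-trips doubles through text exactly and deterministically
fmt_num <- function(x) sprintf("%.17g", x)

# fixed-order deterministic TSV writer for a numeric matrix with an id column
write_id_matrix <- function(m, path, id_col) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

read_id_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one sample column in ", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      stop("non-numeric entries in column '", colnames(body)[j], "' of ", path)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  m
}
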