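#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with gene symbols in the first column and a
#' header row of sample ids. Missing entries are imputed to 0 with a logged
#' message; duplicate gene rows (e.g. transcript-level rows mapping to the
#' same symbol) are collapsed by summation with a warning.
#'
#' @param path file path.
#' @param is_normalized whether the stored values are already
#'   library-size-normalized (default `FALSE`: raw counts).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, is_normalized = FALSE) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected gene column plus at least one sample column in ", path)
  genes <- as.character(df[[1L]])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      stop("non-numeric entries in sample column '", samples[j], "' of ", path)
    }
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  if (anyNA(m)) {
    message(sum(is.na(m)), " missing expression entr(ies) imputed to 0 on load")
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at gene '%s', sample '%s' in %s",
                 genes[bad[1L]], samples[bad[2L]], path))
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("collapsed ", length(dups), " duplicated gene id(s) by summation: ",
            paste(utils::head(dups, 5L), collapse = ", "),
            if (length(dups) > 5L) ", ..." else "")
    m <- rowsum(m, group = genes, reorder = FALSE)
    m <- m[match(unique(genes), rownames(m)), , drop = FALSE]
  }
  expression_matrix(m, is_normalized = is_normalized)
}

#' Write an expression matrix to TSV
#'
#' Values are written with full double precision so that a write/read
#' round trip is the identity.
#'
#' @param x an `expr_matrix`.
#' @param path output file path.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  write_id_matrix(x$values, path, id_col = "gene_id")
}

#' Read an expression matrix from a MatrixMarket triple
#'
#' Alternative sparse input: an MTX file plus one-id-per-line gene and
#' sample lists.
#'
#' @param mtx_path MatrixMarket file (genes x samples).
#' @param genes_path,samples_path plain-text id lists, one per line.
#' @inheritParams read_expression_tsv
#' @return an [expression_matrix()].
#' @export
read_expression_mtx <- function(mtx_path, genes_path, samples_path,
                                is_normalized = FALSE) {
  m <- as.matrix(Matrix::readMM(mtx_path))
  genes <- readLines(genes_path)
  samples <- readLines(samples_path)
  if (nrow(m) != length(genes) || ncol(m) != length(samples)) {
    stop("MTX dimensions do not match gene/sample list lengths")
  }
  rownames(m) <- genes
  colnames(m) <- samples
  expression_matrix(m, is_normalized = is_normalized)
}

#' Read a pathway database in extended GMT ("GMTX") format
#'
#' One pathway per line, tab-separated: id, display name, then `GENE:ARR`
#' tokens with ARR in \{-1, -0.5, 0, 0.5, 1\}.
#'
#' @param path file path.
#' @return a [pathway_db()].
#' @export
read_pathway_gmtx <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no pathways in ", path)
  defs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("line ", i, " of ", path, ": expected id, name and at least one GENE:ARR token")
    }
    toks <- strsplit(fields[-(1:2)], ":", fixed = TRUE)
    bad <- lengths(toks) != 2L
    if (any(bad)) {
      stop("line ", i, " of ", path, ": malformed token '",
           fields[-(1:2)][bad][1L], "' (expected GENE:ARR)")
    }
    arr <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 2L)))
    genes <- vapply(toks, `[`, character(1), 1L)
    if (anyNA(arr) || !all(arr %in% ARR_LEVELS)) {
      off <- which(is.na(arr) | !arr %in% ARR_LEVELS)[1L]
      stop(sprintf("line %d of %s: ARR '%s' for gene '%s' is not in {-1, -0.5, 0, 0.5, 1}",
                   i, path, vapply(toks, `[`, character(1), 2L)[off], genes[off]))
    }
    names(arr) <- genes
    pathway_definition(fields[1L], fields[2L], arr)
  })
  pathway_db(defs)
}

#' Write a pathway database in GMTX format
#' @param db a `pathway_db`.
#' @param path output file path.
#' @export
write_pathway_gmtx <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  lines <- vapply(db$pathways, function(p) {
    toks <- paste0(names(p$members), ":", fmt_num(p$members))
    paste(c(p$pathway_id, p$display_name, toks), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-target table
#'
#' One drug per line: `drug_name<TAB>GENE:w<TAB>...` with w in \{+1, -1\}.
#' The free-text `drug_class` annotation is not part of this format and
#' defaults to `""` on read.
#'
#' @param path file path.
#' @return list of [drug_definition()] objects, named by drug.
#' @export
read_drug_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no drugs in ", path)
  drugs <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L) stop("line ", i, " of ", path, ": expected drug name plus targets")
    toks <- strsplit(fields[-1L], ":", fixed = TRUE)
    if (any(lengths(toks) != 2L)) {
      stop("line ", i, " of ", path, ": malformed target token (expected GENE:+1 or GENE:-1)")
    }
    w <- suppressWarnings(as.numeric(vapply(toks, `[`, character(1), 2L)))
    names(w) <- vapply(toks, `[`, character(1), 1L)
    if (anyNA(w) || !all(w %in% c(-1, 1))) {
      stop("line ", i, " of ", path, ": target weights must be +1 or -1")
    }
    drug_definition(fields[1L], w)
  })
  names(drugs) <- vapply(drugs, function(d) d$drug_name, character(1))
  if (anyDuplicated(names(drugs))) stop("duplicate drug name(s) in ", path)
  drugs
}

#' Write a drug-target table
#' @param drugs list of `drug_definition` objects.
#' @param path output file path.
#' @export
write_drug_tsv <- function(drugs, path) {
  lines <- vapply(drugs, function(d) {
    stopifnot(inherits(d, "drug_definition"))
    paste(c(d$drug_name, paste0(names(d$targets), ":",
                                ifelse(d$targets > 0, "+1", "-1"))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Fixed header: `sample_id patient_id tumor_id region_id stage material
#' pfs_days event` (tab-separated); `pfs_days`/`event` may be `NA`.
#'
#' @param path file path.
#' @return a [sample_metadata()] data.frame.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         patient_id = "character",
                                         tumor_id = "character",
                                         region_id = "character"))
  sample_metadata(df)
}

#' Write sample metadata to TSV
#' @param meta a `sample_metadata` data.frame.
#' @param path output file path.
#' @export
write_metadata_tsv <- function(meta, path) {
  stopifnot(inherits(meta, "sample_metadata"))
  cols <- c("sample_id", "patient_id", "tumor_id", "region_id",
            "stage", "material", "pfs_days", "event")
  out <- as.data.frame(meta)[, cols]
  out$pfs_days <- ifelse(is.na(out$pfs_days), "NA", fmt_num(out$pfs_days))
  out$event <- ifelse(is.na(out$event), "NA", ifelse(out$event, "TRUE", "FALSE"))
  lines <- c(paste(cols, collapse = "\t"),
             apply(out, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a plain named numeric matrix (CNR, PAL, BES) to TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output file path.
#' @param id_col header label for the id column (default `"feature_id"`).
#' @export
write_matrix <- function(m, path, id_col = "feature_id") {
  if (inherits(m, "cnr_matrix")) m <- m$ratios
  if (inherits(m, "pal_matrix")) m <- m$pal
  write_id_matrix(m, path, id_col = id_col)
}

#' Read a plain feature-by-sample matrix written by [write_matrix()]
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix <- function(path) read_id_matrix(path)
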