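fixture_config <- function(size, seed) {
  switch(size,
    tiny = synthetic_config(
      seed = seed, n_genes = 50L, n_pathways = 5L,
      pathway_size_range = c(3L, 6L), n_normals = 4L, n_patients = 2L,
      regions_per_tumor = 1L, paired_fraction = 1, gsc_fraction = 1,
      signature_size = 10L, n_filler_drugs = 3L,
      planted_pathways = data.frame(pathway_id = "PW001", group = "recGB-up",
                                    delta = 1.0)),
    small = synthetic_config(
      seed = seed, n_genes = 5000L, n_pathways = 300L,
      n_normals = 10L, n_patients = 20L, regions_per_tumor = 2L,
      paired_fraction = 0.5, gsc_fraction = 1,
      planted_pathways = data.frame(
        pathway_id = c("PW001", "PW002", "PW003"),
        group = c("recGB-up", "recGB-up", "recGB-down"),
        delta = 1.0)),
    stop("size must be 'tiny' or 'small'"))
}

#' Write a complete worked-example bundle to disk
#'
#' Simulates a cohort at a fixed seed and writes every pipeline input in
#' its standard on-disk format -- expression counts, metadata, pathway
#' database, drug panel, subtype signatures -- together with truth tables,
#' the expected pathway-activation matrix produced by the scoring chain,
#' and an MD5 manifest so corruption is detectable. The `tiny` bundle (50
#' genes, 5 pathways, 12 samples) backs documentation examples and
#' end-to-end tests; `small` (5000 genes, 300 pathways, 100 samples) is a
#' realistic-scale workout.
#'
#' @param size `"tiny"` or `"small"`.
#' @param dir output directory (created if absent).
#' @param seed RNG seed (default 101).
#' @return invisibly, the directory path.
#' @export
make_fixture <- function(size = c("tiny", "small"), dir, seed = 101L) {
  size <- match.arg(size)
  cfg <- fixture_config(size, seed)
  sim <- simulate_cohort(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth_dir <- file.path(dir, "truth")
  if (!dir.exists(truth_dir)) dir.create(truth_dir)

  write_expression_tsv(sim$expression, file.path(dir, "expression.tsv"))
  write_metadata_tsv(sim$metadata, file.path(dir, "metadata.tsv"))
  write_pathway_gmtx(sim$pathway_db, file.path(dir, "pathways.gmtx"))
  write_drug_tsv(sim$drugs, file.path(dir, "drugs.tsv"))

  sig_lines <- vapply(sim$signatures, function(s) {
    paste(c(s$subtype_name, s$signature_genes), collapse = "\t")
  }, character(1))
  writeLines(sig_lines, file.path(dir, "signatures.tsv"))
  centroids <- vapply(sim$signatures, function(s) s$centroid,
                      numeric(length(sim$signatures[[1L]]$centroid)))
  colnames(centroids) <- vapply(sim$signatures, `[[`, character(1), "subtype_name")
  rownames(centroids) <- names(sim$signatures[[1L]]$centroid)
  write_id_matrix(centroids, file.path(dir, "centroids.tsv"), id_col = "gene_id")

  write_truth_df <- function(df, name) {
    lines <- c(paste(colnames(df), collapse = "\t"),
               if (nrow(df)) apply(df, 1L, function(r) paste(trimws(r), collapse = "\t")))
    writeLines(lines, file.path(truth_dir, name))
  }
  write_truth_df(sim$truth$groups, "groups.tsv")
  write_truth_df(sim$truth$planted_pathways, "planted_pathways.tsv")
  write_truth_df(sim$truth$planted_genes, "planted_genes.tsv")
  write_truth_df(sim$truth$subtypes, "subtypes.tsv")

  scored <- score_cohort(sim$expression, sim$metadata, sim$pathway_db)
  write_matrix(scored$pal, file.path(dir, "expected_pal.tsv"), id_col = "pathway_id")

  files <- sort(setdiff(list.files(dir, recursive = TRUE), "MANIFEST.md5"))
  md5 <- tools::md5sum(file.path(dir, files))
  writeLines(paste(unname(md5), files, sep = "  "), file.path(dir, "MANIFEST.md5"))
  invisible(dir)
}

#' Verify a fixture bundle against its MD5 manifest
#'
#' @param dir fixture directory written by [make_fixture()].
#' @return `TRUE` if every file matches; otherwise `FALSE` with the
#'   mismatching files in attribute `"mismatch"`.
#' @export
verify_fixture <- function(dir) {
  manifest <- file.path(dir, "MANIFEST.md5")
  if (!file.exists(manifest)) stop("no MANIFEST.md5 in ", dir)
  lines <- readLines(manifest)
  parts <- strsplit(lines, "  ", fixed = TRUE)
  expected <- stats::setNames(vapply(parts, `[`, character(1), 1L),
                              vapply(parts, `[`, character(1), 2L))
  actual <- tools::md5sum(file.path(dir, names(expected)))
  bad <- names(expected)[is.na(actual) | unname(actual) != unname(expected)]
  ok <- length(bad) == 0L
  if (!ok) attr(ok, "mismatch") <- bad
  ok
}
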