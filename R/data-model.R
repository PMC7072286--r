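#' Construct an expression matrix
#'
#' The central container of the pipeline: a genes-by-samples matrix of
#' nonnegative expression values (raw counts or library-size-normalized),
#' with gene symbols as row names and sample identifiers as column names.
#' A `is_normalized` flag records whether [normalize_counts()] has been
#' applied; downstream stages check it so that ratios are never computed
#' on raw counts by accident.
#'
#' @param values numeric matrix, genes in rows (HGNC-style symbols as
#'   rownames), samples in columns (unique ids as colnames); all entries
#'   finite and >= 0.
#' @param is_normalized logical flag; `FALSE` for raw counts.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `is_normalized`.
#' @seealso [read_expression_tsv()], [normalize_counts()]
#' @export
expression_matrix <- function(values, is_normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry gene row names and sample column names")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing")
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(values))) stop("sample ids must be unique")
  structure(list(values = values, is_normalized = isTRUE(is_normalized)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of pipeline containers
#' @param x an `expr_matrix`, `cnr_matrix` or `pal_matrix`.
#' @return character vector of ids.
#' @export
gene_ids <- function(x) UseMethod("gene_ids")
#' @export
gene_ids.expr_matrix <- function(x) rownames(x$values)
#' @export
gene_ids.cnr_matrix <- function(x) rownames(x$ratios)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.expr_matrix <- function(x) colnames(x$values)
#' @export
sample_ids.cnr_matrix <- function(x) colnames(x$ratios)
#' @export
sample_ids.pal_matrix <- function(x) colnames(x$pal)

#' Validate per-sample study metadata
#'
#' Sample annotations drive every group comparison in the pipeline: disease
#' stage (newly diagnosed `ndGB`, recurrent `recGB`, `secondary-recGB`, or
#' `normal` control), material (`tissue` or `GSC` stem-cell culture), and the
#' patient/tumor/region hierarchy of multi-region sampling. Optional
#' progression-free-survival fields support downstream stratification.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `tumor_id`,
#'   `region_id`, `stage`, `material`, and optionally `pfs_days`, `event`.
#'   `tumor_id`/`region_id` may be `NA` for normal controls.
#' @return the validated data.frame with class `sample_metadata` prepended.
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "patient_id", "tumor_id", "region_id", "stage", "material")
  miss <- setdiff(req, colnames(df))
  if (length(miss)) stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (!"pfs_days" %in% colnames(df)) df$pfs_days <- NA_real_
  if (!"event" %in% colnames(df)) df$event <- NA
  df$event <- as.logical(df$event)
  df$pfs_days <- as.numeric(df$pfs_days)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad_stage <- setdiff(unique(df$stage), STAGE_LEVELS)
  if (length(bad_stage)) stop("unknown stage value(s): ", paste(bad_stage, collapse = ", "))
  bad_mat <- setdiff(unique(df$material), MATERIAL_LEVELS)
  if (length(bad_mat)) stop("unknown material value(s): ", paste(bad_mat, collapse = ", "))
  has_tr <- !is.na(df$tumor_id) & !is.na(df$region_id)
  key <- paste(df$material[has_tr], df$tumor_id[has_tr], df$region_id[has_tr], sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (tumor_id, region_id) pair within a material")
  }
  if (any(!is.na(df$pfs_days) & is.na(df$event))) {
    stop("pfs_days present without an event indicator")
  }
  if (any(!is.na(df$pfs_days) & df$pfs_days <= 0)) stop("pfs_days must be positive")
  class(df) <- unique(c("sample_metadata", class(df)))
  df
}

#' Define a pathway with signed activator/repressor roles
#'
#' A pathway maps each member gene to a discrete activator/repressor role
#' (ARR) in \{-1, -0.5, 0, 0.5, 1\}: +1 a signal activator, -1 a signal
#' repressor, the half-values "more likely" activator/repressor, and 0 an
#' ambivalent or neutral member. Membership itself is the binary indicator
#' used by the activation-level formula; at least one member must have a
#' nonzero role or the pathway score is undefined.
#'
#' @param pathway_id unique identifier.
#' @param display_name human-readable name.
#' @param members named numeric vector, gene id -> ARR value.
#' @return an object of class `pathway_definition`.
#' @export
pathway_definition <- function(pathway_id, display_name, members) {
  if (!is.numeric(members) || is.null(names(members)) || any(names(members) == "")) {
    stop("members must be a named numeric vector of gene -> ARR")
  }
  if (anyDuplicated(names(members))) {
    stop("pathway '", pathway_id, "' lists a gene more than once")
  }
  bad <- !members %in% ARR_LEVELS
  if (any(bad)) {
    stop(sprintf("pathway '%s': ARR value %s for gene '%s' is not in {-1, -0.5, 0, 0.5, 1}",
                 pathway_id, format(members[bad][1L]), names(members)[bad][1L]))
  }
  if (!any(members != 0)) {
    stop("pathway '", pathway_id, "' has no member with nonzero ARR; activation level undefined")
  }
  structure(list(pathway_id = as.character(pathway_id),
                 display_name = as.character(display_name),
                 members = members),
            class = "pathway_definition")
}

#' Assemble a pathway database
#'
#' @param pathways list of [pathway_definition()] objects with unique ids.
#' @return object of class `pathway_db`; element `pathways` is the list,
#'   named by pathway id. The gene universe is always recomputed via
#'   [gene_universe()], never stored.
#' @export
pathway_db <- function(pathways) {
  if (!length(pathways)) stop("pathway database is empty")
  ok <- vapply(pathways, inherits, logical(1), "pathway_definition")
  if (!all(ok)) stop("all elements must be pathway_definition objects")
  ids <- vapply(pathways, function(p) p$pathway_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(pathways) <- ids
  structure(list(pathways = pathways), class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, %d genes in universe\n",
              length(x$pathways), length(gene_universe(x))))
  invisible(x)
}

#' @rdname pathway_db
#' @param db a `pathway_db`.
#' @export
gene_universe <- function(db) {
  stopifnot(inherits(db, "pathway_db"))
  sort(unique(unlist(lapply(db$pathways, function(p) names(p$members)), use.names = FALSE)))
}

#' Define a drug by its signed target genes
#'
#' Targets carry weight +1 for a molecular target or sensitizer (high
#' expression favors response) and -1 for a resistance factor (high
#' expression opposes response) -- e.g. MGMT, the canonical temozolomide
#' resistance factor, enters as a -1 target.
#'
#' @param drug_name drug identifier.
#' @param targets named numeric vector, gene id -> weight in \{+1, -1\}.
#' @param drug_class free-text class annotation (not serialized by
#'   [write_drug_tsv()]).
#' @return object of class `drug_definition`.
#' @export
drug_definition <- function(drug_name, targets, drug_class = "") {
  if (!is.numeric(targets) || !length(targets) || is.null(names(targets))) {
    stop("drug '", drug_name, "' needs at least one named target")
  }
  if (anyDuplicated(names(targets))) stop("drug '", drug_name, "' lists a target twice")
  if (!all(targets %in% c(-1, 1))) {
    stop("drug '", drug_name, "': target weights must be +1 or -1")
  }
  structure(list(drug_name = as.character(drug_name), targets = targets,
                 drug_class = as.character(drug_class)),
            class = "drug_definition")
}

#' Define a molecular subtype signature
#'
#' @param subtype_name e.g. "Proneural" or "Mesenchymal".
#' @param signature_genes nonempty unique character vector of gene ids.
#' @param centroid optional named numeric reference profile; when absent,
#'   [assign_subtype()] falls back to an indicator centroid over the
#'   signature genes.
#' @return object of class `subtype_signature`.
#' @export
subtype_signature <- function(subtype_name, signature_genes, centroid = NULL) {
  if (!length(signature_genes)) stop("signature_genes must be nonempty")
  if (anyDuplicated(signature_genes)) stop("signature_genes must be unique")
  if (!is.null(centroid) && (is.null(names(centroid)) || !is.numeric(centroid))) {
    stop("centroid must be a named numeric vector")
  }
  structure(list(subtype_name = as.character(subtype_name),
                 signature_genes = as.character(signature_genes),
                 centroid = centroid),
            class = "subtype_signature")
}

#' Normal-reference profile for case-to-normal ratios
#'
#' Per-gene average expression in a normal control group (the denominator
#' of every CNR), together with the number of controls it was built from.
#'
#' @param control_mean named numeric vector of per-gene control means
#'   (nonnegative; zeros are tolerated here but rejected by
#'   [compute_cnr()]).
#' @param n_controls number of control samples (>= 2).
#' @return object of class `normal_reference`.
#' @export
normal_reference <- function(control_mean, n_controls) {
  if (!is.numeric(control_mean) || is.null(names(control_mean))) {
    stop("control_mean must be a named numeric vector")
  }
  if (anyNA(control_mean) || any(!is.finite(control_mean)) || any(control_mean < 0)) {
    stop("control_mean must be finite and nonnegative")
  }
  if (any(control_mean == 0)) {
    warning("control_mean contains zeros; such genes cannot enter CNR computation")
  }
  if (n_controls < 2) stop("a normal reference needs at least 2 control samples")
  structure(list(gene_ids = names(control_mean), control_mean = control_mean,
                 n_controls = as.integer(n_controls)),
            class = "normal_reference")
}

#' Case-to-normal ratio matrix
#'
#' @param ratios strictly positive finite numeric matrix, genes x samples.
#' @return object of class `cnr_matrix`.
#' @export
cnr_matrix <- function(ratios) {
  if (!is.matrix(ratios) || !is.numeric(ratios)) stop("'ratios' must be a numeric matrix")
  if (is.null(rownames(ratios)) || is.null(colnames(ratios))) {
    stop("'ratios' must carry gene row names and sample column names")
  }
  if (anyNA(ratios) || any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("case-to-normal ratios must be strictly positive and finite")
  }
  structure(list(ratios = ratios), class = "cnr_matrix")
}

#' @export
print.cnr_matrix <- function(x, ...) {
  cat(sprintf("cnr_matrix: %d genes x %d samples\n", nrow(x$ratios), ncol(x$ratios)))
  invisible(x)
}
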