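#' Configuration for the synthetic glioblastoma cohort generator
#'
#' Collects every knob of [simulate_cohort()] with defaults chosen to
#' emulate the structure of a multi-region, longitudinally sampled
#' glioblastoma RNA-seq study: a normal-brain control group, patients
#' carrying newly diagnosed (`ndGB`) and/or recurrent (`recGB`) tumors
#' sampled in several regions, matched stem-cell cultures derived from a
#' subset of tumors, lognormal baseline expression with nested
#' patient/tumor/region variance components on the natural-log scale, and
#' negative-binomial counts around library-size-scaled latent means.
#' Planted pathway- and gene-level shifts between stages provide ground
#' truth for recovery tests.
#'
#' @param seed integer RNG seed; a fixed seed yields byte-identical output.
#' @param n_genes,n_pathways universe sizes.
#' @param pathway_size_range integer range of member counts per pathway.
#' @param activator_fraction probability that a nonneutral member is an
#'   activator (ARR > 0); magnitudes are drawn uniformly from \{0.5, 1\}.
#' @param neutral_fraction probability of a neutral (ARR = 0) member.
#' @param n_normals number of normal-brain control samples (>= 2).
#' @param n_patients number of tumor patients.
#' @param regions_per_tumor tissue samples per tumor.
#' @param paired_fraction fraction of patients sampled at both stages;
#'   the remaining patients alternate between single-stage ndGB and recGB.
#' @param gsc_fraction probability that a tumor contributes a derived
#'   stem-cell culture sample (shares the tumor's effects plus an
#'   independent culture shift).
#' @param baseline_log_mean,baseline_log_sd per-gene baseline distribution
#'   on the ln scale.
#' @param sigma_patient,sigma_tumor,sigma_region,sigma_gsc standard
#'   deviations of the nested random effects (ln scale).
#' @param planted_pathways data.frame with columns `pathway_id`, `group`
#'   (`"recGB-up"`/`"recGB-down"`), `delta` (ln-scale shift applied to
#'   members in the direction of their ARR sign, so the pathway activation
#'   level moves by `delta` in the designated direction in recGB samples).
#' @param planted_genes data.frame with columns `gene_id`, `group`, `delta`.
#' @param subtype_delta ln-scale elevation of a tumor's own subtype
#'   signature genes (two disjoint signatures are generated per cohort).
#' @param signature_size genes per subtype signature.
#' @param library_size_range uniform range of per-sample library-size
#'   multipliers.
#' @param nb_dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param n_filler_drugs number of randomly targeted drugs in the default
#'   panel.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_genes = 5000L, n_pathways = 300L,
                             pathway_size_range = c(5L, 20L),
                             activator_fraction = 0.7, neutral_fraction = 0.1,
                             n_normals = 10L, n_patients = 20L,
                             regions_per_tumor = 2L, paired_fraction = 0.5,
                             gsc_fraction = 0.5,
                             baseline_log_mean = 3, baseline_log_sd = 1,
                             sigma_patient = 0.3, sigma_tumor = 0.2,
                             sigma_region = 0.15, sigma_gsc = 0.3,
                             planted_pathways = NULL, planted_genes = NULL,
                             subtype_delta = 1.0, signature_size = 30L,
                             library_size_range = c(0.7, 1.3),
                             nb_dispersion = 0.1, n_filler_drugs = 8L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              activator_fraction = activator_fraction,
              neutral_fraction = neutral_fraction,
              n_normals = as.integer(n_normals),
              n_patients = as.integer(n_patients),
              regions_per_tumor = as.integer(regions_per_tumor),
              paired_fraction = paired_fraction, gsc_fraction = gsc_fraction,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              sigma_patient = sigma_patient, sigma_tumor = sigma_tumor,
              sigma_region = sigma_region, sigma_gsc = sigma_gsc,
              planted_pathways = normalize_planting(planted_pathways, "pathway_id"),
              planted_genes = normalize_planting(planted_genes, "gene_id"),
              subtype_delta = subtype_delta,
              signature_size = as.integer(signature_size),
              library_size_range = library_size_range,
              nb_dispersion = nb_dispersion,
              n_filler_drugs = as.integer(n_filler_drugs))
  sds <- c(cfg$baseline_log_sd, cfg$sigma_patient, cfg$sigma_tumor,
           cfg$sigma_region, cfg$sigma_gsc)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$n_normals < 2L) stop("need at least 2 normal controls")
  if (cfg$n_patients < 1L) stop("need at least 1 patient")
  deltas <- c(cfg$planted_pathways$delta, cfg$planted_genes$delta)
  if (length(deltas) && any(!is.finite(deltas))) stop("planted deltas must be finite")
  structure(cfg, class = "synthetic_config")
}

normalize_planting <- function(x, id_col) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x))) {
    out <- data.frame(id = character(), group = character(), delta = numeric(),
                      stringsAsFactors = FALSE)
    names(out)[1L] <- id_col
    return(out)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c(id_col, "group", "delta") %in% names(x))) {
    stop("planting table needs columns ", id_col, ", group, delta")
  }
  bad <- setdiff(unique(x$group), c("recGB-up", "recGB-down"))
  if (length(bad)) stop("planting group must be 'recGB-up' or 'recGB-down'")
  x[, c(id_col, "group", "delta")]
}

#' Simulate a complete synthetic cohort
#'
#' Generates, under a fixed seed, everything the pipeline consumes: a raw
#' count matrix (tumor tissue, stem-cell cultures and normal controls),
#' sample metadata, a signed pathway database, a default drug panel, a
#' pair of subtype signatures with centroids, and truth tables recording
#' every planted effect.
#'
#' Per gene g and sample j the latent ln-expression is
#' `baseline_g + patient + tumor + sample noise (+ culture shift for
#' stem-cell samples) + planted effects`, with all random effects
#' gene-specific and Gaussian. Planted pathway shifts are applied to each
#' member in the direction of its ARR sign (neutral members untouched), so
#' the expected pathway activation of a planted pathway moves by exactly
#' `delta` in recGB samples. Counts are drawn negative-binomially around
#' `library_size * exp(latent)`.
#'
#' Random draws are consumed in a fixed order ending with the count draws,
#' and planted shifts are deterministic; two configurations differing only
#' in their planting therefore generate the identical pathway database,
#' design and noise components.
#'
#' @param config a [synthetic_config()].
#' @return list with elements `expression` (raw-count `expr_matrix`
#'   including normal controls), `metadata`, `pathway_db`, `drugs`,
#'   `signatures` (list of two [subtype_signature()]), `truth` (list of
#'   data.frames: `groups`, `planted_pathways`, `planted_genes`,
#'   `subtypes`), `latent` (the noise-free ln-expression matrix, for
#'   diagnostics) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)

  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_log_mean, cfg$baseline_log_sd)
  names(baseline) <- genes

  ## pathway database
  pw_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  sizes <- sample(seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L]),
                  cfg$n_pathways, replace = TRUE)
  defs <- lapply(seq_len(cfg$n_pathways), function(k) {
    members <- sample(genes, sizes[k])
    neutral <- stats::runif(sizes[k]) < cfg$neutral_fraction
    sgn <- ifelse(stats::runif(sizes[k]) < cfg$activator_fraction, 1, -1)
    mag <- sample(c(0.5, 1), sizes[k], replace = TRUE)
    arr <- ifelse(neutral, 0, sgn * mag)
    if (!any(arr != 0)) arr[1L] <- 1
    names(arr) <- members
    pathway_definition(pw_ids[k], paste("Synthetic pathway", k), arr)
  })
  db <- pathway_db(defs)

  ## subtype signatures (disjoint gene sets)
  sig_genes <- sample(genes, 2L * cfg$signature_size)
  sig_pn <- sig_genes[seq_len(cfg$signature_size)]
  sig_mes <- sig_genes[cfg$signature_size + seq_len(cfg$signature_size)]
  union_genes <- sort(c(sig_pn, sig_mes))
  centroid_of <- function(own) {
    stats::setNames(exp(baseline[union_genes] +
                          cfg$subtype_delta * (union_genes %in% own)),
                    union_genes)
  }
  signatures <- list(
    subtype_signature("Proneural", sig_pn, centroid_of(sig_pn)),
    subtype_signature("Mesenchymal", sig_mes, centroid_of(sig_mes)))

  ## default drug panel (randomly targeted fillers)
  drugs <- list()
  if (cfg$n_filler_drugs > 0L) {
    drugs <- lapply(seq_len(cfg$n_filler_drugs), function(k) {
      nt <- sample(2:4, 1L)
      tg <- sample(genes, nt)
      w <- ifelse(stats::runif(nt) < 0.8, 1, -1)
      names(w) <- tg
      drug_definition(sprintf("Drug%02d", k), w, drug_class = "synthetic")
    })
    names(drugs) <- vapply(drugs, `[[`, character(1), "drug_name")
  }

  ## study design
  pts <- sprintf("P%02d", seq_len(cfg$n_patients))
  n_paired <- round(cfg$paired_fraction * cfg$n_patients)
  design <- do.call(rbind, lapply(seq_along(pts), function(i) {
    stages <- if (i <= n_paired) c("ndGB", "recGB")
      else if ((i - n_paired) %% 2L == 1L) "ndGB" else "recGB"
    data.frame(patient_id = pts[i], stage = stages, stringsAsFactors = FALSE)
  }))
  design$tumor_id <- paste0(design$patient_id, "_",
                            ifelse(design$stage == "ndGB", "nd", "rec"))
  has_gsc <- stats::runif(nrow(design)) < cfg$gsc_fraction
  subtype_draw <- sample(c("Proneural", "Mesenchymal"), nrow(design), replace = TRUE)

  meta_rows <- list()
  for (t in seq_len(nrow(design))) {
    for (r in seq_len(cfg$regions_per_tumor)) {
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = paste0(design$tumor_id[t], "_R", r),
        patient_id = design$patient_id[t], tumor_id = design$tumor_id[t],
        region_id = paste0("R", r), stage = design$stage[t],
        material = "tissue", stringsAsFactors = FALSE)
    }
    if (has_gsc[t]) {
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        sample_id = paste0(design$tumor_id[t], "_GSC"),
        patient_id = design$patient_id[t], tumor_id = design$tumor_id[t],
        region_id = "GSC", stage = design$stage[t],
        material = "GSC", stringsAsFactors = FALSE)
    }
  }
  normals <- sprintf("N%02d", seq_len(cfg$n_normals))
  for (nn in normals) {
    meta_rows[[length(meta_rows) + 1L]] <- data.frame(
      sample_id = nn, patient_id = nn, tumor_id = NA_character_,
      region_id = NA_character_, stage = "normal", material = "tissue",
      stringsAsFactors = FALSE)
  }
  meta <- sample_metadata(do.call(rbind, meta_rows))
  n_samples <- nrow(meta)

  ## validate planting against the generated universe
  bad_pw <- setdiff(cfg$planted_pathways$pathway_id, pw_ids)
  if (length(bad_pw)) stop("planted pathway id(s) not generated: ",
                           paste(bad_pw, collapse = ", "))
  bad_g <- setdiff(cfg$planted_genes$gene_id, genes)
  if (length(bad_g)) stop("planted gene id(s) not generated: ",
                          paste(bad_g, collapse = ", "))

  ## gene-specific random effects (subjects = patients + normal controls)
  subjects <- c(pts, normals)
  eff_subject <- matrix(stats::rnorm(cfg$n_genes * length(subjects),
                                     0, cfg$sigma_patient),
                        cfg$n_genes, dimnames = list(genes, subjects))
  eff_tumor <- matrix(stats::rnorm(cfg$n_genes * nrow(design), 0, cfg$sigma_tumor),
                      cfg$n_genes, dimnames = list(genes, design$tumor_id))
  eff_sample <- matrix(stats::rnorm(cfg$n_genes * n_samples, 0, cfg$sigma_region),
                       cfg$n_genes, dimnames = list(genes, meta$sample_id))
  gsc_samples <- meta$sample_id[meta$material == "GSC"]
  eff_gsc <- if (length(gsc_samples)) {
    matrix(stats::rnorm(cfg$n_genes * length(gsc_samples), 0, cfg$sigma_gsc),
           cfg$n_genes, dimnames = list(genes, gsc_samples))
  } else NULL
  lib <- stats::runif(n_samples, cfg$library_size_range[1L],
                      cfg$library_size_range[2L])

  ## assemble latent ln-expression (planted shifts are deterministic)
  latent <- matrix(baseline, cfg$n_genes, n_samples,
                   dimnames = list(genes, meta$sample_id))
  latent <- latent + eff_subject[, meta$patient_id, drop = FALSE]
  is_tumor <- !is.na(meta$tumor_id)
  latent[, is_tumor] <- latent[, is_tumor] +
    eff_tumor[, meta$tumor_id[is_tumor], drop = FALSE]
  latent <- latent + eff_sample
  if (length(gsc_samples)) latent[, gsc_samples] <- latent[, gsc_samples] + eff_gsc

  ## subtype signature elevation per tumor
  tumor_subtype <- stats::setNames(subtype_draw, design$tumor_id)
  if (cfg$subtype_delta != 0) {
    for (t in design$tumor_id) {
      own <- if (tumor_subtype[t] == "Proneural") sig_pn else sig_mes
      samp <- meta$sample_id[!is.na(meta$tumor_id) & meta$tumor_id == t]
      latent[own, samp] <- latent[own, samp] + cfg$subtype_delta
    }
  }

  rec_samples <- meta$sample_id[meta$stage == "recGB"]
  if (length(rec_samples)) {
    shift <- numeric(cfg$n_genes)
    names(shift) <- genes
    if (nrow(cfg$planted_pathways)) {
      for (k in seq_len(nrow(cfg$planted_pathways))) {
        row <- cfg$planted_pathways[k, ]
        dir <- if (row$group == "recGB-up") 1 else -1
        arr <- db$pathways[[row$pathway_id]]$members
        shift[names(arr)] <- shift[names(arr)] + dir * row$delta * sign(arr)
      }
    }
    if (nrow(cfg$planted_genes)) {
      for (k in seq_len(nrow(cfg$planted_genes))) {
        row <- cfg$planted_genes[k, ]
        dir <- if (row$group == "recGB-up") 1 else -1
        shift[row$gene_id] <- shift[row$gene_id] + dir * row$delta
      }
    }
    latent[, rec_samples] <- latent[, rec_samples] + shift
  }

  ## negative-binomial counts around library-scaled latent means
  mu <- sweep(exp(latent), 2L, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow(mu), dimnames = dimnames(mu))

  truth <- list(
    groups = data.frame(sample_id = meta$sample_id, stage = meta$stage,
                        material = meta$material, stringsAsFactors = FALSE),
    planted_pathways = cfg$planted_pathways,
    planted_genes = cfg$planted_genes,
    subtypes = data.frame(tumor_id = design$tumor_id,
                          subtype = unname(tumor_subtype),
                          stringsAsFactors = FALSE))

  list(expression = expression_matrix(counts, is_normalized = FALSE),
       metadata = meta, pathway_db = db, drugs = drugs,
       signatures = signatures, truth = truth, latent = latent,
       config = cfg)
}
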