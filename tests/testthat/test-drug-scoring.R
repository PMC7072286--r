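# minimal scorable scene: genes A..D, two pathways, configurable drug panel
scene_db <- pathway_db(list(
  pathway_definition("P1", "p1", c(A = 1, B = -0.5)),
  pathway_definition("P2", "p2", c(C = 1, D = 1))))

scene_cnr <- function(logv) {
  # logv: genes x samples matrix of ln CNR
  cnr_matrix(exp(logv))
}

test_that("null profile gives all-zero scores and thin panels error", {
  logv <- matrix(0, 4, 2, dimnames = list(c("A", "B", "C", "D"), c("S1", "S2")))
  cnr <- scene_cnr(logv)
  pal <- compute_pal(cnr, scene_db)
  drugs <- list(drug_definition("D1", c(A = 1)), drug_definition("D2", c(C = 1)))
  bes <- compute_bes(cnr, pal, drugs, scene_db)
  expect_equal(unname(bes$bes), matrix(0, 2, 2))
  expect_equal(unname(bes$G), matrix(0, 2, 2))

  expect_error(compute_bes(cnr, pal, drugs[1], scene_db), "fewer than 2")
  # drugs with no measured target are dropped before the panel-size check
  ghost <- list(drug_definition("D1", c(A = 1)), drug_definition("DX", c(ZZ = 1)))
  expect_error(suppressMessages(compute_bes(cnr, pal, ghost, scene_db)),
               "fewer than 2")
})

test_that("gene component is the weighted mean of target log-ratios", {
  logv <- matrix(c(2, 0, 0, 0), 4, 1, dimnames = list(c("A", "B", "C", "D"), "S1"))
  cnr <- scene_cnr(logv)
  pal <- compute_pal(cnr, scene_db)
  drugs <- list(drug_definition("TwoTargets", c(A = 1, B = 1)),
                drug_definition("Other", c(C = 1)))
  bes <- compute_bes(cnr, pal, drugs, scene_db)
  # mean of (2, 0) = 1
  expect_equal(bes$G["TwoTargets", "S1"], 1)
  expect_equal(bes$G["Other", "S1"], 0)
})

test_that("a resistance-weighted target lowers the score where it is overexpressed", {
  # MGMT-high sample vs MGMT-normal comparator, all else equal
  logv <- matrix(0, 4, 2, dimnames = list(c("MGMT", "B", "C", "D"), c("high", "ref")))
  logv["MGMT", "high"] <- 1
  db <- pathway_db(list(pathway_definition("Prep", "repair", c(MGMT = 1, B = 0.5)),
                        pathway_definition("P2", "p2", c(C = 1, D = 1))))
  cnr <- scene_cnr(logv)
  pal <- compute_pal(cnr, db)
  drugs <- list(drug_definition("TMZ", c(MGMT = -1)),
                drug_definition("Neutral", c(D = 1)))
  bes <- compute_bes(cnr, pal, drugs, db)
  expect_equal(bes$G["TMZ", "high"], -1)
  expect_equal(bes$G["TMZ", "ref"], 0)
  expect_lt(bes$bes["TMZ", "high"], bes$bes["TMZ", "ref"])
})

test_that("pathway component signs follow the target-weighted ARR consensus", {
  logv <- matrix(c(1, 1, 2, 2), 4, 1, dimnames = list(c("A", "B", "C", "D"), "S1"))
  cnr <- scene_cnr(logv)
  pal <- compute_pal(cnr, scene_db)
  drugs <- list(drug_definition("AntiA", c(A = 1)),    # s for P1 = sign(1*1) = +1
                drug_definition("ResistA", c(A = -1))) # s = -1
  bes <- compute_bes(cnr, pal, drugs, scene_db)
  expect_equal(bes$P["AntiA", "S1"], pal$pal["P1", "S1"])
  expect_equal(bes$P["ResistA", "S1"], -pal$pal["P1", "S1"])
  # antisymmetry of the gene component under weight flip
  expect_equal(bes$G["ResistA", "S1"], -bes$G["AntiA", "S1"])
})

test_that("a drug whose targets sit in no scored pathway falls back to z(G)", {
  logv <- matrix(c(1, 0, 0, 0, 0), 5, 1,
                 dimnames = list(c("A", "B", "C", "D", "X"), "S1"))
  cnr <- scene_cnr(logv)
  pal <- compute_pal(cnr, scene_db)
  drugs <- list(drug_definition("InPathway", c(A = 1)),
                drug_definition("Orphan", c(X = 1)),
                drug_definition("Orphan2", c(X = -1)))
  bes <- compute_bes(cnr, pal, drugs, scene_db)
  expect_true(is.na(bes$P["Orphan", "S1"]))
  expect_equal(bes$bes["Orphan", "S1"], bes$zG["Orphan", "S1"])
})

test_that("scores are invariant to a constant added to every drug's component", {
  set.seed(13)
  genes <- c("A", "B", "C", "D")
  logv <- matrix(stats::rnorm(8), 4, 2, dimnames = list(genes, c("S1", "S2")))
  cnr <- scene_cnr(logv)
  pal <- compute_pal(cnr, scene_db)
  drugs <- list(drug_definition("D1", c(A = 1, C = 1)),
                drug_definition("D2", c(B = -1)),
                drug_definition("D3", c(D = 1)))
  bes <- compute_bes(cnr, pal, drugs, scene_db)
  # shifting every gene's ln CNR by a constant shifts every G by the same
  # constant (all-positive weights aside, D2 flips it) -- instead verify the
  # z-score property directly: standardized columns have mean 0, sd 1
  expect_equal(unname(colMeans(bes$zG)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(bes$zG, 2, stats::sd)), c(1, 1), tolerance = 1e-12)

  # monotonicity: raising a +1 target's CNR never lowers that drug's G;
  # raising a -1 target's never raises it
  logv2 <- logv
  logv2["A", "S1"] <- logv2["A", "S1"] + 2
  bes2 <- compute_bes(scene_cnr(logv2), compute_pal(scene_cnr(logv2), scene_db),
                      drugs, scene_db)
  expect_gte(bes2$G["D1", "S1"], bes$G["D1", "S1"])
  logv3 <- logv
  logv3["B", "S1"] <- logv3["B", "S1"] + 2
  bes3 <- compute_bes(scene_cnr(logv3), compute_pal(scene_cnr(logv3), scene_db),
                      drugs, scene_db)
  expect_lte(bes3$G["D2", "S1"], bes$G["D2", "S1"])
})

test_that("group comparison and cross-set drug ranking behave on planted data", {
  set.seed(29)
  genes <- c("A", "B", "C", "D", "E", "F", "G", "H")
  n <- 20
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  # null drugs widen the panel so the within-sample standardization is not
  # dominated by the two planted drugs
  panel <- c(list(drug_definition("AntiA", c(A = 1)),
                  drug_definition("ResistA", c(A = -1)),
                  drug_definition("Other", c(C = 1, D = 1))),
             lapply(c("E", "F", "G", "H"), function(g) {
               drug_definition(paste0("Null", g), stats::setNames(1, g))
             }))
  make_bes <- function(shift_a) {
    logv <- matrix(stats::rnorm(8 * n, 0, 0.3), 8, n,
                   dimnames = list(genes, paste0("S", 1:n)))
    logv["A", labels] <- logv["A", labels] + shift_a
    cnr <- scene_cnr(logv)
    compute_bes(cnr, compute_pal(cnr, scene_db), panel, scene_db)
  }
  bes_t <- make_bes(2)
  cmp <- compare_bes_groups(bes_t, labels)
  expect_lt(cmp$wilcoxon_p[cmp$drug_name == "AntiA"], 0.05)
  expect_equal(cmp$direction[cmp$drug_name == "AntiA"], "up")
  expect_equal(cmp$direction[cmp$drug_name == "ResistA"], "down")

  # identical groups: p near 1, auc 0.5
  logv0 <- matrix(rep(stats::rnorm(8 * n / 2, 0, 0.3), 2), 8, n,
                  dimnames = list(genes, paste0("S", 1:n)))
  cnr0 <- scene_cnr(logv0)
  bes0 <- compute_bes(cnr0, compute_pal(cnr0, scene_db),
                      list(drug_definition("AntiA", c(A = 1)),
                           drug_definition("Other", c(C = 1))), scene_db)
  cmp0 <- compare_bes_groups(bes0, labels)
  expect_equal(cmp0$auc, c(0.5, 0.5))
  expect_true(all(cmp0$wilcoxon_p > 0.9))

  # cross-set ranking: drug differential in both sets is kept, tissue-only is not
  bes_g <- make_bes(2)
  tab <- rank_differential_drugs(bes_t, bes_g, labels, labels)
  expect_true("AntiA" %in% tab$drug_name)
  # exactly exchangeable culture set (duplicated columns): AUC 0.5 for every
  # drug by construction, so nothing survives the both-sets rule
  cnr_null <- scene_cnr(logv0)
  bes_g_null <- compute_bes(cnr_null, compute_pal(cnr_null, scene_db),
                            panel, scene_db)
  tab2 <- rank_differential_drugs(bes_t, bes_g_null, labels, labels)
  expect_equal(nrow(tab2), 0L)
  # and the kept set always equals the intersection of per-set significant calls
  sig_t <- with(compare_bes_groups(bes_t, labels), drug_name[significant])
  sig_g <- with(compare_bes_groups(bes_g, labels), drug_name[significant])
  expect_setequal(tab$drug_name, intersect(sig_t, sig_g))
})

test_that("patient stratification follows the majority-then-mean-sign rule", {
  meta <- sample_metadata(data.frame(
    sample_id = paste0("S", 1:6),
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P4"),
    tumor_id = paste0("T", 1:6), region_id = "R1",
    stage = "ndGB", material = "tissue", stringsAsFactors = FALSE))
  bes <- structure(list(bes = matrix(c(1, 2, -1, 1, -3, 0.5), 1,
                                     dimnames = list("TMZ", paste0("S", 1:6))),
                        panel = "TMZ"), class = "bes_matrix")
  out <- stratify_by_bes(bes, meta, "TMZ")
  expect_equal(out$stratum[out$patient_id == "P1"], "positive")   # (1, 2)
  expect_equal(out$stratum[out$patient_id == "P2"], "negative")   # (-1, 1): mean 0
  expect_equal(out$stratum[out$patient_id == "P3"], "negative")
  expect_equal(out$stratum[out$patient_id == "P4"], "positive")

  # a patient with no scored samples is excluded with a log message
  meta2 <- sample_metadata(rbind(as.data.frame(meta),
    data.frame(sample_id = "S9", patient_id = "P9", tumor_id = "T9",
               region_id = "R1", stage = "ndGB", material = "tissue",
               pfs_days = NA_real_, event = NA)))
  expect_message(out2 <- stratify_by_bes(bes, meta2, "TMZ"), "excluded 1")
  expect_false("P9" %in% out2$patient_id)

  expect_error(stratify_by_bes(bes, meta, "NotADrug"), "not in the scored panel")
})
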