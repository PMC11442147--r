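test_that("equal-cell subsampling takes min(k, n_p) per patient", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  ds <- sim$dataset
  idx <- subsampleEqualCells(ds, "type_1", k = 20, seed = 1)
  pat <- patientIDs(ds)[idx]
  expect_true(all(table(pat) == 20L))  # 25 available per patient
  ## boundary: k equals availability -> all cells, no replacement
  idx2 <- subsampleEqualCells(ds, "type_1", k = 25, seed = 1)
  expect_true(all(table(patientIDs(ds)[idx2]) == 25L))
  expect_false(anyDuplicated(idx2) > 0)
  ## membership: indices stay within the right patient and cell type
  expect_true(all(cellTypeLabels(ds)[idx] == "type_1"))
  expect_error(subsampleEqualCells(ds, "ghost", 5), "lookup error")
})

test_that("responsiveness scoring recovers the perturbed type on signal", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  resp <- rankCellTypes(sim$dataset, responsivenessConfig(seed = 1))
  sc <- responsivenessScores(resp)
  expect_identical(topCellTypes(resp), sim$truth$responsive_cell_type)
  expect_true(all(sc$mean_auroc >= 0 & sc$mean_auroc <= 1))
  expect_identical(sort(sc$rank), seq_len(nrow(sc)))
  ## mean_auroc consistent with the per-repeat scores
  for (ty in sc$cell_type)
    expect_equal(sc$mean_auroc[sc$cell_type == ty],
                 mean(resp@perRepeat[[ty]], na.rm = TRUE))
})

test_that("scoring is invariant to cell id relabeling", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  ds <- sim$dataset
  cfg <- responsivenessConfig(n_repeats = 3L, seed = 5)
  a <- scoreCellType(ds, "type_1", cfg)
  ds2 <- ds
  colnames(ds2) <- paste0("renamed_", seq_len(ncol(ds2)))
  b <- scoreCellType(ds2, "type_1", cfg)
  expect_equal(a$auroc_per_repeat, b$auroc_per_repeat)
})

test_that("no patient straddles the internal train/validation split", {
  ## exercised via the cell-wise/patient-wise contrast: patient-wise scores
  ## on a pure-noise type must hover near chance even with strong patient
  ## random effects, which is only possible if validation patients are
  ## disjoint from training patients
  sim <- cachedFixture("strong", prepared = TRUE)
  cfg <- responsivenessConfig(n_repeats = 8L, seed = 3)
  e <- scoreCellType(sim$dataset, "type_2", cfg)
  expect_lt(e$mean_auroc, 0.72)
  expect_gt(e$mean_auroc, 0.28)
})

test_that("permuting patient condition labels removes all signal", {
  sim <- cachedFixture("strong", prepared = TRUE)
  ds <- sim$dataset
  pat <- patientIDs(ds)
  upat <- sort(unique(pat))
  pcond <- vapply(upat, function(p)
    conditionLabels(ds)[pat == p][1L], integer(1L))
  set.seed(99)
  perm <- setNames(sample(pcond), upat)
  cd <- SummarizedExperiment::colData(ds)
  cd$condition <- unname(perm[pat])
  SummarizedExperiment::colData(ds) <- cd
  resp <- rankCellTypes(ds, responsivenessConfig(seed = 2))
  sc <- responsivenessScores(resp)
  expect_true(all(sc$mean_auroc > 0.35 & sc$mean_auroc < 0.65))
})

test_that("responsiveness rises monotonically with effect size", {
  aurocs <- vapply(c(0, 0.5, 1, 2), function(fc) {
    sim <- simulateDataset(simConfig(log2_fold_change = fc, seed = 11))
    ds <- suppressMessages(filterCellTypes(normalizeTotal(sim$dataset)))
    scoreCellType(ds, sim$truth$responsive_cell_type,
                  responsivenessConfig(seed = 11))$mean_auroc
  }, 0)
  expect_true(all(diff(aurocs) >= -0.02))
  expect_gt(aurocs[4], 0.9)
  expect_lt(aurocs[1], 0.65)
})

test_that("cell-wise splitting scores non-responsive types above patient-wise", {
  ## donor fingerprints leak when train and validation share patients
  diffs <- unlist(lapply(1:5, function(s) {
    sim <- cachedFixture("strong", seed = s, prepared = TRUE)
    vapply(setdiff(unique(cellTypeLabels(sim$dataset)),
                   sim$truth$responsive_cell_type), function(ty) {
      pw <- scoreCellType(sim$dataset, ty,
                          responsivenessConfig(n_repeats = 10L,
                                               seed = s))$mean_auroc
      cw <- scoreCellType(sim$dataset, ty,
                          responsivenessConfig(n_repeats = 10L,
                                               split_by = "cell",
                                               seed = s))$mean_auroc
      cw - pw
    }, 0)
  }))
  expect_gt(mean(diffs), 0)
})

test_that("scoring errors are informative", {
  sim <- smallSim()
  ds <- normalizeTotal(sim$dataset)
  expect_error(scoreCellType(ds, "ghost"), "lookup error")
  one_pat <- subsetDataset(ds, patients = c("ref_01", "per_01", "per_02"))
  expect_error(scoreCellType(one_pat, "type_1", responsivenessConfig()),
               "2 patients per condition")
})
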