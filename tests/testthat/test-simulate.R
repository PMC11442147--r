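test_that("simulation is byte-identical under a repeated seed", {
  a <- smallSim(seed = 42)
  b <- smallSim(seed = 42)
  expect_identical(as.matrix(SummarizedExperiment::assay(a$dataset,
                                                         "counts")),
                   as.matrix(SummarizedExperiment::assay(b$dataset,
                                                         "counts")))
  expect_identical(a$truth, b$truth)
  c <- smallSim(seed = 43)
  expect_false(identical(
    as.matrix(SummarizedExperiment::assay(a$dataset, "counts")),
    as.matrix(SummarizedExperiment::assay(c$dataset, "counts"))))
})

test_that("marker means in the responsive type recover the fold change", {
  sim <- cachedFixture("strong")
  ds <- sim$dataset
  truth <- sim$truth
  sel <- cellTypeLabels(ds) == truth$responsive_cell_type
  cond <- conditionLabels(ds)
  cnt <- as.matrix(SummarizedExperiment::assay(ds, "counts"))
  m <- cnt[truth$marker_genes, ]
  bg <- cnt[setdiff(rownames(ds), truth$marker_genes), ]
  ## chance imbalance in patient effects between classes is cancelled by
  ## normalizing the marker ratio by the non-marker ratio; the adjusted
  ## ratio recovers 2^log2FC = 4 within 10%
  ratio_m <- mean(m[, sel & cond == 1L]) / mean(m[, sel & cond == 0L])
  ratio_bg <- mean(bg[, sel & cond == 1L]) / mean(bg[, sel & cond == 0L])
  ratio <- ratio_m / ratio_bg
  expect_gt(ratio, 4 * 0.9)
  expect_lt(ratio, 4 * 1.1)
  ## non-responsive types show no such shift
  other <- cellTypeLabels(ds) != truth$responsive_cell_type
  ratio2 <- mean(m[, other & cond == 1L]) / mean(m[, other & cond == 0L])
  expect_lt(abs(ratio2 - 1), 0.25)
})

test_that("null cohorts are exchangeable across conditions", {
  ## pooled per-gene mean counts should not differ between conditions:
  ## rank test non-significant at alpha = 0.01 in >= 95% of 20 seeds
  nonsig <- vapply(1:20, function(s) {
    sim <- simulateDataset(simConfig(n_patients_per_class = 4L,
                                     n_cell_types = 2L,
                                     cells_per_patient_per_type = 15L,
                                     n_genes = 60L, n_marker_genes = 5L,
                                     log2_fold_change = 0, seed = s))
    m <- SummarizedExperiment::assay(sim$dataset, "counts")
    cond <- conditionLabels(sim$dataset)
    g1 <- Matrix::rowMeans(m[, cond == 1L])
    g0 <- Matrix::rowMeans(m[, cond == 0L])
    stats::wilcox.test(g1, g0)$p.value > 0.01
  }, logical(1L))
  expect_gte(mean(nonsig), 0.95)
})

test_that("fixture presets match their declared designs", {
  tiny <- cachedFixture("tiny")
  expect_lte(ncol(tiny$dataset), 2000L)
  null <- simulateDataset(simConfig(n_patients_per_class = 2L,
                                    cells_per_patient_per_type = 5L,
                                    n_genes = 30L, n_marker_genes = 3L,
                                    log2_fold_change = 0))
  expect_length(null$truth$marker_genes, 0L)
  imb <- makeFixture("imbalanced", seed = 1)
  lab <- imb$truth$patient_labels
  expect_equal(sum(lab == 1L), 15L)
  expect_equal(sum(lab == 0L), 5L)
  expect_error(makeFixture("nonexistent"), "lookup error")
})

test_that("generated cohorts pass the io invariants and retention filter", {
  sim <- cachedFixture("tiny")
  expect_true(validObject(sim$dataset))
  filtered <- suppressMessages(filterCellTypes(sim$dataset))
  expect_setequal(unique(cellTypeLabels(filtered)),
                  unique(cellTypeLabels(sim$dataset)))
})

test_that("degenerate simulator configs are rejected", {
  expect_error(simConfig(n_genes = 0), "config error")
  expect_error(simConfig(n_marker_genes = 10, n_genes = 10), "config error")
  expect_error(simConfig(log2_fold_change = -1), "config error")
})
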