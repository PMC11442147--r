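test_that("cell weights equalize patients within class and classes overall", {
  ## symmetric cohort: all weights equal
  pat <- rep(c("a", "b", "c", "d"), each = 5)
  cond <- rep(c(0L, 1L), each = 10)
  w <- computeCellWeights(pat, cond)
  expect_equal(w, rep(w[1], 20))
  ## a patient with 10x the cells gets 1/10 the per-cell weight
  pat2 <- c(rep("big", 20), rep("small", 2), rep("x", 5), rep("y", 5))
  cond2 <- c(rep(1L, 22), rep(0L, 10))
  w2 <- computeCellWeights(pat2, cond2)
  expect_equal(w2[1] * 10, w2[21])
  ## class totals match
  expect_equal(sum(w2[cond2 == 0L]), sum(w2[cond2 == 1L]))
  expect_error(computeCellWeights(pat, rep(1L, 20)), "both classes")
})

test_that("the cell graph is symmetric with degree >= k and declared ties", {
  set.seed(2)
  X <- matrix(rnorm(40 * 3), 40, 3)
  g <- buildCellGraph(X, k = 5)
  ## symmetry: every directed edge has its reverse
  key <- paste(g$i, g$j); rev <- paste(g$j, g$i)
  expect_setequal(key, rev)
  deg <- table(factor(g$i, levels = 1:40))
  expect_true(all(deg >= 5))
  ## three equidistant cells, k = 1: ties break by index order
  Y <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), 3, 2, byrow = TRUE)
  g3 <- buildCellGraph(Y, k = 1)
  expect_setequal(paste(g3$i, g3$j), paste(c(1, 2, 1, 3), c(2, 1, 3, 1)))
  ## duplicate points are fine (zero distances allowed)
  gd <- buildCellGraph(rbind(X[1:3, ], X[1:3, ]), k = 2)
  expect_true(all(table(factor(gd$i, levels = 1:6)) >= 2))
  expect_warning(buildCellGraph(X[1:4, ], k = 10), "clipped")
})

test_that("patient AUC is the rank statistic against the 0.5 reference", {
  expect_equal(patientAUC(rep(1, 5)), 1)
  expect_equal(patientAUC(rep(0.5, 4)), 0.5)
  expect_equal(patientAUC(c(0.9, 0.8, 0.3, 0.6)), 0.75)
  expect_error(patientAUC(numeric(0)), "no cells")
  ## invariant under strictly monotone transforms fixing 0.5
  set.seed(5)
  p <- runif(50)
  trans <- function(x) plogis(3 * qlogis(pmin(pmax(x, 1e-9), 1 - 1e-9)))
  expect_equal(patientAUC(p), patientAUC(trans(p)))
})

test_that("bootstrap p-values behave at the degenerate extremes", {
  expect_equal(bootstrapPvalue(rep(1, 10), B = 1000, seed = 1), 1 / 1001)
  expect_equal(bootstrapPvalue(rep(0.5, 10), B = 1000, seed = 1), 1)
  expect_warning(bootstrapPvalue(c(0.9, 0.8), B = 50, seed = 1),
                 "unstable")
  expect_error(bootstrapPvalue(0.7), ">= 2 cells")
})

test_that("bootstrap p matches an independent resampling loop under a seed", {
  set.seed(7)
  probs <- runif(30)
  B <- 500L
  got <- bootstrapPvalue(probs, B = B, seed = 42)
  ## independent re-implementation sharing the RNG protocol
  obs <- (sum(probs > 0.5) + 0.5 * sum(probs == 0.5)) / length(probs)
  boot <- respanel:::withSeed(42, {
    vapply(seq_len(B), function(b) {
      x <- probs[sample.int(length(probs), length(probs), replace = TRUE)]
      (sum(x > 0.5) + 0.5 * sum(x == 0.5)) / length(x)
    }, 0)
  })
  expected <- (1 + if (obs > 0.5) sum(boot <= 0.5) else
                 sum(boot >= 0.5)) / (B + 1)
  expect_equal(got, expected)
})

## Construct CellPredictions by hand for aggregation tests.
mkPreds <- function(consensus, patient, truth) {
  probs <- cbind(A = consensus, B = consensus, C = consensus)
  new("CellPredictions", probs = probs, consensus = consensus,
      patient = patient, cellIds = sprintf("c%d", seq_along(consensus)),
      truth = as.integer(truth))
}

test_that("patient report reproduces confusion-matrix arithmetic", {
  ## truth (1,1,0), predicted (1,0,0)
  preds <- mkPreds(c(rep(0.9, 4), rep(0.2, 4), rep(0.1, 4)),
                   rep(c("p1", "p2", "p3"), each = 4),
                   rep(c(1L, 1L, 0L), each = 4))
  rep <- classifyPatients(preds, B = 200, seed = 1)
  m <- cohortMetrics(rep)
  expect_equal(unname(m["accuracy"]), 2 / 3)
  expect_equal(unname(m["sensitivity"]), 1 / 2)
  expect_equal(unname(m["specificity"]), 1)
  expect_equal(unname(m["precision"]), 1)
  expect_equal(unname(m["F1"]), 2 / 3)
  ## all patients classified perfectly (both classes present)
  perf <- mkPreds(c(rep(1, 3), rep(1, 3), rep(0, 3)),
                  rep(c("p1", "p2", "p3"), each = 3), rep(c(1L, 0L),
                                                          c(6, 3)))
  expect_true(all(cohortMetrics(classifyPatients(perf, B = 200,
                                                 seed = 1)) == 1))
})

test_that("AUC exactly 0.5 is flagged undetermined and counted negative", {
  preds <- mkPreds(rep(0.5, 6), rep("p1", 6), rep(1L, 6))
  tab <- patientResults(classifyPatients(preds, B = 200, seed = 1))
  expect_identical(tab$predicted_label, 0L)
  expect_true(tab$undetermined)
  expect_equal(tab$p_value, 1)
})

test_that("consensus is the member median, order-invariant and bounded", {
  probs <- rbind(c(0.1, 0.2, 0.9, 0.8, 0.6),
                 c(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(apply(probs, 1, median), c(0.6, 0.5))
  ## 4-member fallback: even median
  expect_equal(median(c(0.1, 0.2, 0.9, 0.8)), 0.5)
  ## permutation invariance and min/max bounds
  set.seed(1)
  P <- matrix(runif(40 * 5), 40, 5)
  med <- apply(P, 1, median)
  expect_equal(apply(P[, sample(5)], 1, median), med)
  expect_true(all(med >= apply(P, 1, min) & med <= apply(P, 1, max)))
})

test_that("the ensemble trains, predicts and separates on strong signal", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  ds <- sim$dataset
  sp <- splitByPatient(ds, 0.25, seed = 2)
  tr <- subsetDataset(ds, patients = trainPatients(sp))
  te <- subsetDataset(ds, patients = testPatients(sp))
  panel <- sim$truth$marker_genes
  model <- trainEnsemble(tr, panel, cell_type = "type_1",
                         cfg = ensembleConfig(seed = 3))
  expect_setequal(names(model@members), c("LR", "SVM", "RF", "kNN", "GAT"))
  preds <- predictCells(model, te)
  expect_true(validObject(preds))
  ## every member separates held-out cells well on this effect size
  for (m in colnames(preds@probs)) {
    auc <- respanel:::cellAUROC(preds@truth, preds@probs[, m])
    expect_gt(auc, 0.8)
  }
  ## bit-exact reproducibility under the same seed (all members)
  model2 <- trainEnsemble(tr, panel, cell_type = "type_1",
                          cfg = ensembleConfig(seed = 3))
  preds2 <- predictCells(model2, te)
  expect_equal(preds2@probs, preds@probs, tolerance = 1e-12)
})

test_that("a single-gene panel still trains all members", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  ds <- sim$dataset
  sp <- splitByPatient(ds, 0.25, seed = 2)
  tr <- subsetDataset(ds, patients = trainPatients(sp))
  te <- subsetDataset(ds, patients = testPatients(sp))
  model <- trainEnsemble(tr, sim$truth$marker_genes[1],
                         cell_type = "type_1",
                         cfg = ensembleConfig(seed = 1,
                                              gat_max_epochs = 60L))
  preds <- predictCells(model, te)
  expect_equal(ncol(preds@probs), 5L)
  expect_true(all(preds@probs >= 0 & preds@probs <= 1))
})

test_that("disabling the graph member degrades to four with a warning", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  ds <- sim$dataset
  tr <- subsetDataset(ds, patients = trainPatients(
    splitByPatient(ds, 0.25, seed = 2)))
  expect_warning(
    model <- trainEnsemble(tr, sim$truth$marker_genes,
                           cell_type = "type_1",
                           cfg = ensembleConfig(gat = FALSE, seed = 1)),
    "4 members")
  expect_setequal(names(model@members), c("LR", "SVM", "RF", "kNN"))
})

test_that("missing panel genes in test data are a hard schema error", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  ds <- sim$dataset
  sp <- splitByPatient(ds, 0.25, seed = 2)
  tr <- subsetDataset(ds, patients = trainPatients(sp))
  te <- subsetDataset(ds, patients = testPatients(sp))
  model <- trainEnsemble(tr, sim$truth$marker_genes[1:3],
                         cell_type = "type_1",
                         cfg = ensembleConfig(seed = 1,
                                              gat_max_epochs = 60L))
  te_missing <- te[setdiff(rownames(te), sim$truth$marker_genes[1]), ]
  expect_error(predictCells(model, te_missing), "schema error.*gene")
})
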