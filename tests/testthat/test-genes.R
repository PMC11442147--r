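test_that("elimination schedule removes max(1, floor(fraction * n)) per step", {
  expect_identical(eliminationSchedule(10), as.integer(10:1))
  s1000 <- eliminationSchedule(1000)
  expect_identical(s1000[1:2], c(1000L, 970L))  # 3% of 1000 = 30 removed
  expect_identical(s1000[3], 941L)
  for (n in c(1L, 2L, 7L, 500L)) {
    s <- eliminationSchedule(n)
    expect_identical(s[1], n)
    expect_identical(s[length(s)], 1L)
    expect_true(all(diff(s) < 0))
  }
  expect_error(eliminationSchedule(0))
})

test_that("SVM-RFE ranks a perfect separator first", {
  set.seed(1)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(sep = y * 3 + rnorm(n, sd = 0.2), noise = rnorm(n))
  X <- scale(X)
  colnames(X) <- c("sep", "noise")
  r <- svmRfeRank(X, y)
  expect_identical(r[1], "sep")
  expect_setequal(r, colnames(X))  # ranking is a permutation
  expect_error(svmRfeRank(X, rep(0L, n)), "label error")
})

test_that("SVM-RFE recovers shifted genes on a 6-gene toy", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 80
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("g", 1:6)))
    X[y == 1L, 1:2] <- X[y == 1L, 1:2] + 3  # informative pair, 3 SD shift
    r <- svmRfeRank(scale(X), y)
    setequal(r[1:2], c("g1", "g2"))
  }, logical(1L))
  expect_gte(sum(hits), 19L)
})

test_that("SVM-RFE ranking is deterministic on fixed data", {
  set.seed(3)
  X <- matrix(rnorm(50 * 8), 50, 8, dimnames = list(NULL, paste0("g", 1:8)))
  y <- rep(c(0L, 1L), 25)
  expect_identical(svmRfeRank(scale(X), y), svmRfeRank(scale(X), y))
})

test_that("the perpendicular-line elbow matches hand-computed cases", {
  mk <- function(x, y) new("RFECurve", geneCounts = as.integer(x),
                           meanAccuracy = y, sdAccuracy = y * 0,
                           foldAccuracy = cbind(y), kFolds = 1L,
                           eliminationFraction = 0.03)
  ## knee right after the jump from 0.20 to 0.80
  expect_identical(findElbow(mk(5:1, c(0.93, 0.92, 0.90, 0.80, 0.20))), 2L)
  ## step function jumping at x = 18 on a 100-point curve
  x <- 100:1
  y <- ifelse(x >= 18, 0.95, 0.55)
  expect_identical(findElbow(mk(x, y)), 18L)
  ## collinear curve: warning + smallest count
  expect_warning(out <- findElbow(mk(10:1, seq(1, 0.1, length.out = 10))),
                 "collinear")
  expect_identical(out, 1L)
  expect_error(findElbow(mk(2:1, c(0.9, 0.5))), "degenerate")
})

test_that("elbow ties resolve to the sparser gene count", {
  ## symmetric tent: points 2 and 4 are equidistant from the chord
  curve <- new("RFECurve", geneCounts = c(5L, 4L, 3L, 2L, 1L),
               meanAccuracy = c(0.5, 0.8, 0.9, 0.8, 0.5),
               sdAccuracy = rep(0, 5), foldAccuracy = cbind(rep(0, 5)),
               kFolds = 1L, eliminationFraction = 0.03)
  expect_identical(findElbow(curve), 3L)
  tent <- new("RFECurve", geneCounts = c(4L, 3L, 2L, 1L),
              meanAccuracy = c(0.5, 0.9, 0.9, 0.5),
              sdAccuracy = rep(0, 4), foldAccuracy = cbind(rep(0, 4)),
              kFolds = 1L, eliminationFraction = 0.03)
  expect_identical(findElbow(tent), 2L)
})

test_that("the CV curve uses patient-grouped folds and supports k = 2", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  cfg <- geneSelectionConfig(k_folds = 2L, seed = 4)
  curve <- cvAccuracyCurve(sim$dataset, "type_1", cfg)
  expect_s4_class(curve, "RFECurve")
  expect_identical(curve@kFolds, 2L)
  expect_identical(curve@geneCounts[1], 120L)
  expect_identical(curve@geneCounts[length(curve@geneCounts)], 1L)
  expect_true(all(curve@meanAccuracy >= 0 & curve@meanAccuracy <= 1))
  ## high-count accuracies should be strong on the responsive type
  expect_gt(max(curve@meanAccuracy), 0.85)
})

test_that("k is lowered when a condition has too few patients", {
  sim <- cachedFixture("tiny", prepared = TRUE)  # 4 patients per class
  expect_message(
    curve <- cvAccuracyCurve(sim$dataset, "type_1",
                             geneSelectionConfig(k_folds = 5L, seed = 1)),
    "lowering k")
  expect_identical(curve@kFolds, 4L)
  small <- smallSim()$dataset
  one <- subsetDataset(normalizeTotal(small),
                       patients = c("ref_01", "per_01", "per_02"))
  expect_error(cvAccuracyCurve(one, "type_1", geneSelectionConfig()),
               "insufficient cohort")
})

test_that("panel selection returns unique in-dataset genes at the elbow size", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  cfg <- geneSelectionConfig(k_folds = 2L, seed = 2)
  panel <- selectGenePanel(sim$dataset, "type_1", cfg)
  g <- panelGenes(panel)
  expect_true(all(g %in% rownames(sim$dataset)))
  expect_false(anyDuplicated(g) > 0)
  expect_identical(length(g), panel@nOpt)
  expect_gte(panel@nOpt, 1L)
  expect_lte(panel@nOpt, nrow(sim$dataset))
  ## markers dominate the panel on this strong-signal fixture
  expect_gt(mean(g %in% sim$truth$marker_genes), 0.5)
})

test_that("stable-mode retention keeps genes strictly above the threshold", {
  ## 12/20 subsets -> kept (0.6 > 0.5); 10/20 -> dropped (0.5 not > 0.5)
  panels <- c(replicate(10, c("a", "b"), simplify = FALSE),
              replicate(2, c("b", "c"), simplify = FALSE),
              replicate(8, c("b"), simplify = FALSE))
  agg <- respanel:::.panelFromSubsets(panels, 0.5)
  expect_identical(agg$genes, "b")          # b: 20/20; a: 10/20; c: 2/20
  expect_equal(unname(agg$frequencies["a"]), 0.5)
  panels12 <- c(replicate(12, "a", simplify = FALSE),
                replicate(8, "z", simplify = FALSE))
  expect_identical(respanel:::.panelFromSubsets(panels12, 0.5)$genes, "a")
})

test_that("the fold-consensus final ranking is a valid alternative", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  keep <- union(sim$truth$marker_genes,
                setdiff(rownames(sim$dataset),
                        sim$truth$marker_genes)[1:30])
  ds <- subsetDataset(sim$dataset, genes = sort(keep))
  cfg <- geneSelectionConfig(k_folds = 2L, final_ranking = "consensus",
                             seed = 6)
  panel <- suppressMessages(selectGenePanel(ds, "type_1", cfg))
  g <- panelGenes(panel)
  expect_true(all(g %in% rownames(ds)))
  expect_false(anyDuplicated(g) > 0)
  expect_identical(length(g), panel@nOpt)
  ## markers in the fixture overlap the consensus panel too
  expect_gt(mean(g %in% sim$truth$marker_genes), 0)
})

test_that("stable selection never degrades cross-cohort panel agreement", {
  ## panels from disjoint cohorts of the same generative process; stable
  ## mode is meant to reduce selection variance, so its panels must agree
  ## across cohorts at least as well as standard panels (median pairwise
  ## Jaccard). Small cohorts keep both procedures noisy, making this a
  ## guard against stability actively hurting agreement.
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  std <- list(); stab <- list()
  for (s in 1:4) {
    sim <- simulateDataset(simConfig(
      n_patients_per_class = 5L, n_cell_types = 1L,
      cells_per_patient_per_type = 30L, n_genes = 60L,
      n_marker_genes = 6L, seed = 100 + s))
    ds <- suppressMessages(filterCellTypes(normalizeTotal(sim$dataset)))
    cfg <- geneSelectionConfig(k_folds = 2L, n_subsets = 6L, seed = s)
    std[[s]] <- panelGenes(suppressMessages(
      selectGenePanel(ds, "type_1", cfg)))
    stab[[s]] <- panelGenes(suppressMessages(suppressWarnings(
      stableGenePanel(ds, "type_1", cfg))))
  }
  pairs <- utils::combn(4, 2)
  med <- function(lst) median(apply(pairs, 2L, function(ij)
    jac(lst[[ij[1]]], lst[[ij[2]]])))
  expect_gte(med(stab), med(std))
})

test_that("stable selection bookkeeping matches a scripted recount", {
  sim <- cachedFixture("tiny", prepared = TRUE)
  ds <- subsetDataset(sim$dataset,
                      genes = rownames(sim$dataset)[1:40])
  cfg <- geneSelectionConfig(k_folds = 2L, n_subsets = 6L, seed = 9)
  panel <- stableGenePanel(ds, "type_1", cfg)
  subsets <- panel@subsetPanels
  expect_length(subsets, 6L)
  freq <- selectionFrequencies(panel)
  for (g in names(freq))
    expect_equal(unname(freq[g]),
                 mean(vapply(subsets, function(p) g %in% p, logical(1L))))
  ## the stable panel is a subset of the union of per-subset panels and
  ## respects the strict threshold
  expect_true(all(panelGenes(panel) %in% unlist(subsets)))
  expect_true(all(freq[panelGenes(panel)] > cfg$freq_threshold))
  ## reproducible under the same seed
  panel2 <- stableGenePanel(ds, "type_1", cfg)
  expect_identical(panelGenes(panel2), panelGenes(panel))
  expect_identical(selectionFrequencies(panel2), freq)
})
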