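#' Configuration for gene panel selection
#'
#' @param k_folds patient-grouped cross-validation folds (default 5; lowered
#'   automatically when a condition has fewer patients, minimum 2).
#' @param elimination_fraction fraction of remaining genes removed per
#'   recursive-elimination step (default 0.03; at least one gene is always
#'   removed).
#' @param cost linear SVM regularization constant C (default 1).
#' @param svm_tolerance libsvm convergence tolerance (default 0.01; loose
#'   enough for speed, tight enough for stable weight orderings).
#' @param cells_per_patient equal per-patient cell cap applied before every
#'   SVM fit (default 20, matching the responsiveness module; `Inf` disables).
#' @param n_subsets,subsample_fraction,freq_threshold stable-mode settings:
#'   number of patient-level downsamples (default 20), fraction of patients
#'   kept per class in each subset (default 0.8), and the strict selection
#'   frequency threshold for retention (default 0.5).
#' @param final_ranking `"full"` (rank on all cells; default) or
#'   `"consensus"` (average the per-fold ranks).
#' @param seed integer seed (default 1).
#' @return A `GeneSelectionConfig` list.
#' @export
geneSelectionConfig <- function(k_folds = 5L, elimination_fraction = 0.03,
                                cost = 1, svm_tolerance = 0.01,
                                cells_per_patient = 20L,
                                n_subsets = 20L, subsample_fraction = 0.8,
                                freq_threshold = 0.5,
                                final_ranking = c("full", "consensus"),
                                seed = 1L) {
  stopifnot(k_folds >= 2L, elimination_fraction > 0,
            elimination_fraction < 1, cost > 0)
  cfg <- list(k_folds = as.integer(k_folds),
              elimination_fraction = as.numeric(elimination_fraction),
              cost = as.numeric(cost),
              svm_tolerance = as.numeric(svm_tolerance),
              cells_per_patient = cells_per_patient,
              n_subsets = as.integer(n_subsets),
              subsample_fraction = as.numeric(subsample_fraction),
              freq_threshold = as.numeric(freq_threshold),
              final_ranking = match.arg(final_ranking),
              seed = as.integer(seed))
  class(cfg) <- "GeneSelectionConfig"
  cfg
}

#' Percentage elimination schedule
#'
#' Gene counts visited by recursive elimination: starting from `n_genes`,
#' each step removes `max(1, floor(fraction * current))` genes until one gene
#' remains.
#'
#' @param n_genes starting gene count (>= 1).
#' @param fraction elimination fraction per step (default 0.03).
#' @return Strictly decreasing integer vector from `n_genes` down to 1.
#' @examples
#' eliminationSchedule(10)   # 10 9 8 ... 1
#' head(eliminationSchedule(1000), 3)  # 1000 970 941
#' @export
eliminationSchedule <- function(n_genes, fraction = 0.03) {
  stopifnot(n_genes >= 1L, fraction > 0, fraction < 1)
  n <- as.integer(n_genes)
  out <- integer(0)
  while (n >= 1L) {
    out <- c(out, n)
    if (n == 1L) break
    n <- n - max(1L, as.integer(floor(fraction * n)))
  }
  out
}

## Linear SVM fit wrapper; class weights follow the minority-upweighting rule
## unless supplied.
.fitLinearSVM <- function(X, y, cost, tolerance, class_weights = NULL) {
  yfac <- factor(y, levels = c(0L, 1L))
  if (is.null(class_weights)) {
    n_tab <- table(yfac)
    class_weights <- as.numeric(length(y) / (2 * n_tab))
    names(class_weights) <- names(n_tab)
  }
  e1071::svm(x = X, y = yfac, kernel = "linear", cost = cost,
             scale = FALSE, class.weights = class_weights,
             tolerance = tolerance)
}

## Squared primal weights of a fitted linear SVM, per feature.
.svmWeights2 <- function(fit) {
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)^2
}

## Recursive elimination path. Returns the full ranking (best gene first) and,
## when a test set is supplied, the balanced accuracy of the SVM fitted at
## each schedule count, evaluated on the test cells.
.svmRfePath <- function(X, y, fraction, cost, tolerance,
                        class_weights = NULL, Xtest = NULL, ytest = NULL) {
  stopifnot(!is.null(colnames(X)))
  if (length(unique(y)) < 2L)
    stop("label error: both classes must be present")
  current <- colnames(X)
  batches <- list()
  counts <- integer(0)
  accs <- numeric(0)
  repeat {
    fit <- .fitLinearSVM(X[, current, drop = FALSE], y, cost, tolerance,
                         class_weights)
    if (!is.null(Xtest)) {
      pred <- predict(fit, Xtest[, current, drop = FALSE])
      counts <- c(counts, length(current))
      accs <- c(accs, balancedAccuracy(ytest,
                                       as.integer(as.character(pred))))
    }
    if (length(current) == 1L) break
    w2 <- .svmWeights2(fit)
    nrem <- max(1L, as.integer(floor(fraction * length(current))))
    ord <- order(w2)                      # ties: stable by column position
    drop_idx <- ord[seq_len(nrem)]
    ## within a removed batch, better genes (larger weight) rank ahead
    batches[[length(batches) + 1L]] <-
      current[drop_idx][order(w2[drop_idx], decreasing = TRUE)]
    current <- current[-drop_idx]
  }
  ranking <- c(current, unlist(rev(batches), use.names = FALSE))
  list(ranking = ranking,
       curve = if (!is.null(Xtest)) data.frame(count = counts,
                                               accuracy = accs))
}

#' Rank genes by SVM recursive feature elimination
#'
#' Fits a class-weighted linear SVM on standardized features, removes the
#' genes with the smallest squared primal coefficients
#' (`max(1, floor(fraction * current))` per step), and repeats until one gene
#' remains. The returned ranking orders genes by survival (rank 1 survives
#' longest); within an eliminated batch, larger weights rank ahead.
#'
#' @param X cells x genes matrix, already standardized (zero mean / unit
#'   variance), with column names.
#' @param y binary labels in \{0, 1\}.
#' @param class_weights optional named class weights `c("0" = , "1" = )`;
#'   defaults to minority-class upweighting `n / (2 n_c)`.
#' @param fraction elimination fraction (default 0.03).
#' @param cost,tolerance linear SVM settings.
#' @return Character vector of all genes, best first.
#' @export
svmRfeRank <- function(X, y, class_weights = NULL, fraction = 0.03,
                       cost = 1, tolerance = 0.01) {
  .svmRfePath(X, y, fraction, cost, tolerance,
              class_weights = class_weights)$ranking
}

## Equal per-patient subsample of row indices (cells) for SVM fitting.
.capCellsPerPatient <- function(pat, k, seed) {
  if (!is.finite(k)) return(seq_along(pat))
  withSeed(seed, {
    idx <- unlist(lapply(sort(unique(pat)), function(p) {
      own <- which(pat == p)
      if (length(own) <= k) own else sample(own, k)
    }), use.names = FALSE)
  })
  sort(idx)
}

#' Cross-validated accuracy curve for recursive gene elimination
#'
#' Partitions patients (never cells) into `k` condition-stratified folds. In
#' each fold, genes are ranked by SVM-RFE on the training patients' cells and
#' the balanced accuracy of the step SVM — fitted on the training cells
#' restricted to the genes surviving at that schedule count — is evaluated on
#' the held-out fold's cells. The curve is the per-count mean and sd across
#' folds.
#'
#' @param ds a normalized [SCDataset-class] restricted (or restrictable) to
#'   one cell type.
#' @param cell_type the cell type to work on.
#' @param cfg a [geneSelectionConfig()].
#' @return An [RFECurve-class].
#' @export
cvAccuracyCurve <- function(ds, cell_type, cfg = geneSelectionConfig()) {
  stopifnot(is(ds, "SCDataset"), inherits(cfg, "GeneSelectionConfig"))
  sub <- subsetDataset(ds, cellTypes = cell_type)
  pat <- patientIDs(sub); cond <- conditionLabels(sub)
  upat <- sort(unique(pat))
  pcond <- vapply(upat, function(p) cond[pat == p][1L], integer(1L))
  n_min <- min(table(factor(pcond, levels = c(0L, 1L))))
  if (n_min < 2L)
    stop("insufficient cohort: need >= 2 patients per condition")
  k <- cfg$k_folds
  if (n_min < k) {
    k <- max(2L, n_min)
    msg(sprintf("lowering k to %d (smallest condition has %d patients)",
                k, n_min))
  }
  fold_of <- patientFolds(upat, pcond, k, subSeed(cfg$seed, "folds",
                                                  cell_type))
  X <- .featureMatrix(sub)
  sched <- eliminationSchedule(ncol(X), cfg$elimination_fraction)
  accmat <- matrix(NA_real_, nrow = length(sched), ncol = k)
  for (f in seq_len(k)) {
    tr_pat <- upat[fold_of != f]
    te_pat <- upat[fold_of == f]
    tr_idx <- which(pat %in% tr_pat)
    te_idx <- which(pat %in% te_pat)
    tr_idx <- tr_idx[.capCellsPerPatient(pat[tr_idx], cfg$cells_per_patient,
                                         subSeed(cfg$seed, "cap", cell_type,
                                                 f))]
    st <- featureStats(X[tr_idx, , drop = FALSE])
    Xtr <- applyFeatureStats(X[tr_idx, , drop = FALSE], st)
    Xte <- applyFeatureStats(X[te_idx, , drop = FALSE], st)
    path <- .svmRfePath(Xtr, cond[tr_idx], cfg$elimination_fraction,
                        cfg$cost, cfg$svm_tolerance,
                        Xtest = Xte, ytest = cond[te_idx])
    stopifnot(identical(path$curve$count, sched))
    accmat[, f] <- path$curve$accuracy
  }
  new("RFECurve", geneCounts = sched,
      meanAccuracy = rowMeans(accmat),
      sdAccuracy = apply(accmat, 1L, stats::sd),
      foldAccuracy = accmat, kFolds = as.integer(k),
      eliminationFraction = cfg$elimination_fraction)
}

#' Elbow of an accuracy curve by the perpendicular-line rule
#'
#' With curve points ordered by increasing gene count, the chord joining the
#' two endpoints is drawn and the point with the maximal perpendicular
#' distance to it is chosen; ties go to the smaller gene count (the sparser
#' panel). An exactly collinear curve returns the smallest count with a
#' warning.
#'
#' @param curve an [RFECurve-class] (or anything with `geneCounts` /
#'   `meanAccuracy` slots) with at least 3 points.
#' @return The selected gene count (integer).
#' @export
findElbow <- function(curve) {
  x <- as.numeric(curve@geneCounts)
  y <- as.numeric(curve@meanAccuracy)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n < 3L)
    stop("degenerate curve: need at least 3 points")
  denom <- sqrt((y[n] - y[1L])^2 + (x[n] - x[1L])^2)
  d <- abs((y[n] - y[1L]) * x - (x[n] - x[1L]) * y +
             x[n] * y[1L] - y[n] * x[1L]) / denom
  if (max(d) < 1e-12) {
    warning("curve is collinear; returning the smallest gene count")
    return(as.integer(x[1L]))
  }
  best <- which(d >= max(d) - 1e-12)
  as.integer(min(x[best]))   # tie -> sparser panel
}

#' Select a sparse gene panel for one cell type
#'
#' Computes the cross-validated accuracy curve, picks the parsimonious gene
#' count with [findElbow()], derives the final gene ranking by SVM-RFE on all
#' cells of the cell type (equal per-patient subsample, standardized), and
#' returns the top genes in rank order. When the curve never reaches a mean
#' balanced accuracy of 0.7, the panel is flagged low-confidence.
#'
#' @param ds a normalized [SCDataset-class].
#' @param cell_type the (post-filter) cell type to select from.
#' @param cfg a [geneSelectionConfig()].
#' @return A [GenePanel-class] with the curve embedded.
#' @export
selectGenePanel <- function(ds, cell_type, cfg = geneSelectionConfig()) {
  curve <- cvAccuracyCurve(ds, cell_type, cfg)
  n_opt <- findElbow(curve)
  sub <- subsetDataset(ds, cellTypes = cell_type)
  pat <- patientIDs(sub)
  keep <- .capCellsPerPatient(pat, cfg$cells_per_patient,
                              subSeed(cfg$seed, "final", cell_type))
  X <- .featureMatrix(sub)[keep, , drop = FALSE]
  y <- conditionLabels(sub)[keep]
  st <- featureStats(X)
  ranking <- if (cfg$final_ranking == "full") {
    svmRfeRank(applyFeatureStats(X, st), y,
               fraction = cfg$elimination_fraction, cost = cfg$cost,
               tolerance = cfg$svm_tolerance)
  } else {
    .consensusRanking(ds, cell_type, cfg)
  }
  low <- max(curve@meanAccuracy) < 0.7
  if (low)
    msg(sprintf(
      "low-confidence panel for '%s': best curve accuracy %.2f < 0.7",
      cell_type, max(curve@meanAccuracy)))
  new("GenePanel", genes = ranking[seq_len(n_opt)],
      nOpt = as.integer(n_opt), sourceCellType = cell_type,
      frequencies = numeric(0), subsetPanels = list(), curve = curve,
      lowConfidence = low)
}

## Fold-consensus ranking: average the per-fold RFE ranks.
.consensusRanking <- function(ds, cell_type, cfg) {
  sub <- subsetDataset(ds, cellTypes = cell_type)
  pat <- patientIDs(sub); cond <- conditionLabels(sub)
  upat <- sort(unique(pat))
  pcond <- vapply(upat, function(p) cond[pat == p][1L], integer(1L))
  k <- min(cfg$k_folds, max(2L, min(table(factor(pcond,
                                                 levels = c(0L, 1L))))))
  fold_of <- patientFolds(upat, pcond, k, subSeed(cfg$seed, "folds",
                                                  cell_type))
  X <- .featureMatrix(sub)
  rk <- matrix(NA_real_, nrow = ncol(X), ncol = k,
               dimnames = list(colnames(X), NULL))
  for (f in seq_len(k)) {
    tr_idx <- which(pat %in% upat[fold_of != f])
    tr_idx <- tr_idx[.capCellsPerPatient(pat[tr_idx], cfg$cells_per_patient,
                                         subSeed(cfg$seed, "cap", cell_type,
                                                 f))]
    st <- featureStats(X[tr_idx, , drop = FALSE])
    r <- svmRfeRank(applyFeatureStats(X[tr_idx, , drop = FALSE], st),
                    cond[tr_idx], fraction = cfg$elimination_fraction,
                    cost = cfg$cost, tolerance = cfg$svm_tolerance)
    rk[r, f] <- seq_along(r)
  }
  names(sort(rowMeans(rk)))
}

## Retention rule shared by stable mode and its tests: fraction of subsets
## selecting each gene; keep genes strictly above the threshold, ordered by
## frequency, then mean within-panel rank, then name.
.panelFromSubsets <- function(panels, threshold) {
  n <- length(panels)
  all_genes <- sort(unique(unlist(panels, use.names = FALSE)))
  freq <- vapply(all_genes, function(g)
    mean(vapply(panels, function(p) g %in% p, logical(1L))), 0)
  mean_rank <- vapply(all_genes, function(g) {
    pos <- vapply(panels, function(p) {
      i <- match(g, p); if (is.na(i)) NA_real_ else as.numeric(i)
    }, 0)
    mean(pos, na.rm = TRUE)
  }, 0)
  keep <- all_genes[freq > threshold]
  keep <- keep[order(-freq[keep], mean_rank[keep], keep)]
  list(genes = keep, frequencies = freq, mean_rank = mean_rank)
}

#' Stable gene panel by repeated cohort downsampling
#'
#' Runs [selectGenePanel()] on `n_subsets` patient-level downsamples of the
#' cohort (a fraction of patients per class, drawn without replacement within
#' each subset) and retains the genes selected in strictly more than
#' `freq_threshold` of the subsets, ordered by selection frequency and then
#' mean within-panel rank. When a class is too small to downsample at the
#' patient level (fewer than 2 patients would remain), the subsets fall back
#' to cell-level downsampling with a warning.
#'
#' @param ds a normalized [SCDataset-class].
#' @param cell_type the cell type to select from.
#' @param cfg a [geneSelectionConfig()] (`n_subsets`, `subsample_fraction`,
#'   `freq_threshold`).
#' @return A [GenePanel-class] with `selectionFrequencies()` populated and
#'   the per-subset panels kept for bookkeeping.
#' @export
stableGenePanel <- function(ds, cell_type, cfg = geneSelectionConfig()) {
  stopifnot(inherits(cfg, "GeneSelectionConfig"))
  sub <- subsetDataset(ds, cellTypes = cell_type)
  pat <- patientIDs(sub); cond <- conditionLabels(sub)
  upat <- sort(unique(pat))
  pcond <- vapply(upat, function(p) cond[pat == p][1L], integer(1L))
  n_keep <- vapply(c(0L, 1L), function(cl)
    as.integer(floor(cfg$subsample_fraction * sum(pcond == cl))),
    integer(1L))
  patient_level <- all(n_keep >= 2L)
  if (!patient_level)
    warning("too few patients for patient-level downsampling; ",
            "falling back to cell-level downsampling")
  panels <- vector("list", cfg$n_subsets)
  for (b in seq_len(cfg$n_subsets)) {
    s <- subSeed(cfg$seed, "stable", cell_type, b)
    if (patient_level) {
      keep_pat <- withSeed(s, unlist(lapply(c(0L, 1L), function(cl)
        sample(upat[pcond == cl], n_keep[cl + 1L])), use.names = FALSE))
      dsub <- subsetDataset(sub, patients = keep_pat)
    } else {
      keep_cells <- withSeed(s,
        sort(sample(ncol(sub), max(2L, floor(cfg$subsample_fraction *
                                               ncol(sub))))))
      dsub <- sub[, keep_cells]
    }
    subcfg <- cfg
    subcfg$seed <- s
    panels[[b]] <- panelGenes(selectGenePanel(dsub, cell_type, subcfg))
  }
  agg <- .panelFromSubsets(panels, cfg$freq_threshold)
  new("GenePanel", genes = agg$genes, nOpt = length(agg$genes),
      sourceCellType = cell_type, frequencies = agg$frequencies,
      subsetPanels = panels, curve = NULL, lowConfidence = FALSE)
}
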