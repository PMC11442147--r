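#' Configuration for cell-type responsiveness scoring
#'
#' @param n_repeats number of subsample/split/fit repeats (default 20).
#' @param cells_per_patient equal number of cells drawn from every patient of
#'   the scored type per repeat (default 20; capped at each patient's
#'   available cells).
#' @param internal_validation_fraction fraction of patients held out for
#'   validation within each repeat, stratified by condition (default 0.25).
#' @param rf_trees random-forest trees (default 100).
#' @param rf_max_depth maximum tree depth (`NULL` = unlimited).
#' @param max_genes optional cap on the feature space; when set, the
#'   `max_genes` most variable genes are used.
#' @param split_by `"patient"` (the method's patient-held-out evaluation) or
#'   `"cell"` (naive cell-wise splitting, provided only to demonstrate the
#'   patient-leakage inflation it suffers).
#' @param seed integer seed (default 1).
#' @return A `ResponsivenessConfig` list.
#' @export
responsivenessConfig <- function(n_repeats = 20L, cells_per_patient = 20L,
                                 internal_validation_fraction = 0.25,
                                 rf_trees = 100L, rf_max_depth = NULL,
                                 max_genes = NULL,
                                 split_by = c("patient", "cell"),
                                 seed = 1L) {
  stopifnot(n_repeats >= 1L,
            internal_validation_fraction > 0,
            internal_validation_fraction < 1)
  cfg <- list(n_repeats = as.integer(n_repeats),
              cells_per_patient = as.integer(cells_per_patient),
              internal_validation_fraction =
                as.numeric(internal_validation_fraction),
              rf_trees = as.integer(rf_trees),
              rf_max_depth = rf_max_depth,
              max_genes = max_genes,
              split_by = match.arg(split_by),
              seed = as.integer(seed))
  class(cfg) <- "ResponsivenessConfig"
  cfg
}

#' Equal per-patient cell subsample
#'
#' Draws `min(k, n_p)` cells without replacement from every patient `p`
#' contributing cells of `cell_type`, so each patient enters the classifier
#' with the same weight of evidence. Deterministic under `seed`.
#'
#' @param ds an [SCDataset-class].
#' @param cell_type cell type to sample from.
#' @param k target cells per patient.
#' @param seed integer seed.
#' @return Integer indices into the columns of `ds`.
#' @export
subsampleEqualCells <- function(ds, cell_type, k, seed = 1L) {
  stopifnot(is(ds, "SCDataset"))
  sel <- which(cellTypeLabels(ds) == cell_type)
  if (!length(sel))
    stop("lookup error: cell type not present: ", cell_type)
  pat <- patientIDs(ds)[sel]
  withSeed(seed, {
    idx <- unlist(lapply(sort(unique(pat)), function(p) {
      own <- sel[pat == p]
      if (length(own) <= k) own else sample(own, k)
    }), use.names = FALSE)
  })
  sort(idx)
}

## One scoring repeat: subsample, split, fit RF, AUROC on held-out cells.
## Returns NA when the validation side degenerates to one condition.
.scoreRepeat <- function(X, pat, cond, cfg, seed) {
  upat <- sort(unique(pat))
  pat_cond <- vapply(upat, function(p) cond[pat == p][1L], integer(1L))
  if (cfg$split_by == "patient") {
    if (any(table(factor(pat_cond, levels = c(0L, 1L))) < 2L))
      return(NA_real_)
    val_pat <- character(0)
    withSeed(seed, {
      for (cl in c(0L, 1L)) {
        pats <- upat[pat_cond == cl]
        n_val <- max(1L, round(cfg$internal_validation_fraction *
                                 length(pats)))
        n_val <- min(n_val, length(pats) - 1L)
        val_pat <- c(val_pat, sample(pats, n_val))
      }
    })
    val <- pat %in% val_pat
  } else {
    withSeed(seed, {
      val <- logical(length(pat))
      for (cl in c(0L, 1L)) {
        idx <- which(cond == cl)
        n_val <- max(1L, round(cfg$internal_validation_fraction *
                                 length(idx)))
        val[sample(idx, min(n_val, length(idx) - 1L))] <- TRUE
      }
    })
  }
  ytr <- cond[!val]; yva <- cond[val]
  if (length(unique(yva)) < 2L || length(unique(ytr)) < 2L)
    return(NA_real_)
  ## Minority-class upweighting computed on the training cells of the repeat.
  n_tab <- table(factor(ytr, levels = c(0L, 1L)))
  cw <- as.numeric(length(ytr) / (2 * n_tab))
  names(cw) <- names(n_tab)
  fit <- ranger::ranger(x = X[!val, , drop = FALSE],
                        y = factor(ytr, levels = c(0L, 1L)),
                        num.trees = cfg$rf_trees,
                        max.depth = if (is.null(cfg$rf_max_depth)) 0L
                                    else cfg$rf_max_depth,
                        probability = TRUE, class.weights = cw,
                        seed = seed, num.threads = 1L, verbose = FALSE)
  prob <- predict(fit, data = X[val, , drop = FALSE],
                  num.threads = 1L)$predictions[, "1"]
  cellAUROC(yva, prob)
}

#' Score one cell type's responsiveness to the perturbation
#'
#' For each repeat: an equal number of cells is subsampled from every patient
#' of the type, patients (not cells) are split into internal training and
#' validation sets stratified by condition, a random forest with
#' minority-class weighting is fitted on the training patients' cells, and
#' the AUROC of its probabilities on the validation patients' cells is
#' recorded. Repeats whose validation side collapses to a single condition
#' are redrawn (up to 10 attempts) and then skipped with a warning.
#'
#' @param ds a normalized [SCDataset-class].
#' @param cell_type the type to score (needs >= 2 patients per condition).
#' @param cfg a [responsivenessConfig()].
#' @return List with `cell_type`, `mean_auroc`, `auroc_per_repeat`,
#'   `n_cells_used`, `n_patients_used`.
#' @export
scoreCellType <- function(ds, cell_type, cfg = responsivenessConfig()) {
  stopifnot(is(ds, "SCDataset"), inherits(cfg, "ResponsivenessConfig"))
  sel0 <- which(cellTypeLabels(ds) == cell_type)
  if (!length(sel0))
    stop("lookup error: cell type not present: ", cell_type)
  pat_all <- patientIDs(ds)[sel0]
  cond_all <- conditionLabels(ds)[sel0]
  pc <- vapply(sort(unique(pat_all)),
               function(p) cond_all[pat_all == p][1L], integer(1L))
  if (sum(pc == 0L) < 2L || sum(pc == 1L) < 2L)
    stop("scoring error: need >= 2 patients per condition in cell type '",
         cell_type, "'")
  sub <- ds[, sel0]
  X_full <- .featureMatrix(sub)
  if (!is.null(cfg$max_genes) && ncol(X_full) > cfg$max_genes) {
    v <- apply(X_full, 2L, stats::var)
    X_full <- X_full[, order(v, decreasing = TRUE)[seq_len(cfg$max_genes)],
                     drop = FALSE]
  }
  aurocs <- rep(NA_real_, cfg$n_repeats)
  n_cells_used <- 0L
  for (r in seq_len(cfg$n_repeats)) {
    for (attempt in 0:9) {
      s <- subSeed(cfg$seed, "celltype", cell_type, r, attempt)
      idx <- subsampleEqualCells(sub, cell_type, cfg$cells_per_patient,
                                 seed = s)
      n_cells_used <- max(n_cells_used, length(idx))
      a <- .scoreRepeat(X_full[idx, , drop = FALSE],
                        patientIDs(sub)[idx], conditionLabels(sub)[idx],
                        cfg, seed = subSeed(s, "split"))
      if (!is.na(a)) { aurocs[r] <- a; break }
    }
    if (is.na(aurocs[r]))
      warning("repeat ", r, " skipped for cell type '", cell_type,
              "': validation side kept collapsing to one condition")
  }
  if (all(is.na(aurocs)))
    stop("scoring error: all repeats skipped for cell type '", cell_type, "'")
  list(cell_type = cell_type,
       mean_auroc = mean(aurocs, na.rm = TRUE),
       auroc_per_repeat = aurocs,
       n_cells_used = n_cells_used,
       n_patients_used = length(pc))
}

#' Rank cell types by responsiveness score
#'
#' Scores every cell type present in `ds` with [scoreCellType()] and ranks
#' them by mean AUROC (descending); ties are broken by more cells used, then
#' lexicographic name. Types that fail to score are excluded with a warning.
#'
#' @param ds a normalized, filtered [SCDataset-class].
#' @param cfg a [responsivenessConfig()].
#' @return A [ResponsivenessTable-class].
#' @export
rankCellTypes <- function(ds, cfg = responsivenessConfig()) {
  stopifnot(is(ds, "SCDataset"))
  types <- sort(unique(cellTypeLabels(ds)))
  if (!length(types)) stop("no cell types present")
  entries <- list()
  for (ty in types) {
    e <- tryCatch(scoreCellType(ds, ty, cfg), error = function(err) {
      warning("excluding cell type '", ty, "': ", conditionMessage(err))
      NULL
    })
    if (!is.null(e)) entries[[ty]] <- e
  }
  if (!length(entries)) stop("scoring error: no cell type could be scored")
  tab <- data.frame(
    cell_type = vapply(entries, `[[`, "", "cell_type"),
    mean_auroc = vapply(entries, `[[`, 0, "mean_auroc"),
    sd_auroc = vapply(entries, function(e)
      stats::sd(e$auroc_per_repeat, na.rm = TRUE), 0),
    n_cells_used = vapply(entries, `[[`, 0L, "n_cells_used"),
    n_patients_used = vapply(entries, `[[`, 0L, "n_patients_used"),
    stringsAsFactors = FALSE)
  ord <- order(-tab$mean_auroc, -tab$n_cells_used, tab$cell_type)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("ResponsivenessTable", scores = tab,
      perRepeat = lapply(entries, `[[`, "auroc_per_repeat"),
      config = unclass(cfg))
}
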