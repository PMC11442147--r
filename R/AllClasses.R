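#' SCDataset: annotated single-cell expression for patient-level classification
#'
#' `SCDataset` extends [SingleCellExperiment::SingleCellExperiment] and is the
#' currency of the whole pipeline: a genes x cells expression matrix together
#' with the three per-cell annotations the method needs — patient identifier,
#' binary condition (0 = reference, 1 = perturbed) and cell-type label.
#' Raw counts live in the `"counts"` assay; [normalizeTotal()] adds a
#' `"logcounts"` assay and flips the `normalized` metadata flag. Externally
#' batch-corrected matrices can be supplied directly with
#' `layer = "corrected"`, which downstream steps accept as already normalized.
#'
#' Validity requires: unique gene and cell identifiers, the three annotation
#' columns present, condition constant within every patient, and non-negative
#' counts when the layer is `"raw"`.
#'
#' @slot int_metadata inherited; `metadata(x)$normalized` and
#'   `metadata(x)$layer` track normalization state.
#' @export
setClass("SCDataset", contains = "SingleCellExperiment")

.validSCDataset <- function(object) {
  errs <- character(0)
  cd <- SummarizedExperiment::colData(object)
  need <- c("patient", "condition", "cell_type")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(sprintf("missing cell annotation column(s): %s",
                   paste(miss, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    errs <- c(errs, "gene identifiers must be unique and non-empty")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    errs <- c(errs, "cell identifiers must be unique and non-empty")
  cond <- cd$condition
  if (!all(cond %in% c(0L, 1L)))
    errs <- c(errs, "condition must be coded 0 (reference) / 1 (perturbed)")
  mixed <- tapply(cond, cd$patient, function(x) length(unique(x)) > 1L)
  if (any(mixed))
    errs <- c(errs, sprintf("patient(s) with mixed conditions: %s",
                            paste(names(mixed)[mixed], collapse = ", ")))
  lay <- S4Vectors::metadata(object)$layer %||% "raw"
  if (identical(lay, "raw") &&
      "counts" %in% SummarizedExperiment::assayNames(object)) {
    if (min(SummarizedExperiment::assay(object, "counts")) < 0)
      errs <- c(errs, "raw counts must be non-negative")
  }
  if (length(errs)) errs else TRUE
}
setValidity("SCDataset", .validSCDataset)

#' Construct an SCDataset
#'
#' @param counts genes x cells matrix (dense or sparse), non-negative when
#'   `layer = "raw"`. Row names are gene identifiers, column names cell
#'   identifiers (or supply `gene_ids` / `cell_ids`).
#' @param patient character vector, one patient identifier per cell.
#' @param condition integer/numeric vector in {0, 1} per cell; constant within
#'   a patient (0 = reference class, 1 = perturbed class).
#' @param cell_type character vector of cell-type labels per cell.
#' @param gene_ids,cell_ids optional identifier vectors overriding dimnames.
#' @param condition_label optional character vector of the original condition
#'   labels (kept for provenance).
#' @param normalized logical; `TRUE` when `counts` is already on a
#'   normalized/corrected scale (stored as `"logcounts"`).
#' @param layer `"raw"`, `"normalized"` or `"corrected"`.
#' @return A validated [SCDataset-class] object.
#' @examples
#' m <- matrix(rpois(30, 5), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("c", 1:6)))
#' ds <- SCDataset(m, patient = rep(c("A", "B"), each = 3),
#'                 condition = rep(c(1, 0), each = 3),
#'                 cell_type = rep("T cell", 6))
#' @export
SCDataset <- function(counts, patient, condition, cell_type,
                      gene_ids = NULL, cell_ids = NULL,
                      condition_label = NULL,
                      normalized = FALSE, layer = "raw") {
  counts <- as(counts, "CsparseMatrix")
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(cell_ids)) colnames(counts) <- cell_ids
  n <- ncol(counts)
  stopifnot(length(patient) == n, length(condition) == n,
            length(cell_type) == n)
  cd <- S4Vectors::DataFrame(
    patient = as.character(patient),
    condition = as.integer(condition),
    cell_type = as.character(cell_type),
    row.names = colnames(counts))
  if (!is.null(condition_label))
    cd$condition_label <- as.character(condition_label)
  assays <- if (normalized) list(logcounts = counts) else list(counts = counts)
  sce <- SingleCellExperiment::SingleCellExperiment(assays = assays,
                                                    colData = cd)
  S4Vectors::metadata(sce)$normalized <- isTRUE(normalized)
  S4Vectors::metadata(sce)$layer <- if (normalized && layer == "raw")
    "normalized" else layer
  new("SCDataset", sce)
}

#' @describeIn SCDataset-class per-cell patient identifiers
#' @param x an `SCDataset`
#' @export
setGeneric("patientIDs", function(x) standardGeneric("patientIDs"))
#' @export
setMethod("patientIDs", "SCDataset",
          function(x) SummarizedExperiment::colData(x)$patient)

#' @describeIn SCDataset-class per-cell binary condition (0/1)
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @export
setMethod("conditionLabels", "SCDataset",
          function(x) SummarizedExperiment::colData(x)$condition)

#' @describeIn SCDataset-class per-cell cell-type labels
#' @export
setGeneric("cellTypeLabels", function(x) standardGeneric("cellTypeLabels"))
#' @export
setMethod("cellTypeLabels", "SCDataset",
          function(x) SummarizedExperiment::colData(x)$cell_type)

#' @describeIn SCDataset-class whether the dataset carries normalized values
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @export
setMethod("isNormalized", "SCDataset",
          function(x) isTRUE(S4Vectors::metadata(x)$normalized))

#' @export
setMethod("show", "SCDataset", function(object) {
  cat(sprintf("SCDataset: %d genes x %d cells\n",
              nrow(object), ncol(object)))
  pt <- patientIDs(object); cond <- conditionLabels(object)
  per <- tapply(cond, pt, function(x) x[1L])
  cat(sprintf("  patients: %d (%d reference / %d perturbed)\n",
              length(per), sum(per == 0L), sum(per == 1L)))
  cat(sprintf("  cell types: %s\n",
              paste(sort(unique(cellTypeLabels(object))), collapse = ", ")))
  cat(sprintf("  layer: %s (normalized: %s)\n",
              S4Vectors::metadata(object)$layer %||% "raw",
              isNormalized(object)))
})

#' Patient-wise train/test split
#'
#' Records which patients belong to the training and testing sides of a
#' stratified patient-level split. No patient appears on both sides and each
#' side holds at least one patient of each condition.
#'
#' @slot trainPatients,testPatients character vectors of patient identifiers.
#' @slot seed the integer seed that produced the split.
#' @export
setClass("SplitSpec", representation(trainPatients = "character",
                                     testPatients = "character",
                                     seed = "integer"))

setValidity("SplitSpec", function(object) {
  if (length(intersect(object@trainPatients, object@testPatients)))
    "train and test patient sets overlap" else TRUE
})

#' @export
setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: %d train / %d test patients (seed %d)\n",
              length(object@trainPatients), length(object@testPatients),
              object@seed))
})

#' @describeIn SplitSpec-class training-side patient identifiers
#' @param x a `SplitSpec`
#' @export
setGeneric("trainPatients", function(x) standardGeneric("trainPatients"))
#' @export
setMethod("trainPatients", "SplitSpec", function(x) x@trainPatients)
#' @describeIn SplitSpec-class testing-side patient identifiers
#' @export
setGeneric("testPatients", function(x) standardGeneric("testPatients"))
#' @export
setMethod("testPatients", "SplitSpec", function(x) x@testPatients)

#' Per-cell-type responsiveness scores
#'
#' One row per scored cell type: mean patient-held-out random-forest AUROC
#' (the responsiveness score), the per-repeat spread, the numbers of cells and
#' patients used, and the rank (1 = most responsive).
#'
#' @slot scores data.frame with columns `cell_type`, `mean_auroc`,
#'   `sd_auroc`, `n_cells_used`, `n_patients_used`, `rank`.
#' @slot perRepeat named list of per-repeat AUROC vectors.
#' @slot config the `responsivenessConfig()` used.
#' @export
setClass("ResponsivenessTable", representation(scores = "data.frame",
                                               perRepeat = "list",
                                               config = "list"))

#' @export
setMethod("show", "ResponsivenessTable", function(object) {
  cat("ResponsivenessTable (patient-held-out RF AUROC per cell type)\n")
  print(object@scores, row.names = FALSE)
})

#' @describeIn ResponsivenessTable-class the score table, ordered by rank
#' @param x a `ResponsivenessTable`
#' @export
setGeneric("responsivenessScores",
           function(x) standardGeneric("responsivenessScores"))
#' @export
setMethod("responsivenessScores", "ResponsivenessTable",
          function(x) x@scores)

#' @describeIn ResponsivenessTable-class cell type(s) with rank 1..n
#' @param n number of top-ranked cell types to return
#' @export
setGeneric("topCellTypes", function(x, n = 1L) standardGeneric("topCellTypes"))
#' @export
setMethod("topCellTypes", "ResponsivenessTable", function(x, n = 1L) {
  s <- x@scores[order(x@scores$rank), , drop = FALSE]
  head(s$cell_type, n)
})

#' Accuracy-versus-gene-count curve from grouped cross-validation
#'
#' The parsimony curve of recursive feature elimination: balanced accuracy of
#' a linear SVM at each retained gene count, averaged across patient-grouped
#' folds.
#'
#' @slot geneCounts strictly decreasing integer vector starting at the input
#'   gene count and ending at >= 1.
#' @slot meanAccuracy,sdAccuracy fold mean and sd of balanced accuracy at each
#'   count.
#' @slot foldAccuracy counts x folds matrix of per-fold accuracies.
#' @slot kFolds number of cross-validation folds used.
#' @slot eliminationFraction fraction of genes dropped per iteration.
#' @export
setClass("RFECurve", representation(geneCounts = "integer",
                                    meanAccuracy = "numeric",
                                    sdAccuracy = "numeric",
                                    foldAccuracy = "matrix",
                                    kFolds = "integer",
                                    eliminationFraction = "numeric"))

setValidity("RFECurve", function(object) {
  errs <- character(0)
  if (any(diff(object@geneCounts) >= 0))
    errs <- c(errs, "gene counts must be strictly decreasing")
  acc <- object@meanAccuracy
  if (any(acc < 0 | acc > 1, na.rm = TRUE))
    errs <- c(errs, "accuracies must lie in [0, 1]")
  if (length(errs)) errs else TRUE
})

#' @export
setMethod("show", "RFECurve", function(object) {
  cat(sprintf(
    "RFECurve: %d points from %d genes down to %d (%d folds, %.0f%% elimination)\n",
    length(object@geneCounts), max(object@geneCounts),
    min(object@geneCounts), object@kFolds,
    100 * object@eliminationFraction))
  cat(sprintf("  max mean balanced accuracy: %.3f\n",
              max(object@meanAccuracy)))
})

#' A selected sparse gene panel
#'
#' Ordered gene panel (most informative first) for one cell type, with the
#' cross-validation curve it came from, the elbow-selected size, and — in
#' stable mode — per-gene selection frequencies across downsampled cohorts.
#'
#' @slot genes ordered character vector of panel genes.
#' @slot nOpt elbow-selected gene count.
#' @slot sourceCellType the cell type the panel was selected from.
#' @slot frequencies named numeric selection frequencies (stable mode; empty
#'   otherwise).
#' @slot subsetPanels list of per-subset panels (stable mode bookkeeping).
#' @slot curve the `RFECurve` behind `nOpt` (standard mode).
#' @slot lowConfidence flag set when the best curve accuracy is below 0.7.
#' @export
setClass("GenePanel", representation(genes = "character",
                                     nOpt = "integer",
                                     sourceCellType = "character",
                                     frequencies = "numeric",
                                     subsetPanels = "list",
                                     curve = "ANY",
                                     lowConfidence = "logical"))

setValidity("GenePanel", function(object) {
  if (anyDuplicated(object@genes)) "panel genes must be unique" else TRUE
})

#' @export
setMethod("show", "GenePanel", function(object) {
  cat(sprintf("GenePanel: %d genes from cell type '%s'%s\n",
              length(object@genes), object@sourceCellType,
              if (isTRUE(object@lowConfidence)) " [low confidence]" else ""))
  cat("  ", paste(head(object@genes, 10L), collapse = ", "),
      if (length(object@genes) > 10L) ", ..." else "", "\n", sep = "")
  if (length(object@frequencies))
    cat(sprintf("  stable mode: %d subsets, frequencies %.2f-%.2f\n",
                length(object@subsetPanels),
                min(object@frequencies[object@genes]),
                max(object@frequencies[object@genes])))
})

#' @describeIn GenePanel-class the ordered panel genes
#' @param x a `GenePanel`
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @export
setMethod("panelGenes", "GenePanel", function(x) x@genes)

#' @describeIn GenePanel-class selection frequencies (stable mode)
#' @export
setGeneric("selectionFrequencies",
           function(x) standardGeneric("selectionFrequencies"))
#' @export
setMethod("selectionFrequencies", "GenePanel", function(x) x@frequencies)

#' Fitted cell-level classifier ensemble
#'
#' Holds the five (or, if the graph attention member is disabled, four)
#' fitted cell-level classifiers, the gene panel and cell type they were
#' trained on, and the training standardization statistics applied to any
#' future data.
#'
#' @slot members named list of fitted members (subset of LR, SVM, RF, kNN,
#'   GAT).
#' @slot panel the `GenePanel` used for training.
#' @slot cellType cell type the ensemble is restricted to.
#' @slot featureStats list(center, scale) from the training cells.
#' @slot config ensemble configuration (graph k, kNN k, GAT settings, seed).
#' @export
setClass("EnsembleModel", representation(members = "list",
                                         panel = "GenePanel",
                                         cellType = "character",
                                         featureStats = "list",
                                         config = "list"))

setValidity("EnsembleModel", function(object) {
  if (!length(object@panel@genes)) return("panel must be non-empty")
  ok <- names(object@members) %in% c("LR", "SVM", "RF", "kNN", "GAT")
  if (!all(ok)) return("unknown ensemble member name")
  TRUE
})

#' @export
setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: members {%s} on cell type '%s', %d panel genes\n",
              paste(names(object@members), collapse = ", "),
              object@cellType, length(object@panel@genes)))
})

#' Per-cell ensemble predictions
#'
#' Per-cell class-1 probabilities from every ensemble member plus their
#' element-wise median (the consensus probability used for all downstream
#' patient-level aggregation).
#'
#' @slot probs cells x members probability matrix.
#' @slot consensus per-cell median of the member probabilities.
#' @slot patient,cellIds per-cell patient and cell identifiers.
#' @slot truth per-cell true condition (NA when unknown).
#' @export
setClass("CellPredictions", representation(probs = "matrix",
                                           consensus = "numeric",
                                           patient = "character",
                                           cellIds = "character",
                                           truth = "integer"))

setValidity("CellPredictions", function(object) {
  p <- object@probs
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  med <- apply(p, 1L, stats::median)
  if (max(abs(med - object@consensus)) > 1e-12)
    return("consensus must be the element-wise median of member probabilities")
  TRUE
})

#' @export
setMethod("show", "CellPredictions", function(object) {
  cat(sprintf("CellPredictions: %d cells, members {%s}\n",
              nrow(object@probs), paste(colnames(object@probs),
                                        collapse = ", ")))
})

#' @describeIn CellPredictions-class consensus (median) probabilities
#' @param x a `CellPredictions`
#' @export
setGeneric("consensusProbs", function(x) standardGeneric("consensusProbs"))
#' @export
setMethod("consensusProbs", "CellPredictions", function(x) x@consensus)

#' Patient-level classification report
#'
#' Per-patient AUC score (rank statistic of the patient's consensus cell
#' probabilities against the 0.5 decision reference), bootstrap p-value,
#' predicted label, and — when truth is known — cohort-level accuracy,
#' precision, sensitivity, specificity and F1.
#'
#' @slot patients data.frame with columns `patient`, `auc`, `p_value`,
#'   `predicted_label`, `undetermined`, `n_cells` and (optionally)
#'   `true_label`.
#' @slot metrics named numeric vector of cohort metrics (empty without truth).
#' @export
setClass("PatientReport", representation(patients = "data.frame",
                                         metrics = "numeric"))

#' @export
setMethod("show", "PatientReport", function(object) {
  cat("PatientReport\n")
  print(object@patients, row.names = FALSE, digits = 3)
  if (length(object@metrics)) {
    cat("cohort metrics:\n")
    print(round(object@metrics, 3))
  }
})

#' @describeIn PatientReport-class per-patient results table
#' @param x a `PatientReport`
#' @export
setGeneric("patientResults", function(x) standardGeneric("patientResults"))
#' @export
setMethod("patientResults", "PatientReport", function(x) x@patients)

#' @describeIn PatientReport-class cohort metrics (named numeric)
#' @export
setGeneric("cohortMetrics", function(x) standardGeneric("cohortMetrics"))
#' @export
setMethod("cohortMetrics", "PatientReport", function(x) x@metrics)
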