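#' Load a single-cell dataset with patient/condition/cell-type annotations
#'
#' Reads one of three dialects into an [SCDataset-class]:
#' \describe{
#'   \item{`"csv"`}{`<path>` is a counts CSV (cells as rows, genes as columns,
#'     first column the cell identifier) with a sibling `cells.csv` keyed by
#'     cell id carrying the annotation columns.}
#'   \item{`"mtx"`}{`<path>` is a directory holding a 10x-style triplet
#'     `matrix.mtx` (genes x cells, MatrixMarket coordinate), `features.tsv`
#'     (id, symbol), `barcodes.tsv`, plus a `cells.tsv` sidecar with the
#'     annotation columns.}
#'   \item{`"h5ad"`}{an AnnData HDF5 file (`X`, `obs`, `var`); converted via
#'     the bundled Python bridge (requires `python` with `anndata` on the
#'     PATH).}
#' }
#' The condition column must hold exactly two distinct values;
#' `positive_label` is mapped to 1 (perturbed) and the other value to 0.
#'
#' @param path file (csv, h5ad) or directory (mtx).
#' @param format one of `"csv"`, `"mtx"`, `"h5ad"`.
#' @param patient_key,condition_key,celltype_key names of the annotation
#'   columns.
#' @param positive_label condition value to encode as 1.
#' @return An [SCDataset-class] with the raw layer preserved.
#' @seealso [saveDataset()] for the matching writers.
#' @export
loadDataset <- function(path, format = c("csv", "mtx", "h5ad"),
                        patient_key = "patient",
                        condition_key = "condition",
                        celltype_key = "cell_type",
                        positive_label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path)
  parts <- switch(format,
    csv = .readCSVDialect(path),
    mtx = .readMTXDialect(path),
    h5ad = .readH5ADDialect(path))
  ann <- parts$ann
  for (key in c(patient_key, condition_key, celltype_key)) {
    if (!key %in% colnames(ann))
      stop("annotation error: column '", key, "' not found (available: ",
           paste(colnames(ann), collapse = ", "), ")")
  }
  condraw <- as.character(ann[[condition_key]])
  vals <- sort(unique(condraw))
  if (length(vals) != 2L)
    stop("cardinality error: condition column '", condition_key,
         "' has ", length(vals), " distinct values (need exactly 2): ",
         paste(vals, collapse = ", "))
  if (is.null(positive_label)) positive_label <- vals[2L]
  if (!positive_label %in% vals)
    stop("positive_label '", positive_label,
         "' not among condition values: ", paste(vals, collapse = ", "))
  cond <- as.integer(condraw == positive_label)
  pat <- as.character(ann[[patient_key]])
  mixed <- tapply(cond, pat, function(x) length(unique(x)) > 1L)
  if (any(mixed))
    stop("consistency error: patient(s) with mixed conditions: ",
         paste(names(mixed)[mixed], collapse = ", "))
  SCDataset(parts$counts,
            patient = pat, condition = cond,
            cell_type = as.character(ann[[celltype_key]]),
            condition_label = condraw)
}

.readCSVDialect <- function(path) {
  x <- read.csv(path, check.names = FALSE)
  cell_ids <- as.character(x[[1L]])
  m <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- cell_ids
  sidecar <- file.path(dirname(path), "cells.csv")
  if (!file.exists(sidecar))
    stop("annotation error: sidecar not found: ", sidecar)
  ann <- read.csv(sidecar, check.names = FALSE)
  rownames(ann) <- as.character(ann[[1L]])
  if (!all(cell_ids %in% rownames(ann)))
    stop("annotation error: cells.csv is missing entries for some cells")
  ann <- ann[cell_ids, , drop = FALSE]
  list(counts = Matrix::t(Matrix::Matrix(m, sparse = TRUE)), ann = ann)
}

.readMTXDialect <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  feats <- file.path(path, "features.tsv")
  bars <- file.path(path, "barcodes.tsv")
  cells <- file.path(path, "cells.tsv")
  for (f in c(mtx, feats, bars, cells))
    if (!file.exists(f)) stop("annotation error: missing file: ", f)
  m <- as(Matrix::readMM(mtx), "CsparseMatrix")  # genes x cells on disk
  ft <- read.delim(feats, header = FALSE)
  bc <- read.delim(bars, header = FALSE)
  rownames(m) <- as.character(ft[[1L]])
  colnames(m) <- as.character(bc[[1L]])
  ann <- read.delim(cells)
  rownames(ann) <- as.character(ann[[1L]])
  if (!all(colnames(m) %in% rownames(ann)))
    stop("annotation error: cells.tsv is missing entries for some barcodes")
  ann <- ann[colnames(m), , drop = FALSE]
  list(counts = m, ann = ann)
}

.pythonBin <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("h5ad support needs a 'python' executable with anndata installed")
  py
}

.h5adBridge <- function() {
  system.file("python", "h5ad_bridge.py", package = "respanel",
              mustWork = TRUE)
}

.readH5ADDialect <- function(path) {
  tmp <- tempfile("h5ad2mtx")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  rc <- system2(.pythonBin(),
                c(.h5adBridge(), "to-mtx", shQuote(path), shQuote(tmp)),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(rc, "status")))
    stop("h5ad conversion failed: ", paste(rc, collapse = "\n"))
  .readMTXDialect(tmp)
}

#' Write a dataset in any supported dialect
#'
#' Emits exactly the layouts [loadDataset()] reads, so `load(save(x))`
#' round-trips counts, identifiers and annotations.
#'
#' @param ds an [SCDataset-class] (the raw counts assay is written when
#'   present, otherwise the logcounts assay).
#' @param path output CSV file (csv), directory (mtx) or h5ad file.
#' @param format one of `"csv"`, `"mtx"`, `"h5ad"`.
#' @return `path`, invisibly.
#' @export
saveDataset <- function(ds, path, format = c("csv", "mtx", "h5ad")) {
  format <- match.arg(format)
  stopifnot(is(ds, "SCDataset"))
  anames <- SummarizedExperiment::assayNames(ds)
  m <- SummarizedExperiment::assay(ds,
    if ("counts" %in% anames) "counts" else anames[1L])
  cd <- SummarizedExperiment::colData(ds)
  cond_out <- if ("condition_label" %in% colnames(cd)) cd$condition_label
              else as.character(conditionLabels(ds))
  ann <- data.frame(cell_id = colnames(ds),
                    patient = patientIDs(ds),
                    condition = cond_out,
                    cell_type = cellTypeLabels(ds),
                    stringsAsFactors = FALSE)
  switch(format,
    csv = {
      dense <- as.matrix(Matrix::t(m))
      out <- data.frame(cell_id = rownames(dense), dense,
                        check.names = FALSE)
      write.csv(out, path, row.names = FALSE)
      write.csv(ann, file.path(dirname(path), "cells.csv"),
                row.names = FALSE)
    },
    mtx = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      Matrix::writeMM(as(m, "generalMatrix"), file.path(path, "matrix.mtx"))
      write.table(data.frame(rownames(m), rownames(m)),
                  file.path(path, "features.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE, col.names = FALSE)
      write.table(data.frame(colnames(m)), file.path(path, "barcodes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      write.table(ann, file.path(path, "cells.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    },
    h5ad = {
      tmp <- tempfile("mtx2h5ad")
      on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
      saveDataset(ds, tmp, format = "mtx")
      rc <- system2(.pythonBin(),
                    c(.h5adBridge(), "to-h5ad", shQuote(tmp), shQuote(path)),
                    stdout = TRUE, stderr = TRUE)
      if (!is.null(attr(rc, "status")))
        stop("h5ad conversion failed: ", paste(rc, collapse = "\n"))
    })
  invisible(path)
}

#' Total-count normalization with log transform
#'
#' Scales every cell to the same total (counts-per-`scale`) and applies
#' `log(1 + x)`, the standard UMI normalization. Cells with a zero total are
#' removed (their number is reported). The result carries a `"logcounts"`
#' assay and is flagged normalized; a second call errors.
#'
#' @param ds a raw [SCDataset-class].
#' @param scale target per-cell total (default `1e4`).
#' @return The normalized dataset.
#' @export
normalizeTotal <- function(ds, scale = 1e4) {
  stopifnot(is(ds, "SCDataset"))
  if (isNormalized(ds))
    stop("state error: dataset is already normalized")
  m <- SummarizedExperiment::assay(ds, "counts")
  tot <- Matrix::colSums(m)
  drop <- tot == 0
  if (any(drop)) {
    msg(sprintf("dropping %d cell(s) with zero total counts", sum(drop)))
    ds <- ds[, !drop]
    m <- m[, !drop, drop = FALSE]
    tot <- tot[!drop]
  }
  norm <- m %*% Matrix::Diagonal(x = scale / tot)
  dimnames(norm) <- dimnames(m)
  norm@x <- log1p(norm@x)
  SummarizedExperiment::assay(ds, "logcounts") <- norm
  S4Vectors::metadata(ds)$normalized <- TRUE
  S4Vectors::metadata(ds)$layer <- "normalized"
  S4Vectors::metadata(ds)$norm_scale <- scale
  ds
}

#' Retain cell types with enough cells in enough patients per class
#'
#' Keeps only cell types for which, in each condition separately, at least
#' `min_patients` patients each contribute at least `min_cells` cells of that
#' type. Removed types are reported.
#'
#' @param ds an [SCDataset-class] containing both conditions.
#' @param min_cells minimum cells per qualifying patient (default 20).
#' @param min_patients minimum qualifying patients per condition (default 3).
#' @return The filtered dataset.
#' @export
filterCellTypes <- function(ds, min_cells = 20L, min_patients = 3L) {
  stopifnot(is(ds, "SCDataset"))
  cond <- conditionLabels(ds)
  if (length(unique(cond)) < 2L)
    stop("both conditions must be present before filtering")
  ct <- cellTypeLabels(ds); pat <- patientIDs(ds)
  keep <- vapply(unique(ct), function(type) {
    sel <- ct == type
    all(vapply(c(0L, 1L), function(cl) {
      n_per_pat <- table(pat[sel & cond == cl])
      sum(n_per_pat >= min_cells) >= min_patients
    }, logical(1L)))
  }, logical(1L))
  removed <- unique(ct)[!keep]
  if (length(removed))
    msg("removing cell type(s) below retention thresholds: ",
        paste(removed, collapse = ", "))
  if (!any(keep))
    stop("no cell type survives the retention filter (min_cells = ",
         min_cells, ", min_patients = ", min_patients,
         "); consider relaxing the thresholds")
  ds[, ct %in% unique(ct)[keep]]
}

#' Stratified patient-wise train/test split
#'
#' Partitions patients (never cells) into training and testing sides,
#' stratified by condition. The test side receives `floor(test_fraction * n)`
#' patients per condition but always at least one, and the training side
#' always keeps at least one patient per condition. Deterministic under
#' `seed`.
#'
#' @param ds an [SCDataset-class] with at least two patients per condition.
#' @param test_fraction fraction of patients per condition assigned to the
#'   test side (default 0.2).
#' @param seed integer seed.
#' @return A [SplitSpec-class].
#' @export
splitByPatient <- function(ds, test_fraction = 0.2, seed = 1L) {
  stopifnot(is(ds, "SCDataset"), test_fraction > 0, test_fraction < 1)
  cond <- conditionLabels(ds); pat <- patientIDs(ds)
  percond <- tapply(pat, cond, function(x) sort(unique(x)))
  if (length(percond) < 2L || any(lengths(percond) < 2L))
    stop("insufficient cohort: need at least 2 patients per condition")
  test <- character(0)
  withSeed(seed, {
    for (cl in names(percond)) {
      pats <- percond[[cl]]
      n_test <- max(1L, floor(test_fraction * length(pats)))
      n_test <- min(n_test, length(pats) - 1L)
      test <- c(test, sample(pats, n_test))
    }
  })
  train <- setdiff(unlist(percond, use.names = FALSE), test)
  new("SplitSpec", trainPatients = sort(train), testPatients = sort(test),
      seed = as.integer(seed))
}

#' Restrict a dataset to selected patients, cell types and/or genes
#'
#' @param ds an [SCDataset-class].
#' @param patients,cellTypes optional identifier sets to keep.
#' @param genes optional ordered gene list; the output preserves this order
#'   exactly.
#' @return The restricted dataset.
#' @export
subsetDataset <- function(ds, patients = NULL, cellTypes = NULL,
                          genes = NULL) {
  stopifnot(is(ds, "SCDataset"))
  if (!is.null(patients)) {
    unknown <- setdiff(patients, patientIDs(ds))
    if (length(unknown))
      stop("lookup error: unknown patient(s): ",
           paste(unknown, collapse = ", "))
    ds <- ds[, patientIDs(ds) %in% patients]
  }
  if (!is.null(cellTypes)) {
    unknown <- setdiff(cellTypes, cellTypeLabels(ds))
    if (length(unknown))
      stop("lookup error: unknown cell type(s): ",
           paste(unknown, collapse = ", "))
    ds <- ds[, cellTypeLabels(ds) %in% cellTypes]
  }
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(ds))
    if (length(unknown))
      stop("lookup error: unknown gene(s): ",
           paste(unknown, collapse = ", "))
    ds <- ds[genes, ]
  }
  ds
}

## Feature matrix (cells x genes, dense) for model fitting: logcounts when
## normalized, raw counts otherwise (with a warning — models expect the
## normalized scale).
.featureMatrix <- function(ds) {
  anames <- SummarizedExperiment::assayNames(ds)
  if ("logcounts" %in% anames) {
    m <- SummarizedExperiment::assay(ds, "logcounts")
  } else {
    warning("dataset is not normalized; fitting on raw counts")
    m <- SummarizedExperiment::assay(ds, "counts")
  }
  as.matrix(Matrix::t(m))
}
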