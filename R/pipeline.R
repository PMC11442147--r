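#' Pipeline configuration
#'
#' Bundles all stage settings for [runPipeline()]. Either `input` (path +
#' format + annotation keys) or an in-memory `dataset` must be supplied at
#' run time.
#'
#' @param input optional list(path, format, patient_key, condition_key,
#'   celltype_key, positive_label) for [loadDataset()].
#' @param outdir output directory; each run writes into
#'   `file.path(outdir, paste0("run_", <config hash>))`.
#' @param seed root seed; every stage draws a named substream from it.
#' @param test_fraction patient fraction held out for testing (default 0.2).
#' @param min_cells,min_patients cell-type retention thresholds.
#' @param norm_scale per-cell total for normalization (default 1e4).
#' @param top_n number of top-ranked cell types to take forward (default 1).
#' @param stable logical; use [stableGenePanel()] instead of
#'   [selectGenePanel()].
#' @param responsiveness a [responsivenessConfig()].
#' @param genes a [geneSelectionConfig()].
#' @param ensemble an [ensembleConfig()].
#' @param bootstrap_B bootstrap replicates for patient p-values.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(input = NULL, outdir = tempfile("respanel_"),
                           seed = 1L, test_fraction = 0.2,
                           min_cells = 20L, min_patients = 3L,
                           norm_scale = 1e4, top_n = 1L, stable = FALSE,
                           responsiveness = responsivenessConfig(),
                           genes = geneSelectionConfig(),
                           ensemble = ensembleConfig(),
                           bootstrap_B = 1000L) {
  cfg <- list(input = input, outdir = outdir, seed = as.integer(seed),
              test_fraction = test_fraction,
              min_cells = as.integer(min_cells),
              min_patients = as.integer(min_patients),
              norm_scale = norm_scale, top_n = as.integer(top_n),
              stable = isTRUE(stable),
              responsiveness = responsiveness, genes = genes,
              ensemble = ensemble, bootstrap_B = as.integer(bootstrap_B))
  class(cfg) <- "PipelineConfig"
  cfg
}

## Serialize a config to canonical YAML and hash it (used for run directory
## naming, so a changed config can never overwrite a previous run).
.configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  lst <- .configAsList(cfg)
  lst$outdir <- NULL    # the hash identifies the analysis, not its location
  writeLines(yaml::as.yaml(lst), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 10L)
}

.configAsList <- function(cfg) {
  rapply(unclass(cfg), function(x) x, how = "replace")
}

## The computational core: all stages on an in-memory dataset.
.runStudy <- function(ds, cfg) {
  seed <- cfg$seed
  if (!isNormalized(ds)) ds <- normalizeTotal(ds, scale = cfg$norm_scale)
  ds <- filterCellTypes(ds, cfg$min_cells, cfg$min_patients)
  split <- splitByPatient(ds, cfg$test_fraction,
                          seed = subSeed(seed, "split"))
  stopifnot(length(intersect(trainPatients(split),
                             testPatients(split))) == 0L)
  train <- subsetDataset(ds, patients = trainPatients(split))
  test <- subsetDataset(ds, patients = testPatients(split))

  rcfg <- cfg$responsiveness
  rcfg$seed <- subSeed(seed, "celltype")
  resp <- rankCellTypes(train, rcfg)
  sel_type <- topCellTypes(resp, cfg$top_n)[1L]

  gcfg <- cfg$genes
  gcfg$seed <- subSeed(seed, "genes")
  panel <- if (cfg$stable) stableGenePanel(train, sel_type, gcfg)
           else selectGenePanel(train, sel_type, gcfg)

  ecfg <- cfg$ensemble
  ecfg$seed <- subSeed(seed, "ensemble")
  model <- trainEnsemble(train, panel, cfg = ecfg)
  preds <- predictCells(model, test)
  report <- classifyPatients(preds, B = cfg$bootstrap_B,
                             seed = subSeed(seed, "boot"))
  list(dataset = ds, split = split, responsiveness = resp,
       cell_type = sel_type, panel = panel, model = model,
       predictions = preds, report = report)
}

#' Run the full pipeline
#'
#' Executes load (or accepts an in-memory dataset), normalization, cell-type
#' retention filtering, the stratified patient-wise 80/20 split, cell-type
#' responsiveness ranking, gene panel selection, ensemble training,
#' prediction on the held-out patients and patient-level reporting. All
#' artifacts (responsiveness.tsv, curve.tsv, panel.json, model.rds,
#' patient_report.json, metrics.json, config.yaml, log.txt) are written to a
#' run directory named after the config hash, so re-running with a changed
#' config never overwrites a previous run; identical config + seed reproduce
#' identical outputs.
#'
#' @param cfg a [pipelineConfig()].
#' @param dataset optional in-memory [SCDataset-class] (overrides
#'   `cfg$input`).
#' @return Invisibly, a list with all stage objects plus `run_dir`.
#' @export
runPipeline <- function(cfg = pipelineConfig(), dataset = NULL) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  hash <- .configHash(cfg)
  run_dir <- file.path(cfg$outdir, paste0("run_", hash))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(run_dir, "log.txt")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", sep = "", file = logfile,
                               append = TRUE)
  stage <- "load"
  res <- tryCatch({
    if (is.null(dataset)) {
      if (is.null(cfg$input))
        stop("config missing both an input specification and a dataset")
      inp <- cfg$input
      if (is.null(inp$condition_key))
        stop("config missing condition key")
      dataset <- loadDataset(inp$path, inp$format,
                             patient_key = inp$patient_key %||% "patient",
                             condition_key = inp$condition_key,
                             celltype_key = inp$celltype_key %||%
                               "cell_type",
                             positive_label = inp$positive_label)
    }
    logline("loaded dataset: ", nrow(dataset), " genes x ", ncol(dataset),
            " cells")
    stage <- "analysis"
    .runStudy(dataset, cfg)
  }, error = function(e) {
    logline("ERROR at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline aborted at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  writeLines(yaml::as.yaml(.configAsList(cfg)),
             file.path(run_dir, "config.yaml"))
  sc <- responsivenessScores(res$responsiveness)
  con <- file(file.path(run_dir, "responsiveness.tsv"), "w")
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(sc, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  if (!is.null(res$panel@curve)) {
    cv <- res$panel@curve
    con <- file(file.path(run_dir, "curve.tsv"), "w")
    writeLines(paste0("# config_hash: ", hash), con)
    write.table(data.frame(gene_count = cv@geneCounts,
                           mean_accuracy = cv@meanAccuracy,
                           sd_accuracy = cv@sdAccuracy),
                con, sep = "\t", row.names = FALSE, quote = FALSE)
    close(con)
  }
  jsonlite::write_json(
    list(config_hash = hash,
         cell_type = res$cell_type,
         n_selected = length(panelGenes(res$panel)),
         genes = panelGenes(res$panel),
         frequencies = as.list(selectionFrequencies(res$panel))),
    file.path(run_dir, "panel.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(res$model, file.path(run_dir, "model.rds"))
  rep <- res$report
  jsonlite::write_json(
    list(config_hash = hash, patients = patientResults(rep)),
    file.path(run_dir, "patient_report.json"), auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(
    c(list(config_hash = hash), as.list(cohortMetrics(rep))),
    file.path(run_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  logline("done; selected cell type ", res$cell_type, " with ",
          length(panelGenes(res$panel)), " genes")
  invisible(c(res, list(run_dir = run_dir, config_hash = hash)))
}

#' Downsampling power experiment
#'
#' Re-runs cell-type selection and gene selection on downsampled versions of
#' the cohort (by patients or by cells) and summarizes, per fraction x seed,
#' the top-ranked cell type, the panel size and the Jaccard similarity of the
#' panel against the full-data run.
#'
#' @param ds a (raw or normalized) [SCDataset-class].
#' @param fractions downsampling fractions in (0, 1].
#' @param axis `"patients"` or `"cells"`.
#' @param seeds integer seeds (one run per fraction x seed).
#' @param cfg a [pipelineConfig()] supplying the stage settings.
#' @return data.frame with columns `fraction`, `seed`, `skipped`,
#'   `rank1_cell_type`, `panel_size`, `jaccard_vs_full`.
#' @export
downsampleExperiment <- function(ds, fractions, axis = c("patients", "cells"),
                                 seeds = 1L, cfg = pipelineConfig()) {
  axis <- match.arg(axis)
  stopifnot(is(ds, "SCDataset"), all(fractions > 0), all(fractions <= 1))
  if (!isNormalized(ds)) ds <- normalizeTotal(ds, scale = cfg$norm_scale)
  ds <- filterCellTypes(ds, cfg$min_cells, cfg$min_patients)

  selectOnly <- function(d, seed) {
    rcfg <- cfg$responsiveness; rcfg$seed <- subSeed(seed, "celltype")
    resp <- rankCellTypes(d, rcfg)
    ty <- topCellTypes(resp, 1L)
    gcfg <- cfg$genes; gcfg$seed <- subSeed(seed, "genes")
    panel <- selectGenePanel(d, ty, gcfg)
    list(type = ty, genes = panelGenes(panel))
  }
  full <- selectOnly(ds, cfg$seed)

  pat <- patientIDs(ds); cond <- conditionLabels(ds)
  upat <- sort(unique(pat))
  pcond <- vapply(upat, function(p) cond[pat == p][1L], integer(1L))
  rows <- list()
  for (fr in fractions) for (s in seeds) {
    row <- data.frame(fraction = fr, seed = s, skipped = FALSE,
                      rank1_cell_type = NA_character_,
                      panel_size = NA_integer_,
                      jaccard_vs_full = NA_real_,
                      stringsAsFactors = FALSE)
    sub <- tryCatch({
      if (fr == 1) ds
      else if (axis == "patients") {
        keep <- withSeed(subSeed(s, "down", fr), {
          unlist(lapply(c(0L, 1L), function(cl) {
            pats <- upat[pcond == cl]
            n <- floor(fr * length(pats))
            if (n < 2L) stop("infeasible fraction")
            sample(pats, n)
          }), use.names = FALSE)
        })
        subsetDataset(ds, patients = keep)
      } else {
        keep <- withSeed(subSeed(s, "down", fr),
                         sort(sample(ncol(ds), floor(fr * ncol(ds)))))
        ds[, keep]
      }
    }, error = function(e) NULL)
    if (is.null(sub)) {
      row$skipped <- TRUE
      rows[[length(rows) + 1L]] <- row
      next
    }
    out <- tryCatch(selectOnly(sub, s), error = function(e) NULL)
    if (is.null(out)) {
      row$skipped <- TRUE
    } else {
      row$rank1_cell_type <- out$type
      row$panel_size <- length(out$genes)
      row$jaccard_vs_full <- length(intersect(out$genes, full$genes)) /
        length(union(out$genes, full$genes))
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}
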