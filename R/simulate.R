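#' Configuration for the synthetic cohort generator
#'
#' Defines a two-class patient cohort with several cell types, exactly one of
#' which ("the responsive type") carries marker genes whose mean expression is
#' shifted by `2^log2_fold_change` in perturbed patients. Counts are negative
#' binomial around log-normal gene means, with multiplicative per-patient
#' random effects (shared by all genes of a patient — the patient-level
#' leakage that patient-wise splitting must guard against) and per-cell
#' library-size factors.
#'
#' @param n_patients_per_class patients per condition (default 10; a length-2
#'   vector gives reference/perturbed counts separately).
#' @param n_cell_types number of cell types (default 3).
#' @param cells_per_patient_per_type cells per patient per type (default 60;
#'   a length-2 vector is treated as an inclusive range sampled per
#'   patient/type).
#' @param n_genes genes (default 300).
#' @param n_marker_genes markers carrying the perturbation (default 12).
#' @param responsive_cell_type_index which cell type responds (default 1).
#' @param log2_fold_change log2 effect on marker means in the responsive type
#'   of perturbed patients (default 2, i.e. 4-fold).
#' @param baseline_mean_log `c(mu, sigma)` of the log-normal gene means
#'   (default `c(0, 1)`).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param patient_effect_sd log-scale sd of the per-patient random effect
#'   (default 0.3).
#' @param library_size_sd log-scale sd of the per-cell library factor
#'   (default 0.2).
#' @param seed integer seed (default 1).
#' @return A `SimConfig` (validated list).
#' @export
simConfig <- function(n_patients_per_class = 10L,
                      n_cell_types = 3L,
                      cells_per_patient_per_type = 60L,
                      n_genes = 300L,
                      n_marker_genes = 12L,
                      responsive_cell_type_index = 1L,
                      log2_fold_change = 2,
                      baseline_mean_log = c(0, 1),
                      dispersion = 2,
                      patient_effect_sd = 0.3,
                      library_size_sd = 0.2,
                      seed = 1L) {
  if (length(n_patients_per_class) == 1L)
    n_patients_per_class <- rep(as.integer(n_patients_per_class), 2L)
  cfg <- list(n_patients_per_class = as.integer(n_patients_per_class),
              n_cell_types = as.integer(n_cell_types),
              cells_per_patient_per_type =
                as.integer(cells_per_patient_per_type),
              n_genes = as.integer(n_genes),
              n_marker_genes = as.integer(n_marker_genes),
              responsive_cell_type_index =
                as.integer(responsive_cell_type_index),
              log2_fold_change = as.numeric(log2_fold_change),
              baseline_mean_log = as.numeric(baseline_mean_log),
              dispersion = as.numeric(dispersion),
              patient_effect_sd = as.numeric(patient_effect_sd),
              library_size_sd = as.numeric(library_size_sd),
              seed = as.integer(seed))
  if (any(cfg$n_patients_per_class < 1L) || cfg$n_genes < 1L ||
      cfg$n_cell_types < 1L || any(cfg$cells_per_patient_per_type < 1L))
    stop("config error: patient, gene, cell-type and cell counts must be >= 1")
  if (cfg$n_marker_genes >= cfg$n_genes)
    stop("config error: n_marker_genes must be < n_genes")
  if (cfg$log2_fold_change < 0)
    stop("config error: log2_fold_change must be >= 0")
  if (cfg$responsive_cell_type_index < 1L ||
      cfg$responsive_cell_type_index > cfg$n_cell_types)
    stop("config error: responsive_cell_type_index out of range")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a patient cohort with a known responsive cell type
#'
#' Draws counts for every cell as NB(mean = gene mean x patient effect x
#' library factor x fold change, size = dispersion), where the fold change
#' `2^log2_fold_change` applies only to marker genes in cells of the
#' responsive type belonging to perturbed patients. Fully deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return A list with elements `dataset` (an [SCDataset-class]) and `truth`
#'   (list with `responsive_cell_type`, `marker_genes`, `patient_labels`).
#' @examples
#' sim <- simulateDataset(simConfig(n_patients_per_class = 2,
#'                                  cells_per_patient_per_type = 5,
#'                                  n_genes = 50, n_marker_genes = 5))
#' sim$truth$responsive_cell_type
#' @export
simulateDataset <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  withSeed(cfg$seed, {
    n_ref <- cfg$n_patients_per_class[1L]
    n_per <- cfg$n_patients_per_class[2L]
    patients <- c(sprintf("ref_%02d", seq_len(n_ref)),
                  sprintf("per_%02d", seq_len(n_per)))
    pat_cond <- c(rep(0L, n_ref), rep(1L, n_per))
    names(pat_cond) <- patients
    types <- sprintf("type_%d", seq_len(cfg$n_cell_types))
    responsive <- types[cfg$responsive_cell_type_index]
    genes <- sprintf("gene_%03d", seq_len(cfg$n_genes))
    markers <- sort(sample(genes, cfg$n_marker_genes))

    gene_mean <- rlnorm(cfg$n_genes, cfg$baseline_mean_log[1L],
                        cfg$baseline_mean_log[2L])
    names(gene_mean) <- genes
    pat_effect <- rlnorm(length(patients), 0, cfg$patient_effect_sd)
    names(pat_effect) <- patients

    cpp <- cfg$cells_per_patient_per_type
    blocks <- list()
    meta <- list()
    fc <- 2 ^ cfg$log2_fold_change
    for (p in patients) {
      for (ty in types) {
        n_cells <- if (length(cpp) == 2L)
          sample(seq(cpp[1L], cpp[2L]), 1L) else cpp[1L]
        lib <- rlnorm(n_cells, 0, cfg$library_size_sd)
        mu <- outer(gene_mean * pat_effect[p], lib)  # genes x cells
        if (ty == responsive && pat_cond[p] == 1L)
          mu[markers, ] <- mu[markers, ] * fc
        cnt <- matrix(rnbinom(length(mu), size = cfg$dispersion, mu = mu),
                      nrow = cfg$n_genes)
        blocks[[length(blocks) + 1L]] <- cnt
        meta[[length(meta) + 1L]] <-
          data.frame(patient = p, condition = pat_cond[p], cell_type = ty,
                     n = n_cells, stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(cbind, blocks)
    meta <- do.call(rbind, meta)
    ann <- meta[rep(seq_len(nrow(meta)), meta$n), c("patient", "condition",
                                                    "cell_type")]
    rownames(counts) <- genes
    colnames(counts) <- sprintf("cell_%05d", seq_len(ncol(counts)))
    ds <- SCDataset(counts, patient = ann$patient,
                    condition = ann$condition, cell_type = ann$cell_type,
                    condition_label = ifelse(ann$condition == 1L,
                                             "perturbed", "reference"))
    truth <- list(responsive_cell_type = responsive,
                  marker_genes = if (cfg$log2_fold_change > 0) markers
                                 else character(0),
                  patient_labels = pat_cond)
    list(dataset = ds, truth = truth, config = cfg)
  })
}

#' Preset simulated fixtures
#'
#' Named cohort presets used throughout the test suite:
#' \describe{
#'   \item{`"tiny"`}{4+4 patients, 3 types, 25 cells/patient/type, 120 genes,
#'     8 markers at 4-fold — a ~600-cell dataset that builds in seconds.}
#'   \item{`"null"`}{the default cohort with `log2_fold_change = 0`; no cell
#'     type is separable and no marker genes exist.}
#'   \item{`"strong"`}{the default cohort: 10+10 patients, 3 types, 60
#'     cells/patient/type, 300 genes, 12 markers at 4-fold.}
#'   \item{`"imbalanced"`}{15 perturbed vs 5 reference patients to exercise
#'     minority-class weighting.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed (default 1).
#' @return As [simulateDataset()].
#' @export
makeFixture <- function(name = c("tiny", "null", "strong", "imbalanced"),
                        seed = 1L) {
  if (!is.character(name) || !name[1L] %in%
        c("tiny", "null", "strong", "imbalanced"))
    stop("lookup error: unknown fixture name: ", name[1L])
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = simConfig(n_patients_per_class = 4L,
                     cells_per_patient_per_type = 25L,
                     n_genes = 120L, n_marker_genes = 8L, seed = seed),
    null = simConfig(log2_fold_change = 0, seed = seed),
    strong = simConfig(seed = seed),
    imbalanced = simConfig(n_patients_per_class = c(5L, 15L),
                           cells_per_patient_per_type = 40L,
                           n_genes = 200L, n_marker_genes = 10L,
                           seed = seed))
  simulateDataset(cfg)
}
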