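## Fixtures are generated in code and cached for the session so the large
## simulated cohorts are built once per seed, however many tests use them.

.fixture_cache <- new.env(parent = emptyenv())

cachedFixture <- function(name, seed = 1L, prepared = FALSE) {
  key <- paste(name, seed, prepared, sep = "|")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  sim <- makeFixture(name, seed = seed)
  if (prepared) {
    sim$dataset <- suppressMessages(
      filterCellTypes(normalizeTotal(sim$dataset)))
  }
  .fixture_cache[[key]] <- sim
  sim
}

## A deliberately small cohort for fast structural tests.
smallSim <- function(seed = 1L, log2fc = 2, n_types = 2L) {
  simulateDataset(simConfig(n_patients_per_class = 3L,
                            n_cell_types = n_types,
                            cells_per_patient_per_type = 8L,
                            n_genes = 30L, n_marker_genes = 4L,
                            log2_fold_change = log2fc, seed = seed))
}

## Hand-built 3-cell CSV dataset on disk; returns the counts file path.
writeTinyCSV <- function(dir, conditions = c("case", "case", "ctrl"),
                         patients = c("A", "A", "B")) {
  counts <- data.frame(cell_id = c("c1", "c2", "c3"),
                       g1 = c(2, 0, 5), g2 = c(1, 3, 0))
  write.csv(counts, file.path(dir, "counts.csv"), row.names = FALSE)
  write.csv(data.frame(cell_id = c("c1", "c2", "c3"),
                       patient = patients, condition = conditions,
                       cell_type = c("T", "T", "B")),
            file.path(dir, "cells.csv"), row.names = FALSE)
  file.path(dir, "counts.csv")
}
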