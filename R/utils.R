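#' @import methods
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
## explicit imports so these namespaces (and their S3 predict methods) are
## loaded even in sessions that only deserialize a fitted model
#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
#' @importFrom e1071 svm
#' @importFrom pROC roc auc
#' @importFrom stats rnorm rnbinom rlnorm predict sd median quantile plogis glm
#'   binomial coef wilcox.test
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

## Evaluate an expression under a temporary RNG state; the caller's stream is
## untouched afterwards.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

## Derive a deterministic 31-bit sub-seed from a root seed and a sequence of
## stage labels, so each pipeline stage draws from its own named substream.
subSeed <- function(seed, ...) {
  ids <- as.character(unlist(list(...)))
  h <- as.double(seed %% 2147483647L)
  for (x in ids) {
    for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message("[respanel] ", ...)

## Balanced accuracy of binary predictions (labels in {0,1}).
balancedAccuracy <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  sens <- if (any(truth == 1L)) mean(pred[truth == 1L] == 1L) else NA_real_
  spec <- if (any(truth == 0L)) mean(pred[truth == 0L] == 0L) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

## Cell-level AUROC of a probability score against binary truth.
cellAUROC <- function(truth, score) {
  r <- pROC::roc(response = factor(truth, levels = c(0L, 1L)),
                 predictor = as.numeric(score),
                 levels = c("0", "1"), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

## Column-wise standardization statistics; zero-variance columns get scale 1 so
## they map to constant zero instead of NaN.
featureStats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

applyFeatureStats <- function(X, stats) {
  X <- sweep(X, 2L, stats$center, "-")
  sweep(X, 2L, stats$scale, "/")
}

## Stratified partition of patients into k groups (round-robin after a seeded
## shuffle within each condition).
patientFolds <- function(patients, conditions, k, seed) {
  stopifnot(length(patients) == length(conditions))
  fold <- integer(length(patients))
  withSeed(seed, {
    for (cond in sort(unique(conditions))) {
      idx <- which(conditions == cond)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
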