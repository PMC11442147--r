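#' Configuration for the cell-level classifier ensemble
#'
#' @param graph_k neighbors for the cell kNN graph fed to the graph attention
#'   member (default 15).
#' @param knn_k neighbors for the kNN classifier (default 15).
#' @param gat logical; include the graph attention member (default TRUE).
#' @param gat_hidden,gat_heads GAT width (default 8 units x 4 heads).
#' @param gat_lr,gat_max_epochs,gat_patience Adam learning rate (0.01),
#'   epoch cap (200) and early-stopping patience (20).
#' @param lr_lambda ridge penalty of the logistic member (default 1e-3).
#' @param svm_cost linear SVM cost (default 1).
#' @param seed integer seed (default 1).
#' @return An `EnsembleConfig` list.
#' @export
ensembleConfig <- function(graph_k = 15L, knn_k = 15L, gat = TRUE,
                           gat_hidden = 8L, gat_heads = 4L, gat_lr = 0.01,
                           gat_max_epochs = 200L, gat_patience = 20L,
                           lr_lambda = 1e-3, svm_cost = 1, seed = 1L) {
  cfg <- list(graph_k = as.integer(graph_k), knn_k = as.integer(knn_k),
              gat = isTRUE(gat), gat_hidden = as.integer(gat_hidden),
              gat_heads = as.integer(gat_heads), gat_lr = gat_lr,
              gat_max_epochs = as.integer(gat_max_epochs),
              gat_patience = as.integer(gat_patience),
              lr_lambda = lr_lambda, svm_cost = svm_cost,
              seed = as.integer(seed))
  class(cfg) <- "EnsembleConfig"
  cfg
}

#' Per-cell weights balancing patients within class and classes overall
#'
#' `w(cell i) = N / (C * P_c(i) * n_p(i))` with `N` total cells, `C = 2`
#' classes, `P_c` the number of patients in cell i's class and `n_p` the
#' number of cells of cell i's patient. Consequently every patient
#' contributes the same total weight within its class, and the two classes
#' contribute equal total weight.
#'
#' @param patient per-cell patient identifiers.
#' @param condition per-cell binary condition in \{0, 1\}.
#' @return Numeric weight per cell.
#' @export
computeCellWeights <- function(patient, condition) {
  stopifnot(length(patient) == length(condition),
            all(condition %in% c(0L, 1L)))
  if (length(unique(condition)) < 2L)
    stop("both classes must be present")
  n_total <- length(patient)
  pat_class <- tapply(condition, patient, function(x) x[1L])
  p_per_class <- table(factor(pat_class, levels = c(0L, 1L)))
  n_per_pat <- table(patient)
  as.numeric(n_total /
               (2 * p_per_class[as.character(condition)] *
                  n_per_pat[patient]))
}

#' Symmetrized k-nearest-neighbor cell graph
#'
#' Euclidean kNN on the (standardized) panel features; directed edges are
#' symmetrized by union, self-loops are not duplicated, distance ties break
#' by cell index. `k` is clipped (with a warning) when fewer than `k + 1`
#' cells are available.
#'
#' @param X cells x features matrix.
#' @param k neighbors per cell (default 15).
#' @return List with edge vectors `i`, `j` (each undirected edge appears in
#'   both directions), `n` cells and the effective `k`.
#' @export
buildCellGraph <- function(X, k = 15L) {
  n <- nrow(X)
  stopifnot(n >= 2L)
  if (k >= n) {
    warning("k clipped from ", k, " to ", n - 1L)
    k <- n - 1L
  }
  d2 <- outer(rowSums(X^2), rep(1, n)) +
    outer(rep(1, n), rowSums(X^2)) - 2 * tcrossprod(X)
  diag(d2) <- Inf
  nbr <- apply(d2, 1L, function(row) order(row)[seq_len(k)])
  ei <- rep(seq_len(n), each = k)
  ej <- as.integer(nbr)
  und <- unique(rbind(cbind(pmin(ei, ej), pmax(ei, ej))))
  list(i = c(und[, 1L], und[, 2L]), j = c(und[, 2L], und[, 1L]),
       n = n, k = as.integer(k))
}

## kNN probability: distance-weighted neighbor vote, votes additionally
## weighted by the training cells' compositional weights.
.knnPredict <- function(model, Xnew) {
  Xtr <- model$X
  d2 <- outer(rowSums(Xnew^2), rep(1, nrow(Xtr))) +
    outer(rep(1, nrow(Xnew)), rowSums(Xtr^2)) - 2 * tcrossprod(Xnew, Xtr)
  d2[d2 < 0] <- 0
  k <- min(model$k, nrow(Xtr))
  vapply(seq_len(nrow(Xnew)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]
    v <- model$w[nb] / (sqrt(d2[i, nb]) + 1e-8)
    sum(v[model$y[nb] == 1L]) / sum(v)
  }, 0)
}

#' Train the cell-level classifier ensemble
#'
#' Fits five classifiers on the training cells of the selected cell type,
#' restricted to the panel genes: ridge logistic regression, a linear SVM
#' (probabilities by Platt scaling of its decision values), a probability
#' random forest, a distance-weighted kNN voter, and a two-layer graph
#' attention network on the symmetrized cell kNN graph (weighted
#' cross-entropy, early stopping on a patient-held-out node split). All
#' members see identical cells and standardized features; all are weighted by
#' [computeCellWeights()] (the SVM by its class-level aggregate). With
#' `cfg$gat = FALSE` the ensemble degrades to four members.
#'
#' @param train a normalized [SCDataset-class] of training cells (one cell
#'   type) — it is restricted to `panel`'s cell type and genes internally.
#' @param panel a [GenePanel-class] (or character vector of genes, in which
#'   case `cell_type` must be given).
#' @param cell_type optional cell type override.
#' @param cfg an [ensembleConfig()].
#' @return An [EnsembleModel-class].
#' @export
trainEnsemble <- function(train, panel, cell_type = NULL,
                          cfg = ensembleConfig()) {
  stopifnot(is(train, "SCDataset"))
  if (is.character(panel)) {
    stopifnot(!is.null(cell_type))
    panel <- new("GenePanel", genes = panel, nOpt = length(panel),
                 sourceCellType = cell_type, frequencies = numeric(0),
                 subsetPanels = list(), curve = NULL, lowConfidence = FALSE)
  }
  cell_type <- cell_type %||% panel@sourceCellType
  sub <- subsetDataset(train, cellTypes = cell_type,
                       genes = panel@genes)
  pat <- patientIDs(sub); cond <- conditionLabels(sub)
  pc <- tapply(cond, pat, function(x) x[1L])
  if (sum(pc == 0L) < 2L || sum(pc == 1L) < 2L)
    stop("need >= 2 patients per class to train the ensemble")
  X <- .featureMatrix(sub)
  st <- featureStats(X)
  Xs <- applyFeatureStats(X, st)
  y <- cond
  w <- computeCellWeights(pat, cond)

  members <- list()
  ## LR: ridge logistic regression on standardized features, cell weights.
  Xlr <- if (ncol(Xs) == 1L) cbind(Xs, dummy_ = 0) else Xs
  members$LR <- list(fit = glmnet::glmnet(Xlr, factor(y, levels = c(0L, 1L)),
                                          family = "binomial", alpha = 0,
                                          lambda = cfg$lr_lambda,
                                          weights = w, standardize = FALSE),
                     pad = ncol(Xs) == 1L)
  ## SVM: linear, class-weighted; deterministic Platt scaling on training
  ## decision values.
  cw_raw <- tapply(w, factor(y, levels = c(0L, 1L)), sum)
  cw <- as.numeric(cw_raw / sum(cw_raw) * 2)
  names(cw) <- names(cw_raw)
  svmfit <- e1071::svm(x = Xs, y = factor(y, levels = c(0L, 1L)),
                       kernel = "linear", cost = cfg$svm_cost,
                       scale = FALSE, class.weights = cw)
  dv <- as.numeric(attr(predict(svmfit, Xs, decision.values = TRUE),
                        "decision.values"))
  platt <- suppressWarnings(glm(y ~ dv, family = binomial(),
                                weights = w,
                                data = data.frame(y = y, dv = dv)))
  members$SVM <- list(fit = svmfit, platt = coef(platt))
  ## RF: probability forest with per-cell case weights.
  members$RF <- ranger::ranger(x = Xs, y = factor(y, levels = c(0L, 1L)),
                               probability = TRUE, num.trees = 500L,
                               case.weights = w,
                               seed = subSeed(cfg$seed, "rf"),
                               num.threads = 1L, verbose = FALSE)
  ## kNN: stored training set; distance- and composition-weighted vote.
  members$kNN <- list(X = Xs, y = y, w = w, k = cfg$knn_k)
  ## GAT
  if (cfg$gat) {
    graph <- buildCellGraph(Xs, k = cfg$graph_k)
    members$GAT <- .gatTrain(Xs, y, pat, w, graph,
                             hidden = cfg$gat_hidden, heads = cfg$gat_heads,
                             lr = cfg$gat_lr,
                             max_epochs = cfg$gat_max_epochs,
                             patience = cfg$gat_patience,
                             seed = subSeed(cfg$seed, "gat"))
  } else {
    warning("graph attention member disabled: ensemble degrades to 4 ",
            "members; consensus is the median of the available members")
  }
  new("EnsembleModel", members = members, panel = panel,
      cellType = cell_type, featureStats = st, config = unclass(cfg))
}

## Per-member probability of class 1 on standardized features.
.memberProb <- function(name, member, Xs) {
  switch(name,
    LR = {
      Xp <- if (member$pad) cbind(Xs, dummy_ = 0) else Xs
      as.numeric(predict(member$fit, Xp, type = "response"))
    },
    SVM = {
      dv <- as.numeric(attr(predict(member$fit, Xs,
                                    decision.values = TRUE),
                            "decision.values"))
      as.numeric(plogis(member$platt[1L] + member$platt[2L] * dv))
    },
    RF = predict(member, data = Xs,
                 num.threads = 1L)$predictions[, "1"],
    kNN = .knnPredict(member, Xs),
    GAT = .gatPredict(member, Xs),
    stop("unknown member: ", name))
}

#' Predict cell-level probabilities with a trained ensemble
#'
#' Applies every ensemble member to the test cells (restricted to the model's
#' cell type, transformed with the training standardization statistics) and
#' returns per-member probabilities plus their element-wise median, the
#' consensus probability. Panel genes missing from the test data are a hard
#' error — silent imputation would corrupt the probabilities.
#'
#' @param model an [EnsembleModel-class].
#' @param test a normalized [SCDataset-class].
#' @return A [CellPredictions-class].
#' @export
predictCells <- function(model, test) {
  stopifnot(is(model, "EnsembleModel"), is(test, "SCDataset"))
  missing_genes <- setdiff(model@panel@genes, rownames(test))
  if (length(missing_genes))
    stop("schema error: panel gene(s) absent from test data: ",
         paste(missing_genes, collapse = ", "))
  sub <- subsetDataset(test, cellTypes = model@cellType,
                       genes = model@panel@genes)
  if (!ncol(sub)) stop("no test cells of cell type '", model@cellType, "'")
  Xs <- applyFeatureStats(.featureMatrix(sub), model@featureStats)
  probs <- vapply(names(model@members), function(nm)
    .memberProb(nm, model@members[[nm]], Xs), numeric(nrow(Xs)))
  probs <- matrix(pmin(1, pmax(0, probs)), nrow = nrow(Xs),
                  dimnames = list(colnames(sub), names(model@members)))
  cond <- conditionLabels(sub)
  new("CellPredictions", probs = probs,
      consensus = apply(probs, 1L, stats::median),
      patient = patientIDs(sub), cellIds = colnames(sub),
      truth = if (is.null(cond)) rep(NA_integer_, ncol(sub))
              else as.integer(cond))
}

#' Patient-level AUC score of one patient's consensus probabilities
#'
#' The rank statistic of the patient's cells against the 0.5 decision
#' reference: the fraction of cells with consensus probability above 0.5,
#' plus half the fraction exactly at 0.5. Scores near 1 indicate a perturbed
#' patient, near 0 a reference patient.
#'
#' @param probs consensus probabilities of one patient's cells (>= 1).
#' @return A number in \[0, 1\].
#' @examples
#' patientAUC(c(0.9, 0.8, 0.3, 0.6))  # 0.75
#' @export
patientAUC <- function(probs) {
  if (!length(probs)) stop("patient has no cells")
  (sum(probs > 0.5) + 0.5 * sum(probs == 0.5)) / length(probs)
}

#' Bootstrap p-value for a patient-level AUC
#'
#' Resamples the patient's cells with replacement `B` times, recomputes the
#' patient AUC, and reports the one-sided add-one-corrected p-value: the
#' fraction of replicates falling on the opposite side of 0.5 from the
#' observed AUC (or exactly at 0.5). An observed AUC of exactly 0.5 returns
#' p = 1.
#'
#' @param probs consensus probabilities of one patient's cells (>= 2).
#' @param B bootstrap replicates (default 1000; < 100 warns).
#' @param seed integer seed.
#' @return p-value in (0, 1].
#' @export
bootstrapPvalue <- function(probs, B = 1000L, seed = 1L) {
  if (length(probs) < 2L) stop("need >= 2 cells for the bootstrap")
  if (B < 100L) warning("B < 100 gives an unstable p-value")
  obs <- patientAUC(probs)
  if (obs == 0.5) return(1)
  n <- length(probs)
  boot <- withSeed(seed, {
    vapply(seq_len(B), function(b)
      patientAUC(probs[sample.int(n, n, replace = TRUE)]), 0)
  })
  extreme <- if (obs > 0.5) sum(boot <= 0.5) else sum(boot >= 0.5)
  (1 + extreme) / (B + 1)
}

#' Patient-level classification report
#'
#' Aggregates consensus cell probabilities per patient into an AUC score and
#' bootstrap p-value, predicts the label (AUC > 0.5 is perturbed; exactly 0.5
#' is flagged undetermined and counted as reference), and — when true labels
#' are available — computes cohort accuracy, precision, sensitivity,
#' specificity and F1 with the perturbed class positive.
#'
#' @param preds a [CellPredictions-class].
#' @param truth optional named vector of true patient labels (defaults to the
#'   truth carried in `preds`, when present).
#' @param B,seed bootstrap settings (see [bootstrapPvalue()]).
#' @return A [PatientReport-class].
#' @export
classifyPatients <- function(preds, truth = NULL, B = 1000L, seed = 1L) {
  stopifnot(is(preds, "CellPredictions"))
  pats <- sort(unique(preds@patient))
  if (!length(pats)) stop("no patients to classify")
  rows <- lapply(pats, function(p) {
    pr <- preds@consensus[preds@patient == p]
    auc <- patientAUC(pr)
    pv <- if (length(pr) >= 2L)
      bootstrapPvalue(pr, B = B, seed = subSeed(seed, "boot", p)) else 1
    data.frame(patient = p, auc = auc, p_value = pv,
               predicted_label = as.integer(auc > 0.5),
               undetermined = auc == 0.5,
               n_cells = length(pr), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(truth) && !all(is.na(preds@truth))) {
    truth <- vapply(pats, function(p)
      preds@truth[preds@patient == p][1L], integer(1L))
    names(truth) <- pats
  }
  metrics <- numeric(0)
  if (!is.null(truth)) {
    tab$true_label <- as.integer(truth[tab$patient])
    tp <- sum(tab$predicted_label == 1L & tab$true_label == 1L)
    fp <- sum(tab$predicted_label == 1L & tab$true_label == 0L)
    tn <- sum(tab$predicted_label == 0L & tab$true_label == 0L)
    fn <- sum(tab$predicted_label == 0L & tab$true_label == 1L)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    metrics <- c(accuracy = (tp + tn) / nrow(tab), precision = prec,
                 sensitivity = sens, specificity = spec, F1 = f1)
  }
  new("PatientReport", patients = tab, metrics = metrics)
}
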