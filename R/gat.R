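## A small two-layer graph attention network for binary node classification,
## written directly in R (dense algebra + sparse attention aggregation).
## Layer 1: `heads` attention heads of width `hidden`, ELU, concatenated.
## Layer 2: single attention head producing one logit per cell.
## Trained with weighted binary cross-entropy (per-cell weights) and Adam;
## early stopping monitors the loss on nodes of held-out patients. No dropout
## is used, so training is fully deterministic under the seed.

.lrelu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
.lreluGrad <- function(x, a = 0.2) ifelse(x > 0, 1, a)
.elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
.eluGradFromOut <- function(out) ifelse(out > 0, 1, out + 1)

## Symmetrized kNN edge list (targets ei, sources ej) with self-loops.
.gatEdges <- function(graph) {
  n <- graph$n
  ei <- c(graph$i, seq_len(n))
  ej <- c(graph$j, seq_len(n))
  ord <- order(ei, ej)
  list(ei = ei[ord], ej = ej[ord], n = n,
       groups = split(seq_along(ord), ei[ord]))
}

## Grouped softmax over edges sharing a target node.
.edgeSoftmax <- function(e, edges) {
  alpha <- numeric(length(e))
  for (g in edges$groups) {
    x <- e[g]
    x <- exp(x - max(x))
    alpha[g] <- x / sum(x)
  }
  alpha
}

.gatLayerForward <- function(X, prm, edges, act = c("elu", "none")) {
  act <- match.arg(act)
  z <- X %*% prm$W
  s <- as.numeric(z %*% prm$as)
  t <- as.numeric(z %*% prm$at)
  eraw <- s[edges$ei] + t[edges$ej]
  alpha <- .edgeSoftmax(.lrelu(eraw), edges)
  A <- Matrix::sparseMatrix(i = edges$ei, j = edges$ej, x = alpha,
                            dims = c(edges$n, edges$n))
  agg <- as.matrix(A %*% z)
  out <- if (act == "elu") .elu(agg) else agg
  list(out = out, cache = list(X = X, z = z, eraw = eraw, alpha = alpha,
                               A = A, agg = agg, act = act))
}

.rowsumN <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

.gatLayerBackward <- function(dout, prm, edges, cache) {
  dagg <- if (cache$act == "elu") dout * .eluGradFromOut(cache$out_elu)
          else dout
  z <- cache$z
  dz <- as.matrix(Matrix::crossprod(cache$A, dagg))
  dalpha <- rowSums(dagg[edges$ei, , drop = FALSE] *
                    z[edges$ej, , drop = FALSE])
  gsum <- .rowsumN(cache$alpha * dalpha, edges$ei, edges$n)
  de <- cache$alpha * (dalpha - gsum[edges$ei])
  deraw <- de * .lreluGrad(cache$eraw)
  ds <- .rowsumN(deraw, edges$ei, edges$n)
  dt <- .rowsumN(deraw, edges$ej, edges$n)
  dz <- dz + outer(ds, as.numeric(prm$as)) + outer(dt, as.numeric(prm$at))
  list(dW = crossprod(cache$X, dz),
       das = as.numeric(crossprod(z, ds)),
       dat = as.numeric(crossprod(z, dt)),
       dX = dz %*% t(prm$W))
}

.gatInit <- function(p, hidden, heads, seed) {
  withSeed(seed, {
    heads_prm <- lapply(seq_len(heads), function(h) {
      list(W = matrix(rnorm(p * hidden, sd = sqrt(2 / (p + hidden))),
                      p, hidden),
           as = rnorm(hidden, sd = 0.1),
           at = rnorm(hidden, sd = 0.1))
    })
    out_prm <- list(W = matrix(rnorm(hidden * heads, sd =
                                       sqrt(2 / (hidden * heads + 1))),
                    hidden * heads, 1L),
                    as = rnorm(1L, sd = 0.1), at = rnorm(1L, sd = 0.1))
    list(heads = heads_prm, out = out_prm, b = 0)
  })
}

.gatForward <- function(X, prm, edges) {
  caches1 <- vector("list", length(prm$heads))
  outs <- vector("list", length(prm$heads))
  for (h in seq_along(prm$heads)) {
    fw <- .gatLayerForward(X, prm$heads[[h]], edges, act = "elu")
    fw$cache$out_elu <- fw$out
    caches1[[h]] <- fw$cache
    outs[[h]] <- fw$out
  }
  H <- do.call(cbind, outs)
  fw2 <- .gatLayerForward(H, prm$out, edges, act = "none")
  logit <- as.numeric(fw2$out) + prm$b
  list(logit = logit, H = H, caches1 = caches1, cache2 = fw2$cache)
}

.gatLoss <- function(logit, y, w, mask) {
  p <- plogis(logit[mask])
  eps <- 1e-12
  -sum(w[mask] * (y[mask] * log(p + eps) +
                  (1 - y[mask]) * log(1 - p + eps))) / sum(w[mask])
}

## Adam update in place on a flat list of parameter matrices/vectors.
.adamStep <- function(prm, grads, state, lr, t,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * g
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * g^2
    mhat <- state$m[[k]] / (1 - b1^t)
    vhat <- state$v[[k]] / (1 - b2^t)
    prm[[k]] <- prm[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(prm = prm, state = state)
}

.flattenPrm <- function(prm) {
  out <- list()
  for (h in seq_along(prm$heads))
    for (nm in c("W", "as", "at"))
      out[[paste0("h", h, "_", nm)]] <- prm$heads[[h]][[nm]]
  for (nm in c("W", "as", "at")) out[[paste0("o_", nm)]] <- prm$out[[nm]]
  out$b <- prm$b
  out
}

.unflattenPrm <- function(flat, heads) {
  prm <- list(heads = vector("list", heads), out = list(), b = flat$b)
  for (h in seq_len(heads))
    prm$heads[[h]] <- list(W = flat[[paste0("h", h, "_W")]],
                           as = flat[[paste0("h", h, "_as")]],
                           at = flat[[paste0("h", h, "_at")]])
  prm$out <- list(W = flat$o_W, as = flat$o_as, at = flat$o_at)
  prm
}

.gatTrain <- function(X, y, patient, weights, graph,
                      hidden = 8L, heads = 4L, lr = 0.01,
                      max_epochs = 200L, patience = 20L,
                      min_epochs = 50L, val_fraction = 0.25, seed = 1L) {
  n <- nrow(X)
  edges <- .gatEdges(graph)
  ## patient-held-out validation nodes for early stopping; all nodes stay in
  ## the graph, only the loss mask differs
  upat <- sort(unique(patient))
  pcond <- vapply(upat, function(p) y[patient == p][1L], numeric(1L))
  val_pat <- withSeed(subSeed(seed, "gatval"), {
    unlist(lapply(c(0, 1), function(cl) {
      pats <- upat[pcond == cl]
      n_val <- min(max(1L, round(val_fraction * length(pats))),
                   length(pats) - 1L)
      if (n_val < 1L) character(0) else sample(pats, n_val)
    }), use.names = FALSE)
  })
  val_mask <- patient %in% val_pat
  if (all(val_mask) || !any(val_mask)) {
    val_mask <- rep(FALSE, n)   # degenerate cohort: train on everything
  }
  train_mask <- !val_mask
  has_val <- any(val_mask) && length(unique(y[val_mask])) == 2L

  prm <- .gatInit(ncol(X), hidden, heads, subSeed(seed, "gatinit"))
  flat <- .flattenPrm(prm)
  state <- list(m = lapply(flat, function(x) x * 0),
                v = lapply(flat, function(x) x * 0))
  best <- list(loss = Inf, flat = flat, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(max_epochs)) {
    prm <- .unflattenPrm(flat, heads)
    fw <- .gatForward(X, prm, edges)
    p <- plogis(fw$logit)
    wt <- weights * train_mask
    dlogit <- (p - y) * wt / sum(wt)
    ## backprop
    grads <- list()
    d2 <- .gatLayerBackward(matrix(dlogit, ncol = 1L), prm$out, edges,
                            fw$cache2)
    grads$o_W <- d2$dW; grads$o_as <- d2$das; grads$o_at <- d2$dat
    grads$b <- sum(dlogit)
    dH <- d2$dX
    for (h in seq_along(prm$heads)) {
      cols <- ((h - 1L) * hidden + 1L):(h * hidden)
      dh <- .gatLayerBackward(dH[, cols, drop = FALSE], prm$heads[[h]],
                              edges, fw$caches1[[h]])
      grads[[paste0("h", h, "_W")]] <- dh$dW
      grads[[paste0("h", h, "_as")]] <- dh$das
      grads[[paste0("h", h, "_at")]] <- dh$dat
    }
    upd <- .adamStep(flat, grads, state, lr, epoch)
    flat <- upd$prm; state <- upd$state
    ## burn-in: early stopping neither selects nor halts before the
    ## optimizer has fitted the first-order terms (output bias), otherwise a
    ## barely-trained network with an arbitrary intercept can be returned
    mon <- if (has_val) .gatLoss(fw$logit, y, weights, val_mask)
           else .gatLoss(fw$logit, y, weights, train_mask)
    if (epoch >= min_epochs) {
      if (mon < best$loss - 1e-6) {
        best <- list(loss = mon, flat = flat, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  }
  list(flat = if (best$epoch > 0L) best$flat else flat,
       heads = as.integer(heads),
       hidden = as.integer(hidden), k = graph$k,
       epochs_run = epoch, best_epoch = best$epoch)
}

## Inductive prediction: the graph is rebuilt within the new data.
.gatPredict <- function(model, X) {
  graph <- buildCellGraph(X, k = model$k)
  edges <- .gatEdges(graph)
  prm <- .unflattenPrm(model$flat, model$heads)
  fw <- .gatForward(X, prm, edges)
  plogis(fw$logit)
}
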