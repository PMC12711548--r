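# ReliefF feature ranking, a small dense softmax network, repeated
# stratified cross-validation and Cohen's kappa.

#' ReliefF feature ranking
#'
#' Standard multiclass ReliefF on range-normalised features: every instance
#' is visited, its `kNeighbors` nearest hits (same class) and, for each
#' other class, `kNeighbors` nearest misses are found by Manhattan distance,
#' and feature weights are updated by the usual difference rule with miss
#' contributions weighted by the class prior relative to `1 - P(class)`.
#' Deterministic: all instances are used and ties are resolved by index
#' order.
#'
#' @param X Observations x features numeric matrix.
#' @param y Class labels (factor or character).
#' @param kNeighbors Neighbours per class (default 10).
#' @param nSelect How many top features to retain (default 30).
#' @return List with `weights` (named per-feature), `ranking` (feature
#'   indices, best first) and `selected` (top `nSelect` indices).
#' @export
relieffRank <- function(X, y, kNeighbors = 10, nSelect = 30) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X); m <- ncol(X)
  tab <- table(y)
  if (any(tab < kNeighbors + 1))
    stop("every class needs at least kNeighbors + 1 observations")
  rng <- apply(X, 2, function(c) diff(range(c)))
  rng[rng == 0] <- 1  # constant features contribute zero differences
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  D <- as.matrix(dist(Xn, method = "manhattan"))
  diag(D) <- Inf
  prior <- as.numeric(tab) / n
  names(prior) <- names(tab)
  wts <- numeric(m)
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    hits <- which(y == y[i] & seq_len(n) != i)
    hits <- hits[order(D[i, hits])][seq_len(kNeighbors)]
    hitTerm <- colMeans(abs(Xn[hits, , drop = FALSE] -
                              rep(Xn[i, ], each = kNeighbors)))
    missTerm <- numeric(m)
    for (cl in setdiff(levels(y), ci)) {
      ms <- which(y == cl)
      ms <- ms[order(D[i, ms])][seq_len(kNeighbors)]
      wcl <- prior[cl] / (1 - prior[ci])
      missTerm <- missTerm + wcl * colMeans(abs(Xn[ms, , drop = FALSE] -
                                                  rep(Xn[i, ], each = kNeighbors)))
    }
    wts <- wts - hitTerm / n + missTerm / n
  }
  names(wts) <- colnames(X) %||% as.character(seq_len(m))
  ranking <- order(wts, decreasing = TRUE)
  list(weights = wts, ranking = ranking,
       selected = ranking[seq_len(min(nSelect, m))])
}

#' Dense network hyperparameters
#'
#' Defaults follow the condition classifier design: 30 input features, two
#' hidden layers of 64 and 32 rectified-linear units each followed by 30%
#' dropout, a 3-class softmax output, 200 training epochs with Adam
#' (learning rate 0.001), L2 penalty 0.001 and mini-batches of 16.
#'
#' @param inputDim Number of input features.
#' @param hidden Hidden layer sizes.
#' @param dropout Dropout probability in \[0, 1).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param l2 L2 regularisation strength.
#' @param batch Mini-batch size.
#' @return A `ClassifierSpec` list.
#' @export
classifierSpec <- function(inputDim = 30, hidden = c(64, 32), dropout = 0.30,
                           epochs = 200, lr = 0.001, l2 = 0.001, batch = 16) {
  stopifnot(inputDim > 0, all(hidden > 0), dropout >= 0, dropout < 1,
            epochs > 0, lr > 0, l2 >= 0, batch > 0)
  structure(list(inputDim = inputDim, hidden = hidden, dropout = dropout,
                 epochs = epochs, lr = lr, l2 = l2, batch = batch),
            class = "ClassifierSpec")
}

relu <- function(x) pmax(x, 0)

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the dense softmax network
#'
#' Fully-connected network `inputDim -> hidden[1] -> hidden[2] -> classes`
#' with ReLU activations, inverted dropout after each hidden layer during
#' training, softmax cross-entropy loss with L2 weight penalty, optimised by
#' Adam on shuffled mini-batches. Training is deterministic given `seed`.
#'
#' @param X Observations x features matrix with `ncol(X) == spec$inputDim`.
#' @param y Class labels (exactly the classifier's class set; 3 conditions
#'   in the standard pipeline).
#' @param spec A [classifierSpec()].
#' @param seed Integer seed (weight initialisation, dropout, batch order).
#' @return Model list (weights, class levels) for [predictClassifier()].
#' @export
trainClassifier <- function(X, y, spec = classifierSpec(), seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (ncol(X) != spec$inputDim)
    stop(sprintf("X has %d columns but spec$inputDim = %d", ncol(X), spec$inputDim))
  lv <- levels(y)
  K <- length(lv)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  set.seed(seed)
  dims <- c(spec$inputDim, spec$hidden, K)
  W <- list(); b <- list()
  for (l in seq_len(length(dims) - 1)) {
    W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                     dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  nL <- length(W)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mB <- lapply(b, function(x) x * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  step <- 0
  n <- nrow(X)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample.int(n)
    for (bs in split(ord, ceiling(seq_along(ord) / spec$batch))) {
      xb <- X[bs, , drop = FALSE]
      yb <- Y[bs, , drop = FALSE]
      nb <- length(bs)
      # forward with inverted dropout on hidden activations
      as_ <- list(); masks <- list()
      h <- xb
      for (l in seq_len(nL - 1)) {
        z <- h %*% W[[l]] + rep(b[[l]], each = nb)
        a <- relu(z)
        msk <- matrix(runif(length(a)) >= spec$dropout, nrow(a), ncol(a))
        a <- a * msk / (1 - spec$dropout)
        as_[[l]] <- a; masks[[l]] <- msk
        h <- a
      }
      zo <- h %*% W[[nL]] + rep(b[[nL]], each = nb)
      P <- softmaxRows(zo)
      # backward
      delta <- (P - yb) / nb
      gW <- list(); gB <- list()
      for (l in nL:1) {
        aPrev <- if (l == 1) xb else as_[[l - 1]]
        gW[[l]] <- crossprod(aPrev, delta) + spec$l2 * W[[l]]
        gB[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * masks[[l - 1]] / (1 - spec$dropout)
          delta[as_[[l - 1]] <= 0] <- 0
        }
      }
      step <- step + 1
      for (l in seq_len(nL)) {
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW[[l]]
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW[[l]]^2
        mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB[[l]]
        vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB[[l]]^2
        mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
        mhB <- mB[[l]] / (1 - beta1^step); vhB <- vB[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - spec$lr * mhW / (sqrt(vhW) + epsA)
        b[[l]] <- b[[l]] - spec$lr * mhB / (sqrt(vhB) + epsA)
      }
    }
  }
  structure(list(W = W, b = b, levels = lv, spec = spec), class = "DenseNet")
}

#' Class probabilities from a trained network
#'
#' @param model A `DenseNet` from [trainClassifier()].
#' @param X Observations x features matrix.
#' @return Observations x classes probability matrix (rows sum to 1).
#' @export
predictClassifier <- function(model, X) {
  X <- as.matrix(X)
  h <- X
  nL <- length(model$W)
  for (l in seq_len(nL - 1))
    h <- relu(h %*% model$W[[l]] + rep(model$b[[l]], each = nrow(X)))
  P <- softmaxRows(h %*% model$W[[nL]] + rep(model$b[[nL]], each = nrow(X)))
  colnames(P) <- model$levels
  P
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace / total` and chance agreement
#' `p_e = sum_i row_i * col_i / total^2`.
#'
#' @param confusion Square count matrix (true x predicted).
#' @return Scalar kappa in \[-1, 1\].
#' @export
cohensKappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  tot <- sum(confusion)
  if (tot <= 0) stop("empty confusion matrix")
  po <- sum(diag(confusion)) / tot
  pe <- sum(rowSums(confusion) * colSums(confusion)) / tot^2
  if (pe >= 1) stop("degenerate confusion matrix (chance agreement = 1)")
  (po - pe) / (1 - pe)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so per-class fold sizes differ by at most one
stratifiedFolds <- function(y, folds) {
  y <- factor(y)
  if (folds > min(table(y)))
    stop("fold count exceeds the smallest class size")
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the condition classifier
#'
#' Per repeat, observations are split into stratified folds preserving class
#' proportions. By default ReliefF ranking and feature standardisation are
#' fit on the training folds only (leakage-free); `selectBeforeSplit = TRUE`
#' instead fits the ReliefF ranking once on the full data before
#' cross-validation, reproducing the protocol in which feature selection
#' precedes the split. With `groups` given (e.g. subject ids), whole groups
#' are assigned to folds so that rows of one subject never straddle the
#' train/test boundary.
#'
#' @param X Observations x features matrix (e.g. 120 PLV edges).
#' @param y Condition labels.
#' @param spec A [classifierSpec()]; `spec$inputDim` features are selected.
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 10).
#' @param seed Integer seed.
#' @param kNeighbors ReliefF neighbours.
#' @param selectBeforeSplit Fit ReliefF on all data before splitting.
#' @param groups Optional grouping factor for group-aware folds.
#' @return List of class `CvReport`: `accuracy` (mean %, over repeats),
#'   `kappa` (mean), `perRepeat` data.frame, `confusions` (list of 3x3
#'   matrices per repeat), `folds`, `repeats`, `seed`.
#' @export
crossValidate <- function(X, y, spec = classifierSpec(), folds = 10,
                          repeats = 10, seed = 1, kNeighbors = 10,
                          selectBeforeSplit = FALSE, groups = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  set.seed(seed)
  globalSel <- NULL
  if (selectBeforeSplit)
    globalSel <- relieffRank(X, y, kNeighbors, spec$inputDim)$selected
  lv <- levels(y)
  confusions <- list()
  accs <- numeric(repeats); kaps <- numeric(repeats)
  for (r in seq_len(repeats)) {
    if (is.null(groups)) {
      fold <- stratifiedFolds(y, folds)
    } else {
      g <- factor(groups)
      gFold <- stats::setNames(rep_len(seq_len(folds), nlevels(g)),
                               sample(levels(g)))
      fold <- gFold[as.character(g)]
    }
    conf <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
    for (f in sort(unique(fold))) {
      tr <- fold != f; te <- fold == f
      sel <- if (selectBeforeSplit) globalSel
             else relieffRank(X[tr, , drop = FALSE], y[tr], kNeighbors,
                              spec$inputDim)$selected
      xtr <- X[tr, sel, drop = FALSE]
      mu <- colMeans(xtr)
      sdev <- apply(xtr, 2, sd); sdev[sdev == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sdev, "/")
      xte <- sweep(sweep(X[te, sel, drop = FALSE], 2, mu), 2, sdev, "/")
      model <- trainClassifier(xtr, y[tr], spec,
                               seed = seed + 1000L * r + f)
      pred <- lv[max.col(predictClassifier(model, xte), ties.method = "first")]
      conf <- conf + table(factor(y[te], lv), factor(pred, lv))
    }
    confusions[[r]] <- conf
    accs[r] <- 100 * sum(diag(conf)) / sum(conf)
    kaps[r] <- cohensKappa(conf)
  }
  structure(list(accuracy = mean(accs), kappa = mean(kaps),
                 perRepeat = data.frame(repeat_ = seq_len(repeats),
                                        accuracy = accs, kappa = kaps),
                 confusions = confusions, folds = folds, repeats = repeats,
                 seed = seed),
            class = "CvReport")
}

#' @export
print.CvReport <- function(x, ...) {
  cat(sprintf("CvReport: %d-fold x %d repeats; accuracy = %.2f%%, kappa = %.3f\n",
              x$folds, x$repeats, x$accuracy, x$kappa))
  invisible(x)
}

#' Reference SVM baseline
#'
#' Thin wrapper around a radial-kernel support vector machine, provided as
#' an independent baseline alongside the dense network. Requires the
#' `e1071` package.
#'
#' @param X Observations x features matrix.
#' @param y Class labels.
#' @param ... Passed to `e1071::svm`.
#' @return Fitted SVM model.
#' @export
svmBaseline <- function(X, y, ...) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("svmBaseline requires the e1071 package")
  e1071::svm(as.matrix(X), factor(y), ...)
}
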