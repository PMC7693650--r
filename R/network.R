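#' Feed-forward network configuration
#'
#' The classifier is a fully-connected feed-forward network with two hidden
#' layers of 30 and 5 neurons (hyperbolic tangent sigmoid activations) and a
#' single read-out perceptron with a log-sigmoid activation, trained with a
#' cross-entropy loss for a fixed number of epochs. A case is called HCM
#' when the output strictly exceeds the decision threshold 0.5.
#'
#' @param dIn input dimension (number of features)
#' @param hidden hidden layer sizes (default c(30, 5))
#' @param epochs training epochs (default 100)
#' @param lr learning rate of the full-batch Adam optimizer
#' @param seed RNG seed for weight initialization
#' @param threshold decision threshold (strict >)
#' @return list of class \code{networkConfig}
#' @export
networkConfig <- function(dIn, hidden = c(30L, 5L), epochs = 100L,
                          lr = 0.01, seed = 1L, threshold = 0.5) {
  stopifnot(dIn >= 1, length(hidden) >= 1, epochs >= 1, lr > 0)
  structure(list(layerSizes = c(as.integer(dIn), as.integer(hidden), 1L),
                 epochs = as.integer(epochs), lr = lr,
                 seed = as.integer(seed), threshold = threshold),
            class = "networkConfig")
}

logSigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize network parameters
#'
#' Weights drawn Uniform(-1/sqrt(fanIn), +1/sqrt(fanIn)) per layer, biases
#' zero; seeded for reproducibility.
#'
#' @param config a \code{\link{networkConfig}}
#' @return list with \code{W} (list of matrices, rows = output units) and
#'   \code{b} (list of bias vectors)
#' @export
initNetwork <- function(config) {
  set.seed(config$seed)
  sizes <- config$layerSizes
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    lim <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(runif(sizes[l + 1] * sizes[l], -lim, lim),
                     nrow = sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, center = NULL, scale = NULL)
}

# forward pass with cached activations (X: n x d, rows are subjects)
forwardPass <- function(params, X) {
  A <- list(X)
  nl <- length(params$W)
  for (l in seq_len(nl)) {
    Z <- A[[l]] %*% t(params$W[[l]]) +
      matrix(params$b[[l]], nrow(X), length(params$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < nl) tanh(Z) else logSigmoid(Z)
  }
  A
}

#' Network forward evaluation
#'
#' Applies the stored z-scoring (if the parameters come from
#' \code{\link{trainNetwork}}) and the tanh/tanh/log-sigmoid composition;
#' outputs lie strictly in (0, 1).
#'
#' @param params network parameters
#' @param X matrix (subjects x features) or a single feature vector
#' @return vector of HCM probabilities
#' @export
forwardNetwork <- function(params, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (!is.null(params$center))
    X <- sweep(sweep(X, 2, params$center), 2, params$scale, "/")
  drop(forwardPass(params, X)[[length(params$W) + 1L]])
}

#' Cross-entropy loss
#'
#' Mean of \code{-(y log p + (1-y) log(1-p))} over a batch.
#'
#' @param p predicted probabilities in (0, 1)
#' @param y binary labels
#' @return scalar loss
#' @export
crossEntropy <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Train the feed-forward classifier
#'
#' Features are z-scored with training-set statistics (stored with the
#' parameters for inference; zero-variance columns get unit scale), then the
#' network is trained with full-batch gradient descent using Adam adaptive
#' steps for exactly \code{epochs} epochs. Deterministic under a fixed
#' config seed.
#'
#' @param X matrix subjects x features
#' @param y binary labels (1 = HCM)
#' @param config a \code{\link{networkConfig}}
#' @return trained parameter list (weights, biases, z-scoring statistics,
#'   per-epoch loss trace)
#' @export
trainNetwork <- function(X, y, config) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training set contains a single class")
  stopifnot(nrow(X) == length(y), ncol(X) == config$layerSizes[1])
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scl, "/")
  params <- initNetwork(config)
  nl <- length(params$W)
  mW <- lapply(params$W, function(w) w * 0); vW <- mW
  mB <- lapply(params$b, function(b) b * 0); vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  n <- nrow(Xs)
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    A <- forwardPass(params, Xs)
    p <- drop(A[[nl + 1]])
    losses[ep] <- crossEntropy(p, y)
    if (!is.finite(losses[ep]))
      stop("non-finite loss at epoch ", ep)
    # backward pass: d(loss)/d(z_out) = (p - y)/n for sigmoid + cross-entropy
    delta <- matrix((p - y) / n, ncol = 1)
    for (l in nl:1) {
      gW <- t(delta) %*% A[[l]]
      gB <- colSums(delta)
      if (l > 1)
        delta <- (delta %*% params$W[[l]]) * (1 - A[[l]]^2)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
      vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB^2
      mhW <- mW[[l]] / (1 - beta1^ep); vhW <- vW[[l]] / (1 - beta2^ep)
      mhB <- mB[[l]] / (1 - beta1^ep); vhB <- vB[[l]] / (1 - beta2^ep)
      params$W[[l]] <- params$W[[l]] - config$lr * mhW / (sqrt(vhW) + epsA)
      params$b[[l]] <- params$b[[l]] - config$lr * mhB / (sqrt(vhB) + epsA)
    }
  }
  params$center <- center
  params$scale <- scl
  params$losses <- losses
  params
}

#' Classify subjects
#'
#' HCM if and only if the network output strictly exceeds the threshold;
#' an output of exactly 0.5 is called non-HCM.
#'
#' @param params trained parameters
#' @param X feature matrix or vector
#' @param threshold decision threshold (default 0.5)
#' @return character vector "HCM" / "non-HCM"
#' @export
classifyHCM <- function(params, X, threshold = 0.5) {
  ifelse(forwardNetwork(params, X) > threshold, "HCM", "non-HCM")
}

#' Stratified k-fold assignment
#'
#' Within each class the (shuffled) subjects are dealt round-robin to the k
#' folds, so per-class fold sizes differ by at most one and every subject is
#' tested exactly once.
#'
#' @param labels class labels (any number of classes)
#' @param k number of folds
#' @param seed RNG seed for the shuffle
#' @return integer fold id per subject
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2 (no held-out data otherwise)")
  tab <- table(labels)
  if (any(tab < k))
    stop("class ", names(tab)[which.min(tab)], " has fewer subjects (",
         min(tab), ") than folds (", k, ")")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# interpolate a fold ROC onto a fixed FPR grid (best TPR at FPR <= g)
rocOnGrid <- function(points, grid) {
  vapply(grid, function(g) max(points$tpr[points$fpr <= g + 1e-12]),
         numeric(1))
}

#' Cross-validated training and evaluation
#'
#' Stratified 5-fold protocol: per fold the network is standardized and
#' trained on the 4/5 training portion only and scored on the held-out 1/5;
#' AUC and threshold metrics are computed per fold and summarized as mean
#' with sample SD (n-1). The median ROC is the pointwise median of the fold
#' curves interpolated on a fixed FPR grid. Folds whose PPV/NPV are
#' undefined (zero denominator) are excluded from that metric's summary with
#' a warning.
#'
#' @param se feature \code{SummarizedExperiment} (or a list with elements
#'   \code{features} (features x subjects) and \code{label})
#' @param config a \code{\link{networkConfig}}; its seed also drives the
#'   fold assignment
#' @param k number of folds
#' @return a \code{CVResult}
#' @export
crossValidate <- function(se, config = NULL, k = 5L) {
  if (is(se, "SummarizedExperiment")) {
    X <- t(SummarizedExperiment::assay(se, "features"))
    lab <- se$label
  } else {
    X <- t(se$features)
    lab <- se$label
  }
  y <- as.integer(lab == "HCM")
  if (is.null(config)) config <- networkConfig(ncol(X))
  fold <- stratifiedKFold(lab, k = k, seed = config$seed)
  grid <- seq(0, 1, by = 0.01)
  folds <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(fold != f); teIdx <- which(fold == f)
    cfgF <- config
    cfgF$seed <- deriveSeed(config$seed, 2L, f)
    paramsF <- trainNetwork(X[trIdx, , drop = FALSE], y[trIdx], cfgF)
    scores <- forwardNetwork(paramsF, X[teIdx, , drop = FALSE])
    if (length(unique(y[teIdx])) < 2) {
      warning("fold ", f, " has a single-class test set; AUC undefined")
      roc <- list(points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                  auc = NA_real_)
    } else {
      roc <- rocCurve(scores, y[teIdx])
    }
    cm <- confusionMetrics(scores > config$threshold, y[teIdx])
    folds[[f]] <- list(roc = roc$points, auc = roc$auc, metrics = cm,
                       trainIndex = trIdx, testIndex = teIdx,
                       scores = scores, gridTPR = rocOnGrid(roc$points, grid))
    rows[[f]] <- data.frame(fold = f, auc = roc$auc, t(cm))
  }
  metrics <- do.call(rbind, rows)
  if (anyNA(metrics[, c("ppv", "npv")]))
    warning("undefined PPV/NPV in some fold(s); excluded from summaries")
  mnames <- c("auc", "sensitivity", "specificity", "ppv", "npv", "accuracy")
  summ <- data.frame(
    metric = mnames,
    mean = vapply(mnames, function(m) mean(metrics[[m]], na.rm = TRUE),
                  numeric(1)),
    sd = vapply(mnames, function(m) sd(metrics[[m]], na.rm = TRUE),
                numeric(1)),
    row.names = NULL)
  tprMat <- vapply(folds, `[[`, numeric(length(grid)), "gridTPR")
  med <- data.frame(fpr = grid, tpr = apply(tprMat, 1, median))
  new("CVResult", folds = folds, metrics = metrics, summary = summ,
      medianROC = med, config = list(k = k, network = config))
}
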