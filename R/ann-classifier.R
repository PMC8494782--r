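#' @include AllClasses.R roi-dataset.R
NULL

.featMatrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 5L) stopf("feature matrix must have 5 columns")
    m <- x
  } else if (is.data.frame(x)) {
    miss <- setdiff(.FEATNAMES, names(x))
    if (length(miss)) stopf("feature table lacks column(s): %s", paste(miss, collapse = ", "))
    m <- as.matrix(x[, .FEATNAMES, drop = FALSE])
  } else if (is.numeric(x) && length(x) == 5L) {
    m <- matrix(x, nrow = 1L, dimnames = list(NULL, .FEATNAMES))
  } else stopf("features must be a data.frame, 5-column matrix, or numeric(5)")
  if (any(!is.finite(m))) stopf("non-finite feature value(s)")
  m
}

.softmax <- function(A) {
  A <- A - apply(A, 1L, max)
  E <- exp(A)
  E / rowSums(E)
}

.forward <- function(X, W1, b1, W2, b2) {
  Z <- tanh(sweep(X %*% W1, 2L, b1, "+"))
  P <- .softmax(sweep(Z %*% W2, 2L, b2, "+"))
  list(Z = Z, P = P)
}

.crossEntropy <- function(P, yIdx) {
  -mean(log(pmax(P[cbind(seq_along(yIdx), yIdx)], 1e-15)))
}

#' Train the parenchymal pattern classifier
#'
#' Fits a single-hidden-layer feed-forward network (5 percentile features
#' -> `hiddenUnits` tanh units -> 5-class softmax) by full-batch gradient
#' descent on the multinomial cross-entropy, with a bold-driver adaptive
#' step (grow the step after an accepted epoch, halve and retract after an
#' increase in training loss). Training stops when the validation
#' cross-entropy has not improved for `patience` consecutive epochs, or at
#' `maxEpochs`; the returned weights are those of the best validation
#' epoch. Features are standardized with training-partition statistics
#' only, so no information leaks from the held-out partitions.
#'
#' @param split a `SplitDataset` from [splitDataset()].
#' @param hiddenUnits hidden layer width (default 10).
#' @param maxEpochs cap on gradient epochs (default 400).
#' @param patience epochs without validation improvement before stopping
#'   (default 6).
#' @param learningRate initial step size (default 0.5; adapted per epoch).
#' @param seed integer seed for the weight initialization.
#' @return A [PatternClassifier-class] with the full per-epoch
#'   cross-entropy history for the train, validation and test partitions.
#' @export
trainClassifier <- function(split, hiddenUnits = 10L, maxEpochs = 400L,
                            patience = 6L, learningRate = 0.5, seed = 1L) {
  stopifnot(inherits(split, "SplitDataset"))
  Xtr <- .featMatrix(split$train)
  ytr <- match(split$train$label, .CLASSES)
  Xva <- .featMatrix(split$validation)
  yva <- match(split$validation$label, .CLASSES)
  Xte <- .featMatrix(split$test)
  yte <- match(split$test$label, .CLASSES)
  center <- colMeans(Xtr)
  scale <- apply(Xtr, 2L, sd)
  scale[scale < 1e-12] <- 1
  std <- function(X) sweep(sweep(X, 2L, center), 2L, scale, "/")
  Xtr <- std(Xtr); Xva <- std(Xva); Xte <- std(Xte)
  n <- nrow(Xtr)
  H <- as.integer(hiddenUnits)
  Y <- matrix(0, n, 5L); Y[cbind(seq_len(n), ytr)] <- 1

  withr::local_seed(as.integer(seed))
  W1 <- matrix(rnorm(5L * H, sd = 1 / sqrt(5)), 5L, H)
  b1 <- numeric(H)
  W2 <- matrix(rnorm(H * 5L, sd = 1 / sqrt(H)), H, 5L)
  b2 <- numeric(5L)

  lr <- learningRate
  fw <- .forward(Xtr, W1, b1, W2, b2)
  trLoss <- .crossEntropy(fw$P, ytr)
  hist <- matrix(NA_real_, maxEpochs, 3L)
  best <- list(val = Inf, epoch = 0L)
  sinceBest <- 0L
  epoch <- 0L
  while (epoch < maxEpochs) {
    epoch <- epoch + 1L
    D <- (fw$P - Y) / n
    gW2 <- crossprod(fw$Z, D)
    gb2 <- colSums(D)
    dZ <- (D %*% t(W2)) * (1 - fw$Z^2)
    gW1 <- crossprod(Xtr, dZ)
    gb1 <- colSums(dZ)
    nW1 <- W1 - lr * gW1; nb1 <- b1 - lr * gb1
    nW2 <- W2 - lr * gW2; nb2 <- b2 - lr * gb2
    nfw <- .forward(Xtr, nW1, nb1, nW2, nb2)
    nLoss <- .crossEntropy(nfw$P, ytr)
    if (!is.finite(nLoss))
      stopf("training diverged (non-finite loss) at epoch %d", epoch)
    if (nLoss <= trLoss * (1 + 1e-8)) {
      W1 <- nW1; b1 <- nb1; W2 <- nW2; b2 <- nb2
      fw <- nfw; trLoss <- nLoss
      lr <- lr * 1.1
    } else {
      lr <- lr * 0.5
      if (lr < 1e-12) { epoch <- epoch - 1L; break }
    }
    vaLoss <- .crossEntropy(.forward(Xva, W1, b1, W2, b2)$P, yva)
    teLoss <- .crossEntropy(.forward(Xte, W1, b1, W2, b2)$P, yte)
    hist[epoch, ] <- c(trLoss, vaLoss, teLoss)
    if (vaLoss < best$val - 1e-12) {
      best <- list(val = vaLoss, epoch = epoch,
                   W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= patience) break
    }
  }
  hist <- hist[seq_len(epoch), , drop = FALSE]
  history <- data.frame(epoch = seq_len(epoch), train = hist[, 1],
                        validation = hist[, 2], test = hist[, 3])
  new("PatternClassifier",
      W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
      center = center, scale = scale, classes = .CLASSES,
      history = history, bestEpoch = best$epoch, seed = as.integer(seed))
}

#' Predict parenchymal classes from percentile features
#'
#' @param object a trained [PatternClassifier-class].
#' @param features a feature data.frame (columns `p2_5` .. `p97_5`), a
#'   numeric matrix with 5 columns, or a single numeric(5).
#' @param ... unused.
#' @return A list with `posterior` (rows sum to 1, columns in class order)
#'   and `label` (argmax class; posterior ties broken by class order).
#' @export
setMethod("predict", "PatternClassifier", function(object, features, ...) {
  X <- .featMatrix(features)
  X <- sweep(sweep(X, 2L, object@center), 2L, object@scale, "/")
  P <- .forward(X, object@W1, object@b1, object@W2, object@b2)$P
  colnames(P) <- object@classes
  list(posterior = P,
       label = object@classes[max.col(P, ties.method = "first")])
})

#' Evaluate a classifier on labelled samples
#'
#' Produces the confusion matrix (rows: true class, columns: predicted),
#' overall accuracy, per-class recall (diagonal over row sum; `NA` for a
#' class absent from the sample), and a one-vs-rest ROC curve with
#' trapezoidal AUC per class, obtained by sweeping a threshold over that
#' class's posterior.
#'
#' @param model a [PatternClassifier-class].
#' @param samples data.frame with `label` and the feature columns.
#' @return A list of class `EvalReport`: `confusion`, `accuracy`, `recall`,
#'   `roc` (per class, data.frame `fpr`/`tpr`), `auc`.
#' @export
evaluateClassifier <- function(model, samples) {
  .checkFeatureTable(samples)
  pred <- predict(model, samples)
  truth <- factor(samples$label, levels = .CLASSES)
  predicted <- factor(pred$label, levels = .CLASSES)
  confusion <- table(truth = truth, predicted = predicted)
  accuracy <- sum(diag(confusion)) / sum(confusion)
  rs <- rowSums(confusion)
  recall <- ifelse(rs > 0, diag(confusion) / rs, NA_real_)
  names(recall) <- .CLASSES
  roc <- list(); auc <- setNames(rep(NA_real_, 5L), .CLASSES)
  for (k in seq_along(.CLASSES)) {
    pos <- truth == .CLASSES[k]
    if (!any(pos) || all(pos)) { roc[[.CLASSES[k]]] <- NULL; next }
    r <- .rocCurve(pred$posterior[, k], pos)
    roc[[.CLASSES[k]]] <- r$points
    auc[k] <- r$auc
  }
  structure(list(confusion = confusion, accuracy = accuracy, recall = recall,
                 roc = roc, auc = auc),
            class = "EvalReport")
}

.rocCurve <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- positive[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)   # one point per distinct threshold
  tpr <- c(0, tp[keep] / sum(y))
  fpr <- c(0, fp[keep] / sum(!y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: accuracy %.4f\n", x$accuracy))
  print(x$confusion)
  cat("Per-class recall:\n")
  print(round(x$recall, 4))
  cat("Per-class AUC:\n")
  print(round(x$auc, 4))
  invisible(x)
}

#' Classify every lung voxel of a CT volume
#'
#' For each in-mask voxel, the in-plane disc of in-mask neighbours within
#' `radiusMm` supplies the percentile features, and the voxel receives the
#' argmax posterior class. Voxels whose disc holds fewer than five in-mask
#' neighbours are still classified from whatever neighbours exist (at least
#' the voxel itself) and counted in the map's `qcSmallDisc` flag. With
#' `stride > 1` only voxels on a stride grid are classified directly and
#' the remaining lung voxels inherit the label of their nearest stride
#' point (classifying directly where that point lies outside the lung).
#'
#' @param v a [CTVolume-class].
#' @param mask a [LungLabelMap-class] on the same grid.
#' @param model a trained [PatternClassifier-class].
#' @param radiusMm feature disc radius in mm (default 4).
#' @param stride in-plane classification stride in voxels (default 1 =
#'   every lung voxel).
#' @return A [ClassMap-class].
#' @export
classifyVolume <- function(v, mask, model, radiusMm = 4, stride = 1L) {
  stopifnot(is(v, "CTVolume"), is(mask, "LungLabelMap"),
            is(model, "PatternClassifier"))
  checkGrid(mask@labels, v@voxels)
  d <- dim(v@voxels)
  off <- discOffsets(radiusMm, v@pixelSpacing)
  out <- array(0L, d)
  qc <- 0L
  for (s in seq_len(d[3])) {
    msk <- mask@labels[, , s] > 0L
    if (!any(msk)) next
    pix <- which(msk, arr.ind = TRUE)
    if (stride > 1L) {
      anchor <- (pix[, 1] - 1L) %% stride == 0L & (pix[, 2] - 1L) %% stride == 0L
      near <- cbind(pmin(d[1], ((pix[, 1] - 1L) %/% stride) * stride + 1L),
                    pmin(d[2], ((pix[, 2] - 1L) %/% stride) * stride + 1L))
      nearInLung <- msk[near]
      doRows <- anchor | !nearInLung
    } else {
      doRows <- rep(TRUE, nrow(pix))
      near <- NULL
    }
    target <- pix[doRows, , drop = FALSE]
    if (nrow(target) > 0L) {
      feats <- .discFeatures(v@voxels[, , s], msk, target, off)
      qc <- qc + feats$nSmall
      pr <- predict(model, feats$features)
      lab2d <- array(0L, d[1:2])
      lab2d[target] <- match(pr$label, .CLASSES)
      if (stride > 1L) {
        fill <- which(!doRows)
        lab2d[pix[fill, , drop = FALSE]] <- lab2d[near[fill, , drop = FALSE]]
      }
      out[, , s] <- lab2d
    }
  }
  ClassMap(out, qcSmallDisc = qc)
}

## Percentile features for many centres on one slice, vectorized over the
## disc offsets. Returns the feature matrix and the count of centres whose
## disc held < 5 valid (in-mask, in-bounds) voxels.
.discFeatures <- function(slice, msk, centers, off) {
  d <- dim(slice)
  n <- nrow(centers)
  K <- nrow(off)
  vals <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    rr <- centers[, 1] + off$dr[k]
    cc <- centers[, 2] + off$dc[k]
    ok <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
    idx <- cbind(rr[ok], cc[ok])
    inm <- msk[idx]
    sel <- which(ok)[inm]
    vals[sel, k] <- slice[idx[inm, , drop = FALSE]]
  }
  nValid <- rowSums(!is.na(vals))
  feats <- t(apply(vals, 1L, function(z)
    quantile(z[!is.na(z)], probs = .FEATPROBS, type = 7, names = FALSE)))
  colnames(feats) <- .FEATNAMES
  list(features = feats, nSmall = sum(nValid < 5L))
}

#' Serialize a classifier to JSON / restore it
#'
#' Weights, standardization parameters, class order, training history and
#' metadata are written with maximal JSON numeric precision; predictions
#' from a restored model agree with the original to round-off (~1e-15).
#'
#' @param model a [PatternClassifier-class].
#' @param path JSON file path.
#' @return `writeClassifier` returns `path` invisibly; `readClassifier`
#'   the restored model.
#' @export
writeClassifier <- function(model, path) {
  stopifnot(is(model, "PatternClassifier"))
  jsonlite::write_json(
    list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
         center = model@center, scale = model@scale, classes = model@classes,
         history = model@history, bestEpoch = model@bestEpoch,
         seed = model@seed),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PatternClassifier",
      W1 = structure(as.numeric(j$W1), dim = dim(j$W1)),
      b1 = as.numeric(j$b1),
      W2 = structure(as.numeric(j$W2), dim = dim(j$W2)),
      b2 = as.numeric(j$b2),
      center = setNames(as.numeric(j$center), .FEATNAMES),
      scale = setNames(as.numeric(j$scale), .FEATNAMES),
      classes = as.character(j$classes),
      history = as.data.frame(j$history),
      bestEpoch = as.integer(j$bestEpoch), seed = as.integer(j$seed))
}
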