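#' Multinomial gradient boosting machine
#'
#' Stagewise gradient boosting for K-class classification with the multinomial
#' deviance loss: per boosting round, one small regression tree (rpart) is fit
#' to each class's negative gradient (observed indicator minus current
#' softmax probability) and its terminal-node values are replaced by the
#' one-step Newton estimates \eqn{\gamma = \frac{K-1}{K} \sum r / \sum
#' |r|(1-|r|)}, added to the class score with learning-rate shrinkage. Scores
#' are initialized at the log class proportions.
#'
#' Serves both as one of the eight base learners and as the stacking
#' meta-learner.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of class labels (>= 2 levels present).
#' @param n_trees Boosting rounds, default 100.
#' @param shrinkage Learning rate, default 0.1.
#' @param depth Maximum tree depth, default 3.
#' @param minobs Minimum observations per terminal node, default 5.
#' @return Object of class `scrs_gbm`.
#' @export
gbm_fit <- function(x, y, n_trees = 100, shrinkage = 0.1, depth = 3,
                    minobs = 5) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  if (k < 2) stop("degenerate single-class input")
  n <- nrow(x)
  classes <- levels(y)
  yi <- matrix(0, n, k)
  yi[cbind(seq_len(n), as.integer(y))] <- 1
  pri <- as.vector(table(y)) / n
  f0 <- log(pmax(pri, 1e-12))
  f0 <- f0 - mean(f0)
  fmat <- matrix(f0, n, k, byrow = TRUE)
  df <- as.data.frame(x)
  names(df) <- paste0("V", seq_len(ncol(x)))
  ctrl <- rpart::rpart.control(maxdepth = depth, cp = 0, minsplit = 2 * minobs,
                               minbucket = minobs, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  trees <- vector("list", n_trees)
  for (it in seq_len(n_trees)) {
    emax <- apply(fmat, 1, max)
    pr <- exp(fmat - emax)
    pr <- pr / rowSums(pr)
    round_trees <- vector("list", k)
    for (cl in seq_len(k)) {
      r <- yi[, cl] - pr[, cl]
      df$.r <- r
      tr <- rpart::rpart(.r ~ ., data = df, method = "anova", control = ctrl)
      leaves <- tr$where                      # frame row per training obs
      gam <- tapply(seq_len(n), leaves, function(idx) {
        num <- sum(r[idx])
        den <- sum(abs(r[idx]) * (1 - abs(r[idx])))
        if (den < 1e-12) 0 else (k - 1) / k * num / den
      })
      gam <- pmin(pmax(gam, -4), 4)           # guard against huge Newton steps
      tr$frame$yval <- 0
      tr$frame$yval[as.integer(names(gam))] <- gam
      fmat[, cl] <- fmat[, cl] + shrinkage * tr$frame$yval[leaves]
      tr$y <- NULL                            # drop training payload
      round_trees[[cl]] <- tr
    }
    trees[[it]] <- round_trees
  }
  structure(list(trees = trees, classes = classes, f0 = f0,
                 shrinkage = shrinkage, n_features = ncol(x)),
            class = "scrs_gbm")
}

#' Predict class probabilities from a fitted GBM
#'
#' @param object An `scrs_gbm` model.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   class.
#' @export
predict.scrs_gbm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) stop("feature count mismatch")
  df <- as.data.frame(newdata)
  names(df) <- paste0("V", seq_len(ncol(newdata)))
  k <- length(object$classes)
  fmat <- matrix(object$f0, nrow(newdata), k, byrow = TRUE)
  for (round_trees in object$trees) {
    for (cl in seq_len(k)) {
      fmat[, cl] <- fmat[, cl] +
        object$shrinkage * unname(stats::predict(round_trees[[cl]], df))
    }
  }
  emax <- apply(fmat, 1, max)
  pr <- exp(fmat - emax)
  pr <- pr / rowSums(pr)
  colnames(pr) <- object$classes
  pr
}

#' @export
print.scrs_gbm <- function(x, ...) {
  cat(sprintf("Multinomial GBM: %d rounds, %d classes, shrinkage %.2f\n",
              length(x$trees), length(x$classes), x$shrinkage))
  invisible(x)
}
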