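#' Mixture discriminant analysis
#'
#' Each class is modeled as a Gaussian mixture (default 3 subclasses) with a
#' covariance matrix shared across all subclasses of all classes, fitted by
#' EM with k-means initialization. With one subclass per class the model
#' reduces to linear discriminant analysis with proportional priors.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of class labels.
#' @param subclasses Mixture components per class (reduced to the class size
#'   where necessary), default 3.
#' @param max_iter EM iteration cap, default 100.
#' @param tol Relative log-likelihood convergence tolerance, default 1e-6.
#' @param seed Seed for the k-means initialization.
#' @return Object of class `scrs_mda`.
#' @export
mda_fit <- function(x, y, subclasses = 3, max_iter = 100, tol = 1e-6,
                    seed = 1) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  k <- nlevels(y)
  if (k < 2) stop("degenerate single-class input")
  n <- nrow(x); p <- ncol(x)
  classes <- levels(y)
  priors <- as.vector(table(y)) / n

  set.seed(seed)
  comp <- list()   # per class: means (R x p), weights (R)
  for (ci in seq_len(k)) {
    xc <- x[y == classes[ci], , drop = FALSE]
    r <- min(subclasses, max(1, nrow(xc) - 1), nrow(unique(xc)))
    if (r == 1) {
      comp[[ci]] <- list(means = matrix(colMeans(xc), 1), weights = 1)
    } else {
      km <- tryCatch(stats::kmeans(xc, centers = r, nstart = 3),
                     error = function(e) NULL)
      if (is.null(km)) {
        comp[[ci]] <- list(means = matrix(colMeans(xc), 1), weights = 1)
      } else {
        comp[[ci]] <- list(means = km$centers,
                           weights = km$size / nrow(xc))
      }
    }
  }

  pooled_cov <- function(resp_list) {
    s <- matrix(0, p, p)
    rtot <- 0
    for (ci in seq_len(k)) {
      xc <- x[y == classes[ci], , drop = FALSE]
      z <- resp_list[[ci]]
      rtot <- rtot + ncol(z)
      for (ri in seq_len(ncol(z))) {
        d <- sweep(xc, 2, comp[[ci]]$means[ri, ])
        s <- s + crossprod(d * z[, ri], d)
      }
    }
    # unbiased pooled divisor (reduces to the LDA estimate at 1 subclass)
    s / max(n - rtot, 1)
  }

  # hard-assignment responsibilities for the initial covariance
  resp <- lapply(seq_len(k), function(ci) {
    xc <- x[y == classes[ci], , drop = FALSE]
    r <- nrow(comp[[ci]]$means)
    d2 <- vapply(seq_len(r), function(ri)
      rowSums(sweep(xc, 2, comp[[ci]]$means[ri, ])^2), numeric(nrow(xc)))
    d2 <- matrix(d2, nrow = nrow(xc))
    z <- matrix(0, nrow(xc), r)
    z[cbind(seq_len(nrow(xc)), max.col(-d2, ties.method = "first"))] <- 1
    z
  })
  sigma <- pooled_cov(resp)
  ridge <- function(s) s + diag(max(1e-10, 1e-8 * mean(diag(s))), p)

  loglik_old <- -Inf
  for (iter in seq_len(max_iter)) {
    sig <- ridge(sigma)
    ch <- chol(sig)
    logdet <- 2 * sum(log(diag(ch)))
    ll <- 0
    for (ci in seq_len(k)) {
      xc <- x[y == classes[ci], , drop = FALSE]
      cmp <- comp[[ci]]
      r <- nrow(cmp$means)
      logd <- vapply(seq_len(r), function(ri) {
        d <- sweep(xc, 2, cmp$means[ri, ])
        q <- colSums(backsolve(ch, t(d), transpose = TRUE)^2)
        log(pmax(cmp$weights[ri], 1e-12)) - 0.5 * (q + logdet + p * log(2 * pi))
      }, numeric(nrow(xc)))
      logd <- matrix(logd, nrow = nrow(xc))
      mx <- apply(logd, 1, max)
      lse <- mx + log(rowSums(exp(logd - mx)))
      ll <- ll + sum(lse)
      resp[[ci]] <- exp(logd - lse)
    }
    # M step
    for (ci in seq_len(k)) {
      xc <- x[y == classes[ci], , drop = FALSE]
      z <- resp[[ci]]
      nk <- colSums(z)
      keep <- nk > 1e-8
      z <- z[, keep, drop = FALSE]; nk <- nk[keep]
      comp[[ci]]$means <- sweep(crossprod(z, xc), 1, nk, `/`)
      comp[[ci]]$weights <- nk / nrow(xc)
      resp[[ci]] <- z
    }
    sigma <- pooled_cov(resp)
    if (is.finite(loglik_old) &&
        abs(ll - loglik_old) < tol * (abs(loglik_old) + 1)) break
    loglik_old <- ll
  }
  structure(list(classes = classes, priors = priors, comp = comp,
                 sigma = ridge(sigma), loglik = loglik_old,
                 n_features = p),
            class = "scrs_mda")
}

#' Predict class probabilities from a fitted MDA model
#'
#' Posterior probabilities proportional to class prior times the class's
#' Gaussian-mixture density, evaluated with the shared covariance.
#'
#' @param object An `scrs_mda` model.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Matrix of class probabilities, columns named by class.
#' @export
predict.scrs_mda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) stop("feature count mismatch")
  k <- length(object$classes)
  p <- object$n_features
  ch <- chol(object$sigma)
  logdet <- 2 * sum(log(diag(ch)))
  logp <- vapply(seq_len(k), function(ci) {
    cmp <- object$comp[[ci]]
    r <- nrow(cmp$means)
    logd <- vapply(seq_len(r), function(ri) {
      d <- sweep(newdata, 2, cmp$means[ri, ])
      q <- colSums(backsolve(ch, t(d), transpose = TRUE)^2)
      log(pmax(cmp$weights[ri], 1e-12)) - 0.5 * (q + logdet + p * log(2 * pi))
    }, numeric(nrow(newdata)))
    logd <- matrix(logd, nrow = nrow(newdata))
    mx <- apply(logd, 1, max)
    log(object$priors[ci]) + mx + log(rowSums(exp(logd - mx)))
  }, numeric(nrow(newdata)))
  logp <- matrix(logp, nrow = nrow(newdata))
  mx <- apply(logp, 1, max)
  pr <- exp(logp - mx)
  pr <- pr / rowSums(pr)
  colnames(pr) <- object$classes
  pr
}

#' @export
print.scrs_mda <- function(x, ...) {
  cat(sprintf("MDA: %d classes, %s subclasses, shared covariance (%d features)\n",
              length(x$classes),
              paste(vapply(x$comp, function(c) nrow(c$means), 1L), collapse = "/"),
              x$n_features))
  invisible(x)
}
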