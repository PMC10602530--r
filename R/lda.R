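#' Collapse five-group labels to the three-group task
#'
#' Maps the ME severity subgroups (`MildME`, `ModME`, `SevME`) to a single
#' `ME` label; `HC` and `MS` are unchanged.
#'
#' @param labels Character or factor labels.
#' @return Character vector of collapsed labels.
#' @export
collapse_groups <- function(labels) {
  l <- as.character(labels)
  l[l %in% c("MildME", "ModME", "SevME")] <- "ME"
  l
}

# canonical class orders; used for factor levels and tie-breaking
group_levels <- function(labels) {
  known <- c("HC", "MildME", "ModME", "SevME", "ME", "MS")
  u <- unique(as.character(labels))
  c(intersect(known, u), setdiff(u, known))
}

# Ledoit-Wolf-style shrinkage intensity toward the scaled-identity target,
# computed on rows already centered (here: within-class deviations)
lw_shrinkage <- function(xc) {
  n <- nrow(xc); p <- ncol(xc)
  s <- crossprod(xc) / n
  m <- sum(diag(s)) / p
  d2 <- sum((s - diag(m, p))^2) / p
  if (d2 < .Machine$double.eps) return(list(lambda = 0, s = s, m = m))
  xsq <- rowSums(xc^2)
  b2bar <- (sum(xsq^2) / n^2 - sum(s^2) / n) / p
  b2 <- min(max(b2bar, 0), d2)
  list(lambda = b2 / d2, s = s, m = m)
}

#' Fit a supervised linear discriminant model to spectra
#'
#' Solves the generalized eigenproblem of between- over within-class scatter,
#' with the within-class covariance regularized by Ledoit--Wolf-style
#' shrinkage toward a scaled identity — necessary because the number of
#' spectral channels typically exceeds the number of cells per class. With
#' `level = "subject"` each subject's cell spectra are averaged before
#' fitting. Discriminant directions are unit-normalized with the sign fixed so
#' the largest-magnitude coefficient is positive; explained variance ratios
#' are the eigenvalue fractions over the retained axes (at most one fewer
#' axis than classes).
#'
#' @param x An [scrs_set] or numeric matrix (rows = cells, columns = features).
#' @param labels Group label per row of `x`.
#' @param level `"cell"` or `"subject"`.
#' @param subjects Subject id per row (taken from `x$meta` for an
#'   [scrs_set]); required for subject-level fits.
#' @param region Optional wavenumber range `c(start, end)` to restrict the fit
#'   (e.g. the fingerprint region `c(300, 1800)`).
#' @param shrinkage `"auto"` (Ledoit--Wolf) or a fixed value in \[0, 1\].
#' @return Object of class `scrs_lda`: discriminant directions (`scaling`),
#'   `explained_variance_ratio`, class means in LD space, projected
#'   coordinates `x`, labels, and the feature wavenumbers.
#' @export
fit_lda <- function(x, labels, level = c("cell", "subject"), subjects = NULL,
                    region = NULL, shrinkage = "auto") {
  level <- match.arg(level)
  if (inherits(x, "scrs_set")) {
    if (is.null(subjects)) subjects <- x$meta$subject_id
    features <- x$wavenumbers
    xm <- x$intensities
  } else {
    xm <- as.matrix(x)
    features <- if (!is.null(colnames(xm))) suppressWarnings(as.numeric(colnames(xm))) else
      seq_len(ncol(xm))
    if (any(is.na(features))) features <- seq_len(ncol(xm))
  }
  if (!is.null(region)) {
    keep <- which(features >= region[1] & features <= region[2])
    xm <- xm[, keep, drop = FALSE]
    features <- features[keep]
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(xm)) stop("labels must match rows of x")
  if (level == "subject") {
    if (is.null(subjects)) stop("subject-level fit requires subject ids")
    sl <- tapply(labels, subjects, function(v) v[1])
    xm <- rowsum(xm, subjects, reorder = TRUE) /
      as.vector(table(subjects)[sort(unique(subjects))])
    labels <- as.character(sl[rownames(xm)])
  }
  f <- factor(labels, levels = group_levels(labels))
  if (nlevels(f) < 2) stop("need at least 2 classes")
  if (any(table(f) < 2)) stop("every class needs at least 2 members")
  n <- nrow(xm); p <- ncol(xm)
  mu <- colMeans(xm)
  cls <- levels(f)
  means <- t(vapply(cls, function(c) colMeans(xm[f == c, , drop = FALSE]),
                    numeric(p)))
  xc <- xm - means[as.integer(f), , drop = FALSE]
  lw <- lw_shrinkage(xc)
  lambda <- if (identical(shrinkage, "auto")) lw$lambda else shrinkage
  w <- (1 - lambda) * lw$s + diag(lambda * lw$m, p)
  if (lambda == 0 && rcond(w) < .Machine$double.eps)
    stop("singular within-class scatter; use shrinkage")
  nc <- as.vector(table(f))
  h <- t(sqrt(nc / n) * (means - rep(mu, each = length(cls))))   # p x C
  a <- solve(w, h)
  m <- crossprod(h, a)                                           # C x C
  eg <- eigen((m + t(m)) / 2, symmetric = TRUE)
  k <- min(length(cls) - 1, sum(eg$values > max(eg$values) * 1e-10))
  vals <- pmax(eg$values[seq_len(k)], 0)
  v <- a %*% eg$vectors[, seq_len(k), drop = FALSE]
  v <- apply(v, 2, function(col) {
    col <- col / sqrt(sum(col^2))
    if (col[which.max(abs(col))] < 0) -col else col
  })
  v <- matrix(v, nrow = p)
  colnames(v) <- paste0("LD", seq_len(k))
  scores <- sweep(xm, 2, mu) %*% v
  cmeans <- sweep(means, 2, mu) %*% v
  rownames(cmeans) <- cls
  structure(list(classes = cls, scaling = v,
                 explained_variance_ratio = vals / sum(vals),
                 center = mu, class_means_ld = cmeans,
                 x = scores, labels = f, features = features,
                 level = level, shrinkage = lambda),
            class = "scrs_lda")
}

#' @export
print.scrs_lda <- function(x, ...) {
  cat(sprintf("Shrinkage LDA (%s level): %d classes (%s), %d features, shrinkage %.3f\n",
              x$level, length(x$classes), paste(x$classes, collapse = ", "),
              nrow(x$scaling), x$shrinkage))
  cat("explained variance ratio:",
      paste(sprintf("%s %.1f%%", colnames(x$scaling),
                    100 * x$explained_variance_ratio), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.scrs_lda <- function(object, newdata, ...) {
  if (inherits(newdata, "scrs_set")) newdata <- newdata$intensities
  newdata <- as.matrix(newdata)
  sc <- sweep(newdata, 2, object$center) %*% object$scaling
  d <- vapply(object$classes, function(c)
    rowSums(sweep(sc, 2, object$class_means_ld[c, ])^2), numeric(nrow(sc)))
  d <- matrix(d, nrow = nrow(sc))
  cls <- object$classes[max.col(-d, ties.method = "first")]
  list(class = factor(cls, levels = object$classes), x = sc)
}

#' @export
plot.scrs_lda <- function(x, axes = c(1, 2), ...) {
  k <- ncol(x$x)
  if (k == 1) axes <- c(1, 1)
  cols <- seq_along(x$classes)[as.integer(x$labels)]
  graphics::plot(x$x[, axes[1]], x$x[, axes[2]], col = cols, pch = 16,
                 xlab = sprintf("LD%d (%.0f%%)", axes[1],
                                100 * x$explained_variance_ratio[axes[1]]),
                 ylab = if (k == 1) "LD1" else
                   sprintf("LD%d (%.0f%%)", axes[2],
                           100 * x$explained_variance_ratio[axes[2]]), ...)
  graphics::legend("topright", legend = x$classes, col = seq_along(x$classes),
                   pch = 16, bty = "n")
  invisible(x)
}

#' Top discriminant features along an LD axis
#'
#' Ranks channels by the magnitude of their discriminant coefficient on the
#' chosen axis. Ties are broken toward the lower wavenumber; tied channels are
#' all reported.
#'
#' @param model A channel-space [fit_lda()] model.
#' @param axis LD axis index (1 = LD1).
#' @param n Number of features to return; 0 gives an empty table.
#' @return Data frame: `wavenumber`, `coefficient`, `sign`, ranked.
#' @export
top_features <- function(model, axis = 1, n = 20) {
  stopifnot(inherits(model, "scrs_lda"))
  if (axis > ncol(model$scaling)) stop("axis beyond model rank")
  co <- model$scaling[, axis]
  ord <- order(-abs(co), model$features)
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(wavenumber = model$features[ord], coefficient = co[ord],
             sign = sign(co[ord]), row.names = NULL)
}

#' Screen covariates for confounding with LD coordinates
#'
#' Pearson correlation of each covariate against each LD axis. Logical
#' covariates are coded 0/1 and categorical covariates are one-hot expanded.
#' Covariates with |r| above the threshold are flagged; zero-variance
#' covariates yield `NA` and are never flagged.
#'
#' @param coords Matrix of LD coordinates (e.g. `fit$x`), one row per unit.
#' @param covariates Data frame of covariates, rows aligned with `coords`.
#' @param threshold Flagging threshold on |r|, default 0.75.
#' @return List of class `confounder_report`: `table` (covariate, axis, r,
#'   flagged), `threshold`, `flagged` covariate names.
#' @export
confounder_scan <- function(coords, covariates, threshold = 0.75) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need n >= 3")
  if (is.null(colnames(coords))) colnames(coords) <- paste0("LD", seq_len(ncol(coords)))
  cols <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.logical(v)) cols[[nm]] <- as.numeric(v)
    else if (is.numeric(v)) cols[[nm]] <- v
    else {
      f <- factor(v)
      for (lv in levels(f)) cols[[paste0(nm, ":", lv)]] <- as.numeric(f == lv)
    }
  }
  rows <- list()
  for (nm in names(cols)) {
    for (ax in colnames(coords)) {
      r <- if (stats::sd(cols[[nm]]) == 0 || stats::sd(coords[, ax]) == 0)
        NA_real_ else stats::cor(cols[[nm]], coords[, ax])
      rows[[length(rows) + 1]] <- data.frame(
        covariate = nm, axis = ax, r = r,
        flagged = !is.na(r) && abs(r) > threshold, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, threshold = threshold,
                 flagged = unique(tab$covariate[tab$flagged])),
            class = "confounder_report")
}

#' @export
print.confounder_report <- function(x, ...) {
  top <- x$table[order(-abs(x$table$r)), ]
  cat(sprintf("Confounder scan (threshold |r| > %.2f): %d flagged\n",
              x$threshold, length(x$flagged)))
  print(utils::head(top, 5), row.names = FALSE)
  invisible(x)
}
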