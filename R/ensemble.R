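#' Hyperparameter control for the ensemble classifier
#'
#' Small fixed hyperparameter settings for the eight base learners and the
#' stacking meta-learner. Only the multilayer perceptron's hidden-layer size
#' is a genuine grid (chosen by repeated-CV accuracy); the other learners use
#' one fixed, documented setting each.
#'
#' @param xgb_nrounds,xgb_depth,xgb_eta Extreme gradient boosting settings.
#' @param rf_ntree Random forest tree count.
#' @param svm_cost SVM cost parameter (both kernels).
#' @param mlp_sizes Candidate hidden-layer sizes for the perceptron.
#' @param mlp_decay,mlp_maxit Perceptron weight decay and iteration cap.
#' @param mda_subclasses Mixture components per class for MDA.
#' @param gbm_trees,gbm_depth,gbm_shrinkage Base GBM settings.
#' @param meta_trees,meta_depth Stacking GBM settings.
#' @return List of class `ensemble_control`.
#' @export
ensemble_control <- function(xgb_nrounds = 60, xgb_depth = 3, xgb_eta = 0.3,
                             rf_ntree = 200, svm_cost = 1,
                             mlp_sizes = c(8, 32, 64), mlp_decay = 0.01,
                             mlp_maxit = 150, mda_subclasses = 3,
                             gbm_trees = 100, gbm_depth = 3,
                             gbm_shrinkage = 0.1,
                             meta_trees = 100, meta_depth = 3) {
  structure(as.list(environment()), class = "ensemble_control")
}

#' Stratified train/test split
#'
#' Splits units into train and test partitions stratified by the class label.
#' With `grouping = "subject"` (the default) the unit is the subject, so all
#' cells of one subject land in the same partition — preventing within-subject
#' leakage; `grouping = "cell"` splits cells independently. Every class is
#' represented in both partitions.
#'
#' @param labels Class label per row.
#' @param subjects Subject id per row (required for subject grouping).
#' @param ratio Train fraction, default 0.8.
#' @param grouping `"subject"` or `"cell"`.
#' @param seed Integer seed; identical seeds give identical plans.
#' @return Object of class `split_plan` with integer row indices `train` and
#'   `test`.
#' @export
split_train_test <- function(labels, subjects = NULL, ratio = 0.8,
                             grouping = c("subject", "cell"), seed = 1) {
  grouping <- match.arg(grouping)
  labels <- as.character(labels)
  n <- length(labels)
  set.seed(spawn_seed(seed, 41))
  test <- integer(0)
  if (grouping == "cell") {
    for (g in unique(labels)) {
      idx <- which(labels == g)
      if (length(idx) < 2) stop("class ", g, " has a single unit")
      n_test <- min(max(1L, round((1 - ratio) * length(idx))), length(idx) - 1L)
      test <- c(test, sample(idx, n_test))
    }
  } else {
    if (is.null(subjects)) stop("subject grouping requires subject ids")
    subjects <- as.character(subjects)
    slab <- tapply(labels, subjects, function(v) {
      if (length(unique(v)) != 1) stop("subject spans multiple classes")
      v[1]
    })
    for (g in unique(slab)) {
      su <- names(slab)[slab == g]
      if (length(su) < 2) stop("class ", g, " has a single unit")
      n_test <- min(max(1L, round((1 - ratio) * length(su))), length(su) - 1L)
      test_subj <- sample(su, n_test)
      test <- c(test, which(subjects %in% test_subj))
    }
  }
  test <- sort(test)
  structure(list(train = setdiff(seq_len(n), test), test = test,
                 ratio = ratio, grouping = grouping, seed = seed),
            class = "split_plan")
}

#' Fit the center/scale + PCA feature transform
#'
#' Centering, unit-variance scaling (zero-variance channels get scale 1 and
#' are recorded), and principal component reduction to at most
#' `n_components` scores — all fitted on training data only. Components with
#' negligible variance are dropped, so rank-deficient data yield exactly
#' their rank.
#'
#' @param x_train Training matrix (rows = cells).
#' @param n_components Maximum retained components, default 100.
#' @return Object of class `feature_transform`.
#' @export
fit_transform <- function(x_train, n_components = 100) {
  x_train <- as.matrix(x_train)
  if (nrow(x_train) < 2) stop("need at least 2 training rows")
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, stats::sd)
  zero_var <- which(scl == 0)
  scl[zero_var] <- 1
  xs <- sweep(sweep(x_train, 2, ctr), 2, scl, `/`)
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  k <- min(n_components, nrow(x_train) - 1, ncol(x_train))
  nondeg <- sum(pc$sdev > pc$sdev[1] * 1e-8)
  k <- min(k, nondeg)
  structure(list(center = ctr, scale = scl, rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev[seq_len(k)], n_components = k,
                 zero_variance = zero_var),
            class = "feature_transform")
}

#' Apply a fitted feature transform
#'
#' @param transform A [fit_transform()] object.
#' @param x Matrix on the same channels as the training data.
#' @return Score matrix (rows x components).
#' @export
apply_transform <- function(transform, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, transform$center), 2, transform$scale, `/`)
  xs %*% transform$rotation
}

# reorder/pad a probability matrix to the full class set
align_prob <- function(pr, classes) {
  out <- matrix(0, nrow(pr), length(classes), dimnames = list(NULL, classes))
  common <- intersect(colnames(pr), classes)
  out[, common] <- pr[, common, drop = FALSE]
  sw <- rowSums(out)
  sw[sw == 0] <- 1
  out / sw
}

# the eight base learner specifications: fit(x, y, params, seed) and
# prob(fit, x); `grid` is a list of candidate parameter lists
base_learner_specs <- function(control) {
  list(
    lda = list(grid = list(list()),
      fit = function(x, y, params, seed) MASS::lda(x, grouping = y),
      prob = function(fit, x) stats::predict(fit, x)$posterior),
    xgb = list(grid = list(list()),
      fit = function(x, y, params, seed) {
        xgboost::xgboost(x, y, nrounds = control$xgb_nrounds,
                         max_depth = control$xgb_depth,
                         learning_rate = control$xgb_eta,
                         nthreads = 1, verbosity = 0, seed = seed %% 100000)
      },
      prob = function(fit, x) {
        pr <- stats::predict(fit, x, type = "response")
        if (is.null(dim(pr))) {   # binary: probability of the second level
          cls <- attr(fit, "scrsdx_classes")
          pr <- cbind(1 - pr, pr)
          colnames(pr) <- cls
        }
        pr
      }),
    svm_linear = list(grid = list(list()),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        e1071::svm(x, y, kernel = "linear", cost = control$svm_cost,
                   probability = TRUE)
      },
      prob = function(fit, x) {
        attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      }),
    svm_radial = list(grid = list(list()),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        e1071::svm(x, y, kernel = "radial", cost = control$svm_cost,
                   probability = TRUE)
      },
      prob = function(fit, x) {
        attr(stats::predict(fit, x, probability = TRUE), "probabilities")
      }),
    mlp = list(grid = lapply(control$mlp_sizes, function(s) list(size = s)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        fit <- nnet::nnet(x, stats::model.matrix(~ y - 1), size = params$size,
                          softmax = TRUE, decay = control$mlp_decay,
                          maxit = control$mlp_maxit, trace = FALSE,
                          MaxNWts = 50000)
        fit
      },
      prob = function(fit, x) {
        pr <- stats::predict(fit, x, type = "raw")
        colnames(pr) <- attr(fit, "scrsdx_classes")
        pr
      }),
    rf = list(grid = list(list()),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        randomForest::randomForest(x, y, ntree = control$rf_ntree)
      },
      prob = function(fit, x) stats::predict(fit, x, type = "prob")),
    mda = list(grid = list(list()),
      fit = function(x, y, params, seed)
        mda_fit(x, y, subclasses = control$mda_subclasses, seed = seed),
      prob = function(fit, x) stats::predict(fit, x)),
    gbm = list(grid = list(list()),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        gbm_fit(x, y, n_trees = control$gbm_trees, depth = control$gbm_depth,
                shrinkage = control$gbm_shrinkage)
      },
      prob = function(fit, x) stats::predict(fit, x))
  )
}

# stratified fold assignment
make_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (g in levels(y)) {
    idx <- which(y == g)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Fit the eight base learners with repeated cross-validation
#'
#' Runs stratified k-fold cross-validation (10-fold, 5 repeats by default)
#' over the eight base learners — LDA, extreme gradient boosting, linear- and
#' radial-kernel SVM, multilayer perceptron, random forest, mixture
#' discriminant analysis and a gradient boosting machine — recording each
#' learner's out-of-fold class probabilities (averaged over repeats) and its
#' per-resample accuracy trace. Learners with a hyperparameter grid are tuned
#' by mean CV accuracy. Each learner is then refit on the full training data
#' for later prediction.
#'
#' @param x Training score matrix (e.g. PCA scores).
#' @param y Factor of class labels.
#' @param folds CV folds, default 10 (reduced with a warning when a class is
#'   smaller than the fold count).
#' @param repeats CV repetitions, default 5.
#' @param seed Integer seed.
#' @param control An [ensemble_control()].
#' @return Object of class `base_learner_set`: fitted learners, `oof` matrix
#'   (train rows x 8 x classes probability features), accuracy traces.
#' @export
fit_base_learners <- function(x, y, folds = 10, repeats = 5, seed = 1,
                              control = ensemble_control()) {
  x <- as.matrix(x)
  y <- droplevels(factor(y, levels = group_levels(y)))
  k <- nlevels(y)
  if (k < 2) stop("need at least 2 classes")
  min_class <- min(table(y))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning("class smaller than fold count; folds reduced to ", folds)
  }
  specs <- base_learner_specs(control)
  n <- nrow(x)
  n_resamp <- folds * repeats
  oof_sum <- lapply(specs, function(s)
    lapply(s$grid, function(g) matrix(0, n, k, dimnames = list(NULL, levels(y)))))
  oof_cnt <- lapply(specs, function(s) lapply(s$grid, function(g) numeric(n)))
  trace <- lapply(specs, function(s)
    lapply(s$grid, function(g) numeric(0)))
  for (r in seq_len(repeats)) {
    fold <- make_folds(y, folds, spawn_seed(seed, 100 + r))
    for (fi in seq_len(folds)) {
      tr_idx <- which(fold != fi)
      te_idx <- which(fold == fi)
      if (length(unique(y[tr_idx])) < k || length(te_idx) == 0) next
      for (ln in names(specs)) {
        sp <- specs[[ln]]
        for (gi in seq_along(sp$grid)) {
          fit <- sp$fit(x[tr_idx, , drop = FALSE], droplevels(y[tr_idx]),
                        sp$grid[[gi]], spawn_seed(seed, 1000 * r + 10 * fi + gi))
          attr(fit, "scrsdx_classes") <- levels(droplevels(y[tr_idx]))
          pr <- align_prob(sp$prob(fit, x[te_idx, , drop = FALSE]), levels(y))
          oof_sum[[ln]][[gi]][te_idx, ] <- oof_sum[[ln]][[gi]][te_idx, ] + pr
          oof_cnt[[ln]][[gi]][te_idx] <- oof_cnt[[ln]][[gi]][te_idx] + 1
          acc <- mean(levels(y)[max.col(pr, ties.method = "first")] ==
                        as.character(y[te_idx]))
          trace[[ln]][[gi]] <- c(trace[[ln]][[gi]], acc)
        }
      }
    }
  }
  learners <- list()
  oof_cols <- list()
  traces <- matrix(NA_real_, n_resamp, length(specs),
                   dimnames = list(NULL, names(specs)))
  for (ln in names(specs)) {
    sp <- specs[[ln]]
    best <- which.max(vapply(trace[[ln]], mean, 0))
    cnt <- pmax(oof_cnt[[ln]][[best]], 1)
    oof <- oof_sum[[ln]][[best]] / cnt
    colnames(oof) <- paste(ln, levels(y), sep = ".")
    oof_cols[[ln]] <- oof
    tvec <- trace[[ln]][[best]]
    traces[seq_along(tvec), ln] <- tvec
    fit <- sp$fit(x, y, sp$grid[[best]], spawn_seed(seed, 77))
    attr(fit, "scrsdx_classes") <- levels(y)
    learners[[ln]] <- list(fit = fit, params = sp$grid[[best]],
                           prob = sp$prob)
  }
  structure(list(learners = learners, oof = do.call(cbind, oof_cols),
                 traces = traces, classes = levels(y), y = y,
                 folds = folds, repeats = repeats),
            class = "base_learner_set")
}

#' @export
print.base_learner_set <- function(x, ...) {
  acc <- colMeans(x$traces, na.rm = TRUE)
  cat(sprintf("base_learner_set: %d learners, %d-fold x %d CV\n",
              length(x$learners), x$folds, x$repeats))
  print(round(acc, 3))
  invisible(x)
}

#' Fit the stacking meta-learner
#'
#' A gradient boosting machine over the out-of-fold class-probability
#' features of the eight base learners (8 x C columns).
#'
#' @param oof Out-of-fold probability matrix from [fit_base_learners()].
#' @param y Factor of training labels.
#' @param control An [ensemble_control()].
#' @return An `scrs_gbm` meta-learner.
#' @export
fit_meta <- function(oof, y, control = ensemble_control()) {
  if (any(!is.finite(oof))) stop("OOF matrix must be complete")
  gbm_fit(oof, y, n_trees = control$meta_trees, depth = control$meta_depth)
}

# base probability features for arbitrary data
base_features <- function(learners, classes, x) {
  do.call(cbind, lapply(names(learners), function(ln) {
    pr <- align_prob(learners[[ln]]$prob(learners[[ln]]$fit, x), classes)
    colnames(pr) <- paste(ln, classes, sep = ".")
    pr
  }))
}

#' Fit the two-layer stacked ensemble diagnostic model
#'
#' The full training protocol: stratified train/test split (subject-grouped
#' by default so no subject straddles partitions), center/scale + PCA feature
#' transform fitted on the train partition, eight base learners with repeated
#' stratified cross-validation, and a gradient boosting meta-learner stacked
#' on their out-of-fold class probabilities. A subject-level aggregator is
#' trained on the train subjects' predicted cell-label fractions (GBM when at
#' least 20 train subjects are available, otherwise mean cell probability).
#' The held-out test cells are evaluated automatically.
#'
#' @param x An [scrs_set] or numeric matrix (rows = cells).
#' @param labels Five-group (or already collapsed) label per row.
#' @param subjects Subject id per row; taken from `x$meta` for an `scrs_set`.
#' @param classes 5 (default) or 3; 3 collapses the ME subgroups before
#'   training.
#' @param ratio Train fraction, default 0.8.
#' @param grouping `"subject"` (default) or `"cell"` split unit.
#' @param folds,repeats Cross-validation plan, default 10 x 5.
#' @param n_components Maximum PCA components, default 100.
#' @param seed Integer seed driving every stochastic step.
#' @param control An [ensemble_control()].
#' @return Object of class `scrs_ensemble` with the split plan, transform,
#'   base learner set, meta-learner, subject aggregator and held-out test
#'   evaluation (`$test_eval`).
#' @export
fit_ensemble <- function(x, labels, subjects = NULL, classes = 5, ratio = 0.8,
                         grouping = c("subject", "cell"), folds = 10,
                         repeats = 5, n_components = 100, seed = 1,
                         control = ensemble_control()) {
  grouping <- match.arg(grouping)
  if (inherits(x, "scrs_set")) {
    if (is.null(subjects)) subjects <- x$meta$subject_id
    xm <- x$intensities
  } else xm <- as.matrix(x)
  labels <- as.character(labels)
  if (classes == 3) labels <- collapse_groups(labels)
  y_all <- factor(labels, levels = group_levels(labels))
  plan <- split_train_test(labels, subjects, ratio, grouping, seed)
  tr <- plan$train; te <- plan$test
  transform <- fit_transform(xm[tr, , drop = FALSE], n_components)
  str <- apply_transform(transform, xm[tr, , drop = FALSE])
  bls <- fit_base_learners(str, y_all[tr], folds, repeats, seed, control)
  meta <- fit_meta(bls$oof, bls$y, control)

  # subject aggregator trained on stacked train-cell predictions
  subj_model <- NULL
  aggregator <- "mean_prob"
  if (!is.null(subjects)) {
    meta_tr_prob <- stats::predict(meta, bls$oof)
    tr_lab <- bls$classes[max.col(meta_tr_prob, ties.method = "first")]
    su <- as.character(subjects[tr])
    frac <- vapply(bls$classes, function(cl)
      tapply(tr_lab == cl, su, mean), numeric(length(unique(su))))
    frac <- matrix(frac, ncol = length(bls$classes),
                   dimnames = list(sort(unique(su)), bls$classes))
    su_lab <- factor(tapply(as.character(y_all[tr]), su, `[`, 1)[rownames(frac)],
                     levels = bls$classes)
    if (nrow(frac) >= 20) {
      subj_model <- gbm_fit(frac, su_lab, n_trees = control$meta_trees,
                            depth = 2)
      aggregator <- "meta_gbm"
    }
  }

  obj <- structure(list(plan = plan, transform = transform, base = bls,
                        meta = meta, classes = bls$classes,
                        n_classes = length(bls$classes),
                        subject_model = subj_model, aggregator = aggregator,
                        subjects = subjects, labels = y_all, seed = seed),
                   class = "scrs_ensemble")
  te_prob <- predict(obj, xm[te, , drop = FALSE], type = "prob")
  te_lab <- factor(obj$classes[max.col(te_prob, ties.method = "first")],
                   levels = obj$classes)
  obj$test_prob <- te_prob
  obj$test_eval <- evaluate(te_lab, factor(as.character(y_all[te]),
                                           levels = obj$classes))
  obj
}

#' Predict cell-level class probabilities or labels
#'
#' Applies the fitted transform, the eight refit base learners and the
#' stacking meta-learner. With `classes = 3` on a five-class model the ME
#' subgroup probabilities are summed into a single ME class before the
#' argmax, so three-class output is an exact marginalization of the
#' five-class probabilities. Ties are broken by the fixed class order
#' (HC < MildME < ModME < SevME < MS).
#'
#' @param object An `scrs_ensemble`.
#' @param newdata [scrs_set] or matrix on the training channels.
#' @param type `"prob"` or `"class"`.
#' @param classes Output granularity: `NULL` (native) or 3.
#' @param ... Unused.
#' @return Probability matrix or factor of labels.
#' @export
predict.scrs_ensemble <- function(object, newdata, type = c("prob", "class"),
                                  classes = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "scrs_set")) newdata <- newdata$intensities
  sc <- apply_transform(object$transform, as.matrix(newdata))
  feats <- base_features(object$base$learners, object$classes, sc)
  pr <- stats::predict(object$meta, feats)
  if (!is.null(classes) && classes == 3 && object$n_classes == 5) {
    me <- c("MildME", "ModME", "SevME")
    pr <- cbind(HC = pr[, "HC"], ME = rowSums(pr[, me, drop = FALSE]),
                MS = pr[, "MS"])
  }
  if (type == "prob") return(pr)
  factor(colnames(pr)[max.col(pr, ties.method = "first")],
         levels = colnames(pr))
}

#' @rdname predict.scrs_ensemble
#' @param model An `scrs_ensemble`.
#' @param scrs Data to classify.
#' @export
predict_cells <- function(model, scrs, classes = NULL) {
  pr <- stats::predict(model, scrs, type = "prob", classes = classes)
  list(prob = pr,
       label = factor(colnames(pr)[max.col(pr, ties.method = "first")],
                      levels = colnames(pr)))
}

#' Aggregate cell predictions into subject diagnoses
#'
#' @param prob Cell-level probability matrix.
#' @param subjects Subject id per cell.
#' @param aggregator `"meta_gbm"` (per-subject class-fraction features through
#'   the trained subject GBM; requires `model`), `"majority"` (modal cell
#'   label) or `"mean_prob"` (argmax of averaged probabilities). Ties go to
#'   the first class in the fixed order and are flagged.
#' @param model Optional `scrs_ensemble` supplying the subject GBM.
#' @return Data frame: `subject_id`, `diagnosis`, `confidence`, `tie`.
#' @export
diagnose_subjects <- function(prob, subjects,
                              aggregator = c("mean_prob", "majority", "meta_gbm"),
                              model = NULL) {
  aggregator <- match.arg(aggregator)
  subjects <- as.character(subjects)
  classes <- colnames(prob)
  us <- unique(subjects)
  if (aggregator == "meta_gbm") {
    if (is.null(model) || is.null(model$subject_model))
      stop("meta_gbm aggregation requires a model with a trained subject GBM")
    lab <- classes[max.col(prob, ties.method = "first")]
    frac <- vapply(classes, function(cl)
      tapply(lab == cl, factor(subjects, levels = us), mean), numeric(length(us)))
    frac <- matrix(frac, ncol = length(classes), dimnames = list(us, classes))
    pr <- stats::predict(model$subject_model, frac)
    pr <- align_prob(pr, classes)
  } else if (aggregator == "mean_prob") {
    pr <- rowsum(prob, factor(subjects, levels = us), reorder = FALSE)
    pr <- pr / as.vector(table(factor(subjects, levels = us)))
  } else {
    lab <- classes[max.col(prob, ties.method = "first")]
    pr <- vapply(classes, function(cl)
      tapply(lab == cl, factor(subjects, levels = us), mean), numeric(length(us)))
    pr <- matrix(pr, ncol = length(classes), dimnames = list(us, classes))
  }
  best <- max.col(pr, ties.method = "first")
  tie <- apply(pr, 1, function(v) sum(v == max(v)) > 1)
  data.frame(subject_id = us,
             diagnosis = factor(classes[best], levels = classes),
             confidence = pr[cbind(seq_along(us), best)],
             tie = tie, row.names = NULL, stringsAsFactors = FALSE)
}

#' Evaluate predictions against the truth
#'
#' Row-normalized percent confusion matrix; per-class sensitivity
#' (TP/(TP+FN)) and one-vs-rest specificity (TN/(TN+FP)); overall accuracy
#' with its exact 95% Clopper--Pearson binomial confidence interval. A class
#' absent from the truth has undefined sensitivity, and when the truth
#' contains a single class that class's specificity is undefined; both are
#' reported as `NA`.
#'
#' @param predictions,truth Factors (or vectors) on the same class set.
#' @param classes Optional explicit class order.
#' @return Object of class `confusion_summary`.
#' @export
evaluate <- function(predictions, truth, classes = NULL) {
  if (is.null(classes)) classes <- group_levels(c(as.character(truth),
                                                  as.character(predictions)))
  if (!all(as.character(predictions) %in% classes) ||
      !all(as.character(truth) %in% classes))
    stop("label outside class set")
  predictions <- factor(as.character(predictions), levels = classes)
  truth <- factor(as.character(truth), levels = classes)
  if (length(predictions) != length(truth)) stop("length mismatch")
  cm <- table(truth = truth, predicted = predictions)
  n_by_class <- rowSums(cm)
  pct <- cm / ifelse(n_by_class == 0, 1, n_by_class) * 100
  sens <- ifelse(n_by_class == 0, NA_real_, diag(cm) / n_by_class)
  spec <- vapply(seq_along(classes), function(ci) {
    tn <- sum(cm[-ci, -ci]); fp <- sum(cm[-ci, ci])
    if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  }, numeric(1))
  names(sens) <- names(spec) <- classes
  n <- length(truth)
  x <- sum(as.character(predictions) == as.character(truth))
  ci <- c(if (x == 0) 0 else stats::qbeta(0.025, x, n - x + 1),
          if (x == n) 1 else stats::qbeta(0.975, x + 1, n - x))
  structure(list(confusion_pct = as.matrix(pct), counts = as.matrix(cm),
                 sensitivity = sens, specificity = spec,
                 accuracy = x / n, ci95 = ci, n_test = n),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("accuracy %.1f%% (95%% CI %.1f-%.1f%%, n = %d)\n",
              100 * x$accuracy, 100 * x$ci95[1], 100 * x$ci95[2], x$n_test))
  cat("confusion (% by true class):\n")
  print(round(x$confusion_pct, 1))
  cat("sensitivity:", paste(sprintf("%s %.2f", names(x$sensitivity),
                                    x$sensitivity), collapse = ", "), "\n")
  cat("specificity:", paste(sprintf("%s %.2f", names(x$specificity),
                                    x$specificity), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.scrs_ensemble <- function(x, ...) {
  cat(sprintf("scrs_ensemble: %d classes (%s), %s split, %d train / %d test cells\n",
              x$n_classes, paste(x$classes, collapse = ", "),
              x$plan$grouping, length(x$plan$train), length(x$plan$test)))
  cat(sprintf("subject aggregator: %s\n", x$aggregator))
  print(x$test_eval)
  invisible(x)
}

#' @export
summary.scrs_ensemble <- function(object, ...) {
  cat("Base learner CV accuracies (mean over resamples):\n")
  print(round(colMeans(object$base$traces, na.rm = TRUE), 3))
  cat("\nHeld-out test performance:\n")
  print(object$test_eval)
  invisible(object)
}

#' Correlation between base learners' resampled accuracies
#'
#' Pearson correlation of the learners' per-resample accuracy traces; low
#' off-diagonal correlations indicate complementary learners that a stacker
#' can exploit. Constant traces give `NA` entries; the diagonal is 1.
#'
#' @param bls A [fit_base_learners()] result (or an `scrs_ensemble`).
#' @return 8 x 8 correlation matrix.
#' @export
model_correlation <- function(bls) {
  if (inherits(bls, "scrs_ensemble")) bls <- bls$base
  tr <- bls$traces[stats::complete.cases(bls$traces), , drop = FALSE]
  if (nrow(tr) < 3) stop("need at least 3 resamples")
  cc <- suppressWarnings(stats::cor(tr))
  diag(cc) <- 1
  cc
}
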