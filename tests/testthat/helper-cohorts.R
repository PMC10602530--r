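# Shared fixture builders. Everything is generated in code; no stored data.

# small Raman cohort on the full canonical axis
tiny_cohort <- function(seed = 1, sizes = c(HC = 4, MildME = 4, ModME = 4,
                                            SevME = 4, MS = 4),
                        cells = 4, acq = c(2, 2), channels = 1019, ...) {
  generate_cohort(cohort_config(group_sizes = sizes, cells_per_subject = cells,
                                acquisitions_per_cell = acq,
                                axis = c(319, 3401, channels), seed = seed, ...))
}

subject_label_map <- function(cohort) {
  stats::setNames(cohort$subjects$group, cohort$subjects$subject_id)
}

# a Lorentzian peak on an axis (unit height)
lorentz <- function(wn, center, fwhm = 10) {
  g <- fwhm / 2
  g^2 / ((wn - center)^2 + g^2)
}

# fast control settings for ensemble tests; model hyperparameters only
fast_control <- function(...) {
  defaults <- list(gbm_trees = 50, meta_trees = 60, meta_depth = 2,
                   xgb_nrounds = 40, rf_ntree = 150, mlp_sizes = c(8, 16),
                   mlp_maxit = 120)
  do.call(ensemble_control, utils::modifyList(defaults, list(...)))
}

# Five-class task with three complementary structure families, so that no
# single learner family can capture everything and stacking has real gains:
# a dense rotated linear signal separating superclasses {HC, MildME},
# {ModME, SevME}, {MS}; an axis-aligned XOR mixture splitting HC from MildME;
# and an annulus-vs-disc split of ModME vs SevME (which a shared-covariance
# Gaussian model cannot represent).
make_nonlinear_task <- function(n_per = 50, seed = 1) {
  set.seed(seed)
  classes <- c("HC", "MildME", "ModME", "SevME", "MS")
  n <- n_per * 5
  y <- factor(rep(classes, each = n_per), levels = classes)
  ci <- as.integer(y)
  x <- matrix(stats::rnorm(n * 12), n, 12)
  sup <- c(1, 1, 2, 2, 3)[ci]
  v1 <- stats::rnorm(6); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- stats::rnorm(6); v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  mu <- rbind(c(-1.8, 0), c(1.8, 0), c(0, 2.4))
  x[, 1:6] <- x[, 1:6] + outer(mu[sup, 1], v1) + outer(mu[sup, 2], v2)
  flip <- sample(c(-1, 1), n, TRUE)
  s12 <- ifelse(ci == 1, 1, ifelse(ci == 2, -1, 0))
  x[, 7] <- flip * 1.7 + stats::rnorm(n, sd = 0.6)
  x[, 8] <- ifelse(s12 != 0, flip * s12 * 1.7, stats::rnorm(n)) +
    stats::rnorm(n, sd = 0.6)
  th <- stats::runif(n, 0, 2 * pi)
  r <- ifelse(ci == 3, 2.6, ifelse(ci == 4, 0.6, 1.5)) + stats::rnorm(n, sd = 0.35)
  x[, 9] <- r * cos(th)
  x[, 10] <- r * sin(th)
  list(x = x, y = y)
}

# held-out accuracies of the stacked ensemble and each base learner
stack_vs_bases <- function(task, seed, folds = 5, repeats = 2,
                           control = fast_control()) {
  pl <- split_train_test(as.character(task$y), ratio = 0.8, grouping = "cell",
                         seed = seed)
  tr <- pl$train; te <- pl$test
  bls <- fit_base_learners(task$x[tr, ], task$y[tr], folds = folds,
                           repeats = repeats, seed = seed, control = control)
  meta <- fit_meta(bls$oof, bls$y, control)
  fe <- scrsdx:::base_features(bls$learners, bls$classes, task$x[te, ])
  ep <- predict(meta, fe)
  truth <- as.character(task$y[te])
  ens <- mean(bls$classes[max.col(ep, ties.method = "first")] == truth)
  base <- vapply(names(bls$learners), function(ln) {
    pr <- scrsdx:::align_prob(
      bls$learners[[ln]]$prob(bls$learners[[ln]]$fit, task$x[te, ]),
      bls$classes)
    mean(bls$classes[max.col(pr, ties.method = "first")] == truth)
  }, numeric(1))
  list(ensemble = ens, base = base)
}
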