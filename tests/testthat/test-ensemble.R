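test_that("stratified cell splits have the expected arithmetic", {
  lab <- rep(c("HC", "MildME", "ModME", "SevME", "MS"), each = 20)
  pl <- split_train_test(lab, ratio = 0.8, grouping = "cell", seed = 2)
  expect_length(pl$train, 80)
  expect_length(pl$test, 20)
  expect_true(all(table(lab[pl$test]) == 4))
  expect_identical(pl, split_train_test(lab, ratio = 0.8, grouping = "cell",
                                        seed = 2))
  expect_error(split_train_test(c("A", rep("B", 9)), grouping = "cell"),
               "single unit")
})

test_that("subject-grouped splits never divide a subject", {
  lab <- rep(rep(c("HC", "MS"), each = 5), times = 12)    # 12 cells/subject
  subj <- rep(paste0("S", 1:10), times = 12)
  for (s in 1:25) {
    pl <- split_train_test(lab, subj, grouping = "subject", seed = s)
    expect_length(intersect(unique(subj[pl$train]), unique(subj[pl$test])), 0)
    expect_setequal(unique(lab[pl$test]), c("HC", "MS"))
  }
  badlab <- lab; badlab[1] <- "MS"
  expect_error(split_train_test(badlab, subj, grouping = "subject"),
               "spans multiple classes")
})

test_that("the feature transform centers, scales and truncates by rank", {
  set.seed(8)
  x <- matrix(rnorm(40 * 30), 40, 30)
  tr <- fit_transform(x, 100)
  sc <- apply_transform(tr, x)
  expect_lt(max(abs(colMeans(sc))), 1e-9)
  v <- apply(sc, 2, stats::var)
  expect_true(all(diff(v) < 1e-9))          # non-increasing variances
  expect_equal(tr$n_components, min(100, 39, 30))
  # rank-2 data keep exactly 2 components
  r2 <- outer(rnorm(40), rnorm(30)) + outer(rnorm(40), rnorm(30))
  expect_equal(fit_transform(r2, 100)$n_components, 2)
  # zero-variance channel handled with unit scale
  x0 <- cbind(x, 5)
  t0 <- fit_transform(x0, 10)
  expect_equal(t0$scale[31], 1)
  expect_equal(t0$zero_variance, 31)
})

test_that("every base learner masters a linearly separable task", {
  set.seed(9)
  n <- 50
  x <- rbind(matrix(rnorm(n * 4), n, 4),
             sweep(matrix(rnorm(n * 4), n, 4), 2, c(8, 0, 0, 0), `+`))
  y <- factor(rep(c("A", "B"), each = n))
  bls <- fit_base_learners(x, y, folds = 5, repeats = 1, seed = 1,
                           control = fast_control(mlp_sizes = 8))
  acc <- colMeans(bls$traces, na.rm = TRUE)
  expect_true(all(acc > 0.95))
  expect_equal(dim(bls$oof), c(2 * n, 8 * 2))
  expect_equal(unname(rowSums(bls$oof[, 1:2])), rep(1, 2 * n), tolerance = 1e-6)
})

test_that("fold counts shrink with a warning for small classes", {
  set.seed(10)
  x <- matrix(rnorm(24 * 3), 24, 3)
  y <- factor(rep(c("A", "B", "C"), each = 8))
  expect_warning(
    bls <- fit_base_learners(x, y, folds = 10, repeats = 1, seed = 1,
                             control = fast_control(mlp_sizes = 8,
                                                    rf_ntree = 50,
                                                    gbm_trees = 20,
                                                    xgb_nrounds = 15)),
    "folds reduced")
  expect_equal(bls$folds, 8)
})

test_that("base learners sit at chance under permuted labels", {
  set.seed(11)
  x <- matrix(rnorm(90 * 5), 90, 5)
  y <- factor(sample(rep(c("A", "B", "C"), each = 30)))
  bls <- fit_base_learners(x, y, folds = 5, repeats = 1, seed = 3,
                           control = fast_control(mlp_sizes = 8, rf_ntree = 100,
                                                  gbm_trees = 30,
                                                  xgb_nrounds = 20))
  acc <- colMeans(bls$traces, na.rm = TRUE)
  se <- sqrt((1 / 3) * (2 / 3) / 90)
  expect_true(all(abs(acc - 1 / 3) < 3 * se + 0.02))
})

test_that("the stacker reproduces unanimous correct base probabilities", {
  set.seed(12)
  y <- factor(rep(c("A", "B", "C"), each = 30))
  onehot <- matrix(0, 90, 3, dimnames = list(NULL, levels(y)))
  onehot[cbind(1:90, as.integer(y))] <- 1
  oof <- do.call(cbind, rep(list(onehot), 8))
  meta <- fit_meta(oof, y, fast_control(meta_trees = 30))
  pr <- predict(meta, oof)
  expect_identical(colnames(pr)[max.col(pr)], as.character(y))
  expect_error(fit_meta(oof * NA, y), "complete")
})

test_that("complementary learners combine to beat each individual", {
  set.seed(13)
  n <- 240
  y <- factor(rep(c("A", "B", "C", "D"), each = n / 4))
  mk_oof <- function(y) {
    # learner 1 resolves A vs B only; learner 2 resolves C vs D only
    k <- nlevels(y); n <- length(y)
    l1 <- matrix(1 / k, n, k, dimnames = list(NULL, levels(y)))
    l2 <- l1
    ab <- y %in% c("A", "B"); cd <- !ab
    l1[ab, ] <- 0.05; l1[cbind(which(ab), as.integer(y[ab]))] <- 0.85
    l1[cd, c("C", "D")] <- 0.425; l1[cd, c("A", "B")] <- 0.075
    l2[cd, ] <- 0.05; l2[cbind(which(cd), as.integer(y[cd]))] <- 0.85
    l2[ab, c("A", "B")] <- 0.425; l2[ab, c("C", "D")] <- 0.075
    jitter <- function(m) {
      m <- m * matrix(exp(rnorm(length(m), 0, 0.05)), nrow(m))
      m / rowSums(m)
    }
    cbind(jitter(l1), jitter(l2))
  }
  tr_oof <- mk_oof(y)
  meta <- fit_meta(tr_oof, y, fast_control(meta_trees = 60))
  te_y <- factor(rep(c("A", "B", "C", "D"), each = 30))
  te_oof <- mk_oof(te_y)
  acc <- function(pr, truth) mean(colnames(pr)[max.col(pr)] == as.character(truth))
  ens_acc <- acc(predict(meta, te_oof), te_y)
  base1 <- acc(te_oof[, 1:4], te_y)
  base2 <- acc(te_oof[, 5:8], te_y)
  expect_gt(ens_acc, base1)
  expect_gt(ens_acc, base2)
  expect_gt(ens_acc, 0.9)
})

# one small but complete ensemble fit reused by the remaining blocks
coh_ens <- tiny_cohort(seed = 44, sizes = c(HC = 5, MildME = 5, ModME = 5,
                                            SevME = 5, MS = 5),
                       cells = 5, acq = c(2, 2), channels = 500)
scrs_ens <- run_preprocess(coh_ens$spectra,
                           preprocess_config(baseline_segments = 8))
lab_ens <- unname(subject_label_map(coh_ens)[scrs_ens$meta$subject_id])
fit_ens <- fit_ensemble(scrs_ens, lab_ens, classes = 5, folds = 5, repeats = 1,
                        n_components = 25, seed = 7,
                        control = fast_control(mlp_sizes = 8))

test_that("the fitted ensemble keeps subjects out of both partitions", {
  tr_subj <- unique(scrs_ens$meta$subject_id[fit_ens$plan$train])
  te_subj <- unique(scrs_ens$meta$subject_id[fit_ens$plan$test])
  expect_length(intersect(tr_subj, te_subj), 0)
  expect_s3_class(fit_ens$test_eval, "confusion_summary")
})

test_that("cell predictions are simplex probabilities with fixed-order argmax", {
  pr <- predict(fit_ens, scrs_ens, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, nrow(pr)), tolerance = 1e-9)
  expect_identical(colnames(pr), c("HC", "MildME", "ModME", "SevME", "MS"))
  pc <- predict_cells(fit_ens, scrs_ens)
  expect_identical(as.character(pc$label),
                   colnames(pr)[max.col(pr, ties.method = "first")])
})

test_that("three-class output marginalizes the five-class probabilities", {
  p5 <- predict(fit_ens, scrs_ens, type = "prob")
  p3 <- predict(fit_ens, scrs_ens, type = "prob", classes = 3)
  expect_identical(colnames(p3), c("HC", "ME", "MS"))
  expect_equal(p3[, "ME"],
               rowSums(p5[, c("MildME", "ModME", "SevME")]), tolerance = 1e-12)
  c3 <- predict(fit_ens, scrs_ens, type = "class", classes = 3)
  expect_identical(as.character(c3),
                   colnames(p3)[max.col(p3, ties.method = "first")])
})

test_that("subject aggregation honors each aggregator and its tie rule", {
  pr <- matrix(c(0, 0, 1,
                 0, 0, 1), 2, 3, byrow = TRUE,
               dimnames = list(NULL, c("HC", "ME", "MS")))
  for (ag in c("mean_prob", "majority")) {
    d <- diagnose_subjects(pr, c("S1", "S1"), ag)
    expect_equal(as.character(d$diagnosis), "MS")
  }
  maj <- matrix(c(0.1, 0.8, 0.1,
                  0.2, 0.6, 0.2,
                  0.9, 0.05, 0.05), 3, 3, byrow = TRUE,
                dimnames = list(NULL, c("HC", "ME", "MS")))
  d <- diagnose_subjects(maj, rep("S1", 3), "majority")
  expect_equal(as.character(d$diagnosis), "ME")
  tie <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2, byrow = TRUE,
                dimnames = list(NULL, c("HC", "ME")))
  d2 <- diagnose_subjects(tie, c("S1", "S1"), "mean_prob")
  expect_equal(as.character(d2$diagnosis), "HC")   # first class in fixed order
  expect_true(d2$tie)
  expect_error(diagnose_subjects(tie, c("S1", "S1"), "meta_gbm"),
               "requires a model")
})

test_that("evaluation matches exact binomial oracles", {
  perfect <- evaluate(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(unname(diag(perfect$confusion_pct)), c(100, 100))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$sensitivity), c(1, 1))
  expect_equal(unname(perfect$specificity), c(1, 1))
  # 9 of 10 correct: Clopper-Pearson equals the beta-quantile oracle
  pred <- c(rep("A", 5), rep("B", 4), "A")
  truth <- c(rep("A", 5), rep("B", 5))
  ev <- evaluate(pred, truth)
  oracle <- stats::binom.test(9, 10)$conf.int
  expect_equal(ev$accuracy, 0.9)
  expect_equal(ev$ci95, as.numeric(oracle), tolerance = 1e-9)
  expect_equal(ev$ci95, c(0.555, 0.997), tolerance = 1e-3)
  expect_true(all(abs(rowSums(ev$confusion_pct) - 100) < 1e-9))
  # single-class truth: that class's specificity is undefined
  ev2 <- evaluate(c("A", "A", "B"), c("A", "A", "A"), classes = c("A", "B"))
  expect_true(is.na(ev2$specificity["A"]))
  expect_error(evaluate(c("A", "Z"), c("A", "A"), classes = c("A", "B")),
               "outside")
})

test_that("learner correlations behave like Pearson r on accuracy traces", {
  fake <- structure(list(traces = cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4),
                                        c = c(4, 1, 3, 2), d = rep(0.5, 4))),
                    class = "base_learner_set")
  cc <- model_correlation(fake)
  expect_equal(cc["a", "a"], 1)
  expect_equal(cc["a", "b"], 1)
  expect_true(is.na(cc["a", "d"]))
  set.seed(20)
  null <- structure(list(traces = matrix(runif(50 * 8), 50, 8,
                                         dimnames = list(NULL, letters[1:8]))),
                    class = "base_learner_set")
  cn <- model_correlation(null)
  expect_lt(mean(abs(cn[upper.tri(cn)])), 0.3)
  tiny <- structure(list(traces = matrix(1, 2, 2)), class = "base_learner_set")
  expect_error(model_correlation(tiny), "3 resamples")
})
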