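test_that("cohort generation is a deterministic function of config and seed", {
  a <- tiny_cohort(seed = 9, cells = 2, channels = 120)
  b <- tiny_cohort(seed = 9, cells = 2, channels = 120)
  expect_identical(a$spectra$intensities, b$spectra$intensities)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$symptoms, b$symptoms)
  c <- tiny_cohort(seed = 10, cells = 2, channels = 120)
  expect_false(identical(a$spectra$intensities, c$spectra$intensities))
})

test_that("an all-zero configuration yields an empty cohort", {
  coh <- generate_cohort(cohort_config(group_sizes = c(HC = 0, MS = 0),
                                       cells_per_subject = 0))
  expect_equal(nrow(coh$subjects), 0)
  expect_equal(nrow(coh$spectra$intensities), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(group_sizes = c(Bogus = 3)), "invalid group")
  expect_error(cohort_config(axis = c(3401, 319, 100)), "axis")
  et <- default_effect_table(); et[1, 2] <- -1
  expect_error(cohort_config(effect_table = et), "> 0")
  expect_error(cohort_config(missing_rate = 1.5), "missing_rate")
  expect_error(cohort_config(spike_params = list(prob = 2, amp_range = c(1, 2))),
               "probability")
})

test_that("clinical scores hit the configured medians and ranges exactly", {
  coh <- generate_cohort(cohort_config(cells_per_subject = 0, seed = 3))
  s <- coh$subjects
  me <- s$group %in% c("MildME", "ModME", "SevME")
  expect_equal(stats::median(s$fss[me]), 59)
  expect_true(all(s$fss[me] >= 44 & s$fss[me] <= 63))
  expect_equal(stats::median(s$fss[s$group == "HC"]), 17)
  expect_true(all(s$fss[s$group == "HC"] >= 11 & s$fss[s$group == "HC"] <= 37))
  expect_equal(stats::median(s$fss[s$group == "MS"]), 54)
  # severity definition through SF-36 physical function
  expect_true(all(s$sf36_pf[s$group == "MildME"] > 25))
  expect_true(all(s$sf36_pf[s$group %in% c("ModME", "SevME")] < 25))
})

test_that("a collapsed score range assigns a single value to everyone", {
  tg <- default_clinical_targets()
  tg$HC$fss <- c(20, 20, 20)
  coh <- generate_cohort(cohort_config(group_sizes = c(HC = 7, MS = 2),
                                       cells_per_subject = 0,
                                       clinical_targets = tg))
  expect_true(all(coh$subjects$fss[coh$subjects$group == "HC"] == 20))
  expect_error(scrsdx:::scores_for_group(3, c(5, 10, 4)), "range")
})

test_that("disabling effects removes group differences at the channel level", {
  et <- default_effect_table(); et[] <- 1
  coh <- generate_cohort(cohort_config(
    group_sizes = c(HC = 10, MS = 10), cells_per_subject = 6,
    acquisitions_per_cell = c(2, 2), axis = c(319, 3401, 300),
    effect_table = et, seed = 21))
  scrs <- run_preprocess(coh$spectra, preprocess_config(baseline_segments = 8))
  g <- subject_label_map(coh)[scrs$meta$subject_id]
  pvals <- apply(scrs$intensities, 2, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)   # fully clipped channel
    stats::t.test(v[g == "HC"], v[g == "MS"])$p.value
  })
  # rejection rate compatible with the nominal alpha = 0.01
  expect_lt(mean(pvals < 0.01, na.rm = TRUE), 0.05)
})

test_that("spike-free cohorts contain no spike-like outliers", {
  coh <- tiny_cohort(seed = 13, sizes = c(HC = 3, MS = 3), cells = 4,
                     spike_params = list(prob = 0, amp_range = c(30, 120)))
  ints <- coh$spectra$intensities
  # scan oracle: residual from a running median against the local MAD
  roll_mad <- function(y, k) {
    n <- length(y); h <- k %/% 2
    1.4826 * vapply(seq_len(n), function(j) {
      w <- y[max(1, j - h):min(n, j + h)]
      stats::median(abs(w - stats::median(w)))
    }, numeric(1))
  }
  worst <- max(apply(ints, 1, function(y) {
    med <- stats::runmed(y, 5, endrule = "median")
    max(abs(y - med) / pmax(roll_mad(y, 25), 1e-12))
  }))
  expect_lt(worst, 10)
})

test_that("an injected phenylalanine deficit is recovered end-to-end", {
  et <- default_effect_table(); et[] <- 1
  et["phenylalanine", "SevME"] <- 0.7
  coh <- generate_cohort(cohort_config(
    group_sizes = c(HC = 10, SevME = 10), cells_per_subject = 10,
    acquisitions_per_cell = c(2, 2), effect_table = et, seed = 31))
  scrs <- run_preprocess(coh$spectra)
  g <- subject_label_map(coh)[scrs$meta$subject_id]
  band <- band_registry()$phenylalanine
  vals <- apply(scrs$intensities, 1, integrate_band,
                wavenumbers = scrs$wavenumbers, band = band)
  tt <- stats::t.test(vals[g == "SevME"], vals[g == "HC"], alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("symptom tables respect the ordinal scale, gradient and missingness", {
  coh <- generate_cohort(cohort_config(cells_per_subject = 0, seed = 8))
  sym <- coh$symptoms
  expect_equal(ncol(sym), 63)
  expect_true(all(sym[!is.na(sym)] %in% 0:3))
  g <- coh$subjects$group
  sev_means <- vapply(c("HC", "MildME", "ModME", "SevME"), function(gr)
    mean(sym[g == gr, ], na.rm = TRUE), numeric(1))
  expect_true(all(diff(sev_means) > 0))   # HC < mild < moderate < severe
  # no missingness when the rate is zero
  coh0 <- generate_cohort(cohort_config(group_sizes = c(HC = 3, MS = 3),
                                        cells_per_subject = 0,
                                        missing_rate = 0))
  expect_false(anyNA(coh0$symptoms))
})

test_that("equal symptom propensities leave almost nothing selected", {
  cfg <- cohort_config(group_sizes = c(HC = 10, SevME = 40, MS = 40),
                       cells_per_subject = 0,
                       symptom_params = list(n_variables = 63,
                                             base = c(HC = 0.4, MildME = 0.4,
                                                      ModME = 0.4, SevME = 0.4),
                                             ms_range = c(0.4, 0.4)),
                       missing_rate = 0, seed = 17)
  coh <- generate_cohort(cfg)
  sel <- select_symptoms(coh$symptoms, coh$subjects$group)
  expect_lte(sum(sel$included), 3)
})
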