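wn_full <- make_canonical_axis()

test_that("despiking preserves clean peaks and constants", {
  clean <- lorentz(wn_full, 1003) + 0.5 * lorentz(wn_full, 1450) +
    0.8 * lorentz(wn_full, 2935)
  expect_identical(despike(clean), clean)       # peaks survive the filter
  const <- rep(5, 300)
  expect_identical(despike(const), const)       # zero-MAD guard
  expect_error(despike(rep(1, 4), window = 5), "smaller")
})

test_that("a lone spike on a constant background is removed exactly", {
  y <- rep(2, 400)
  y[203] <- 9
  out <- despike(y)
  expect_equal(out, rep(2, 400), tolerance = 1e-12)
})

test_that("spike recovery reproduces the clean spectrum to 1e-6", {
  clean <- lorentz(wn_full, 1003) + 0.8 * lorentz(wn_full, 2935) + 0.2
  spiked <- clean
  k <- which.min(abs(wn_full - 2000))           # silent-region channel
  spiked[k] <- spiked[k] + 3
  out <- despike(spiked)
  expect_lt(max(abs(out - clean)), 1e-6)
})

test_that("despiking is idempotent on noisy spiked spectra", {
  set.seed(4)
  y <- 2 * lorentz(wn_full, 1003) + rnorm(1019, 0, 0.05) + 1
  y[c(100, 600)] <- y[c(100, 600)] + c(4, 6)
  d1 <- despike(y)
  expect_identical(despike(d1), d1)
  expect_lt(max(abs(d1[c(100, 600)] - c(1, 1))), 0.5)   # spikes gone
})

test_that("polyline baseline removes affine trends exactly", {
  ramp <- 3 * wn_full + 100
  res <- fit_polyline_baseline(ramp, wn_full, 12)
  expect_lt(max(abs(res$corrected)), 1e-6 * diff(range(ramp)))
  z <- rep(0, 100)
  rz <- fit_polyline_baseline(z, seq_len(100), 4)
  expect_equal(rz$baseline, z)
  expect_equal(rz$corrected, z)
  expect_error(fit_polyline_baseline(1:5, 1:5, 12), "fewer channels")
})

test_that("baseline correction preserves peak height on a ramp", {
  peak <- 2 * lorentz(wn_full, 1003)
  ramp <- 0.001 * wn_full + 0.5
  res <- fit_polyline_baseline(peak + ramp, wn_full, 12)
  win <- which(abs(wn_full - 1003) < 20)
  expect_lt(abs(max(res$corrected[win]) - max(peak)) / max(peak), 0.02)
  # reconstruction where nothing was clipped
  unclipped <- res$corrected > 0
  expect_equal((res$corrected + res$baseline)[unclipped],
               (peak + ramp)[unclipped], tolerance = 1e-10)
})

test_that("vector normalization produces exact unit norm", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  set.seed(2)
  y <- abs(rnorm(500)) + 0.1
  expect_equal(sqrt(sum(vector_normalize(y)^2)), 1, tolerance = 1e-12)
  expect_error(vector_normalize(rep(0, 10)), "zero-norm")
  # fingerprint-region normalization normalizes over that region only
  wn <- make_canonical_axis(319, 3401, 500)
  v <- vector_normalize(y, wn, region = c(300, 1800))
  idx <- which(wn >= 300 & wn <= 1800)
  expect_equal(sqrt(sum(v[idx]^2)), 1, tolerance = 1e-12)
})

test_that("SNR quality control separates noise from signal", {
  set.seed(11)
  noise <- pmax(matrix(rnorm(2 * 1019, 0, 1), 2), 0)
  sig <- noise
  sig[, which.min(abs(wn_full - 1445))] <- 20
  x <- spectra_set(wn_full, rbind(noise, sig),
                   data.frame(subject_id = "S1", cell_id = paste0("c", 1:4),
                              acquisition_id = "a1"))
  qc <- qc_filter(x, preprocess_config())
  expect_equal(qc$report$kept, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(nrow(qc$kept$intensities), 2)
  # empty input passes through
  empty <- spectra_set(wn_full, matrix(numeric(0), 0, 1019),
                       data.frame(subject_id = character(0),
                                  cell_id = character(0),
                                  acquisition_id = character(0)))
  expect_equal(nrow(qc_filter(empty)$report), 0)
  expect_error(qc_filter(x, preprocess_config(snr_noise_band = c(1800, 1803))),
               "3 channels")
})

test_that("SCRS averaging is the channel-wise mean", {
  wn <- c(100, 200, 300)
  m <- data.frame(subject_id = "S1", cell_id = "c1",
                  acquisition_id = c("a1", "a2"))
  x <- spectra_set(wn, rbind(c(0, 2, 4), c(2, 2, 0)), m)
  sc <- average_to_scrs(x)
  expect_equal(sc$intensities[1, ], c(1, 2, 2))
  expect_equal(sc$meta$n_acquisitions, 2)
  # idempotent on identical replicates
  x2 <- spectra_set(wn, rbind(c(1, 2, 3), c(1, 2, 3)), m)
  expect_equal(average_to_scrs(x2)$intensities[1, ], c(1, 2, 3))
  m2 <- m; m2$cell_id <- c("c1", "c2")
  expect_error(average_to_scrs(spectra_set(wn, rbind(1:3, 1:3), m2)),
               "multiple cells")
})

test_that("spikes are suppressed to the noise-replacement scale in the SCRS", {
  # A replaced channel cannot recover the specific noise draw the spike
  # destroyed, so the twin comparison bottoms out at O(noise SD / n_acq),
  # not at zero: assert suppression to that scale and by a large factor
  # relative to the injected spike amplitudes.
  mk <- function(prob) tiny_cohort(seed = 6, sizes = c(HC = 3, MS = 3),
                                   cells = 4, acq = c(3, 3),
                                   spike_params = list(prob = prob,
                                                       amp_range = c(30, 120)))
  raw_spiky <- mk(0.10)$spectra
  raw_twin <- mk(0)$spectra
  spiky <- run_preprocess(raw_spiky)
  twin <- run_preprocess(raw_twin)
  peak_height <- max(twin$intensities)
  resid <- max(abs(spiky$intensities - twin$intensities))
  expect_lt(resid, 0.03 * peak_height)
  # without despiking the same spikes would dominate the SCRS: measure the
  # worst unsuppressed spike by skipping correction (QC/baseline/norm only)
  cfgoff <- preprocess_config(despike_threshold = Inf)
  spiky_off <- run_preprocess(raw_spiky, cfgoff)
  twin_off <- run_preprocess(raw_twin, cfgoff)
  resid_off <- max(abs(spiky_off$intensities - twin_off$intensities))
  expect_gt(resid_off, 20 * resid)
})

test_that("the pipeline normalizes after averaging by default", {
  coh <- tiny_cohort(seed = 14, sizes = c(HC = 2, MS = 2), cells = 3)
  per_scrs <- run_preprocess(coh$spectra)
  expect_true(per_scrs$normalized)
  expect_equal(unname(sqrt(rowSums(per_scrs$intensities^2))),
               rep(1, nrow(per_scrs$intensities)), tolerance = 1e-9)
  per_acq <- run_preprocess(coh$spectra,
                            preprocess_config(normalize_per = "acquisition"))
  # the two orders are genuinely different operations
  expect_false(isTRUE(all.equal(per_scrs$intensities, per_acq$intensities)))
  expect_s3_class(attr(per_scrs, "qc_report"), "data.frame")
})

test_that("an empty cohort preprocesses to an empty SCRS collection", {
  empty <- spectra_set(wn_full, matrix(numeric(0), 0, 1019),
                       data.frame(subject_id = character(0),
                                  cell_id = character(0),
                                  acquisition_id = character(0)))
  out <- run_preprocess(empty)
  expect_equal(nrow(out$intensities), 0)
})
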