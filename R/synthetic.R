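#' Default Raman peak library for synthetic PBMC spectra
#'
#' Eight biomarker bands (aromatic amino acids, lipid and energy metabolites)
#' carry group-specific concentration effects; the remaining generic cellular
#' bands (nucleic acid, protein and CH-stretch vibrations) are identical across
#' groups, so classifiers must locate the informative channels rather than any
#' channel. Peak heights are relative (a.u.); all peaks share a Lorentzian
#' shape whose FWHM is set in the cohort configuration.
#'
#' @return Data frame with columns `name`, `center` (cm^-1), `amplitude`,
#'   `band` (biomarker band name, or `NA` for generic peaks).
#' @export
default_peak_library <- function() {
  biom <- data.frame(
    name = c("glucose", "glycogen", "cholesterol", "tryptophan", "tyrosine",
             "phenylalanine", "glycerol", "unsat_fa"),
    center = c(405, 485, 617, 758, 860, 1003, 1114, 3010),
    amplitude = c(0.45, 0.55, 0.50, 0.80, 0.70, 1.00, 0.60, 0.90),
    stringsAsFactors = FALSE)
  biom$band <- biom$name
  gen <- data.frame(
    name = c("s_s", "c_c_def", "ring728", "dna785", "tyr_b828", "pro898",
             "pro937", "c_c967", "dna1095", "c_n1128", "c_h1176", "amideIII1250",
             "ch2_1304", "ch2_1340", "ch2_1450", "phe_trp1578", "amideI1660",
             "ester1745", "ch2_2850", "ch2_2885", "ch3_2935", "ch_3060"),
    center = c(536, 665, 728, 785, 828, 898, 937, 967, 1095, 1128, 1176, 1250,
               1304, 1340, 1450, 1578, 1660, 1745, 2850, 2885, 2935, 3060),
    amplitude = c(0.30, 0.25, 0.40, 0.70, 0.35, 0.30, 0.45, 0.30, 0.50, 0.40,
                  0.35, 0.55, 0.60, 0.55, 1.00, 0.45, 1.10, 0.30, 0.80, 0.70,
                  1.20, 0.50),
    stringsAsFactors = FALSE)
  gen$band <- NA_character_
  rbind(biom, gen)
}

#' Default group effect table
#'
#' Multiplicative concentration factors per biomarker band and diagnostic
#' group, relative to healthy controls (HC = 1). Directions mirror the
#' observed cohort phenotypes: tryptophan, tyrosine and glycerol elevated in
#' all disease groups; phenylalanine reduced in moderate/severe ME but raised
#' in mild ME and MS; unsaturated fatty acids raised in mild ME and MS and
#' reduced in moderate/severe ME; cholesterol reduced everywhere and most in
#' MS; glycogen reduced in mild/severe ME and MS; glucose reduced in all
#' disease groups with MS lowest.
#'
#' @return Numeric matrix, bands x groups (`HC, MildME, ModME, SevME, MS`).
#' @export
default_effect_table <- function() {
  groups <- c("HC", "MildME", "ModME", "SevME", "MS")
  e <- rbind(
    tryptophan    = c(1, 1.20, 1.30, 1.35, 1.30),
    tyrosine      = c(1, 1.20, 1.25, 1.30, 1.25),
    phenylalanine = c(1, 1.25, 0.75, 0.70, 1.25),
    glycerol      = c(1, 1.25, 1.25, 1.25, 1.25),
    unsat_fa      = c(1, 1.25, 0.80, 0.75, 1.30),
    cholesterol   = c(1, 0.85, 0.85, 0.80, 0.70),
    glycogen      = c(1, 0.80, 1.00, 0.75, 0.80),
    glucose       = c(1, 0.80, 0.80, 0.75, 0.70))
  colnames(e) <- groups
  e
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults emulate the study cohort: 98 subjects in five groups (HC 16,
#' mild ME 25, moderate ME 15, severe ME 21, MS 21), 30 cells per subject,
#' 5--10 acquisitions per cell on the canonical 319--3401 cm^-1 axis with 1019
#' channels. Each acquisition is a sum of Lorentzian peaks scaled by a shared
#' per-cell latent concentration, plus a random positive polynomial
#' fluorescence baseline, Gaussian noise, a per-spectrum multiplicative scale,
#' and occasional single-channel cosmic-ray spikes.
#'
#' @param group_sizes Named integer vector of subjects per group.
#' @param cells_per_subject Cells measured per subject.
#' @param acquisitions_per_cell Integer range `c(min, max)` of point spectra
#'   per cell.
#' @param axis Numeric `c(start, end, n_channels)` for [make_canonical_axis()].
#' @param peaks Peak library data frame (see [default_peak_library()]).
#' @param effect_table Bands x groups multiplicative factors, HC column 1.
#' @param peak_fwhm Lorentzian full width at half maximum (cm^-1).
#' @param cell_sigma SD of the per-cell log-normal concentration multiplier
#'   shared by all of that cell's acquisitions.
#' @param band_sigma SD of the per-cell, per-peak log-normal biological
#'   variability.
#' @param baseline_params List: `order` of the random polynomial and
#'   `amp_range`, the baseline amplitude range in multiples of the mean peak
#'   height.
#' @param noise_params List: `additive_sd` (a.u.) and `scale_sd`
#'   (per-spectrum log-normal multiplicative scale SD).
#' @param spike_params List: per-spectrum spike `prob` and `amp_range` in
#'   multiples of the spectrum noise scale.
#' @param clinical_targets Per-group list of `fss = c(median, lo, hi)` and
#'   `sf36 = c(median, lo, hi)`.
#' @param symptom_params List: `n_variables`, per-group base symptom
#'   propensities `base`, MS propensity range `ms_range` (high to low across
#'   the ME-specificity gradient).
#' @param missing_rate Fraction of symptom entries set missing (MCAR).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   configuration including this seed.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(HC = 16, MildME = 25, ModME = 15,
                                          SevME = 21, MS = 21),
                          cells_per_subject = 30,
                          acquisitions_per_cell = c(5, 10),
                          axis = c(319, 3401, 1019),
                          peaks = default_peak_library(),
                          effect_table = default_effect_table(),
                          peak_fwhm = 10,
                          cell_sigma = 0.15,
                          band_sigma = 0.10,
                          baseline_params = list(order = 5, amp_range = c(0, 5)),
                          noise_params = list(additive_sd = 0.05, scale_sd = 0.10),
                          spike_params = list(prob = 0.05, amp_range = c(30, 120)),
                          clinical_targets = default_clinical_targets(),
                          symptom_params = list(n_variables = 63,
                                                base = c(HC = 0.08, MildME = 0.35,
                                                         ModME = 0.50, SevME = 0.65),
                                                ms_range = c(0.60, 0.25)),
                          missing_rate = 0.05,
                          seed = 1L) {
  groups <- c("HC", "MildME", "ModME", "SevME", "MS")
  if (is.null(names(group_sizes)) || !all(names(group_sizes) %in% groups))
    stop("invalid group name in group_sizes")
  if (any(group_sizes < 0) || cells_per_subject < 0)
    stop("counts must be >= 0")
  if (axis[2] <= axis[1] || axis[3] < 2) stop("non-positive axis")
  if (any(effect_table <= 0)) stop("effect factors must be > 0")
  if (spike_params$prob < 0 || spike_params$prob > 1)
    stop("spike probability must be in [0, 1]")
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  if (length(acquisitions_per_cell) != 2 ||
      acquisitions_per_cell[1] > acquisitions_per_cell[2] ||
      acquisitions_per_cell[1] < 1)
    stop("acquisitions_per_cell must be an increasing range >= 1")
  wn <- make_canonical_axis(axis[1], axis[2], axis[3])
  if (any(peaks$center < axis[1] | peaks$center > axis[2]))
    stop("band center outside axis")
  if (!all(rownames(effect_table) %in% peaks$band[!is.na(peaks$band)]))
    stop("effect_table rows must be biomarker bands in the peak library")
  structure(list(group_sizes = group_sizes, groups = groups,
                 cells_per_subject = as.integer(cells_per_subject),
                 acquisitions_per_cell = as.integer(acquisitions_per_cell),
                 axis = axis, wavenumbers = wn, peaks = peaks,
                 effect_table = effect_table, peak_fwhm = peak_fwhm,
                 cell_sigma = cell_sigma, band_sigma = band_sigma,
                 baseline_params = baseline_params, noise_params = noise_params,
                 spike_params = spike_params,
                 clinical_targets = clinical_targets,
                 symptom_params = symptom_params,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default clinical score targets
#'
#' FSS (Fatigue Severity Scale, 9--63) medians and ranges follow the study's
#' clinical summary: all ME subgroups 59 (44--63), MS 54 (16--63), HC 17
#' (11--37). SF-36 Physical Function ranges respect the severity definition:
#' mild ME > 25, moderate/severe ME < 25.
#'
#' @return Named list per group with `fss` and `sf36` as `c(median, lo, hi)`.
#' @export
default_clinical_targets <- function() {
  list(HC     = list(fss = c(17, 11, 37), sf36 = c(95, 80, 100)),
       MildME = list(fss = c(59, 44, 63), sf36 = c(50, 30, 80)),
       ModME  = list(fss = c(59, 44, 63), sf36 = c(15, 5, 24)),
       SevME  = list(fss = c(59, 44, 63), sf36 = c(5, 0, 15)),
       MS     = list(fss = c(54, 16, 63), sf36 = c(50, 20, 80)))
}

# deterministic sub-seed derivation; keeps values < 2^31
spawn_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483587)
}

# median-anchored inverse-CDF score assignment: the middle order statistic(s)
# are pinned at the configured median (so the group sample median is exact at
# any n), and each half is filled by a linear inverse CDF over its range.
scores_for_group <- function(n, target) {
  med <- target[1]; lo <- target[2]; hi <- target[3]
  if (lo > hi || med < lo || med > hi) stop("empty or inconsistent score range")
  if (n == 0) return(integer(0))
  n_mid <- if (n %% 2 == 1) 1L else 2L
  n_low <- (n - n_mid) %/% 2L
  n_up <- n - n_mid - n_low
  low <- if (n_low > 0) round(seq(lo, med, length.out = n_low + 1))[seq_len(n_low)] else integer(0)
  up <- if (n_up > 0) round(seq(med, hi, length.out = n_up + 1))[-1] else integer(0)
  as.integer(c(low, rep(med, n_mid), up))
}

#' Assign clinical scores to cohort subjects
#'
#' Fills `fss` and `sf36_pf` by stratified, median-anchored inverse-CDF
#' assignment within each group, then permutes the values among the group's
#' subjects. Group sample medians equal the configured medians exactly and all
#' scores lie within the configured ranges.
#'
#' @param subjects Data frame with a `group` column.
#' @param config A [cohort_config].
#' @param seed Integer seed for the within-group permutation.
#' @return `subjects` with `fss` and `sf36_pf` columns filled.
#' @export
assign_clinical_scores <- function(subjects, config, seed = config$seed) {
  subjects$fss <- rep(NA_integer_, nrow(subjects))
  subjects$sf36_pf <- rep(NA_integer_, nrow(subjects))
  set.seed(spawn_seed(seed, 11))
  for (g in unique(subjects$group)) {
    idx <- which(subjects$group == g)
    tg <- config$clinical_targets[[g]]
    if (is.null(tg)) stop("no clinical targets for group ", g)
    subjects$fss[idx] <- sample(scores_for_group(length(idx), tg$fss))
    subjects$sf36_pf[idx] <- sample(scores_for_group(length(idx), tg$sf36))
  }
  subjects
}

#' Generate raw spectra for all cells of one subject
#'
#' Each acquisition is the sum over library peaks of
#' `amplitude x effect(band, group) x cell concentration x per-cell band
#' jitter x Lorentzian(center, fwhm)`, multiplied by a per-spectrum scale,
#' plus a positive polynomial fluorescence baseline, additive Gaussian noise
#' and (with configured probability) a single-channel cosmic-ray spike. The
#' latent concentration and band jitters are shared by all acquisitions of a
#' cell, which is what makes averaging into an SCRS meaningful.
#'
#' @param subject One-row data frame with `subject_id` and `group`.
#' @param config A [cohort_config].
#' @param seed Integer seed (sub-streams are derived per component so that,
#'   e.g., a spike-free twin cohort shares every other random draw).
#' @return A [spectra_set] for this subject's cells.
#' @export
synth_cell_spectra <- function(subject, config, seed = config$seed) {
  group <- as.character(subject$group)
  if (!group %in% config$groups) stop("invalid group name: ", group)
  wn <- config$wavenumbers
  p <- length(wn)
  pk <- config$peaks
  npk <- nrow(pk)
  n_cells <- config$cells_per_subject
  if (n_cells == 0) {
    return(spectra_set(wn, matrix(numeric(0), 0, p),
                       data.frame(subject_id = character(0), cell_id = character(0),
                                  acquisition_id = character(0))))
  }

  # effect factor per peak for this group (generic peaks: 1)
  eff <- rep(1, npk)
  has_band <- !is.na(pk$band)
  eff[has_band] <- config$effect_table[pk$band[has_band], group]

  # Lorentzian basis, peaks x channels
  gam <- config$peak_fwhm / 2
  basis <- gam^2 / (outer(pk$center, wn, `-`)^2 + gam^2)

  # structure: acquisitions per cell
  set.seed(spawn_seed(seed, 1))
  acq_rng <- config$acquisitions_per_cell
  n_acq <- if (acq_rng[1] == acq_rng[2]) rep(acq_rng[1], n_cells) else
    sample(acq_rng[1]:acq_rng[2], n_cells, replace = TRUE)
  n_tot <- sum(n_acq)
  cell_of <- rep(seq_len(n_cells), n_acq)

  # latent per-cell concentration and per-cell band jitter
  set.seed(spawn_seed(seed, 2))
  conc <- exp(stats::rnorm(n_cells, 0, config$cell_sigma))
  jitter <- matrix(exp(stats::rnorm(n_cells * npk, 0, config$band_sigma)),
                   n_cells, npk)
  # per-spectrum multiplicative scale
  scale_i <- exp(stats::rnorm(n_tot, 0, config$noise_params$scale_sd))

  # amplitude matrix (acquisitions x peaks) -> signal
  amp_cell <- sweep(jitter, 2, pk$amplitude * eff, `*`) * conc
  sig <- (amp_cell[cell_of, , drop = FALSE] %*% basis) * scale_i

  # fluorescence baseline: random positive polynomial in t = [0, 1]
  set.seed(spawn_seed(seed, 3))
  bp <- config$baseline_params
  mean_peak <- mean(pk$amplitude)
  tgrid <- seq(0, 1, length.out = p)
  tbasis <- t(vapply(0:bp$order, function(m) tgrid^m, numeric(p)))
  coefs <- matrix(stats::runif(n_tot * (bp$order + 1), -1, 1), n_tot)
  bl <- coefs %*% tbasis
  bl_min <- apply(bl, 1, min)
  bl_rng <- apply(bl, 1, max) - bl_min
  bl_rng[bl_rng == 0] <- 1
  amp_bl <- stats::runif(n_tot, bp$amp_range[1], bp$amp_range[2]) * mean_peak
  bl <- (bl - bl_min) / bl_rng * amp_bl

  # additive noise
  set.seed(spawn_seed(seed, 4))
  noise <- matrix(stats::rnorm(n_tot * p, 0, config$noise_params$additive_sd),
                  n_tot, p)
  y <- sig + bl + noise

  # cosmic-ray spikes, drawn from their own sub-stream so that a spike-free
  # twin cohort (prob = 0) is channel-identical elsewhere
  set.seed(spawn_seed(seed, 5))
  sp <- config$spike_params
  hit <- stats::runif(n_tot) < sp$prob
  for (i in which(hit)) {
    ch <- sample.int(p, 1)
    y[i, ch] <- y[i, ch] + stats::runif(1, sp$amp_range[1], sp$amp_range[2]) *
      config$noise_params$additive_sd
  }

  meta <- data.frame(
    subject_id = rep(subject$subject_id, n_tot),
    cell_id = paste0(subject$subject_id, "_c", sprintf("%02d", cell_of)),
    acquisition_id = unlist(lapply(n_acq, function(k) sprintf("a%02d", seq_len(k)))),
    stringsAsFactors = FALSE)
  spectra_set(wn, y, meta)
}

#' Generate the ordinal symptom table
#'
#' 63 variables by default, entries on the 0--3 ordinal scale (0 absent, 3
#' severe) or missing. Each variable draws entries from Binomial(3, p) with a
#' group-specific propensity p; ME propensities rise with severity
#' (HC < mild < moderate < severe) while the MS propensity declines along a
#' per-variable "ME specificity" gradient, so a subset of variables is
#' genuinely enriched in severe ME relative to MS. Missingness is MCAR at the
#' configured rate.
#'
#' @param subjects Data frame with `subject_id` and `group`.
#' @param config A [cohort_config].
#' @param seed Integer seed.
#' @return Integer matrix subjects x variables with `NA` for missing.
#' @export
synth_symptom_table <- function(subjects, config, seed = config$seed) {
  sp <- config$symptom_params
  nv <- sp$n_variables
  ns <- nrow(subjects)
  set.seed(spawn_seed(seed, 21))
  w <- sample(seq(0, 1, length.out = nv))        # ME-specificity per variable
  p_ms <- sp$ms_range[1] + (sp$ms_range[2] - sp$ms_range[1]) * w
  prop <- rbind(HC = rep(sp$base[["HC"]], nv),
                MildME = rep(sp$base[["MildME"]], nv),
                ModME = rep(sp$base[["ModME"]], nv),
                SevME = rep(sp$base[["SevME"]], nv),
                MS = p_ms)
  pm <- prop[as.character(subjects$group), , drop = FALSE]
  m <- matrix(stats::rbinom(ns * nv, 3, as.vector(pm)), ns, nv)
  if (config$missing_rate > 0)
    m[stats::runif(ns * nv) < config$missing_rate] <- NA_integer_
  rownames(m) <- subjects$subject_id
  colnames(m) <- sprintf("sym%02d", seq_len(nv))
  m
}

#' Generate a complete synthetic cohort
#'
#' Deterministic function of the configuration (including its seed). Produces
#' the subject manifest with clinical covariates and scores, raw spectra for
#' every cell, and the ordinal symptom table.
#'
#' @param config A [cohort_config].
#' @return Object of class `raman_cohort`: list with `subjects`, `spectra`
#'   (a [spectra_set]), `symptoms` (matrix) and `config`.
#' @examples
#' cfg <- cohort_config(group_sizes = c(HC = 2, MS = 2), cells_per_subject = 2,
#'                      acquisitions_per_cell = c(2, 2), axis = c(319, 3401, 200))
#' coh <- generate_cohort(cfg)
#' table(coh$subjects$group)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  gs <- config$group_sizes
  n <- sum(gs)
  groups <- rep(names(gs), gs)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(max(n, 0))),
    group = groups,
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  subjects$severity <- ifelse(subjects$group %in% c("MildME", "ModME", "SevME"),
                              sub("ME$", "", subjects$group), "none")

  # demographics / covariates
  set.seed(spawn_seed(config$seed, 31))
  disease <- subjects$group != "HC"
  me <- subjects$group %in% c("MildME", "ModME", "SevME")
  subjects$sex <- ifelse(stats::runif(n) < ifelse(me, 0.70, 0.60), "F", "M")
  subjects$age <- round(stats::runif(n, 25, 60))
  subjects$bmi <- round(pmin(pmax(stats::rnorm(n, 26, 4), 17), 42), 1)
  subjects$disease_duration <- ifelse(disease, round(stats::runif(n, 1, 20)), 0)
  subjects$med_opiate <- disease & stats::runif(n) < 0.20
  subjects$med_tricyclic <- disease & stats::runif(n) < 0.15

  subjects <- assign_clinical_scores(subjects, config, config$seed)

  # spectra per subject (per-subject derived seeds keep the whole cohort
  # deterministic while synth_cell_spectra stays usable standalone)
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    specs[[i]] <- synth_cell_spectra(subjects[i, ], config,
                                     seed = spawn_seed(config$seed, 1000 + i))
  }
  if (n > 0 && config$cells_per_subject > 0) {
    ints <- do.call(rbind, lapply(specs, `[[`, "intensities"))
    meta <- do.call(rbind, lapply(specs, `[[`, "meta"))
    spectra <- spectra_set(config$wavenumbers, ints, meta)
  } else {
    spectra <- spectra_set(config$wavenumbers,
                           matrix(numeric(0), 0, length(config$wavenumbers)),
                           data.frame(subject_id = character(0),
                                      cell_id = character(0),
                                      acquisition_id = character(0)))
  }
  symptoms <- if (n > 0) synth_symptom_table(subjects, config, config$seed) else
    matrix(NA_integer_, 0, config$symptom_params$n_variables)

  structure(list(subjects = subjects, spectra = spectra, symptoms = symptoms,
                 config = config),
            class = "raman_cohort")
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat(sprintf("raman_cohort: %d subjects (%s), %d acquisitions\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            as.integer(table(x$subjects$group))), collapse = ", "),
              nrow(x$spectra$intensities)))
  invisible(x)
}
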