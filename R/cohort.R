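#' @importFrom data.table data.table fread fwrite setDF setDT :=
NULL

# ---------------------------------------------------------------------------
# Group calibration targets (means/SDs, medians/IQRs, frequencies) for the
# three diagnostic groups.  Continuous mean/SD variables are sampled from
# (possibly truncated) normals whose location is solved so the *truncated*
# mean equals the target; median/IQR variables (MMSE, p-tau) are matched on
# the printed quantiles instead (see the methods vignette).
# ---------------------------------------------------------------------------

.group_calibration <- list(
  CN = list(
    n = 67L,
    age   = c(mean = 71.48, sd = 5.93),
    male  = 0.507,
    moca  = c(mean = 26.28, sd = 2.56),
    adas13 = c(mean = 8.62, sd = 4.51),
    apoe4 = 0.134,
    abeta42 = c(mean = 231.97, sd = 23.31),
    education = c(mean = 16.76, sd = 2.58),
    ptau  = c(median = 27.60, q1 = 22.38, q3 = 38.82),
    # t-tau is not summarized in the source table; synthetic plausible values
    ttau  = c(median = 70, sdlog = 0.35),
    mmse  = list(values = 30:27, probs = c(0.55, 0.30, 0.10, 0.05))
  ),
  EMCI = list(
    n = 83L,
    age   = c(mean = 72.78, sd = 6.78),
    male  = 0.614,
    moca  = c(mean = 23.69, sd = 3.22),
    adas13 = c(mean = 13.56, sd = 5.06),
    apoe4 = 0.578,
    abeta42 = c(mean = 143.06, sd = 25.27),
    education = c(mean = 16.35, sd = 2.76),
    ptau  = c(median = 40.40, q1 = 28.82, q3 = 59.30),
    ttau  = c(median = 95, sdlog = 0.35),
    mmse  = list(values = 30:26, probs = c(0.30, 0.30, 0.25, 0.10, 0.05))
  ),
  LMCI = list(
    n = 58L,
    age   = c(mean = 72.00, sd = 7.20),
    male  = 0.483,
    moca  = c(mean = 21.64, sd = 3.16),
    adas13 = c(mean = 20.06, sd = 6.63),
    apoe4 = 0.741,
    abeta42 = c(mean = 131.40, sd = 23.03),
    education = c(mean = 16.67, sd = 2.66),
    ptau  = c(median = 53.00, q1 = 39.62, q3 = 71.50),
    ttau  = c(median = 115, sdlog = 0.35),
    mmse  = list(values = 30:24,
                 probs = c(0.10, 0.20, 0.25, 0.15, 0.15, 0.08, 0.07))
  )
)

# amyloid positivity thresholds
.ABETA_CUTOFF <- 192      # pg/mL, CSF Abeta1-42; below => A+
.SUVR_CUTOFF  <- c(FBP = 1.11, FBB = 1.08)  # strictly above => A+

# Logical Memory II cutoffs, one column per education stratum
# (>=16 y, 8-15 y, 0-7 y)
.LM2_CN_MIN   <- c(9L, 5L, 3L)
.LM2_EMCI_LO  <- c(9L, 5L, 3L)
.LM2_EMCI_HI  <- c(11L, 9L, 6L)
.LM2_LMCI_MAX <- c(8L, 4L, 2L)

.edu_stratum <- function(education) {
  ifelse(education >= 16, 1L, ifelse(education >= 8, 2L, 3L))
}

#' Amyloid status from CSF and/or amyloid-PET
#'
#' Classifies a participant as amyloid-positive (`"Apos"`), negative
#' (`"Aneg"`) or `"unknown"`.  CSF Abeta1-42 below 192 pg/mL means positive
#' and, when both modalities are available, the CSF result is definitive.
#' With PET only, the summary SUVR must exceed the tracer-specific cutoff
#' (1.11 for FBP, 1.08 for FBB) to be called positive.
#'
#' All arguments are vectorized; `NA` marks an absent measurement.
#'
#' @param abeta42 CSF Abeta1-42 concentration in pg/mL, or `NA`.
#' @param suvr Amyloid-PET summary SUVR, or `NA`.
#' @param tracer `"FBP"`, `"FBB"` or `"none"`; must not be `"none"` when
#'   `suvr` is given.
#' @return Character vector with values `"Apos"`, `"Aneg"`, `"unknown"`.
#' @export
#' @examples
#' assign_amyloid_status(150, NA, "none")        # "Apos"
#' assign_amyloid_status(231.97, 1.20, "FBP")    # "Aneg" (CSF overrides PET)
#' assign_amyloid_status(NA, 1.08, "FBB")        # "Aneg" (not strictly above)
assign_amyloid_status <- function(abeta42, suvr = NA_real_, tracer = "none") {
  n <- max(length(abeta42), length(suvr), length(tracer))
  abeta42 <- rep_len(as.numeric(abeta42), n)
  suvr <- rep_len(as.numeric(suvr), n)
  tracer <- rep_len(as.character(tracer), n)
  bad <- !is.na(suvr) & (is.na(tracer) | tracer == "none")
  if (any(bad)) {
    stop_klsnet("SUVR given without a tracer ('FBP' or 'FBB')",
                "klsnet_config_error")
  }
  out <- rep("unknown", n)
  pet <- is.na(abeta42) & !is.na(suvr)
  out[pet] <- ifelse(suvr[pet] > .SUVR_CUTOFF[tracer[pet]], "Apos", "Aneg")
  csf <- !is.na(abeta42)
  out[csf] <- ifelse(abeta42[csf] < .ABETA_CUTOFF, "Apos", "Aneg")
  out
}

#' Diagnostic group from Logical Memory II, education and amyloid status
#'
#' Applies the education-stratified Logical Memory II (delayed recall)
#' cutoffs.  The education strata are 16+ years, 8-15 years and 0-7 years.
#' Cognitively-normal (CN) assignment requires amyloid negativity and a
#' score at or above the stratum's impairment threshold (9 / 5 / 3); EMCI
#' requires amyloid positivity and a score in the mild-impairment band
#' (9-11 / 5-9 / 3-6); LMCI requires amyloid positivity and a score at or
#' below 8 / 4 / 2.  Where the CN and EMCI score bands overlap numerically,
#' amyloid status decides.  Anything else is `"excluded"`.
#'
#' @param lm2 Logical Memory II score (non-negative).
#' @param education Years of education (non-negative).
#' @param amyloid `"Apos"` or `"Aneg"` (`"unknown"` is not a valid input).
#' @return Character vector: `"CN"`, `"EMCI"`, `"LMCI"` or `"excluded"`.
#' @export
#' @examples
#' assign_group_label(10, 17, "Apos") # EMCI
#' assign_group_label(3, 10, "Apos")  # LMCI
#' assign_group_label(5, 6, "Aneg")   # CN
assign_group_label <- function(lm2, education, amyloid) {
  n <- max(length(lm2), length(education), length(amyloid))
  lm2 <- rep_len(lm2, n); education <- rep_len(education, n)
  amyloid <- rep_len(as.character(amyloid), n)
  assert_that(all(lm2 >= 0) && all(education >= 0),
              "lm2 and education must be non-negative",
              "klsnet_validation_error")
  assert_that(all(amyloid %in% c("Apos", "Aneg")),
              "amyloid status must be known ('Apos' or 'Aneg')",
              "klsnet_validation_error")
  s <- .edu_stratum(education)
  out <- rep("excluded", n)
  neg <- amyloid == "Aneg"
  out[neg & lm2 >= .LM2_CN_MIN[s]] <- "CN"
  pos <- amyloid == "Apos"
  out[pos & lm2 >= .LM2_EMCI_LO[s] & lm2 <= .LM2_EMCI_HI[s]] <- "EMCI"
  out[pos & lm2 <= .LM2_LMCI_MAX[s]] <- "LMCI"
  out
}

# sample Logical Memory II scores consistent with an assigned group,
# given each subject's education stratum
.sample_lm2 <- function(group, stratum) {
  n <- length(stratum)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- stratum[i]
    out[i] <- switch(group,
      CN = {
        lo <- .LM2_CN_MIN[s]
        # healthy recall: concentrated a few points above the threshold
        min(25L, lo + stats::rpois(1, 6))
      },
      EMCI = sample(seq.int(.LM2_EMCI_LO[s], .LM2_EMCI_HI[s]), 1),
      LMCI = sample(seq.int(0L, .LM2_LMCI_MAX[s]), 1)
    )
  }
  out
}

.sample_lognormal_iqr <- function(n, median, q1, q3) {
  mu <- log(median)
  sdlog <- log(q3 / q1) / (2 * stats::qnorm(0.75))
  stats::rlnorm(n, mu, sdlog)
}

# one group's worth of subject records
.generate_group <- function(group, n, id_offset) {
  cal <- .group_calibration[[group]]
  mk <- function(v, lower = -Inf, upper = Inf) {
    mu <- truncnorm_match_mean(v[["mean"]], v[["sd"]], lower, upper)
    rtruncnorm_icdf(n, mu, v[["sd"]], lower, upper)
  }
  age <- mk(cal$age, 55, 90)
  sex <- ifelse(stats::runif(n) < cal$male, "M", "F")
  education <- pmin(22L, pmax(0L, round(mk(cal$education, 4, 22))))
  apoe4 <- as.integer(stats::runif(n) < cal$apoe4)
  tiv <- rtruncnorm_icdf(n, 1450, 140, 900, 2100)
  mmse <- sample(cal$mmse$values, n, replace = TRUE, prob = cal$mmse$probs)
  moca <- pmin(30L, pmax(0L, round(mk(cal$moca, 0, 30))))
  adas13 <- mk(cal$adas13, 0, 85)
  if (group == "CN") {
    abeta42 <- mk(cal$abeta42, .ABETA_CUTOFF, Inf)
  } else {
    abeta42 <- mk(cal$abeta42, 0, .ABETA_CUTOFF - 1e-6)
  }
  ptau <- .sample_lognormal_iqr(n, cal$ptau[["median"]], cal$ptau[["q1"]],
                                cal$ptau[["q3"]])
  ttau <- stats::rlnorm(n, log(cal$ttau[["median"]]), cal$ttau[["sdlog"]])
  # ~65% of subjects also have amyloid PET; SUVR is generated consistent
  # with amyloid status but the CSF value remains definitive
  has_pet <- stats::runif(n) < 0.65
  tracer <- ifelse(has_pet, ifelse(stats::runif(n) < 0.5, "FBP", "FBB"),
                   "none")
  cut <- ifelse(tracer == "none", NA_real_, .SUVR_CUTOFF[tracer])
  suvr <- rep(NA_real_, n)
  if (group == "CN") {
    suvr[has_pet] <- rtruncnorm_icdf(sum(has_pet), 1.00, 0.06,
                                     0.8, cut[has_pet])
  } else {
    suvr[has_pet] <- rtruncnorm_icdf(sum(has_pet), 1.30, 0.10,
                                     cut[has_pet] + 1e-6, 2.2)
  }
  stratum <- .edu_stratum(education)
  lm2 <- .sample_lm2(group, stratum)
  amyloid <- assign_amyloid_status(abeta42, suvr, tracer)
  data.frame(
    subject_id = sprintf("S%04d", id_offset + seq_len(n)),
    group = rep(group, n), age = age, sex = sex, education = as.integer(education),
    apoe4 = apoe4, tiv = tiv, mmse = as.integer(mmse),
    moca = as.integer(moca), adas13 = adas13, lm2 = as.integer(lm2),
    abeta42 = abeta42, ptau = ptau, ttau = ttau, suvr = suvr,
    tracer = tracer, amyloid = amyloid,
    stringsAsFactors = FALSE
  )
}

#' Generate a calibrated synthetic cohort
#'
#' Draws per-group demographics, cognition and fluid biomarkers from
#' distributions calibrated to the study's group summary table (means/SDs
#' for normal-like variables, median/IQR matching for MMSE and p-tau,
#' printed frequencies for sex and APOE e4).  Amyloid status and group
#' labels of every generated record are self-consistent under
#' [assign_amyloid_status()] and [assign_group_label()] (this is asserted
#' internally).
#'
#' @param n_cn,n_emci,n_lmci Group sizes; defaults are the study sizes
#'   (67 / 83 / 58, total 208).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `data.frame` (class `klsnet_cohort`) with one row per subject
#'   and columns `subject_id, group, age, sex, education, apoe4, tiv, mmse,
#'   moca, adas13, lm2, abeta42, ptau, ttau, suvr, tracer, amyloid`.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort) # 208
#' table(cohort$group)
generate_cohort <- function(n_cn = 67L, n_emci = 83L, n_lmci = 58L,
                            seed = 1L) {
  ns <- c(CN = n_cn, EMCI = n_emci, LMCI = n_lmci)
  assert_that(all(ns >= 0) && all(ns == floor(ns)),
              "group sizes must be non-negative integers",
              "klsnet_argument_error")
  set.seed(derive_seed(seed, "cohort"))
  parts <- list()
  offset <- 0L
  for (g in names(ns)) {
    if (ns[[g]] > 0) {
      parts[[g]] <- .generate_group(g, ns[[g]], offset)
      offset <- offset + as.integer(ns[[g]])
    }
  }
  cohort <- if (length(parts)) do.call(rbind, c(parts, make.row.names = FALSE))
  else .generate_group("CN", 0L, 0L)
  # self-consistency of the labeling rules
  if (nrow(cohort)) {
    relabel <- assign_group_label(cohort$lm2, cohort$education,
                                  cohort$amyloid)
    stopifnot(identical(relabel, cohort$group))
  }
  class(cohort) <- c("klsnet_cohort", "data.frame")
  cohort
}

# ---------------------------------------------------------------------------
# ROI-level morphometric sample generation
# ---------------------------------------------------------------------------

# metric value scales: plausible units for each morphometric measure
.metric_scale <- list(
  GMV = c(lo = 0.30, hi = 0.80),  # gray-matter density (a.u.)
  CT  = c(lo = 1.80, hi = 3.40),  # cortical thickness (mm)
  SD  = c(lo = 5.0,  hi = 25.0),  # sulcal depth (mm)
  FD  = c(lo = 2.20, hi = 2.60),  # fractal dimension
  GI  = c(lo = 1.50, hi = 3.50)   # gyrification index
)

# deterministic per-ROI baseline means: low-discrepancy spread over the
# metric's value range so ROI densities differ without an RNG draw
.roi_base_means <- function(labels, metric) {
  sc <- .metric_scale[[metric]]
  phi <- (sqrt(5) - 1) / 2
  frac <- (seq_along(labels) * phi) %% 1
  stats::setNames(sc[["lo"]] + 0.2 * (sc[["hi"]] - sc[["lo"]]) +
                  0.6 * (sc[["hi"]] - sc[["lo"]]) * frac, labels)
}

#' Effect configuration for the synthetic ROI-sample generator
#'
#' Encodes where and how strongly the diagnostic groups differ in the
#' synthetic world: which ROIs carry atrophy, the standardized group mean
#' shifts (Cohen's d units of the between-subject SD; negative = atrophy),
#' the slope coupling regional value to ADAS-Cog-13, and sampling scales.
#'
#' Defaults mirror the qualitative post-hoc pattern of the study: for GMV,
#' bilateral hippocampus plus left thalamus with EMCI -0.3 SD and LMCI
#' -0.8 SD; for CT, left entorhinal / isthmus-cingulate / supramarginal
#' with EMCI 0 and LMCI -0.6 SD.  These are package defaults, not reported
#' quantities.
#'
#' @param metric Morphometric metric the config applies to.
#' @param affected_rois Character vector of ROI labels carrying the group
#'   effect; `NULL` uses the metric-specific default panel.
#' @param effect_size_emci,effect_size_lmci Standardized mean shifts.
#' @param cognition_coupling ADAS-Cog-13 points per unit of mean affected
#'   regional value (negative: atrophy worsens cognition).
#' @param noise_sd Residual SD of the regenerated ADAS-Cog-13 (points).
#' @param samples_per_roi_mean Poisson mean of per-ROI sample counts;
#'   default 500 for voxel-based GMV, 300 for surface metrics.
#' @param between_sd_frac,within_sd_frac Between-subject and within-ROI
#'   SDs as fractions of the metric's value range.
#' @param seed Integer seed for the sample draw.
#' @return List of class `klsnet_effect_config`.
#' @export
effect_config <- function(metric = c("GMV", "CT", "SD", "FD", "GI"),
                          affected_rois = NULL,
                          effect_size_emci = NULL,
                          effect_size_lmci = NULL,
                          cognition_coupling = NULL,
                          noise_sd = 3,
                          samples_per_roi_mean = NULL,
                          between_sd_frac = 0.06,
                          within_sd_frac = 0.12,
                          seed = 1L) {
  metric <- match.arg(metric)
  atlas <- metric_atlas(metric)
  if (is.null(affected_rois)) {
    affected_rois <- if (metric == "GMV") {
      c("Hippocampus_L", "Hippocampus_R", "Thalamus_L")
    } else if (metric == "CT") {
      c("lh_entorhinal", "lh_isthmuscingulate", "lh_supramarginal")
    } else character(0)
  }
  if (is.null(effect_size_emci)) {
    effect_size_emci <- if (metric == "GMV") -0.3 else 0.0
  }
  if (is.null(effect_size_lmci)) {
    effect_size_lmci <- if (metric == "GMV") -0.8 else
      if (metric == "CT") -0.6 else 0.0
  }
  if (is.null(samples_per_roi_mean)) {
    samples_per_roi_mean <- if (atlas == "AAL116") 500 else 300
  }
  if (is.null(cognition_coupling)) {
    sc <- .metric_scale[[metric]]
    # about -3 ADAS points per between-subject SD of regional value
    cognition_coupling <- -3 / (between_sd_frac * (sc[["hi"]] - sc[["lo"]]))
  }
  assert_that(noise_sd > 0, "noise_sd must be positive",
              "klsnet_config_error")
  assert_that(samples_per_roi_mean >= 10,
              "samples_per_roi_mean must be >= min_samples (10)",
              "klsnet_config_error")
  structure(list(
    metric = metric, atlas = atlas, affected_rois = affected_rois,
    effect_size_emci = effect_size_emci, effect_size_lmci = effect_size_lmci,
    cognition_coupling = cognition_coupling, noise_sd = noise_sd,
    samples_per_roi_mean = samples_per_roi_mean,
    between_sd_frac = between_sd_frac, within_sd_frac = within_sd_frac,
    seed = as.integer(seed)
  ), class = "klsnet_effect_config")
}

#' Generate per-subject ROI morphometric samples
#'
#' For every subject and ROI, draws voxel-/vertex-like values from a
#' subject-specific Gaussian.  The subject's ROI mean is the ROI baseline
#' plus a group shift (in `cfg` effect-size units of the between-subject
#' SD, applied in `cfg$affected_rois` only) plus a subject random effect.
#' ADAS-Cog-13 in the returned cohort is regenerated as the group baseline
#' plus `cognition_coupling` times the subject's deviation in mean affected
#' regional value plus noise, so atrophy and cognition are coupled with the
#' correct sign.
#'
#' @param cohort A `klsnet_cohort` data frame.
#' @param metric Morphometric metric to simulate.
#' @param cfg An [effect_config()]; its `metric` must agree.
#' @param rois Optional character subset of atlas labels to generate
#'   (desk-scale runs); default all labels of the metric's atlas.
#' @return List of class `klsnet_roi_samples` with elements `samples`
#'   (long `data.table`: subject_id, atlas, roi_label, value), `metric`,
#'   `atlas`, `cohort` (copy with regenerated ADAS-Cog-13), `config`.
#' @export
generate_roi_samples <- function(cohort, metric = "GMV",
                                 cfg = effect_config(metric),
                                 rois = NULL) {
  assert_that(nrow(cohort) > 0, "cohort must be non-empty",
              "klsnet_argument_error")
  metric <- match.arg(metric, names(.metric_scale))
  stopifnot(identical(cfg$metric, metric))
  atlas <- metric_atlas(metric)
  labels <- atlas_labels(atlas)
  if (length(cfg$affected_rois)) {
    unknown <- setdiff(cfg$affected_rois, labels)
    if (length(unknown)) {
      stop_klsnet(sprintf("unknown ROI label(s) in effect config: %s",
                          paste(unknown, collapse = ", ")),
                  "klsnet_config_error")
    }
  }
  if (is.null(rois)) rois <- labels
  unknown <- setdiff(rois, labels)
  if (length(unknown)) {
    stop_klsnet(sprintf("unknown ROI label(s): %s",
                        paste(unknown, collapse = ", ")),
                "klsnet_config_error")
  }
  sc <- .metric_scale[[metric]]
  rng <- sc[["hi"]] - sc[["lo"]]
  sd_b <- cfg$between_sd_frac * rng   # between-subject SD of ROI means
  sd_w <- cfg$within_sd_frac * rng    # within-ROI sample SD
  base <- .roi_base_means(labels, metric)[rois]
  shift <- c(CN = 0, EMCI = cfg$effect_size_emci,
             LMCI = cfg$effect_size_lmci) * sd_b

  set.seed(derive_seed(cfg$seed, paste0("roi_", metric)))
  nsub <- nrow(cohort)
  nroi <- length(rois)
  # subject x ROI mean matrix
  grp <- as.character(cohort$group)
  mu <- matrix(rep(base, each = nsub), nsub, nroi,
               dimnames = list(cohort$subject_id, rois))
  aff <- rois %in% cfg$affected_rois
  if (any(aff)) mu[, aff] <- mu[, aff] + shift[grp]
  mu <- mu + matrix(stats::rnorm(nsub * nroi, 0, sd_b), nsub, nroi)

  counts <- matrix(pmax(10L, stats::rpois(nsub * nroi,
                                          cfg$samples_per_roi_mean)),
                   nsub, nroi)
  total <- sum(counts)
  values <- stats::rnorm(total,
                         mean = rep(as.vector(t(mu)), as.vector(t(counts))),
                         sd = sd_w)
  samples <- data.table::data.table(
    subject_id = rep(cohort$subject_id, rowSums(counts)),
    atlas = atlas,
    roi_label = rep(rep(rois, nsub), as.vector(t(counts))),
    value = values
  )

  out_cohort <- cohort
  if (any(aff)) {
    dev <- rowMeans(mu[, aff, drop = FALSE]) -
      (mean(base[aff]) + shift[grp])
    grp_base <- vapply(grp, function(g)
      .group_calibration[[g]]$adas13[["mean"]], numeric(1))
    adas <- grp_base + cfg$cognition_coupling * dev +
      stats::rnorm(nsub, 0, cfg$noise_sd)
    out_cohort$adas13 <- pmax(0, adas)
  }
  structure(list(samples = samples, metric = metric, atlas = atlas,
                 cohort = out_cohort, config = cfg),
            class = "klsnet_roi_samples")
}

#' Extract one subject's ROI sample set
#'
#' @param roi_samples A `klsnet_roi_samples` object or its long
#'   `data.table`.
#' @param subject_id Subject identifier.
#' @param metric,atlas Metric/atlas tags when a bare table is given.
#' @return List of class `klsnet_sample_set`: `subject_id`, `metric`,
#'   `atlas`, `samples` (named list ROI label -> numeric vector).
#' @export
subject_sample_set <- function(roi_samples, subject_id,
                               metric = NULL, atlas = NULL) {
  if (inherits(roi_samples, "klsnet_roi_samples")) {
    metric <- roi_samples$metric
    atlas <- roi_samples$atlas
    tab <- roi_samples$samples
  } else {
    tab <- data.table::as.data.table(roi_samples)
  }
  idx <- which(tab[["subject_id"]] == subject_id)
  sub <- tab[idx, ]
  assert_that(nrow(sub) > 0,
              sprintf("no samples for subject '%s'", subject_id),
              "klsnet_validation_error")
  samples <- split(sub$value, sub$roi_label)
  roi_sample_set(subject_id, metric, atlas, samples)
}

#' Construct an ROI sample set
#'
#' @param subject_id Subject identifier.
#' @param metric,atlas Metric and atlas tags (may be `NULL` for ad-hoc
#'   sets used outside the atlas contracts).
#' @param samples Named list mapping ROI label to a numeric vector of
#'   morphometric samples (all finite, length >= 10).
#' @return List of class `klsnet_sample_set`.
#' @export
roi_sample_set <- function(subject_id, metric, atlas, samples) {
  assert_that(is.list(samples) && length(samples) > 0 &&
                !is.null(names(samples)),
              "samples must be a non-empty named list",
              "klsnet_validation_error")
  fin <- vapply(samples, function(v) all(is.finite(v)), logical(1))
  assert_that(all(fin), "all sample values must be finite",
              "klsnet_validation_error")
  structure(list(subject_id = subject_id, metric = metric, atlas = atlas,
                 samples = samples), class = "klsnet_sample_set")
}

# ---------------------------------------------------------------------------
# Cohort / sample I/O
# ---------------------------------------------------------------------------

.cohort_columns <- c("subject_id", "group", "age", "sex", "education",
                     "apoe4", "tiv", "mmse", "moca", "adas13", "lm2",
                     "abeta42", "ptau", "ttau", "suvr", "tracer", "amyloid")

#' Write a cohort and its ROI sample tables to disk
#'
#' Emits `cohort.csv` plus one `roi_samples_<metric>.tsv` long-format file
#' per supplied metric.  Files round-trip losslessly through
#' [read_cohort()] / [read_roi_samples()].
#'
#' @param cohort A `klsnet_cohort` data frame.
#' @param roi_samples A single `klsnet_roi_samples` object, a list of
#'   them, or `NULL`.
#' @param directory Output directory (created if missing).
#' @return Invisibly, the character vector of file paths written.
#' @export
write_cohort <- function(cohort, roi_samples = NULL, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory, "cohort.csv")
  df <- as.data.frame(cohort)[, .cohort_columns, drop = FALSE]
  ok <- tryCatch({
    data.table::fwrite(df, paths[1], na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_klsnet(sprintf("failed writing '%s': %s", paths[1],
                        conditionMessage(ok)), "klsnet_io_error")
  }
  if (!is.null(roi_samples)) {
    if (inherits(roi_samples, "klsnet_roi_samples")) {
      roi_samples <- list(roi_samples)
    }
    for (rs in roi_samples) {
      p <- file.path(directory,
                     sprintf("roi_samples_%s.tsv", rs$metric))
      data.table::fwrite(rs$samples, p, sep = "\t")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read a cohort table written by [write_cohort()]
#' @param path Path to `cohort.csv`.
#' @return A `klsnet_cohort` data frame.
#' @export
read_cohort <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              "klsnet_io_error")
  df <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "group", "sex", "tracer", "amyloid")),
    na.strings = "")
  data.table::setDF(df)
  missing <- setdiff(.cohort_columns, names(df))
  assert_that(length(missing) == 0,
              sprintf("cohort file missing column(s): %s",
                      paste(missing, collapse = ", ")),
              "klsnet_validation_error")
  df <- df[, .cohort_columns]
  for (col in c("education", "apoe4", "mmse", "moca", "lm2")) {
    df[[col]] <- as.integer(df[[col]])
  }
  if (nrow(df) == 0) df$suvr <- numeric(0)
  class(df) <- c("klsnet_cohort", "data.frame")
  df
}

#' Read a long-format ROI sample table
#' @param path Path to a `roi_samples_<metric>.tsv` file.
#' @param metric Metric tag; inferred from the filename when `NULL`.
#' @return A `klsnet_roi_samples` object (without cohort attachment).
#' @export
read_roi_samples <- function(path, metric = NULL) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              "klsnet_io_error")
  if (is.null(metric)) {
    m <- regmatches(basename(path),
                    regexec("roi_samples_([A-Z]+)\\.tsv", basename(path)))[[1]]
    assert_that(length(m) == 2, "cannot infer metric from filename",
                "klsnet_io_error")
    metric <- m[2]
  }
  tab <- data.table::fread(path, colClasses = list(
    character = c("subject_id", "atlas", "roi_label")))
  structure(list(samples = tab, metric = metric,
                 atlas = if (nrow(tab)) tab$atlas[1] else
                   metric_atlas(metric),
                 cohort = NULL, config = NULL),
            class = "klsnet_roi_samples")
}
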