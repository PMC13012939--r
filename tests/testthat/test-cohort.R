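test_that("amyloid status follows the CSF-definitive rule set", {
  # CSF below / above cutoff
  expect_equal(assign_amyloid_status(150), "Apos")
  expect_equal(assign_amyloid_status(231.97, 1.20, "FBP"), "Aneg")
  # PET-only, strictly-above rule per tracer
  expect_equal(assign_amyloid_status(NA, 1.08, "FBB"), "Aneg")
  expect_equal(assign_amyloid_status(NA, 1.081, "FBB"), "Apos")
  expect_equal(assign_amyloid_status(NA, 1.11, "FBP"), "Aneg")
  expect_equal(assign_amyloid_status(NA, 1.12, "FBP"), "Apos")
  # CSF overrides PET in both directions
  expect_equal(assign_amyloid_status(150, 1.00, "FBP"), "Apos")
  expect_equal(assign_amyloid_status(NA, NA, "none"), "unknown")
  expect_error(assign_amyloid_status(NA, 1.2, "none"),
               class = "klsnet_config_error")
  # vectorized
  expect_equal(assign_amyloid_status(c(150, 250), c(NA, NA),
                                     c("none", "none")),
               c("Apos", "Aneg"))
})

test_that("group labels apply education-stratified LM-II cutoffs", {
  expect_equal(assign_group_label(10, 17, "Apos"), "EMCI")
  expect_equal(assign_group_label(3, 10, "Apos"), "LMCI")
  expect_equal(assign_group_label(5, 6, "Aneg"), "CN")
  # overlap band: amyloid status decides
  expect_equal(assign_group_label(10, 17, "Aneg"), "CN")
  # A+ above the EMCI band is excluded; A- below the CN threshold too
  expect_equal(assign_group_label(20, 17, "Apos"), "excluded")
  expect_equal(assign_group_label(2, 17, "Aneg"), "excluded")
  expect_error(assign_group_label(5, 10, "unknown"),
               class = "klsnet_validation_error")
})

test_that("labeling is total: exactly one outcome on the full grid", {
  outcomes <- c("CN", "EMCI", "LMCI", "excluded")
  for (edu in c(6, 10, 17)) {
    for (amy in c("Apos", "Aneg")) {
      lab <- assign_group_label(0:25, rep(edu, 26), rep(amy, 26))
      expect_true(all(lab %in% outcomes))
      expect_length(lab, 26)
    }
  }
  # each stratum's bands cover the A+ side contiguously below the EMCI top
  for (edu in c(17, 10, 6)) {
    top <- c(`17` = 11, `10` = 9, `6` = 6)[[as.character(edu)]]
    lab <- assign_group_label(0:top, rep(edu, top + 1),
                              rep("Apos", top + 1))
    expect_true(all(lab %in% c("EMCI", "LMCI")))
  }
})

test_that("generate_cohort returns study-sized, self-consistent cohorts", {
  co <- generate_cohort(seed = 1)
  expect_equal(nrow(co), 208)
  expect_equal(as.vector(table(co$group)[c("CN", "EMCI", "LMCI")]),
               c(67, 83, 58))
  # invariants
  expect_true(all(co$age >= 55 & co$age <= 90))
  expect_true(all(co$apoe4 %in% 0:1))
  expect_true(all(co$mmse >= 0 & co$mmse <= 30))
  expect_true(all(co$moca >= 0 & co$moca <= 30))
  expect_true(all(co$tiv > 0) && all(co$education >= 0))
  # labels self-consistent under the labeling rules
  expect_identical(assign_group_label(co$lm2, co$education, co$amyloid),
                   co$group)
  expect_identical(assign_amyloid_status(co$abeta42, co$suvr, co$tracer),
                   co$amyloid)
  # determinism and empty case
  expect_identical(co, generate_cohort(seed = 1))
  expect_false(identical(co, generate_cohort(seed = 2)))
  expect_equal(nrow(generate_cohort(0, 0, 0, seed = 1)), 0)
})

test_that("large-n group means match the calibration targets (2 SE)", {
  n <- 10000L
  co <- generate_cohort(n, n, n, seed = 7)
  targets <- list(
    CN   = c(age = 71.48, moca = 26.28, adas13 = 8.62, abeta42 = 231.97,
             education = 16.76),
    EMCI = c(age = 72.78, moca = 23.69, adas13 = 13.56, abeta42 = 143.06,
             education = 16.35),
    LMCI = c(age = 72.00, moca = 21.64, adas13 = 20.06, abeta42 = 131.40,
             education = 16.67)
  )
  sds <- list(
    CN   = c(age = 5.93, moca = 2.56, adas13 = 4.51, abeta42 = 23.31,
             education = 2.58),
    EMCI = c(age = 6.78, moca = 3.22, adas13 = 5.06, abeta42 = 25.27,
             education = 2.76),
    LMCI = c(age = 7.20, moca = 3.16, adas13 = 6.63, abeta42 = 23.03,
             education = 2.66)
  )
  for (g in names(targets)) {
    sub <- co[co$group == g, ]
    for (v in names(targets[[g]])) {
      se <- sds[[g]][[v]] / sqrt(n)
      expect_lt(abs(mean(sub[[v]]) - targets[[g]][[v]]), 2 * se,
                label = sprintf("|%s %s mean - target|", g, v))
    }
  }
  # printed frequencies (3 SE binomial)
  tgt_male <- c(CN = 0.507, EMCI = 0.614, LMCI = 0.483)
  tgt_apoe <- c(CN = 0.134, EMCI = 0.578, LMCI = 0.741)
  for (g in names(tgt_male)) {
    sub <- co[co$group == g, ]
    se <- sqrt(tgt_male[[g]] * (1 - tgt_male[[g]]) / n)
    expect_lt(abs(mean(sub$sex == "M") - tgt_male[[g]]), 3 * se)
    se <- sqrt(tgt_apoe[[g]] * (1 - tgt_apoe[[g]]) / n)
    expect_lt(abs(mean(sub$apoe4) - tgt_apoe[[g]]), 3 * se)
  }
  # median/IQR-matched variables hit the printed quantiles
  cn <- co[co$group == "CN", ]
  lmci <- co[co$group == "LMCI", ]
  expect_equal(unname(quantile(cn$mmse, c(0.25, 0.5, 0.75))),
               c(29, 30, 30))
  expect_equal(unname(quantile(lmci$mmse, c(0.25, 0.5, 0.75))),
               c(26, 28, 29))
  expect_lt(abs(median(cn$ptau) - 27.60) / 27.60, 0.02)
  expect_lt(abs(median(lmci$ptau) - 53.00) / 53.00, 0.02)
})

test_that("ROI sample generation is deterministic and validates config", {
  co <- generate_cohort(3, 3, 3, seed = 2)
  cfg <- effect_config("GMV", seed = 4, samples_per_roi_mean = 30)
  rois <- c("Hippocampus_L", "Precuneus_R", "Thalamus_L")
  a <- generate_roi_samples(co, "GMV", cfg, rois = rois)
  b <- generate_roi_samples(co, "GMV", cfg, rois = rois)
  expect_identical(a$samples, b$samples)
  expect_identical(a$cohort, b$cohort)
  expect_setequal(unique(a$samples$roi_label), rois)
  expect_true(all(is.finite(a$samples$value)))
  bad <- effect_config("GMV", affected_rois = "No_Such_Region")
  expect_error(generate_roi_samples(co, "GMV", bad),
               class = "klsnet_config_error")
  expect_error(generate_roi_samples(co[0, ], "GMV", cfg),
               class = "klsnet_argument_error")
})

test_that("injected atrophy orders group means and couples to cognition", {
  co <- generate_cohort(200, 200, 200, seed = 11)
  cfg <- effect_config("GMV", seed = 11, samples_per_roi_mean = 50)
  rd <- generate_roi_samples(co, "GMV", cfg, rois = "Hippocampus_L")
  m <- tapply(rd$samples$value, rd$samples$subject_id, mean)[co$subject_id]
  gm <- tapply(m, co$group, mean)
  expect_gt(gm[["CN"]], gm[["EMCI"]])
  expect_gt(gm[["EMCI"]], gm[["LMCI"]])
  # regenerated ADAS-Cog-13 correlates negatively with regional value
  # within group (the coupling), and group means stay near calibration
  cn <- co$group == "CN"
  expect_lt(cor(m[cn], rd$cohort$adas13[cn]), -0.3)
  expect_lt(abs(mean(rd$cohort$adas13[cn]) - 8.62), 1)
})

test_that("null effect config gives nominal two-sample rejection rate", {
  cfg0 <- effect_config("GMV", effect_size_emci = 0, effect_size_lmci = 0,
                        samples_per_roi_mean = 10)
  rej <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(15, 15, 0, seed = 1000 + s)
    cfg <- effect_config("GMV", effect_size_emci = 0,
                         effect_size_lmci = 0, samples_per_roi_mean = 10,
                         seed = 1000 + s)
    rd <- generate_roi_samples(co, "GMV", cfg, rois = "Hippocampus_L")
    m <- tapply(rd$samples$value, rd$samples$subject_id,
                mean)[co$subject_id]
    p <- t.test(m[co$group == "CN"], m[co$group == "EMCI"])$p.value
    rej <- rej + (p < 0.05)
  }
  # Binomial(100, 0.05): reject the null behavior only far outside range
  expect_lte(rej, 13)
})

test_that("cohort and ROI samples round-trip through disk", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(4, 4, 4, seed = 3)
  cfg <- effect_config("CT", seed = 5, samples_per_roi_mean = 15)
  rd <- generate_roi_samples(co, "CT", cfg,
                             rois = c("lh_entorhinal", "rh_insula"))
  paths <- write_cohort(rd$cohort, rd, dir)
  expect_true(all(file.exists(paths)))
  co2 <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(as.data.frame(co2), as.data.frame(rd$cohort),
               tolerance = 1e-12)
  rd2 <- read_roi_samples(file.path(dir, "roi_samples_CT.tsv"))
  expect_equal(rd2$metric, "CT")
  expect_equal(as.data.frame(rd2$samples), as.data.frame(rd$samples),
               tolerance = 1e-12)
  # empty cohort: valid header-only file
  p0 <- write_cohort(generate_cohort(0, 0, 0), NULL, dir)
  co0 <- read_cohort(p0[1])
  expect_equal(nrow(co0), 0)
  expect_error(read_cohort(file.path(dir, "nope.csv")),
               class = "klsnet_io_error")
})
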