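make_groups <- function(n_per) rep(c("CN", "EMCI", "LMCI"), each = n_per)

test_that("ANCOVA reduces to one-way ANOVA without covariates", {
  set.seed(1)
  g <- make_groups(20)
  y <- rnorm(60) + (g == "LMCI") * 0.5
  a <- ancova_group_effect(y, g, covariates = NULL)
  expect_equal(a$f_stat, oracle_anova_f(y, g), tolerance = 1e-8)
  # partial eta2 recomputable from the F statistic
  eta_from_f <- a$f_stat * a$df1 / (a$f_stat * a$df1 + a$df2)
  expect_equal(a$partial_eta2, eta_from_f, tolerance = 1e-10)
})

test_that("ANCOVA with covariates matches the lm/anova reference", {
  set.seed(2)
  g <- make_groups(25)
  cov <- data.frame(age = rnorm(75, 72, 6),
                    sex = sample(c("M", "F"), 75, TRUE),
                    education = rnorm(75, 16, 2))
  y <- rnorm(75) + 0.1 * cov$age + (g == "EMCI") * 0.8
  a <- ancova_group_effect(y, g, cov)
  full <- lm(y ~ age + sex + education + factor(g, levels = unique(g)),
             data = cov)
  red <- lm(y ~ age + sex + education, data = cov)
  ref <- anova(red, full)
  expect_equal(a$f_stat, ref$F[2], tolerance = 1e-8)
  expect_equal(a$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
  # adjusted means are at covariate grand means
  expect_equal(mean(a$adjusted_means), mean(y), tolerance = 1e-10)
})

test_that("identical groups give null effect; shifted group is detected", {
  y <- rep(c(1.3, 2.1, 0.7, 1.8, 1.1), 3)
  g <- make_groups(5)
  a <- ancova_group_effect(y, g, NULL)
  expect_equal(a$f_stat, 0, tolerance = 1e-12)
  expect_equal(a$p, 1, tolerance = 1e-12)
  expect_equal(a$partial_eta2, 0, tolerance = 1e-12)
  set.seed(3)
  g2 <- make_groups(200)
  y2 <- rnorm(600) + (g2 == "LMCI")
  expect_lt(ancova_group_effect(y2, g2, NULL)$p, 0.001)
})

test_that("rank-deficient designs name the collinear column", {
  set.seed(4)
  g <- make_groups(10)
  cov <- data.frame(a = rnorm(30))
  cov$b <- 2 * cov$a
  expect_error(ancova_group_effect(rnorm(30), g, cov), "collinear",
               class = "klsnet_rank_error")
})

test_that("post-hoc contrasts use adjusted pooled-SD Cohen's d", {
  # CN={0,1,2}, EMCI={1,2,3}, LMCI={2,3,4}: residual SD exactly 1
  y <- c(0, 1, 2, 1, 2, 3, 2, 3, 4)
  g <- make_groups(3)
  a <- ancova_group_effect(y, g, NULL)
  ph <- a$pairwise
  expect_equal(ph$cohens_d[ph$pair == "CN-EMCI"], -1)
  expect_equal(ph$cohens_d[ph$pair == "CN-LMCI"], -2)
  expect_equal(ph$cohens_d[ph$pair == "EMCI-LMCI"], -1)
  # Bonferroni: 3 * p capped at 1
  expect_equal(ph$p_bonf, pmin(1, 3 * ph$p_raw))
  # sign convention: d is antisymmetric in the contrast direction
  expect_equal(ph$diff[ph$pair == "CN-LMCI"], -2)
})

test_that("BH adjustment matches the naive oracle exactly", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(5)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(c(1, 3), 1)
    adj <- fdr_adjust(p)
    expect_identical(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    # monotone: ordering of adjusted p follows ordering of raw p
    expect_true(all(diff(adj[order(p)]) >= 0))
  }
  # also agrees with the independent stats reference
  set.seed(6)
  p <- runif(200)
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"), tolerance = 1e-14)
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "klsnet_validation_error")
})

test_that("edgewise ANCOVA covers every unique pair with FDR", {
  set.seed(7)
  n <- 18
  g <- make_groups(6)
  mats68 <- lapply(1:n, function(i) random_similarity(68, seed = 700 + i))
  cov <- data.frame(age = rnorm(n, 72, 6), sex = sample(c("M", "F"), n,
                                                        TRUE))
  e68 <- edgewise_stats(mats68, g, cov, include_tiv = FALSE)
  expect_equal(nrow(e68), 68 * 67 / 2)  # 2278
  expect_true(all(e68$p_fdr >= e68$p - 1e-15))
  # null data: no FDR-significant edges expected
  expect_equal(sum(e68$p_fdr < 0.05), 0)
  # one random edge must match the scalar ANCOVA route
  i <- 321
  yv <- vapply(mats68, function(m) m$values[e68$roi_i[i], e68$roi_j[i]],
               numeric(1))
  a <- ancova_group_effect(yv, g, cov, include_tiv = FALSE)
  expect_equal(e68$f[i], a$f_stat, tolerance = 1e-10)
  expect_equal(e68$partial_eta2[i], a$partial_eta2, tolerance = 1e-10)
  expect_equal(e68$d_CN_LMCI[i],
               a$pairwise$cohens_d[a$pairwise$pair == "CN-LMCI"],
               tolerance = 1e-10)
  # seed-ROI filter keeps only touching edges
  seed_rois <- c("R001", "R002")
  ef <- edgewise_stats(mats68, g, cov, include_tiv = FALSE,
                       seed_rois = seed_rois)
  expect_true(all(ef$roi_i %in% seed_rois | ef$roi_j %in% seed_rois))
  expect_equal(nrow(ef), 67 + 66)
  # label mismatch
  bad <- mats68
  bad[[2]] <- random_similarity(10, seed = 1)
  expect_error(edgewise_stats(bad, g, cov),
               class = "klsnet_validation_error")
})

test_that("116-node edgewise table has 6670 rows", {
  set.seed(8)
  n <- 12
  g <- rep(c("CN", "EMCI", "LMCI"), each = 4)
  mats <- lapply(1:n, function(i) random_similarity(116, seed = 800 + i))
  e <- edgewise_stats(mats, g, NULL)
  expect_equal(nrow(e), 6670)
})

test_that("correlations: plain, partial and degenerate cases", {
  set.seed(9)
  x <- rnorm(200)
  out <- correlate_with_outcomes(data.frame(f = x),
                                 data.frame(o = 2 * x))
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_lt(out$p, 1e-10)
  # independent variables
  out2 <- correlate_with_outcomes(data.frame(f = rnorm(1000)),
                                  data.frame(o = rnorm(1000)))
  expect_lt(abs(out2$r), 0.1)
  # partial correlation removes a shared driver
  z <- rnorm(500)
  out3 <- correlate_with_outcomes(data.frame(f = z),
                                  data.frame(o = z + rnorm(500)),
                                  covariates = data.frame(z = z))
  expect_lt(abs(out3$r), 0.1)
  expect_true(out3$partial)
  # matches R's residualization-based partial r
  a <- rnorm(300); b <- a * 0.5 + rnorm(300); cc <- rnorm(300) + a
  out4 <- correlate_with_outcomes(data.frame(f = b), data.frame(o = cc),
                                  covariates = data.frame(z = a))
  ref <- cor(resid(lm(b ~ a)), resid(lm(cc ~ a)))
  expect_equal(out4$r, ref, tolerance = 1e-10)
  # zero-variance feature flagged, not an error
  out5 <- correlate_with_outcomes(data.frame(f = rep(1, 10)),
                                  data.frame(o = rnorm(10)))
  expect_true(is.na(out5$r))
  # FDR across the family
  set.seed(10)
  fam <- correlate_with_outcomes(as.data.frame(matrix(rnorm(500), 50)),
                                 data.frame(o = rnorm(50)))
  expect_true(all(fam$p_fdr >= fam$p))
})

test_that("cohort summary table reports the expected rows and tests", {
  co <- generate_cohort(40, 40, 40, seed = 12)
  tab <- cohort_table(co)
  expect_true(all(c("age", "mmse", "ptau", "sex", "apoe4", "adas13")
                  %in% tab$variable))
  expect_equal(tab$test[tab$variable == "mmse"], "Kruskal-Wallis")
  expect_equal(tab$test[tab$variable == "age"], "one-way ANOVA")
  expect_equal(tab$test[tab$variable == "sex"], "chi-square")
  expect_true(all(c("CN", "EMCI", "LMCI") %in% names(tab)))
  # strong group differences in calibrated variables, none injected in age
  expect_lt(tab$p[tab$variable == "adas13"], 0.001)
  expect_lt(tab$p[tab$variable == "abeta42"], 0.001)
  # single-level categorical is skipped with a note
  co$sex <- "M"
  tab2 <- cohort_table(co)
  expect_match(tab2$test[tab2$variable == "sex"], "skipped")
  expect_true(is.na(tab2$p[tab2$variable == "sex"]))
  expect_error(cohort_table(co[co$group == "CN", ]),
               class = "klsnet_contract_error")
})

test_that("type-I error of the FDR-nodal route is controlled (null)", {
  # 60 null cohorts: 116 null "nodal" outcomes each, with covariates;
  # count cohorts with any FDR-significant node
  n_seeds <- 60
  hits <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(3000 + s)
    n <- 45
    g <- make_groups(15)
    cov <- data.frame(age = rnorm(n, 72, 6),
                      sex = sample(c("M", "F"), n, TRUE))
    Y <- matrix(rnorm(n * 116), n)
    mats <- NULL
    p <- vapply(seq_len(ncol(Y)), function(j)
      ancova_group_effect(Y[, j], g, cov, include_tiv = FALSE)$p,
      numeric(1))
    hits <- hits + any(fdr_adjust(p) < 0.05)
  }
  # Binomial(60, 0.05): P(X > 9) < 0.002
  expect_lte(hits, 9)
})

test_that("the injected hippocampal effect is recovered with covariates", {
  recovered <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(seed = 5000 + s)
    cfg <- effect_config("GMV", seed = 5000 + s, samples_per_roi_mean = 60)
    rd <- generate_roi_samples(co, "GMV", cfg, rois = "Hippocampus_L")
    m <- tapply(rd$samples$value, rd$samples$subject_id,
                mean)[co$subject_id]
    cov <- data.frame(age = co$age, sex = co$sex,
                      education = co$education, apoe4 = co$apoe4,
                      tiv = co$tiv)
    a <- ancova_group_effect(as.numeric(m), co$group, cov)
    dir_ok <- a$adjusted_means[["CN"]] > a$adjusted_means[["LMCI"]]
    recovered <- recovered + (a$p < 0.05 && dir_ok)
  }
  expect_gte(recovered / n_seeds, 0.9)
})
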