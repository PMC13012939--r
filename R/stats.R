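# ---------------------------------------------------------------------------
# Group statistics: covariate-adjusted ANCOVA with Type III group block,
# Bonferroni post-hoc contrasts with Cohen's d, Benjamini-Hochberg FDR,
# edgewise network comparisons and correlation analyses.
# ---------------------------------------------------------------------------

.GROUP_LEVELS <- c("CN", "EMCI", "LMCI")
.GROUP_PAIRS <- list(c("CN", "EMCI"), c("CN", "LMCI"), c("EMCI", "LMCI"))

# covariate model matrix (no intercept column), centered so adjusted
# means fall at covariate grand means
.covariate_matrix <- function(covariates, include_tiv = TRUE) {
  if (is.null(covariates) || ncol(covariates) == 0) {
    return(NULL)
  }
  covariates <- as.data.frame(covariates)
  if (!include_tiv && "tiv" %in% names(covariates)) {
    covariates$tiv <- NULL
  }
  if (ncol(covariates) == 0) return(NULL)
  X <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  scale(X, center = TRUE, scale = FALSE)
}

# multi-outcome ANCOVA on a response matrix Y (subjects x outcomes):
# Type III F for the group block (full model vs covariates-only model)
.ancova_core <- function(Y, group, Xc) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  lev <- if (all(group %in% .GROUP_LEVELS))
    intersect(.GROUP_LEVELS, unique(group)) else unique(group)
  group <- factor(group, levels = lev)
  assert_that(all(table(group) >= 3), "need >= 3 subjects per group",
              "klsnet_contract_error")
  G <- stats::model.matrix(~ group)[, -1, drop = FALSE]
  Xf <- cbind(`(Intercept)` = rep(1, n), G, Xc)
  Xr <- cbind(`(Intercept)` = rep(1, n), Xc)
  qf <- qr(Xf)
  if (qf$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qf$pivot[(qf$rank + 1):ncol(Xf)]]
    stop_klsnet(sprintf("rank-deficient design; collinear column(s): %s",
                        paste(bad, collapse = ", ")),
                "klsnet_rank_error")
  }
  qr_ <- qr(Xr)
  res_f <- qr.resid(qf, Y)
  res_r <- qr.resid(qr_, Y)
  rss_f <- colSums(res_f^2)
  rss_r <- colSums(res_r^2)
  df1 <- ncol(G)
  df2 <- n - ncol(Xf)
  ss_g <- pmax(rss_r - rss_f, 0)
  fstat <- (ss_g / df1) / (rss_f / df2)
  pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  beta <- qr.coef(qf, Y)
  # covariate-adjusted values: remove the (centered) covariate part
  Yadj <- if (is.null(Xc)) Y else
    Y - Xc %*% beta[seq.int(ncol(G) + 2, ncol(Xf)), , drop = FALSE]
  list(f = fstat, p = pval, partial_eta2 = ss_g / (ss_g + rss_f),
       df1 = df1, df2 = df2, group = group, Yadj = Yadj,
       resid_sd = sqrt(rss_f / df2), n = n)
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits a linear model with two group indicators plus covariates (by
#' default age, sex, education and APOE e4 status; total intracranial
#' volume additionally for volume-derived outcomes) and reports the Type
#' III F test for the group block, partial eta squared, adjusted group
#' means at the covariate grand means, and Bonferroni-corrected pairwise
#' contrasts with Cohen's d.
#'
#' @param values Numeric outcome vector, one value per subject.
#' @param group Group labels (`"CN"`, `"EMCI"`, `"LMCI"`), >= 3 subjects
#'   per group.
#' @param covariates Data frame of covariates aligned with `values`
#'   (may be `NULL` for a plain one-way ANOVA).
#' @param include_tiv Keep a `tiv` column in the covariates?  Set `TRUE`
#'   for GMV-derived outcomes, `FALSE` otherwise.
#' @param outcome_id Label carried into the result.
#' @return List of class `klsnet_ancova`: `outcome_id`, `f_stat`, `p`,
#'   `partial_eta2`, `adjusted_means`, `pairwise` (see
#'   [posthoc_pairwise()]), degrees of freedom and `n`.
#' @export
ancova_group_effect <- function(values, group, covariates = NULL,
                                include_tiv = TRUE,
                                outcome_id = "outcome") {
  assert_that(all(is.finite(values)), "outcome contains non-finite values",
              "klsnet_validation_error")
  Xc <- .covariate_matrix(covariates, include_tiv)
  fit <- .ancova_core(matrix(values, ncol = 1), group, Xc)
  adj <- tapply(fit$Yadj[, 1], fit$group, mean)
  out <- list(outcome_id = outcome_id, f_stat = unname(fit$f),
              p = unname(fit$p), partial_eta2 = unname(fit$partial_eta2),
              adjusted_means = adj, df1 = fit$df1, df2 = fit$df2,
              n = fit$n, .fit = fit)
  out$pairwise <- posthoc_pairwise(out)
  class(out) <- "klsnet_ancova"
  out
}

#' Bonferroni post-hoc pairwise contrasts of an ANCOVA
#'
#' Two-sample pooled-variance t tests between the three group pairs on
#' covariate-adjusted values; Cohen's d is the adjusted mean difference
#' over the full-model residual SD; raw p values are Bonferroni-scaled by
#' 3 and capped at 1.
#'
#' @param model A `klsnet_ancova` (or its in-progress internals).
#' @return `data.frame` with columns `pair`, `diff`, `cohens_d`, `p_raw`,
#'   `p_bonf`.
#' @export
posthoc_pairwise <- function(model) {
  fit <- model$.fit
  assert_that(!is.null(fit), "no fitted ANCOVA internals available",
              "klsnet_contract_error")
  yadj <- fit$Yadj[, 1]
  grp <- fit$group
  sd_pool <- fit$resid_sd[1]
  pairs <- Filter(function(pr) all(pr %in% levels(grp)), .GROUP_PAIRS)
  if (!length(pairs)) pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
  n_pairs <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- yadj[grp == pr[1]]
    b <- yadj[grp == pr[2]]
    assert_that(length(a) > 0 && length(b) > 0,
                sprintf("empty group in contrast %s-%s", pr[1], pr[2]),
                "klsnet_contract_error")
    dmean <- mean(a) - mean(b)
    se <- sd_pool * sqrt(1 / length(a) + 1 / length(b))
    tt <- dmean / se
    p <- 2 * stats::pt(abs(tt), fit$df2, lower.tail = FALSE)
    data.frame(pair = paste(pr, collapse = "-"), diff = dmean,
               cohens_d = dmean / sd_pool, p_raw = p,
               p_bonf = min(1, n_pairs * p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply by `n/rank`, take
#' the running minimum from the largest rank down, cap at 1.  Output is
#' monotone in the input and never smaller than the raw p.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(pvalues) {
  assert_that(all(is.finite(pvalues)) && all(pvalues >= 0) &&
                all(pvalues <= 1),
              "p-values must lie in [0, 1]", "klsnet_validation_error")
  n <- length(pvalues)
  if (n <= 1) return(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  # multiply by the ratio n/rank (>= 1): guarantees adjusted >= raw even
  # in floating point
  pmin(1, cummin(pvalues[o] * (n / (n:1))))[ro]
}

#' Edgewise group comparison of KLS networks
#'
#' Runs one covariate-adjusted ANCOVA per unique off-diagonal ROI pair of
#' the subjects' similarity matrices (6,670 edges for 116 nodes, 2,278
#' for 68), adjusts the group-effect p-values by FDR across all edges and
#' attaches partial eta squared plus Bonferroni-corrected pairwise
#' Cohen's d per edge.
#'
#' @param matrices List of `klsnet_similarity` objects, one per subject,
#'   all sharing identical labels (subject order aligned with `group`).
#' @param group Group labels per subject.
#' @param covariates Covariate data frame per subject (or `NULL`).
#' @param include_tiv Keep `tiv` as covariate (GMV-derived networks).
#' @param seed_rois Optional ROI labels; restricts the returned table to
#'   edges touching at least one of them (FDR is still computed across
#'   all edges first).
#' @return `data.table` with one row per edge: `roi_i`, `roi_j`, `f`,
#'   `p`, `p_fdr`, `partial_eta2`, per-pair `d_*` and `p_bonf_*` columns.
#' @export
edgewise_stats <- function(matrices, group, covariates = NULL,
                           include_tiv = TRUE, seed_rois = NULL) {
  labels <- matrices[[1]]$labels
  same <- vapply(matrices, function(m) identical(m$labels, labels),
                 logical(1))
  assert_that(all(same), "all matrices must share identical labels",
              "klsnet_validation_error")
  n <- length(matrices)
  N <- length(labels)
  ut <- upper.tri(matrices[[1]]$values)
  Y <- t(vapply(matrices, function(m) m$values[ut], numeric(sum(ut))))
  ii <- row(diag(N))[ut]
  jj <- col(diag(N))[ut]
  Xc <- .covariate_matrix(covariates, include_tiv)
  fit <- .ancova_core(Y, group, Xc)
  grp <- fit$group
  out <- data.table::data.table(
    roi_i = labels[ii], roi_j = labels[jj],
    f = fit$f, p = fit$p, p_fdr = fdr_adjust(fit$p),
    partial_eta2 = fit$partial_eta2, n = n
  )
  edge_pairs <- Filter(function(pr) all(pr %in% levels(grp)), .GROUP_PAIRS)
  for (pr in edge_pairs) {
    a <- grp == pr[1]; b <- grp == pr[2]
    dmean <- colMeans(fit$Yadj[a, , drop = FALSE]) -
      colMeans(fit$Yadj[b, , drop = FALSE])
    d <- dmean / fit$resid_sd
    se <- fit$resid_sd * sqrt(1 / sum(a) + 1 / sum(b))
    praw <- 2 * stats::pt(abs(dmean / se), fit$df2, lower.tail = FALSE)
    tag <- paste(pr, collapse = "_")
    out[[paste0("d_", tag)]] <- d
    out[[paste0("p_bonf_", tag)]] <- pmin(1, 3 * praw)
  }
  if (!is.null(seed_rois)) {
    unknown <- setdiff(seed_rois, labels)
    assert_that(length(unknown) == 0,
                sprintf("unknown seed ROI(s): %s",
                        paste(unknown, collapse = ", ")),
                "klsnet_validation_error")
    out <- out[out$roi_i %in% seed_rois | out$roi_j %in% seed_rois, ]
  }
  out[]
}

#' Correlations of imaging features with cognition / biomarkers
#'
#' Pearson correlation of every feature-outcome pair, optionally partial
#' (both sides residualized on the covariates before correlating), with
#' BH-FDR adjustment across the whole tested family.  Zero-variance
#' features yield a flagged `NA` row rather than an error; missing values
#' are handled by complete-case analysis per pair.
#'
#' @param features Data frame / matrix, subjects x features.
#' @param outcomes Data frame / matrix, subjects x outcomes, row-aligned.
#' @param covariates Optional covariate data frame for partial
#'   correlations.
#' @return `data.frame`: `feature_id`, `outcome_id`, `r`, `p`, `p_fdr`,
#'   `n`, `partial`.
#' @export
correlate_with_outcomes <- function(features, outcomes,
                                    covariates = NULL) {
  features <- as.data.frame(features)
  outcomes <- as.data.frame(outcomes)
  assert_that(nrow(features) == nrow(outcomes),
              "features and outcomes must be row-aligned",
              "klsnet_validation_error")
  partial <- !is.null(covariates)
  Xc <- .covariate_matrix(covariates, include_tiv = TRUE)
  rows <- list()
  for (f in names(features)) {
    for (o in names(outcomes)) {
      x <- features[[f]]
      y <- outcomes[[o]]
      ok <- is.finite(x) & is.finite(y)
      if (partial) ok <- ok & apply(is.finite(Xc), 1, all)
      nok <- sum(ok)
      if (nok < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          feature_id = f, outcome_id = o, r = NA_real_, p = NA_real_,
          n = nok, partial = partial, stringsAsFactors = FALSE)
        next
      }
      xr <- x[ok]; yr <- y[ok]
      df_adj <- 0
      if (partial) {
        Z <- cbind(1, Xc[ok, , drop = FALSE])
        xr <- stats::lm.fit(Z, xr)$residuals
        yr <- stats::lm.fit(Z, yr)$residuals
        df_adj <- ncol(Z) - 1
      }
      r <- stats::cor(xr, yr)
      df <- nok - 2 - df_adj
      tt <- r * sqrt(df / (1 - r^2))
      p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        feature_id = f, outcome_id = o, r = r, p = p, n = nok,
        partial = partial, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- is.finite(out$p)
  out$p_fdr[ok] <- fdr_adjust(out$p[ok])
  out[, c("feature_id", "outcome_id", "r", "p", "p_fdr", "n", "partial")]
}

#' Demographic / clinical summary table with group tests
#'
#' Summarizes a cohort the way clinical papers present their first table:
#' mean +/- SD with one-way ANOVA for normal-like continuous variables,
#' median (IQR) with Kruskal-Wallis for skewed ones (MMSE, p-tau), counts
#' (percent) with a chi-square test for categorical variables.
#'
#' @param cohort A `klsnet_cohort` data frame with >= 2 groups present.
#' @return `data.frame`: `variable`, one column per group, `p`, `test`.
#' @export
cohort_table <- function(cohort) {
  grp <- factor(cohort$group, levels = intersect(.GROUP_LEVELS,
                                                 unique(cohort$group)))
  assert_that(nlevels(grp) >= 2, "need at least 2 groups",
              "klsnet_contract_error")
  fmt_mean <- function(x) sprintf("%.2f ± %.2f", mean(x),
                                  stats::sd(x))
  fmt_med <- function(x) sprintf("%.2f (%.2f, %.2f)", stats::median(x),
                                 stats::quantile(x, 0.25),
                                 stats::quantile(x, 0.75))
  fmt_cat <- function(x, lev) sprintf("%d (%.1f%%)", sum(x == lev),
                                      100 * mean(x == lev))
  spec <- list(
    age = "anova", education = "anova", moca = "anova",
    adas13 = "anova", abeta42 = "anova", ttau = "anova", tiv = "anova",
    mmse = "kruskal", ptau = "kruskal",
    sex = list(test = "chisq", level = "M"),
    apoe4 = list(test = "chisq", level = 1)
  )
  rows <- list()
  for (v in names(spec)) {
    if (!v %in% names(cohort)) next
    x <- cohort[[v]]
    s <- spec[[v]]
    if (identical(s, "anova")) {
      cells <- tapply(x, grp, fmt_mean)
      p <- summary(stats::aov(x ~ grp))[[1]][["Pr(>F)"]][1]
      test <- "one-way ANOVA"
    } else if (identical(s, "kruskal")) {
      cells <- tapply(x, grp, fmt_med)
      p <- stats::kruskal.test(x, grp)$p.value
      test <- "Kruskal-Wallis"
    } else {
      cells <- tapply(x, grp, fmt_cat, lev = s$level)
      tab <- table(x, grp)
      if (nrow(tab) < 2) {
        p <- NA_real_
        test <- "chi-square (skipped: single level)"
      } else {
        p <- suppressWarnings(stats::chisq.test(tab)$p.value)
        test <- "chi-square"
      }
    }
    row <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (g in levels(grp)) row[[g]] <- unname(cells[g])
    row$p <- p
    row$test <- test
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
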