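# ---------------------------------------------------------------------------
# End-to-end orchestration: JSON config, staged execution
# (simulate -> networks -> topology -> stats -> classify), stable file
# formats and a reproducibility manifest.
# ---------------------------------------------------------------------------

.config_defaults <- function() {
  list(
    output_dir = "klsnet_run",
    seed = 1L,
    cohort = list(n_cn = 67L, n_emci = 83L, n_lmci = 58L),
    metrics = list("GMV"),
    rois = NULL,                 # optional ROI subset for desk-scale runs
    kde = list(m = 256L, bandwidth = "botev", epsilon = 2.2e-16),
    topology = list(n_nulls = 20L),   # study value: 1000
    stats = list(fdr_alpha = 0.05),
    classifier = list(outer_folds = 10L, inner_folds = 5L,
                      n_permutations = 0L),  # study value: 5000
    stages = list(simulate = TRUE, networks = TRUE, topology = TRUE,
                  stats = TRUE, classify = TRUE)
  )
}

#' Build a validated pipeline configuration
#'
#' Merges user settings over the package defaults and rejects unknown
#' keys.  Defaults are desk-scale (20 null networks per threshold, no
#' permutation test); the study-scale values are 1000 nulls and 5000
#' permutations.
#'
#' @param ... Named top-level settings (`output_dir`, `seed`, `cohort`,
#'   `metrics`, `rois`, `kde`, `topology`, `stats`, `classifier`,
#'   `stages`); sub-lists are merged key-wise.
#' @return List of class `klsnet_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  def <- .config_defaults()
  unknown <- setdiff(names(user), names(def))
  assert_that(length(unknown) == 0,
              sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")),
              "klsnet_config_error")
  cfg <- def
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      sub <- user[[k]]
      bad <- setdiff(names(sub), names(def[[k]]))
      assert_that(length(bad) == 0,
                  sprintf("unknown config key(s) under '%s': %s", k,
                          paste(bad, collapse = ", ")),
                  "klsnet_config_error")
      cfg[[k]][names(sub)] <- sub
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg$metrics <- as.list(unlist(cfg$metrics))
  bad <- setdiff(unlist(cfg$metrics), c("GMV", "CT", "SD", "FD", "GI"))
  assert_that(length(bad) == 0,
              sprintf("unknown metric(s): %s", paste(bad, collapse = ", ")),
              "klsnet_config_error")
  assert_that(cfg$kde$m >= 16, "kde$m must be >= 16", "klsnet_config_error")
  class(cfg) <- c("klsnet_config", "list")
  cfg
}

#' Read a pipeline configuration from JSON
#' @param path Path to a JSON config file.
#' @return Validated `klsnet_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

# stable hash of the semantically meaningful config content
.config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$output_dir <- NULL   # where outputs land does not change results
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a KLS similarity matrix to TSV
#'
#' Full square matrix with a header row and a leading label column;
#' numeric cells use shortest round-trip representation, so write-read
#' is lossless.
#'
#' @param mat A `klsnet_similarity`.
#' @param path Output path (convention:
#'   `<subject>_<metric>_<atlas>.klsm.tsv`).
#' @return Invisibly, `path`.
#' @export
write_similarity_matrix <- function(mat, path) {
  n <- length(mat$labels)
  # 17 significant digits: doubles round-trip exactly
  cells <- sprintf("%.17g", mat$values)
  dim(cells) <- c(n, n)
  lines <- c(paste(c("roi", mat$labels), collapse = "\t"),
             vapply(seq_len(n), function(i)
               paste(c(mat$labels[i], cells[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a KLS similarity matrix from TSV
#'
#' Symmetry (to 1e-12), the exact unit diagonal and the (0, 1] range are
#' re-validated on read; violations raise an error naming the cell.
#'
#' @param path Path to a `.klsm.tsv` file.
#' @param metric,atlas,subject_id Optional tags (inferred from a
#'   `<subject>_<metric>_<atlas>.klsm.tsv` filename when `NULL`).
#' @return A `klsnet_similarity`.
#' @export
read_similarity_matrix <- function(path, metric = NULL, atlas = NULL,
                                   subject_id = NULL) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path),
              "klsnet_io_error")
  tab <- data.table::fread(path, sep = "\t")
  labels <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1])
  dimnames(vals) <- list(labels, colnames(vals))
  assert_that(identical(labels, colnames(vals)),
              "row and column labels disagree", "klsnet_validation_error")
  m <- regmatches(basename(path),
                  regexec("^(.*)_([A-Z]+)_([A-Z0-9]+)\\.klsm\\.tsv$",
                          basename(path)))[[1]]
  if (length(m) == 4) {
    subject_id <- subject_id %||% m[2]
    metric <- metric %||% m[3]
    atlas <- atlas %||% m[4]
  }
  new_similarity_matrix(vals, metric = metric, atlas = atlas,
                        subject_id = subject_id)
}

# default 13-feature "local imaging" panel from GMV data: affected-ROI
# mean values (3) + degree / betweenness / nodal-efficiency AUCs at the
# three seed ROIs (9) + nodal local efficiency AUC at the left thalamus
.panel_rois <- c("Hippocampus_L", "Hippocampus_R", "Thalamus_L")

.assemble_features <- function(cohort, roi_data, topo_list) {
  sub <- cohort$subject_id
  tab <- roi_data$samples
  fm <- list()
  means <- tab[tab$roi_label %in% .panel_rois,
               list(v = mean(value)), by = c("subject_id", "roi_label")]
  for (r in .panel_rois) {
    col <- stats::setNames(means$v[means$roi_label == r],
                           means$subject_id[means$roi_label == r])
    fm[[paste0("gmv_", r)]] <- unname(col[sub])
  }
  if (!is.null(topo_list)) {
    for (mcol in c("degree", "betweenness", "nodal_efficiency")) {
      for (r in .panel_rois) {
        fm[[paste0(mcol, "_auc_", r)]] <- vapply(
          sub, function(s) topo_list[[s]]$auc$nodal[r, mcol], numeric(1))
      }
    }
    fm[["nodal_local_efficiency_auc_Thalamus_L"]] <- vapply(
      sub, function(s)
        topo_list[[s]]$auc$nodal["Thalamus_L", "nodal_local_efficiency"],
      numeric(1))
  }
  out <- as.data.frame(fm, check.names = FALSE)
  rownames(out) <- sub
  out
}

.pipeline_covariates <- function(cohort, include_tiv = TRUE) {
  cov <- data.frame(age = cohort$age, sex = cohort$sex,
                    education = cohort$education, apoe4 = cohort$apoe4,
                    row.names = cohort$subject_id)
  if (include_tiv) cov$tiv <- cohort$tiv
  cov
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes (subject to the config's stage toggles):
#' simulate (calibrated cohort + ROI samples) -> networks (per-subject
#' KLS matrices) -> topology (metrics across the sparsity grid with null
#' normalization and AUCs) -> stats (summary table, nodal-AUC ANCOVA with
#' FDR, edgewise comparisons, correlations) -> classify (pairwise nested
#' CV).  All randomness flows from per-stage substreams of the single
#' config seed, so a rerun with the same config reproduces all outputs.
#'
#' @param config A `klsnet_config` (see [pipeline_config()]).
#' @return Invisibly, the run manifest (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "klsnet_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  paths <- character(0)
  t0 <- Sys.time()
  log_msg <- function(fmt, ...) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_klsnet(sprintf("stage '%s' failed: %s", stage,
                          conditionMessage(e)), "klsnet_stage_error")
    })
  }

  cohort <- NULL
  roi_by_metric <- list()
  mats_by_metric <- list()
  topo_by_metric <- list()

  if (isTRUE(config$stages$simulate)) {
    stage_guard("simulate", {
      log_msg("simulate: generating cohort and ROI samples")
      cohort <- generate_cohort(config$cohort$n_cn, config$cohort$n_emci,
                                config$cohort$n_lmci, seed = config$seed)
      for (metric in unlist(config$metrics)) {
        cfg <- effect_config(metric, seed = derive_seed(config$seed,
                                                        metric))
        rd <- generate_roi_samples(cohort, metric, cfg,
                                   rois = unlist(config$rois))
        roi_by_metric[[metric]] <- rd
        if (metric == unlist(config$metrics)[1]) cohort <- rd$cohort
      }
      paths <- c(paths, write_cohort(cohort, roi_by_metric,
                                     config$output_dir))
    })
  }

  if (isTRUE(config$stages$networks)) {
    stage_guard("networks", {
      log_msg("networks: building KLS similarity matrices")
      for (metric in names(roi_by_metric)) {
        rd <- roi_by_metric[[metric]]
        subset_atlas <- !is.null(config$rois)
        mats <- lapply(cohort$subject_id, function(s) {
          ss <- subject_sample_set(rd, s)
          if (subset_atlas) ss$atlas <- NULL
          m <- build_similarity_matrix(ss, m = config$kde$m,
                                       bandwidth = config$kde$bandwidth,
                                       epsilon = config$kde$epsilon)
          m$metric <- metric
          m$atlas <- rd$atlas
          m$subject_id <- s
          p <- out(sprintf("%s_%s_%s.klsm.tsv", s, metric, rd$atlas))
          write_similarity_matrix(m, p)
          m
        })
        names(mats) <- cohort$subject_id
        mats_by_metric[[metric]] <- mats
        paths <- c(paths, out(sprintf("%s_%s_%s.klsm.tsv",
                                      cohort$subject_id, metric,
                                      rd$atlas)))
      }
    })
  }

  if (isTRUE(config$stages$topology)) {
    stage_guard("topology", {
      log_msg("topology: graph metrics across sparsity grid")
      for (metric in names(mats_by_metric)) {
        mats <- mats_by_metric[[metric]]
        thresholds <- if (is.null(config$rois)) NULL else
          sparsity_grid("AAL116")
        topo <- lapply(names(mats), function(s) {
          topology_profile(mats[[s]], thresholds = thresholds,
                           n_nulls = config$topology$n_nulls,
                           seed = derive_seed(config$seed,
                                              paste0("topo", s)))
        })
        names(topo) <- names(mats)
        topo_by_metric[[metric]] <- topo
        glob <- do.call(rbind, lapply(names(topo), function(s)
          cbind(subject_id = s, metric = metric, topo[[s]]$global)))
        nod <- do.call(rbind, lapply(names(topo), function(s)
          cbind(subject_id = s, metric = metric, topo[[s]]$nodal)))
        auc <- do.call(rbind, lapply(names(topo), function(s) {
          a <- topo[[s]]$auc
          data.frame(subject_id = s, metric = metric,
                     name = c(names(a$global),
                              paste(rep(colnames(a$nodal),
                                        each = nrow(a$nodal)),
                                    rownames(a$nodal), sep = ".")),
                     auc = c(unname(a$global), as.vector(a$nodal)))
        }))
        for (nm in c("global", "nodal", "auc")) {
          p <- out(sprintf("topology_%s_%s.csv", nm, metric))
          data.table::fwrite(get(switch(nm, global = "glob",
                                        nodal = "nod", auc = "auc")), p)
          paths <- c(paths, p)
        }
      }
    })
  }

  if (isTRUE(config$stages$stats) && !is.null(cohort)) {
    stage_guard("stats", {
      log_msg("stats: group comparisons and correlations")
      tab <- cohort_table(cohort)
      p <- out("cohort_table.csv")
      data.table::fwrite(tab, p)
      paths <- c(paths, p)
      cov <- .pipeline_covariates(cohort)
      for (metric in names(topo_by_metric)) {
        topo <- topo_by_metric[[metric]]
        rois <- rownames(topo[[1]]$auc$nodal)
        anc_rows <- list(); ph_rows <- list()
        for (mcol in colnames(topo[[1]]$auc$nodal)) {
          vals <- vapply(cohort$subject_id,
                         function(s) topo[[s]]$auc$nodal[, mcol],
                         numeric(length(rois)))
          for (i in seq_along(rois)) {
            a <- ancova_group_effect(vals[i, ], cohort$group, cov,
                                     include_tiv = metric == "GMV",
                                     outcome_id = paste(mcol, rois[i],
                                                        sep = "."))
            anc_rows[[length(anc_rows) + 1]] <- data.frame(
              outcome_id = a$outcome_id, metric = metric,
              f = a$f_stat, p = a$p, partial_eta2 = a$partial_eta2,
              n = a$n)
            ph <- a$pairwise
            ph$outcome_id <- a$outcome_id
            ph_rows[[length(ph_rows) + 1]] <- ph
          }
        }
        anc <- do.call(rbind, anc_rows)
        # FDR across nodes, separately per nodal metric family
        anc$p_fdr <- NA_real_
        fam <- sub("\\..*$", "", anc$outcome_id)
        for (f in unique(fam)) {
          anc$p_fdr[fam == f] <- fdr_adjust(anc$p[fam == f])
        }
        p <- out(sprintf("ancova_results_%s.csv", metric))
        data.table::fwrite(anc, p); paths <- c(paths, p)
        p <- out(sprintf("posthoc_%s.csv", metric))
        data.table::fwrite(do.call(rbind, ph_rows), p)
        paths <- c(paths, p)
        if (length(mats_by_metric[[metric]])) {
          edges <- edgewise_stats(unname(mats_by_metric[[metric]]),
                                  cohort$group, cov,
                                  include_tiv = metric == "GMV")
          p <- out(sprintf("edges_stats_%s.csv", metric))
          data.table::fwrite(edges, p); paths <- c(paths, p)
        }
      }
      if ("GMV" %in% names(roi_by_metric)) {
        feats <- .assemble_features(cohort, roi_by_metric$GMV,
                                    topo_by_metric$GMV)
        outc <- cohort[, c("adas13", "moca", "mmse", "abeta42", "ptau",
                           "ttau")]
        cors <- correlate_with_outcomes(feats, outc, covariates = NULL)
        p <- out("correlations.csv")
        data.table::fwrite(cors, p); paths <- c(paths, p)
      }
    })
  }

  reports <- list()
  if (isTRUE(config$stages$classify) && "GMV" %in% names(roi_by_metric)) {
    stage_guard("classify", {
      log_msg("classify: pairwise nested-CV logistic models")
      feats <- .assemble_features(cohort, roi_by_metric$GMV,
                                  topo_by_metric$GMV)
      cov <- .pipeline_covariates(cohort)
      cov$subject_id <- rownames(cov)
      for (pr in list(c("CN", "EMCI"), c("CN", "LMCI"),
                      c("EMCI", "LMCI"))) {
        idx <- cohort$group %in% pr
        if (min(table(cohort$group[idx])) < config$classifier$outer_folds)
          next
        fmx <- feature_matrix(as.matrix(feats[idx, , drop = FALSE]),
                              cohort$group[idx],
                              cohort$subject_id[idx],
                              task = paste(pr, collapse = "-"))
        rep_ <- nested_cv_classify(
          fmx, cov, outer_folds = config$classifier$outer_folds,
          inner_folds = config$classifier$inner_folds,
          seed = derive_seed(config$seed, fmx$task))
        if (config$classifier$n_permutations > 0) {
          pt <- permutation_test_auc(
            fmx, cov, observed_auc = rep_$auc,
            B = config$classifier$n_permutations,
            seed = derive_seed(config$seed, paste0("perm_", fmx$task)),
            outer_folds = config$classifier$outer_folds,
            inner_folds = config$classifier$inner_folds)
          rep_$permutation_p <- pt$p
        }
        reports[[fmx$task]] <- rep_
        roc <- data.frame(task = fmx$task,
                          subject_id = fmx$subject_ids,
                          label = rep_$labels, score = rep_$pooled_scores)
        p <- out(sprintf("roc_points_%s.csv", fmx$task))
        data.table::fwrite(roc, p); paths <- c(paths, p)
      }
      summ <- lapply(reports, function(r) {
        list(task = r$task, auc = r$auc, accuracy = r$accuracy,
             sensitivity = r$sensitivity, specificity = r$specificity,
             threshold = r$threshold, permutation_p = r$permutation_p,
             seed = r$seed,
             selection_frequency = as.list(r$selection_frequency))
      })
      p <- out("classification_report.json")
      jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      paths <- c(paths, p)
    })
  }

  manifest <- list(
    package = "klsnet",
    version = as.character(utils::packageVersion("klsnet")),
    seed = config$seed,
    config_hash = .config_hash(config),
    config = unclass(config),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = lapply(stats::setNames(nm = basename(paths)), function(b) {
      unname(tools::md5sum(out(b)))
    })
  )
  mp <- out("manifest.json")
  m2 <- manifest
  m2$elapsed_sec <- NULL  # wall time must not break bit-reproducibility
  jsonlite::write_json(m2, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_msg("done: %d output file(s) in %s", length(paths),
          config$output_dir)
  invisible(manifest)
}
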