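# ---------------------------------------------------------------------------
# Graph topology across sparsity thresholds: binarization of KLS matrices,
# global and nodal metrics, degree-preserving null-model normalization
# (small-world gamma / lambda / sigma) and AUC summaries over the grid.
# ---------------------------------------------------------------------------

#' Sparsity threshold grid for an atlas
#'
#' The 116-node GMV networks are profiled at sparsities 0.05 to 0.30 in
#' 0.01 steps (26 values); the smaller 68-node surface-based networks
#' start at 0.07 (24 values) so the binary graphs remain connected.
#'
#' @param atlas `"AAL116"` or `"DK68"`.
#' @return Numeric vector of thresholds, exact to two decimals.
#' @export
sparsity_grid <- function(atlas = c("AAL116", "DK68")) {
  atlas <- match.arg(atlas)
  from <- if (atlas == "AAL116") 5L else 7L
  seq.int(from, 30L) / 100
}

#' Binarize a similarity matrix at a sparsity threshold
#'
#' Keeps the `k = round(s * N(N-1)/2)` largest off-diagonal weights as
#' edges, so every network has the same edge count at a given sparsity.
#' Ties in weight are broken deterministically by ascending lexicographic
#' node-pair order (row index, then column index, in label order).
#'
#' @param mat A `klsnet_similarity` object (or bare symmetric matrix).
#' @param s Sparsity in (0, 1].
#' @return List of class `klsnet_graph`: `labels`, `adjacency` (binary,
#'   symmetric, zero diagonal), `sparsity`.
#' @export
binarize_at_sparsity <- function(mat, s) {
  assert_that(is.numeric(s) && length(s) == 1 && s > 0 && s <= 1,
              "sparsity must lie in (0, 1]", "klsnet_contract_error")
  vals <- if (inherits(mat, "klsnet_similarity")) mat$values else mat
  labels <- rownames(vals) %||% sprintf("V%03d", seq_len(nrow(vals)))
  n <- nrow(vals)
  k <- round(s * n * (n - 1) / 2)
  ut <- which(upper.tri(vals))
  w <- vals[ut]
  # order: weight descending, then row index, then column index ascending
  rows <- ((ut - 1) %% n) + 1
  cols <- ((ut - 1) %/% n) + 1
  ord <- order(-w, rows, cols)
  adj <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (k == 0) {
    warning("sparsity yields zero edges: returning empty graph")
  } else {
    keep <- ut[ord[seq_len(min(k, length(ut)))]]
    adj[keep] <- 1L
    adj <- adj + t(adj)
  }
  structure(list(labels = labels, adjacency = adj, sparsity = s),
            class = "klsnet_graph")
}

.as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                      diag = FALSE)
}

# global efficiency of an igraph object: mean over ordered pairs of 1/d,
# disconnected pairs contributing zero
.global_efficiency <- function(ig) {
  n <- igraph::vcount(ig)
  if (n < 2) return(0)
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

# efficiency of the subgraph induced by each node's neighbors
.nodal_local_efficiency <- function(ig) {
  n <- igraph::vcount(ig)
  vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::neighbors(ig, i))
    if (length(nb) < 2) return(0)
    .global_efficiency(igraph::induced_subgraph(ig, nb))
  }, numeric(1))
}

#' Global graph metrics of a binary network
#'
#' Clustering coefficient `Cp` (mean Watts-Strogatz local clustering,
#' degree-<2 nodes counted as 0), characteristic path length `Lp` (mean
#' shortest path over *connected* pairs only; `NA` when no pair is
#' connected), global efficiency `Eg` (mean inverse shortest path over
#' all ordered pairs, disconnected pairs contributing 0) and local
#' efficiency `Eloc` (mean nodal local efficiency).
#'
#' @param g A `klsnet_graph`.
#' @return Named list `Cp`, `Lp`, `Eg`, `Eloc`, `connected`.
#' @export
global_metrics <- function(g) {
  n <- length(g$labels)
  assert_that(n >= 3, "graph metrics need at least 3 nodes",
              "klsnet_contract_error")
  ig <- .as_igraph(g)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  d <- igraph::distances(ig)
  fin <- d[upper.tri(d)]
  fin <- fin[is.finite(fin) & fin > 0]
  lp <- if (length(fin)) mean(fin) else NA_real_
  list(
    Cp = mean(cc),
    Lp = lp,
    Eg = .global_efficiency(ig),
    Eloc = mean(.nodal_local_efficiency(ig)),
    connected = igraph::is_connected(ig)
  )
}

#' Nodal graph metrics of a binary network
#'
#' Degree (row sum of the adjacency matrix), shortest-path betweenness
#' centrality normalized by `(N-1)(N-2)/2`, nodal efficiency
#' (`1/(N-1) * sum_j 1/d(i,j)`, disconnected pairs contributing 0) and
#' nodal local efficiency (global efficiency of the neighbor-induced
#' subgraph).
#'
#' @param g A `klsnet_graph`.
#' @return `data.frame` with columns `roi`, `degree`, `betweenness`,
#'   `nodal_efficiency`, `nodal_local_efficiency`.
#' @export
nodal_metrics <- function(g) {
  n <- length(g$labels)
  assert_that(n >= 3, "graph metrics need at least 3 nodes",
              "klsnet_contract_error")
  ig <- .as_igraph(g)
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  data.frame(
    roi = g$labels,
    degree = as.integer(rowSums(g$adjacency)),
    betweenness = igraph::betweenness(ig, normalized = TRUE),
    nodal_efficiency = rowSums(inv) / (n - 1),
    nodal_local_efficiency = .nodal_local_efficiency(ig),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Degree-preserving random null networks
#'
#' Generates `n_nulls` randomized graphs with exactly the degree sequence
#' of `g` by Maslov-Sneppen double-edge swaps (default 10 swap attempts
#' per edge).  Reproducible under `seed`.
#'
#' @param g A `klsnet_graph`.
#' @param n_nulls Number of null networks (study default 1000).
#' @param seed Integer seed.
#' @param swaps_per_edge Swap attempts per edge.
#' @return List of `klsnet_graph` objects.
#' @export
random_null_ensemble <- function(g, n_nulls = 1000L, seed = 1L,
                                 swaps_per_edge = 10L) {
  assert_that(n_nulls >= 1, "n_nulls must be >= 1", "klsnet_contract_error")
  ig <- .as_igraph(g)
  ne <- igraph::ecount(ig)
  if (ne < 2) {
    warning("graph has fewer than 2 edges: null networks are copies")
    return(replicate(n_nulls, g, simplify = FALSE))
  }
  set.seed(derive_seed(seed, "nulls"))
  lapply(seq_len(n_nulls), function(i) {
    rg <- igraph::rewire(ig, igraph::keeping_degseq(
      loops = FALSE, niter = swaps_per_edge * ne))
    adj <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
    storage.mode(adj) <- "integer"
    dimnames(adj) <- list(g$labels, g$labels)
    structure(list(labels = g$labels, adjacency = adj,
                   sparsity = g$sparsity), class = "klsnet_graph")
  })
}

# clustering coefficient and characteristic path length only (the two
# quantities needed per null network); much cheaper than global_metrics
.cp_lp <- function(g) {
  ig <- .as_igraph(g)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  cc[is.nan(cc)] <- 0
  d <- igraph::distances(ig)
  fin <- d[upper.tri(d)]
  fin <- fin[is.finite(fin) & fin > 0]
  c(Cp = mean(cc), Lp = if (length(fin)) mean(fin) else NA_real_)
}

#' Small-world normalization against a null ensemble
#'
#' `gamma = Cp / mean(Cp_null)`, `lambda = Lp / mean(Lp_null)`,
#' `sigma = gamma / lambda`.  A zero (or undefined) null mean yields `NA`
#' for the affected index.
#'
#' @param g A `klsnet_graph`.
#' @param nulls List of null `klsnet_graph`s (from
#'   [random_null_ensemble()]).
#' @return Named list `gamma`, `lambda`, `sigma` (plus the raw `Cp`,
#'   `Lp` and null means).
#' @export
smallworld_normalize <- function(g, nulls) {
  assert_that(length(nulls) >= 1, "null ensemble must be non-empty",
              "klsnet_contract_error")
  gm <- global_metrics(g)
  null_cl <- vapply(nulls, .cp_lp, numeric(2))
  mcp <- mean(null_cl["Cp", ])
  mlp <- mean(null_cl["Lp", ])
  gamma <- if (is.na(mcp) || mcp == 0) NA_real_ else gm$Cp / mcp
  lambda <- if (is.na(mlp) || is.na(gm$Lp) || mlp == 0) NA_real_ else
    gm$Lp / mlp
  sigma <- if (is.na(gamma) || is.na(lambda) || lambda == 0) NA_real_ else
    gamma / lambda
  list(gamma = gamma, lambda = lambda, sigma = sigma,
       Cp = gm$Cp, Lp = gm$Lp, null_Cp = mcp, null_Lp = mlp)
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of metric values over the (strictly increasing)
#' sparsity thresholds; summarizes a metric over the whole grid to avoid
#' dependence on any single threshold.  `NA` values are dropped pairwise
#' with a warning.
#'
#' @param values Metric values, one per threshold.
#' @param thresholds Strictly increasing thresholds (length >= 2).
#' @return Scalar AUC in metric-times-threshold units.
#' @export
metric_auc <- function(values, thresholds) {
  assert_that(length(values) == length(thresholds) &&
                length(values) >= 2,
              "values/thresholds must have equal length >= 2",
              "klsnet_contract_error")
  assert_that(all(diff(thresholds) > 0),
              "thresholds must be strictly increasing",
              "klsnet_contract_error")
  ok <- is.finite(values)
  if (!all(ok)) {
    warning(sprintf("dropping %d missing value(s) from AUC", sum(!ok)))
    values <- values[ok]
    thresholds <- thresholds[ok]
    if (length(values) < 2) return(NA_real_)
  }
  sum(diff(thresholds) * (utils::head(values, -1) +
                            utils::tail(values, -1)) / 2)
}

#' Absolute-threshold network density curve
#'
#' For each cutoff `tau`, the fraction of off-diagonal ROI pairs whose
#' KLS weight exceeds `tau`.  (Under sparsity thresholding the binary
#' density is fixed by construction; this curve profiles the weighted
#' matrix itself.)
#'
#' @param mat A `klsnet_similarity` (or bare symmetric matrix).
#' @param cutoffs Numeric cutoffs in (0, 1).
#' @return Numeric vector of densities, one per cutoff.
#' @export
density_curve <- function(mat, cutoffs) {
  assert_that(all(cutoffs > 0) && all(cutoffs < 1),
              "cutoffs must lie in (0, 1)", "klsnet_contract_error")
  vals <- if (inherits(mat, "klsnet_similarity")) mat$values else mat
  w <- vals[upper.tri(vals)]
  vapply(cutoffs, function(tau) mean(w > tau), numeric(1))
}

#' Full topology profile of one similarity matrix
#'
#' Binarizes the matrix at every threshold of the atlas grid, computes
#' global metrics with small-world normalization against a seeded null
#' ensemble, nodal metrics per threshold, and trapezoidal AUC summaries
#' across the grid.
#'
#' @param mat A `klsnet_similarity`.
#' @param thresholds Sparsity grid; default [sparsity_grid()] of the
#'   matrix atlas (AAL116 grid for unknown atlases).
#' @param n_nulls Null networks per threshold (study default 1000; use a
#'   few dozen at desk scale).
#' @param seed Integer seed for the null ensembles.
#' @return List of class `klsnet_topology`: `global` (data.frame with one
#'   row per threshold), `nodal` (long data.frame), `auc` (list with
#'   `global` named vector and `nodal` matrix ROI x metric).
#' @export
topology_profile <- function(mat, thresholds = NULL, n_nulls = 100L,
                             seed = 1L) {
  if (is.null(thresholds)) {
    thresholds <- sparsity_grid(if (identical(mat$atlas, "DK68"))
      "DK68" else "AAL116")
  }
  glob <- vector("list", length(thresholds))
  nod <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    g <- binarize_at_sparsity(mat, thresholds[i])
    nulls <- random_null_ensemble(g, n_nulls,
                                  seed = derive_seed(seed, paste0("t", i)))
    nm <- nodal_metrics(g)
    cl <- .cp_lp(g)
    # Eg is the mean nodal efficiency; Eloc the mean nodal local
    # efficiency (avoids recomputing subgraph efficiencies)
    eg <- mean(nm$nodal_efficiency)
    eloc <- mean(nm$nodal_local_efficiency)
    null_cl <- vapply(nulls, .cp_lp, numeric(2))
    mcp <- mean(null_cl["Cp", ])
    mlp <- mean(null_cl["Lp", ])
    gamma <- if (is.na(mcp) || mcp == 0) NA_real_ else cl[["Cp"]] / mcp
    lambda <- if (is.na(mlp) || is.na(cl[["Lp"]]) || mlp == 0) NA_real_
      else cl[["Lp"]] / mlp
    sigma <- if (is.na(gamma) || is.na(lambda) || lambda == 0) NA_real_
      else gamma / lambda
    glob[[i]] <- data.frame(threshold = thresholds[i], Cp = cl[["Cp"]],
                            Lp = cl[["Lp"]], Eg = eg, Eloc = eloc,
                            gamma = gamma, lambda = lambda,
                            sigma = sigma,
                            connected = igraph::is_connected(.as_igraph(g)))
    nm$threshold <- thresholds[i]
    nod[[i]] <- nm
  }
  glob <- do.call(rbind, glob)
  nod <- do.call(rbind, nod)
  gauc <- vapply(c("Cp", "Lp", "Eg", "Eloc", "gamma", "lambda", "sigma"),
                 function(mcol) suppressWarnings(
                   metric_auc(glob[[mcol]], glob$threshold)),
                 numeric(1))
  rois <- unique(nod$roi)
  nmetrics <- c("degree", "betweenness", "nodal_efficiency",
                "nodal_local_efficiency")
  nauc <- sapply(nmetrics, function(mcol) {
    vapply(rois, function(r) metric_auc(nod[[mcol]][nod$roi == r],
                                        nod$threshold[nod$roi == r]),
           numeric(1))
  })
  rownames(nauc) <- rois
  structure(list(global = glob, nodal = nod,
                 auc = list(global = gauc, nodal = nauc),
                 subject_id = mat$subject_id, metric = mat$metric),
            class = "klsnet_topology")
}
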