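# ---------------------------------------------------------------------------
# Individual KLS networks: kernel density estimation of regional value
# distributions on a per-subject common grid, symmetric Kullback-Leibler
# divergence between all ROI pairs, exponential mapping to a similarity in
# (0, 1].
# ---------------------------------------------------------------------------

.MIN_SAMPLES <- 10L
.EPSILON_FLOOR <- 2.2e-16

# discrete cosine transform (DCT-II) via FFT, as used by the diffusion
# bandwidth estimator
.dct1d <- function(v) {
  n <- length(v)
  w <- c(1, 2 * exp(-1i * (1:(n - 1)) * pi / (2 * n)))
  idx <- c(seq(1L, n, by = 2L),
           seq(if (n %% 2 == 0) n else n - 1L, 2L, by = -2L))
  Re(w * stats::fft(v[idx]))
}

#' Automatic KDE bandwidth by the diffusion (plug-in) method
#'
#' Solves the fixed-point equation of the diffusion-based plug-in rule on
#' a dyadic histogram of the data.  This mirrors the "automatic" Gaussian
#' KDE bandwidth used by common KDE toolboxes and is scale-equivariant.
#' Falls back to Silverman's rule ([stats::bw.nrd0()]) when the fixed
#' point cannot be bracketed (tiny or pathological samples).
#'
#' @param x Numeric sample vector (finite, non-degenerate).
#' @param n_hist Dyadic histogram size used internally.
#' @return Positive bandwidth on the scale of `x`.
#' @export
bw_botev <- function(x, n_hist = 2^10) {
  x <- x[is.finite(x)]
  nx <- length(x)
  rng <- range(x)
  R <- rng[2] - rng[1]
  assert_that(R > 0, "zero-variance sample: bandwidth undefined",
              "klsnet_degenerate_error")
  # standardize to [0, 1] before binning so the whole computation is
  # affine-equivariant (the returned bandwidth then scales exactly with
  # the data up to floating-point ulps)
  u <- (x - rng[1]) / R
  R2 <- 1.2 * R          # grid padded by R/10 on both sides
  bins <- pmin(n_hist, pmax(1L, floor((u + 0.1) / 1.2 * n_hist) + 1L))
  p <- tabulate(bins, nbins = n_hist) / nx
  a <- .dct1d(p)
  N <- length(unique(x))
  I <- as.numeric(1:(n_hist - 1))^2
  a2 <- (a[2:n_hist] / 2)^2

  fixed_point <- function(t) {
    l <- 7
    f <- 2 * pi^(2 * l) * sum(I^l * a2 * exp(-I * pi^2 * t))
    if (f <= 0) return(NA_real_)
    for (s in seq(l - 1, 2)) {
      k0 <- prod(seq(1, 2 * s - 1, by = 2)) / sqrt(2 * pi)
      cst <- (1 + (1 / 2)^(s + 0.5)) / 3
      tm <- (2 * cst * k0 / (N * f))^(2 / (3 + 2 * s))
      f <- 2 * pi^(2 * s) * sum(I^s * a2 * exp(-I * pi^2 * tm))
      if (f <= 0) return(NA_real_)
    }
    t - (2 * N * sqrt(pi) * f)^(-2 / 5)
  }

  t_star <- tryCatch({
    # bracket the root; the scaled squared bandwidth is tiny
    ts <- c(1e-10, 1e-6, 1e-4, 1e-2, 0.1, 1)
    fv <- vapply(ts, fixed_point, numeric(1))
    ok <- which(is.finite(fv))
    ts <- ts[ok]; fv <- fv[ok]
    i <- which(diff(sign(fv)) != 0)[1]
    if (is.na(i)) NA_real_ else
      stats::uniroot(fixed_point, c(ts[i], ts[i + 1]), tol = 1e-12)$root
  }, error = function(e) NA_real_)

  if (is.na(t_star) || t_star <= 0) {
    return(stats::bw.nrd0(x))
  }
  sqrt(t_star) * R2
}

#' Common evaluation grid for one subject's ROI densities
#'
#' All ROI densities of one subject-and-metric are evaluated on a shared
#' uniform grid spanning the minimum to the maximum sample value across
#' *all* ROIs of that subject, endpoints included, so densities from
#' different regions are directly comparable.
#'
#' @param sample_set A `klsnet_sample_set` (see [roi_sample_set()]).
#' @param m Number of grid points (>= 16; default 256).
#' @return Numeric vector of `m` uniformly spaced values.
#' @export
build_common_grid <- function(sample_set, m = 256L) {
  assert_that(m >= 16, "grid size m must be >= 16", "klsnet_contract_error")
  lens <- vapply(sample_set$samples, length, integer(1))
  assert_that(all(lens >= .MIN_SAMPLES),
              sprintf("every ROI needs >= %d samples", .MIN_SAMPLES),
              "klsnet_validation_error")
  all_vals <- unlist(sample_set$samples, use.names = FALSE)
  assert_that(all(is.finite(all_vals)), "non-finite sample values",
              "klsnet_validation_error")
  lo <- min(all_vals)
  hi <- max(all_vals)
  assert_that(hi > lo,
              "degenerate input: all samples identical (zero range)",
              "klsnet_degenerate_error")
  seq(lo, hi, length.out = m)
}

#' Gaussian-kernel density estimate on a fixed grid
#'
#' Estimates the probability distribution of a vector of morphometric
#' samples by Gaussian KDE with an automatically selected bandwidth,
#' evaluates it on `grid`, adds a small positive floor to every density
#' value (so Kullback-Leibler terms are always defined) and renormalizes
#' the resulting probability masses to sum to one.
#'
#' @param samples Numeric vector (>= 10 finite values, positive SD).
#' @param grid Uniform evaluation grid (e.g. from [build_common_grid()]).
#' @param bandwidth `"botev"` (diffusion plug-in, default) or
#'   `"silverman"`; alternatively a positive number used as-is.
#' @param epsilon Density floor added before renormalization.
#' @param roi_label Optional label carried along.
#' @return List of class `klsnet_density` with `grid`, `mass` (sums to 1,
#'   strictly positive), `roi_label`, `bandwidth`.
#' @export
estimate_density <- function(samples, grid, bandwidth = "botev",
                             epsilon = .EPSILON_FLOOR, roi_label = NULL) {
  assert_that(all(is.finite(samples)), "non-finite sample values",
              "klsnet_validation_error")
  assert_that(length(samples) >= .MIN_SAMPLES,
              sprintf("need >= %d samples", .MIN_SAMPLES),
              "klsnet_validation_error")
  assert_that(stats::sd(samples) > 0,
              "zero-variance samples: density degenerate",
              "klsnet_degenerate_error")
  h <- if (is.numeric(bandwidth)) {
    assert_that(bandwidth > 0, "bandwidth must be positive",
                "klsnet_contract_error")
    bandwidth
  } else {
    switch(match.arg(bandwidth, c("botev", "silverman")),
           botev = bw_botev(samples),
           silverman = stats::bw.nrd0(samples))
  }
  # mean over sample kernels, evaluated at each grid point
  z <- outer(grid, samples, "-") / h
  dens <- rowMeans(stats::dnorm(z)) / h
  # floor on the normalized mass scale: scale-free, so affinely rescaled
  # data produce identical masses (density-scale flooring would not)
  mass <- dens / sum(dens)
  mass <- mass + epsilon
  mass <- mass / sum(mass)
  structure(list(grid = grid, mass = mass, roi_label = roi_label,
                 bandwidth = h),
            class = "klsnet_density")
}

#' Symmetric Kullback-Leibler divergence between two densities
#'
#' Computes `sum_i P(i) log(P(i)/Q(i)) + Q(i) log(Q(i)/P(i))` over the
#' probability masses of two densities sharing an identical grid, with
#' the natural logarithm and a canonical ascending-index summation order
#' (so the result is bit-identical under argument exchange).  Zero if and
#' only if the two mass vectors are equal.
#'
#' @param p,q `klsnet_density` objects sharing one grid, or bare numeric
#'   probability-mass vectors of equal length (all entries positive).
#' @return Non-negative scalar divergence (nats).
#' @export
symmetric_kl <- function(p, q) {
  if (inherits(p, "klsnet_density") || inherits(q, "klsnet_density")) {
    assert_that(inherits(p, "klsnet_density") &&
                  inherits(q, "klsnet_density"),
                "p and q must both be densities or both mass vectors",
                "klsnet_contract_error")
    assert_that(identical(p$grid, q$grid),
                "p and q must share an identical grid",
                "klsnet_contract_error")
    pm <- p$mass; qm <- q$mass
  } else {
    pm <- as.numeric(p); qm <- as.numeric(q)
    assert_that(length(pm) == length(qm),
                "mass vectors must have equal length",
                "klsnet_contract_error")
  }
  assert_that(all(pm > 0) && all(qm > 0),
              "all probability masses must be strictly positive",
              "klsnet_contract_error")
  sum(pm * log(pm / qm) + qm * log(qm / pm))
}

#' KLS: exponential similarity transform of a divergence
#'
#' Maps a non-negative symmetric KL divergence `d` to `exp(-d)`, a
#' similarity in (0, 1]: 1 for identical distributions, approaching 0 for
#' completely dissimilar ones.
#'
#' @param d Non-negative finite divergence (vectorized).
#' @return Similarity values in (0, 1].
#' @export
#' @examples
#' kls_similarity(0)       # 1
#' kls_similarity(0.8789)  # ~0.4152
kls_similarity <- function(d) {
  assert_that(all(is.finite(d)) && all(d >= 0),
              "divergence must be finite and non-negative",
              "klsnet_contract_error")
  exp(-d)
}

# pairwise symmetric-KL similarity over rows of a mass matrix (N x m)
.kls_values_from_masses <- function(M) {
  L <- log(M)
  H <- rowSums(M * L)              # sum p log p per ROI
  cross <- M %*% t(L)              # [i, j] = sum_i p_i log q_i
  D <- (H - cross) + t(H - cross)  # symmetric KL, exactly symmetric
  vals <- exp(-pmax(D, 0))
  diag(vals) <- 1
  vals
}

#' Per-subject KLS similarity matrix (individual structural covariance
#' network)
#'
#' Estimates every ROI's density on the subject's common grid, computes
#' all pairwise symmetric KL divergences, maps them through [kls_similarity()]
#' and sets the diagonal to 1.  For GMV/AAL116 input the result is
#' 116 x 116; for surface metrics on DK68 it is 68 x 68.
#'
#' @param sample_set A `klsnet_sample_set`.  When its `atlas` field is
#'   `"AAL116"` or `"DK68"` the ROI labels must match that atlas exactly
#'   (rows are ordered canonically); with `atlas = NULL` any label set is
#'   allowed (ad-hoc networks, used at desk scale).
#' @param m Grid size (default 256).
#' @param bandwidth,epsilon Passed to [estimate_density()].
#' @return List of class `klsnet_similarity`: `labels`, `values`
#'   (symmetric matrix, unit diagonal, off-diagonal in (0, 1]), `metric`,
#'   `atlas`, `subject_id`.
#' @export
build_similarity_matrix <- function(sample_set, m = 256L,
                                    bandwidth = "botev",
                                    epsilon = .EPSILON_FLOOR) {
  labels <- names(sample_set$samples)
  if (!is.null(sample_set$atlas) && !is.na(sample_set$atlas %||% NA)) {
    want <- atlas_labels(sample_set$atlas)
    missing <- setdiff(want, labels)
    if (length(missing)) {
      stop_klsnet(sprintf("missing atlas label(s): %s",
                          paste(utils::head(missing, 5), collapse = ", ")),
                  "klsnet_validation_error")
    }
    extra <- setdiff(labels, want)
    if (length(extra)) {
      stop_klsnet(sprintf("label(s) not in atlas %s: %s", sample_set$atlas,
                          paste(utils::head(extra, 5), collapse = ", ")),
                  "klsnet_validation_error")
    }
    labels <- want
  }
  grid <- build_common_grid(sample_set, m)
  M <- t(vapply(labels, function(lb) {
    estimate_density(sample_set$samples[[lb]], grid, bandwidth = bandwidth,
                     epsilon = epsilon, roi_label = lb)$mass
  }, numeric(m)))
  vals <- .kls_values_from_masses(M)
  dimnames(vals) <- list(labels, labels)
  new_similarity_matrix(vals, metric = sample_set$metric,
                        atlas = sample_set$atlas,
                        subject_id = sample_set$subject_id)
}

#' Construct / validate a similarity matrix object
#'
#' @param values Square numeric matrix with dimnames; must be symmetric
#'   (to 1e-12), have a unit diagonal and off-diagonal entries in (0, 1].
#' @param metric,atlas,subject_id Optional tags.
#' @return List of class `klsnet_similarity`.
#' @export
new_similarity_matrix <- function(values, metric = NULL, atlas = NULL,
                                  subject_id = NULL) {
  assert_that(is.matrix(values) && nrow(values) == ncol(values),
              "values must be a square matrix", "klsnet_validation_error")
  labels <- rownames(values) %||% sprintf("V%03d", seq_len(nrow(values)))
  asym <- abs(values - t(values))
  if (any(asym > 1e-12)) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_klsnet(sprintf("matrix not symmetric at (%s, %s): |diff| = %.3g",
                        labels[ij[1]], labels[ij[2]], max(asym)),
                "klsnet_validation_error")
  }
  dg <- diag(values)
  if (any(dg != 1)) {
    stop_klsnet(sprintf("diagonal must be exactly 1 (first offender: %s)",
                        labels[which(dg != 1)[1]]),
                "klsnet_validation_error")
  }
  off <- values[upper.tri(values)]
  assert_that(all(off > 0) && all(off <= 1),
              "off-diagonal similarities must lie in (0, 1]",
              "klsnet_validation_error")
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, metric = metric,
                 atlas = atlas, subject_id = subject_id),
            class = "klsnet_similarity")
}

#' @export
print.klsnet_similarity <- function(x, ...) {
  cat(sprintf("KLS similarity matrix: %d x %d (%s, %s, subject %s)\n",
              length(x$labels), length(x$labels),
              x$metric %||% "?", x$atlas %||% "ad-hoc",
              x$subject_id %||% "?"))
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("  off-diagonal KLS: min %.4f, median %.4f, max %.4f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}
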