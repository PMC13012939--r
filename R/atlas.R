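#' Atlas node labels
#'
#' Returns the ordered region-of-interest (ROI) labels of a parcellation
#' atlas.  Two atlases are supported: `"AAL116"` (116 regions, used for
#' gray-matter-volume networks) and `"DK68"` (68 cortical regions of the
#' Desikan-Killiany parcellation, used for surface-based metrics: cortical
#' thickness, sulcal depth, fractal dimension, gyrification index).
#'
#' @param atlas Character, `"AAL116"` or `"DK68"`.
#' @return Character vector of ROI labels in canonical atlas order.
#' @export
#' @examples
#' length(atlas_labels("AAL116")) # 116
#' head(atlas_labels("DK68"))
atlas_labels <- function(atlas = c("AAL116", "DK68")) {
  atlas <- match.arg(atlas)
  file <- switch(atlas,
    AAL116 = "aal116_labels.txt",
    DK68   = "dk68_labels.txt"
  )
  path <- system.file("extdata", file, package = "klsnet", mustWork = TRUE)
  readLines(path)
}

#' Number of nodes of an atlas
#' @param atlas Character, `"AAL116"` or `"DK68"`.
#' @return Integer node count (116 or 68).
#' @export
atlas_size <- function(atlas = c("AAL116", "DK68")) {
  atlas <- match.arg(atlas)
  if (atlas == "AAL116") 116L else 68L
}

#' Atlas paired with a morphometric metric
#'
#' Gray matter volume (GMV) is voxel-based and parcellated with AAL116;
#' the four surface-based metrics (CT, SD, FD, GI) use DK68.
#'
#' @param metric One of `"GMV"`, `"CT"`, `"SD"`, `"FD"`, `"GI"`.
#' @return `"AAL116"` for GMV, `"DK68"` otherwise.
#' @export
metric_atlas <- function(metric = c("GMV", "CT", "SD", "FD", "GI")) {
  metric <- match.arg(metric)
  if (metric == "GMV") "AAL116" else "DK68"
}
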