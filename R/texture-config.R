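#' Texture extraction configuration
#'
#' Parameters of the GLCM/GLRLM texture extractor. The defaults reproduce
#' the IBEX-style parameterization used throughout the pipeline: intensities
#' quantized over gray limits `[0, 2100]` into 100 levels, GLCM computed in
#' four in-plane directions (0, 45, 90, 135 degrees) at pixel offsets 1, 4
#' and 7, and GLRLM computed in two directions (0 and 90 degrees).
#'
#' With these defaults the extractor emits, per sequence, one value per
#' (GLCM feature, direction, offset) plus a direction-averaged value per
#' (GLCM feature, offset) — `22 * (4*3 + 3) = 330` columns — and one value
#' per (GLRLM feature, direction) plus a direction-averaged value per GLRLM
#' feature — `11 * (2 + 1) = 33` columns — i.e. 363 columns per sequence and
#' 1452 for four sequences.
#'
#' @param gray_limits Numeric length-2 `(low, high)` intensity bounds.
#' @param num_levels Number of quantization levels (>= 2).
#' @param glcm_directions GLCM directions in degrees (subset of 0/45/90/135).
#' @param glcm_offsets GLCM pixel distances (>= 1).
#' @param glrlm_directions GLRLM directions in degrees.
#' @param symmetric_glcm Accumulate both orderings of each pixel pair.
#' @param normalize_glcm Normalize the co-occurrence matrix to sum 1.
#' @param direction_average Also emit direction-averaged feature columns.
#' @param slice_aggregate `"sum_matrices"` (2.5-D: per-slice matrices are
#'   summed before feature evaluation) or `"mean_features"` (features
#'   evaluated per slice, then averaged).
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(gray_limits = c(0, 2100), num_levels = 100,
                           glcm_directions = c(0, 45, 90, 135),
                           glcm_offsets = c(1, 4, 7),
                           glrlm_directions = c(0, 90),
                           symmetric_glcm = TRUE, normalize_glcm = TRUE,
                           direction_average = TRUE,
                           slice_aggregate = c("sum_matrices", "mean_features")) {
  slice_aggregate <- match.arg(slice_aggregate)
  stopifnot(length(gray_limits) == 2, gray_limits[1] < gray_limits[2])
  if (num_levels < 2) stop("num_levels must be >= 2")
  if (any(glcm_offsets < 1)) stop("offsets must be >= 1")
  ok_dir <- c(0, 45, 90, 135)
  if (!all(glcm_directions %in% ok_dir) || !all(glrlm_directions %in% ok_dir)) {
    stop("directions must be among 0, 45, 90, 135 degrees")
  }
  structure(
    list(
      gray_limits = as.numeric(gray_limits),
      num_levels = as.integer(num_levels),
      glcm_directions = as.numeric(glcm_directions),
      glcm_offsets = as.integer(glcm_offsets),
      glrlm_directions = as.numeric(glrlm_directions),
      symmetric_glcm = isTRUE(symmetric_glcm),
      normalize_glcm = isTRUE(normalize_glcm),
      direction_average = isTRUE(direction_average),
      slice_aggregate = slice_aggregate
    ),
    class = "texture_config"
  )
}

#' Read/write a texture configuration as YAML
#'
#' The YAML mirrors the extractor's parameter names (`GrayLimits`,
#' `NumLevels`, `Direction`, `Offset`).
#'
#' @param cfg A [texture_config()].
#' @param path File path.
#' @return `write_texture_config` invisibly returns `path`;
#'   `read_texture_config` returns a [texture_config()].
#' @export
write_texture_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "texture_config"))
  yaml::write_yaml(list(
    GrayLimits = cfg$gray_limits, NumLevels = cfg$num_levels,
    GLCM = list(Direction = cfg$glcm_directions, Offset = cfg$glcm_offsets,
                Symmetric = cfg$symmetric_glcm, Normalize = cfg$normalize_glcm),
    GLRLM = list(Direction = cfg$glrlm_directions),
    DirectionAverage = cfg$direction_average,
    SliceAggregate = cfg$slice_aggregate
  ), path)
  invisible(path)
}

#' @rdname write_texture_config
#' @export
read_texture_config <- function(path) {
  y <- yaml::read_yaml(path)
  texture_config(
    gray_limits = unlist(y$GrayLimits), num_levels = y$NumLevels,
    glcm_directions = unlist(y$GLCM$Direction),
    glcm_offsets = unlist(y$GLCM$Offset),
    glrlm_directions = unlist(y$GLRLM$Direction),
    symmetric_glcm = y$GLCM$Symmetric, normalize_glcm = y$GLCM$Normalize,
    direction_average = y$DirectionAverage,
    slice_aggregate = y$SliceAggregate
  )
}
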