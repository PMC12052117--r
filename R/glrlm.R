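# Extract the scan lines of a matrix along a direction, as a list of
# integer vectors with consecutive elements adjacent along that direction.
# Masked-out pixels are NA and break runs.
scan_lines <- function(level_img, direction, mask = NULL) {
  nr <- nrow(level_img); nc <- ncol(level_img)
  m <- level_img
  if (!is.null(mask)) m[!mask] <- NA_integer_
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  key <- switch(as.character(direction),
    "0"   = r,        # runs along rows (left-right)
    "90"  = c_,       # runs along columns
    "45"  = r + c_,   # anti-diagonals (up-right)
    "135" = c_ - r,   # main diagonals (down-right)
    stop("unsupported direction: ", direction)
  )
  # column-major order within each group preserves adjacency for all four
  unname(split(as.vector(m), as.vector(key)))
}

#' Gray-level run-length matrix of a level image
#'
#' Entry `(i, j)` counts the maximal runs of gray level `i` having length
#' `j` along the scan direction. The number of run-length columns is the
#' longest possible line for the given direction and image size, so
#' matrices from equally-sized slices can be summed.
#'
#' @inheritParams compute_glcm
#' @return `num_levels x max_run` numeric matrix of run counts.
#' @export
compute_glrlm <- function(level_img, direction, num_levels, mask = NULL) {
  stopifnot(is.matrix(level_img))
  lines <- scan_lines(level_img, direction, mask)
  max_run <- max(lengths(lines))
  # single rle over all lines, separated by NA sentinels
  flat <- unlist(lapply(lines, function(x) c(x, NA_integer_)), use.names = FALSE)
  runs <- rle(flat)
  keep <- !is.na(runs$values)
  lev <- runs$values[keep]; len <- runs$lengths[keep]
  R <- matrix(0, num_levels, max_run)
  if (length(lev)) {
    counts <- tabulate(lev + (len - 1L) * num_levels, nbins = num_levels * max_run)
    R <- matrix(as.numeric(counts), num_levels, max_run)
  }
  R
}

#' Galloway run-length features of a GLRLM
#'
#' Evaluates the 11 run-length features: GrayLevelNonuniformity,
#' HighGrayLevelRunEmpha, LongRunEmphasis, LongRunHighGrayLevelEmpha,
#' LongRunLowGrayLevelEmpha, LowGrayLevelRunEmpha, RunLengthNonuniformity,
#' RunPercentage, ShortRunEmphasis, ShortRunHighGrayLevelEmpha,
#' ShortRunLowGrayLevelEmpha. `Nr` is the total number of runs and `Np` the
#' number of pixels traversed; a single run of length `N` therefore has
#' ShortRunEmphasis `1/N^2`, LongRunEmphasis `N^2` and RunPercentage `1/N`.
#'
#' @param glrlm Run-count matrix from [compute_glrlm()].
#' @param n_pixels Number of pixels traversed by the scan (`Np`).
#' @return Named numeric vector of length 11.
#' @export
glrlm_features <- function(glrlm, n_pixels) {
  stopifnot(is.matrix(glrlm))
  Nr <- sum(glrlm)
  if (Nr <= 0) stop("empty run-length matrix (no runs)")
  L <- nrow(glrlm); J <- ncol(glrlm)
  i2 <- matrix(seq_len(L)^2, L, J)
  j2 <- matrix(rep(seq_len(J)^2, each = L), L, J)
  p <- glrlm
  c(
    GrayLevelNonuniformity = sum(rowSums(p)^2) / Nr,
    HighGrayLevelRunEmpha = sum(p * i2) / Nr,
    LongRunEmphasis = sum(p * j2) / Nr,
    LongRunHighGrayLevelEmpha = sum(p * i2 * j2) / Nr,
    LongRunLowGrayLevelEmpha = sum(p * j2 / i2) / Nr,
    LowGrayLevelRunEmpha = sum(p / i2) / Nr,
    RunLengthNonuniformity = sum(colSums(p)^2) / Nr,
    RunPercentage = Nr / n_pixels,
    ShortRunEmphasis = sum(p / j2) / Nr,
    ShortRunHighGrayLevelEmpha = sum(p * i2 / j2) / Nr,
    ShortRunLowGrayLevelEmpha = sum(p / (i2 * j2)) / Nr
  )
}
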