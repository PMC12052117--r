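#' Quantize an intensity image to discrete gray levels
#'
#' Uniform binning of intensities over `gray_limits` into `num_levels`
#' levels `1..num_levels` with bin width `(high - low) / num_levels`.
#' Intensities outside the limits are clipped into the end bins. With the
#' default limits `[0, 2100]` and 100 levels the bin width is 21, so
#' intensity 20 maps to level 1 and intensity 21 to level 2.
#'
#' @param img Numeric matrix (one slice) or array.
#' @param gray_limits Numeric `(low, high)`.
#' @param num_levels Integer >= 2.
#' @return Integer array of the same shape with values in `1..num_levels`.
#' @export
quantize <- function(img, gray_limits = c(0, 2100), num_levels = 100) {
  if (num_levels < 2) stop("num_levels must be >= 2")
  lo <- gray_limits[1]; hi <- gray_limits[2]
  if (lo >= hi) stop("gray_limits must satisfy low < high")
  bw <- (hi - lo) / num_levels
  lev <- floor((img - lo) / bw) + 1
  lev[lev < 1] <- 1L
  lev[lev > num_levels] <- num_levels
  storage.mode(lev) <- "integer"
  lev
}

# direction in degrees -> (row, col) displacement at distance d
dir_displacement <- function(direction, d) {
  switch(as.character(direction),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("unsupported direction: ", direction)
  )
}

#' Gray-level co-occurrence matrix of a level image
#'
#' Counts pairs of gray levels co-occurring at a fixed displacement (the
#' direction/offset pair). With `symmetric = TRUE` both orderings of each
#' pair are accumulated, making the matrix equal to its transpose; with
#' `normalize = TRUE` the matrix is scaled to sum 1.
#'
#' @param level_img Integer matrix of levels in `1..num_levels`
#'   (see [quantize()]).
#' @param direction Angle in degrees: 0, 45, 90 or 135.
#' @param offset Pixel distance (>= 1).
#' @param num_levels Number of levels (matrix dimension).
#' @param symmetric,normalize See description.
#' @param mask Optional logical matrix; only pairs with both pixels inside
#'   the mask are counted.
#' @return `num_levels x num_levels` numeric matrix.
#' @export
compute_glcm <- function(level_img, direction, offset, num_levels,
                         symmetric = TRUE, normalize = TRUE, mask = NULL) {
  stopifnot(is.matrix(level_img))
  d <- dir_displacement(direction, as.integer(offset))
  nr <- nrow(level_img); nc <- ncol(level_img)
  r1 <- max(1L, 1L - d[1]):min(nr, nr - d[1])
  c1 <- max(1L, 1L - d[2]):min(nc, nc - d[2])
  if (abs(d[1]) >= nr || abs(d[2]) >= nc) {
    warning("offset exceeds image extent; returning zero matrix")
    return(matrix(0, num_levels, num_levels))
  }
  a <- level_img[r1, c1, drop = FALSE]
  b <- level_img[r1 + d[1], c1 + d[2], drop = FALSE]
  i <- as.vector(a); j <- as.vector(b)
  if (!is.null(mask)) {
    keep <- as.vector(mask[r1, c1, drop = FALSE]) &
      as.vector(mask[r1 + d[1], c1 + d[2], drop = FALSE])
    i <- i[keep]; j <- j[keep]
  }
  counts <- tabulate(i + (j - 1L) * num_levels, nbins = num_levels^2)
  P <- matrix(as.numeric(counts), num_levels, num_levels)
  if (symmetric) P <- P + t(P)
  if (normalize && sum(P) > 0) P <- P / sum(P)
  P
}

#' Haralick-style features of a (normalized) GLCM
#'
#' Evaluates the 22 co-occurrence features of the extractor's feature list:
#' AutoCorrelation, ClusterProminence, ClusterShade, ClusterTendency,
#' Contrast, Correlation, DifferenceEntropy, Dissimilarity, Energy, Entropy,
#' Homogeneity, Homogeneity2, InformationMeasureCorr1,
#' InformationMeasureCorr2, InverseDiffMomentNorm, InverseDiffNorm,
#' InverseVariance, MaxProbability, SumAverage, SumEntropy, SumVariance,
#' Variance. Conventions: all logs are natural, `0 * log 0 := 0`,
#' `Variance` is the variance of the row-marginal level distribution,
#' `SumVariance` is centered on `SumAverage`, and degenerate
#' Correlation/InformationMeasureCorr on a constant image are 0.
#'
#' @param glcm Square co-occurrence matrix; normalized internally (with a
#'   warning) if its entries do not sum to 1.
#' @return Named numeric vector of length 22, all finite.
#' @export
glcm_features <- function(glcm) {
  stopifnot(is.matrix(glcm), nrow(glcm) == ncol(glcm))
  s <- sum(glcm)
  if (s <= 0) stop("GLCM has no counts")
  if (abs(s - 1) > 1e-8) {
    warning("GLCM not normalized; normalizing internally")
    glcm <- glcm / s
  }
  L <- nrow(glcm)
  p <- glcm
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(L) * px); mu_y <- sum(seq_len(L) * py)
  sd_x <- sqrt(sum((seq_len(L) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(L) - mu_y)^2 * py))
  xlogx <- function(x) {
    out <- x * log(x)
    out[x <= 0] <- 0
    out
  }
  # p_{x+y}(k), k = 2..2L and p_{x-y}(k), k = 0..L-1
  ipj <- as.vector(i + j); imj <- abs(as.vector(i - j))
  pxy_sum <- as.vector(rowsum(as.vector(p), ipj))   # all k in 2..2L occur
  pxy_diff <- as.vector(rowsum(as.vector(p), imj))  # all k in 0..L-1 occur
  ksum <- 2:(2 * L); kdiff <- 0:(L - 1)
  HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
  HXY <- -sum(xlogx(p))
  pxpy <- outer(px, py)
  hxy1_terms <- p * log(pxpy)
  hxy1_terms[p <= 0 | pxpy <= 0] <- 0
  HXY1 <- -sum(hxy1_terms)
  HXY2 <- -sum(xlogx(pxpy))
  sum_avg <- sum(ksum * pxy_sum)
  dd <- i - j
  autocorr <- sum(i * j * p)
  corr <- if (sd_x > 0 && sd_y > 0) (autocorr - mu_x * mu_y) / (sd_x * sd_y) else 0
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY))))
  c(
    AutoCorrelation = autocorr,
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * p),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * p),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * p),
    Contrast = sum(dd^2 * p),
    Correlation = corr,
    DifferenceEntropy = -sum(xlogx(pxy_diff)),
    Dissimilarity = sum(abs(dd) * p),
    Energy = sum(p^2),
    Entropy = HXY,
    Homogeneity = sum(p / (1 + abs(dd))),
    Homogeneity2 = sum(p / (1 + dd^2)),
    InformationMeasureCorr1 = imc1,
    InformationMeasureCorr2 = imc2,
    InverseDiffMomentNorm = sum(p / (1 + (dd / L)^2)),
    InverseDiffNorm = sum(p / (1 + abs(dd) / L)),
    InverseVariance = {
      iv <- p / dd^2
      iv[dd == 0] <- 0
      sum(iv)
    },
    MaxProbability = max(p),
    SumAverage = sum_avg,
    SumEntropy = -sum(xlogx(pxy_sum)),
    SumVariance = sum((ksum - sum_avg)^2 * pxy_sum),
    Variance = sum((seq_len(L) - mu_x)^2 * px)
  )
}
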