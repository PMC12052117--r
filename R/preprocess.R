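#' Normalize signal intensities of a volume
#'
#' Maps each sequence's intensities into the fixed range used by the texture
#' quantizer (default `[0, 2100]`, the gray limits of the GLCM/GLRLM
#' configuration), so the `num_levels` quantization bins are meaningful for
#' arbitrary scanner units. Mode `"rescale"` maps `[min, max]` linearly onto
#' the range; `"clip"` leaves in-range values untouched and clips the rest.
#'
#' @param vol A [volume_sequence()].
#' @param mode `"rescale"` (default) or `"clip"`.
#' @param range Numeric length-2 target intensity range.
#' @return A [volume_sequence()] with normalized intensities.
#' @export
normalize_intensity <- function(vol, mode = c("rescale", "clip"),
                                range = c(0, 2100)) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "volume_sequence"), length(range) == 2, range[1] < range[2])
  seqs <- vol$sequences
  for (nm in names(seqs)) {
    v <- seqs[[nm]]
    if (mode == "rescale") {
      lo <- min(v); hi <- max(v)
      if (hi == lo) {
        warning(sprintf("sequence '%s' is constant; left unchanged", nm))
      } else {
        seqs[[nm]] <- (v - lo) / (hi - lo) * (range[2] - range[1]) + range[1]
      }
    } else {
      seqs[[nm]] <- pmin(pmax(v, range[1]), range[2])
    }
  }
  vol$sequences <- seqs
  vol
}

# Cell-centered trilinear interpolation of a 3-D array to new dims.
trilinear_resample <- function(arr, new_dim) {
  old <- dim(arr)
  coord <- function(n_out, n_in) {
    # map output cell centers onto input cell-center coordinates
    x <- (seq_len(n_out) - 0.5) / n_out * n_in + 0.5
    pmin(pmax(x, 1), n_in)
  }
  cs <- coord(new_dim[1], old[1])
  cy <- coord(new_dim[2], old[2])
  cx <- coord(new_dim[3], old[3])
  lower <- function(x, n_in) {
    if (n_in == 1L) rep(1L, length(x)) else pmin(as.integer(floor(x)), n_in - 1L)
  }
  s0 <- lower(cs, old[1]); y0 <- lower(cy, old[2]); x0 <- lower(cx, old[3])
  ws <- cs - s0; wy <- cy - y0; wx <- cx - x0
  s1 <- pmin(s0 + 1L, old[1]); y1 <- pmin(y0 + 1L, old[2]); x1 <- pmin(x0 + 1L, old[3])
  out <- array(0, dim = new_dim)
  # gather the 8 corners with outer-product weights, vectorized per corner
  corners <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  for (k in seq_len(nrow(corners))) {
    a <- corners$a[k]; b <- corners$b[k]; cc <- corners$c[k]
    si <- if (a == 0) s0 else s1
    yi <- if (b == 0) y0 else y1
    xi <- if (cc == 0) x0 else x1
    w <- outer(outer(if (a == 0) 1 - ws else ws,
                     if (b == 0) 1 - wy else wy),
               if (cc == 0) 1 - wx else wx)
    out <- out + w * arr[si, yi, xi, drop = FALSE]
  }
  out
}

#' Resample a volume to target dimensions
#'
#' Trilinear (cell-centered) interpolation of every sequence to exactly the
#' requested shape. The target is given as `height x width x slices`,
#' mirroring the conventional in-plane-first notation (e.g. `c(256, 256, 16)`
#' for 256 x 256 slices, 16 of them).
#'
#' @param vol A [volume_sequence()].
#' @param target Integer length-3 vector `c(height, width, slices)`.
#' @return A [volume_sequence()] with resampled arrays.
#' @export
resample_volume <- function(vol, target) {
  stopifnot(inherits(vol, "volume_sequence"), length(target) == 3)
  if (any(target < 1)) stop("target dimensions must all be >= 1")
  new_dim <- as.integer(c(target[3], target[1], target[2])) # slices x H x W
  old <- dim(vol)
  scale <- old / new_dim
  seqs <- lapply(vol$sequences, trilinear_resample, new_dim = new_dim)
  vol$sequences <- seqs
  vol$voxel_spacing <- vol$voxel_spacing * scale
  vol
}

#' Augment a volume
#'
#' Applies the requested augmentation operations in a fixed order. Geometric
#' operations act identically on every sequence of the patient; the label is
#' never changed. `rotate` applies a seeded number of in-plane 90-degree
#' rotations, `reflect` mirrors the width axis, `flip` mirrors the height
#' axis, and `intensity_adjust` applies a seeded per-sequence multiplicative
#' gain (0.9-1.1).
#'
#' @param vol A [volume_sequence()].
#' @param ops Character vector, a non-empty subset of
#'   `c("rotate", "reflect", "flip", "intensity_adjust")`.
#' @param seed Integer seed used by the stochastic operations.
#' @return The augmented [volume_sequence()].
#' @export
augment <- function(vol, ops, seed = 1L) {
  stopifnot(inherits(vol, "volume_sequence"))
  known <- c("rotate", "reflect", "flip", "intensity_adjust")
  if (length(ops) == 0) stop("ops must be non-empty")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  with_seed(seed, {
    seqs <- vol$sequences
    if ("rotate" %in% ops) {
      k <- sample(1:3, 1L) # quarter turns, common to all sequences
      seqs <- lapply(seqs, rotate90_stack, k = k)
    }
    if ("reflect" %in% ops) {
      seqs <- lapply(seqs, function(a) a[, , dim(a)[3]:1, drop = FALSE])
    }
    if ("flip" %in% ops) {
      seqs <- lapply(seqs, function(a) a[, dim(a)[2]:1, , drop = FALSE])
    }
    if ("intensity_adjust" %in% ops) {
      for (nm in names(seqs)) {
        gain <- stats::runif(1, 0.9, 1.1)
        seqs[[nm]] <- seqs[[nm]] * gain
      }
    }
    vol$sequences <- seqs
    vol
  })
}

# Rotate each slice of a (slices x H x W) stack by k quarter turns.
rotate90_stack <- function(a, k = 1L) {
  k <- k %% 4L
  if (k == 0L) return(a)
  for (i in seq_len(k)) {
    d <- dim(a)
    out <- array(0, dim = c(d[1], d[3], d[2]))
    for (s in seq_len(d[1])) {
      m <- a[s, , ]
      if (is.null(dim(m))) m <- matrix(m, d[2], d[3])
      out[s, , ] <- t(m)[d[3]:1, , drop = FALSE] # 90 deg counter-clockwise
    }
    a <- out
  }
  a
}
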