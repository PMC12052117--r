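#' Specification of a synthetic phantom cohort
#'
#' Describes a cohort of multi-sequence phantom "patients" whose tumor-region
#' texture differs between the two genotype classes. The class signal is
#' carried by the spatial correlation length of the texture field (and hence
#' by its gray-level co-occurrence and run-length structure), not by mean
#' intensity or marginal variance, so first-order statistics alone cannot
#' separate the classes.
#'
#' @param n_labeled_mutant,n_labeled_wild Number of labeled patients per class.
#' @param n_unlabeled Number of unlabeled patients (their true class is drawn
#'   50/50 and retained as `hidden_label` for recovery scoring only).
#' @param slices,height,width Volume dimensions.
#' @param sequence_names MRI sequences to simulate (subset of T1C, T2, FLAIR,
#'   DWI).
#' @param class_texture_effect Non-negative real controlling how strongly the
#'   texture correlation length separates the classes; 0 means the two
#'   classes are drawn from one distribution.
#' @param noise_sd Standard deviation of additive white scanner noise, in
#'   intensity units (> 0).
#' @param seed Integer seed; cohorts are a pure function of the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_labeled_mutant = 20, n_labeled_wild = 20,
                        n_unlabeled = 20, slices = 8, height = 64, width = 64,
                        sequence_names = c("T1C", "T2", "FLAIR", "DWI"),
                        class_texture_effect = 2, noise_sd = 20, seed = 1L) {
  if (any(c(n_labeled_mutant, n_labeled_wild, n_unlabeled) < 0)) {
    stop("patient counts must be >= 0")
  }
  if (slices < 1 || height < 1 || width < 1) {
    stop("image dimensions must all be >= 1 (zero-size images are rejected)")
  }
  if (class_texture_effect < 0) stop("class_texture_effect must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(
    list(
      n_labeled_mutant = as.integer(n_labeled_mutant),
      n_labeled_wild = as.integer(n_labeled_wild),
      n_unlabeled = as.integer(n_unlabeled),
      slices = as.integer(slices), height = as.integer(height),
      width = as.integer(width),
      sequence_names = sequence_names,
      class_texture_effect = class_texture_effect,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur with edge renormalization; sigma in pixels.
gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(x) {
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (d in -r:r) {
      src <- pmin(pmax(seq_len(n) + d, 1L), n) # replicate edges
      out <- out + k[d + r + 1L] * x[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

# Baseline per-sequence tissue intensities (arbitrary scanner units).
.seq_base <- c(T1C = 1100, T2 = 1400, FLAIR = 1000, DWI = 800)

#' Generate a synthetic phantom cohort
#'
#' Each patient carries an ellipsoidal "tumor" blob embedded in a smooth
#' background. Inside the blob, the texture is a Gaussian random field whose
#' correlation length depends on the class: the mutant-class field is
#' smoothed with a wider kernel than the wild-class field, then rescaled to
#' a fixed marginal standard deviation so the classes share mean and
#' variance. GLCM features such as Contrast (sensitive to short-range
#' autocorrelation) and GLRLM run structure therefore carry the class
#' signal. Additive white noise of `noise_sd` models scanner noise.
#'
#' @param spec A [cohort_spec()].
#' @return List of [volume_sequence()] objects: labeled mutants, labeled
#'   wilds, then unlabeled patients (with `hidden_label` set).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    classes <- c(
      rep("mutant", spec$n_labeled_mutant),
      rep("wild", spec$n_labeled_wild)
    )
    hidden <- character(0)
    if (spec$n_unlabeled > 0) {
      hidden <- sample(c("mutant", "wild"), spec$n_unlabeled, replace = TRUE)
    }
    n_lab <- length(classes)
    out <- vector("list", n_lab + spec$n_unlabeled)
    for (i in seq_len(n_lab + spec$n_unlabeled)) {
      labeled <- i <= n_lab
      cls <- if (labeled) classes[i] else hidden[i - n_lab]
      id <- sprintf("P%03d", i)
      out[[i]] <- phantom_patient(id, cls, spec, labeled)
    }
    out
  })
}

# One phantom patient; called inside the cohort RNG stream.
phantom_patient <- function(id, cls, spec, labeled) {
  S <- spec$slices; H <- spec$height; W <- spec$width
  # correlation length of the blob texture: the mutant-class field is rough
  # (short correlation length, high GLCM Contrast), the wild-class field is
  # progressively smoother as the effect grows
  sigma_mutant <- 0.6
  sigma <- if (cls == "mutant") sigma_mutant else {
    sigma_mutant + 0.45 * spec$class_texture_effect
  }
  amp <- 300                      # texture amplitude (shared across classes)
  # ellipsoidal blob geometry, shared by all sequences of the patient
  cy <- H / 2 + stats::runif(1, -H / 10, H / 10)
  cx <- W / 2 + stats::runif(1, -W / 10, W / 10)
  ry <- H * stats::runif(1, 0.28, 0.38)
  rx <- W * stats::runif(1, 0.28, 0.38)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  mid <- (S + 1) / 2
  seqs <- list()
  for (nm in spec$sequence_names) {
    base <- unname(.seq_base[nm])
    if (is.na(base)) base <- 1000
    base <- base * stats::runif(1, 0.95, 1.05) # patient-level scanner gain
    vol <- array(0, dim = c(S, H, W))
    for (s in seq_len(S)) {
      shrink <- if (S == 1) 1 else sqrt(max(0.2, 1 - ((s - mid) / (0.7 * S))^2))
      blob <- ((yy - cy) / (ry * shrink))^2 + ((xx - cx) / (rx * shrink))^2 <= 1
      background <- 0.35 * base +
        0.1 * base * ((yy - H / 2)^2 + (xx - W / 2)^2) / (H^2 / 4 + W^2 / 4)
      tex <- gauss_blur2d(matrix(stats::rnorm(H * W), H, W), sigma)
      tex <- tex / stats::sd(tex) * amp # fixed marginal sd across classes
      sl <- background
      sl[blob] <- base + tex[blob]
      sl <- sl + stats::rnorm(H * W, sd = spec$noise_sd)
      vol[s, , ] <- pmax(sl, 0)
    }
    seqs[[nm]] <- vol
  }
  volume_sequence(
    id, seqs, voxel_spacing = c(1, 1, 1),
    label = if (labeled) cls else NA_character_,
    label_source = if (labeled) "ground_truth" else "none",
    hidden_label = if (labeled) NA_character_ else cls
  )
}
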