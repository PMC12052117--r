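#' Extract the radiomics feature row of one patient
#'
#' Computes GLCM and GLRLM texture features for every requested sequence of
#' a patient volume. Per-slice 2-D matrices are aggregated across slices
#' according to `cfg$slice_aggregate` (default: count matrices summed before
#' feature evaluation, the usual 2.5-D convention). Per sequence the output
#' holds one value per (GLCM feature, direction, offset), a
#' direction-averaged value per (GLCM feature, offset), one value per
#' (GLRLM feature, direction) and a direction-averaged value per GLRLM
#' feature — 363 columns per sequence under the default configuration.
#'
#' Column descriptors are `sequence|matrix|feature|direction[|offset]`, with
#' direction `avg` for direction-averaged columns.
#'
#' @param vol A [volume_sequence()].
#' @param cfg A [texture_config()].
#' @param sequences Sequences to extract (default: all present in `vol`).
#'   A requested sequence missing from the volume is an error.
#' @param mask Optional logical array (`slices x height x width`) restricting
#'   the computation to a region of interest; by default the whole slice is
#'   used (the pipeline requires no tumor pre-segmentation).
#' @return Named numeric vector (one feature-table row).
#' @export
extract_features <- function(vol, cfg = texture_config(),
                             sequences = NULL, mask = NULL) {
  stopifnot(inherits(vol, "volume_sequence"), inherits(cfg, "texture_config"))
  if (is.null(sequences)) sequences <- seq_names(vol)
  missing <- setdiff(sequences, seq_names(vol))
  if (length(missing)) {
    stop("requested sequence(s) not present in volume: ",
         paste(missing, collapse = ", "))
  }
  out <- numeric(0)
  for (nm in sequences) {
    arr <- vol$sequences[[nm]]
    S <- dim(arr)[1]
    slices <- lapply(seq_len(S), function(s) {
      m <- arr[s, , ]
      if (is.null(dim(m))) m <- matrix(m, dim(arr)[2], dim(arr)[3])
      m
    })
    masks <- if (is.null(mask)) vector("list", S) else {
      lapply(seq_len(S), function(s) {
        mm <- mask[s, , ]
        if (is.null(dim(mm))) mm <- matrix(mm, dim(arr)[2], dim(arr)[3])
        mm
      })
    }
    lv <- lapply(slices, quantize, gray_limits = cfg$gray_limits,
                 num_levels = cfg$num_levels)
    out <- c(out, sequence_glcm_features(nm, lv, masks, cfg),
             sequence_glrlm_features(nm, lv, masks, cfg))
  }
  out
}

sequence_glcm_features <- function(seq_name, lv, masks, cfg) {
  L <- cfg$num_levels
  out <- numeric(0)
  for (off in cfg$glcm_offsets) {
    per_dir <- list()
    for (dir in cfg$glcm_directions) {
      if (cfg$slice_aggregate == "sum_matrices") {
        P <- Reduce(`+`, lapply(seq_along(lv), function(s) {
          compute_glcm(lv[[s]], dir, off, L, symmetric = cfg$symmetric_glcm,
                       normalize = FALSE, mask = masks[[s]])
        }))
        if (cfg$normalize_glcm && sum(P) > 0) P <- P / sum(P)
        fv <- glcm_features(P)
      } else {
        per_slice <- lapply(seq_along(lv), function(s) {
          P <- compute_glcm(lv[[s]], dir, off, L,
                            symmetric = cfg$symmetric_glcm,
                            normalize = cfg$normalize_glcm, mask = masks[[s]])
          glcm_features(P)
        })
        fv <- colMeans(do.call(rbind, per_slice))
      }
      names(fv) <- sprintf("%s|GLCM|%s|%g|%d", seq_name, names(fv), dir, off)
      per_dir[[as.character(dir)]] <- fv
      out <- c(out, fv)
    }
    if (cfg$direction_average) {
      avg <- colMeans(do.call(rbind, lapply(per_dir, unname)))
      base <- sub("^.*\\|GLCM\\|([^|]+)\\|.*$", "\\1", names(per_dir[[1]]))
      names(avg) <- sprintf("%s|GLCM|%s|avg|%d", seq_name, base, off)
      out <- c(out, avg)
    }
  }
  out
}

sequence_glrlm_features <- function(seq_name, lv, masks, cfg) {
  L <- cfg$num_levels
  out <- numeric(0)
  per_dir <- list()
  np <- sum(vapply(seq_along(lv), function(s) {
    if (is.null(masks[[s]])) length(lv[[s]]) else sum(masks[[s]])
  }, 0))
  for (dir in cfg$glrlm_directions) {
    R <- NULL
    for (s in seq_along(lv)) {
      Rs <- compute_glrlm(lv[[s]], dir, L, mask = masks[[s]])
      R <- if (is.null(R)) Rs else R + Rs
    }
    fv <- glrlm_features(R, np)
    names(fv) <- sprintf("%s|GLRLM|%s|%g", seq_name, names(fv), dir)
    per_dir[[as.character(dir)]] <- fv
    out <- c(out, fv)
  }
  if (cfg$direction_average) {
    avg <- colMeans(do.call(rbind, lapply(per_dir, unname)))
    base <- sub("^.*\\|GLRLM\\|([^|]+)\\|.*$", "\\1", names(per_dir[[1]]))
    names(avg) <- sprintf("%s|GLRLM|%s|avg", seq_name, base)
    out <- c(out, avg)
  }
  out
}

#' Extract the feature table of a cohort
#'
#' @param cohort List of [volume_sequence()] objects.
#' @param cfg A [texture_config()].
#' @param sequences Sequences to extract (default: all in the first patient).
#' @param normalize Normalize intensities ([normalize_intensity()]) before
#'   quantization so the gray limits are meaningful for arbitrary units.
#' @return A `data.frame` with columns `patient_id`, `label` and one numeric
#'   column per feature descriptor.
#' @export
extract_feature_table <- function(cohort, cfg = texture_config(),
                                  sequences = NULL, normalize = TRUE) {
  stopifnot(length(cohort) >= 1)
  rows <- lapply(cohort, function(vol) {
    if (normalize) {
      vol <- suppressWarnings(normalize_intensity(vol, range = cfg$gray_limits))
    }
    extract_features(vol, cfg, sequences = sequences)
  })
  feat <- do.call(rbind, rows)
  df <- data.frame(
    patient_id = vapply(cohort, function(v) v$patient_id, ""),
    label = vapply(cohort, function(v) v$label, ""),
    stringsAsFactors = FALSE
  )
  df$label[which(df$label == "NA")] <- NA_character_
  cbind(df, as.data.frame(feat, check.names = FALSE))
}

#' Numeric feature matrix of a feature table
#'
#' @param ft A feature table from [extract_feature_table()].
#' @return Numeric matrix (patients x features) with patient ids as rownames.
#' @export
feature_matrix <- function(ft) {
  m <- as.matrix(ft[, setdiff(names(ft), c("patient_id", "label")), drop = FALSE])
  rownames(m) <- ft$patient_id
  m
}
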