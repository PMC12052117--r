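#' Multi-sequence MRI volume for one patient
#'
#' A `volume_sequence` bundles the co-registered MRI pulse sequences of a
#' single patient (any subset of T1C, T2, FLAIR, DWI), each stored as a 3-D
#' intensity array in `slices x height x width` order, together with voxel
#' spacing metadata and an optional binary genotype label.
#'
#' @param patient_id Character scalar identifying the patient.
#' @param sequences Named list of 3-D numeric arrays (`slices x height x
#'   width`), all with identical dimensions. Names are sequence identifiers
#'   such as `"T1C"`, `"T2"`, `"FLAIR"`, `"DWI"`. Intensities must be finite
#'   and non-negative (arbitrary scanner units).
#' @param voxel_spacing Numeric length-3 vector of voxel spacing in mm
#'   (slice, row, column).
#' @param label Optional class label, `"mutant"` or `"wild"`; `NA` for
#'   unlabeled patients.
#' @param label_source One of `"ground_truth"`, `"pseudo"`, `"none"`.
#' @param hidden_label Optional true class of a synthetic unlabeled patient,
#'   kept aside so pseudo-label recovery can be scored; never consulted by
#'   the pipeline itself.
#'
#' @return An object of class `volume_sequence`.
#' @export
volume_sequence <- function(patient_id, sequences, voxel_spacing = c(1, 1, 1),
                            label = NA_character_,
                            label_source = c("none", "ground_truth", "pseudo"),
                            hidden_label = NA_character_) {
  label_source <- match.arg(label_source)
  if (!is.character(patient_id) || length(patient_id) != 1L) {
    stop("patient_id must be a single character string")
  }
  if (!is.list(sequences) || is.null(names(sequences)) ||
      any(!nzchar(names(sequences)))) {
    stop("sequences must be a named list of 3-D arrays")
  }
  dims <- lapply(sequences, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("every sequence must be a 3-D array (slices x height x width)")
  }
  ref <- dims[[1L]]
  if (any(ref < 1L)) stop("image dimensions must all be >= 1")
  for (nm in names(sequences)) {
    if (!identical(dim(sequences[[nm]]), ref)) {
      stop(sprintf(
        "sequence '%s' has dimensions %s but '%s' has %s; all sequences of one patient must match",
        nm, paste(dim(sequences[[nm]]), collapse = "x"),
        names(sequences)[1L], paste(ref, collapse = "x")
      ))
    }
    v <- sequences[[nm]]
    if (!all(is.finite(v))) stop(sprintf("sequence '%s' contains non-finite intensities", nm))
    if (min(v) < 0) stop(sprintf("sequence '%s' contains negative intensities", nm))
  }
  if (!is.na(label) && !label %in% c("mutant", "wild")) {
    stop("label must be 'mutant', 'wild' or NA")
  }
  structure(
    list(
      patient_id = patient_id,
      sequences = sequences,
      voxel_spacing = as.numeric(voxel_spacing),
      label = label,
      label_source = if (is.na(label)) "none" else label_source,
      hidden_label = hidden_label
    ),
    class = "volume_sequence"
  )
}

#' @export
print.volume_sequence <- function(x, ...) {
  d <- dim(x$sequences[[1L]])
  cat(sprintf(
    "<volume_sequence> patient %s: %d sequence(s) [%s], %d slices of %dx%d, label=%s (%s)\n",
    x$patient_id, length(x$sequences), paste(names(x$sequences), collapse = ","),
    d[1L], d[2L], d[3L],
    ifelse(is.na(x$label), "NA", x$label), x$label_source
  ))
  invisible(x)
}

#' @export
dim.volume_sequence <- function(x) dim(x$sequences[[1L]])

seq_names <- function(vol) names(vol$sequences)

#' Write a multi-sequence volume as one NIfTI file per sequence
#'
#' Each sequence is written to `<dir>/<patient_id>_<sequence>.nii.gz` with
#' voxel spacing recorded in the NIfTI header. Arrays are stored in
#' conventional `height x width x slices` order on disk.
#'
#' @param vol A [volume_sequence()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of file paths per sequence.
#' @export
write_volume <- function(vol, dir) {
  stopifnot(inherits(vol, "volume_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in seq_names(vol)) {
    arr <- aperm(vol$sequences[[nm]], c(2L, 3L, 1L)) # H x W x slices on disk
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, vol$voxel_spacing[c(2L, 3L, 1L)])
    path <- file.path(dir, sprintf("%s_%s.nii.gz", vol$patient_id, nm))
    RNifti::writeNifti(img, path)
    paths[nm] <- path
  }
  invisible(paths)
}

#' Read a multi-sequence volume from NIfTI files
#'
#' @param paths Named character vector mapping sequence name to NIfTI path,
#'   as produced by [write_volume()].
#' @param patient_id Patient identifier for the returned object.
#' @param label,label_source Optional label metadata; see [volume_sequence()].
#' @return A [volume_sequence()].
#' @export
read_volume <- function(paths, patient_id, label = NA_character_,
                        label_source = c("none", "ground_truth", "pseudo")) {
  label_source <- match.arg(label_source)
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("paths must be a named vector (sequence name -> file)")
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf(
      "missing NIfTI file for sequence(s) %s: %s",
      paste(names(missing), collapse = ", "), paste(missing, collapse = ", ")
    ))
  }
  seqs <- list()
  spacing <- NULL
  for (nm in names(paths)) {
    img <- RNifti::readNifti(paths[[nm]])
    pd <- RNifti::pixdim(img)
    arr <- aperm(as.array(img), c(3L, 1L, 2L)) # back to slices x H x W
    seqs[[nm]] <- arr
    spacing <- c(pd[3L], pd[1L], pd[2L])
  }
  dims <- vapply(seqs, function(a) dim(a)[1L], 1L)
  if (length(unique(dims)) > 1L) {
    stop("mismatched slice counts across sequences: ",
         paste(sprintf("%s=%d", names(dims), dims), collapse = ", "))
  }
  volume_sequence(patient_id, seqs, voxel_spacing = spacing,
                  label = label, label_source = label_source)
}

#' Write a cohort manifest CSV
#'
#' The manifest has one row per patient with the patient id, one column per
#' sequence holding the NIfTI path, and the label (`mutant`, `wild` or `NA`).
#'
#' @param cohort List of [volume_sequence()] objects.
#' @param dir Directory receiving the NIfTI files and `manifest.csv`.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(vol) {
    paths <- write_volume(vol, dir)
    c(patient_id = vol$patient_id, as.list(paths),
      label = vol$label)
  })
  manifest <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest CSV
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_cohort()].
#' @return List of [volume_sequence()] objects.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  seq_cols <- setdiff(names(manifest), c("patient_id", "label"))
  lapply(seq_len(nrow(manifest)), function(i) {
    paths <- unlist(manifest[i, seq_cols, drop = TRUE])
    names(paths) <- seq_cols
    lab <- manifest$label[i]
    read_volume(paths, manifest$patient_id[i],
                label = if (is.na(lab) || lab == "") NA_character_ else lab,
                label_source = if (is.na(lab) || lab == "") "none" else "ground_truth")
  })
}
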