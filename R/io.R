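#' Read a 3D volume from NIfTI or NRRD
#'
#' Supported formats are NIfTI-1 (`.nii`, `.nii.gz`, read through RNifti) and
#' NRRD (`.nrrd`, raw encoding). NIfTI volumes are re-oriented on load to the
#' canonical RAS convention (first axis increasing to the right, then
#' anterior, then superior) so that texture direction labels are comparable
#' across files; NRRD volumes are taken in stored order with their stated
#' spacing. Files without voxel spacing information are rejected rather than
#' silently defaulted.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return an [image_volume].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[^.]+)$", "\\1", path))
  vol <- tryCatch({
    if (ext %in% c(".nii", ".nii.gz")) {
      read_nifti_volume(path)
    } else if (ext == ".nrrd") {
      read_nrrd(path)
    } else {
      stop(sprintf("unsupported volume format '%s'", ext), call. = FALSE)
    }
  }, error = function(e) {
    stop(sprintf("cannot read volume '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  vol
}

read_nifti_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  RNifti::orientation(nii) <- "RAS"
  pd <- RNifti::pixdim(nii)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("NIfTI header carries no usable voxel spacing")
  }
  xf <- RNifti::xform(nii)
  origin <- as.numeric(xf[1:3, 4])
  image_volume(as_array3d(nii), spacing = as.numeric(pd[1:3]), origin = origin)
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' @param vol an [image_volume] or [mask_volume].
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.nrrd`).
#' @return invisibly, `path`.
#' @export
write_image <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume") || inherits(vol, "mask_volume"))
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[^.]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    xf <- diag(c(vol$spacing, 1))
    xf[1:3, 4] <- vol$origin
    nii <- RNifti::asNifti(vol$voxels)
    RNifti::pixdim(nii) <- vol$spacing
    nii <- RNifti::`sform<-`(nii, structure(xf, code = 2L))
    RNifti::writeNifti(nii, path, datatype = "double")
  } else if (ext == ".nrrd") {
    write_nrrd(vol, path)
  } else {
    stop(sprintf("unsupported volume format '%s'", ext), call. = FALSE)
  }
  invisible(path)
}

#' Read a binary tumor mask and check it against its reference image
#'
#' Any non-zero label is treated as foreground. The mask grid must match the
#' reference grid (shape identical; spacing and origin within 1e-4 mm), and a
#' VOI must contain at least one foreground voxel.
#'
#' @param path mask file path (same formats as [read_image]).
#' @param reference the [image_volume] the mask belongs to.
#' @return a [mask_volume].
#' @export
read_mask <- function(path, reference) {
  raw <- read_image(path)
  m <- mask_volume(raw$voxels, spacing = raw$spacing, origin = raw$origin)
  validate_pair(reference, m)
  m
}

#' Read and validate a clinical table
#'
#' Expects a CSV with header columns `patient_id, sex, age_years, smoking,
#' pfs_days, event` and optionally `cohort_label`. Categorical levels are
#' normalized case-insensitively (`sex` to male/female, `smoking` to
#' smoker/nonsmoker). PFS is in days from treatment start to progression
#' (event = 1) or censoring (event = 0).
#'
#' @param path CSV file path.
#' @return a validated `data.frame` with one row per patient.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param df a data.frame to validate in-memory.
#' @export
validate_clinical <- function(df) {
  need <- c("patient_id", "sex", "age_years", "smoking", "pfs_days", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("clinical table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"cohort_label" %in% names(df)) df$cohort_label <- NA_character_
  df$patient_id <- as.character(df$patient_id)
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup)) {
    stop(sprintf("duplicate patient_id: %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  df$sex <- norm_level(df$sex, c("male", "female"), "sex")
  df$smoking <- norm_level(df$smoking, c("smoker", "nonsmoker"), "smoking")
  df$age_years <- as.numeric(df$age_years)
  if (any(!is.finite(df$age_years)) || any(df$age_years <= 0)) {
    stop("age_years must be positive", call. = FALSE)
  }
  df$pfs_days <- as.numeric(df$pfs_days)
  if (any(!is.finite(df$pfs_days)) || any(df$pfs_days <= 0)) {
    stop(sprintf("non-positive pfs_days for patient(s): %s",
                 paste(df$patient_id[!(is.finite(df$pfs_days) & df$pfs_days > 0)],
                       collapse = ", ")), call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (progression observed)", call. = FALSE)
  }
  df$event <- as.integer(df$event)
  df
}

norm_level <- function(x, levels, what) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("non-smoker", "non smoker", "never")] <- "nonsmoker"
  x[x %in% c("m")] <- "male"
  x[x %in% c("f")] <- "female"
  bad <- setdiff(unique(x), levels)
  if (length(bad)) {
    stop(sprintf("invalid %s level(s): %s (expected %s)", what,
                 paste(bad, collapse = ", "), paste(levels, collapse = "/")),
         call. = FALSE)
  }
  x
}

#' Write / read a radiomic feature table
#'
#' The on-disk form is a CSV with a `patient_id` column followed by the
#' feature columns in registry order, written at full double precision
#' (15 significant digits) so that write-then-read round-trips numerically.
#'
#' @param table a `data.frame` whose first column is `patient_id`.
#' @param path CSV output path.
#' @return invisibly, `path` (writer); the feature `data.frame` (reader).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (!"patient_id" %in% names(table)) {
    stop("feature table needs a patient_id column", call. = FALSE)
  }
  table <- table[, c("patient_id", setdiff(names(table), "patient_id")),
                 drop = FALSE]
  old <- options(digits = 15, scipen = 100)
  on.exit(options(old))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Write / read pipeline JSON artifacts
#'
#' Pipeline stages persist their results as pretty-printed JSON with scalars
#' unboxed and doubles at full precision, so artifacts are diffable and
#' byte-stable across reruns.
#'
#' @param x a (nested) list to serialize.
#' @param path JSON file path.
#' @return invisibly, `path` (writer); the parsed list (reader).
#' @export
write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_json_artifact
#' @export
read_json_artifact <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
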