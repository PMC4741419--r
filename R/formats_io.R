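# NIfTI volume and cohort-table I/O.
#
# All volumes of one subject must live on a single grid; nothing here
# resamples or registers. T1 values are carried in milliseconds and stored
# on disk as 32-bit float gzipped NIfTI-1.

#' Quantitative T1 volume
#'
#' A 3D grid of longitudinal relaxation times (ms) with its voxel-to-world
#' affine. This is the carrier of the voxel intensities the partial-volume
#' model unmixes.
#'
#' @param values 3D numeric array of T1 values in milliseconds.
#' @param affine 4x4 voxel-to-world matrix (1 mm isotropic identity by
#'   default).
#' @param subject_id Optional subject identifier.
#' @return An object of class `t1_volume` with elements `values`, `affine`
#'   and `subject_id`.
#' @export
t1_volume <- function(values, affine = diag(4), subject_id = NA_character_) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume", call. = FALSE)
  if (any(dim(values) < 1L)) stop("grid dimensions must be >= 1", call. = FALSE)
  if (!is.numeric(values)) stop("non-scalar datatype", call. = FALSE)
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 matrix", call. = FALSE)
  structure(list(values = values, affine = unname(affine),
                 subject_id = subject_id),
            class = "t1_volume")
}

#' @export
print.t1_volume <- function(x, ...) {
  cat("<t1_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, subject ", x$subject_id, "\n", sep = "")
  v <- x$values[x$values > 0]
  if (length(v))
    cat("  nonzero T1 range: ", round(min(v), 1), "-", round(max(v), 1),
        " ms\n", sep = "")
  invisible(x)
}

#' Label volume for deep gray matter regions
#'
#' @param labels 3D integer array; 0 is background.
#' @param dictionary Named integer vector mapping region name to label
#'   value. Every nonzero label in `labels` must appear here.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, dictionary = default_region_labels(),
                         affine = diag(4)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("expected 3D label volume", call. = FALSE)
  lv <- sort(unique(as.vector(labels)))
  lv <- lv[lv != 0]
  if (any(lv != as.integer(lv)) || any(lv < 0))
    stop("labels must be non-negative integers", call. = FALSE)
  missing <- setdiff(lv, dictionary)
  if (length(missing))
    stop("labels not in dictionary: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(labels = labels, dictionary = dictionary,
                 affine = unname(affine)),
            class = "label_volume")
}

#' Default label dictionary for the four deep gray matter nuclei
#' @return Named integer vector.
#' @export
default_region_labels <- function() {
  c(thalamus = 1L, caudate = 2L, putamen = 3L, pallidum = 4L)
}

#' Binary mask on a volume grid
#'
#' @param mask 3D logical array (numeric input is coerced; nonzero = TRUE).
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(mask, affine = diag(4)) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("expected 3D mask", call. = FALSE)
  if (!is.logical(mask)) {
    m <- array(mask != 0, dim = dim(mask))
    mask <- m
  }
  structure(list(mask = mask, affine = unname(affine)), class = "binary_mask")
}

grid_of <- function(x) {
  if (inherits(x, "t1_volume")) list(dim = dim(x$values), affine = x$affine)
  else if (inherits(x, "label_volume")) list(dim = dim(x$labels), affine = x$affine)
  else if (inherits(x, "binary_mask")) list(dim = dim(x$mask), affine = x$affine)
  else if (is.array(x)) list(dim = dim(x), affine = NULL)
  else stop("not a volume-like object", call. = FALSE)
}

#' Check that two volumes share one grid
#'
#' True iff the grid shapes match and the affines agree within `tol`.
#' Symmetric; never raises, callers decide whether a mismatch is fatal.
#'
#' @param a,b Volume-like objects (`t1_volume`, `label_volume`,
#'   `binary_mask`, or bare 3D arrays).
#' @param tol Absolute tolerance on affine entries.
#' @return Logical scalar.
#' @export
check_grid_compatibility <- function(a, b, tol = 1e-3) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (length(ga$dim) != length(gb$dim) || any(ga$dim != gb$dim)) return(FALSE)
  if (is.null(ga$affine) || is.null(gb$affine)) return(TRUE)
  all(abs(ga$affine - gb$affine) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!check_grid_compatibility(a, b))
    stop(what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

read_nifti_3d <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    d <- d[1:3]
  } else if (length(d) != 3L) {
    stop("expected 3D volume, got ", length(d), "D in ", path, call. = FALSE)
  }
  vals <- as.array(img)
  if (!is.numeric(vals)) stop("non-scalar datatype in ", path, call. = FALSE)
  # plain array + plain matrix, free of image-header attributes
  vals <- array(as.vector(vals), dim = d)
  aff <- RNifti::xform(img)
  aff <- matrix(as.vector(aff), 4, 4)
  list(values = vals, affine = aff)
}

#' Read a quantitative T1 map from NIfTI
#'
#' @param path Path to a 3D `.nii` / `.nii.gz` file with voxel values in
#'   milliseconds.
#' @param scale Multiplicative factor applied to the stored values (use
#'   e.g. 1000 for maps stored in seconds).
#' @param subject_id Subject identifier; defaults to the file base name.
#' @param mask Optional `binary_mask` of tissue; in-mask voxels are
#'   validated to be finite and positive, with a warning otherwise.
#' @return A [t1_volume].
#' @export
read_t1_volume <- function(path, scale = 1,
                           subject_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
                           mask = NULL) {
  raw <- read_nifti_3d(path)
  vol <- t1_volume(raw$values * scale, affine = raw$affine,
                   subject_id = subject_id)
  if (!is.null(mask)) validate_t1_volume(vol, mask)
  vol
}

#' Validate in-mask T1 values
#'
#' Records a warning if any voxel inside `mask` is non-finite or
#' non-positive; such voxels are dropped later by the fitting stage.
#'
#' @param volume A [t1_volume].
#' @param mask A [binary_mask] delimiting tissue.
#' @return Invisibly, the number of invalid in-mask voxels.
#' @export
validate_t1_volume <- function(volume, mask) {
  stop_if_grid_mismatch(volume, mask)
  v <- volume$values[mask$mask]
  n_bad <- sum(!is.finite(v) | v <= 0)
  if (n_bad > 0)
    warning(n_bad, " non-positive or non-finite T1 value(s) inside mask",
            call. = FALSE)
  invisible(n_bad)
}

write_volume_file <- function(values, affine, path, datatype = "float") {
  img <- RNifti::asNifti(values, datatype = datatype)
  # sform only: RNifti's quaternion qform does not carry anisotropic
  # spacing faithfully through a write-read cycle
  img <- RNifti::`sform<-`(img, value = structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a T1 volume (or any scalar map) as gzipped NIfTI-1
#'
#' Values are stored as 32-bit float, so a write-read round trip is
#' bit-exact after the first float conversion.
#'
#' @param volume A [t1_volume].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return The path, invisibly.
#' @export
write_t1_volume <- function(volume, path) {
  write_volume_file(volume$values, volume$affine, path, "float")
}

#' Read a label volume from NIfTI
#'
#' @param path Path to a 3D integer-valued NIfTI file.
#' @param dictionary Named integer vector mapping region names to labels.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path, dictionary = default_region_labels()) {
  raw <- read_nifti_3d(path)
  storage.mode(raw$values) <- "integer"
  label_volume(raw$values, dictionary = dictionary, affine = raw$affine)
}

#' @rdname read_label_volume
#' @param labels A [label_volume] to write.
#' @export
write_label_volume <- function(labels, path) {
  write_volume_file(labels$labels, labels$affine, path, "int16")
}

#' Read a binary (e.g. lesion) mask from NIfTI
#'
#' @param path Path to a 3D NIfTI file; nonzero voxels become TRUE.
#' @return A [binary_mask].
#' @export
read_mask <- function(path) {
  raw <- read_nifti_3d(path)
  binary_mask(raw$values != 0, affine = raw$affine)
}

#' @rdname read_mask
#' @param mask A [binary_mask] to write.
#' @export
write_mask <- function(mask, path) {
  write_volume_file(array(as.integer(mask$mask), dim = dim(mask$mask)),
                    mask$affine, path, "uint8")
}

normalize_group <- function(g) {
  g <- toupper(trimws(as.character(g)))
  out <- rep(NA_character_, length(g))
  out[g %in% c("HC", "CONTROL", "CONTROLS", "HEALTHY")] <- "HC"
  out[g %in% c("PATIENT", "PATIENTS", "RRMS", "MS")] <- "PATIENT"
  if (anyNA(out))
    stop("unknown group label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

normalize_sex <- function(s) {
  s <- toupper(substr(trimws(as.character(s)), 1, 1))
  if (!all(s %in% c("F", "M")))
    stop("sex must be F or M", call. = FALSE)
  s
}

#' Read a cohort table
#'
#' A CSV with one row per subject and required columns `subject_id`,
#' `group`, `age`, `sex`. Group labels are normalized to HC / PATIENT
#' (accepting control/healthy and patient/RRMS/MS spellings); extra
#' columns (typically volume paths) are kept and a note is logged.
#'
#' @param path Path to a CSV file with a header.
#' @return A data.frame with normalized types.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(df), c(required, "t1_path", "labels_path", "lesion_path"))
  if (length(extra))
    message("cohort table: ignoring extra column(s) ",
            paste(extra, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  df$group <- normalize_group(df$group)
  df$age <- as.numeric(df$age)
  if (anyNA(df$age) || any(df$age <= 0))
    stop("age must be positive and numeric", call. = FALSE)
  df$sex <- normalize_sex(df$sex)
  df
}

#' @rdname read_cohort_table
#' @param cohort A cohort data.frame to write.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
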