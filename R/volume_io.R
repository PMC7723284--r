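# Volume and segmentation I/O, intensity normalization, ROI code catalog.
#
# Volumes are plain 3-D numeric arrays indexed `vol[x, y, z]`; segmentation
# maps are 3-D arrays of non-negative integer region codes with the same
# shape as their paired volume.  All geometry in this package lives in raw
# 1-based voxel index space: NIfTI orientation metadata is read but never
# used to reorient, so patch extraction is deterministic and directly
# checkable against array slicing.

#' Read a 3-D intensity volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a 3-D numeric array indexed `[x, y, z]`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(array(rnorm(8^3), c(8, 8, 8)), f)
#' v <- read_volume(f)
#' dim(v)
read_volume <- function(path) {
  if (!file.exists(path)) stopf("volume file does not exist: %s", path)
  img <- RNifti::readNifti(path)
  v <- as.array(img)
  if (length(dim(v)) != 3L) {
    stopf("expected a 3-D volume, got %d dimensions", length(dim(v)))
  }
  if (!all(is.finite(v))) stopf("volume contains non-finite values")
  storage.mode(v) <- "double"
  array(v, dim = dim(v))
}

#' Write a 3-D volume to a NIfTI file
#'
#' @param vol 3-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  check_volume(vol)
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "double"), path)
  invisible(path)
}

#' Read an integer segmentation map from a NIfTI file
#'
#' Region codes follow the FreeSurfer labeling convention (see
#' [default_roi_catalog()]).  Voxel values must be integers up to a
#' rounding tolerance of `1e-6`.
#'
#' @param path path to a `.nii` or `.nii.gz` label map.
#' @param volume optional companion intensity volume; if supplied the
#'   shapes are required to match.
#' @return a 3-D array of non-negative integer codes (stored as integer).
#' @export
read_segmentation <- function(path, volume = NULL) {
  seg <- read_volume(path)
  if (max(abs(seg - round(seg))) > 1e-6) {
    stopf("segmentation contains non-integer voxel values")
  }
  seg <- round(seg)
  storage.mode(seg) <- "integer"
  if (!is.null(volume)) check_paired(volume, seg)
  seg
}

#' Write a segmentation map to a NIfTI file
#'
#' @param seg 3-D integer array of region codes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  check_volume(seg)
  RNifti::writeNifti(RNifti::asNifti(seg + 0, datatype = "int32"), path)
  invisible(path)
}

check_volume <- function(vol) {
  if (!is.array(vol) || length(dim(vol)) != 3L) {
    stopf("expected a 3-D array")
  }
  invisible(vol)
}

# A volume and its segmentation must live on the same voxel grid.
check_paired <- function(vol, seg) {
  check_volume(vol)
  check_volume(seg)
  if (!identical(dim(vol), dim(seg))) {
    stopf(
      "volume shape (%s) does not match segmentation shape (%s)",
      paste(dim(vol), collapse = "x"), paste(dim(seg), collapse = "x")
    )
  }
  invisible(TRUE)
}

#' Z-score a volume to zero mean and unit variance
#'
#' Normalizes over the whole scan, using the population variance
#' (denominator `n`).  Patch classifiers expect their inputs on this scale,
#' so normalization happens once per scan before any patch extraction.
#' A degenerate (near-constant, variance below `1e-12`) volume maps to all
#' zeros instead of raising, so constant synthetic backgrounds remain
#' usable.
#'
#' @param vol 3-D numeric array.
#' @return the normalized volume, same shape.
#' @export
znormalize_volume <- function(vol) {
  check_volume(vol)
  if (!all(is.finite(vol))) stopf("volume contains non-finite values")
  m <- mean(vol)
  v <- mean((vol - m)^2)
  if (v < 1e-12) {
    return(array(0, dim = dim(vol)))
  }
  (vol - m) / sqrt(v)
}

#' Default catalog of the six target regions
#'
#' The bilateral hippocampi, amygdalae and insulae under their FreeSurfer
#' integer codes: LH:17, RH:53, LA:18, RA:54, LI:1035, RI:2035.  The
#' catalog records the left/right pairing (17-53, 18-54, 1035-2035) used
#' when whole structure pairs are selected.
#'
#' @return a data frame of class `roi_catalog` with columns `name`,
#'   `abbrev`, `code`, `hemisphere` and `partner_code`.
#' @export
#' @examples
#' cat6 <- default_roi_catalog()
#' roi_code(cat6, "LH")      # 17
#' roi_abbrev(cat6, 54)      # "RA"
#' roi_partner(cat6, 1035)   # 2035
default_roi_catalog <- function() {
  cat6 <- data.frame(
    name = c(
      "left_hippocampus", "right_hippocampus",
      "left_amygdala", "right_amygdala",
      "left_insula", "right_insula"
    ),
    abbrev = c("LH", "RH", "LA", "RA", "LI", "RI"),
    code = c(17L, 53L, 18L, 54L, 1035L, 2035L),
    hemisphere = c("left", "right", "left", "right", "left", "right"),
    partner_code = c(53L, 17L, 54L, 18L, 2035L, 1035L),
    stringsAsFactors = FALSE
  )
  class(cat6) <- c("roi_catalog", "data.frame")
  validate_roi_catalog(cat6)
}

validate_roi_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  if (anyDuplicated(catalog$code)) stopf("catalog codes must be unique")
  if (any(catalog$code <= 0)) stopf("catalog codes must be positive")
  if (!all(catalog$partner_code %in% catalog$code)) {
    stopf("every partner_code must itself be a catalog code")
  }
  catalog
}

#' Look up a region code by abbreviation or name
#'
#' @param catalog an `roi_catalog`.
#' @param region abbreviation (e.g. `"LH"`) or full name.
#' @return integer region code.
#' @export
roi_code <- function(catalog, region) {
  i <- match(region, catalog$abbrev)
  if (is.na(i)) i <- match(region, catalog$name)
  if (is.na(i)) stopf("unknown region: %s", region)
  catalog$code[i]
}

#' Look up a region name by integer code
#'
#' @inheritParams roi_code
#' @param code integer region code.
#' @return full region name.
#' @export
roi_name <- function(catalog, code) {
  i <- match(code, catalog$code)
  if (is.na(i)) stopf("unknown region code: %s", code)
  catalog$name[i]
}

#' @rdname roi_name
#' @export
roi_abbrev <- function(catalog, code) {
  i <- match(code, catalog$code)
  if (is.na(i)) stopf("unknown region code: %s", code)
  catalog$abbrev[i]
}

#' Contralateral partner of a region code
#'
#' @inheritParams roi_name
#' @return the paired (opposite hemisphere) region code.
#' @export
roi_partner <- function(catalog, code) {
  i <- match(code, catalog$code)
  if (is.na(i)) stopf("unknown region code: %s", code)
  catalog$partner_code[i]
}

#' Serialize / restore an ROI catalog as two-column CSV
#'
#' The on-disk format is `name,code`.  On read, laterality pairing is
#' reconstructed from the `left_`/`right_` name prefixes.
#'
#' @param catalog an `roi_catalog`.
#' @param path CSV path.
#' @return `write_roi_catalog()`: `path`, invisibly;
#'   `read_roi_catalog()`: an `roi_catalog`.
#' @export
write_roi_catalog <- function(catalog, path) {
  utils::write.csv(catalog[, c("name", "code")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_catalog
#' @export
read_roi_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "code") %in% names(df)))
  base <- sub("^(left|right)_", "", df$name)
  hemi <- ifelse(grepl("^left_", df$name), "left",
    ifelse(grepl("^right_", df$name), "right", NA_character_)
  )
  partner <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    j <- which(base == base[i] & seq_len(nrow(df)) != i)
    partner[i] <- if (length(j) == 1L) df$code[j] else df$code[i]
  }
  initials <- toupper(substr(hemi, 1, 1))
  out <- data.frame(
    name = df$name,
    abbrev = paste0(initials, toupper(substr(base, 1, 1))),
    code = as.integer(df$code),
    hemisphere = hemi,
    partner_code = partner,
    stringsAsFactors = FALSE
  )
  class(out) <- c("roi_catalog", "data.frame")
  validate_roi_catalog(out)
}
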