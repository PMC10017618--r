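#' Read a 3D volume from NIfTI or a DICOM series
#'
#' @param path A NIfTI file (`.nii` / `.nii.gz`) or a directory containing the
#'   files of exactly one DICOM series.
#' @return An [image_volume()] with spacing taken from the file header. The
#'   orientation tag is set to `"coronal"` when the header supports it (slice
#'   axis anterior-posterior) and to `"unknown"` when the header contradicts
#'   it; when no orientation is derivable a coronal stack is assumed with a
#'   warning.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("cannot read '%s' as NIfTI: %s",
                                                   path, conditionMessage(e))))
  arr <- as_array3d(unclass(as.array(img)))
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3 - length(sp)))
  ori <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  tag <- if (is.na(ori) || nchar(ori) < 3L) {
    warning("orientation not derivable from header; assuming coronal stack")
    "coronal"
  } else if (toupper(substr(ori, 3L, 3L)) %in% c("A", "P")) "coronal" else "unknown"
  image_volume(arr, spacing = abs(sp[1:3]), orientation = tag)
}

#' Write a volume or mask to NIfTI-1
#'
#' NIfTI-1 is the canonical on-disk format; spacing is stored in the header
#' `pixdim`. `write_mask` stores the binary mask as-is.
#'
#' @param vol An [image_volume()].
#' @param mask A [seg_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, the path written.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  img <- RNifti::asNifti(mask$data)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' Tolerates label maps saved with a scaled foreground value (e.g. {0, 255}):
#' a two-level input is binarized at half its maximum, with a warning. Any
#' other non-binary content is a validation error.
#'
#' @param path NIfTI file path.
#' @return A [seg_mask()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  x <- vol$data
  u <- sort(unique(as.vector(x)))
  if (!all(u %in% c(0, 1))) {
    mx <- max(u)
    two_level <- length(u) <= 2L && all(abs(x) < 1e-6 | abs(x - mx) < 1e-6 * max(1, mx))
    if (two_level && mx >= 0.5) {
      warning(sprintf("mask values {%s} are not {0,1}; binarizing at %g",
                      paste(format(u), collapse = ", "), mx / 2))
      x <- ifelse(x > mx / 2, 1, 0)
    } else {
      stop(sprintf("mask at '%s' is not binary (values include %s)",
                   path, paste(utils::head(format(u), 5), collapse = ", ")))
    }
  }
  seg_mask(array(x, dim(x)), spacing = vol$spacing)
}

MANIFEST_COLUMNS <- c("case_id", "image_path", "mask_path", "composition",
                      "lobulated", "ica_contact", "sinus_invasion", "center")

parse_flag <- function(x, column) {
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true", "t", "yes")] <- TRUE
  out[s %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out))
    stop(sprintf("column '%s' contains values not parseable as logical: %s",
                 column, paste(unique(s[is.na(out)]), collapse = ", ")))
  out
}

#' Read a case manifest CSV
#'
#' The manifest carries one row per case with file locations and the
#' radiological feature labels used for subgroup analysis. Required columns:
#' `case_id, image_path, mask_path, composition, lobulated, ica_contact,
#' sinus_invasion, center`. Booleans accept `0/1/true/false` in any case;
#' `composition` is parsed case-insensitively.
#'
#' @param path CSV file with a header row.
#' @return A `data.frame`, one row per case, with typed columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' not found", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  comp <- tolower(trimws(df$composition))
  bad <- setdiff(unique(comp), COMPOSITIONS)
  if (length(bad))
    stop(sprintf("unknown composition value(s): %s", paste(bad, collapse = ", ")))
  data.frame(case_id = df$case_id,
             image_path = df$image_path,
             mask_path = df$mask_path,
             composition = comp,
             lobulated = parse_flag(df$lobulated, "lobulated"),
             ica_contact = parse_flag(df$ica_contact, "ica_contact"),
             sinus_invasion = parse_flag(df$sinus_invasion, "sinus_invasion"),
             center = df$center,
             stringsAsFactors = FALSE)
}

#' Write a case manifest CSV
#'
#' @param manifest Data frame with the columns of [read_manifest()].
#' @param path Output CSV path.
#' @return Invisibly, the path written.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(MANIFEST_COLUMNS, names(manifest))
  if (length(missing))
    stop(sprintf("manifest is missing required column(s): %s",
                 paste(missing, collapse = ", ")))
  out <- manifest[, MANIFEST_COLUMNS]
  out$lobulated <- as.integer(out$lobulated)
  out$ica_contact <- as.integer(out$ica_contact)
  out$sinus_invasion <- as.integer(out$sinus_invasion)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
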