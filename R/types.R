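#' Construct a 3D image volume
#'
#' The unit all pipeline stages pass around: a 3D scalar array of coronal
#' slices (in-plane rows x cols, slices stacked along the third axis) together
#' with its voxel spacing in millimetres.
#'
#' @param data 3D numeric array; no dimension may be zero.
#' @param spacing Numeric length-3 vector `(sx, sy, sz)` in mm, all > 0.
#' @param orientation Label for the in-plane axes; `"coronal"` for coronal
#'   stacks, `"unknown"` when the source header did not say.
#' @return An object of class `image_volume` with fields `data`, `spacing`,
#'   `orientation`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), orientation = "coronal") {
  data <- as_array3d(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  structure(list(data = data, spacing = spacing, orientation = orientation),
            class = "image_volume")
}

#' Construct a binary segmentation mask
#'
#' @param data 3D array with values in {0, 1}.
#' @param spacing Voxel spacing in mm, as in [image_volume()].
#' @return An object of class `seg_mask`.
#' @export
seg_mask <- function(data, spacing = c(1, 1, 1)) {
  data <- as_array3d(data)
  if (!all(data %in% c(0, 1)))
    stop("mask voxels must be exactly 0 or 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers (mm)")
  structure(list(data = data, spacing = spacing), class = "seg_mask")
}

as_array3d <- function(data) {
  if (is.null(dim(data))) {
    if (!is.numeric(data)) stop("data must be an array")
    dim(data) <- length(data)
  }
  d <- dim(data)
  while (length(d) < 3L) d <- c(d, 1L)           # promote 1-D/2-D inputs
  while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
  if (length(d) != 3L) stop("data must have exactly 3 dimensions")
  if (any(d == 0L)) stop("no dimension may have size 0")
  data <- array(as.numeric(data), d)             # drop foreign attributes
  data
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing (%s) mm, %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "), x$orientation))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, %d foreground, spacing (%s) mm\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.seg_mask <- function(x) dim(x$data)

check_aligned <- function(vol, mask) {
  if (!identical(dim(vol$data), dim(mask$data)))
    stop("image and mask shapes differ")
  if (max(abs(vol$spacing - mask$spacing)) > 1e-9)
    stop("image and mask spacings differ")
  invisible(TRUE)
}

# Valid tumour composition categories (radiological feature taxonomy).
COMPOSITIONS <- c("cystic", "solid", "mixed")

#' Per-case radiological metadata
#'
#' @param case_id Case identifier string.
#' @param composition One of `"cystic"`, `"solid"`, `"mixed"` (case-insensitive).
#' @param lobulated,ica_contact,sinus_invasion Logical feature flags:
#'   lobulated outline, compressed/enclosed internal carotid artery, cavernous
#'   sinus invasion.
#' @param center Acquisition centre label (`"A"`, `"B"`, or `"synthetic"`).
#' @return A one-row `data.frame` of class `case_meta`.
#' @export
case_meta <- function(case_id, composition, lobulated = FALSE,
                      ica_contact = FALSE, sinus_invasion = FALSE,
                      center = "synthetic") {
  composition <- tolower(as.character(composition))
  if (!composition %in% COMPOSITIONS)
    stop(sprintf("unknown composition '%s' (expected one of %s)",
                 composition, paste(COMPOSITIONS, collapse = ", ")))
  out <- data.frame(case_id = as.character(case_id),
                    composition = composition,
                    lobulated = as.logical(lobulated),
                    ica_contact = as.logical(ica_contact),
                    sinus_invasion = as.logical(sinus_invasion),
                    center = as.character(center),
                    stringsAsFactors = FALSE)
  class(out) <- c("case_meta", class(out))
  out
}
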