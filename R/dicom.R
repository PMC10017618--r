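# Minimal DICOM series reader: uncompressed little-endian transfer syntaxes
# (implicit VR 1.2.840.10008.1.2 and explicit VR 1.2.840.10008.1.2.1),
# single-frame grayscale images. DICOM is a read-only input format here;
# everything is written back out as NIfTI-1.

u16 <- function(raw2) sum(as.integer(raw2) * c(1L, 256L))
u32 <- function(raw4) sum(as.numeric(raw4) * c(1, 256, 65536, 16777216))

# VRs whose explicit encoding uses a 2-byte reserved field + 4-byte length
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

dicom_parse_elements <- function(raw, pos, explicit, stop_at = length(raw), wanted) {
  out <- list()
  while (pos + 7 <= stop_at) {
    group <- u16(raw[pos:(pos + 1)]); elem <- u16(raw[(pos + 2):(pos + 3)])
    pos <- pos + 4
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1)])
      if (vr %in% LONG_VRS) {
        len <- u32(raw[(pos + 4):(pos + 7)]); pos <- pos + 8
      } else {
        len <- u16(raw[(pos + 2):(pos + 3)]); pos <- pos + 4
      }
    } else {
      vr <- NA_character_
      len <- u32(raw[pos:(pos + 3)]); pos <- pos + 4
    }
    if (len == 4294967295)
      stop("DICOM element with undefined length (sequences/encapsulation unsupported)")
    key <- sprintf("%04X,%04X", group, elem)
    if (key %in% wanted)
      out[[key]] <- list(vr = vr, bytes = if (len > 0) raw[pos:(pos + len - 1)] else raw(0))
    pos <- pos + len
    if (all(wanted %in% names(out))) break
  }
  out
}

# UI values are NUL-padded to even length; drop NULs before decoding
dicom_str <- function(el) {
  if (is.null(el)) return(NA_character_)
  trimws(rawToChar(el$bytes[el$bytes != as.raw(0)]))
}
dicom_us  <- function(el) if (is.null(el)) NA_integer_ else u16(el$bytes[1:2])
dicom_ds  <- function(el) {
  if (is.null(el)) return(NA_real_)
  as.numeric(strsplit(dicom_str(el), "\\\\")[[1]])
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop(sprintf("'%s' is not a DICOM part-10 file", path))
  # File meta group (0002) is always explicit VR little endian
  meta <- dicom_parse_elements(raw, 133, explicit = TRUE, wanted = "0002,0010")
  ts <- dicom_str(meta[["0002,0010"]])
  if (is.na(ts)) stop("missing transfer syntax UID")
  if (!ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop(sprintf("unsupported DICOM transfer syntax '%s'", ts))
  explicit <- ts == "1.2.840.10008.1.2.1"
  # Skip past the meta group: re-scan from after preamble counting group 0002
  pos <- 133
  repeat {
    group <- u16(raw[pos:(pos + 1)])
    if (group != 2L) break
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- u32(raw[(pos + 8):(pos + 11)]); pos <- pos + 12 + len
    } else {
      len <- u16(raw[(pos + 6):(pos + 7)]); pos <- pos + 8 + len
    }
  }
  wanted <- c("0008,0060", "0020,000E", "0020,0013", "0020,1041", "0020,0032",
              "0018,0050", "0018,0088", "0028,0010", "0028,0011", "0028,0030",
              "0028,0100", "0028,0103", "7FE0,0010")
  el <- dicom_parse_elements(raw, pos, explicit, wanted = wanted)
  rows <- dicom_us(el[["0028,0010"]]); cols <- dicom_us(el[["0028,0011"]])
  bits <- dicom_us(el[["0028,0100"]]); signed <- identical(dicom_us(el[["0028,0103"]]), 1L)
  px <- el[["7FE0,0010"]]
  if (is.null(px) || is.na(rows) || is.na(cols))
    stop(sprintf("'%s' lacks image pixel data", path))
  if (!bits %in% c(8L, 16L))
    stop(sprintf("unsupported BitsAllocated %d", bits))
  vals <- readBin(px$bytes, what = "integer", n = rows * cols,
                  size = bits / 8L, signed = if (bits == 8L) FALSE else signed,
                  endian = "little")
  if (bits == 16L && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
  list(series_uid = dicom_str(el[["0020,000E"]]),
       instance = suppressWarnings(as.integer(dicom_str(el[["0020,0013"]]))),
       slice_loc = suppressWarnings(dicom_ds(el[["0020,1041"]])[1]),
       ipp = dicom_ds(el[["0020,0032"]]),
       thickness = dicom_ds(el[["0018,0050"]])[1],
       gap = dicom_ds(el[["0018,0088"]])[1],
       pixel_spacing = dicom_ds(el[["0028,0030"]]),
       # DICOM pixel data is row-major; R arrays are column-major
       pixels = t(matrix(as.numeric(vals), nrow = cols, ncol = rows)))
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop(sprintf("directory '%s' contains no DICOM files", dir))
  slices <- lapply(files, read_dicom_file)
  uids <- unique(vapply(slices, function(s) s$series_uid, character(1)))
  if (length(uids) > 1L)
    stop(sprintf("directory '%s' mixes %d DICOM series; expected exactly one",
                 dir, length(uids)))
  loc <- vapply(slices, function(s) {
    if (!is.na(s$slice_loc)) s$slice_loc
    else if (length(s$ipp) == 3 && !anyNA(s$ipp)) s$ipp[2]  # coronal: sort on A-P
    else as.numeric(s$instance)
  }, numeric(1))
  ord <- order(loc)
  slices <- slices[ord]; loc <- loc[ord]
  first <- slices[[1]]
  dz <- if (length(loc) > 1L && !anyNA(loc)) {
    d <- abs(diff(loc)); if (all(d > 0)) stats::median(d) else NA_real_
  } else NA_real_
  if (is.na(dz) || dz == 0) dz <- if (!is.na(first$gap)) first$gap else first$thickness
  if (is.na(dz) || dz <= 0) dz <- 1
  ps <- first$pixel_spacing
  if (length(ps) < 2 || anyNA(ps)) ps <- c(1, 1)
  arr <- array(0, c(dim(first$pixels), length(slices)))
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]$pixels), dim(first$pixels)))
      stop("DICOM slices in series have inconsistent dimensions")
    arr[, , i] <- slices[[i]]$pixels
  }
  image_volume(arr, spacing = c(ps[1], ps[2], dz), orientation = "coronal")
}
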