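#' Preprocessing configuration
#'
#' Defaults mirror the training recipe: in-plane size 256 x 256, isotropic
#' 1 x 1 x 1 mm resampling, per-volume min-max normalization to \[0,1\], then
#' slice-wise CLAHE.
#'
#' @param out_size In-plane output size `(H, W)` in pixels; components >= 8.
#' @param target_spacing Target voxel spacing `(sx, sy, sz)` in mm.
#' @param clahe_clip Normalized CLAHE clip limit (fraction of tile pixels per
#'   histogram bin before clipping; skimage convention). Default 0.01.
#' @param clahe_tiles CLAHE tile grid `(rows, cols)`; each tile must cover at
#'   least 4 px.
#' @param intensity_eps Range guard: volumes whose max-min falls below this are
#'   mapped to all zeros instead of being divided by ~0.
#' @param order Order in which the four steps run. The default resamples to
#'   isotropic spacing first and resizes last among the geometric steps, so
#'   the output slice size is always exactly `out_size` (the network's fixed
#'   input size); the in-plane spacing is rescaled by the final resize and
#'   recorded honestly. Reorderable (e.g. resize before resample) because
#'   which came first is not a settled convention.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(out_size = c(256, 256),
                              target_spacing = c(1, 1, 1),
                              clahe_clip = 0.01,
                              clahe_tiles = c(8, 8),
                              intensity_eps = 1e-8,
                              order = c("resample", "resize", "normalize", "clahe")) {
  out_size <- as.integer(out_size)
  if (length(out_size) != 2L || any(out_size < 8L))
    stop("out_size must be two integers >= 8")
  if (any(target_spacing <= 0)) stop("target_spacing must be positive")
  if (clahe_clip <= 0) stop("clahe_clip must be > 0")
  clahe_tiles <- as.integer(clahe_tiles)
  if (any(clahe_tiles < 1L) || any(out_size / clahe_tiles < 4))
    stop("each CLAHE tile must cover at least 4 px")
  if (!all(order %in% c("resize", "resample", "normalize", "clahe")))
    stop("order may contain only resize/resample/normalize/clahe")
  structure(list(out_size = out_size, target_spacing = as.numeric(target_spacing),
                 clahe_clip = clahe_clip, clahe_tiles = clahe_tiles,
                 intensity_eps = intensity_eps, order = order),
            class = "preprocess_config")
}

#' Augmentation configuration
#'
#' Per-epoch augmentation of training sections: random horizontal and vertical
#' flips and a rotation drawn uniformly from `rot_range_deg` (default
#' -10..10 degrees), applied identically to image and mask.
#'
#' @param p_hflip,p_vflip Flip probabilities in \[0,1\].
#' @param rot_range_deg Rotation range `(low, high)` in degrees, `low <= high`.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(p_hflip = 0.5, p_vflip = 0.5,
                           rot_range_deg = c(-10, 10)) {
  if (p_hflip < 0 || p_hflip > 1 || p_vflip < 0 || p_vflip > 1)
    stop("flip probabilities must be in [0,1]")
  if (length(rot_range_deg) != 2L || rot_range_deg[1] > rot_range_deg[2])
    stop("rot_range_deg must be (low, high) with low <= high")
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 rot_range_deg = as.numeric(rot_range_deg)),
            class = "augment_config")
}

# 1D linear interpolation tables for one axis: output index -> input lo/hi/frac.
# Center-aligned: input coordinate of output voxel i is (i+0.5)*ratio - 0.5.
interp_axis <- function(n_in, n_out, ratio) {
  x <- (seq_len(n_out) - 0.5) * ratio + 0.5  # 1-based input coordinate
  x <- pmin(pmax(x, 1), n_in)
  lo <- pmin(floor(x), n_in - ifelse(n_in > 1, 1, 0))
  if (n_in == 1L) lo <- rep(1, n_out)
  frac <- x - lo
  list(lo = as.integer(lo), hi = as.integer(pmin(lo + 1, n_in)), frac = frac)
}

trilinear_resample <- function(arr, n_out, ratios) {
  ax <- mapply(interp_axis, dim(arr), n_out, ratios, SIMPLIFY = FALSE)
  out <- array(0, n_out)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - ax[[1]]$frac else ax[[1]]$frac
    wy <- if (dy == 0) 1 - ax[[2]]$frac else ax[[2]]$frac
    wz <- if (dz == 0) 1 - ax[[3]]$frac else ax[[3]]$frac
    w <- outer(outer(wx, wy), wz)
    ix <- if (dx == 0) ax[[1]]$lo else ax[[1]]$hi
    iy <- if (dy == 0) ax[[2]]$lo else ax[[2]]$hi
    iz <- if (dz == 0) ax[[3]]$lo else ax[[3]]$hi
    out <- out + w * arr[ix, iy, iz, drop = FALSE]
  }
  out
}

nearest_resample <- function(arr, n_out, ratios) {
  idx <- mapply(function(n_in, n_o, r) {
    i <- round((seq_len(n_o) - 0.5) * r + 0.5)
    as.integer(pmin(pmax(i, 1), n_in))
  }, dim(arr), n_out, ratios, SIMPLIFY = FALSE)
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Resample a volume (and optionally its mask) to a target spacing
#'
#' The output grid has `round(size * spacing / target)` voxels per axis
#' (minimum 1), preserving physical extent to within one output voxel. Images
#' are interpolated trilinearly, masks by nearest neighbour so they stay
#' binary. Already-at-target inputs are returned unchanged.
#'
#' @param vol An [image_volume()].
#' @param mask Optional aligned [seg_mask()].
#' @param target_spacing Spacing triple in mm, all > 0.
#' @return `list(vol = , mask = )` (mask `NULL` when not supplied).
#' @export
resample_isotropic <- function(vol, mask = NULL, target_spacing = c(1, 1, 1)) {
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(target_spacing <= 0))
    stop("target_spacing must be three positive numbers")
  if (!is.null(mask)) check_aligned(vol, mask)
  if (max(abs(vol$spacing - target_spacing)) < 1e-9)
    return(list(vol = vol, mask = mask))
  n_in <- dim(vol$data)
  n_out <- pmax(1L, as.integer(round(n_in * vol$spacing / target_spacing)))
  ratios <- n_in / n_out
  out_vol <- image_volume(trilinear_resample(vol$data, n_out, ratios),
                          spacing = target_spacing, orientation = vol$orientation)
  out_mask <- NULL
  if (!is.null(mask))
    out_mask <- seg_mask(nearest_resample(mask$data, n_out, ratios),
                         spacing = target_spacing)
  list(vol = out_vol, mask = out_mask)
}

resize_slice_2d <- function(m, out_size, bilinear = TRUE) {
  img <- EBImage::resize(EBImage::Image(m), w = out_size[1], h = out_size[2],
                         filter = if (bilinear) "bilinear" else "none")
  matrix(EBImage::imageData(img), nrow = out_size[1], ncol = out_size[2])
}

#' Resize every slice to a fixed in-plane size
#'
#' Bilinear for the image, nearest neighbour for the mask; the in-plane
#' spacing is rescaled by `old_size / new_size` so the slice keeps its
#' physical extent.
#'
#' @inheritParams resample_isotropic
#' @param out_size `(H, W)` target in pixels.
#' @return `list(vol = , mask = )`.
#' @export
resize_slices <- function(vol, mask = NULL, out_size = c(256, 256)) {
  out_size <- as.integer(out_size)
  if (!is.null(mask)) check_aligned(vol, mask)
  d <- dim(vol$data)
  if (all(d[1:2] == out_size)) return(list(vol = vol, mask = mask))
  new_spacing <- c(vol$spacing[1:2] * d[1:2] / out_size, vol$spacing[3])
  arr <- array(0, c(out_size, d[3]))
  for (k in seq_len(d[3])) arr[, , k] <- resize_slice_2d(vol$data[, , k], out_size)
  out_vol <- image_volume(arr, spacing = new_spacing, orientation = vol$orientation)
  out_mask <- NULL
  if (!is.null(mask)) {
    marr <- array(0, c(out_size, d[3]))
    for (k in seq_len(d[3]))
      marr[, , k] <- resize_slice_2d(mask$data[, , k], out_size, bilinear = FALSE)
    marr[] <- ifelse(marr > 0.5, 1, 0)
    out_mask <- seg_mask(marr, spacing = new_spacing)
  }
  list(vol = out_vol, mask = out_mask)
}

#' Min-max normalize a volume to \[0,1\]
#'
#' `(x - min) / (max - min)` over the whole volume; a constant volume (range
#' below `eps`) maps to all zeros.
#'
#' @param vol An [image_volume()].
#' @param eps Range guard; default `1e-8`.
#' @return The normalized [image_volume()].
#' @export
normalize_unit <- function(vol, eps = 1e-8) {
  r <- range(vol$data)
  data <- if (diff(r) < eps) array(0, dim(vol$data)) else (vol$data - r[1]) / diff(r)
  image_volume(data, spacing = vol$spacing, orientation = vol$orientation)
}

#' Slice-wise contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE to each coronal slice of a \[0,1\] volume. Constant slices are
#' passed through unchanged (there is no contrast to redistribute). Output is
#' clamped to \[0,1\].
#'
#' @param vol An [image_volume()] with intensities in \[0,1\].
#' @param clahe_clip Normalized clip limit (see [preprocess_config()]).
#' @param clahe_tiles Tile grid `(rows, cols)`.
#' @return The enhanced [image_volume()].
#' @export
clahe_enhance <- function(vol, clahe_clip = 0.01, clahe_tiles = c(8, 8)) {
  r <- range(vol$data)
  if (r[1] < -1e-6 || r[2] > 1 + 1e-6)
    stop("clahe_enhance expects intensities in [0,1]; normalize first")
  bins <- 256L
  d <- dim(vol$data)
  arr <- vol$data
  for (k in seq_len(d[3])) {
    sl <- arr[, , k]
    if (diff(range(sl)) < 1e-12) next
    eq <- EBImage::clahe(EBImage::Image(pmin(pmax(sl, 0), 1)),
                         nx = clahe_tiles[1], ny = clahe_tiles[2],
                         bins = bins, limit = clahe_clip * bins)
    arr[, , k] <- matrix(EBImage::imageData(eq), d[1], d[2])
  }
  arr[] <- pmin(pmax(arr, 0), 1)
  image_volume(arr, spacing = vol$spacing, orientation = vol$orientation)
}

#' Full preprocessing chain for one case
#'
#' Runs resize, isotropic resampling, \[0,1\] normalization, and slice-wise
#' CLAHE (in `cfg$order`). The mask, when given, follows the image through
#' every geometric step and stays binary and aligned.
#'
#' @param vol An [image_volume()].
#' @param mask Optional aligned [seg_mask()].
#' @param cfg A [preprocess_config()].
#' @return `list(vol = , mask = )`.
#' @export
preprocess_case <- function(vol, mask = NULL, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  for (step in cfg$order) {
    res <- switch(step,
      resize = resize_slices(vol, mask, cfg$out_size),
      resample = resample_isotropic(vol, mask, cfg$target_spacing),
      normalize = list(vol = normalize_unit(vol, cfg$intensity_eps), mask = mask),
      clahe = list(vol = clahe_enhance(vol, cfg$clahe_clip, cfg$clahe_tiles),
                   mask = mask))
    vol <- res$vol; mask <- res$mask
  }
  list(vol = vol, mask = mask)
}

# Bilinear/nearest rotation of one slice about its center, zero fill outside.
rotate_slice <- function(m, angle_deg, bilinear = TRUE) {
  if (angle_deg == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  tgt <- cbind(rep(seq_len(h), times = w) - ci, rep(seq_len(w), each = h) - cj)
  # inverse mapping: rotate target grid by -theta into source coordinates
  si <- cos(th) * tgt[, 1] + sin(th) * tgt[, 2] + ci
  sj <- -sin(th) * tgt[, 1] + cos(th) * tgt[, 2] + cj
  if (bilinear) {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    val <- numeric(h * w)
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di; jj <- j0 + dj
      ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
      wgt <- (if (di == 0) 1 - fi else fi) * (if (dj == 0) 1 - fj else fj)
      idx <- (jj[ok] - 1) * h + ii[ok]
      val[ok] <- val[ok] + wgt[ok] * m[idx]
    }
  } else {
    ii <- round(si); jj <- round(sj)
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    val <- numeric(h * w)
    val[ok] <- m[(jj[ok] - 1) * h + ii[ok]]
  }
  matrix(val, h, w)
}

#' Randomly augment one image/mask slice pair
#'
#' Draws one horizontal-flip, one vertical-flip and one rotation angle and
#' applies the identical geometric transform to both slices: image rotation is
#' bilinear, mask rotation nearest neighbour re-binarized, out-of-canvas
#' pixels are zero-filled. Uses the R random stream, so results are
#' reproducible given the RNG state (e.g. after `set.seed()`).
#'
#' @param image_slice,mask_slice Matrices of identical shape.
#' @param cfg An [augment_config()].
#' @return `list(image = , mask = )`.
#' @export
augment_pair <- function(image_slice, mask_slice, cfg = augment_config()) {
  if (!identical(dim(image_slice), dim(mask_slice)))
    stop("image and mask slices must have the same shape")
  do_h <- stats::runif(1) < cfg$p_hflip
  do_v <- stats::runif(1) < cfg$p_vflip
  ang <- stats::runif(1, cfg$rot_range_deg[1], cfg$rot_range_deg[2])
  if (do_h) { image_slice <- image_slice[, ncol(image_slice):1]
              mask_slice <- mask_slice[, ncol(mask_slice):1] }
  if (do_v) { image_slice <- image_slice[nrow(image_slice):1, ]
              mask_slice <- mask_slice[nrow(mask_slice):1, ] }
  if (ang != 0) {
    image_slice <- rotate_slice(image_slice, ang, bilinear = TRUE)
    mask_slice <- rotate_slice(mask_slice, ang, bilinear = FALSE)
    mask_slice[] <- ifelse(mask_slice > 0.5, 1, 0)
  }
  list(image = image_slice, mask = mask_slice)
}
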