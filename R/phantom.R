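# Synthetic sellar-tumor phantoms: coronal T1CE-like appearance with an
# enhancing rim, dark cyst fluid, bright solid component, optional lobulated
# outline, and a bright tubular vessel distractor adjacent to (but excluded
# from) the ground-truth mask -- the annotation convention for peripheral
# vessels such as the internal carotid artery.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Geometry and appearance parameters for one synthetic case. Intensity
#' defaults reproduce the contrast that makes cystic tumors hard: a dark cyst
#' interior (darker than brain) enclosed by a thin enhancing rim, with the
#' vessel as bright as the rim. The ordering
#' `cyst_intensity < brain_intensity < rim_intensity` is enforced.
#'
#' @param size Volume size `(H, W, S)` in voxels (in-plane rows, cols, slices).
#' @param spacing Voxel spacing in mm.
#' @param composition `"cystic"`, `"solid"` or `"mixed"`.
#' @param lobulated Logical; lobulated outline (union of overlapping lobes).
#' @param n_lobes Number of ellipsoidal lobes; >= 2 required when lobulated.
#' @param vessel_distractor Paint a bright tube touching the tumor boundary
#'   (emulates a compressed/enclosed carotid; never part of the mask).
#' @param sinus_extension Small lateral protrusion of the mask (drives the
#'   cavernous-sinus subgroup label).
#' @param rim_intensity,solid_intensity,cyst_intensity,brain_intensity,background_intensity
#'   Rendering intensities in \[0,1\].
#' @param noise_sigma Additive Gaussian noise SD.
#' @param smoothing_sigma_mm Gaussian smoothing applied before noise, in mm.
#' @param lobe_radius_mm In-plane lobe semi-axis range `(lo, hi)` in mm;
#'   through-plane semi-axes are 0.3x this range so tumors span several slices.
#' @param rim_voxels Rim shell thickness in voxels.
#' @param seed Integer seed; the phantom is a deterministic function of the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256, 256, 24), spacing = c(1, 1, 1),
                         composition = "mixed", lobulated = FALSE,
                         n_lobes = if (lobulated) 3L else 1L,
                         vessel_distractor = FALSE, sinus_extension = FALSE,
                         rim_intensity = 0.85, solid_intensity = 0.6,
                         cyst_intensity = 0.15, brain_intensity = 0.35,
                         background_intensity = 0.02,
                         noise_sigma = 0.03, smoothing_sigma_mm = 0.5,
                         lobe_radius_mm = c(8, 25), rim_voxels = 2L,
                         seed = 1L) {
  composition <- tolower(composition)
  if (!composition %in% COMPOSITIONS) stop("unknown composition")
  if (!(cyst_intensity < brain_intensity && brain_intensity < rim_intensity))
    stop("intensity ordering violated: need cyst < brain < rim")
  if (lobulated && n_lobes < 2L) stop("a lobulated phantom needs n_lobes >= 2")
  if (n_lobes < 1L) stop("n_lobes must be >= 1")
  if (noise_sigma < 0 || smoothing_sigma_mm < 0) stop("sigmas must be >= 0")
  structure(list(size = as.integer(size), spacing = as.numeric(spacing),
                 composition = composition, lobulated = lobulated,
                 n_lobes = as.integer(n_lobes),
                 vessel_distractor = vessel_distractor,
                 sinus_extension = sinus_extension,
                 rim_intensity = rim_intensity, solid_intensity = solid_intensity,
                 cyst_intensity = cyst_intensity, brain_intensity = brain_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma,
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 lobe_radius_mm = as.numeric(lobe_radius_mm),
                 rim_voxels = as.integer(rim_voxels), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian smoothing; sigma in voxels per axis, edge replication.
gauss_smooth3d <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-6) next
    h <- max(1L, ceiling(3 * s))
    k <- exp(-((-h:h)^2) / (2 * s^2)); k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    mp <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(d[1], h), , drop = FALSE])
    out <- matrix(0, d[1], ncol(m))
    for (t in seq_len(2 * h + 1))
      out <- out + k[t] * mp[t:(t + d[1] - 1), , drop = FALSE]
    arr <- aperm(array(out, d), order(perm))
  }
  arr
}

# One 6-neighbour erosion step (image border counts as background).
erode6 <- function(m) {
  d <- dim(m)
  shift <- function(ax, by) {
    out <- array(0, d)
    n <- d[ax]
    if (n == 1L) return(out)  # border is background: size-1 axes erode away
    idx_src <- lapply(d, seq_len); idx_dst <- idx_src
    if (by == 1) { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- 1:(n - 1) }
    else { idx_dst[[ax]] <- 1:(n - 1); idx_src[[ax]] <- 2:n }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  out <- m
  for (ax in 1:3) for (by in c(1, -1)) out <- out * shift(ax, by)
  out
}

ellipsoid_mask <- function(size, spacing, center_mm, semi_mm) {
  cx <- (seq_len(size[1]) - 0.5) * spacing[1]
  cy <- (seq_len(size[2]) - 0.5) * spacing[2]
  cz <- (seq_len(size[3]) - 0.5) * spacing[3]
  dx2 <- ((cx - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((cy - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((cz - center_mm[3]) / semi_mm[3])^2
  q <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(as.numeric(q <= 1), size)
}

#' Generate one synthetic image/mask/metadata triple
#'
#' Renders an elliptical "head" of brain-intensity tissue on a dark
#' background, places a tumor (union of overlapping ellipsoidal lobes) in a
#' midline suprasellar position, renders it per composition (solid: uniform
#' bright; cystic: enhancing rim around dark fluid; mixed: rim plus a
#' solid/cystic split interior), optionally adds a bright tubular vessel
#' hugging the tumor boundary (excluded from the mask) and a lateral sinus
#' protrusion (included), then smooths and adds Gaussian noise. Deterministic
#' given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return `list(vol = image_volume, mask = seg_mask, meta = case_meta row)`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  size <- spec$size; sp <- spec$spacing
  ext <- size * sp                     # physical extent, mm
  head_c <- ext / 2
  head_semi <- c(0.45, 0.42, 0.55) * ext
  # tumor centroid jittered within the central third of the head
  tum_c <- head_c + stats::runif(3, -1, 1) * ext / 6 * c(1, 1, 0.5)
  rad <- spec$lobe_radius_mm
  lobes <- vector("list", spec$n_lobes)
  centers <- matrix(0, spec$n_lobes, 3)
  semis <- matrix(0, spec$n_lobes, 3)
  for (l in seq_len(spec$n_lobes)) {
    semi <- c(stats::runif(2, rad[1], rad[2]), stats::runif(1, 0.3 * rad[1], 0.3 * rad[2]))
    if (l == 1L) ctr <- tum_c
    else {
      # offset in-plane by ~60% of the parent radius so lobes overlap
      phi <- stats::runif(1, 0, 2 * pi)
      ctr <- centers[1, ] + 0.6 * mean(semis[1, 1:2]) * c(cos(phi), sin(phi), 0)
    }
    centers[l, ] <- ctr; semis[l, ] <- semi
    lobes[[l]] <- ellipsoid_mask(size, sp, ctr, semi)
  }
  mask <- array(as.numeric(Reduce(`+`, lobes) > 0), size)
  if (spec$sinus_extension) {
    # small lateral protrusion toward the vessel side, part of the mask
    lat <- tum_c + c(0, 0.9 * max(semis[, 2]), 0)
    mask <- array(as.numeric(
      mask + ellipsoid_mask(size, sp, lat, c(0.35, 0.5, 0.3) * max(3, rad[1])) > 0), size)
  }
  if (sum(mask) == 0) stop("degenerate phantom: empty tumor mask")
  # the tumor must sit inside the head ellipse
  hx <- ((seq_len(size[1]) - 0.5) * sp[1] - head_c[1]) / (0.95 * head_semi[1])
  hy <- ((seq_len(size[2]) - 0.5) * sp[2] - head_c[2]) / (0.95 * head_semi[2])
  hz <- ((seq_len(size[3]) - 0.5) * sp[3] - head_c[3]) / (0.95 * head_semi[3])
  inside_head <- outer(outer(hx^2, hy^2, "+"), hz^2, "+") <= 1
  if (any(mask > 0 & !inside_head))
    stop("tumor does not fit inside the head ellipse; reduce lobe_radius_mm")
  # render
  img <- array(spec$background_intensity, size)
  head_full <- outer(outer(((seq_len(size[1]) - 0.5) * sp[1] - head_c[1])^2 / head_semi[1]^2,
                           ((seq_len(size[2]) - 0.5) * sp[2] - head_c[2])^2 / head_semi[2]^2, "+"),
                     ((seq_len(size[3]) - 0.5) * sp[3] - head_c[3])^2 / head_semi[3]^2, "+") <= 1
  texture <- gauss_smooth3d(array(stats::rnorm(prod(size)), size), 2 / sp)
  texture <- 0.04 * texture / max(stats::sd(texture), 1e-8)
  img[head_full] <- spec$brain_intensity + texture[head_full]
  interior <- mask
  for (k in seq_len(spec$rim_voxels)) interior <- erode6(interior)
  rim <- mask - interior
  if (spec$composition == "solid") {
    img[mask > 0] <- spec$solid_intensity
    img[rim > 0] <- spec$rim_intensity   # enhancing margin
  } else if (spec$composition == "cystic") {
    img[interior > 0] <- spec$cyst_intensity
    img[rim > 0] <- spec$rim_intensity
  } else {
    phi <- stats::runif(1, 0, 2 * pi)
    ci <- tum_c[1] / sp[1]; cj <- tum_c[2] / sp[2]
    split <- outer(cos(phi) * (seq_len(size[1]) - ci), sin(phi) * (seq_len(size[2]) - cj), "+")
    split3 <- array(rep(split, size[3]), size)
    img[interior > 0 & split3 >= 0] <- spec$solid_intensity
    img[interior > 0 & split3 < 0] <- spec$cyst_intensity
    img[rim > 0] <- spec$rim_intensity
  }
  if (spec$vessel_distractor) {
    zs <- which(apply(mask, 3, sum) > 0)
    kz <- zs[ceiling(length(zs) / 2)]
    sl <- mask[, , kz]
    jmax <- max(which(colSums(sl) > 0))
    irow <- round(mean(which(sl[, jmax] > 0)))
    vi <- irow; vj <- jmax + 2  # tube center one voxel beyond the boundary
    if (vj + 1 <= size[2]) {
      di2 <- (seq_len(size[1]) - vi)^2
      dj2 <- (seq_len(size[2]) - vj)^2
      tube2d <- outer(di2, dj2, "+") <= 1.6^2
      zr <- max(1, min(zs) - 2):min(size[3], max(zs) + 2)
      for (k in zr) {
        paint <- tube2d & mask[, , k] == 0  # vessel never enters the mask
        slk <- img[, , k]; slk[paint] <- spec$rim_intensity; img[, , k] <- slk
      }
    }
  }
  if (spec$smoothing_sigma_mm > 0)
    img <- gauss_smooth3d(img, spec$smoothing_sigma_mm / sp)
  if (spec$noise_sigma > 0)
    img <- img + array(stats::rnorm(prod(size), 0, spec$noise_sigma), size)
  img <- pmin(pmax(img, 0), 1)
  meta <- case_meta(case_id = sprintf("synth-%08d", spec$seed),
                    composition = spec$composition, lobulated = spec$lobulated,
                    ica_contact = spec$vessel_distractor,
                    sinus_invasion = spec$sinus_extension, center = "synthetic")
  list(vol = image_volume(img, spacing = sp),
       mask = seg_mask(mask, spacing = sp), meta = meta)
}

#' Generate a synthetic cohort
#'
#' Draws each case's composition from `composition_mix` and its feature flags
#' from `feature_rates`, with per-case seeds derived from the master seed so
#' the whole cohort is reproducible from one integer. The default mix and
#' rates follow the reported cohort: 34.4% cystic / 17.9% solid / 47.7% mixed
#' composition, 43% lobulated, 40.1% carotid contact, 54% sinus invasion.
#'
#' @param n Number of cases (> 0).
#' @param composition_mix Named probabilities over cystic/solid/mixed; must
#'   sum to 1.
#' @param feature_rates Named probabilities for `lobulated`, `ica_contact`,
#'   `sinus_invasion`.
#' @param seed Master seed.
#' @param size,spacing,lobe_radius_mm,noise_sigma Forwarded to [phantom_spec()].
#' @param out_dir Optional directory: when given, NIfTI image/mask pairs and a
#'   `manifest.csv` are written there and the manifest paths point at them.
#' @return `list(cases = , manifest = )`; `cases` is a list of
#'   `list(vol, mask, meta, spec)`.
#' @export
generate_cohort <- function(n,
                            composition_mix = c(cystic = 0.344, solid = 0.179, mixed = 0.477),
                            feature_rates = c(lobulated = 0.43, ica_contact = 0.401,
                                              sinus_invasion = 0.54),
                            seed = 1L,
                            size = c(256, 256, 24), spacing = c(1, 1, 1),
                            lobe_radius_mm = c(8, 25), noise_sigma = 0.03,
                            out_dir = NULL) {
  if (n <= 0) stop("n must be positive")
  if (abs(sum(composition_mix) - 1) > 1e-9)
    stop("composition_mix must sum to 1")
  comp_names <- names(composition_mix)
  if (!setequal(comp_names, COMPOSITIONS)) stop("composition_mix must name cystic/solid/mixed")
  cases <- with_seed(seed, {
    case_seeds <- sample.int(.Machine$integer.max, n)
    comps <- sample(comp_names, n, replace = TRUE, prob = composition_mix)
    lob <- stats::runif(n) < feature_rates[["lobulated"]]
    ica <- stats::runif(n) < feature_rates[["ica_contact"]]
    sin_ <- stats::runif(n) < feature_rates[["sinus_invasion"]]
    lapply(seq_len(n), function(i) {
      sp <- phantom_spec(size = size, spacing = spacing, composition = comps[i],
                         lobulated = lob[i],
                         vessel_distractor = ica[i], sinus_extension = sin_[i],
                         lobe_radius_mm = lobe_radius_mm, noise_sigma = noise_sigma,
                         seed = case_seeds[i])
      out <- generate_phantom(sp)
      out$meta$case_id <- sprintf("synth-%04d", i)
      out$spec <- sp
      out
    })
  })
  manifest <- do.call(rbind, lapply(cases, function(cs) {
    cbind(cs$meta[, "case_id", drop = FALSE],
          image_path = NA_character_, mask_path = NA_character_,
          cs$meta[, c("composition", "lobulated", "ica_contact",
                      "sinus_invasion", "center")])
  }))
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      ip <- file.path(out_dir, sprintf("%s_img.nii.gz", manifest$case_id[i]))
      mp <- file.path(out_dir, sprintf("%s_mask.nii.gz", manifest$case_id[i]))
      write_volume(cases[[i]]$vol, ip)
      write_mask(cases[[i]]$mask, mp)
      manifest$image_path[i] <- ip
      manifest$mask_path[i] <- mp
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  attr(cases, "noise_sigma") <- noise_sigma
  list(cases = cases, manifest = manifest)
}

#' Apply a synthetic acquisition shift to a cohort
#'
#' Emulates an external test set acquired elsewhere: a gamma transform of the
#' \[0,1\] intensities, extra Gaussian noise (`noise_scale` times the cohort's
#' rendering noise; 1 adds none), and optional re-sampling to a different
#' spacing (e.g. thick slices). Masks only change through re-sampling. The
#' identity shift returns the dataset unchanged.
#'
#' @param dataset Output of [generate_cohort()].
#' @param noise_scale Multiplier on the cohort noise SD; extra noise SD is
#'   `(noise_scale - 1) * noise_sigma`.
#' @param intensity_gamma Exponent applied to intensities.
#' @param spacing Optional new spacing triple to resample to.
#' @param seed Seed for the extra noise.
#' @return A dataset of the same shape.
#' @export
domain_shift <- function(dataset, noise_scale = 1, intensity_gamma = 1,
                         spacing = NULL, seed = 1L) {
  base_sigma <- attr(dataset$cases, "noise_sigma")
  if (is.null(base_sigma)) base_sigma <- 0.03
  extra_sd <- max(0, (noise_scale - 1) * base_sigma)
  shifted <- with_seed(seed, lapply(dataset$cases, function(cs) {
    img <- cs$vol$data
    if (intensity_gamma != 1) img <- pmin(pmax(img, 0), 1)^intensity_gamma
    if (extra_sd > 0)
      img <- pmin(pmax(img + array(stats::rnorm(length(img), 0, extra_sd), dim(img)), 0), 1)
    vol <- image_volume(img, spacing = cs$vol$spacing, orientation = cs$vol$orientation)
    mask <- cs$mask
    if (!is.null(spacing) && max(abs(spacing - vol$spacing)) > 1e-9) {
      res <- resample_isotropic(vol, mask, spacing)
      vol <- res$vol; mask <- res$mask
    }
    out <- cs; out$vol <- vol; out$mask <- mask; out
  }))
  attr(shifted, "noise_sigma") <- base_sigma * max(1, noise_scale)
  list(cases = shifted, manifest = dataset$manifest)
}
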