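test_that("resampling to the same spacing is the identity", {
  ph <- desk_phantom(seed = 2)
  out <- resample_isotropic(ph$vol, ph$mask, c(1, 1, 1))
  expect_identical(out$vol$data, ph$vol$data)
  expect_identical(out$mask$data, ph$mask$data)
})

test_that("resampling follows the physical-extent grid rule", {
  # 10 slices at 5 mm thickness, in-plane already 1 mm -> round(10*5/1) = 50
  vol <- image_volume(array(runif(20 * 20 * 10), c(20, 20, 10)),
                      spacing = c(1, 1, 5))
  msk <- seg_mask(array(as.numeric(runif(20 * 20 * 10) > 0.8), c(20, 20, 10)),
                  spacing = c(1, 1, 5))
  out <- resample_isotropic(vol, msk, c(1, 1, 1))
  expect_equal(dim(out$vol$data), c(20L, 20L, 50L))
  expect_equal(out$vol$spacing, c(1, 1, 1))
  expect_true(all(out$mask$data %in% c(0, 1)))
  # physical extent preserved within one output voxel per axis
  expect_lte(abs(50 * 1 - 10 * 5), 1)
  expect_error(resample_isotropic(vol, NULL, c(1, 0, 1)), "positive")
})

test_that("slice resizing preserves physical extent through spacing", {
  vol <- image_volume(array(runif(128 * 128 * 4), c(128, 128, 4)),
                      spacing = c(2, 2, 3))
  msk <- seg_mask(array(as.numeric(runif(128 * 128 * 4) > 0.7), c(128, 128, 4)),
                  spacing = c(2, 2, 3))
  out <- resize_slices(vol, msk, c(256, 256))
  expect_equal(dim(out$vol$data), c(256L, 256L, 4L))
  expect_equal(out$vol$spacing, c(1, 1, 3))
  expect_true(all(out$mask$data %in% c(0, 1)))
  # already at size -> identity
  same <- resize_slices(out$vol, out$mask, c(256, 256))
  expect_identical(same$vol$data, out$vol$data)
})

test_that("unit normalization maps min/max to 0/1 and constants to zero", {
  v <- image_volume(array(seq(100, 300, length.out = 4 * 4 * 2), c(4, 4, 2)))
  nv <- normalize_unit(v)
  expect_equal(range(nv$data), c(0, 1))
  # value 200 with min 100 / max 300 -> 0.5
  v2 <- image_volume(array(c(100, 200, 300), c(3, 1, 1)))
  expect_equal(normalize_unit(v2)$data[2, 1, 1], 0.5)
  const <- image_volume(array(7, c(4, 4, 2)))
  expect_true(all(normalize_unit(const)$data == 0))
})

test_that("CLAHE stays in [0,1], passes constants, and raises local contrast", {
  set.seed(4)
  v <- image_volume(array(runif(64 * 64 * 3), c(64, 64, 3)))
  out <- clahe_enhance(v)
  expect_gte(min(out$data), 0)
  expect_lte(max(out$data), 1)

  const <- image_volume(array(0.4, c(64, 64, 2)))
  expect_equal(clahe_enhance(const)$data, const$data)

  # a low-contrast two-level slice must come out with at least its input
  # contrast between the two level populations
  lv <- array(0.45, c(64, 64, 1)); lv[20:44, 20:44, 1] <- 0.55
  enh <- clahe_enhance(image_volume(lv))
  in_contrast <- 0.55 - 0.45
  out_contrast <- mean(enh$data[20:44, 20:44, 1]) -
    mean(enh$data[, , 1][lv[, , 1] == 0.45])
  expect_gte(out_contrast, in_contrast)

  expect_error(clahe_enhance(image_volume(array(1.5, c(8, 8, 1)))), "\\[0,1\\]")
})

test_that("the full preprocessing chain meets all its postconditions", {
  # anisotropic input: slice size is guaranteed, spacing recorded honestly
  ph <- generate_phantom(phantom_spec(size = c(80, 80, 6), spacing = c(1.5, 1.5, 4),
                                      lobe_radius_mm = c(5, 12), seed = 8))
  cfg <- preprocess_config(out_size = c(64, 64))
  out <- preprocess_case(ph$vol, ph$mask, cfg)
  expect_equal(dim(out$vol$data)[1:2], c(64L, 64L))
  expect_equal(out$vol$spacing[3], 1)                  # resampled through-plane
  expect_equal(out$vol$spacing[1:2], c(120 / 64, 120 / 64))  # resize bookkeeping
  expect_gte(min(out$vol$data), 0)
  expect_lte(max(out$vol$data), 1)
  expect_true(all(out$mask$data %in% c(0, 1)))
  expect_identical(dim(out$vol$data), dim(out$mask$data))

  # geometry-consistent input (1 mm, already out_size): all four hold at once
  ph2 <- desk_phantom(seed = 8)
  out2 <- preprocess_case(ph2$vol, ph2$mask, cfg)
  expect_equal(dim(out2$vol$data)[1:2], c(64L, 64L))
  expect_equal(out2$vol$spacing, c(1, 1, 1))
  expect_gte(min(out2$vol$data), 0)
  expect_lte(max(out2$vol$data), 1)

  # an already-preprocessed case is stable up to CLAHE re-application
  cfg2 <- preprocess_config(out_size = c(64, 64),
                            order = c("resample", "resize", "normalize"))
  once <- preprocess_case(ph2$vol, ph2$mask, cfg2)
  twice <- preprocess_case(once$vol, once$mask, cfg2)
  expect_lt(max(abs(twice$vol$data - once$vol$data)), 1e-6)
  expect_identical(twice$mask$data, once$mask$data)
})

test_that("augmentation is identity-configurable, deterministic, and alignment-safe", {
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- matrix(as.numeric(runif(64 * 64) > 0.8), 64, 64)
  idcfg <- augment_config(p_hflip = 0, p_vflip = 0, rot_range_deg = c(0, 0))
  out <- augment_pair(img, msk, idcfg)
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)

  cfg <- augment_config()
  set.seed(99); a <- augment_pair(img, msk, cfg)
  set.seed(99); b <- augment_pair(img, msk, cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_error(augment_pair(img, msk[1:32, ]), "same shape")
})

test_that("rotation of a centered disk changes its mask area by less than 15%", {
  # rasterized disk, radius 18 px, centered in a 64x64 slice
  idx <- expand.grid(i = 1:64, j = 1:64)
  disk <- matrix(as.numeric((idx$i - 32.5)^2 + (idx$j - 32.5)^2 <= 18^2), 64, 64)
  cfg <- augment_config(p_hflip = 0, p_vflip = 0, rot_range_deg = c(-10, 10))
  set.seed(123)
  for (r in 1:20) {
    out <- augment_pair(disk, disk, cfg)
    expect_lt(abs(sum(out$mask) - sum(disk)) / sum(disk), 0.15)
  }
})
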