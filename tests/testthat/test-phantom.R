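test_that("phantoms are deterministic functions of their spec", {
  sp <- phantom_spec(size = c(48, 48, 10), lobe_radius_mm = c(3, 7),
                     composition = "mixed", vessel_distractor = TRUE, seed = 42)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$vol$data, b$vol$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$meta, b$meta)
})

test_that("spec invariants are enforced at construction", {
  expect_error(phantom_spec(cyst_intensity = 0.5, brain_intensity = 0.35),
               "ordering")
  expect_error(phantom_spec(lobulated = TRUE, n_lobes = 1), "n_lobes")
  expect_error(phantom_spec(composition = "calcified"), "composition")
  # a tumor larger than the head must be refused
  expect_error(generate_phantom(
    phantom_spec(size = c(32, 32, 8), lobe_radius_mm = c(30, 40), seed = 1)),
    "fit inside")
})

test_that("masks are non-empty, binary, and single-component under 6-connectivity", {
  for (seed in 1:6) {
    ph <- generate_phantom(phantom_spec(size = c(64, 64, 12),
                                        lobe_radius_mm = c(3, 8),
                                        lobulated = TRUE, n_lobes = 3,
                                        seed = seed))
    m <- ph$mask$data
    expect_gt(sum(m), 0)
    expect_true(all(m %in% c(0, 1)))
    # flood fill from one foreground voxel reaches all of them
    start <- which(m == 1)[1]
    lab <- array(0, dim(m)); lab[start] <- 1
    repeat {
      grown <- lab
      d <- dim(m)
      grown[-1, , ] <- pmax(grown[-1, , ], lab[-d[1], , ])
      grown[-d[1], , ] <- pmax(grown[-d[1], , ], lab[-1, , ])
      grown[, -1, ] <- pmax(grown[, -1, ], lab[, -d[2], ])
      grown[, -d[2], ] <- pmax(grown[, -d[2], ], lab[, -1, ])
      grown[, , -1] <- pmax(grown[, , -1], lab[, , -d[3]])
      grown[, , -d[3]] <- pmax(grown[, , -d[3]], lab[, , -1])
      grown <- grown * m
      if (identical(grown, lab)) break
      lab <- grown
    }
    expect_equal(sum(lab), sum(m))
  }
})

test_that("cystic phantoms show the dark-interior / bright-rim contrast", {
  # large enough that the interior is not dominated by rim bleed-through
  ph <- generate_phantom(phantom_spec(size = c(96, 96, 16),
                                      lobe_radius_mm = c(8, 14),
                                      composition = "cystic", seed = 21))
  img <- ph$vol$data; m <- ph$mask$data
  interior <- m
  for (k in 1:2) interior <- cranioseg:::erode6(interior)
  rim <- m - interior
  brain <- cranioseg:::erode6(1 - m) * (img > 0.1)  # head tissue off-tumor
  expect_lt(mean(img[interior == 1]), mean(img[brain == 1 & m == 0]))
  expect_gt(mean(img[rim == 1]), mean(img[brain == 1 & m == 0]))
})

test_that("the vessel distractor is bright, adjacent to, and disjoint from the mask", {
  ph <- desk_phantom(seed = 33, composition = "solid", vessel_distractor = TRUE)
  m <- ph$mask$data
  # 1-voxel dilation ring of the mask
  dil <- m
  d <- dim(m)
  dil[-1, , ] <- pmax(dil[-1, , ], m[-d[1], , ])
  dil[-d[1], , ] <- pmax(dil[-d[1], , ], m[-1, , ])
  dil[, -1, ] <- pmax(dil[, -1, ], m[, -d[2], ])
  dil[, -d[2], ] <- pmax(dil[, -d[2], ], m[, -1, ])
  dil[, , -1] <- pmax(dil[, , -1], m[, , -d[3]])
  dil[, , -d[3]] <- pmax(dil[, , -d[3]], m[, , -1])
  ring <- dil - m
  expect_gt(max(ph$vol$data[ring == 1]), 0.85 - 0.2)  # rim-bright up to smoothing/noise
})

test_that("cohorts follow the requested composition mix and are reproducible", {
  solid_only <- generate_cohort(10, composition_mix = c(cystic = 0, solid = 1, mixed = 0),
                                seed = 7, size = c(32, 32, 8), lobe_radius_mm = c(2, 4))
  expect_true(all(solid_only$manifest$composition == "solid"))

  a <- generate_cohort(6, seed = 9, size = c(32, 32, 8), lobe_radius_mm = c(2, 4))
  b <- generate_cohort(6, seed = 9, size = c(32, 32, 8), lobe_radius_mm = c(2, 4))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$cases[[3]]$vol$data, b$cases[[3]]$vol$data)
  expect_error(generate_cohort(0), "positive")
  expect_error(generate_cohort(5, composition_mix = c(cystic = 0.5, solid = 0.4,
                                                      mixed = 0.2)), "sum to 1")
})

test_that("cohort composition counts are near the documented mix at scale", {
  # the default mix documents the reported cohort: at n = 302 the expected
  # (cystic, solid, mixed) counts are approximately (104, 54, 144)
  expect_equal(round(302 * c(0.344, 0.179, 0.477)), c(104, 54, 144))
  coh <- generate_cohort(60, seed = 31, size = c(32, 32, 8),
                         lobe_radius_mm = c(2, 4))
  counts <- table(factor(coh$manifest$composition,
                         levels = c("cystic", "solid", "mixed")))
  # with n = 60, expected ~ (20.6, 10.7, 28.6); allow 4 sd of multinomial noise
  expected <- 60 * c(0.344, 0.179, 0.477)
  sds <- sqrt(60 * c(0.344, 0.179, 0.477) * (1 - c(0.344, 0.179, 0.477)))
  expect_true(all(abs(as.numeric(counts) - expected) < 4 * sds))
})

test_that("cohort output directory contains readable NIfTI pairs and manifest", {
  dir <- tempfile()
  coh <- generate_cohort(3, seed = 13, size = c(32, 32, 6),
                         lobe_radius_mm = c(2, 4), out_dir = dir)
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(mf), 3L)
  v <- read_volume(mf$image_path[2])
  m <- read_mask(mf$mask_path[2])
  expect_equal(v$data, coh$cases[[2]]$vol$data, tolerance = 1e-6)
  expect_identical(m$data, coh$cases[[2]]$mask$data)
})

test_that("domain shift behaves as an acquisition change", {
  coh <- generate_cohort(4, seed = 17, size = c(32, 32, 8), lobe_radius_mm = c(2, 4))
  ident <- domain_shift(coh, noise_scale = 1, intensity_gamma = 1)
  expect_identical(ident$cases[[1]]$vol$data, coh$cases[[1]]$vol$data)
  expect_identical(ident$cases[[2]]$mask$data, coh$cases[[2]]$mask$data)

  noisy <- domain_shift(coh, noise_scale = 3, intensity_gamma = 1, seed = 2)
  dvar <- var(as.vector(noisy$cases[[1]]$vol$data - coh$cases[[1]]$vol$data))
  expect_gt(dvar, 0)

  thick <- domain_shift(coh, spacing = c(1, 1, 4), seed = 2)
  expect_equal(dim(thick$cases[[1]]$vol$data)[3], 2L)  # 8 slices at 1mm -> 2 at 4mm
  back <- preprocess_case(thick$cases[[1]]$vol, thick$cases[[1]]$mask,
                          preprocess_config(out_size = c(32, 32)))
  expect_equal(back$vol$spacing, c(1, 1, 1))
  expect_equal(dim(back$vol$data)[3], 8L)
})
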