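test_that("degenerate ranges give deterministic configs at the bounds", {
  rg <- sampling_ranges(
    pixel_size = c(93, 93), propagation_angle = c(0, 0),
    incident_angle = c(0.76, 0.76), bfp_offset = c(100, 100),
    film_thickness = c(50, 50), phase_offset = c(0.2, 0.2)
  )
  set.seed(1); c1 <- sample_config(rg)
  set.seed(2); c2 <- sample_config(rg)
  expect_equal(c1$pixel_size, 93)
  expect_equal(c1$phase_offset, 0.2)
  expect_identical(unclass(c1), unclass(c2))
})

test_that("config sampling is seeded and uniform over its intervals", {
  rg <- sampling_ranges()
  set.seed(7); a <- sample_config(rg)
  set.seed(7); b <- sample_config(rg)
  expect_identical(unclass(a), unclass(b))

  set.seed(123)
  th <- replicate(1e4, sample_config(rg)$incident_angle)
  iv <- rg$incident_angle
  se <- diff(iv) / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(th) - mean(iv)), 3 * se)
  expect_true(all(th >= iv[1] & th <= iv[2]))
})

test_that("scatterer sampling respects margins and circular phase uniformity", {
  rg <- sampling_ranges(margin = 8)
  set.seed(11)
  sc <- dplyr::bind_rows(lapply(1:500, function(i) {
    sample_scatterers(rg, 80, 80)
  }))
  expect_true(all(sc$x >= 8 & sc$x < 72))
  expect_true(all(sc$y >= 8 & sc$y < 72))
  expect_true(all(table(rep(1:500, each = 1)) == 1))  # exactly one per draw
  expect_true(all(sc$amplitude >= rg$amplitude[1] &
                    sc$amplitude <= rg$amplitude[2]))

  set.seed(5)
  ph <- replicate(1e4, sample_scatterers(rg, 80, 80)$phase)
  resultant <- Mod(mean(exp(1i * ph)))
  expect_lt(resultant, 3 / sqrt(1e4) * 1.5)  # ~3 sigma for uniform angles

  expect_error(sample_scatterers(sampling_ranges(margin = 40), 80, 80),
               "margin")
})

test_that("target encoding rounds half-up to one hot pixel per scatterer", {
  rg <- sampling_ranges()
  cfg <- denormalize_variables(rep(0.5, 6), rg)
  sc <- scatterers(40.2, 39.8, amplitude = 0.05, phase = 1.0)
  tg <- encode_targets(sc, 80, 80, rg, cfg)
  expect_equal(sum(tg$prob), 1)
  expect_equal(tg$prob[41, 41], 1)       # 0-based (40, 40)
  expect_equal(tg$amp[41, 41], 0.05)
  expect_equal(tg$phase[41, 41], 1.0)
  expect_equal(sum(tg$amp != 0), 1)
  expect_equal(tg$pixels$x, 40L)
  expect_equal(tg$pixels$y, 40L)

  # collision: two scatterers rounding to one pixel
  sc2 <- scatterers(c(10.2, 9.9), c(20.1, 19.8), c(0.05, 0.06), c(0, 1))
  expect_error(encode_targets(sc2, 80, 80, rg, cfg),
               class = "ipmnet_collision")
})

test_that("variable normalization is invertible and order-preserving", {
  rg <- sampling_ranges()
  lo_cfg <- optical_config(
    pixel_size = rg$pixel_size[1], propagation_angle = rg$propagation_angle[1],
    incident_angle = rg$incident_angle[1], bfp_offset = rg$bfp_offset[1],
    film_thickness = rg$film_thickness[1], phase_offset = rg$phase_offset[1]
  )
  expect_equal(unname(normalize_variables(lo_cfg, rg)), rep(0, 6))

  set.seed(3)
  for (i in 1:10) {
    cfg <- sample_config(rg)
    v <- normalize_variables(cfg, rg)
    expect_true(all(v >= 0 & v <= 1))
    back <- denormalize_variables(v, rg)
    for (nm in variable_names()) {
      expect_equal(back[[nm]], cfg[[nm]], tolerance = 1e-12)
    }
  }

  # order preservation per component
  v1 <- normalize_variables(denormalize_variables(rep(0.2, 6), rg), rg)
  v2 <- normalize_variables(denormalize_variables(rep(0.8, 6), rg), rg)
  expect_true(all(v2 > v1))
})

test_that("augmentation applies exact no-ops, calibrated noise, and mean-conserving blur", {
  img <- matrix(rnorm(80 * 80), 80, 80)
  expect_identical(augment_image(img, 0, 0)[, ], img)

  set.seed(21)
  noisy <- augment_image(matrix(0, 80, 80), blur_sigma = 0, noise_sigma = 0.1)
  expect_equal(stats::sd(noisy), 0.1, tolerance = 0.05)

  blurred <- augment_image(img, blur_sigma = 1.3, noise_sigma = 0)
  expect_equal(mean(blurred), mean(img), tolerance = 1e-10)
  expect_lt(stats::sd(blurred), stats::sd(img))   # blur smooths

  expect_error(augment_image(img, -1, 0))
})

test_that("datasets are deterministic, sparse, and honest about provenance", {
  rg <- sampling_ranges()
  ds1 <- generate_dataset(10, rg, seed = 42)
  ds2 <- generate_dataset(10, rg, seed = 42)
  expect_equal(nrow(ds1$manifest), 10)
  expect_identical(ds1$samples, ds2$samples)

  for (s in ds1$samples) {
    expect_equal(dim(s$image), c(80L, 80L))
    expect_equal(sum(s$prob), nrow(s$scene))            # sparsity conservation
    expect_true(all(s$amp[s$prob == 0] == 0))
    expect_true(all(s$variables >= 0 & s$variables <= 1))
    expect_true(all(is.finite(s$image)))
  }

  # augmentation never alters targets: same seed, toggled augmentation
  dsa <- generate_dataset(5, rg, seed = 9, augment = TRUE)
  dsb <- generate_dataset(5, rg, seed = 9, augment = FALSE)
  for (i in 1:5) {
    expect_identical(dsa$samples[[i]]$prob, dsb$samples[[i]]$prob)
    expect_identical(dsa$samples[[i]]$variables, dsb$samples[[i]]$variables)
    expect_false(identical(dsa$samples[[i]]$image, dsb$samples[[i]]$image))
  }

  # clean images normalized into [-1, 1] by the fixed scale
  expect_true(all(vapply(dsb$samples,
                         function(s) max(abs(s$image)) <= 1, logical(1))))

  # interior-margin scan over generated target pixels
  ds3 <- generate_dataset(50, rg, seed = 3)
  px <- dplyr::bind_rows(lapply(ds3$samples, function(s) s$pixels))
  expect_true(all(px$x >= rg$margin & px$x < 80 - rg$margin + 1))
  expect_true(all(px$y >= rg$margin & px$y < 80 - rg$margin + 1))
})

test_that("datasets round-trip through TIFF + JSON sidecars", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, sampling_ranges(), seed = 1, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n, 3)
  expect_length(man$files, 3)
  for (i in 1:3) {
    pages <- tiff::readTIFF(file.path(dir, man$files[[i]]), all = TRUE)
    expect_length(pages, 4)
    side <- jsonlite::read_json(file.path(dir,
                                          sub("\\.tif$", ".json", man$files[[i]])))
    img <- (pages[[1]] - 0.5) * side$transform$scale
    expect_equal(img, unclass(ds$samples[[i]]$image), tolerance = 1e-6,
                 ignore_attr = TRUE)
    prob <- round((pages[[2]] - 0.5) * side$transform$scale)
    expect_equal(prob, unclass(ds$samples[[i]]$prob), ignore_attr = TRUE)
  }
})
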