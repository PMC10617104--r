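test_that("contours trace the region boundary", {
  # filled square: x, y in 2..7 on a 10x10 grid
  m <- matrix(0L, 10, 10)
  m[3:8, 3:8] <- 1L
  ct <- extract_contour(m, 1L)
  expect_gte(nrow(ct), 20L)
  expect_lte(nrow(ct), 24L)
  expect_true(all(ct[, 1L] >= 2 & ct[, 1L] <= 7))
  expect_true(all(ct[, 2L] >= 2 & ct[, 2L] <= 7))
  # every boundary point touches the square's edge
  expect_true(all(ct[, 1L] %in% c(2, 7) | ct[, 2L] %in% c(2, 7)))
})

test_that("a disk contour lies within a pixel of its radius", {
  size <- 80L; r <- 30
  xs <- matrix(rep(0:(size - 1L), each = size), size, size)
  ys <- matrix(rep(0:(size - 1L), times = size), size, size)
  m <- matrix(0L, size, size)
  m[(xs - 40)^2 + (ys - 40)^2 <= r^2] <- 1L
  ct <- extract_contour(m, 1L)
  d <- sqrt((ct[, 1L] - 40)^2 + (ct[, 2L] - 40)^2)
  expect_true(all(abs(d - r) <= 1))
})

test_that("only the largest component is traced and holes are filled", {
  m <- matrix(0L, 60, 60)
  m[10:32, 10:32] <- 1L   # ~500 px after carving the hole
  m[18:24, 18:24] <- 0L   # hole, must be filled
  m[45:51, 45:51] <- 1L   # small second component (49 px)
  ct <- extract_contour(m, 1L)
  expect_true(all(ct[, 1L] <= 35 & ct[, 2L] <= 35))
  # hole filled: contour length matches the outer rectangle, not the hole
  expect_true(all(ct[, 1L] %in% c(9, 31) | ct[, 2L] %in% c(9, 31)))
  expect_error(extract_contour(m, 2L), "empty region")
})

test_that("the cavity line follows the long axis of an elliptical mask", {
  case <- make_phantom(phantom_spec(uterus_center = c(256, 256),
                                    semi_axes = c(150, 80), orientation = 0,
                                    infiltration_fraction = 0, noise_sd = 0, seed = 1))
  ucl <- generate_ucl(case$mask)
  ep <- ucl$endpoints[order(ucl$endpoints[, 1L]), ]
  expect_lt(max(abs(ep[1L, ] - c(106, 256))), 1.5)
  expect_lt(max(abs(ep[2L, ] - c(406, 256))), 1.5)
  expect_equal(nrow(ucl$samples), 200L)
  # samples are collinear and equally spaced on the segment
  gaps <- sqrt(diff(ucl$samples[, 1L])^2 + diff(ucl$samples[, 2L])^2)
  expect_lt(diff(range(gaps)), 1e-9)
})

test_that("a circular mask yields a diameter as the cavity line", {
  size <- 200L
  xs <- matrix(rep(0:(size - 1L), each = size), size, size)
  ys <- matrix(rep(0:(size - 1L), times = size), size, size)
  m <- matrix(0L, size, size)
  m[(xs - 100)^2 + (ys - 100)^2 <= 70^2] <- 1L
  ucl <- generate_ucl(m)
  len <- sqrt(sum((ucl$endpoints[2L, ] - ucl$endpoints[1L, ])^2))
  expect_lt(abs(len - 140), 2)
  mid <- colMeans(ucl$endpoints)
  expect_lt(max(abs(mid - c(100, 100))), 1.5)
})

test_that("the cavity line stays inside a bent uterus", {
  case <- make_phantom(phantom_spec(semi_axes = c(150, 60), bend = 0.0015,
                                    infiltration_fraction = 0.2, seed = 6))
  ucl <- generate_ucl(case$mask)
  region <- case$mask >= 1L
  inside <- uclga:::points_in_mask(region, ucl$samples[, 1L], ucl$samples[, 2L])
  expect_true(all(inside))
})

test_that("MI extremes behave: no tumor gives 0, full-uterus tumor gives 1", {
  case <- make_phantom(phantom_spec(infiltration_fraction = 0.4, seed = 3))
  ucl <- generate_ucl(case$mask)
  empty <- case$mask
  empty[empty == 2L] <- 1L
  m0 <- measure_mi(empty, empty, ucl)
  expect_identical(m0$mi_depth, 0)
  expect_identical(m0$stage, "IA")

  full <- case$mask
  full[full == 1L] <- 2L
  m1 <- measure_mi(full, full, ucl)
  expect_identical(m1$mi_depth, 1)
  expect_identical(m1$stage, "IB")
})

test_that("a rectangular slab with a known tumor depth measures 0.30", {
  h <- 40L  # half-thickness
  m <- matrix(0L, 120, 200)
  m[21:100, 21:180] <- 1L                # uterus slab, midline at y = 60
  m[61:(60 + 0.3 * h), 60:140] <- 2L     # tumor 0.3 h below midline
  ucl <- list(endpoints = rbind(c(30, 59.5), c(170, 59.5)),
              samples = cbind(seq(30, 170, length.out = 100), 59.5),
              direction = c(1, 0), normal = c(0, 1),
              geometry = list(semi_major = 80, semi_minor = 40))
  mi <- measure_mi(m, m, ucl)
  expect_lt(abs(mi$mi_depth - 0.30), 0.02)
  expect_identical(mi$stage, "IA")
})

test_that("dilating the tumor never decreases the measured depth", {
  case <- make_phantom(phantom_spec(infiltration_fraction = 0.35, seed = 8))
  ucl <- generate_ucl(case$mask)
  r0 <- measure_mi(case$mask, case$mask, ucl)$mi_depth
  grown <- case$mask
  tum <- EBImage::dilate(EBImage::Image(t(grown == 2L)), EBImage::makeBrush(9, "disc"))
  grown[t(EBImage::imageData(tum)) > 0 & grown >= 1L] <- 2L
  r1 <- measure_mi(grown, grown, ucl)$mi_depth
  expect_gte(r1, r0)
})

test_that("upscaling both masks leaves the depth nearly unchanged", {
  case <- make_phantom(phantom_spec(image_size = c(160L, 160L),
                                    uterus_center = c(80, 80),
                                    semi_axes = c(55, 28),
                                    infiltration_fraction = 0.45,
                                    band_halfwidth = 1, seed = 12))
  r1 <- measure_mi(case$mask, case$mask, generate_ucl(case$mask))$mi_depth
  big <- case$mask[rep(seq_len(160), each = 2L), rep(seq_len(160), each = 2L)]
  r2 <- measure_mi(big, big, generate_ucl(big))$mi_depth
  expect_lt(abs(r1 - r2), 0.02)
})

test_that("fast ray casting matches the exhaustive walker on small grids", {
  for (seed in 1:6) {
    case <- random_small_case(seed)
    ucl <- generate_ucl(case$mask, n_samples = 60L)
    fast <- measure_mi(case$mask, case$mask, ucl)$mi_depth
    slow <- bf_measure_mi(case$mask, case$mask, ucl)
    expect_lt(abs(fast - slow), 0.02)
  }
})

test_that("the global-maxima variant is exposed and bounded by construction", {
  case <- make_phantom(phantom_spec(infiltration_fraction = 0.5, seed = 10))
  ucl <- generate_ucl(case$mask)
  pr <- measure_mi(case$mask, case$mask, ucl, variant = "per_ray")
  gl <- measure_mi(case$mask, case$mask, ucl, variant = "global")
  expect_true(gl$mi_depth >= 0 && gl$mi_depth <= 1)
  # global divides max m by max n, so it cannot exceed the per-ray maximum
  expect_lte(gl$mi_depth, pr$mi_depth + 1e-12)
})

test_that("staging applies the 0.5 threshold with ties going to IB", {
  expect_identical(classify_stage(0.49), "IA")
  expect_identical(classify_stage(0.51), "IB")
  expect_identical(classify_stage(0.50), "IB")
  expect_error(classify_stage(1.2), "\\[0, 1\\]")
  expect_error(classify_stage(-0.1), "\\[0, 1\\]")
})

test_that("MI results serialize to the documented JSON shape", {
  case <- make_phantom(phantom_spec(seed = 14))
  ucl <- generate_ucl(case$mask)
  mi <- measure_mi(case$mask, case$mask, ucl)
  js <- jsonlite::fromJSON(mi_result_to_json(mi, ucl))
  expect_named(js, c("mi_depth", "stage", "ucl", "argmax_ray"))
  expect_equal(js$mi_depth, mi$mi_depth)
  expect_true(js$stage %in% c("IA", "IB"))
})
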