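# Synthetic MRI phantom and histology scene generators

test_that("phantom with no MPIO foci has identical pre and post states", {
  spec <- phantom_spec(grid_dim = c(24L, 24L, 24L))
  ph <- generate_phantom(spec)
  expect_identical(ph$r2star_pre, ph$r2star_post)
})

test_that("an MPIO focus alters exactly the voxels inside its sphere", {
  grid <- c(16L, 16L, 16L)
  vox <- c(1, 1, 1)
  # radius 1 mm on a 1 mm grid: the centre voxel plus its 6 face neighbours
  f <- focus_spec(c(8, 8, 8), radius_mm = 1, delta_r2star = 500)
  masks <- default_striatum_masks(grid, vox, radius_mm = 2)
  spec <- phantom_spec(grid_dim = grid, voxel_mm = vox,
                       striatum_ipsi_mask = masks$ipsi,
                       striatum_contra_mask = masks$contra,
                       mpio_foci = list(f))
  ph <- generate_phantom(spec)
  changed <- which(ph$r2star_post != ph$r2star_pre, arr.ind = TRUE)
  expected <- oracle_sphere_voxels(grid, vox, c(8, 8, 8), 1)
  expect_equal(nrow(expected), 7L)
  expect_equal(changed[order(changed[, 1], changed[, 2], changed[, 3]), ],
               expected[order(expected[, 1], expected[, 2], expected[, 3]), ],
               ignore_attr = TRUE)
  expect_true(all(ph$r2star_post[changed] - ph$r2star_pre[changed] == 500))
})

test_that("phantom generation is deterministic and validates masks", {
  spec <- phantom_spec(grid_dim = c(24L, 24L, 24L),
                       mpio_foci = list(focus_spec(c(8, 12, 12), 0.5, 400)))
  expect_identical(generate_phantom(spec), generate_phantom(spec))
  m <- default_striatum_masks(c(24L, 24L, 24L))
  expect_error(
    phantom_spec(grid_dim = c(24L, 24L, 24L),
                 striatum_ipsi_mask = m$ipsi, striatum_contra_mask = m$ipsi),
    "overlap")
  expect_error(focus_spec(c(1, 1, 1), -1, 10), "positive")
  expect_error(focus_spec(c(1, 1, 1), 1, -5), "non-negative")
})

test_that("MGE signal is constant across echoes when R2* is zero", {
  acq <- acq_params()
  r2 <- array(0, dim = c(6, 6, 6))
  es <- simulate_mge3d(r2, acq, snr = Inf)
  for (i in 2:acq$n_echoes) {
    expect_equal(es$data[, , , i], es$data[, , , 1])
  }
})

test_that("noiseless echo ratios follow exp(-dTE * R2*) per voxel", {
  acq <- acq_params()
  set.seed(11)
  r2 <- array(runif(4^3, 5, 80), dim = c(4, 4, 4))
  es <- simulate_mge3d(r2, acq, t1 = 1.7, proton_density = 100, snr = Inf)
  te <- es$te
  for (v in seq_len(length(r2))) {
    idx <- arrayInd(v, dim(r2))
    for (e in seq_along(te)) {
      expect_equal(es$data[idx[1], idx[2], idx[3], e],
                   oracle_spgr(r2[v], te[e], acq$tr, 1.7, acq$flip_angle, 100),
                   tolerance = 1e-12)
    }
    ratio <- es$data[idx[1], idx[2], idx[3], 2] /
      es$data[idx[1], idx[2], idx[3], 1]
    expect_equal(ratio, exp(-(te[2] - te[1]) * r2[v]), tolerance = 1e-12)
  }
})

test_that("default acquisition yields the six standard echo times", {
  expect_equal(echo_times(acq_params()) * 1000,
               c(2.5, 6.5, 10.5, 14.5, 18.5, 22.5))
  expect_error(simulate_mge3d(array(10, dim = c(4, 4, 4)), acq_params(),
                              t1 = -1), "positive")
  expect_error(acq_params(tr = 0), "positive")
})

test_that("Rician noise: zero sigma is identity, Rayleigh mean at s = 0, seeded draws reproduce", {
  x <- array(runif(1000), dim = c(10, 10, 10))
  expect_identical(add_rician_noise(x, 0), x)
  z <- add_rician_noise(array(0, dim = c(100, 100, 20)), sigma = 2, seed = 4)
  expect_equal(mean(z), 2 * sqrt(pi / 2), tolerance = 0.01)
  expect_identical(add_rician_noise(x, 0.5, seed = 7),
                   add_rician_noise(x, 0.5, seed = 7))
  expect_error(add_rician_noise(x, -1), "non-negative")
})

test_that("increasing a focus delta-R2* never increases the noiseless signal", {
  acq <- acq_params()
  grid <- c(20L, 20L, 20L)
  masks <- default_striatum_masks(grid, radius_mm = 2)
  for (delta in c(50, 200, 800)) {
    lo <- phantom_spec(grid_dim = grid, striatum_ipsi_mask = masks$ipsi,
                       striatum_contra_mask = masks$contra,
                       mpio_foci = list(focus_spec(c(7, 10, 10), 1.2, delta)))
    hi <- phantom_spec(grid_dim = grid, striatum_ipsi_mask = masks$ipsi,
                       striatum_contra_mask = masks$contra,
                       mpio_foci = list(focus_spec(c(7, 10, 10), 1.2, delta * 2)))
    s_lo <- simulate_mge3d(generate_phantom(lo)$r2star_post, acq, snr = Inf)
    s_hi <- simulate_mge3d(generate_phantom(hi)$r2star_post, acq, snr = Inf)
    expect_true(all(s_hi$data <= s_lo$data + 1e-12))
  }
})

test_that("histology scene distances follow the calibrated lognormal", {
  sc <- generate_histo_scene(100, 10000, 0, seed = 2,
                             field_um = c(4000, 4000), min_separation_um = 0)
  d <- sc$macrophages$distance_um
  expect_equal(median(d), 10, tolerance = 0.05)
  expect_lt(abs(mean(d <= 25) - 0.90), 0.02)
})

test_that("histology scenes are seed-reproducible and validate geometry", {
  a <- generate_histo_scene(5, 30, 10, seed = 6, field_um = c(400, 400))
  b <- generate_histo_scene(5, 30, 10, seed = 6, field_um = c(400, 400))
  expect_identical(a, b)
  expect_equal(nrow(generate_histo_scene(3, 0, 0, seed = 1,
                                         field_um = c(400, 400))$macrophages),
               0L)
  # all coordinates inside the field
  expect_true(all(a$macrophages$x >= 0 & a$macrophages$x <= 400))
  expect_true(all(a$vessels$lumen_radius > 0))
  # a field too small for the requested vessel spacing must error
  expect_error(generate_histo_scene(10, 0, 0, seed = 1,
                                    field_um = c(100, 100)),
               "too small")
})

test_that("assigned vessel is the nearest lumen centre for every macrophage", {
  sc <- generate_histo_scene(8, 60, 0, seed = 12, field_um = c(500, 500))
  v <- as.matrix(sc$vessels[, c("x", "y")])
  m <- as.matrix(sc$macrophages[, c("x", "y")])
  nearest <- oracle_nearest(m, v)
  expect_equal(nearest, sc$macrophages$distance_um, tolerance = 1e-10)
})

test_that("rendering maps objects to connected blue components one-to-one", {
  empty <- generate_histo_scene(2, 0, 0, seed = 1, field_um = c(300, 300),
                                vessel_min_spacing_um = 50)
  img0 <- render_histo(empty)
  expect_equal(oracle_blue_count(img0), 0L)

  sc <- generate_histo_scene(3, 5, 0, seed = 5, field_um = c(300, 300),
                             vessel_min_spacing_um = 50)
  img <- render_histo(sc)
  blue <- img[, , 3] - pmax(img[, , 1], img[, , 2]) > 0.12
  expect_equal(max(oracle_label(blue)), 5L)
})

test_that("a rendered single MPIO covers approximately the bead disc area", {
  sc <- generate_histo_scene(2, 0, 1, seed = 9, field_um = c(200, 200),
                             pixel_size_um = 0.1, vessel_min_spacing_um = 50,
                             edge_margin_um = 30)
  img <- render_histo(sc)
  n_blue <- oracle_blue_count(img)
  expect_equal(n_blue, pi / 4 / 0.1^2, tolerance = 0.15)
})
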