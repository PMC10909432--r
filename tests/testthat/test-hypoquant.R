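# Contralateral-ROI calibration, hypointense-voxel detection, differencing

make_grid <- function(n = 10) array(100, dim = c(n, n, n))

test_that("roi_stats matches constants, small sets, and a loop oracle", {
  v <- make_grid()
  m <- array(TRUE, dim = dim(v))
  s <- roi_stats(v, m)
  expect_equal(s$mean, 100)
  expect_equal(s$sd, 0)
  v2 <- array(0, dim = c(3, 1, 1)); v2[] <- c(1, 2, 3)
  expect_equal(roi_stats(v2, array(TRUE, dim = c(3, 1, 1)))$mean, 2)
  expect_equal(roi_stats(v2, array(TRUE, dim = c(3, 1, 1)))$sd, 1)
  set.seed(31)
  v3 <- array(rnorm(6^3), dim = c(6, 6, 6))
  m3 <- array(runif(6^3) < 0.4, dim = c(6, 6, 6))
  o <- oracle_roi_stats(v3, m3)
  s3 <- roi_stats(v3, m3)
  expect_equal(s3$mean, o$mean, tolerance = 1e-12)
  expect_equal(s3$sd, o$sd, tolerance = 1e-12)
  expect_equal(s3$n_voxels, o$n)
  expect_error(roi_stats(v, array(FALSE, dim = dim(v))), "empty")
})

test_that("hypointensity threshold is strict at mean - k*sd", {
  stats <- structure(list(mean = 100, sd = 5, n_voxels = 50),
                     class = "roi_stats")
  v <- make_grid(4)
  v[1, 1, 1] <- 84   # below threshold 85 -> flagged
  v[2, 1, 1] <- 85   # exactly at threshold -> not flagged
  res <- detect_hypointense(v, stats, array(TRUE, dim = dim(v)), k = 3)
  expect_equal(res$threshold, 85)
  expect_equal(res$count, 1L)
  expect_true(res$mask[1, 1, 1])
  expect_false(res$mask[2, 1, 1])
})

test_that("noiseless low voxels are counted exactly; zero SD flags nothing", {
  v <- make_grid(8)
  target <- array(TRUE, dim = dim(v))
  v[seq_len(10)] <- 0
  stats <- structure(list(mean = 100, sd = 1, n_voxels = 100),
                     class = "roi_stats")
  expect_equal(detect_hypointense(v, stats, target)$count, 10L)
  # sd = 0 with voxels exactly at the mean: strict '<' flags none
  flat <- make_grid(4)
  s0 <- structure(list(mean = 100, sd = 0, n_voxels = 64),
                  class = "roi_stats")
  expect_equal(detect_hypointense(flat, s0, array(TRUE, dim = dim(flat)))$count,
               0L)
})

test_that("flagged fraction of pure Gaussian noise approximates the 3-sigma tail", {
  set.seed(32)
  n <- 60L
  v <- array(1000 + rnorm(n^3, 0, 10), dim = c(n, n, n))
  contra <- array(FALSE, dim = dim(v)); contra[, , 1:30] <- TRUE
  target <- !contra
  frac <- detect_hypointense(v, roi_stats(v, contra), target)$count / sum(target)
  expect_lt(abs(frac - pnorm(-3)), 5e-4)
})

test_that("post-minus-pre differencing clips negative values to zero", {
  grid <- c(12L, 12L, 12L)
  ipsi <- array(FALSE, dim = grid); ipsi[1:6, , ] <- TRUE
  contra <- array(FALSE, dim = grid); contra[7:12, , ] <- TRUE
  masks <- roi_mask_set(ipsi, contra)
  base <- array(100, dim = grid)
  # contralateral gets slight structure so the SD is defined and nonzero
  set.seed(33)
  base[contra] <- 100 + rnorm(sum(contra), 0, 0.1)
  ipsi_idx <- which(ipsi)
  pre <- base; pre[ipsi_idx[1:30]] <- 0
  post <- base; post[ipsi_idx[1:10]] <- 0
  res <- mpio_induced_voxels(pre, post, masks)
  expect_equal(res$n_hypo_ipsi_pre, 30L)
  expect_equal(res$n_hypo_ipsi_post, 10L)
  expect_equal(res$diff_raw[["ipsi"]], -20L)
  expect_equal(res$diff_clipped[["ipsi"]], 0L)
  # more post than pre: plain difference
  res2 <- mpio_induced_voxels(post, pre, masks)
  expect_equal(res2$diff_raw[["ipsi"]], 20L)
  expect_equal(res2$diff_clipped[["ipsi"]], 20L)
  # identical volumes: zero difference
  res3 <- mpio_induced_voxels(pre, pre, masks)
  expect_equal(res3$diff_raw[["ipsi"]], 0L)
  expect_error(mpio_induced_voxels(pre, array(100, dim = c(6, 6, 6)), masks),
               "grid")
})

test_that("flagging is equivariant under affine intensity maps a*x + b", {
  set.seed(34)
  grid <- c(10L, 10L, 10L)
  v <- array(rnorm(prod(grid), 50, 4), dim = grid)
  ipsi <- array(FALSE, dim = grid); ipsi[1:5, , ] <- TRUE
  contra <- array(FALSE, dim = grid); contra[6:10, , ] <- TRUE
  base <- detect_hypointense(v, roi_stats(v, contra), ipsi)
  for (ab in list(c(2, 0), c(0.5, 10), c(3, -7))) {
    w <- ab[1] * v + ab[2]
    mapped <- detect_hypointense(w, roi_stats(w, contra), ipsi)
    expect_identical(mapped$mask, base$mask)
  }
})

test_that("noise_floor summarises control differences", {
  nf <- noise_floor(c(1, 2, 3))
  expect_equal(nf$mean, 2)
  expect_equal(nf$sd, 1)
  nf0 <- noise_floor(c(0, 0, 0, 0), contra_n_voxels = 500)
  expect_equal(nf0$mean, 0)
  expect_equal(nf0$sd, 0)
  expect_equal(nf0$fraction_of_roi, 0)
  set.seed(35)
  d <- rnorm(40, 5, 12)
  nf2 <- noise_floor(d, contra_n_voxels = 1000)
  expect_equal(nf2$mean, sum(d) / 40, tolerance = 1e-12)
  expect_equal(nf2$sd, sqrt(sum((d - mean(d))^2) / 39), tolerance = 1e-12)
  expect_equal(nf2$fraction_of_roi, mean(d) / 1000)
  expect_error(noise_floor(numeric(0)), "no control")
  expect_error(noise_floor(5), "at least two")
})

test_that("cohort_table emits one row per case and hemisphere and round-trips CSV", {
  empty <- cohort_table(list())
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("id", "scenario", "hemisphere", "n_hypo_pre",
                        "n_hypo_post", "diff_raw", "diff_clipped",
                        "threshold_pre", "threshold_post"))
  grid <- c(10L, 10L, 10L)
  ipsi <- array(FALSE, dim = grid); ipsi[1:5, , ] <- TRUE
  contra <- array(FALSE, dim = grid); contra[6:10, , ] <- TRUE
  masks <- roi_mask_set(ipsi, contra)
  set.seed(36)
  mk <- function() {
    v <- array(rnorm(prod(grid), 100, 3), dim = grid)
    mpio_induced_voxels(v, v - 1, masks)
  }
  tab <- cohort_table(list(mk(), mk()), ids = c("a", "b"), scenario = "RGD")
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$hemisphere, c("ipsi", "contra", "ipsi", "contra"))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(tab, path)
  back <- read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back, tab, tolerance = 1e-12)
})
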