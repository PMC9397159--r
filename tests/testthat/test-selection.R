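test_that("prefilter: identity at sigma 0, conserves constants, matches kernel on impulse", {
  set.seed(1)
  s <- array(runif(5 * 5 * 5), c(5, 5, 5))
  expect_identical(prefilter(s, 0), s)
  expect_error(prefilter(s, -1), "sigma_pre")

  const <- array(3.5, c(6, 6, 6))
  expect_equal(prefilter(const, 2), const, tolerance = 1e-12)

  imp <- array(0, c(9, 9, 9))
  imp[5, 5, 5] <- 100
  sm <- prefilter(imp, 1)
  expect_equal(sm[5, 5, 5], 100 * oracle_gauss_central_weight(1),
               tolerance = 1e-12)
})

test_that("find_z_maxima matches the worked column and handles degenerate columns", {
  a <- array(0, c(1, 1, 5))
  a[1, 1, ] <- c(2, 8, 3, 9, 1)
  m <- find_z_maxima(a)
  expect_equal(m$z, c(1, 3))
  expect_equal(m$amplitude, c(5, 6))

  mono <- array(rep(1:6, each = 1), c(1, 1, 6))
  expect_equal(nrow(find_z_maxima(mono)), 0)
  expect_equal(nrow(find_z_maxima(array(4, c(2, 2, 5)))), 0)
})

test_that("find_z_maxima equals the per-column scan oracle on random stacks", {
  for (seed in 1:5) {
    set.seed(seed)
    s <- array(sample(0:9, 4 * 4 * 8, replace = TRUE), c(4, 4, 8))
    got <- as.matrix(find_z_maxima(s))
    want <- oracle_z_maxima(s)
    expect_equal(unname(got), unname(want), info = paste("seed", seed))
  }
})

test_that("amplitude classifier keeps the stated quantile and is monotone", {
  cands <- data.frame(x = 0:19, y = 0, z = 1, intensity = 1,
                      amplitude = 1:20)
  expect_identical(classify_amplitude(cands, 0), cands)
  kept <- classify_amplitude(cands, 10, n_levels = 20)
  expect_equal(sort(kept$amplitude), 10:20)   # >= the 0.5-quantile

  eq <- transform(cands, amplitude = 7)
  expect_equal(nrow(classify_amplitude(eq, 15)), nrow(eq))
  expect_error(classify_amplitude(cands, 20), "t_a")

  # monotone: raising t_a never adds voxels
  set.seed(3)
  rc <- data.frame(x = 1:200, y = 0, z = 1, intensity = 1,
                   amplitude = rexp(200))
  prev <- rc
  for (t_a in c(2, 5, 9, 14, 19)) {
    cur <- classify_amplitude(rc, t_a)
    expect_true(all(cur$x %in% prev$x))
    prev <- cur
  }
})

test_that("intensity classifier separates a bimodal sample and caps degenerate histograms", {
  cands <- data.frame(x = 1:20, y = 0, z = 1,
                      intensity = rep(c(5, 100), each = 10), amplitude = 1)
  expect_identical(classify_intensity(cands, 0), cands)
  kept <- suppressWarnings(classify_intensity(cands, 1, n_classes = 2))
  expect_equal(sort(kept$intensity), rep(100, 10))

  flat <- transform(cands, intensity = 42)
  expect_equal(nrow(suppressWarnings(classify_intensity(flat, 9))), 20)
  expect_warning(classify_intensity(flat, 9), "distinct")
  expect_error(classify_intensity(cands, 17), "t_otsu")
})

test_that("multi-level Otsu agrees with EBImage's two-class threshold split", {
  skip_if_not_installed("EBImage")
  set.seed(11)
  # well-separated modes: both methods must place the cut inside the gap
  x <- c(rnorm(300, 0.2, 0.02), rnorm(200, 0.75, 0.02))
  x <- pmin(pmax(x, 0), 1)
  thr <- multi_otsu(x, 2)
  eb <- EBImage::otsu(EBImage::Image(matrix(x, 25)), range = c(0, 1))
  expect_identical(x >= thr, x > eb)
})

test_that("island removal follows 26-connectivity and the size threshold", {
  mk <- function(coords, d = c(6, 6, 6)) {
    cands <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        intensity = 1, amplitude = 1)
    rasterize_candidates(cands, d)
  }
  lone <- mk(cbind(2, 2, 2))
  expect_equal(sum(remove_islands(lone, 2)$mask), 0)
  expect_equal(sum(remove_islands(lone, 0)$mask), 1)
  expect_equal(sum(remove_islands(lone, 1)$mask), 1)

  diag3 <- mk(cbind(1:3, 1:3, 1:3))   # 26-connected diagonal chain
  expect_equal(sum(remove_islands(diag3, 3)$mask), 3)
  expect_equal(sum(remove_islands(diag3, 4)$mask), 0)
})

test_that("consolidation fills plane holes but keeps distant planes disjoint", {
  d <- c(21, 21, 15)
  idx <- as.matrix(expand.grid(x = 0:20, y = 0:20))
  plane <- data.frame(x = idx[, 1], y = idx[, 2], z = 7,
                      intensity = 1, amplitude = 5)
  hole <- !(plane$x == 10 & plane$y == 10)
  sel <- rasterize_candidates(plane[hole, ], d)

  expect_identical(consolidate(sel, 0, 0), sel)

  out <- consolidate(sel, 2, 1, tau = 0.25)
  expect_true(out$mask[11, 11, 8])          # hole filled
  expect_true(out$added[11, 11, 8])         # flagged as consolidation fill
  expect_true(out$amplitude[11, 11, 8] > 0) # amplitude interpolated
  expect_true(all(out$mask[, , 8]))         # original plane kept (union)

  # two planes 12 slices apart must not bleed into the midplane
  two <- rbind(transform(plane, z = 1), transform(plane, z = 13))
  sel2 <- rasterize_candidates(two, d)
  out2 <- consolidate(sel2, 2, 1, tau = 0.25)
  expect_false(any(out2$mask[, , 5:9]))
})

test_that("select_voxels with fully permissive thresholds equals the raw maxima set", {
  ph <- small_two_plane(seed = 5)
  p <- extraction_params(t_a = 0L, t_otsu = 0L, s_min = 0L,
                         sigma_xy = 0, sigma_z = 0, sigma_pre = 0)
  sel <- select_voxels(ph$stack, p)
  cands <- find_z_maxima(ph$stack)
  expect_equal(sum(sel$mask), nrow(cands))
  expect_true(all(sel$mask[cbind(cands$x + 1, cands$y + 1, cands$z + 1)]))

  zero <- array(0, c(8, 8, 6))
  expect_equal(sum(select_voxels(zero, p)$mask), 0)
})

test_that("selection sets shrink as t_a or t_otsu rise", {
  ph <- small_two_plane(seed = 9)
  base <- extraction_params(s_min = 0L, sigma_xy = 0, sigma_z = 0)
  prev <- NULL
  for (t_a in c(0L, 6L, 12L, 18L)) {
    p <- extraction_params(t_a = t_a, t_otsu = 0L, s_min = 0L,
                           sigma_xy = 0, sigma_z = 0)
    cur <- sum(select_voxels(ph$stack, p)$mask)
    if (!is.null(prev)) expect_lte(cur, prev)
    prev <- cur
  }
  prev <- NULL
  for (t_otsu in c(0L, 4L, 10L, 16L)) {
    p <- extraction_params(t_a = 0L, t_otsu = t_otsu, s_min = 0L,
                           sigma_xy = 0, sigma_z = 0)
    cur <- sum(suppressWarnings(select_voxels(ph$stack, p))$mask)
    if (!is.null(prev)) expect_lte(cur, prev)
    prev <- cur
  }
})
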