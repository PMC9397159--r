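test_that("analytic height maps follow the stated shape formulas", {
  d <- c(100L, 100L, 64L)
  plane <- analytic_height_map(surface_spec("plane", z0 = 5), d)
  expect_true(all(plane$h == 5))
  expect_true(all(plane$covered))

  flat_sin <- analytic_height_map(
    surface_spec("sinusoid", z0 = 9, amplitude = 0, period = 32), d)
  expect_true(all(flat_sin$h == 9))

  par <- surface_spec("paraboloid", z0 = 4, curvature = 0.01,
                      apex = c(50, 50))
  hc <- attr(analytic_height_map(par, c(100L, 100L, 90L)), "exact")
  expect_equal(hc[1, 1], 4 + 0.01 * (50^2 + 50^2))  # corner: z0 + 50

  expect_error(analytic_height_map(par, c(100L, 100L, 30L)), "exits stack")
})

test_that("two-site Voronoi texture renders the perpendicular bisector band", {
  set.seed(123)
  tex <- voronoi_texture(c(60, 60), n_cells = 2, edge_width = 2,
                         fg = 200, bg = 10, rng_seed = 17)
  set.seed(17)
  sx <- runif(2, 0, 59); sy <- runif(2, 0, 59)
  px <- matrix(0:59, 60, 60); py <- matrix(0:59, 60, 60, byrow = TRUE)
  d1 <- sqrt((px - sx[1])^2 + (py - sy[1])^2)
  d2 <- sqrt((px - sx[2])^2 + (py - sy[2])^2)
  expect_equal(tex == 200, abs(d1 - d2) <= 2)

  expect_equal(voronoi_texture(c(20, 20), 5, 2, 50, 50, rng_seed = 1),
               matrix(50, 20, 20))                       # fg == bg
  expect_identical(voronoi_texture(c(30, 30), 8, 2, 9, 1, rng_seed = 3),
                   voronoi_texture(c(30, 30), 8, 2, 9, 1, rng_seed = 3))
})

test_that("noise-free rendering puts the column argmax on the ground truth", {
  spec <- phantom_spec(dim = c(32L, 32L, 20L),
                       surfaces = surface_spec("sinusoid", z0 = 8,
                                               amplitude = 3, period = 16,
                                               texture = "constant"),
                       background = 10, noise_sd = 0, rng_seed = 5)
  ph <- render_phantom(spec)
  am <- apply(ph$stack, c(1, 2), which.max) - 1
  expect_equal(am, unname(ph$gt[[1]]$h))
})

test_that("two separated planes give two distinct axial maxima per column", {
  spec <- phantom_spec(dim = c(16L, 16L, 30L),
                       surfaces = list(
                         surface_spec("plane", z0 = 8, texture = "constant"),
                         surface_spec("plane", z0 = 18, texture = "constant")),
                       background = 0, noise_sd = 0, rng_seed = 5)
  ph <- render_phantom(spec)
  cands <- find_z_maxima(ph$stack)
  expect_equal(nrow(cands), 2 * 16 * 16)
  expect_setequal(unique(cands$z), c(8, 18))
})

test_that("rendering is bit-reproducible and does not disturb the RNG stream", {
  spec <- default_phantom_spec(rng_seed = 3, dim = c(40L, 40L, 64L))
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- render_phantom(spec)
  after <- runif(1)
  b <- render_phantom(spec)
  expect_identical(a$stack, b$stack)
  expect_identical(before, after)   # ambient RNG state restored
})

test_that("surfaces within one slice of each other trigger an ambiguity warning", {
  spec <- phantom_spec(dim = c(16L, 16L, 20L),
                       surfaces = list(
                         surface_spec("plane", z0 = 8),
                         surface_spec("plane", z0 = 8.6)),
                       noise_sd = 0, rng_seed = 1)
  expect_warning(render_phantom(spec), "ambiguous")
})

test_that("default phantom keeps its three surfaces mutually separated", {
  spec <- default_phantom_spec(rng_seed = 1)
  hms <- lapply(spec$surfaces, function(s)
    attr(analytic_height_map(s, spec$dim), "exact"))
  expect_gte(min(abs(hms[[1]] - hms[[2]])), 10)
  expect_gte(min(abs(hms[[2]] - hms[[3]])), 10)
})
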