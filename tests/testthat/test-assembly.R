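mk_ose <- function(px, index = 0L, axis = "y") {
  px <- px[order(px[, 1]), , drop = FALSE]
  structure(list(pixels = px, axis = axis, index = as.integer(index),
                 size = nrow(px)), class = "ose")
}

test_that("overlap and connectivity reproduce the two-candidate worked example", {
  # front line of the surface in the adjacent section: 5 pixels at z = 4
  line <- cbind(u = 0:4, z = 4L)
  # two candidate OSEs in the next section, each sharing 3 u-positions with
  # the line, every overlapping pixel within one slice of the line
  ose_a <- mk_ose(cbind(u = 0:2, z = c(4L, 5L, 5L)))
  ose_b <- mk_ose(cbind(u = c(2:4, 5L, 6L), z = c(3L, 4L, 4L, 4L, 5L)))

  expect_equal(overlap_R(line, ose_a), 3)
  expect_equal(overlap_R(line, ose_b), 3)
  expect_equal(as.numeric(connectivity_C(line, ose_a)), 1)
  expect_equal(as.numeric(connectivity_C(line, ose_b)), 1)
  expect_true(accept_ose(line, ose_a, r0 = 3, c0 = 1))
  expect_true(accept_ose(line, ose_b, r0 = 3, c0 = 1))
})

test_that("overlap/connectivity handle disjoint, nested and far candidates", {
  line <- cbind(u = 0:4, z = 2L)
  expect_equal(overlap_R(line, mk_ose(cbind(u = 10:12, z = 2L))), 0)

  nested <- mk_ose(cbind(u = 0:4, z = 2L))
  expect_equal(overlap_R(line, nested), 5)
  expect_equal(as.numeric(connectivity_C(line, nested)), 1)

  mixed <- mk_ose(cbind(u = 0:3, z = c(2L, 3L, 5L, 1L)))  # one pixel 3 away
  expect_equal(overlap_R(line, mixed), 4)
  expect_equal(as.numeric(connectivity_C(line, mixed)), 0.75)

  far <- mk_ose(cbind(u = 9L, z = 0L))
  cc <- connectivity_C(line, far)
  expect_true(isTRUE(attr(cc, "undefined")))
  expect_true(accept_ose(line, far, 0, 0))      # fully permissive
  expect_false(accept_ose(line, mixed, 3, 0.8)) # C below threshold
})

test_that("grow_surface covers a full plane from any seed and never crosses a 10-slice gap", {
  d <- c(20, 15, 30)
  idx <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1)))
  two <- data.frame(x = rep(idx[, 1], 2), y = rep(idx[, 2], 2),
                    z = rep(c(8, 18), each = nrow(idx)),
                    intensity = 1, amplitude = 1)
  sel <- rasterize_candidates(two, c(d[1], d[2], d[3]))

  oses <- list()
  for (i in 0:(d[1] - 1)) oses <- c(oses, build_oses(section_of(sel, "y", i)))
  expect_length(oses, 2 * d[1])   # one chain per plane per section

  res <- grow_surface(1, oses, r0 = 3, c0 = 1)
  zs <- unlist(lapply(oses[res$ids], function(o) o$pixels[, 2]))
  expect_equal(length(res$ids), d[1])          # whole plane, one section each
  expect_true(all(zs == zs[1]))                # never mixes the two planes

  # remaining pool still holds the other plane intact
  expect_equal(sum(res$alive), d[1])
})

test_that("assemble_round finds each well-separated surface once", {
  ph <- small_two_plane(seed = 21)
  p <- extraction_params(t_a = 14L, t_otsu = 1L, s_min = 16L,
                         sigma_xy = 2, sigma_z = 0.5, sigma_pre = 0.5)
  sel <- select_voxels(ph$stack, p)
  drafts <- assemble_round(sel, "x", 0.8, 3, 0.75)
  expect_length(drafts, 2)

  empty <- rasterize_candidates(
    data.frame(x = integer(0), y = integer(0), z = integer(0),
               intensity = numeric(0), amplitude = numeric(0)),
    c(10, 10, 5))
  expect_equal(length(assemble_round(empty, "x", 0.8, 3, 0.75)), 0)
})

test_that("footprint filter drops debris drafts but keeps the main surface", {
  d <- c(30, 30, 12)
  idx <- as.matrix(expand.grid(x = 0:29, y = 0:29))
  plane <- data.frame(x = idx[, 1], y = idx[, 2], z = 3,
                      intensity = 1, amplitude = 1)
  debris <- data.frame(x = 4:6, y = 5, z = 9, intensity = 1, amplitude = 1)
  sel <- rasterize_candidates(rbind(plane, debris), d)
  drafts <- assemble_round(sel, "x", 1, 3, 0.75, min_footprint_frac = 0.01)
  expect_length(drafts, 1)
  expect_equal(nrow(drafts[[1]]), 900)
})

test_that("merge_rounds self-pairs identical lists and concatenates disjoint ones", {
  d <- c(20, 20, 10)
  mkdraft <- function(xr, yr, z) {
    g <- as.matrix(expand.grid(x = xr, y = yr))
    cbind(x = g[, 1], y = g[, 2], z = z)
  }
  a <- mkdraft(0:9, 0:19, 3)
  b <- mkdraft(12:19, 0:19, 7)

  same <- merge_rounds(list(a, b), list(a, b), d)
  expect_length(same, 2)
  expect_equal(sort(vapply(same, nrow, integer(1))), c(160L, 200L))

  disj <- merge_rounds(list(a), list(b), d)
  expect_length(disj, 2)

  # partial overlap (60% of the smaller) with dz 0 pairs up; plus a new surface
  a2 <- mkdraft(0:5, 0:19, 3)
  merged <- merge_rounds(list(a), list(a2, b), d)
  expect_length(merged, 2)
  areas <- sort(vapply(merged, nrow, integer(1)))
  expect_equal(areas, c(160L, 200L))   # a2 absorbed into a, b passes through
})

test_that("draft height maps take the column median rounded half down", {
  d <- c(6, 6, 12)
  draft <- cbind(x = c(0, 1, 1, 1, 2, 2), y = 0L,
                 z = c(5, 4, 5, 9, 3, 4))
  hm <- draft_to_height_map(draft, d)
  expect_equal(hm$h[1, 1], 5)   # single voxel
  expect_equal(hm$h[2, 1], 5)   # median of {4,5,9}
  expect_equal(hm$h[3, 1], 3)   # even count {3,4}: 3.5 rounds half down
  expect_equal(sum(hm$covered), 3)
  expect_error(draft_to_height_map(draft[0, , drop = FALSE], d), "empty")
})

test_that("near-vertical folds still give a single-valued height map", {
  d <- c(8, 4, 40)
  draft <- do.call(rbind, lapply(0:7, function(x)
    cbind(x = x, y = 0:3, z = rep(x * 5 + 0:0, 4))))
  steep <- rbind(draft, cbind(x = 7, y = 0:3, z = 36:39))
  hm <- draft_to_height_map(steep, d)
  expect_equal(sum(hm$covered), 32)
  expect_true(all(table(which(hm$covered)) == 1))
})

test_that("extract_surfaces returns an empty list on an empty stack", {
  zero <- array(0, c(12, 12, 6))
  expect_message(res <- extract_surfaces(zero, extraction_params()),
                 "no surface voxels")
  expect_length(res, 0)
})

test_that("extraction is deterministic and insensitive to rng state", {
  ph <- small_two_plane(seed = 33)
  p <- extraction_params(t_a = 14L, t_otsu = 1L, s_min = 16L,
                         sigma_xy = 2, sigma_z = 0.5, sigma_pre = 0.5)
  set.seed(1); m1 <- extract_surfaces(ph$stack, p)
  set.seed(999); m2 <- extract_surfaces(ph$stack, p)
  expect_length(m1, 2)
  expect_identical(lapply(m1, function(m) m$h), lapply(m2, function(m) m$h))
})

test_that("a too-small timeout raises a phase-naming timeout error", {
  ph <- small_two_plane(seed = 2)
  p <- extraction_params(timeout_seconds = 1e-6)
  expect_error(extract_surfaces(ph$stack, p), class = "multisurf_timeout")
})
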