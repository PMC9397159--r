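#' Specify one phantom surface
#'
#' Describes an analytic surface to be rendered into a phantom stack:
#' a flat plane, an axial sinusoid (along x) or a paraboloid, textured
#' either with constant intensity or with a Voronoi mesh (bright cell
#' boundaries over dark interiors, emulating a junctional marker).
#'
#' @param shape `"plane"`, `"sinusoid"` or `"paraboloid"`.
#' @param z0 base slice (plane height, sinusoid midline, paraboloid apex).
#' @param amplitude,period sinusoid parameters (voxel units);
#'   `h = z0 + amplitude * sin(2 * pi * x / period)`.
#' @param curvature,apex paraboloid parameters:
#'   `h = z0 + curvature * ((x - apex[1])^2 + (y - apex[2])^2)`; `apex`
#'   defaults to the lateral field centre.
#' @param texture `"constant"` or `"voronoi"`.
#' @param fg foreground intensity (surface signal).
#' @param texture_bg background intensity inside Voronoi cells.
#' @param n_cells number of Voronoi cells.
#' @param edge_width width of rendered Voronoi boundaries in pixels.
#' @param z_thickness Gaussian sigma (slices) of the surface's axial
#'   intensity profile.
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(shape = c("plane", "sinusoid", "paraboloid"),
                         z0, amplitude = 0, period = 64, curvature = 0,
                         apex = NULL, texture = c("constant", "voronoi"),
                         fg = 200, texture_bg = 10, n_cells = 150,
                         edge_width = 3, z_thickness = 1) {
  shape <- match.arg(shape)
  texture <- match.arg(texture)
  structure(list(shape = shape, z0 = z0, amplitude = amplitude,
                 period = period, curvature = curvature, apex = apex,
                 texture = texture, fg = fg, texture_bg = texture_bg,
                 n_cells = n_cells, edge_width = edge_width,
                 z_thickness = z_thickness),
            class = "surface_spec")
}

#' Specify a phantom stack
#'
#' @param dim stack dimensions `(nx, ny, nz)`.
#' @param surfaces list of [surface_spec()] objects (at least one).
#' @param background constant background intensity.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param rng_seed integer seed; rendering is bit-reproducible for a fixed
#'   spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(256L, 256L, 64L), surfaces,
                         background = 10, noise_sd = 20, rng_seed = 1L) {
  if (inherits(surfaces, "surface_spec")) surfaces <- list(surfaces)
  stopifnot(length(surfaces) >= 1L,
            all(vapply(surfaces, inherits, logical(1), "surface_spec")))
  structure(list(dim = as.integer(dim), surfaces = surfaces,
                 background = background, noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# continuous (unrounded) analytic height values
analytic_height_values <- function(spec, dim) {
  nx <- dim[1]; ny <- dim[2]
  x <- matrix(0:(nx - 1), nx, ny)
  y <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  switch(spec$shape,
         plane = matrix(spec$z0, nx, ny),
         sinusoid = spec$z0 + spec$amplitude * sin(2 * pi * x / spec$period),
         paraboloid = {
           apex <- if (is.null(spec$apex)) c((nx - 1) / 2, (ny - 1) / 2)
                   else spec$apex
           spec$z0 + spec$curvature *
             ((x - apex[1])^2 + (y - apex[2])^2)
         })
}

#' Analytic ground-truth height map of a surface spec
#'
#' Evaluates the surface's analytic height over the full lateral grid,
#' rounds to the nearest slice and validates that the surface stays within
#' the interior slice range `[1, nz - 2]` (so an axial maximum can flank it
#' on both sides).
#'
#' @param spec a [surface_spec()].
#' @param dim stack dimensions `(nx, ny, nz)`.
#' @return A fully covered [height_map()]; attribute `exact` carries the
#'   unrounded values.
#' @export
analytic_height_map <- function(spec, dim) {
  hc <- analytic_height_values(spec, dim)
  if (min(hc) < 1 || max(hc) > dim[3] - 2)
    stop("surface exits stack: z range [", round(min(hc), 2), ", ",
         round(max(hc), 2), "] outside [1, ", dim[3] - 2, "]")
  structure(height_map(floor(hc + 0.5)), exact = hc)
}

#' Voronoi mesh texture
#'
#' Renders a junctional-mesh-like 2D texture: `n_cells` sites are placed
#' uniformly at random, and pixels whose distances to the two nearest sites
#' differ by at most `edge_width` (a band around the Voronoi boundaries of
#' total width about `edge_width`) receive the foreground intensity; all
#' other pixels receive the background intensity.
#'
#' @param dim_xy lateral dimensions `(nx, ny)`.
#' @param n_cells number of sites (`>= 2`).
#' @param edge_width boundary band parameter in pixels.
#' @param fg,bg foreground / background intensities.
#' @param rng_seed integer seed; `NULL` draws from the ambient RNG stream
#'   (used by [render_phantom()], which seeds the whole rendering).
#' @return An `nx` x `ny` numeric matrix.
#' @export
voronoi_texture <- function(dim_xy, n_cells, edge_width, fg, bg,
                            rng_seed = NULL) {
  stopifnot(n_cells >= 2)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nx <- dim_xy[1]; ny <- dim_xy[2]
  sx <- runif(n_cells, 0, nx - 1)
  sy <- runif(n_cells, 0, ny - 1)
  px <- matrix(0:(nx - 1), nx, ny)
  py <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  d1 <- matrix(Inf, nx, ny)
  d2 <- matrix(Inf, nx, ny)
  for (i in seq_len(n_cells)) {
    di <- sqrt((px - sx[i])^2 + (py - sy[i])^2)
    closer <- di < d1
    d2 <- ifelse(closer, d1, pmin(d2, di))
    d1 <- ifelse(closer, di, d1)
  }
  ifelse(d2 - d1 <= edge_width, fg, bg)
}

#' Render a phantom stack with exact ground truth
#'
#' Each surface deposits its texture intensity at its analytic height,
#' spread axially by a Gaussian profile of sigma `z_thickness` (profile
#' centred at the unrounded height, so sub-slice surface positions are
#' represented). Surface contributions sum; a constant background and
#' seeded Gaussian noise are added and intensities are clamped at 0.
#' Surfaces passing within one slice of each other trigger a warning
#' (ambiguous ground truth).
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (numeric 3D array), `gt` (list of exact
#'   [height_map()]s, one per surface) and `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$rng_seed)

  stack <- array(0, dim = d)
  gts <- vector("list", length(spec$surfaces))
  hcs <- vector("list", length(spec$surfaces))
  for (i in seq_along(spec$surfaces)) {
    s <- spec$surfaces[[i]]
    gts[[i]] <- analytic_height_map(s, d)
    hcs[[i]] <- attr(gts[[i]], "exact")
    tex <- if (s$texture == "constant") {
      matrix(s$fg, d[1], d[2])
    } else {
      voronoi_texture(d[1:2], s$n_cells, s$edge_width, s$fg, s$texture_bg)
    }
    # deposit is relative to the phantom background so that texture_bg equal
    # to the background leaves cell interiors signal-free
    dep <- pmax(tex - spec$background, 0)
    for (z in seq_len(d[3]) - 1L) {
      w <- exp(-0.5 * (z - hcs[[i]])^2 / s$z_thickness^2)
      if (max(w) > 1e-8) stack[, , z + 1L] <- stack[, , z + 1L] + dep * w
    }
  }
  if (length(hcs) > 1L) {
    for (i in seq_along(hcs)) for (j in seq_along(hcs)) {
      if (j <= i) next
      if (min(abs(hcs[[i]] - hcs[[j]])) <= 1)
        warning("surfaces ", i, " and ", j,
                " approach within one slice: ground truth is ambiguous")
    }
  }
  stack <- stack + spec$background +
    array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
  stack <- pmax(stack, 0)
  list(stack = stack, gt = gts, spec = spec)
}

#' Default three-surface phantom
#'
#' The package's reference synthetic dataset: a constant-intensity sinusoid,
#' a flat surface supported by a coarse Voronoi mesh and a paraboloid
#' supported by a finer Voronoi mesh, in a 256 x 256 x 64 stack with
#' background 10, foreground 200 and additive Gaussian noise of sd 20
#' (peak signal-to-noise around 10). Surfaces are mutually separated by at
#' least 10 slices everywhere.
#'
#' @param rng_seed integer seed.
#' @param dim stack dimensions.
#' @param noise_sd noise level override.
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(rng_seed = 1L, dim = c(256L, 256L, 64L),
                                 noise_sd = 20) {
  nx <- dim[1]; ny <- dim[2]
  phantom_spec(
    dim = dim,
    surfaces = list(
      surface_spec("sinusoid", z0 = 14, amplitude = 6, period = nx / 2,
                   texture = "constant"),
      surface_spec("plane", z0 = 32, texture = "voronoi", n_cells = 250,
                   edge_width = 3),
      surface_spec("paraboloid", z0 = 44,
                   curvature = 12 / ((nx / 2)^2 + (ny / 2)^2),
                   texture = "voronoi", n_cells = 650, edge_width = 3)
    ),
    background = 10, noise_sd = noise_sd, rng_seed = rng_seed
  )
}

#' Well-separated multi-plane phantom
#'
#' Convenience generator for surface-count experiments: `n` flat
#' constant-texture surfaces evenly spaced along z.
#'
#' @param n number of surfaces (1 to 4 fit comfortably in 48 slices).
#' @param dim stack dimensions.
#' @param rng_seed integer seed.
#' @param noise_sd noise level.
#' @return A [phantom_spec()].
#' @export
stacked_planes_spec <- function(n, dim = c(128L, 128L, 48L), rng_seed = 1L,
                                noise_sd = 20) {
  z0 <- round(seq(8, dim[3] - 8, length.out = max(n, 2)))[seq_len(n)]
  phantom_spec(
    dim = dim,
    surfaces = lapply(z0, function(z)
      surface_spec("plane", z0 = z, texture = "constant")),
    background = 10, noise_sd = noise_sd, rng_seed = rng_seed
  )
}
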