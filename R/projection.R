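#' Smooth a height map for display
#'
#' Gaussian smoothing of `h` restricted to covered pixels, by normalized
#' (masked) convolution: uncovered pixels contribute nothing and the
#' coverage mask itself is unchanged. Used to soften the staircase artifact
#' of integer height maps before rendering; metrics are always computed on
#' the unsmoothed map. `radius` is the Gaussian sigma in pixels; 0 is the
#' identity.
#'
#' @param hm a [height_map()].
#' @param radius Gaussian sigma in pixels (`>= 0`).
#' @return A `height_map` with smoothed (non-integer) heights.
#' @export
smooth_height_map <- function(hm, radius) {
  stopifnot(inherits(hm, "height_map"), radius >= 0)
  if (radius == 0) return(hm)
  d <- dim(hm$h)
  hz <- hm$h
  hz[!hm$covered] <- 0
  arr <- function(m) array(m, c(d[1], d[2], 1L))
  num <- cpp_gauss3d(arr(hz), c(d, 1L), radius, radius, 0, FALSE)
  den <- cpp_gauss3d(arr(hm$covered + 0), c(d, 1L), radius, radius, 0, FALSE)
  out <- matrix(NA_real_, d[1], d[2])
  ok <- hm$covered & den[, , 1] > 0
  out[ok] <- num[, , 1][ok] / den[, , 1][ok]
  height_map(out, hm$covered)
}

#' Localized maximum intensity projection
#'
#' For every covered lateral pixel, takes the maximum stack intensity within
#' `delta_z` slices of the height map (window clipped at the stack
#' boundaries); uncovered pixels are 0. `delta_z = 0` samples the stack
#' exactly at the surface; `delta_z >= nz` degenerates to a full-column
#' maximum projection.
#'
#' @param stack numeric 3D array `[x, y, z]`.
#' @param hm a [height_map()]; non-integer heights are rounded to the
#'   nearest slice.
#' @param delta_z window half-width in slices (`>= 0`).
#' @return A numeric `nx` x `ny` matrix in stack intensity units.
#' @export
localized_projection <- function(stack, hm, delta_z) {
  stopifnot(length(dim(stack)) == 3L, inherits(hm, "height_map"),
            delta_z >= 0)
  d <- dim(stack)
  stopifnot(identical(dim(hm$h), d[1:2]))
  img <- matrix(0, d[1], d[2])
  idx <- which(hm$covered, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(img)
  h0 <- floor(hm$h[idx] + 0.5)
  best <- rep(-Inf, nrow(idx))
  for (dz in -delta_z:delta_z) {
    z <- pmin(pmax(h0 + dz, 0), d[3] - 1)
    best <- pmax(best, stack[cbind(idx, z + 1)])
  }
  img[idx] <- best
  img
}
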