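#' Isotropic Gaussian prefilter
#'
#' Smooths the stack with a 3D Gaussian of width `sigma_pre` (mirror
#' boundaries) to suppress noise before axial maxima are detected.
#' `sigma_pre = 0` returns the input unchanged.
#'
#' @param stack numeric 3D array `[x, y, z]`.
#' @param sigma_pre Gaussian sigma in pixels (`>= 0`).
#' @return Smoothed stack of the same shape.
#' @export
prefilter <- function(stack, sigma_pre) {
  stopifnot(length(dim(stack)) == 3L)
  if (sigma_pre < 0) stop("sigma_pre must be >= 0")
  if (sigma_pre == 0) return(stack)
  cpp_gauss3d(stack, dim(stack), sigma_pre, sigma_pre, sigma_pre, FALSE)
}

#' Axial local maxima with amplitudes
#'
#' Scans every (x, y) column for local maxima of intensity along z. A plateau
#' of equal values counts once, at its first slice; boundary slices are never
#' maxima. Each maximum carries an amplitude
#' `A(p) = min(I(p) - I(p1), I(p) - I(p2))`, the smaller of the drops to the
#' nearest local minima `p1`, `p2` on either side (the stack boundary counts
#' as a minimum at the boundary value).
#'
#' @param stack numeric 3D array, normally already prefiltered.
#' @return A data frame with 0-based `x`, `y`, `z` and `intensity`,
#'   `amplitude` columns; zero rows when the stack has no axial maxima.
#' @export
find_z_maxima <- function(stack) {
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3] >= 3L)
  m <- cpp_z_maxima(stack, dim(stack))
  data.frame(x = as.integer(m[, 1]), y = as.integer(m[, 2]),
             z = as.integer(m[, 3]),
             intensity = m[, 4], amplitude = m[, 5])
}

#' Amplitude classifier
#'
#' Keeps candidates whose amplitude reaches the empirical quantile
#' `t_a / n_levels` of the amplitude distribution over all candidates
#' (lower empirical quantile, i.e. the `ceil(p * n)`-th smallest amplitude).
#' `t_a = 0` keeps everything. Raising `t_a` never adds candidates.
#'
#' @param cands candidate data frame from [find_z_maxima()].
#' @param t_a integer level in `[0, n_levels - 1]`.
#' @param n_levels number of quantile levels on the scale.
#' @return The retained subset of `cands`.
#' @export
classify_amplitude <- function(cands, t_a, n_levels = 20L) {
  if (t_a < 0 || t_a > n_levels - 1L)
    stop("t_a must be in [0, ", n_levels - 1L, "]")
  if (t_a == 0 || nrow(cands) == 0L) return(cands)
  amps <- sort(cands$amplitude)
  thr <- amps[max(1L, ceiling(t_a / n_levels * length(amps)))]
  cands[cands$amplitude >= thr, , drop = FALSE]
}

#' Intensity classifier (multi-level Otsu)
#'
#' Quantizes candidate intensities into `n_classes` classes by multi-level
#' Otsu and keeps candidates whose class index (0-based) is at least
#' `t_otsu`. With fewer distinct intensities than classes the quantization
#' falls back to one class per distinct value (with a warning), and `t_otsu`
#' is capped at the top class so a degenerate histogram never empties the
#' selection.
#'
#' @inheritParams classify_amplitude
#' @param t_otsu integer level in `[0, n_classes - 1]`.
#' @param n_classes number of Otsu classes.
#' @return The retained subset of `cands`.
#' @export
classify_intensity <- function(cands, t_otsu, n_classes = 17L) {
  if (t_otsu < 0 || t_otsu > n_classes - 1L)
    stop("t_otsu must be in [0, ", n_classes - 1L, "]")
  if (t_otsu == 0 || nrow(cands) == 0L) return(cands)
  n_distinct <- length(unique(cands$intensity))
  k <- min(as.integer(n_classes), n_distinct)
  if (k < n_classes)
    warning("only ", n_distinct, " distinct intensities; using ", k,
            " Otsu classes")
  thr <- multi_otsu(cands$intensity, k)
  cls <- findInterval(cands$intensity, thr)
  cands[cls >= min(t_otsu, k - 1L), , drop = FALSE]
}

#' Selection masks
#'
#' A selection mask is the binary 3D output of the voxel-selection step:
#' logical `mask`, per-voxel `amplitude` (0 where the mask is false) and a
#' logical `added` array flagging voxels introduced by consolidation rather
#' than classified as axial maxima.
#'
#' @param cands candidate data frame (0-based coordinates).
#' @param dim stack dimensions `(nx, ny, nz)`.
#' @return An object of class `selection_mask`.
#' @export
rasterize_candidates <- function(cands, dim) {
  mask <- array(FALSE, dim)
  amp <- array(0, dim)
  if (nrow(cands) > 0L) {
    idx <- cbind(cands$x + 1L, cands$y + 1L, cands$z + 1L)
    mask[idx] <- TRUE
    amp[idx] <- cands$amplitude
  }
  structure(list(mask = mask, amplitude = amp, added = array(FALSE, dim)),
            class = "selection_mask")
}

#' @export
print.selection_mask <- function(x, ...) {
  cat(sprintf("selection_mask %s, %d voxels selected (%d consolidated)\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              sum(x$added)))
  invisible(x)
}

#' Remove small isolated islands
#'
#' Deletes 26-connected 3D components with fewer than `s_min` voxels.
#' `s_min` of 0 or 1 is the identity.
#'
#' @param sel a `selection_mask`.
#' @param s_min minimum component size in voxels.
#' @return The cleaned `selection_mask`.
#' @export
remove_islands <- function(sel, s_min) {
  stopifnot(inherits(sel, "selection_mask"), s_min >= 0)
  if (s_min <= 1) return(sel)
  labels <- cpp_label26(sel$mask, dim(sel$mask))
  if (max(labels) == 0L) return(sel)
  sizes <- tabulate(labels[labels > 0L])
  drop <- labels > 0L & sizes[pmax(labels, 1L)] < s_min
  sel$mask[drop] <- FALSE
  sel$amplitude[drop] <- 0
  sel$added[drop] <- FALSE
  sel
}

#' Consolidate the selection mask
#'
#' Treats the binary mask as a density, smooths it with a separable Gaussian
#' (`sigma_xy` laterally, `sigma_z` axially) and adds every voxel whose
#' density reaches `tau` to the mask (dilative fill: original voxels are
#' never removed). The axial kernel is peak-normalized so that a
#' one-slice-thick sheet keeps density 1 at its own slice; the lateral kernel
#' is sum-normalized. This is what closes the holes of a junctional mesh
#' (cell interiors have no axial maximum of their own) while leaving two
#' well-separated surfaces disjoint. Amplitudes of added voxels are
#' interpolated by normalized convolution from the retained candidates.
#' `sigma_xy = sigma_z = 0` is the identity.
#'
#' @param sel a `selection_mask`.
#' @param sigma_xy lateral smoothing extent in pixels.
#' @param sigma_z axial smoothing extent in slices.
#' @param tau density threshold for the fill.
#' @return The consolidated `selection_mask` with `added` flagging new voxels.
#' @export
consolidate <- function(sel, sigma_xy, sigma_z, tau = 0.25) {
  stopifnot(inherits(sel, "selection_mask"))
  if (sigma_xy < 0 || sigma_z < 0) stop("sigmas must be >= 0")
  if (sigma_xy == 0 && sigma_z == 0) return(sel)
  d <- dim(sel$mask)
  dens <- cpp_gauss3d(sel$mask + 0, d, sigma_xy, sigma_xy, sigma_z, TRUE)
  new <- !sel$mask & dens >= tau
  if (any(new)) {
    # amplitudes of filled voxels: normalized convolution with a compact
    # kernel, i.e. a weighted mean of the nearby retained candidates
    num <- cpp_gauss3d(sel$amplitude * sel$mask, d, 2, 2, 1, FALSE)
    den <- cpp_gauss3d(sel$mask + 0, d, 2, 2, 1, FALSE)
    amp_new <- ifelse(den[new] > 0, num[new] / den[new], 0)
    sel$amplitude[new] <- amp_new
    sel$mask[new] <- TRUE
    sel$added[new] <- TRUE
  }
  sel
}

#' Surface voxel selection (step 1)
#'
#' Full selection pipeline: prefilter, axial maxima detection, amplitude and
#' intensity classification, rasterization, island removal and consolidation.
#' Deterministic for fixed inputs.
#'
#' @param stack numeric 3D array `[x, y, z]`.
#' @param params an [extraction_params()] object.
#' @return A `selection_mask`.
#' @export
select_voxels <- function(stack, params) {
  validate_extraction_params(params)
  sm <- prefilter(stack, params$sigma_pre)
  cands <- find_z_maxima(sm)
  cands <- classify_amplitude(cands, params$t_a, params$n_amp_levels)
  cands <- classify_intensity(cands, params$t_otsu, params$n_otsu_classes)
  sel <- rasterize_candidates(cands, dim(stack))
  sel <- remove_islands(sel, params$s_min)
  consolidate(sel, params$sigma_xy, params$sigma_z, params$consolidation_tau)
}
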