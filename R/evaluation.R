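common_mask <- function(hm, gt) {
  if (!identical(dim(hm$h), dim(gt$h)))
    stop("height map dimensions differ: ",
         paste(dim(hm$h), collapse = "x"), " vs ",
         paste(dim(gt$h), collapse = "x"))
  hm$covered & gt$covered
}

#' Per-pixel height error map
#'
#' Absolute axial distance `|h - h_gt|` on pixels covered by both maps,
#' `NA` elsewhere.
#'
#' @param hm reconstructed [height_map()].
#' @param gt ground-truth [height_map()].
#' @return A numeric matrix.
#' @export
error_map <- function(hm, gt) {
  cm <- common_mask(hm, gt)
  out <- matrix(NA_real_, nrow(hm$h), ncol(hm$h))
  out[cm] <- abs(hm$h[cm] - gt$h[cm])
  out
}

#' Root mean square height error
#'
#' RMSE of the height difference over the pixels common to the
#' reconstructed and ground-truth maps (in slice/pixel units). Symmetric in
#' its arguments.
#'
#' @inheritParams error_map
#' @return Non-negative scalar.
#' @export
rmse <- function(hm, gt) {
  cm <- common_mask(hm, gt)
  if (!any(cm)) stop("no common covered pixels")
  sqrt(mean((hm$h[cm] - gt$h[cm])^2))
}

#' Coverage of the ground truth
#'
#' Percentage of ground-truth-covered pixels that the reconstruction also
#' covers. Not symmetric: the denominator is always the ground truth.
#'
#' @inheritParams error_map
#' @return Percentage in `[0, 100]`.
#' @export
coverage <- function(hm, gt) {
  if (!identical(dim(hm$h), dim(gt$h))) stop("height map dimensions differ")
  n_gt <- sum(gt$covered)
  if (n_gt == 0L) stop("ground truth has no covered pixels")
  100 * sum(hm$covered & gt$covered) / n_gt
}

#' Fraction of common pixels within a height tolerance
#'
#' Percentage of pixels common to both maps where `|h - h_gt| <= tol`.
#' Non-decreasing in `tol`; 100 at infinite tolerance.
#'
#' @inheritParams error_map
#' @param tol tolerance in slices.
#' @return Percentage in `[0, 100]`.
#' @export
fraction_within <- function(hm, gt, tol) {
  cm <- common_mask(hm, gt)
  if (!any(cm)) stop("no common covered pixels")
  100 * mean(abs(hm$h[cm] - gt$h[cm]) <= tol)
}

#' Pair reconstructed surfaces with ground-truth surfaces
#'
#' Extraction output is unordered, so surfaces are assigned greedily to
#' ground truths by decreasing common-pixel count (ties broken by lower
#' RMSE). Unmatched entries on either side are reported.
#'
#' @param recons list of reconstructed [height_map()]s.
#' @param gts list of ground-truth [height_map()]s.
#' @return List with `pairs` (two-column matrix `recon`, `gt` of indices),
#'   `unmatched_recon` and `unmatched_gt`.
#' @export
pair_surfaces <- function(recons, gts) {
  stopifnot(length(recons) > 0L, length(gts) > 0L)
  nr <- length(recons); ng <- length(gts)
  ov <- matrix(0L, nr, ng)
  er <- matrix(Inf, nr, ng)
  for (i in seq_len(nr)) for (j in seq_len(ng)) {
    cm <- common_mask(recons[[i]], gts[[j]])
    ov[i, j] <- sum(cm)
    if (ov[i, j] > 0L)
      er[i, j] <- sqrt(mean((recons[[i]]$h[cm] - gts[[j]]$h[cm])^2))
  }
  pairs <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("recon", "gt")))
  free_r <- rep(TRUE, nr); free_g <- rep(TRUE, ng)
  repeat {
    m <- ov * outer(free_r, free_g)
    if (max(m) == 0L) break
    best <- which(m == max(m), arr.ind = TRUE)
    if (nrow(best) > 1L)
      best <- best[order(er[best]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    pairs <- rbind(pairs, c(i, j))
    free_r[i] <- FALSE; free_g[j] <- FALSE
  }
  list(pairs = pairs,
       unmatched_recon = which(free_r),
       unmatched_gt = which(free_g))
}

#' Evaluation report against ground truth
#'
#' Pairs reconstructions with ground truths and tabulates the quality
#' metrics per ground-truth surface.
#'
#' @param recons list of reconstructed [height_map()]s.
#' @param gts list of ground-truth [height_map()]s.
#' @return A data frame with one row per ground-truth surface: paired
#'   reconstruction index (`NA` if unmatched), `rmse`, `coverage`,
#'   `fraction_within_1`, `fraction_within_2` and `n_common`.
#' @export
eval_report <- function(recons, gts) {
  rows <- lapply(seq_along(gts), function(j) {
    data.frame(gt = j, recon = NA_integer_, rmse = NA_real_, coverage = 0,
               fraction_within_1 = NA_real_, fraction_within_2 = NA_real_,
               n_common = 0L)
  })
  if (length(recons) > 0L) {
    pr <- pair_surfaces(recons, gts)
    for (k in seq_len(nrow(pr$pairs))) {
      i <- pr$pairs[k, 1]; j <- pr$pairs[k, 2]
      cm <- common_mask(recons[[i]], gts[[j]])
      if (!any(cm)) next
      rows[[j]] <- data.frame(
        gt = j, recon = i,
        rmse = rmse(recons[[i]], gts[[j]]),
        coverage = coverage(recons[[i]], gts[[j]]),
        fraction_within_1 = fraction_within(recons[[i]], gts[[j]], 1),
        fraction_within_2 = fraction_within(recons[[i]], gts[[j]], 2),
        n_common = sum(cm))
    }
  }
  do.call(rbind, rows)
}

#' One-parameter-at-a-time sensitivity sweep
#'
#' Re-runs the full extraction on `stack` for every value of one control
#' parameter (all others fixed), evaluates each run against the ground
#' truths and tabulates value x surface x metric. The attribute
#' `stability` lists the swept values at which every ground-truth surface
#' is recovered with RMSE <= 1.5 and coverage >= 85% and the surface count
#' matches the ground truth.
#'
#' @param stack numeric 3D array.
#' @param gts list of ground-truth [height_map()]s.
#' @param params baseline [extraction_params()].
#' @param name name of the parameter to sweep (a field of
#'   `extraction_params`).
#' @param values vector of values to try.
#' @param rmse_max,coverage_min stability-interval criteria.
#' @return A data frame (one row per value x ground-truth surface) with
#'   attribute `stability`.
#' @export
sweep_parameter <- function(stack, gts, params, name, values,
                            rmse_max = 1.5, coverage_min = 85) {
  validate_extraction_params(params)
  if (!name %in% names(params))
    stop("unknown parameter: ", name)
  out <- list()
  stable <- logical(length(values))
  for (k in seq_along(values)) {
    p <- params
    p[[name]] <- if (is.integer(params[[name]])) as.integer(values[k])
                 else as.numeric(values[k])
    validate_extraction_params(p)
    recons <- extract_surfaces(stack, p)
    rep_k <- eval_report(recons, gts)
    rep_k <- cbind(parameter = name, value = values[k], rep_k,
                   n_surfaces_found = length(recons))
    out[[k]] <- rep_k
    stable[k] <- length(recons) == length(gts) &&
      all(!is.na(rep_k$rmse)) &&
      all(rep_k$rmse <= rmse_max) &&
      all(rep_k$coverage >= coverage_min)
  }
  res <- do.call(rbind, out)
  attr(res, "stability") <- values[stable]
  res
}
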