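as_pixels <- function(x) {
  if (inherits(x, "ose")) return(x$pixels)
  if (is.matrix(x) && ncol(x) == 2L) return(x)
  stop("expected an ose or a 2-column (u, z) matrix")
}

# logical occupancy matrix of a pixel set, dimensioned to hold both arguments
front_grid <- function(line_px, nu, nz) {
  g <- matrix(FALSE, nu, nz)
  g[line_px + 1L] <- TRUE
  g
}

#' Overlap between a surface front line and a candidate OSE
#'
#' The front line is the intersection of the growing surface with the
#' section adjacent to the candidate. The overlap `R` is the number of
#' candidate pixels whose in-plane coordinate `u` coincides with some front
#' line pixel's `u`.
#'
#' @param line front line pixels: a 2-column `(u, z)` matrix or an `ose`.
#' @param ose candidate: an `ose` or a 2-column `(u, z)` matrix.
#' @return Integer pixel count.
#' @export
overlap_R <- function(line, ose) {
  lp <- as_pixels(line); op <- as_pixels(ose)
  sum(op[, 1] %in% lp[, 1])
}

#' Connectivity between a surface front line and a candidate OSE
#'
#' Among the overlapping pixels of the candidate (see [overlap_R()]), the
#' fraction lying within one slice (`|dz| <= 1`) of a front line pixel at
#' the same `u` — i.e. 6-connected to the front line within their common
#' orthogonal section. When the overlap is zero the connectivity is
#' undefined; 0 is returned with attribute `undefined = TRUE`.
#'
#' @inheritParams overlap_R
#' @return Fraction in `[0, 1]`.
#' @export
connectivity_C <- function(line, ose) {
  lp <- as_pixels(line); op <- as_pixels(ose)
  ov <- op[op[, 1] %in% lp[, 1], , drop = FALSE]
  if (nrow(ov) == 0L) return(structure(0, undefined = TRUE))
  nu <- max(lp[, 1], op[, 1]) + 1L
  nz <- max(lp[, 2], op[, 2]) + 2L
  g <- front_grid(lp, nu, nz + 1L)
  u1 <- ov[, 1] + 1L
  z1 <- ov[, 2] + 1L
  conn <- g[cbind(u1, z1)] |
    g[cbind(u1, pmax(z1 - 1L, 1L))] |
    g[cbind(u1, z1 + 1L)]
  sum(conn) / nrow(ov)
}

#' Accept or reject a candidate OSE against a front line
#'
#' A candidate is added to the surface iff its overlap reaches `r0` and its
#' connectivity reaches `c0`.
#'
#' @inheritParams overlap_R
#' @param r0 overlap threshold (pixel count).
#' @param c0 connectivity threshold (fraction).
#' @return Logical.
#' @export
accept_ose <- function(line, ose, r0, c0) {
  R <- overlap_R(line, ose)
  if (R < r0) return(FALSE)
  if (R == 0L) return(r0 <= 0 && c0 <= 0)
  as.numeric(connectivity_C(line, ose)) >= c0
}

# internal: grow from seed over per-section ose index, mutating `alive`
# front-line matching uses a dense (nu x nz) occupancy grid for speed.
grow_ids <- function(seed_id, oses, sec_of, alive, nu, nz, r0, c0) {
  consumed <- seed_id
  n_sec_max <- max(sec_of)
  by_sec <- split(seq_along(oses), sec_of)

  sweep_side <- function(start_front, s0, step) {
    front <- start_front
    ids <- integer(0)
    s <- s0
    repeat {
      s <- s + step
      if (s < 0L || s > n_sec_max) break
      cand <- by_sec[[as.character(s)]]
      cand <- cand[alive[cand]]
      if (length(cand) == 0L) break
      g <- front_grid(front, nu, nz + 1L)
      fu <- which(rowSums(g) > 0L)
      acc <- logical(length(cand))
      for (i in seq_along(cand)) {
        px <- oses[[cand[i]]]$pixels
        ovm <- (px[, 1] + 1L) %in% fu
        R <- sum(ovm)
        if (R < r0) next
        if (R == 0L) { acc[i] <- (r0 <= 0 && c0 <= 0); next }
        ov <- px[ovm, , drop = FALSE]
        u1 <- ov[, 1] + 1L; z1 <- ov[, 2] + 1L
        conn <- g[cbind(u1, z1)] |
          g[cbind(u1, pmax(z1 - 1L, 1L))] |
          g[cbind(u1, pmin(z1 + 1L, nz + 1L))]
        acc[i] <- (sum(conn) / R) >= c0
      }
      if (!any(acc)) break
      taken <- cand[acc]
      alive[taken] <<- FALSE
      ids <- c(ids, taken)
      front <- do.call(rbind, lapply(oses[taken], function(o) o$pixels))
    }
    ids
  }

  seed_front <- oses[[seed_id]]$pixels
  s0 <- sec_of[seed_id]
  alive[seed_id] <- FALSE
  up <- sweep_side(seed_front, s0, +1L)
  down <- sweep_side(seed_front, s0, -1L)
  list(ids = c(consumed, up, down), alive = alive)
}

#' Grow one surface draft from a seed OSE
#'
#' Bidirectional sweep along the assembly axis starting at the seed's
#' section: in each adjacent section every still-available OSE passing
#' [accept_ose()] against the current front line is added (several per
#' section allowed); the front line becomes the union of the pixels just
#' added; growth on a side stops at the first section where nothing is
#' accepted.
#'
#' @param seed_id index of the seed in `oses`.
#' @param oses list of `ose` objects of one assembly round (any sections).
#' @param r0,c0 matching thresholds.
#' @param alive logical vector marking OSEs still available; defaults to all
#'   except none.
#' @return List with `ids` (indices of consumed OSEs, seed first) and the
#'   updated `alive` vector.
#' @export
grow_surface <- function(seed_id, oses, r0, c0, alive = NULL) {
  stopifnot(length(oses) > 0L, seed_id >= 1L, seed_id <= length(oses))
  if (is.null(alive)) alive <- rep(TRUE, length(oses))
  sec_of <- vapply(oses, function(o) o$index, integer(1))
  nu <- max(vapply(oses, function(o) max(o$pixels[, 1]), numeric(1))) + 1L
  nz <- max(vapply(oses, function(o) max(o$pixels[, 2]), numeric(1))) + 1L
  grow_ids(seed_id, oses, sec_of, alive, nu, nz, r0, c0)
}

#' One assembly round
#'
#' Builds all OSEs on the stated assembly axis (round along x uses yz
#' sections; round along y uses xz sections), determines the seed-size
#' threshold, then repeatedly grows a surface from the largest remaining
#' seed-eligible OSE until no eligible seed is left. Drafts whose lateral
#' footprint is below `min_footprint_frac * nx * ny` are discarded (their
#' OSEs stay consumed).
#'
#' @param sel a `selection_mask`.
#' @param axis assembly axis, `"x"` (round 1) or `"y"` (round 2).
#' @param t_ose seed-size fraction.
#' @param r0,c0 matching thresholds.
#' @param min_footprint_frac minimum reported footprint fraction.
#' @param deadline optional POSIXct wall-clock deadline.
#' @return List of surface drafts; each draft is a 3-column `(x, y, z)`
#'   matrix of 0-based voxel coordinates.
#' @export
assemble_round <- function(sel, axis = c("x", "y"), t_ose, r0, c0,
                           min_footprint_frac = 0.01, deadline = NULL) {
  stopifnot(inherits(sel, "selection_mask"))
  axis <- match.arg(axis)
  d <- dim(sel$mask)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  n_sections <- if (axis == "x") nx else ny
  sec_axis <- if (axis == "x") "y" else "x"

  oses <- list()
  for (i in seq_len(n_sections) - 1L) {
    s <- section_of(sel, sec_axis, i)
    oses <- c(oses, build_oses(s))
  }
  if (length(oses) == 0L) return(list())
  check_deadline(deadline, "assembly")

  sizes <- vapply(oses, function(o) o$size, numeric(1))
  sec_of <- vapply(oses, function(o) o$index, integer(1))
  min_u <- vapply(oses, function(o) min(o$pixels[, 1]), numeric(1))
  thr <- seed_threshold(oses, t_ose)
  nu <- if (axis == "x") ny else nx
  alive <- rep(TRUE, length(oses))
  ord <- order(-sizes, sec_of, min_u)

  drafts <- list()
  for (seed in ord) {
    if (!alive[seed] || sizes[seed] < thr) next
    check_deadline(deadline, "assembly")
    res <- grow_ids(seed, oses, sec_of, alive, nu, nz, r0, c0)
    alive <- res$alive
    vox <- do.call(rbind, lapply(res$ids, function(i) {
      px <- oses[[i]]$pixels
      s <- oses[[i]]$index
      if (axis == "x") cbind(x = rep(s, nrow(px)), y = px[, 1], z = px[, 2])
      else cbind(x = px[, 1], y = rep(s, nrow(px)), z = px[, 2])
    }))
    footprint <- length(unique(vox[, 1] + nx * vox[, 2]))
    if (footprint >= min_footprint_frac * nx * ny)
      drafts[[length(drafts) + 1L]] <- vox
  }
  drafts
}

# per-(x,y)-column median z of a draft; returns key (0-based x + nx*y) and
# the median rounded half down
col_medians <- function(vox, nx) {
  k <- vox[, 1] + nx * vox[, 2]
  o <- order(k, vox[, 3])
  k <- k[o]; z <- vox[o, 3]
  ends <- c(which(diff(k) != 0), length(k))
  starts <- c(1L, head(ends, -1L) + 1L)
  len <- ends - starts + 1L
  med <- (z[starts + (len - 1L) %/% 2L] + z[starts + len %/% 2L]) / 2
  list(key = k[starts], h = ceiling(med - 0.5), med = med)
}

#' Merge the drafts of the two assembly rounds
#'
#' Drafts from the two orthogonal rounds that describe the same physical
#' surface are united: two drafts are paired when at least `overlap_frac` of
#' the smaller draft's lateral footprint overlaps the other's and the median
#' `|dz|` over the common columns is at most `max_dz`. Pairing is transitive
#' (connected groups merge into one surface), unpaired drafts pass through,
#' and the results are made voxel-disjoint (a conflicting voxel stays with
#' the larger draft).
#'
#' @param drafts1,drafts2 draft lists from [assemble_round()] on the same
#'   selection mask.
#' @param dim stack dimensions `(nx, ny, nz)`.
#' @param overlap_frac footprint-overlap fraction required for pairing.
#' @param max_dz maximum median `|dz|` for pairing, in slices.
#' @return A list of voxel-disjoint drafts.
#' @export
merge_rounds <- function(drafts1, drafts2, dim, overlap_frac = 0.5,
                         max_dz = 2) {
  nx <- dim[1]
  all_drafts <- c(drafts1, drafts2)
  n1 <- length(drafts1)
  n <- length(all_drafts)
  if (n == 0L) return(list())
  cm <- lapply(all_drafts, col_medians, nx = nx)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  if (n1 > 0L && n > n1) {
    for (i in seq_len(n1)) for (j in (n1 + 1L):n) {
      mi <- match(cm[[i]]$key, cm[[j]]$key)
      common <- which(!is.na(mi))
      ov <- length(common)
      if (ov < overlap_frac * min(length(cm[[i]]$key), length(cm[[j]]$key)))
        next
      dz <- abs(cm[[i]]$med[common] - cm[[j]]$med[mi[common]])
      if (median(dz) <= max_dz) union(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  merged <- lapply(unique(roots), function(r) {
    vox <- do.call(rbind, all_drafts[roots == r])
    vox[!duplicated(vox[, 1] + nx * (vox[, 2] + dim[2] * vox[, 3])), ,
        drop = FALSE]
  })
  # voxel-disjointness across drafts: keep conflicts in the larger draft
  sizes <- vapply(merged, nrow, integer(1))
  merged <- merged[order(-sizes)]
  taken <- integer(0)
  out <- list()
  for (d in merged) {
    keys <- d[, 1] + nx * (d[, 2] + dim[2] * d[, 3])
    keep <- !(keys %in% taken)
    taken <- c(taken, keys[keep])
    if (any(keep)) out[[length(out) + 1L]] <- d[keep, , drop = FALSE]
  }
  out
}

#' Height map of a surface draft
#'
#' Collapses a draft's voxel set to a single-valued height map: for every
#' lateral column with at least one draft voxel, `h` is the median of that
#' column's z-values (rounded half down); other columns are uncovered.
#'
#' @param draft 3-column `(x, y, z)` voxel matrix (0-based).
#' @param dim stack dimensions `(nx, ny, nz)`.
#' @return A [height_map()].
#' @export
draft_to_height_map <- function(draft, dim) {
  if (is.null(draft) || nrow(draft) == 0L)
    stop("cannot build a height map from an empty draft")
  cm <- col_medians(draft, dim[1])
  h <- matrix(NA_real_, dim[1], dim[2])
  h[cbind(cm$key %% dim[1] + 1L, cm$key %/% dim[1] + 1L)] <- cm$h
  height_map(h)
}

check_deadline <- function(deadline, phase) {
  if (!is.null(deadline) && Sys.time() > deadline)
    stop(structure(class = c("multisurf_timeout", "error", "condition"),
                   list(message = paste0("run timeout exceeded during ",
                                         phase),
                        call = NULL)))
  invisible(NULL)
}

#' Extract all surfaces of a stack
#'
#' Full two-step pipeline: voxel selection, two orthogonal assembly rounds,
#' round merging, and conversion of every draft to a height map. The number
#' of surfaces is an output of the algorithm, never an input. Height maps
#' are returned sorted by decreasing covered area.
#'
#' @param stack numeric 3D array `[x, y, z]`.
#' @param params an [extraction_params()] object.
#' @return A list of [height_map()] objects (possibly empty), with attribute
#'   `params`.
#' @export
extract_surfaces <- function(stack, params = extraction_params()) {
  validate_extraction_params(params)
  deadline <- Sys.time() + params$timeout_seconds
  sel <- select_voxels(stack, params)
  check_deadline(deadline, "selection")
  if (!any(sel$mask)) {
    message("no surface voxels selected; returning an empty surface list")
    return(structure(list(), params = params))
  }
  r1 <- assemble_round(sel, "x", params$t_ose1, params$r1, params$c1,
                       params$min_footprint_frac, deadline)
  r2 <- assemble_round(sel, "y", params$t_ose2, params$r2, params$c2,
                       params$min_footprint_frac, deadline)
  drafts <- merge_rounds(r1, r2, dim(stack))
  d <- dim(stack)
  keep <- vapply(drafts, function(v)
    length(unique(v[, 1] + d[1] * v[, 2])) >=
      params$min_footprint_frac * d[1] * d[2], logical(1))
  drafts <- drafts[keep]
  if (length(drafts) == 0L) {
    message("no surface drafts survived assembly")
    return(structure(list(), params = params))
  }
  maps <- lapply(drafts, draft_to_height_map, dim = d)
  areas <- vapply(maps, function(m) sum(m$covered), integer(1))
  structure(maps[order(-areas)], params = params)
}
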