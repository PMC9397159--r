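#' Extract one orthogonal section of a selection mask
#'
#' An orthogonal section is a 2D slice perpendicular to the imaging plane:
#' an xz section (fixed y, in-plane coordinate `u = x`) or a yz section
#' (fixed x, in-plane coordinate `u = y`).
#'
#' @param sel a `selection_mask`.
#' @param axis `"x"` for xz sections (fixed y) or `"y"` for yz sections
#'   (fixed x); names the in-plane axis.
#' @param index 0-based index of the fixed coordinate.
#' @return A `section_mask`: list with `axis`, `index` and a logical `mask`
#'   matrix (rows = in-plane coordinate `u`, cols = z).
#' @export
section_of <- function(sel, axis = c("x", "y"), index) {
  stopifnot(inherits(sel, "selection_mask"))
  axis <- match.arg(axis)
  d <- dim(sel$mask)
  n_fixed <- if (axis == "x") d[2] else d[1]
  if (index < 0 || index >= n_fixed)
    stop("section index ", index, " out of range [0, ", n_fixed - 1, "]")
  m <- if (axis == "x") sel$mask[, index + 1L, ] else sel$mask[index + 1L, , ]
  structure(list(axis = axis, index = as.integer(index),
                 mask = matrix(m, nrow = if (axis == "x") d[1] else d[2])),
            class = "section_mask")
}

new_ose <- function(pixels, axis, index) {
  # pixels: 2-col matrix (u, z), 0-based, sorted by u
  structure(list(pixels = pixels, axis = axis, index = as.integer(index),
                 size = nrow(pixels)),
            class = "ose")
}

#' Build the orthogonal surface elements of one section
#'
#' Partitions the selected pixels of a section into contiguous chains
#' (orthogonal surface elements, OSEs) under the section connectivity rules:
#' a pixel `(u, z)` joins a chain ending at `(u - 1, z')` when
#' `|z - z'| <= 1`; a single missing column is bridged only when the
#' flanking pixels share the same z; chains never fork (a chain with several
#' admissible continuations takes the one with the smallest `|dz|`, ties
#' going to the smaller z, and the remaining pixels start their own chains).
#' Every selected pixel belongs to exactly one OSE, possibly a singleton.
#'
#' @param section a `section_mask` from [section_of()].
#' @return A list of `ose` objects, ordered by creation (first pixel in
#'   column-major scan order).
#' @export
build_oses <- function(section) {
  stopifnot(inherits(section, "section_mask"))
  labels <- cpp_build_oses(section$mask)
  k <- max(labels)
  if (k == 0L) return(list())
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[idx]
  out <- vector("list", k)
  for (i in seq_len(k)) {
    px <- idx[lab == i, , drop = FALSE]
    px <- px[order(px[, 1]), , drop = FALSE] - 1L  # to 0-based
    colnames(px) <- c("u", "z")
    out[[i]] <- new_ose(px, section$axis, section$index)
  }
  out
}

#' Seed-size threshold
#'
#' An OSE may seed a new surface only if its size reaches the `(1 - t_ose)`
#' empirical quantile of all OSE sizes in the round. `t_ose = 1` makes every
#' OSE seed-eligible; raising `t_ose` enlarges the eligible set
#' monotonically.
#'
#' @param oses list of `ose` objects (all sections of one round).
#' @param t_ose seed-size fraction in `[0, 1]`.
#' @return The size threshold (an OSE is eligible iff `size >= threshold`).
#' @export
seed_threshold <- function(oses, t_ose) {
  stopifnot(t_ose >= 0, t_ose <= 1)
  if (length(oses) == 0L)
    stop("no surface structure detected: empty OSE set")
  sizes <- sort(vapply(oses, function(o) o$size, numeric(1)))
  p <- 1 - t_ose
  sizes[max(1L, ceiling(p * length(sizes)))]
}
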