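#' @section Coordinate conventions:
#' Stacks are plain numeric 3D arrays indexed `[x, y, z]` where `x` is the
#' image column (fastest axis), `y` the row and `z` the slice. All coordinates
#' reported by the package (candidate tables, height-map CSVs) are 0-based.
#' On disk, multi-page TIFF pages are z-slices and each page stores rows = y,
#' columns = x.
#' @name stack-conventions
NULL

MAX_U16 <- 65535

#' Read a 3D stack from a multi-page TIFF
#'
#' @param path path to a single-channel multi-page TIFF with at least 3 pages.
#' @return A numeric 3D array indexed `[x, y, z]`; integer intensities are
#'   preserved exactly.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read stack: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  if (length(d) == 3L)
    stop("unsupported format: expected a single-channel image, got ",
         d[3], " channels")
  nz <- length(pages)
  if (nz < 3L)
    stop("stack must have at least 3 slices (got ", nz, ")")
  ny <- d[1]; nx <- d[2]
  arr <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    pg <- pages[[k]]
    if (!identical(dim(pg), d)) stop("inconsistent page dimensions in ", path)
    arr[, , k] <- t(pg)
  }
  if (!all(is.finite(arr))) stop("stack contains non-finite intensities")
  arr
}

#' Write a 3D stack as a multi-page TIFF
#'
#' Intensities are stored as unsigned integers; `bits` selects 8- or 16-bit
#' output. Values must lie within the representable range and are rounded.
#'
#' @param stack numeric 3D array `[x, y, z]`.
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(length(dim(stack)) == 3L, bits %in% c(8L, 16L))
  top <- if (bits == 8L) 255 else MAX_U16
  v <- round(stack)
  if (min(v) < 0 || max(v) > top)
    stop("intensities out of range [0, ", top, "] for ", bits, "-bit output")
  pages <- lapply(seq_len(dim(stack)[3]), function(k) t(v[, , k]) / top)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Height maps
#'
#' A height map is a partial mapping `z = h(x, y)` giving, for every lateral
#' pixel covered by a surface, the 0-based slice index of the surface voxel.
#' In memory it is a list with an `h` matrix (`nx` x `ny`, `NA` where
#' uncovered) and a logical `covered` matrix. On disk (16-bit single-page
#' TIFF) covered pixels store `z + 1` and uncovered pixels store the sentinel
#' 0, so the usual background-is-zero raster convention holds without
#' sacrificing slice 0.
#'
#' @param h numeric matrix of z-values (0-based); entries at uncovered pixels
#'   are ignored.
#' @param covered logical matrix of the same shape; defaults to `!is.na(h)`.
#' @return An object of class `height_map`.
#' @export
height_map <- function(h, covered = NULL) {
  stopifnot(is.matrix(h))
  if (is.null(covered)) covered <- !is.na(h)
  stopifnot(is.logical(covered), identical(dim(covered), dim(h)))
  h[!covered] <- NA_real_
  if (any(h[covered] < 0, na.rm = TRUE))
    stop("height map contains negative z-values")
  structure(list(h = h, covered = covered, sentinel = 0L),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height_map %d x %d, %d covered pixels (%.1f%%)\n",
              nrow(x$h), ncol(x$h), sum(x$covered),
              100 * mean(x$covered)))
  invisible(x)
}

#' Write / read a height map
#'
#' @param hm a [height_map()].
#' @param path file path; `.tif`/`.tiff` selects the 16-bit TIFF encoding,
#'   `.csv` a table of 0-based `x,y,z` triplets (covered pixels only).
#' @param dim for the CSV reader, the expected `(nx, ny)` lateral dimensions.
#' @return `read_height_map()` returns a `height_map`.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    idx <- which(hm$covered, arr.ind = TRUE)
    df <- data.frame(x = idx[, 1] - 1L, y = idx[, 2] - 1L,
                     z = hm$h[hm$covered])
    df <- df[order(df$y, df$x), ]
    write.csv(df, path, row.names = FALSE)
  } else {
    enc <- matrix(0, nrow(hm$h), ncol(hm$h))
    enc[hm$covered] <- hm$h[hm$covered] + 1
    if (max(enc) > MAX_U16) stop("z-values exceed 16-bit range")
    tiff::writeTIFF(t(enc) / MAX_U16, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path, dim = NULL) {
  if (!file.exists(path)) stop("cannot read height map: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (is.null(dim)) stop("reading a CSV height map requires dim = c(nx, ny)")
    df <- read.csv(path)
    stopifnot(all(c("x", "y", "z") %in% names(df)))
    if (any(df$x < 0 | df$x >= dim[1] | df$y < 0 | df$y >= dim[2]))
      stop("height map coordinates outside the expected ", dim[1], " x ",
           dim[2], " grid")
    h <- matrix(NA_real_, dim[1], dim[2])
    h[cbind(df$x + 1L, df$y + 1L)] <- df$z
    height_map(h)
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (is.list(img)) stop("expected a single-page height map image")
    enc <- t(img)
    if (!is.null(dim) && !identical(base::dim(enc), as.integer(dim)))
      stop("height map dimensions ", paste(base::dim(enc), collapse = "x"),
           " do not match expected ", paste(dim, collapse = "x"))
    h <- matrix(NA_real_, nrow(enc), ncol(enc))
    cov <- enc > 0
    h[cov] <- enc[cov] - 1
    height_map(h, cov)
  }
}
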