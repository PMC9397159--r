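# Independent brute-force oracles. These deliberately re-derive results with
# naive loops, never calling the implementation paths they are used to check.

# per-column scan for axial maxima and amplitudes, plain R
oracle_z_maxima <- function(stack) {
  d <- dim(stack)
  out <- NULL
  for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    col <- stack[x, y, ]
    nz <- length(col)
    a <- 1
    while (a <= nz) {
      b <- a
      while (b + 1 <= nz && col[b + 1] == col[a]) b <- b + 1
      rises <- a > 1 && col[a - 1] < col[a]
      drops <- b < nz && col[b + 1] < col[b]
      if (rises && drops) {
        j <- a
        while (j > 1 && col[j - 1] <= col[j]) j <- j - 1
        leftmin <- col[j]
        j <- b
        while (j < nz && col[j + 1] <= col[j]) j <- j + 1
        rightmin <- col[j]
        out <- rbind(out, c(x - 1, y - 1, a - 1, col[a],
                            min(col[a] - leftmin, col[b] - rightmin)))
      }
      a <- b + 1
    }
  }
  if (is.null(out)) out <- matrix(numeric(0), 0, 5)
  colnames(out) <- c("x", "y", "z", "intensity", "amplitude")
  out
}

# chain-rule application with explicit per-column edge enumeration; returns
# the partition of section pixels as a list of (u, z) matrices (0-based)
oracle_oses <- function(mask) {
  nu <- nrow(mask); nz <- ncol(mask)
  chains <- list()   # each: list(pixels = matrix, last_u, last_z, open)
  for (u in seq_len(nu)) {
    zs <- which(mask[u, ])
    taken <- rep(FALSE, length(zs))
    # enumerate admissible direct edges, pick greedily by (|dz|, pixel z, chain z)
    if (length(zs) > 0 && length(chains) > 0) {
      edges <- NULL
      for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        if (!ch$open || ch$last_u != u - 1) next
        for (pi in seq_along(zs)) {
          dz <- abs(zs[pi] - ch$last_z)
          if (dz <= 1) edges <- rbind(edges, c(dz, zs[pi], ch$last_z, ci, pi))
        }
      }
      if (!is.null(edges)) {
        edges <- edges[order(edges[, 1], edges[, 2], edges[, 3]), , drop = FALSE]
        used_chain <- rep(FALSE, length(chains))
        for (e in seq_len(nrow(edges))) {
          ci <- edges[e, 4]; pi <- edges[e, 5]
          if (used_chain[ci] || taken[pi]) next
          used_chain[ci] <- TRUE; taken[pi] <- TRUE
          chains[[ci]]$pixels <- rbind(chains[[ci]]$pixels, c(u, zs[pi]))
          chains[[ci]]$last_u <- u; chains[[ci]]$last_z <- zs[pi]
        }
      }
      # single straight gaps from u-2, same z only
      for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        if (!ch$open || ch$last_u != u - 2) next
        for (pi in seq_along(zs)) {
          if (!taken[pi] && zs[pi] == ch$last_z) {
            taken[pi] <- TRUE
            chains[[ci]]$pixels <- rbind(chains[[ci]]$pixels, c(u, zs[pi]))
            chains[[ci]]$last_u <- u; chains[[ci]]$last_z <- zs[pi]
            break
          }
        }
      }
    }
    for (pi in seq_along(zs)) {
      if (!taken[pi])
        chains[[length(chains) + 1]] <- list(pixels = matrix(c(u, zs[pi]), 1),
                                             last_u = u, last_z = zs[pi],
                                             open = TRUE)
    }
    for (ci in seq_along(chains))
      if (chains[[ci]]$last_u < u - 1) chains[[ci]]$open <- FALSE
  }
  lapply(chains, function(ch) {
    px <- ch$pixels - 1L  # to 0-based (u was 1-based row, z 1-based col)
    px[order(px[, 1]), , drop = FALSE]
  })
}

# canonical form of a pixel-set partition for comparison
canon_partition <- function(sets) {
  keys <- lapply(sets, function(px)
    paste(sort(paste(px[, 1], px[, 2], sep = ",")), collapse = ";"))
  sort(unlist(keys))
}

# triple-loop localized projection
oracle_projection <- function(stack, hm, delta_z) {
  d <- dim(stack)
  img <- matrix(0, d[1], d[2])
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    if (!hm$covered[x, y]) next
    h <- round(hm$h[x, y])
    zlo <- max(0, h - delta_z); zhi <- min(d[3] - 1, h + delta_z)
    img[x, y] <- max(stack[x, y, (zlo:zhi) + 1])
  }
  img
}

# discrete 3D gaussian kernel weight at offset 0 (radius 3*sigma), matching
# the mirror-boundary separable convolution for an interior impulse
oracle_gauss_central_weight <- function(sigma) {
  r <- max(1, ceiling(3 * sigma))
  w <- exp(-0.5 * (-r:r)^2 / sigma^2)
  (w[r + 1] / sum(w))^3
}

# small deterministic section mask generator
random_section <- function(nu, nz, p, seed) {
  set.seed(seed)
  matrix(runif(nu * nz) < p, nu, nz)
}

make_section <- function(mask, axis = "x", index = 0L) {
  structure(list(axis = axis, index = as.integer(index), mask = mask),
            class = "section_mask")
}

# quick phantom for unit tests: two flat constant surfaces, small field
small_two_plane <- function(seed = 1, nz = 24) {
  render_phantom(phantom_spec(
    dim = c(48L, 48L, nz),
    surfaces = list(surface_spec("plane", z0 = 6, texture = "constant"),
                    surface_spec("plane", z0 = 16, texture = "constant")),
    background = 10, noise_sd = 5, rng_seed = seed))
}
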