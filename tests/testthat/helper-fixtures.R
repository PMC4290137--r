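# Fixtures and independent oracles, all built in code at test time.
# Voxel coordinates are 0-based throughout (matching seed/tree conventions);
# R array indices are coordinates + 1.

# binary ball on a grid (no intensity ramp)
ball_region <- function(shape, center, radius) {
  dx2 <- (seq_len(shape[1]) - 1 - center[1])^2
  dy2 <- (seq_len(shape[2]) - 1 - center[2])^2
  dz2 <- (seq_len(shape[3]) - 1 - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

make_ball_volume <- function(shape, center, radius, inside = 500, outside = 0) {
  image_volume(array(ifelse(ball_region(shape, center, radius),
                            inside, outside), shape))
}

# analytic distance from every voxel center to a sphere surface
sphere_distance <- function(shape, center, radius) {
  dx2 <- (seq_len(shape[1]) - 1 - center[1])^2
  dy2 <- (seq_len(shape[2]) - 1 - center[2])^2
  dz2 <- (seq_len(shape[3]) - 1 - center[3])^2
  r <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  radius - r   # positive inside
}

# a small straight-trunk + one-branch tree that fits inside `shape`
small_tree <- function(shape, dim_factor = 1, radius = 4) {
  ext <- shape - 1
  trunk <- list(
    points = cbind(0.5 * ext[1], 0.5 * ext[2],
                   seq(0.15, 0.6, length.out = 5) * ext[3]),
    radii = rep(radius, 5), dim_factor = 1)
  branch <- list(
    points = cbind(seq(0.5, 0.75, length.out = 5) * ext[1],
                   0.5 * ext[2],
                   seq(0.6, 0.85, length.out = 5) * ext[3]),
    radii = seq(radius * 0.75, radius * 0.6, length.out = 5),
    dim_factor = dim_factor)
  structure(list(trunk, branch), class = "centerline_tree")
}

# brute-force maximum intensity projection
naive_mip <- function(data, axis) {
  keep <- setdiff(1:3, axis)
  out <- matrix(-Inf, dim(data)[keep[1]], dim(data)[keep[2]])
  for (i in seq_len(dim(data)[1]))
    for (j in seq_len(dim(data)[2]))
      for (k in seq_len(dim(data)[3])) {
        idx <- c(i, j, k)
        out[idx[keep[1]], idx[keep[2]]] <-
          max(out[idx[keep[1]], idx[keep[2]]], data[i, j, k])
      }
  out
}

# independent loop implementation of div(g * grad(phi)), same stencil:
# central differences in the interior, one-sided at the faces
naive_diff <- function(f, along) {
  n <- dim(f)[along]
  idx <- function(shift) {
    i <- pmin(pmax(seq_len(n) + shift, 1), n)
    switch(along, f[i, , , drop = FALSE], f[, i, , drop = FALSE],
           f[, , i, drop = FALSE])
  }
  d <- (idx(1) - idx(-1)) / 2
  edge_lo <- (idx(1) - idx(0))
  edge_hi <- (idx(0) - idx(-1))
  sel <- function(a, i) switch(along, a[i, , , drop = FALSE],
                               a[, i, , drop = FALSE], a[, , i, drop = FALSE])
  assign_slice <- function(a, i, v) {
    switch(along,
           a[i, , ] <- v, a[, i, ] <- v, a[, , i] <- v)
    a
  }
  d <- assign_slice(d, 1, sel(edge_lo, 1))
  d <- assign_slice(d, n, sel(edge_hi, n))
  array(d, dim(f))
}

naive_ewdiv <- function(phi, g) {
  fx <- g * naive_diff(phi, 1)
  fy <- g * naive_diff(phi, 2)
  fz <- g * naive_diff(phi, 3)
  naive_diff(fx, 1) + naive_diff(fy, 2) + naive_diff(fz, 3)
}

# flood-fill 26-connectivity component count, queue-based
naive_components <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  count <- 0L
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  for (s in which(mask == 1 & !seen)) {
    if (seen[s]) next
    count <- count + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ijk <- arrayInd(v, d)
      nb <- sweep(off, 2, as.integer(ijk), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1) + d[1] * d[2] * (nb[, 3] - 1)
      lin <- lin[mask[lin] == 1 & !seen[lin]]
      seen[lin] <- TRUE
      queue <- c(queue, lin)
    }
  }
  count
}
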