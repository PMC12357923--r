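# Independent brute-force oracles, written against the set definitions
# (city-block / diamond morphology) rather than the package's code paths.

diamond_offsets <- function(k) {
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g[abs(g$dy) + abs(g$dx) <= k, , drop = FALSE]
}

# Dilation by k diamond steps: every pixel within city-block distance k of
# the set, realized by stamping the diamond around each set pixel.
oracle_dilate <- function(set, k, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  if (k == 0) {
    out[set] <- TRUE
    return(out)
  }
  idx <- which(set, arr.ind = TRUE)
  off <- diamond_offsets(k)
  for (j in seq_len(nrow(off))) {
    r <- idx[, 1] + off$dy[j]
    c <- idx[, 2] + off$dx[j]
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out[cbind(r[ok], c[ok])] <- TRUE
  }
  out
}

# Erosion by k diamond steps: set pixels whose entire city-block
# k-neighbourhood stays inside the set (outside the canvas counts as
# background).
oracle_erode <- function(set, k, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  idx <- which(set, arr.ind = TRUE)
  off <- diamond_offsets(k)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1] + off$dy
    c <- idx[i, 2] + off$dx
    inside <- all(r >= 1 & r <= nr & c >= 1 & c <= nc) &&
      all(set[cbind(r, c)])
    out[idx[i, 1], idx[i, 2]] <- inside
  }
  out
}

# Per-label nuclear core and perinuclear ring pixel sets and means by
# direct enumeration of the definitions.
oracle_measure <- function(label_map, target, mask, erosion_px = 1,
                           gap = 1, width = 3) {
  nr <- nrow(label_map); nc <- ncol(label_map)
  any_dil <- oracle_dilate(label_map > 0, gap, nr, nc)
  ids <- sort(unique(label_map[label_map > 0]))
  out <- lapply(ids, function(id) {
    own <- label_map == id
    core <- oracle_erode(own, erosion_px, nr, nc)
    ring <- oracle_dilate(own, gap + width, nr, nc) & !any_dil & mask
    list(
      label = id,
      core = core,
      ring = ring,
      nuclear_mean = if (any(core)) mean(target[core]) else NA_real_,
      ring_mean = if (any(ring)) mean(target[ring]) else NA_real_
    )
  })
  out
}

# Shape oracle: area by pixel count; crack perimeter by explicit
# neighbour-pair counting in loop form.
oracle_shape <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  edges <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cc <- c + d[2]
        outside <- rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]
        if (outside) edges <- edges + 1L
      }
    }
  }
  a <- sum(mask)
  p <- edges * pi / 4
  c(area = a, perimeter = p, circularity = 4 * pi * a / p^2)
}

# Student-t upper quantile by root-finding on the CDF, independent of qt().
oracle_t_quantile <- function(p, df) {
  uniroot(function(x) stats::pt(x, df) - p, c(0, 1e4), tol = 1e-12)$root
}

# Analytic integral of A1 e^{-k1 t} + A2 e^{-k2 t} over [0, T].
oracle_biexp_integral <- function(a1, k1, a2, k2, t_end) {
  term <- function(a, k) if (k == 0) a * t_end else a * (1 - exp(-k * t_end)) / k
  term(a1, k1) + term(a2, k2)
}

# Filled disk mask by direct pixel enumeration.
oracle_disk_mask <- function(nr, nc, cy, cx, r) {
  m <- matrix(FALSE, nr, nc)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      if ((x - cx)^2 + (y - cy)^2 <= r^2) m[y, x] <- TRUE
    }
  }
  m
}
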