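# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain loops and queue-based flood fill only.

# 4-connected component labelling of a logical matrix via BFS
oracle_label <- function(mask) {
  lbl <- matrix(0L, nrow(mask), ncol(mask))
  current <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] && lbl[i, j] == 0L) {
      current <- current + 1L
      queue <- list(c(i, j))
      lbl[i, j] <- current
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (step in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + step
          if (q[1] >= 1 && q[1] <= nrow(mask) &&
              q[2] >= 1 && q[2] <= ncol(mask) &&
              mask[q[1], q[2]] && lbl[q[1], q[2]] == 0L) {
            lbl[q[1], q[2]] <- current
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  lbl
}

# element-wise accumulation for sqrt-sum-of-squares along the first axis
oracle_sos_axis1 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = d[-1])
  n_rest <- prod(d[-1])
  xm <- matrix(x, nrow = d[1])
  for (j in seq_len(n_rest)) {
    acc <- 0
    for (i in seq_len(d[1])) acc <- acc + Mod(xm[i, j])^2
    out[j] <- sqrt(acc)
  }
  out
}

oracle_roi_stats <- function(volume, mask) {
  vals <- c()
  for (i in seq_along(volume)) if (mask[i]) vals <- c(vals, volume[i])
  n <- length(vals)
  m <- sum(vals) / n
  s <- sqrt(sum((vals - m)^2) / (n - 1))
  list(mean = m, sd = s, n = n)
}

# voxels whose centres fall inside a sphere (physical distance, <= radius)
oracle_sphere_voxels <- function(grid_dim, voxel_mm, centre, radius_mm) {
  hits <- matrix(0L, 0, 3)
  for (k in seq_len(grid_dim[3])) for (j in seq_len(grid_dim[2])) {
    for (i in seq_len(grid_dim[1])) {
      d2 <- ((i - centre[1]) * voxel_mm[1])^2 +
        ((j - centre[2]) * voxel_mm[2])^2 +
        ((k - centre[3]) * voxel_mm[3])^2
      if (d2 <= radius_mm^2) hits <- rbind(hits, c(i, j, k))
    }
  }
  hits
}

# scalar spoiled gradient-echo signal, written out long-hand
oracle_spgr <- function(r2, te, tr, t1, fa_deg, pd) {
  fa <- fa_deg / 180 * pi
  e1 <- exp(-tr / t1)
  pd * sin(fa) * (1 - e1) / (1 - cos(fa) * e1) * exp(-te * r2)
}

# exhaustive all-pairs nearest distance
oracle_nearest <- function(points, refs) {
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    best <- Inf
    for (j in seq_len(nrow(refs))) {
      d <- sqrt((points[i, 1] - refs[j, 1])^2 +
                (points[i, 2] - refs[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# blue-class pixel count, independent of segment_iron's vector code
oracle_blue_count <- function(img, margin = 0.12) {
  n <- 0L
  for (j in seq_len(dim(img)[2])) for (i in seq_len(dim(img)[1])) {
    if (img[i, j, 3] - max(img[i, j, 1], img[i, j, 2]) > margin) n <- n + 1L
  }
  n
}
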