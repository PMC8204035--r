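# Independent oracle implementations and small fixture builders used across
# the suite. These deliberately do not share code with the package internals.

# O(V^2) Dijkstra on the 8-connected pixel grid with the same edge-weight
# definition as the livewire: len * (cost_from + cost_to) / 2.
brute_dijkstra_cost <- function(cost, seed, target) {
  nr <- nrow(cost); nc <- ncol(cost)
  n <- nr * nc
  id <- function(r, c) (c - 1L) * nr + r
  dist <- rep(Inf, n)
  done <- rep(FALSE, n)
  dist[id(seed[1], seed[2])] <- 0
  repeat {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) stop("unreachable")
    if (u == id(target[1], target[2])) return(dist[u])
    done[u] <- TRUE
    r <- (u - 1L) %% nr + 1L
    c <- (u - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
      len <- if (dr != 0 && dc != 0) sqrt(2) else 1
      w <- dist[u] + len * (cost[r, c] + cost[rr, cc]) / 2
      v <- id(rr, cc)
      if (w < dist[v]) dist[v] <- w
    }
  }
}

# exact point-to-triangle distance by projection + edge/vertex cases,
# scanned over every triangle (independent of the package's C++ routine)
brute_point_mesh_dist <- function(pts, mesh) {
  V <- mesh$vertices; F <- mesh$faces
  pt_tri <- function(p, a, b, c) {
    # minimize |a + s(b-a) + t(c-a) - p| over the triangle via constrained QP
    e1 <- b - a; e2 <- c - a; w <- p - a
    A <- matrix(c(sum(e1 * e1), sum(e1 * e2), sum(e1 * e2), sum(e2 * e2)), 2)
    rhs <- c(sum(e1 * w), sum(e2 * w))
    st <- tryCatch(solve(A, rhs), error = function(e) c(0, 0))
    s <- st[1]; t <- st[2]
    cand <- list()
    if (s >= 0 && t >= 0 && s + t <= 1) cand <- c(cand, list(a + s * e1 + t * e2))
    seg <- function(p0, p1) {
      d <- p1 - p0
      u <- sum((p - p0) * d) / sum(d * d)
      u <- min(max(u, 0), 1)
      p0 + u * d
    }
    cand <- c(cand, list(seg(a, b), seg(b, c), seg(a, c)))
    min(vapply(cand, function(q) sqrt(sum((p - q)^2)), 0))
  }
  apply(pts, 1, function(p) {
    min(vapply(seq_len(nrow(F)), function(i)
      pt_tri(p, V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ]), 0))
  })
}

# ICC(2,1) from scratch: explicit double loops over the two-way layout
brute_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + x[i, j]
  grand <- grand / (n * k)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(x[i, ]) - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(x[, j]) - grand)^2
  sse <- 0
  for (i in 1:n) for (j in 1:k)
    sse <- sse + (x[i, j] - mean(x[i, ]) - mean(x[, j]) + grand)^2
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  unname((msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
}

# exact two-sided Wilcoxon signed-rank p by explicit enumeration of all 2^n
# sign assignments, average ranks for ties
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- signs %*% r
  p_le <- mean(Wall <= W)
  p_ge <- mean(Wall >= W)
  min(1, 2 * min(p_le, p_ge))
}

# quick phantom at coarser voxels for unit tests (same scene in mm)
fast_spec <- function(...) {
  phantom_spec(voxel_mm = 0.4, grid_dims = c(60L, 60L, 90L), ...)
}

# small random volume with smooth content
smooth_volume <- function(dims = c(16, 18, 14), spacing = c(0.5, 0.5, 0.5),
                          seed = 1) {
  g1 <- seq_len(dims[1]); g2 <- seq_len(dims[2]); g3 <- seq_len(dims[3])
  a <- outer(outer(sin(g1 / 3), cos(g2 / 4)), sin(g3 / 2 + 1))
  image_volume(a * 50 + 60, spacing = spacing, origin = c(-2, 1, 0))
}

# analytic sphere mesh via gray-value isosurface of the radial field
sphere_mesh <- function(r = 5, h = 0.25, center = c(0, 0, 0)) {
  n <- ceiling(2 * (r + 3 * h) / h)
  org <- center - (n - 1) * h / 2
  vol <- image_volume(array(0, c(n, n, n)), spacing = rep(h, 3), origin = org)
  pts <- voxel_centers(vol)
  vol$data[] <- r - sqrt(rowSums(sweep(pts, 2, center)^2))
  iso_surface(vol, 0)
}

expect_rigid_close <- function(a, b, tol_t = 1e-6, tol_r_deg = 1e-5) {
  expect_lt(max(abs(a[1:3, 4] - b[1:3, 4])), tol_t)
  expect_lt(rotation_angle_deg(a[1:3, 1:3] %*% t(b[1:3, 1:3])), tol_r_deg)
}
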