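# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, power iteration, sorting.

# principal eigenvector / eigenvalue of a positive matrix by power iteration
power_iteration <- function(m, iters = 500, tol = 1e-14) {
  v <- rep(1, nrow(m))
  lambda <- 0
  for (i in seq_len(iters)) {
    nv <- as.vector(m %*% v)
    new_lambda <- max(nv)
    nv <- nv / sum(nv)
    if (max(abs(nv - v)) < tol && abs(new_lambda - lambda) < tol) break
    v <- nv
    lambda <- new_lambda
  }
  list(vector = v / sum(v), value = mean(as.vector(m %*% v) / v))
}

# per-cell weighted sum with explicit loops
pacp_oracle <- function(score_layers, weights) {
  ref <- score_layers[[1]]$values
  out <- matrix(NA_real_, nrow(ref), ncol(ref))
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) {
      acc <- 0
      ok <- TRUE
      for (nm in names(score_layers)) {
        v <- score_layers[[nm]]$values[i, j]
        if (is.na(v)) { ok <- FALSE; break }
        acc <- acc + weights[[nm]] * v
      }
      if (ok) out[i, j] <- acc
    }
  }
  out
}

# per-cell distance to a vertex set / segment list by explicit minimisation
distance_oracle <- function(grid, features) {
  cc <- cell_centers(grid)
  out <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  seg_dist <- function(px, py, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    if (dx == 0 && dy == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
    t <- ((px - x1) * dx + (py - y1) * dy) / (dx^2 + dy^2)
    t <- min(1, max(0, t))
    sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
  }
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(ncol(out))) {
      best <- Inf
      for (fid in unique(features$feature_id)) {
        pts <- features[features$feature_id == fid, ]
        if (nrow(pts) == 1) {
          best <- min(best, sqrt((cc$x[j] - pts$x)^2 + (cc$y[i] - pts$y)^2))
        } else {
          for (k in seq_len(nrow(pts) - 1)) {
            best <- min(best, seg_dist(cc$x[j], cc$y[i], pts$x[k], pts$y[k],
                                       pts$x[k + 1], pts$y[k + 1]))
          }
        }
      }
      out[i, j] <- best
    }
  }
  out
}

# small helper: uniform random score layer with optional NA holes
random_score_layer <- function(nr, nc, pixel = 10, na_frac = 0) {
  v <- matrix(sample(1:3, nr * nc, replace = TRUE), nr, nc)
  if (na_frac > 0) {
    holes <- sample(nr * nc, round(na_frac * nr * nc))
    v[holes] <- NA
  }
  grid_layer(v, pixel_size = pixel)
}

# the five published judgment matrices, by name
worked_matrices <- function() {
  h <- coffee_hierarchy()
  c(list(main = h$main), h$subs)
}
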