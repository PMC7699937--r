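# Independent oracles used across the suite.

# Brute-force empty-circumcircle check: TRUE when every triangle's
# circumcircle contains no other point strictly inside (relative slack for
# floating point).
check_delaunay_property <- function(points, triangles, rtol = 1e-7) {
  pts <- as.matrix(points)
  for (t in seq_len(nrow(triangles))) {
    tri <- triangles[t, ]
    p1 <- pts[tri[1L], ]; p2 <- pts[tri[2L], ]; p3 <- pts[tri[3L], ]
    ax <- p1[1L]; ay <- p1[2L]
    bx <- p2[1L]; by <- p2[2L]
    cx <- p3[1L]; cy <- p3[2L]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(FALSE)        # degenerate triangle
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(seq_len(nrow(pts)), tri)
    if (length(others)) {
      d2 <- (pts[others, 1L] - ux)^2 + (pts[others, 2L] - uy)^2
      if (any(d2 < r2 * (1 - rtol))) return(FALSE)
    }
  }
  TRUE
}

# Literal reimplementation of the median-absolute-deviation area criterion.
brute_force_mad_flags <- function(r, b = 1.4826, cutoff = 3) {
  med <- median(r)
  mad <- b * median(abs(r - med))
  if (mad == 0) return(rep(TRUE, length(r)))
  sapply(r, function(ri) abs(ri - med) / mad < cutoff)
}

# Maximum-cardinality one-to-one matching under a radius, by exhaustive
# recursion (feasible for <= 8 points per side).
brute_force_max_matching <- function(truth, pred, radius) {
  nt <- nrow(truth); np <- nrow(pred)
  if (nt == 0L || np == 0L) return(0L)
  ok <- outer(seq_len(nt), seq_len(np), Vectorize(function(i, j) {
    sqrt(sum((unlist(truth[i, 1:2]) - unlist(pred[j, 1:2]))^2)) < radius
  }))
  rec <- function(i, used) {
    if (i > nt) return(0L)
    best <- rec(i + 1L, used)            # leave truth i unmatched
    for (j in seq_len(np)) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, np))
}

# Straight-loop explicit Perona-Malik scheme (reference implementation).
reference_perona_malik <- function(img, iterations, kappa, step,
                                   conductance = "exponential") {
  g <- if (conductance == "exponential") {
    function(d) exp(-(d / kappa)^2)
  } else {
    function(d) 1 / (1 + (d / kappa)^2)
  }
  n <- nrow(img); m <- ncol(img)
  for (it in seq_len(iterations)) {
    out <- img
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        dN <- img[max(i - 1L, 1L), j] - img[i, j]
        dS <- img[min(i + 1L, n), j] - img[i, j]
        dW <- img[i, max(j - 1L, 1L)] - img[i, j]
        dE <- img[i, min(j + 1L, m)] - img[i, j]
        out[i, j] <- img[i, j] + step * (g(abs(dN)) * dN + g(abs(dS)) * dS +
                                           g(abs(dW)) * dW + g(abs(dE)) * dE)
      }
    }
    img <- out
  }
  pmin(pmax(img, 0), 1)
}

# Rayleigh sampler via inverse CDF (independent of any package code).
rayleigh_draws <- function(n, sigma) {
  sqrt(-2 * sigma^2 * log(runif(n)))
}
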