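#' Delaunay tessellation of centroid points
#'
#' Triangulates a planar point set so that no point lies strictly inside any
#' triangle's circumcircle (points in cocircular position admit either
#' diagonal). Duplicate points are collapsed before triangulating.
#'
#' @param points Two-column matrix or data.frame of `(x, y)` coordinates,
#'   at least 3 non-collinear points.
#' @return A `Tessellation`: list with `points` (matrix), `triangles`
#'   (`n x 3` integer matrix of vertex indices into `points`) and `n`
#'   (triangle count).
#' @export
delaunay <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) < 2L) {
    stop("points must be a two-column numeric matrix")
  }
  pts <- pts[, 1:2, drop = FALSE]
  colnames(pts) <- c("x", "y")
  pts <- unique(pts)
  if (nrow(pts) < 3L) {
    stop_degenerate("need at least 3 distinct points to tessellate")
  }
  if (is_collinear(pts)) {
    stop_degenerate("points are collinear; no triangulation exists")
  }
  dd <- suppressMessages(deldir::deldir(pts[, 1L], pts[, 2L],
                                        suppressMsge = TRUE))
  tri <- tryCatch(deldir::triMat(dd), error = function(e) NULL)
  if (is.null(tri) || length(tri) == 0L) {
    stop_degenerate("degenerate geometry: no triangles produced")
  }
  if (!is.matrix(tri)) tri <- matrix(tri, ncol = 3L)
  structure(list(points = pts, triangles = tri, n = nrow(tri)),
            class = "Tessellation")
}

is_collinear <- function(pts, tol = 1e-9) {
  p0 <- pts[1L, ]
  v <- sweep(pts[-1L, , drop = FALSE], 2L, p0)
  cross <- v[1L, 1L] * v[, 2L] - v[1L, 2L] * v[, 1L]
  scale <- max(abs(v)) ^ 2
  all(abs(cross) <= tol * max(scale, 1))
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("drtb_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

#' @export
print.Tessellation <- function(x, ...) {
  cat("Delaunay tessellation:", nrow(x$points), "points,",
      x$n, "triangles\n")
  invisible(x)
}

#' Edge-length vector of a tessellation
#'
#' Collects the three Euclidean side lengths of every triangle, in the order
#' (v1,v2), (v2,v3), (v1,v3), giving a vector of exactly `3n` entries.
#' Edges shared by two triangles are counted once per triangle; set
#' `unique_edges = TRUE` to keep each undirected edge once (sensitivity
#' analysis only).
#'
#' @param tess A `Tessellation` from [delaunay()].
#' @param unique_edges Drop duplicated shared edges (default `FALSE`).
#' @return Numeric vector of positive distances (length `3n` when
#'   `unique_edges = FALSE`).
#' @export
edge_distances <- function(tess, unique_edges = FALSE) {
  if (!inherits(tess, "Tessellation")) stop("tess must be a Tessellation")
  if (is.null(tess$triangles) || nrow(tess$triangles) == 0L) {
    stop("tessellation has no triangles")
  }
  tri <- tess$triangles
  p <- tess$points
  i1 <- tri[, 1L]; i2 <- tri[, 2L]; i3 <- tri[, 3L]
  from <- c(i1, i2, i1)
  to   <- c(i2, i3, i3)
  if (unique_edges) {
    key <- paste(pmin(from, to), pmax(from, to))
    keep <- !duplicated(key)
    from <- from[keep]; to <- to[keep]
  } else {
    ## interleave back to per-triangle order [d12, d23, d13] x n
    ord <- as.vector(t(matrix(seq_along(from), ncol = 3L)))
    from <- from[ord]; to <- to[ord]
  }
  sqrt((p[from, 1L] - p[to, 1L])^2 + (p[from, 2L] - p[to, 2L])^2)
}
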