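#' Binarize a grey image at level l
#'
#' Pixels strictly greater than `level` become foreground (1), the rest
#' background (0).
#'
#' @param F Numeric matrix in `[0, 1]`.
#' @param level Threshold in the open interval (0, 1).
#' @return Integer 0/1 matrix with attribute `"level"`.
#' @export
binarize <- function(F, level) {
  assert_gray(F, "F")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must lie strictly inside (0, 1)")
  }
  mask <- matrix(as.integer(F > level), nrow = nrow(F))
  attr(mask, "level") <- level
  mask
}

#' Label connected foreground regions
#'
#' Maximal connected components of 1-pixels are labeled `1..nR`
#' (4- or 8-connectivity). Areas are pixel counts; centroids are first-order
#' moment mass centers `(M10/M00, M01/M00)` with sub-pixel precision, in
#' 0-based `(x = column, y = row)` coordinates, origin top-left.
#'
#' @param mask Integer/logical 0-1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return A `RegionSet`: list with `labels` (integer matrix), `n_regions`,
#'   `areas`, `centroids` (data.frame `x`, `y`), `on_border` (logical per
#'   region).
#' @export
label_regions <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0 or 1")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(mask)))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  if (connectivity == 8L && max(lab) > 1L) {
    lab <- merge_diagonal_labels(lab)
  }
  region_set(lab)
}

## bwlabel is 4-connected; union labels that touch diagonally to get
## 8-connectivity, then relabel consecutively.
merge_diagonal_labels <- function(lab) {
  n <- nrow(lab)
  m <- ncol(lab)
  a1 <- lab[-n, -m]; b1 <- lab[-1, -1]   # down-right neighbours
  a2 <- lab[-n, -1]; b2 <- lab[-1, -m]   # down-left neighbours
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(max(lab))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  remap <- c(0L, match(root, sort(unique(root))))
  matrix(remap[lab + 1L], nrow = n)
}

region_set <- function(labels) {
  nR <- max(labels)
  if (nR == 0L) {
    return(structure(list(labels = labels, n_regions = 0L,
                          areas = integer(0),
                          centroids = data.frame(x = numeric(0),
                                                 y = numeric(0)),
                          on_border = logical(0)),
                     class = "RegionSet"))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  n <- nrow(labels)
  row0 <- (idx - 1L) %% n          # 0-based row -> y
  col0 <- (idx - 1L) %/% n         # 0-based col -> x
  areas <- tabulate(lab, nbins = nR)
  cx <- as.vector(rowsum(as.numeric(col0), lab)) / areas
  cy <- as.vector(rowsum(as.numeric(row0), lab)) / areas
  border <- row0 == 0L | row0 == n - 1L | col0 == 0L | col0 == ncol(labels) - 1L
  on_border <- as.vector(rowsum(as.numeric(border), lab)) > 0
  structure(list(labels = labels, n_regions = nR, areas = areas,
                 centroids = data.frame(x = cx, y = cy),
                 on_border = on_border),
            class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  cat("RegionSet:", x$n_regions, "regions,",
      sum(x$areas), "foreground pixels\n")
  invisible(x)
}

#' Robust region-area outlier filter (median absolute deviation)
#'
#' Computes `MAD = b * median(|r - median(r)|)` and keeps region `i` when
#' `|r_i - median(r)| / MAD < cutoff`. When `MAD = 0` (all areas tied, or a
#' single region) there is no spread evidence for outliers and every region
#' is kept.
#'
#' @param areas Non-empty numeric vector of region areas in pixels.
#' @param b Normality constant (default 1.4826).
#' @param cutoff Outlier score threshold (default 3).
#' @return Logical vector, `TRUE` for inliers.
#' @export
mad_filter <- function(areas, b = 1.4826, cutoff = 3) {
  if (length(areas) == 0L) stop("areas must be non-empty")
  if (b <= 0 || cutoff <= 0) stop("b and cutoff must be positive")
  med <- stats::median(areas)
  mad <- b * stats::median(abs(areas - med))
  if (mad == 0) return(rep(TRUE, length(areas)))
  abs(areas - med) / mad < cutoff
}

#' Inlier centroids of a labeled region set
#'
#' Applies the minimum-area floor, optional border rejection and the MAD
#' area filter, and returns the surviving mass centers.
#'
#' @param regions A `RegionSet` from [label_regions()].
#' @param min_area Discard regions smaller than this many pixels before MAD
#'   filtering (speckle guard).
#' @param mad_b,mad_cutoff Passed to [mad_filter()].
#' @param drop_border Discard regions touching the image frame.
#' @return data.frame with `region_id`, `x`, `y`, `area` for inlier regions.
#' @export
inlier_centroids <- function(regions, min_area = 4L, mad_b = 1.4826,
                             mad_cutoff = 3, drop_border = FALSE) {
  if (!inherits(regions, "RegionSet")) stop("regions must be a RegionSet")
  keep <- regions$areas >= min_area
  if (drop_border) keep <- keep & !regions$on_border
  ids <- which(keep)
  if (length(ids) == 0L) {
    return(data.frame(region_id = integer(0), x = numeric(0),
                      y = numeric(0), area = numeric(0)))
  }
  inl <- mad_filter(regions$areas[ids], b = mad_b, cutoff = mad_cutoff)
  ids <- ids[inl]
  data.frame(region_id = ids,
             x = regions$centroids$x[ids],
             y = regions$centroids$y[ids],
             area = regions$areas[ids])
}
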