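#' Threshold scan: Rayleigh RMSD at every binarization level
#'
#' For each level `l` on the grid, the preprocessed image is binarized,
#' foreground regions are labeled and filtered (minimum-area floor, optional
#' border rejection, MAD area-outlier filter), the surviving centroids are
#' Delaunay-tessellated, and the edge-length histogram is fitted against a
#' Rayleigh distribution over the sigma grid. Levels yielding fewer than 3
#' usable centroids, collinear centroids, or more than `max_points`
#' centroids are marked invalid (`rmsd = Inf`) — never an exception.
#'
#' @param F Preprocessed grey matrix in `[0, 1]` (see
#'   [preprocess_pipeline()]).
#' @param config Configuration list ([drtb_config()]); the `drtb` block
#'   drives the scan.
#' @param progress Print per-level progress lines.
#' @return data.frame with one row per level: `level`, `sigma` (Rayleigh
#'   scale in histogram-bin units; multiply by `bin_width` for pixels),
#'   `rmsd`, `bin_width` (pixels per bin at that level), `n_regions`
#'   (usable centroids), `n_triangles`, `valid`.
#' @export
scan_levels <- function(F, config = drtb_config(), progress = FALSE) {
  assert_gray(F, "F")
  dcfg <- config$drtb
  img <- if (isTRUE(dcfg$invert)) 1 - F else F
  grid <- dcfg$level_grid
  out <- data.frame(level = grid, sigma = NA_real_, rmsd = Inf,
                    bin_width = NA_real_, n_regions = 0L,
                    n_triangles = 0L, valid = FALSE)
  best <- Inf
  for (k in seq_along(grid)) {
    l <- grid[k]
    res <- scan_one_level(img, l, dcfg)
    out$sigma[k] <- res$sigma
    out$rmsd[k] <- res$rmsd
    out$bin_width[k] <- res$bin_width
    out$n_regions[k] <- res$n_regions
    out$n_triangles[k] <- res$n_triangles
    out$valid[k] <- res$valid
    if (res$valid && res$rmsd < best) best <- res$rmsd
    if (progress) {
      message(sprintf("level %.2f: %d regions, best RMSD so far %.5g",
                      l, res$n_regions, best))
    }
  }
  if (!any(out$valid)) {
    stop(structure(class = c("drtb_no_tessellation", "error", "condition"),
                   list(message = paste(
                     "no valid tessellation at any binarization level;",
                     "every level produced < 3 usable (non-collinear)",
                     "centroids"), call = sys.call())))
  }
  out
}

scan_one_level <- function(img, l, dcfg) {
  invalid <- list(sigma = NA_real_, rmsd = Inf, bin_width = NA_real_,
                  n_regions = 0L, n_triangles = 0L, valid = FALSE)
  mask <- binarize(img, l)
  regions <- label_regions(mask, connectivity = dcfg$connectivity)
  cent <- inlier_centroids(regions, min_area = dcfg$min_area,
                           mad_b = dcfg$mad_b, mad_cutoff = dcfg$mad_cutoff,
                           drop_border = dcfg$drop_border)
  invalid$n_regions <- nrow(cent)
  if (nrow(cent) < 3L || nrow(cent) > dcfg$max_points) return(invalid)
  tess <- tryCatch(delaunay(cent[, c("x", "y")]),
                   drtb_degenerate = function(e) NULL)
  if (is.null(tess)) return(invalid)
  d <- edge_distances(tess, unique_edges = isTRUE(dcfg$unique_edges))
  ## default: express distances in units of a fixed number of equal bins
  ## over the observed range, so sigma and RMSD are magnification-free;
  ## a user-set bin_width switches to fixed-width pixel bins
  if (is.null(dcfg$bin_width)) {
    bw <- max(d) / dcfg$n_bins
    hist <- distance_histogram(d / bw, bin_width = 1)
  } else {
    bw <- dcfg$bin_width
    hist <- distance_histogram(d, bin_width = bw)
  }
  fit <- fit_sigma(hist, sigma_grid = dcfg$sigma_grid)
  list(sigma = fit$sigma, rmsd = fit$rmsd, bin_width = bw,
       n_regions = nrow(cent), n_triangles = tess$n, valid = TRUE)
}

#' Select the optimal binarization level from a scan
#'
#' Returns the valid scan row with minimum RMSD; ties break toward the
#' smaller level.
#'
#' @param scan data.frame from [scan_levels()].
#' @return Single-row data.frame (`level`, `sigma`, `rmsd`, `n_regions`,
#'   `n_triangles`, `valid`).
#' @export
optimal_level <- function(scan) {
  if (!is.data.frame(scan) || !all(c("level", "rmsd", "valid") %in%
                                   names(scan))) {
    stop("scan must be a data.frame produced by scan_levels()")
  }
  ok <- scan[scan$valid & is.finite(scan$rmsd), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no valid levels in scan")
  ok <- ok[order(ok$rmsd, ok$level), , drop = FALSE]
  ok[1L, , drop = FALSE]
}

#' Segment an image at its optimal Rayleigh-consistent threshold
#'
#' Runs the full threshold scan, selects the RMSD-minimizing level and
#' re-binarizes at that level to produce the final segmentation.
#'
#' @inheritParams scan_levels
#' @return List with `scan` (per-level data.frame), `best` (optimal row),
#'   `mask` (final 0/1 matrix), `regions` (final `RegionSet`), `centroids`
#'   (data.frame `region_id`, `x`, `y`, `area` of detected stomata).
#' @export
drtb_segment <- function(F, config = drtb_config(), progress = FALSE) {
  scan <- scan_levels(F, config = config, progress = progress)
  best <- optimal_level(scan)
  dcfg <- config$drtb
  img <- if (isTRUE(dcfg$invert)) 1 - F else F
  mask <- binarize(img, best$level)
  regions <- label_regions(mask, connectivity = dcfg$connectivity)
  cent <- inlier_centroids(regions, min_area = dcfg$min_area,
                           mad_b = dcfg$mad_b, mad_cutoff = dcfg$mad_cutoff,
                           drop_border = dcfg$drop_border)
  list(scan = scan, best = best, mask = mask, regions = regions,
       centroids = cent)
}
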