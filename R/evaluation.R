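#' Match predicted centroids to annotated stoma centers
#'
#' One-to-one greedy matching by ascending Euclidean distance: candidate
#' pairs closer than `radius` are sorted by distance and accepted when both
#' endpoints are still free. Unmatched annotations count as false negatives,
#' unmatched predictions as false positives.
#'
#' @param truth Two-column matrix/data.frame of annotated `(x, y)` centers
#'   (may be empty).
#' @param predictions Two-column matrix/data.frame of predicted centers.
#' @param radius Positive matching threshold in pixels; a pair is a true
#'   positive when its distance is strictly below `radius`.
#' @return A `MatchResult`: list with integers `TP`, `FP`, `FN` and `pairs`,
#'   a data.frame (`truth`, `prediction`, `distance`) of accepted matches.
#' @export
match_detections <- function(truth, predictions, radius = 30) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("radius must be a positive scalar")
  }
  tr <- as_points(truth, "truth")
  pr <- as_points(predictions, "predictions")
  nt <- nrow(tr)
  np <- nrow(pr)
  pairs <- data.frame(truth = integer(0), prediction = integer(0),
                      distance = numeric(0))
  if (nt > 0L && np > 0L) {
    dx <- outer(tr[, 1L], pr[, 1L], "-")
    dy <- outer(tr[, 2L], pr[, 2L], "-")
    dist <- sqrt(dx^2 + dy^2)
    cand <- which(dist < radius, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      cand <- cand[order(dist[cand]), , drop = FALSE]
      t_free <- rep(TRUE, nt)
      p_free <- rep(TRUE, np)
      keep_t <- integer(0); keep_p <- integer(0); keep_d <- numeric(0)
      for (r in seq_len(nrow(cand))) {
        ti <- cand[r, 1L]; pj <- cand[r, 2L]
        if (t_free[ti] && p_free[pj]) {
          t_free[ti] <- FALSE
          p_free[pj] <- FALSE
          keep_t <- c(keep_t, ti)
          keep_p <- c(keep_p, pj)
          keep_d <- c(keep_d, dist[ti, pj])
        }
      }
      pairs <- data.frame(truth = keep_t, prediction = keep_p,
                          distance = keep_d)
    }
  }
  structure(list(TP = nrow(pairs), FP = np - nrow(pairs),
                 FN = nt - nrow(pairs), pairs = pairs),
            class = "MatchResult")
}

as_points <- function(x, arg) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) ||
      (is.matrix(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(matrix(numeric(0), ncol = 2L))
  }
  m <- as.matrix(as.data.frame(x))
  if (!is.numeric(m) || ncol(m) < 2L) {
    stop(arg, " must be a two-column numeric (x, y) table")
  }
  m[, 1:2, drop = FALSE]
}

#' @export
print.MatchResult <- function(x, ...) {
  cat(sprintf("MatchResult: TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

#' Precision and recall of a match result
#'
#' `PPV = TP / (TP + FP)` and `TPR = TP / (TP + FN)`. A metric whose
#' denominator is zero is undefined and reported as `NA` (distinct from 0),
#' so that empty-prediction images do not silently deflate averages.
#'
#' @param m A `MatchResult` from [match_detections()].
#' @return List with `ppv` and `tpr` (each in `[0, 1]` or `NA`).
#' @export
precision_recall <- function(m) {
  if (!inherits(m, "MatchResult")) stop("m must be a MatchResult")
  ppv <- if (m$TP + m$FP > 0L) m$TP / (m$TP + m$FP) else NA_real_
  tpr <- if (m$TP + m$FN > 0L) m$TP / (m$TP + m$FN) else NA_real_
  list(ppv = ppv, tpr = tpr)
}

#' Evaluate one image's detections against its annotation
#'
#' @inheritParams match_detections
#' @return List with `TP`, `FP`, `FN`, `ppv`, `tpr`.
#' @export
evaluate_detections <- function(truth, predictions, radius = 30) {
  m <- match_detections(truth, predictions, radius = radius)
  pr <- precision_recall(m)
  list(TP = m$TP, FP = m$FP, FN = m$FN, ppv = pr$ppv, tpr = pr$tpr)
}

#' Aggregate per-image detection metrics
#'
#' Reports both the mean +/- SD of the per-image metrics (undefined values
#' excluded) and the pooled metrics recomputed from summed TP/FP/FN; the two
#' differ whenever images carry unequal numbers of stomata.
#'
#' @param results List of per-image results from [evaluate_detections()].
#' @return List with `per_image` (data.frame), `mean_ppv`, `sd_ppv`,
#'   `mean_tpr`, `sd_tpr`, `pooled_ppv`, `pooled_tpr`.
#' @export
aggregate_metrics <- function(results) {
  if (length(results) == 0L) stop("no per-image results to aggregate")
  per <- do.call(rbind, lapply(results, function(r) {
    data.frame(TP = r$TP, FP = r$FP, FN = r$FN, ppv = r$ppv, tpr = r$tpr)
  }))
  tp <- sum(per$TP); fp <- sum(per$FP); fn <- sum(per$FN)
  list(per_image = per,
       mean_ppv = mean(per$ppv, na.rm = TRUE),
       sd_ppv = stats::sd(per$ppv, na.rm = TRUE),
       mean_tpr = mean(per$tpr, na.rm = TRUE),
       sd_tpr = stats::sd(per$tpr, na.rm = TRUE),
       pooled_ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
       pooled_tpr = if (tp + fn > 0L) tp / (tp + fn) else NA_real_)
}
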