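test_that("matching handles identity, misses and the nearest-pair case", {
  pts <- data.frame(x = c(3, 50, 90), y = c(4, 60, 10))
  m <- match_detections(pts, pts, radius = 5)
  expect_equal(m$TP, 3L); expect_equal(m$FP, 0L); expect_equal(m$FN, 0L)

  m2 <- match_detections(data.frame(x = 0, y = 0),
                         data.frame(x = 100, y = 100), radius = 30)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 1L))

  m3 <- match_detections(data.frame(x = c(0, 10), y = c(0, 0)),
                         data.frame(x = 1, y = 0), radius = 5)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(1L, 0L, 1L))
  expect_equal(m3$pairs$truth, 1L)      # matched the closer annotation
  expect_equal(m3$pairs$distance, 1)
})

test_that("matching counts are symmetric and rigid-motion invariant", {
  set.seed(151)
  for (i in 1:20) {
    nt <- sample(0:8, 1); np <- sample(0:8, 1)
    truth <- data.frame(x = runif(nt, 0, 50), y = runif(nt, 0, 50))
    pred <- data.frame(x = runif(np, 0, 50), y = runif(np, 0, 50))
    a <- match_detections(truth, pred, radius = 12)
    b <- match_detections(pred, truth, radius = 12)
    expect_equal(a$TP, b$TP)
    expect_equal(a$FP, b$FN)
    expect_equal(a$FN, b$FP)
    shift <- match_detections(truth + 17.3, pred + 17.3, radius = 12)
    expect_equal(shift$TP, a$TP)
    perm <- match_detections(truth[sample(seq_len(max(nt, 1))[seq_len(nt)]), ,
                                   drop = FALSE],
                             pred, radius = 12)
    expect_equal(perm$TP, a$TP)
  }
})

test_that("greedy matching attains the optimal TP count for spaced annotations", {
  # with annotations separated by more than twice the radius (the regime
  # hard-core stomatal patterns guarantee), each prediction can reach at
  # most one annotation and greedy matching is exactly optimal
  set.seed(161)
  for (i in 1:40) {
    nt <- sample(1:8, 1); np <- sample(1:8, 1)
    r <- runif(1, 5, 12)
    repeat {
      truth <- data.frame(x = runif(nt, 0, 120), y = runif(nt, 0, 120))
      dm <- as.matrix(stats::dist(truth)); diag(dm) <- Inf
      if (nt == 1L || min(dm) > 2 * r) break
    }
    pred <- data.frame(x = runif(np, 0, 120), y = runif(np, 0, 120))
    g <- match_detections(truth, pred, radius = r)
    expect_equal(g$TP, brute_force_max_matching(truth, pred, r))
  }
})

test_that("precision and recall follow the TP/FP/FN definitions", {
  m <- match_detections(data.frame(x = 1, y = 1), data.frame(x = 1, y = 1),
                        radius = 1)
  # hand-built counts: recompute the published recall from its raw counts
  fake <- structure(list(TP = 2752L, FP = 0L, FN = 335L,
                         pairs = data.frame()), class = "MatchResult")
  pr <- precision_recall(fake)
  expect_equal(pr$tpr, 2752 / 3087, tolerance = 1e-12)
  expect_equal(round(100 * pr$tpr, 1), 89.1)

  none <- structure(list(TP = 0L, FP = 0L, FN = 3L, pairs = data.frame()),
                    class = "MatchResult")
  pn <- precision_recall(none)
  expect_true(is.na(pn$ppv))
  expect_equal(pn$tpr, 0)

  even <- structure(list(TP = 1L, FP = 1L, FN = 1L, pairs = data.frame()),
                    class = "MatchResult")
  pe <- precision_recall(even)
  expect_equal(pe$ppv, 0.5)
  expect_equal(pe$tpr, 0.5)
  expect_equal(precision_recall(m)$ppv, 1)
})

test_that("aggregation reports both mean/SD and pooled metrics", {
  res <- list(list(TP = 8L, FP = 2L, FN = 0L, ppv = 0.8, tpr = 1),
              list(TP = 1L, FP = 0L, FN = 1L, ppv = 1, tpr = 0.5),
              list(TP = 0L, FP = 0L, FN = 2L, ppv = NA_real_, tpr = 0))
  agg <- aggregate_metrics(res)
  expect_equal(agg$mean_ppv, 0.9)
  expect_equal(agg$mean_tpr, 0.5)
  expect_equal(agg$pooled_ppv, 9 / 11)
  expect_equal(agg$pooled_tpr, 9 / 12)
})
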