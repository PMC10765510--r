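test_that("degenerate K-means cases match closed forms", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)
  m1 <- kmeansStates(x, k = 1, restarts = 3, seed = 1)
  expect_equal(as.vector(stateCentroids(m1)[, , 1][upper.tri(diag(3))]),
               colMeans(x), tolerance = 1e-10)
  expect_equal(modelInertia(m1), sum(sweep(x, 2, colMeans(x))^2),
               tolerance = 1e-10)

  xu <- matrix(c(0, 0, 1, 1, 5, 5), 3, 2, byrow = TRUE)
  mk <- kmeansStates(xu, k = 3, restarts = 5, seed = 1)
  expect_equal(modelInertia(mk), 0)
  expect_error(kmeansStates(rbind(xu, xu), k = 4, restarts = 2, seed = 1),
               "degenerate clustering")
})

test_that("well-separated planted groups are recovered exactly", {
  set.seed(7)
  g1 <- matrix(rnorm(50 * 3, mean = 0, sd = 0.1), 50, 3)
  g2 <- matrix(rnorm(50 * 3, mean = 5, sd = 0.1), 50, 3)
  truth <- rep(c(2L, 1L), each = 50)  # group 2 has larger mean = state 1
  m <- kmeansStates(rbind(g1, g2), k = 2, restarts = 5, seed = 3)
  expect_equal(mclust::adjustedRandIndex(stateLabels(m), truth), 1)
  expect_equal(stateLabels(m), truth)  # canonical order: strongest first
})

test_that("Lloyd inertia is monotone and restarts only help", {
  set.seed(5)
  x <- matrix(rnorm(300 * 4), 300, 4)
  m <- kmeansStates(x, k = 4, restarts = 1, seed = 2)
  expect_true(all(diff(m@inertiaPath) <= 1e-8))
  many <- kmeansStates(x, k = 4, restarts = 10, seed = 2)
  for (s in 1:5) {
    one <- kmeansStates(x, k = 4, restarts = 1, seed = s)
    expect_lte(modelInertia(many), modelInertia(one) + 1e-8)
  }
})

test_that("inertia agrees with stats::kmeans Lloyd on a shared problem", {
  set.seed(8)
  x <- rbind(matrix(rnorm(100 * 2), 100, 2),
             matrix(rnorm(100 * 2, 4), 100, 2))
  ours <- kmeansStates(x, k = 2, restarts = 10, seed = 1)
  set.seed(1)
  ref <- stats::kmeans(x, 2, nstart = 10, algorithm = "Lloyd",
                       iter.max = 300)
  expect_equal(modelInertia(ours), ref$tot.withinss, tolerance = 1e-6)
})

test_that("quality criteria reproduce the hand-evaluated 1-D example", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  labels <- c(1L, 1L, 2L, 2L)
  q <- qualityCriteria(x, labels)
  # per-sample: point 1 has a = 0.1, b = (10 + 10.1)/2 = 10.05; the report
  # averages the four hand-computed coefficients
  handS <- mean(c((10.05 - 0.1) / 10.05, (9.95 - 0.1) / 9.95,
                  (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(q$silhouette, handS, tolerance = 1e-12)
  expect_equal(q$calinski_harabasz, (100 / 1) / (0.01 / 2), tolerance = 1e-12)
  expect_equal(q$davies_bouldin, (0.05 + 0.05) / 10, tolerance = 1e-12)
  expect_equal(q$inertia, 4 * 0.05^2, tolerance = 1e-12)
})

test_that("quality criteria match brute-force evaluation on random instances", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:40, 1)
    k <- sample(2:4, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    labels <- sample.int(k, n, replace = TRUE)
    labels <- as.integer(factor(labels))  # make clusters 1..k' nonempty
    if (max(labels) < 2) next
    q <- qualityCriteria(x, labels)
    expect_equal(q$silhouette, bruteSilhouette(x, labels), tolerance = 1e-10)
    expect_equal(q$calinski_harabasz, bruteCH(x, labels), tolerance = 1e-10)
    expect_equal(q$davies_bouldin, bruteDB(x, labels), tolerance = 1e-10)
    expect_equal(q$inertia, bruteInertia(x, labels), tolerance = 1e-10)
  }
  expect_error(qualityCriteria(matrix(1:4, 2), c(1L, 2L)), "singleton")
})

test_that("state metrics follow the stated occupancy/dwell/transition conventions", {
  mkModel <- function(labels, participants = "p1", stepTr = 1L, tr = 2) {
    w <- length(labels)
    prov <- data.frame(participant_id = rep(participants, each = w /
                         length(participants)),
                       session = "pre_op", run_id = "r1",
                       window_index = rep(seq_len(w / length(participants)),
                                          length(participants)),
                       start_tr = 0L, tr_seconds = tr,
                       step_tr = stepTr, window_strength = 0.1,
                       stringsAsFactors = FALSE)
    prov$start_tr <- prov$window_index - 1L
    new("StateModel", k = 2L, centroids = array(rep(diag(3), 2), c(3, 3, 2)),
        labels = labels, strengths = c(0.3, 0.1), inertia = 0,
        inertiaPath = 0, seed = 1L, restarts = 1L, provenance = prov,
        roiNames = c("a", "b", "c"))
  }
  sm <- stateMetrics(mkModel(c(1L, 1L, 1L, 2L)))
  expect_equal(sm$occupancy_rate, c(0.75, 0.25))

  sm2 <- stateMetrics(mkModel(c(1L, 1L, 2L, 2L, 2L, 1L)))
  expect_equal(sm2$dwell_time_seconds[1], mean(c(2, 1)) * 2)  # 3 s
  expect_equal(sm2$dwell_time_seconds[2], 6)
  # 2 label changes over 6 windows x 1 TR x 2 s = 12 s -> 10 per minute
  expect_equal(unique(sm2$transitions_per_minute), 2 / (12 / 60))
  expect_equal(sum(sm2$occupancy_rate), 1, tolerance = 1e-12)

  # p1 never leaves state 1 (state 2 stays globally nonempty via p2)
  both <- stateMetrics(mkModel(c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L),
                               participants = c("p1", "p2")))
  p1 <- both[both$participant_id == "p1", ]
  expect_equal(p1$transitions_per_minute, c(0, 0))
  expect_equal(p1$occupancy_rate, c(1, 0))
  expect_true(is.na(p1$dwell_time_seconds[2]))  # missing, not zero
})

test_that("dwell visits never cross run boundaries", {
  prov <- data.frame(participant_id = "p1", session = "pre_op",
                     run_id = rep(c("r1", "r2"), each = 3),
                     window_index = rep(1:3, 2), start_tr = rep(0:2, 2),
                     tr_seconds = 2, step_tr = 1L, window_strength = 0.1,
                     stringsAsFactors = FALSE)
  m <- new("StateModel", k = 2L, centroids = array(rep(diag(3), 2), c(3, 3, 2)),
           labels = c(1L, 1L, 1L, 1L, 2L, 2L), strengths = c(0.3, 0.1),
           inertia = 0, inertiaPath = 0, seed = 1L, restarts = 1L,
           provenance = prov, roiNames = c("a", "b", "c"))
  sm <- stateMetrics(m)
  # state 1: visits of 3 (run1) and 1 (run2) windows, never a merged 4
  expect_equal(sm$dwell_time_seconds[1], mean(c(3, 1)) * 2)
  # the r1->r2 boundary is not a transition
  expect_equal(unique(sm$transitions_per_minute), 1 / (12 / 60))
})

test_that("relabelling states permutes metrics without changing their multiset", {
  sim <- smallTwoStateRun(400, seed = 13)
  d <- slidingWindows(sim$run, windowSpec(30, 1))
  pool <- poolWindows(list(d))
  m <- kmeansStates(pool, k = 2, restarts = 5, seed = 1)
  sm <- stateMetrics(m)
  flipped <- m
  flipped@labels <- 3L - m@labels
  flipped@strengths <- rev(m@strengths)
  flipped@centroids <- m@centroids[, , 2:1]
  smf <- stateMetrics(flipped)
  for (col in c("occupancy_rate", "dwell_time_seconds", "strength"))
    expect_equal(sort(sm[[col]]), sort(smf[[col]]))
})

test_that("lobe summaries average the right blocks", {
  lm <- list(roi_to_lobe = c(a = "L1", b = "L1", c = "L2", d = "L2"),
             lobes = c("L1", "L2"))
  m <- rbind(c(1, 0.5, 0.2, 0.3), c(0.5, 1, 0.1, 0.2),
             c(0.2, 0.1, 1, 0.8), c(0.3, 0.2, 0.8, 1))
  dimnames(m) <- list(letters[1:4], letters[1:4])
  ls <- lobeSummary(m, lm)
  expect_equal(ls$mean_r[ls$lobe_i == "L1" & ls$lobe_j == "L1"], 0.5)
  expect_equal(ls$mean_r[ls$lobe_i == "L2" & ls$lobe_j == "L2"], 0.8)
  expect_equal(ls$mean_r[ls$lobe_i == "L1" & ls$lobe_j == "L2"],
               mean(c(0.2, 0.3, 0.1, 0.2)))

  const <- devectorizeUpper(rep(0.4, 6), roiNames = letters[1:4])
  lc <- lobeSummary(const, lm)
  expect_true(all(lc$mean_r == 0.4))

  expect_equal(lobeSummary(m - m + diag(0, 4), lm)$mean_r, rep(0, 3))

  bad <- m; rownames(bad)[1] <- "zz"
  expect_error(lobeSummary(bad, lm), "unmapped")
})

test_that("sweeps report per-value results and record per-value errors", {
  sim1 <- smallTwoStateRun(200, seed = 1)
  sim2 <- smallTwoStateRun(200, seed = 2)
  runs <- list(sim1$run, sim2$run)
  sw <- sweepClustering(runs, "step_tr", grid = c(2, 5), k = 2,
                        lengthSeconds = 40, restarts = 3, seed = 9)
  expect_equal(nrow(sw), 2L)
  expect_true(all(is.na(sw$error)))

  # direct evaluation equals a one-value sweep
  pool <- poolWindows(lapply(runs, slidingWindows, spec = windowSpec(40, 2)))
  m <- kmeansStates(pool, 2, restarts = 3, seed = 9)
  q <- qualityCriteria(windowFeatures(pool), stateLabels(m))
  expect_equal(sw$silhouette[1], q$silhouette, tolerance = 1e-12)

  # an impossible window length is recorded, not fatal
  sw2 <- sweepClustering(runs, "window_seconds", grid = c(40, 2000),
                         k = 2, restarts = 2, seed = 1)
  expect_true(is.na(sw2$error[1]) && !is.na(sw2$error[2]))
  expect_true(is.finite(sw2$silhouette[1]) && is.na(sw2$silhouette[2]))
})
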