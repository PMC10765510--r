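test_that("density binarization keeps the top edges with exact tie handling", {
  fc <- devectorizeUpper(c(0.9, 0.8, 0.3, 0.2, 0.1, 0.05))
  net <- binarizeFC(fc, "density", 1 / 3)
  expect_equal(net$n_edges, 2L)
  expect_equal(net$adjacency[1, 2], 1L)  # r = 0.9
  expect_equal(net$adjacency[1, 3], 1L)  # r = 0.8
  expect_equal(sum(net$adjacency), 4L)

  full <- binarizeFC(fc, "density", 1)
  expect_equal(full$n_edges, 6L)

  # ties at the cutoff resolved by (smaller i, smaller j)
  tied <- devectorizeUpper(rep(0.5, 6))
  t1 <- binarizeFC(tied, "density", 2 / 6)
  expect_equal(t1$n_edges, 2L)
  expect_equal(t1$adjacency[1, 2], 1L)
  expect_equal(t1$adjacency[1, 3], 1L)
  expect_equal(t1$adjacency[2, 3], 0L)

  # negative correlations never become edges by default
  neg <- devectorizeUpper(c(0.4, -0.9, -0.8, -0.7, -0.6, -0.5))
  expect_equal(binarizeFC(neg, "density", 0.5)$n_edges, 1L)
  expect_equal(binarizeFC(neg, "density", 0.5, positiveOnly = FALSE)$n_edges, 3L)
})

test_that("density edge counts equal floor(density x pairs) on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    fc <- randomFc(n)
    dens <- runif(1, 0.1, 1)
    want <- floor(dens * n * (n - 1) / 2)
    net <- binarizeFC(fc, "density", dens, positiveOnly = FALSE)
    expect_equal(net$n_edges, want)
    expect_equal(sum(net$adjacency) / 2, want)
    expect_equal(net$adjacency, t(net$adjacency))
    expect_true(all(diag(net$adjacency) == 0))
  }
})

test_that("absolute thresholding keeps edges strictly above the cutoff", {
  fc <- devectorizeUpper(c(0.9, 0.5, 0.5, 0.1, -0.2, 0.3))
  expect_equal(binarizeFC(fc, "absolute", 0.5)$n_edges, 1L)
  expect_equal(binarizeFC(fc, "absolute", 0.0)$n_edges, 5L)
  # no off-diagonal r can exceed 1: empty graph at the boundary
  expect_equal(binarizeFC(randomFc(6), "absolute", 1)$n_edges, 0L)
})

test_that("indicators reproduce closed-form values on canonical graphs", {
  k3 <- matrix(1, 3, 3) - diag(3)
  i3 <- graphIndicators(k3)
  expect_equal(i3$clustering_coefficient, 1)
  expect_equal(i3$global_efficiency, 1)
  expect_equal(i3$k_core, 2L)
  expect_true(is.na(i3$assortativity))  # regular graph: undefined

  p3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
  expect_equal(graphIndicators(p3)$global_efficiency, 5 / 6)

  twoK3 <- rbind(cbind(k3, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), k3))
  i2 <- graphIndicators(twoK3)
  expect_equal(i2$modularity, 0.5)
  expect_equal(i2$k_core, 2L)

  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(graphIndicators(k5)$k_core, 4L)

  empty <- matrix(0L, 4, 4)
  ie <- graphIndicators(empty)
  expect_equal(ie$k_core, 0L)
  expect_equal(ie$global_efficiency, 0)
  expect_equal(ie$local_efficiency, 0)
  expect_true(is.na(ie$modularity))
})

test_that("indicators match brute-force oracles on random graphs", {
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    adj <- matrix(0L, n, n)
    ut <- which(upper.tri(adj))
    on <- sample(ut, size = max(1, rbinom(1, length(ut), 0.45)))
    adj[on] <- 1L
    adj <- adj + t(adj)
    ind <- graphIndicators(adj)
    expect_equal(ind$global_efficiency, bfGlobalEff(adj), tolerance = 1e-12)
    expect_equal(ind$local_efficiency, bfLocalEff(adj), tolerance = 1e-12)
    expect_equal(ind$clustering_coefficient, bfClustering(adj),
                 tolerance = 1e-12)
    expect_equal(ind$k_core, bfMaxCore(adj))
    if (is.na(ind$assortativity)) {
      expect_true(is.na(bfAssortativity(adj)))
    } else {
      expect_equal(ind$assortativity, bfAssortativity(adj), tolerance = 1e-10)
    }
  }
})

test_that("adding an edge never decreases global efficiency or max k-core", {
  set.seed(23)
  for (rep in 1:8) {
    n <- 7
    adj <- matrix(0L, n, n)
    ut <- which(upper.tri(adj))
    on <- sample(ut, 8)
    adj[on] <- 1L
    adj <- adj + t(adj)
    off <- setdiff(ut, on)
    add <- sample(off, 1)
    adj2 <- adj
    adj2[add] <- 1L
    adj2[arrayInd(add, c(n, n))[, c(2, 1), drop = FALSE]] <- 1L
    expect_gte(graphIndicators(adj2)$global_efficiency,
               graphIndicators(adj)$global_efficiency)
    expect_gte(graphIndicators(adj2)$k_core, graphIndicators(adj)$k_core)
  }
})

test_that("dynamic indicator series track windows in order", {
  sim <- smallTwoStateRun(150, seed = 19)
  d <- slidingWindows(sim$run, windowSpec(30, 5))
  di <- dynamicIndicators(d, "density", 0.2)
  expect_equal(nrow(di), nWindows(d))
  expect_equal(di$window_index, seq_len(nWindows(d)))
  expect_equal(di$start_tr, windowStarts(d))

  # constant dFC (single window replicated) gives a constant series
  one <- windowMatrix(d, 1)
  attr(one, "window_index") <- NULL; attr(one, "start_tr") <- NULL
  attr(one, "end_tr") <- NULL
  const <- new("DfcSeries", mats = array(rep(one, 3), c(8, 8, 3)),
               startsTr = c(0L, 1L, 2L), lengthTr = 15L, stepTr = 1L,
               trSeconds = 2, participantId = "p", session = "pre_op",
               runId = "r")
  dc <- dynamicIndicators(const, "density", 0.2)
  expect_equal(nrow(unique(dc[, 6:11])), 1L)
})

test_that("strong-state windows are more efficient under absolute thresholding", {
  sim <- smallTwoStateRun(600, seed = 29)
  d <- slidingWindows(sim$run, windowSpec(30, 1))
  gt <- windowMajorityLabels(sim$truth$state_labels_per_tr, 15L, 1L)
  di <- dynamicIndicators(d, "absolute", 0.25)
  expect_gt(mean(di$global_efficiency[gt == 1]),
            mean(di$global_efficiency[gt == 2]))
})
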