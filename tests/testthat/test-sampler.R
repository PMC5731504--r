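test_that("acceptance probability follows the Metropolis-Hastings rule", {
  expect_equal(acceptanceProbability(5, 5, 1, 0.3, 0.3), 1)
  expect_equal(acceptanceProbability(5, Inf, 1), 0)
  expect_equal(acceptanceProbability(5, 5 + log(2), 1), 0.5)
  # proposal-ratio correction on and off
  expect_equal(acceptanceProbability(0, 0, 1, qForward = 0.5, qReverse = 0.1),
               0.2)
  expect_equal(acceptanceProbability(0, 0, 1, qForward = 0.5, qReverse = 0.1,
                                     hastings = FALSE), 1)
  expect_equal(acceptanceProbability(0, 0, 1, qForward = 0.5, qReverse = 0), 0)
  expect_error(acceptanceProbability(0, 0, 0), "positive")
})

test_that("cooling is geometric", {
  expect_equal(cool(1), 0.999999)
  expect_equal(Reduce(function(t, .) cool(t), 1:50, accumulate = FALSE,
                      init = 1), 0.999999^50)
  expect_equal(cool(0.37, coolingFactor = 1), 0.37)
  expect_error(cool(-1), "positive")
})

test_that("exponent proposals are Gaussian around the current value with a floor", {
  set.seed(4)
  draws <- replicate(1e5, proposeGamma(2.5))
  expect_lt(abs(mean(draws) - 2.5), 0.001)
  expect_lt(abs(stats::sd(draws) / sqrt(0.001) - 1), 0.02)
  expect_true(all(draws > 0))
  expect_equal(proposeGamma(1e-10, gammaStepSd = 1e-12), 1e-10,
               tolerance = 1e-6)
})

test_that("single-choice proposals report the hand-computed probabilities", {
  net <- ppiNetwork(data.frame(a = "A", b = "B", w = 1))
  sp <- scoreParams(sMax = 3L)
  set.seed(1)

  p <- proposeAddCluster(net, clusterSet(), sp)
  expect_false(p$noop)
  expect_equal(p$qForward, 0.25 * 1)
  expect_equal(p$qReverse, 0.25 * 1)
  expect_equal(clusters(p$candidate), list(c("A", "B")))

  # duplicate cluster: state unchanged
  p2 <- proposeAddCluster(net, clusterSet(list(c("A", "B"))), sp)
  expect_true(p2$noop)

  # nothing to extend / shrink / remove
  expect_true(proposeAddProtein(net, clusterSet(), sp)$noop)
  expect_true(proposeRemoveProtein(net, clusterSet(list(c("A", "B"))), sp)$noop)
  tri <- ppiNetwork(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                               w = 1))
  expect_true(
    proposeRemoveCluster(tri, clusterSet(list(c("A", "B", "C"))), sp)$noop)

  # single dimer removal
  p3 <- proposeRemoveCluster(net, clusterSet(list(c("A", "B"))), sp)
  expect_equal(p3$qForward, 0.25 * 1)
  expect_length(clusters(p3$candidate), 0L)

  # single extension candidate: C adjacent to B only
  p4 <- proposeAddProtein(pathNet(), clusterSet(list(c("A", "B"))), sp)
  expect_false(p4$noop)
  expect_equal(p4$qForward, 0.25 * 1 * 1)
  expect_equal(clusters(p4$candidate), list(c("A", "B", "C")))
})

test_that("reverse proposal probabilities match the paired move recomputed on the new state", {
  sp <- scoreParams(sMax = 6L)
  pp <- samplerParams()
  alpha <- pp@moveProbs
  set.seed(99)
  checkedAdd <- 0L
  checkedExt <- 0L
  for (i in 1:400) {
    net <- randomNet(8L, p = 0.45)
    # feasible starting set: dimers on actual edges
    et <- edgeTable(net)
    k <- sample(seq_len(nrow(et)), min(2L, nrow(et)))
    X <- tryCatch(
      clusterSet(lapply(k, function(r) c(et$proteinA[r], et$proteinB[r]))),
      error = function(e) NULL)
    if (is.null(X)) next

    p <- proposeAddCluster(net, X, sp, pp)
    if (!p$noop && !p$infeasible) {
      Xp <- p$candidate
      dimers <- Filter(function(x) length(x) == 2L, clusters(Xp))
      invSum <- sum(vapply(dimers, function(d) 1 / clusterWeight(net, d), 0))
      w <- clusterWeight(net, sort(p$pick))
      expect_equal(p$qReverse, alpha[3L] * (1 / w) / invSum)
      checkedAdd <- checkedAdd + 1L
    }

    p <- proposeAddProtein(net, X, sp, pp)
    if (!p$noop && !p$infeasible) {
      Xp <- clusters(p$candidate)
      grown <- Xp[[which(lengths(Xp) >= 3L)[1L]]]
      u <- p$pick
      n3 <- sum(lengths(Xp) >= 3L)
      inv <- vapply(grown, function(v) 1 / nodeClusterWeight(net, v, grown), 0)
      expect_equal(p$qReverse,
                   alpha[4L] * (1 / n3) *
                     (1 / nodeClusterWeight(net, u, grown)) / sum(inv))
      checkedExt <- checkedExt + 1L
    }
  }
  expect_gt(checkedAdd, 50L)
  expect_gt(checkedExt, 50L)
})

test_that("runs are reproducible from the seed", {
  net <- cycleNet()
  sp <- scoreParams(sMax = 3L, cCluDis = 1, cCluSize = 1, cProNum = 0.02)
  pp <- samplerParams(L = 5000, seed = 12)
  r1 <- runSampler(net, sp, pp)
  r2 <- runSampler(net, sp, pp)
  expect_identical(clusters(bestClusters(r1)), clusters(bestClusters(r2)))
  expect_identical(bestScore(r1), bestScore(r2))
  expect_identical(scoreTrace(r1), scoreTrace(r2))
  expect_identical(r1@acceptanceRate, r2@acceptanceRate)
})

test_that("a single-edge network yields the single possible dimer", {
  net <- ppiNetwork(data.frame(a = "A", b = "B", w = 1))
  sp <- scoreParams(sMax = 3L)
  # the two-state space is enumerable: {} vs {{A,B}}; the dimer wins
  # whenever the density gain plus size-fit beats the empty state
  fEmpty <- totalScore(net, clusterSet(), sp@gamma0, sp)@total
  fDimer <- totalScore(net, clusterSet(list(c("A", "B"))), sp@gamma0, sp)@total
  expect_lt(fDimer, fEmpty)
  res <- runSampler(net, sp, samplerParams(L = 1e4, seed = 5))
  expect_equal(clusters(bestClusters(res)), list(c("A", "B")))
})

test_that("the best score bounds the trace and visited states are feasible", {
  net <- cycleNet()
  sp <- scoreParams(sMax = 3L, cCluDis = 1, cCluSize = 1, cProNum = 0.02)
  res <- runSampler(net, sp, samplerParams(L = 3e4, seed = 8,
                                           traceEvery = 100L,
                                           recordStates = TRUE,
                                           recomputeEvery = 2000L))
  expect_lte(bestScore(res), min(scoreTrace(res)$score))
  expect_lte(res@maxScoreDrift, 1e-8)

  # every visited state: clusters connected, sizes within [2, sMax],
  # finite score
  keys <- names(res@stateCounts)
  for (key in keys) {
    if (key == "{}") next
    members <- strsplit(strsplit(key, "|", fixed = TRUE)[[1L]], "+",
                        fixed = TRUE)
    for (m in members) {
      expect_gte(length(m), 2L)
      expect_lte(length(m), 3L)
      expect_true(isClusterConnected(net, m))
    }
    f <- totalScore(net, clusterSet(members), 2.5, sp)@total
    expect_true(is.finite(f))
  }
})

test_that("incremental scores track full recomputation through long runs", {
  set.seed(2024)
  bench <- generateBenchmark(nComplexes = 8, seed = 77)
  res <- runSampler(bench@network, benchmarkScoreParams(),
                    samplerParams(L = 2e4, seed = 3, recomputeEvery = 1000L,
                                  coolingFactor = benchmarkCooling(2e4)))
  expect_lte(res@maxScoreDrift, 1e-8)
})
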