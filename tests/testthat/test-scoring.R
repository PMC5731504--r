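test_that("feasibility term fires on disconnected and oversized clusters", {
  net <- pathNet()
  expect_identical(booleanTerm(net, clusterSet(list(c("A", "B")))), 0)
  expect_identical(booleanTerm(net, clusterSet(list(c("A", "C")))), Inf)
  expect_identical(
    booleanTerm(net, clusterSet(list(c("A", "B", "C"))), sMax = 2L), Inf)
})

test_that("generalized density follows w(x)/sqrt(|x|)", {
  net <- pathNet()
  expect_equal(clusterDensity(net, c("B", "C")), 1 / sqrt(2))
  expect_equal(clusterDensity(net, c("A", "B", "C")), 1.5 / sqrt(3))
  expect_equal(clusterDensity(net, c("A", "C")), 0)

  expect_equal(densityTerm(net, clusterSet()), 0)
  expect_equal(densityTerm(net, clusterSet(list(c("B", "C")))), -1 / sqrt(2))
  two <- ppiNetwork(data.frame(a = c("A", "C"), b = c("B", "D"), w = 1))
  expect_equal(densityTerm(two, clusterSet(list(c("A", "B"), c("C", "D")))),
               -2 / sqrt(2))
})

test_that("adding an internal edge strictly decreases the density term", {
  base <- data.frame(a = c("A", "B"), b = c("B", "C"), w = c(0.5, 1))
  net1 <- ppiNetwork(base)
  net2 <- ppiNetwork(rbind(base, data.frame(a = "A", b = "C", w = 1)))
  X <- clusterSet(list(c("A", "B", "C")))
  expect_lt(densityTerm(net2, X), densityTerm(net1, X))
})

test_that("pairwise overlap penalty applies the size-stratified rule", {
  expect_equal(pairDissimilarity(c("A", "B"), c("B", "C")), 1 / 3)
  expect_identical(
    pairDissimilarity(c("A", "B", "C"), c("A", "B", "D", "E", "F")), Inf)
  four1 <- c("A", "B", "C", "D")
  four2 <- c("A", "B", "E", "F")
  expect_identical(pairDissimilarity(four1, four2, beta = 0.2), Inf)
  expect_equal(pairDissimilarity(four1, four2, beta = 0.6), 2 / 6)
  expect_equal(pairDissimilarity(c("A", "B"), c("C", "D")), 0)
})

test_that("overlap term sums unordered distinct pairs", {
  expect_equal(overlapTerm(clusterSet(list(c("A", "B"), c("C", "D")))), 0)
  expect_equal(overlapTerm(clusterSet(list(c("A", "B"), c("B", "C")))), 1 / 3)

  # three disjoint clusters plus one single-protein-sharing dimer pair:
  # brute-force pair scan as the oracle
  X <- clusterSet(list(c("A", "B"), c("B", "C"), c("D", "E", "F"),
                       c("G", "H")))
  cl <- clusters(X)
  brute <- 0
  for (i in 1:(length(cl) - 1)) {
    for (j in (i + 1):length(cl)) {
      brute <- brute + pairDissimilarity(cl[[i]], cl[[j]])
    }
  }
  expect_equal(brute, 1 / 3)
  expect_equal(overlapTerm(X), brute)

  expect_identical(
    overlapTerm(clusterSet(list(c("A", "B", "C"), c("A", "B", "D")))), Inf)
  expect_equal(overlapTerm(clusterSet(list(c("A", "B")))), 0)
})

test_that("truncated power-law pmf is normalized and matches hand values", {
  expect_equal(powerLawPmf(2:3, gamma = 1, sMax = 3L), c(0.6, 0.4))
  expect_equal(powerLawPmf(2:4, gamma = 0, sMax = 4L), rep(1 / 3, 3))
  for (g in c(0.5, 1, 2, 2.5, 3.5)) {
    for (sm in c(3L, 10L, 100L)) {
      expect_lt(abs(sum(powerLawPmf(2:sm, g, sm)) - 1), 1e-12)
    }
  }
  expect_error(powerLawPmf(1L, 1, 10L), "outside")
  expect_error(powerLawPmf(11L, 1, 10L), "outside")
})

test_that("empirical size fractions count cluster sizes", {
  X <- clusterSet(list(c("A", "B"), c("C", "D"), c("E", "F", "G")))
  expect_equal(sizeFraction(X, 2L), 2 / 3)
  expect_equal(sizeFraction(X, 3L), 1 / 3)
  expect_equal(sizeFraction(X, 4L), 0)
  expect_equal(sum(sizeFraction(X, 2:10)), 1)
  expect_equal(sizeFraction(clusterSet(), 2:5), rep(0, 4))
})

test_that("size-distribution term matches hand-computed squared errors", {
  # pmf (0.6, 0.4) at gamma 1, sMax 3: a 3:2 dimer/trimer mix fits exactly
  fit <- clusterSet(list(c("A", "B"), c("C", "D"), c("E", "F"),
                         c("G", "H", "I"), c("J", "K", "L")))
  expect_equal(sizeTerm(fit, gamma = 1, sMax = 3L), 0)

  one <- clusterSet(list(c("A", "B")))
  expect_equal(sizeTerm(one, gamma = 1, sMax = 3L), 0.4^2 + 0.4^2)

  psi <- powerLawPmf(2:3, gamma = 1, sMax = 3L)
  expect_equal(sizeTerm(clusterSet(), gamma = 1, sMax = 3L), sum(psi^2))
})

test_that("size term is minimized by the histogram closest to the power law", {
  # brute force over all achievable histograms with |X| <= 4, sMax = 4
  sMax <- 4L
  pool <- list(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"),
               c("I", "J", "K"), c("L", "M", "N"), c("O", "P", "Q"),
               c("R", "S", "T"), c("U", "V", "W", "X"),
               c("a", "b", "c", "d"), c("e", "f", "g", "h"),
               c("i", "j", "k", "l"))
  for (gamma in c(0.8, 2, 3)) {
    psi <- powerLawPmf(2:sMax, gamma, sMax)
    for (n in 1:4) {
      hists <- expand.grid(n2 = 0:n, n3 = 0:n, n4 = 0:n)
      hists <- hists[rowSums(hists) == n, , drop = FALSE]
      direct <- apply(hists, 1L, function(h) sum((h / n - psi)^2))
      viaTerm <- apply(hists, 1L, function(h) {
        cl <- c(pool[seq_len(h[1L])],
                pool[4L + seq_len(h[2L])],
                pool[8L + seq_len(h[3L])])
        sizeTerm(clusterSet(cl), gamma, sMax)
      })
      expect_equal(viaTerm, direct, ignore_attr = TRUE)
      expect_equal(which.min(viaTerm), which.min(direct))
    }
  }
})

test_that("exponent prior is a symmetric quadratic", {
  expect_equal(hyperPriorTerm(2.5), 0)
  expect_equal(hyperPriorTerm(2.0), 0.25)
  expect_equal(hyperPriorTerm(2.5 + 0.7), hyperPriorTerm(2.5 - 0.7))
})

test_that("protein-count term squares the union size", {
  expect_equal(proteinCountTerm(clusterSet()), 0)
  expect_equal(proteinCountTerm(clusterSet(list(c("A", "B"), c("C", "D")))), 16)
  expect_equal(proteinCountTerm(clusterSet(list(c("A", "B"), c("B", "C")))), 9)
})

test_that("total score decomposes into its six terms", {
  net <- pathNet()
  sp <- scoreParams(sMax = 10L)

  # empty state: only the size term remains
  empty <- totalScore(net, clusterSet(), sp@gamma0, sp)
  psi <- powerLawPmf(2:10, sp@gamma0, 10L)
  expect_equal(empty@total, sp@cCluSize * sum(psi^2))

  # a disconnected cluster forces an infinite total
  bad <- totalScore(net, clusterSet(list(c("A", "C"))), 2.5, sp)
  expect_identical(bad@total, Inf)
  expect_identical(bad@b, Inf)

  set.seed(31)
  for (i in 1:50) {
    net <- randomNet(10L)
    X <- randomClusterSet(net)
    gamma <- stats::runif(1, 0.5, 4)
    br <- totalScore(net, X, gamma, sp)
    manual <- booleanTerm(net, X, sp@sMax) + densityTerm(net, X) +
      sp@cCluDis * overlapTerm(X, sp@beta) +
      sp@cCluSize * sizeTerm(X, gamma, sp@sMax) +
      sp@cHy * hyperPriorTerm(gamma, sp@gamma0) +
      sp@cProNum * proteinCountTerm(X)
    if (is.infinite(manual)) {
      expect_identical(br@total, Inf)
    } else {
      expect_equal(br@total, manual)
    }
  }
})
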