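test_that("edge lists load with self-loop removal, thresholding and normalization", {
  path <- writeEdgeFile(c("A\tB\t2.0", "B\tC\t4.0", "C\tC\t9.9"))
  net <- loadPPINetwork(path)
  expect_setequal(proteins(net), c("A", "B", "C"))
  et <- edgeTable(net)
  expect_equal(nrow(et), 2L)
  expect_equal(clusterWeight(net, c("A", "B")), 0.5)
  expect_equal(clusterWeight(net, c("B", "C")), 1.0)

  net2 <- loadPPINetwork(path, weightThreshold = 3.0)
  expect_equal(numEdges(net2), 1L)
  expect_equal(clusterWeight(net2, c("B", "C")), 1.0)

  # comments and 2-column rows (implicit weight 1)
  path3 <- writeEdgeFile(c("# a comment", "A\tB", "B\tC\t0.5"))
  net3 <- loadPPINetwork(path3, normalize = FALSE)
  expect_equal(clusterWeight(net3, c("A", "B")), 1.0)
  expect_equal(clusterWeight(net3, c("B", "C")), 0.5)
})

test_that("malformed input is rejected with the offending line number", {
  expect_error(loadPPINetwork(writeEdgeFile("A\tB\tx")), "line 1")
  expect_error(loadPPINetwork(writeEdgeFile(c("A\tB\t1", "A\tB\tC\tD\t1"))),
               "line 2")
  expect_error(loadPPINetwork(writeEdgeFile("A\tB\t-0.5")), "negative")
  expect_error(loadPPINetwork(writeEdgeFile("A\tB\t1"), weightThreshold = 5),
               "empty")
  # raw weights above 1 need normalization
  expect_error(loadPPINetwork(writeEdgeFile("A\tB\t2"), normalize = FALSE),
               "weight")
})

test_that("duplicate edges collapse to the maximum weight with a warning", {
  path <- writeEdgeFile(c("A\tB\t0.3", "B\tA\t0.7", "B\tC\t1"))
  expect_warning(net <- loadPPINetwork(path, normalize = FALSE), "duplicate")
  expect_equal(clusterWeight(net, c("A", "B")), 0.7)
})

test_that("normalized networks have maximum weight exactly 1", {
  set.seed(101)
  for (i in 1:5) {
    net <- randomNet(7L)
    df <- edgeTable(net)
    df$weight <- df$weight * stats::runif(1, 1, 50)
    renorm <- ppiNetwork(df, normalize = TRUE)
    expect_equal(max(edgeTable(renorm)$weight), 1)
  }
})

test_that("cluster weight, node-cluster weight and the handshake identity agree", {
  net <- ppiNetwork(data.frame(a = c("A", "B", "C", "C"),
                               b = c("B", "C", "A", "E"),
                               w = c(0.5, 1, 0.25, 0.4)), normalize = FALSE)
  expect_equal(clusterWeight(net, c("A", "B", "C")), 1.75)
  expect_equal(nodeClusterWeight(net, "C", c("A", "B")), 1.25)
  expect_equal(nodeClusterWeight(net, "A", c("A", "B")), 0.5)  # in-cluster
  expect_equal(nodeClusterWeight(net, "E", c("A", "B")), 0)
  expect_equal(clusterWeight(net, c("A", "E")), 0)  # non-edge pair
  expect_error(clusterWeight(net, c("A", "Z")), "unknown")

  set.seed(7)
  for (i in 1:20) {
    net <- randomNet(8L)
    x <- sample(proteins(net), sample(2:5, 1L))
    half <- sum(vapply(x, nodeClusterWeight, 0, net = net, members = x)) / 2
    expect_equal(clusterWeight(net, x), half)
  }
})

test_that("cluster neighbors are exactly the adjacent outside nodes", {
  net <- pathNet()
  expect_equal(clusterNeighbors(net, c("A", "B")), "C")
  tri <- ppiNetwork(data.frame(a = c("A", "A", "B"), b = c("B", "C", "C"),
                               w = 1))
  expect_length(clusterNeighbors(tri, c("A", "B", "C")), 0L)
  two <- ppiNetwork(data.frame(a = c("A", "C"), b = c("B", "D"), w = 1))
  expect_length(clusterNeighbors(two, c("A", "B")), 0L)

  set.seed(11)
  for (i in 1:10) {
    net <- randomNet(8L)
    x <- sample(proteins(net), 3L)
    expect_length(intersect(clusterNeighbors(net, x), x), 0L)
  }
})

test_that("induced-subgraph connectivity matches an independent implementation", {
  skip_if_not_installed("igraph")
  net <- pathNet()
  expect_true(isClusterConnected(net, c("A", "B")))
  expect_false(isClusterConnected(net, c("A", "C")))
  expect_true(isClusterConnected(net, c("A", "B", "C")))

  set.seed(23)
  for (i in 1:15) {
    net <- randomNet(8L)
    g <- igraph::graph_from_data_frame(edgeTable(net)[, 1:2],
                                       directed = FALSE,
                                       vertices = proteins(net))
    for (j in 1:10) {
      x <- sample(proteins(net), sample(2:5, 1L))
      expect_identical(
        isClusterConnected(net, x),
        igraph::is_connected(igraph::induced_subgraph(g, x))
      )
    }
  }
})

test_that("cluster files round-trip through the shared line-per-complex format", {
  X <- clusterSet(list(c("A", "B"), c("B", "C", "D")))
  path <- tempfile()
  writeClusterSet(X, path, header = c("meta one", "meta two"))
  Y <- readClusterSet(path)
  expect_equal(clusters(Y), clusters(X))
})

test_that("cluster sets reject duplicates, singletons and repeated members", {
  expect_error(clusterSet(list(c("A", "B"), c("B", "A"))), "duplicate")
  expect_error(clusterSet(list("A")), "two members")
  expect_error(clusterSet(list(c("A", "A"))), "distinct")
})
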