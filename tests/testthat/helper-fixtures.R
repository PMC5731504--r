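# Shared in-code fixtures: tiny deterministic networks and random-graph
# builders. Everything is generated programmatically; no data files.

# Path A - B - C with weights 0.5 and 1.
pathNet <- function() {
  ppiNetwork(data.frame(a = c("A", "B"), b = c("B", "C"), w = c(0.5, 1)))
}

# 4-cycle A-B-C-D-A with distinct weights; the exactly enumerable
# state space used by the chain oracle.
cycleNet <- function() {
  ppiNetwork(data.frame(a = c("A", "B", "C", "D"),
                        b = c("B", "C", "D", "A"),
                        w = c(1, 0.8, 0.6, 0.9)))
}

# Erdos-Renyi weighted network on n named nodes (draws from the current
# RNG stream; callers set the seed).
randomNet <- function(n = 8L, p = 0.35) {
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  repeat {
    keep <- stats::runif(ncol(pairs)) < p
    if (any(keep)) break
  }
  ppiNetwork(data.frame(a = pairs[1L, keep], b = pairs[2L, keep],
                        w = stats::runif(sum(keep), 0.1, 1)))
}

# Random cluster set over a network's nodes: sizes 2-5, duplicates
# removed; clusters may be disconnected or overlapping (useful for
# exercising infinite terms).
randomClusterSet <- function(net, k = 4L, maxSize = 5L) {
  nodes <- proteins(net)
  cl <- list()
  for (i in seq_len(k)) {
    s <- sample(2:min(maxSize, length(nodes)), 1L)
    cl[[i]] <- sample(nodes, s)
  }
  keys <- vapply(cl, function(x) paste(sort(x), collapse = "+"), "")
  clusterSet(cl[!duplicated(keys)])
}

# Write an edge list to a temp file and return the path.
writeEdgeFile <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
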