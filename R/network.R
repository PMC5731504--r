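#' Construct a PPI network from an edge table
#'
#' Builds a [PPINetwork-class] from a three-column table of interactions.
#' Self-loops are dropped, duplicate edges are collapsed to their maximum
#' weight (with a warning), and weights may optionally be rescaled so the
#' maximum is exactly 1.
#'
#' @param edges data.frame (or coercible) whose first two columns are
#'   protein identifiers and whose optional third column holds positive
#'   interaction weights; a missing third column means weight 1.
#' @param normalize logical; divide all weights by the maximum surviving
#'   weight. When \code{FALSE}, weights must already lie in (0, 1].
#' @param weightThreshold optional numeric; edges with raw weight strictly
#'   below it are dropped before normalization.
#'
#' @return A [PPINetwork-class].
#' @examples
#' net <- ppiNetwork(data.frame(a = c("A", "B"), b = c("B", "C"),
#'                              w = c(2, 4)), normalize = TRUE)
#' edgeTable(net)
#' @export
ppiNetwork <- function(edges, normalize = FALSE, weightThreshold = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) == 2L) edges$weight <- 1
  if (ncol(edges) != 3L) {
    stop("edge table must have two or three columns")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  w <- edges[[3L]]
  if (!is.numeric(w) || any(is.na(w))) {
    stop("edge weights must be numeric and non-missing")
  }
  if (any(w < 0)) stop("negative edge weights are not allowed")
  keep <- a != b  # self-loops removed in preprocessing
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (!is.null(weightThreshold)) {
    keep <- w >= weightThreshold
    a <- a[keep]; b <- b[keep]; w <- w[keep]
  }
  keep <- w > 0
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  nodes <- sort(unique(c(a, b)))
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  lo <- pmin(ia, ib)
  hi <- pmax(ia, ib)
  key <- (lo - 1) * length(nodes) + hi
  if (anyDuplicated(key)) {
    warning("duplicate edges collapsed; keeping the maximum weight")
    ord <- order(key, -w)
    first <- !duplicated(key[ord])
    lo <- lo[ord][first]; hi <- hi[ord][first]; w <- w[ord][first]
  }
  if (normalize && length(w)) w <- w / max(w)
  ord <- order(lo, hi)
  new("PPINetwork",
    nodes = nodes,
    edgeMat = cbind(lo, hi, deparse.level = 0)[ord, , drop = FALSE],
    weights = as.numeric(w[ord])
  )
}

#' Load a weighted PPI network from an edge-list file
#'
#' Reads a tab- or whitespace-separated edge list with two or three
#' columns (proteinA, proteinB, optional weight; two columns imply weight
#' 1). Lines starting with \code{#} are skipped. Self-loops are removed,
#' duplicate edges keep their maximum weight, and edges below
#' \code{weightThreshold} (applied to raw weights) are dropped before
#' normalization.
#'
#' @param path file path of the edge list.
#' @param weightThreshold optional numeric; minimum raw weight to keep.
#' @param normalize logical; divide surviving weights by their maximum so
#'   the largest weight is exactly 1 (default TRUE).
#'
#' @return A [PPINetwork-class].
#' @export
loadPPINetwork <- function(path, weightThreshold = NULL, normalize = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no edges in ", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(parts)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop("parse error at line ", lineNo[bad[1L]],
         ": expected 2 or 3 columns, found ", nf[bad[1L]])
  }
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  wchr <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "1", "")
  w <- suppressWarnings(as.numeric(wchr))
  if (anyNA(w)) {
    bad <- which(is.na(w))[1L]
    stop("parse error at line ", lineNo[bad],
         ": non-numeric weight '", wchr[bad], "'")
  }
  if (any(w < 0)) {
    bad <- which(w < 0)[1L]
    stop("validation error at line ", lineNo[bad], ": negative weight")
  }
  net <- ppiNetwork(data.frame(a = a, b = b, w = w),
                    normalize = normalize, weightThreshold = weightThreshold)
  if (numEdges(net) == 0L) {
    stop("network is empty after filtering")
  }
  net
}

#' Write a network as a tab-separated edge list
#'
#' @param net a [PPINetwork-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePPINetwork <- function(net, path) {
  et <- edgeTable(net)
  utils::write.table(et, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- accessors ----------------------------------------------------------

#' @describeIn PPINetwork-class protein identifiers of the network.
#' @param object,x a \code{PPINetwork}.
#' @export
setGeneric("proteins", function(object) standardGeneric("proteins"))

#' @rdname PPINetwork-class
#' @export
setMethod("proteins", "PPINetwork", function(object) object@nodes)

#' @describeIn PPINetwork-class number of nodes.
#' @export
setGeneric("numNodes", function(object) standardGeneric("numNodes"))

#' @rdname PPINetwork-class
#' @export
setMethod("numNodes", "PPINetwork", function(object) length(object@nodes))

#' @describeIn PPINetwork-class number of edges.
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' @rdname PPINetwork-class
#' @export
setMethod("numEdges", "PPINetwork", function(object) nrow(object@edgeMat))

#' @describeIn PPINetwork-class edge table with columns
#'   \code{proteinA}, \code{proteinB}, \code{weight}.
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname PPINetwork-class
#' @export
setMethod("edgeTable", "PPINetwork", function(object) {
  data.frame(
    proteinA = object@nodes[object@edgeMat[, 1L]],
    proteinB = object@nodes[object@edgeMat[, 2L]],
    weight = object@weights,
    stringsAsFactors = FALSE
  )
})

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork with", numNodes(object), "proteins and",
      numEdges(object), "interactions\n")
  if (numEdges(object)) {
    cat("  weights in [", format(min(object@weights), digits = 4), ", ",
        format(max(object@weights), digits = 4), "]\n", sep = "")
  }
})

# ---- internal indexed representation ------------------------------------

# Adjacency-list index used by every scoring and proposal primitive.
# Kept outside the S4 slots: it is derived data, rebuilt in O(E).
netIndex <- function(net) {
  n <- length(net@nodes)
  em <- net@edgeMat
  w <- net@weights
  both <- c(em[, 1L], em[, 2L])
  other <- c(em[, 2L], em[, 1L])
  ww <- c(w, w)
  ord <- order(both)
  both <- both[ord]; other <- other[ord]; ww <- ww[ord]
  starts <- findInterval(seq_len(n) - 1L, both) + 1L
  ends <- findInterval(seq_len(n), both)
  adj <- vector("list", n)
  adjw <- vector("list", n)
  for (i in seq_len(n)) {
    if (starts[i] <= ends[i]) {
      idx <- starts[i]:ends[i]
      adj[[i]] <- other[idx]
      adjw[[i]] <- ww[idx]
    } else {
      adj[[i]] <- integer(0)
      adjw[[i]] <- numeric(0)
    }
  }
  list(
    n = n, names = net@nodes, adj = adj, adjw = adjw,
    edges = em, ew = w, totw = sum(w)
  )
}

# Members (character) -> validated integer indices.
memberIdx <- function(idx, members) {
  i <- match(members, idx$names)
  if (anyNA(i)) {
    stop("unknown protein(s): ",
         paste(members[is.na(i)], collapse = ", "))
  }
  i
}

# Sum of weights from node u (index) into the member set flagged by inx.
wNodeSet <- function(idx, u, inx) {
  nb <- idx$adj[[u]]
  if (!length(nb)) return(0)
  sum(idx$adjw[[u]][inx[nb]])
}

# Connectivity of the subgraph induced by integer member vector x,
# using only edges with both endpoints in x (breadth-first search).
inducedConnected <- function(idx, x) {
  s <- length(x)
  if (s <= 1L) return(TRUE)
  inx <- logical(idx$n)
  inx[x] <- TRUE
  seen <- logical(idx$n)
  queue <- x[1L]
  seen[queue] <- TRUE
  count <- 1L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    nb <- idx$adj[[v]]
    nb <- nb[inx[nb] & !seen[nb]]
    if (length(nb)) {
      seen[nb] <- TRUE
      count <- count + length(nb)
      queue <- c(queue, nb)
    }
  }
  count == s
}

# ---- exported graph primitives ------------------------------------------

#' Total internal edge weight of a cluster
#'
#' Sum of the weights of the network edges with both endpoints in the
#' cluster, each unordered edge counted once. A member pair with no edge
#' contributes 0.
#'
#' @param net a [PPINetwork-class].
#' @param members character vector of cluster members (must be network
#'   nodes).
#' @return A single numeric weight sum.
#' @examples
#' net <- ppiNetwork(data.frame(a = c("A", "B"), b = c("B", "C"),
#'                              w = c(0.5, 1)))
#' clusterWeight(net, c("A", "B", "C"))
#' @export
clusterWeight <- function(net, members) {
  idx <- netIndex(net)
  x <- memberIdx(idx, members)
  inx <- logical(idx$n)
  inx[x] <- TRUE
  sum(vapply(x, wNodeSet, 0, idx = idx, inx = inx)) / 2
}

#' Weight between one protein and a cluster
#'
#' Sum of the weights of the edges joining protein \code{u} to the members
#' of the cluster. Works both for \code{u} outside the cluster (extension
#' strength) and for \code{u} inside it (attachment strength; \code{u}
#' itself contributes nothing since self-loops are absent).
#'
#' @inheritParams clusterWeight
#' @param u a single protein identifier.
#' @return A single numeric weight sum.
#' @export
nodeClusterWeight <- function(net, u, members) {
  idx <- netIndex(net)
  ui <- memberIdx(idx, u)
  if (length(ui) != 1L) stop("u must be a single protein")
  x <- memberIdx(idx, members)
  inx <- logical(idx$n)
  inx[x] <- TRUE
  wNodeSet(idx, ui, inx)
}

#' Neighboring proteins of a cluster
#'
#' Proteins outside the cluster adjacent to at least one member.
#'
#' @inheritParams clusterWeight
#' @return Character vector of neighbor identifiers (sorted).
#' @export
clusterNeighbors <- function(net, members) {
  idx <- netIndex(net)
  x <- memberIdx(idx, members)
  nb <- unique(unlist(idx$adj[x]))
  nb <- setdiff(nb, x)
  sort(idx$names[nb])
}

#' Is a cluster connected in its induced subgraph?
#'
#' TRUE when every pair of members is joined by a path using only edges
#' with both endpoints in the cluster.
#'
#' @inheritParams clusterWeight
#' @return Logical scalar.
#' @export
isClusterConnected <- function(net, members) {
  idx <- netIndex(net)
  inducedConnected(idx, memberIdx(idx, members))
}
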