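#' Construct a cluster set or complex catalogue
#'
#' Validates and canonicalizes a collection of protein sets: members are
#' sorted and must be distinct, every cluster needs at least two members,
#' and duplicate clusters are rejected.
#'
#' @param clusters list of character vectors (one vector per cluster), or
#'   a single character vector for a one-cluster set.
#' @return A [ClusterSet-class].
#' @examples
#' clusterSet(list(c("A", "B"), c("B", "C", "D")))
#' @export
clusterSet <- function(clusters = list()) {
  if (is.character(clusters)) clusters <- list(clusters)
  clusters <- lapply(clusters, function(x) sort(as.character(x)))
  new("ClusterSet", clusters = clusters)
}

#' @describeIn ClusterSet-class the clusters as a plain list of character
#'   vectors.
#' @param object,x a \code{ClusterSet}.
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname ClusterSet-class
#' @export
setMethod("clusters", "ClusterSet", function(object) object@clusters)

#' @rdname ClusterSet-class
#' @export
setMethod("length", "ClusterSet", function(x) length(x@clusters))

#' @describeIn ClusterSet-class sizes of the clusters.
#' @export
setGeneric("clusterSizes", function(object) standardGeneric("clusterSizes"))

#' @rdname ClusterSet-class
#' @export
setMethod("clusterSizes", "ClusterSet",
          function(object) lengths(object@clusters))

setMethod("show", "ClusterSet", function(object) {
  n <- length(object)
  cat("ClusterSet with", n, "clusters\n")
  if (n) {
    sz <- clusterSizes(object)
    cat("  sizes: min", min(sz), "/ median", stats::median(sz),
        "/ max", max(sz), "\n")
    cat("  distinct proteins:", length(unique(unlist(object@clusters))), "\n")
  }
})

#' Read a line-per-complex membership file
#'
#' Each non-comment line lists the members of one cluster, separated by
#' tabs (or runs of whitespace). Lines starting with \code{#} are skipped.
#'
#' @param path file path.
#' @return A [ClusterSet-class].
#' @export
readClusterSet <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  clusterSet(parts)
}

#' Write clusters in the shared line-per-complex format
#'
#' @param x a [ClusterSet-class].
#' @param path output file path.
#' @param header optional character vector of metadata lines, written
#'   first with a \code{#} prefix so the file stays parseable by
#'   [readClusterSet()].
#' @return Invisibly, \code{path}.
#' @export
writeClusterSet <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  writeLines(vapply(clusters(x), paste, "", collapse = "\t"), con)
  invisible(path)
}

# Canonical string key of one cluster / of a whole set; used for duplicate
# detection and for state occupancy tallies on small networks.
clusterKey <- function(members) paste(sort(members), collapse = "+")

clusterSetKey <- function(clusterList) {
  if (!length(clusterList)) return("{}")
  paste(sort(vapply(clusterList, clusterKey, "")), collapse = "|")
}
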