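#' Read a connectome from disk
#'
#' Reads a square adjacency matrix (headerless CSV/TSV) or a whitespace
#' delimited edge list (\code{"i j [w]"} with 0-based indices) into a
#' \linkS4class{WeightedNetwork}. Asymmetric matrix input is symmetrized by
#' the elementwise maximum with a warning.
#'
#' @param path path to the network file.
#' @param format \code{"matrix-csv"} or \code{"edge-list"}.
#' @param coords_path optional path to a coordinate table (CSV with header
#'   columns \code{node,label,x,y,z}); used to attach a
#'   \linkS4class{NodeGeometry}.
#' @param n number of nodes, required for edge lists when it cannot be
#'   inferred from a coordinate table.
#' @return a \linkS4class{WeightedNetwork}.
#' @export
readNetwork <- function(path, format = c("matrix-csv", "edge-list"),
                        coords_path = NULL, n = NULL) {
  format <- match.arg(format)
  geo <- NULL
  if (!is.null(coords_path)) {
    geo <- readGeometry(coords_path)
    n <- nNodes(geo)
  }
  if (format == "matrix-csv") {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
    a <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
    dimnames(a) <- NULL
    if (nrow(a) != ncol(a)) stop("adjacency matrix must be square")
    if (any(a < 0)) stop("negative weights are not allowed")
    if (any(a != t(a))) {
      warning("asymmetric input symmetrized by elementwise maximum")
      a <- pmax(a, t(a))
    }
    diag(a) <- 0
  } else {
    el <- utils::read.table(path, header = FALSE)
    if (is.null(n)) stop("edge-list input needs `n` or a coordinate table")
    a <- matrix(0, n, n)
    if (nrow(el) > 0) {
      i <- el[[1]] + 1L
      j <- el[[2]] + 1L
      if (any(i < 1 | i > n | j < 1 | j > n))
        stop("edge list indices out of range")
      w <- if (ncol(el) >= 3) el[[3]] else rep(1, nrow(el))
      if (any(w < 0)) stop("negative weights are not allowed")
      a[cbind(i, j)] <- w
      a <- pmax(a, t(a))
    }
  }
  if (!is.null(geo) && nNodes(geo) != nrow(a))
    stop("coordinate row count does not match network size")
  weightedNetwork(a, geo)
}

#' Read a node coordinate table
#'
#' @param path CSV file with header columns \code{node,label,x,y,z}.
#' @return a \linkS4class{NodeGeometry}, ordered by the \code{node} column.
#' @export
readGeometry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node", "label", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[order(tab$node), ]
  nodeGeometry(as.matrix(tab[, c("x", "y", "z")]), labels = tab$label)
}

#' Write a network (and its geometry) to disk
#'
#' Matrix format is headerless CSV with full double precision so that a
#' write/read round trip reproduces the adjacency exactly.
#'
#' @param net a \linkS4class{WeightedNetwork} or \linkS4class{BinaryNetwork}.
#' @param path output file for the adjacency matrix.
#' @param coords_path optional output file for the coordinate table.
#' @export
writeNetwork <- function(net, path, coords_path = NULL) {
  a <- adjacency(net)
  utils::write.table(format(a, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(coords_path)) {
    geo <- geometry(net)
    if (is.null(geo)) stop("network has no geometry to write")
    tab <- data.frame(node = seq_len(nNodes(geo)) - 1L,
                      label = nodeLabels(geo), coords(geo))
    names(tab)[3:5] <- c("x", "y", "z")
    utils::write.csv(tab, coords_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Threshold a weighted network into a binary one
#'
#' An edge is kept iff its weight is \emph{greater than or equal to} the
#' threshold (so streamline-count matrices thresholded at an absolute cutoff
#' keep ties at the cutoff). Geometry is carried over.
#'
#' @param net a \linkS4class{WeightedNetwork}.
#' @param threshold nonnegative cutoff; with \code{threshold = 0} the edge
#'   set is the nonzero support.
#' @return a \linkS4class{BinaryNetwork}.
#' @export
binarize <- function(net, threshold) {
  stopifnot(is(net, "WeightedNetwork"), threshold >= 0)
  a <- adjacency(net)
  ## >= cutoff, but absent pairs (weight 0) never become edges
  b <- 1 * (a >= threshold & a > 0)
  diag(b) <- 0
  binaryNetwork(b, geometry(net))
}

#' Euclidean distance matrix of a geometry
#'
#' @param geo a \linkS4class{NodeGeometry}.
#' @return symmetric n x n matrix of straight-line distances with zero
#'   diagonal, in the units of the coordinates.
#' @export
distanceMatrix <- function(geo) {
  stopifnot(is(geo, "NodeGeometry"))
  d <- as.matrix(stats::dist(coords(geo)))
  dimnames(d) <- NULL
  d
}

#' Connection density of a binary network
#'
#' Two denominators are exposed: \code{"standard"} = 2E / (n(n-1)), the usual
#' undirected density; \code{"directed-denominator"} = E / (n(n-1)), the
#' convention under which 400 edges on 116 nodes give 3\%. Both appear in
#' descriptions of the same protocols, so neither is silently preferred.
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @param convention \code{"standard"} or \code{"directed-denominator"}.
#' @return density as a fraction.
#' @export
edgeDensity <- function(net, convention = c("standard",
                                            "directed-denominator")) {
  convention <- match.arg(convention)
  n <- nNodes(net)
  e <- edgeCount(net)
  if (convention == "standard") 2 * e / (n * (n - 1)) else e / (n * (n - 1))
}

#' Encode and decode undirected edges as upper-triangle indices
#'
#' Edges (i, j) with i < j (1-based) are encoded as the column-major linear
#' index \code{i + (j - 1) * n} of the upper triangle of an n x n matrix.
#' Archives store per-run edge sets in this form.
#'
#' @param pairs integer m x 2 matrix of node pairs.
#' @param n number of nodes.
#' @return \code{edgeIndices}: sorted integer vector of codes;
#'   \code{indexToPairs}: m x 2 matrix with i < j.
#' @export
edgeIndices <- function(pairs, n) {
  i <- pmin(pairs[, 1], pairs[, 2])
  j <- pmax(pairs[, 1], pairs[, 2])
  sort(as.integer(i + (j - 1) * n))
}

#' @param idx integer vector of edge codes.
#' @rdname edgeIndices
#' @export
indexToPairs <- function(idx, n) {
  j <- ((idx - 1) %/% n) + 1L
  i <- idx - (j - 1L) * n
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Build a binary network from encoded edge indices
#'
#' @param idx integer vector of edge codes (see \code{\link{edgeIndices}}).
#' @param n number of nodes.
#' @param geometry optional \linkS4class{NodeGeometry}.
#' @return a \linkS4class{BinaryNetwork}.
#' @export
networkFromIndices <- function(idx, n, geometry = NULL) {
  a <- matrix(0, n, n)
  p <- indexToPairs(idx, n)
  a[p] <- 1
  a[p[, c(2, 1), drop = FALSE]] <- 1
  binaryNetwork(a, geometry)
}

#' The packaged 116-node brain-like centroid geometry
#'
#' A synthetic stand-in for a standard 116-region whole-brain parcellation:
#' bilaterally symmetric brain-shaped centroid coordinates (mm scale) with
#' conventional region labels. Shipped so that every simulation protocol can
#' run without access-restricted atlas data. The first 90 rows are the
#' cerebral regions; rows 91-116 are cerebellar/vermis regions.
#'
#' @param n either 116 (full geometry) or 90 (cerebral subset).
#' @return a \linkS4class{NodeGeometry}.
#' @export
packagedAtlas <- function(n = 116) {
  if (!n %in% c(90, 116))
    stop("packaged geometry is available for n = 116 or its 90-node subset")
  path <- system.file("extdata", "atlas116_centroids_synthetic.csv",
                      package = "stochnet", mustWork = TRUE)
  geo <- readGeometry(path)
  if (n == 90) geo <- nodeGeometry(coords(geo)[1:90, ], nodeLabels(geo)[1:90])
  geo
}
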