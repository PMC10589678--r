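#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib stochnet, .registration = TRUE
NULL

setClassUnion("NodeGeometryOrNULL", "NULL")

#' Node geometry: labels and 3-D positions
#'
#' Holds the node labels and centroid coordinates (in mm for atlas-derived
#' geometries, arbitrary units for synthetic ones) used to compute the
#' Euclidean connection costs of the wiring model.
#'
#' @slot labels character vector of unique node names.
#' @slot coords numeric matrix, one row per node, three columns (x, y, z).
#'
#' @examples
#' geo <- nodeGeometry(coords = cbind(c(0, 3), c(0, 4), c(0, 0)))
#' distanceMatrix(geo)
#' @export
setClass("NodeGeometry",
  representation(labels = "character", coords = "matrix"))

setValidity("NodeGeometry", function(object) {
  n <- nrow(object@coords)
  if (n < 2) return("geometry needs at least 2 nodes")
  if (ncol(object@coords) != 3) return("coords must have 3 columns (x, y, z)")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@labels) != n) return("labels length must match coords rows")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  TRUE
})

setIs("NodeGeometry", "NodeGeometryOrNULL")

#' @param coords numeric n x 3 matrix of node positions.
#' @param labels optional character vector of node names; defaults to
#'   \code{"n1"}, \code{"n2"}, ...
#' @rdname NodeGeometry-class
#' @export
nodeGeometry <- function(coords, labels = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (is.null(labels)) labels <- paste0("n", seq_len(nrow(coords)))
  new("NodeGeometry", labels = as.character(labels), coords = coords)
}

#' Undirected binary network
#'
#' A symmetric 0/1 adjacency matrix with zero diagonal, optionally carrying a
#' \linkS4class{NodeGeometry}. This is the object every analysis in the
#' package operates on.
#'
#' @slot adjacency integer-valued symmetric 0/1 matrix with zero diagonal.
#' @slot geometry a \linkS4class{NodeGeometry} or \code{NULL}.
#'
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
#' net <- binaryNetwork(a)
#' edgeCount(net)
#' @export
setClass("BinaryNetwork",
  representation(adjacency = "matrix", geometry = "NodeGeometryOrNULL"))

.check_square_sym <- function(a) {
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (nrow(a) < 2) return("network needs at least 2 nodes")
  if (!all(is.finite(a))) return("adjacency entries must be finite")
  if (any(a != t(a))) return("adjacency must be symmetric")
  if (any(diag(a) != 0)) return("self-loops are not allowed")
  TRUE
}

setValidity("BinaryNetwork", function(object) {
  ok <- .check_square_sym(object@adjacency)
  if (!isTRUE(ok)) return(ok)
  if (!all(object@adjacency %in% c(0, 1)))
    return("adjacency entries must be 0 or 1")
  if (!is.null(object@geometry) &&
      nrow(object@geometry@coords) != nrow(object@adjacency))
    return("geometry size does not match adjacency")
  TRUE
})

#' @param adjacency square symmetric matrix.
#' @param geometry optional \linkS4class{NodeGeometry}.
#' @rdname BinaryNetwork-class
#' @export
binaryNetwork <- function(adjacency, geometry = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- NULL
  new("BinaryNetwork", adjacency = adjacency, geometry = geometry)
}

#' Undirected weighted network
#'
#' Symmetric nonnegative adjacency (e.g. streamline counts), with optional
#' geometry. Thresholding via \code{\link{binarize}} yields a
#' \linkS4class{BinaryNetwork}.
#'
#' @slot adjacency symmetric nonnegative matrix with zero diagonal.
#' @slot geometry a \linkS4class{NodeGeometry} or \code{NULL}.
#' @export
setClass("WeightedNetwork",
  representation(adjacency = "matrix", geometry = "NodeGeometryOrNULL"))

setValidity("WeightedNetwork", function(object) {
  ok <- .check_square_sym(object@adjacency)
  if (!isTRUE(ok)) return(ok)
  if (any(object@adjacency < 0)) return("weights must be nonnegative")
  if (!is.null(object@geometry) &&
      nrow(object@geometry@coords) != nrow(object@adjacency))
    return("geometry size does not match adjacency")
  TRUE
})

#' @param adjacency square symmetric nonnegative matrix.
#' @param geometry optional \linkS4class{NodeGeometry}.
#' @rdname WeightedNetwork-class
#' @export
weightedNetwork <- function(adjacency, geometry = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  dimnames(adjacency) <- NULL
  new("WeightedNetwork", adjacency = adjacency, geometry = geometry)
}

#' Result of one generative-model run
#'
#' The grown network together with the ordered log of edge formation (seed
#' edges first), the wiring parameters, the RNG seed and any noise window, so
#' that every run is exactly reproducible and can be truncated to any
#' intermediate developmental stage.
#'
#' @slot network the final \linkS4class{BinaryNetwork}.
#' @slot edgeOrder integer m x 2 matrix of node pairs (1-based, i < j) in
#'   formation order; the first rows are the seed edges.
#' @slot eta,gamma the wiring exponents used.
#' @slot rngSeed integer seed the run was grown from.
#' @slot noise numeric length-2 vector (start, end fractions) or NULL.
#' @export
setClass("SimulationResult",
  representation(network = "BinaryNetwork", edgeOrder = "matrix",
                 eta = "numeric", gamma = "numeric", rngSeed = "numeric",
                 noise = "ANY"))

setValidity("SimulationResult", function(object) {
  eo <- object@edgeOrder
  if (ncol(eo) != 2) return("edgeOrder must have two columns")
  n <- nrow(object@network@adjacency)
  key <- (pmin(eo[, 1], eo[, 2]) - 1) * n + pmax(eo[, 1], eo[, 2])
  if (anyDuplicated(key)) return("edgeOrder contains duplicate edges")
  if (nrow(eo) != sum(object@network@adjacency) / 2)
    return("edgeOrder does not match the network's edge set size")
  TRUE
})

#' Archive of a repeated-runs parameter sweep
#'
#' All repetitions at all (eta, gamma) grid cells: per-run five-metric
#' topology profiles, per-run edge sets (encoded as upper-triangle linear
#' indices), per-run seeds, and a manifest sufficient to regenerate the
#' archive bit-identically.
#'
#' @slot eta,gamma numeric vectors of grid values.
#' @slot reps integer repetitions per cell.
#' @slot nNodes,mTarget integer network size and stop criterion (edge count).
#' @slot profiles data.frame with one row per run: eta, gamma, rep, seed and
#'   the five topology metrics.
#' @slot edgeSets list (one per run, same order as \code{profiles}) of sorted
#'   integer edge codes, see \code{\link{edgeIndices}}.
#' @slot manifest list recording grid, reps, master seed, noise window,
#'   normalization policy and package version.
#' @export
setClass("SweepArchive",
  representation(eta = "numeric", gamma = "numeric", reps = "integer",
                 nNodes = "integer", mTarget = "integer",
                 profiles = "data.frame", edgeSets = "list",
                 manifest = "list"))

setValidity("SweepArchive", function(object) {
  nruns <- length(object@eta) * length(object@gamma) * object@reps
  if (nrow(object@profiles) != nruns)
    return("profiles must have one row per run")
  if (length(object@edgeSets) != nruns)
    return("edgeSets must have one entry per run")
  TRUE
})

#' Rich-club curve with degree-preserving null calibration
#'
#' Per degree threshold k: the rich-club coefficient phi(k), the mean of
#' phi over rewired null networks, the normalized coefficient
#' phi(k)/<phi_rand(k)> and one-sided permutation p-values. Levels with fewer
#' than two qualifying nodes are flagged undefined rather than fabricated.
#'
#' @slot table data.frame with columns \code{k}, \code{n_nodes},
#'   \code{n_edges}, \code{phi}, \code{phi_rand_mean}, \code{phi_norm},
#'   \code{p_perm} (rank/n_nulls, the plain rank form),
#'   \code{p_perm_smoothed} ((1 + #nulls >= empirical)/(1 + n_nulls)) and
#'   logical \code{defined}.
#' @slot nNulls integer number of null networks used.
#' @export
setClass("RichClubCurve",
  representation(table = "data.frame", nNulls = "integer"))
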