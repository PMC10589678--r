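#' Accessors for network objects
#'
#' @param x a network, geometry, simulation result or archive object.
#' @name accessors
NULL

#' @describeIn accessors the adjacency matrix.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @export
setMethod("adjacency", "BinaryNetwork", function(x) x@adjacency)
#' @export
setMethod("adjacency", "WeightedNetwork", function(x) x@adjacency)

#' @describeIn accessors the \linkS4class{NodeGeometry} (or NULL).
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @export
setMethod("geometry", "BinaryNetwork", function(x) x@geometry)
#' @export
setMethod("geometry", "WeightedNetwork", function(x) x@geometry)
#' @export
setMethod("geometry", "SimulationResult", function(x) x@network@geometry)

#' @describeIn accessors number of nodes.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @export
setMethod("nNodes", "BinaryNetwork", function(x) nrow(x@adjacency))
#' @export
setMethod("nNodes", "WeightedNetwork", function(x) nrow(x@adjacency))
#' @export
setMethod("nNodes", "NodeGeometry", function(x) nrow(x@coords))
#' @export
setMethod("nNodes", "SweepArchive", function(x) as.integer(x@nNodes))

#' @describeIn accessors number of (undirected) edges.
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @export
setMethod("edgeCount", "BinaryNetwork", function(x) sum(x@adjacency) / 2)
#' @export
setMethod("edgeCount", "WeightedNetwork", function(x) sum(x@adjacency > 0) / 2)

#' @describeIn accessors node labels (NULL when no geometry is attached).
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @export
setMethod("nodeLabels", "NodeGeometry", function(x) x@labels)
#' @export
setMethod("nodeLabels", "BinaryNetwork",
          function(x) if (is.null(x@geometry)) NULL else x@geometry@labels)
#' @export
setMethod("nodeLabels", "WeightedNetwork",
          function(x) if (is.null(x@geometry)) NULL else x@geometry@labels)

#' @describeIn accessors coordinates matrix of a geometry.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @export
setMethod("coords", "NodeGeometry", function(x) x@coords)

#' @describeIn accessors ordered edge-formation log of a simulation.
#' @export
setGeneric("edgeOrder", function(x) standardGeneric("edgeOrder"))

#' @export
setMethod("edgeOrder", "SimulationResult", function(x) x@edgeOrder)

#' @describeIn accessors per-run topology-profile table of an archive.
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @export
setMethod("profiles", "SweepArchive", function(x) x@profiles)

#' @describeIn accessors per-run edge sets of an archive (encoded, see
#'   \code{\link{edgeIndices}}).
#' @export
setGeneric("edgeSets", function(x) standardGeneric("edgeSets"))

#' @export
setMethod("edgeSets", "SweepArchive", function(x) x@edgeSets)

#' @describeIn accessors reproducibility manifest of an archive.
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @export
setMethod("manifest", "SweepArchive", function(x) x@manifest)

#' @describeIn accessors rich-club curve table.
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @export
setMethod("curveTable", "RichClubCurve", function(x) x@table)

setMethod("show", "NodeGeometry", function(object) {
  cat("NodeGeometry with", nrow(object@coords), "nodes\n")
  cat("  labels:", paste(utils::head(object@labels, 3), collapse = ", "),
      if (length(object@labels) > 3) "..." else "", "\n")
})

setMethod("show", "BinaryNetwork", function(object) {
  cat("BinaryNetwork:", nrow(object@adjacency), "nodes,",
      sum(object@adjacency) / 2, "edges",
      if (is.null(object@geometry)) "(no geometry)" else "(with geometry)",
      "\n")
})

setMethod("show", "WeightedNetwork", function(object) {
  a <- object@adjacency
  cat("WeightedNetwork:", nrow(a), "nodes,", sum(a > 0) / 2,
      "weighted edges; weight range [", min(a[a > 0], 0), ",", max(a), "]\n")
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult: eta =", object@eta, ", gamma =", object@gamma,
      ", seed =", object@rngSeed, "\n  ")
  show(object@network)
  if (!is.null(object@noise))
    cat("  noise window: [", object@noise[1], ",", object@noise[2], ")\n")
})

setMethod("show", "SweepArchive", function(object) {
  cat("SweepArchive:", length(object@eta), "x", length(object@gamma),
      "grid,", object@reps, "reps/cell (",
      nrow(object@profiles), "runs of", object@mTarget, "edges on",
      object@nNodes, "nodes )\n")
})

setMethod("show", "RichClubCurve", function(object) {
  tab <- object@table
  sig <- sum(tab$defined & tab$phi_norm > 1 & tab$p_perm < 0.05)
  cat("RichClubCurve over", nrow(tab), "degree levels (",
      object@nNulls, "nulls );", sig,
      "levels with phi_norm > 1 and p_perm < 0.05\n")
})
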