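.as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(adjacency(net), mode = "undirected",
                                      diag = FALSE)
}

## run code with its own RNG stream without disturbing the caller's
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Matching index (homophily) matrix
#'
#' The matching index of nodes i and j is the normalized overlap of their
#' neighborhoods with i and j excluded from each other's neighbor sets:
#' \deqn{m_{ij} = |\Gamma_{i/j} \cap \Gamma_{j/i}| /
#'               |\Gamma_{i/j} \cup \Gamma_{j/i}|,}
#' the "value" term of the homophily wiring rule. Pairs whose neighborhood
#' union is empty get 0; the diagonal is 0.
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @return symmetric n x n matrix with entries in [0, 1].
#' @examples
#' tri <- binaryNetwork(1 - diag(3))
#' matchingMatrix(tri)  # every pair has perfect neighborhood overlap
#' @export
matchingMatrix <- function(net) {
  a <- adjacency(net)
  deg <- rowSums(a)
  cn <- a %*% a                    # common neighbors; k != i, j automatically
  un <- outer(deg, deg, "+") - 2 * a - cn
  m <- ifelse(un > 0, cn / un, 0)
  diag(m) <- 0
  m
}

#' Five-metric global topology profile
#'
#' Computes the five global measures used throughout the dissimilarity
#' analyses: mean nodal clustering coefficient, mean nodal betweenness
#' centrality (unit edge lengths), total Euclidean edge length, global
#' efficiency and Louvain modularity Q. The Louvain pass is seeded so the
#' profile is deterministic. Empty graphs return an all-zero profile.
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @param dist distance matrix matching \code{net} (from
#'   \code{\link{distanceMatrix}}); \code{NULL} is allowed when the network
#'   carries geometry.
#' @param mod_seed RNG seed for the Louvain community detection.
#' @return named numeric vector: \code{clustering}, \code{betweenness},
#'   \code{total_edge_length}, \code{efficiency}, \code{modularity}.
#' @export
topologyProfile <- function(net, dist = NULL, mod_seed = 42L) {
  a <- adjacency(net)
  if (is.null(dist)) {
    if (is.null(geometry(net)))
      stop("supply `dist` or a network with geometry")
    dist <- distanceMatrix(geometry(net))
  }
  if (nrow(dist) != nrow(a)) stop("distance matrix size mismatch")
  out <- c(clustering = 0, betweenness = 0, total_edge_length = 0,
           efficiency = 0, modularity = 0)
  if (sum(a) == 0) return(out)
  g <- .as_igraph(binaryNetwork(a))
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  out["clustering"] <- mean(cl)
  out["betweenness"] <- mean(igraph::betweenness(g, directed = FALSE))
  out["total_edge_length"] <- sum(dist[upper.tri(dist)] * a[upper.tri(a)])
  out["efficiency"] <- igraph::global_efficiency(g, directed = FALSE)
  comm <- .with_seed(mod_seed, igraph::cluster_louvain(g))
  out["modularity"] <- igraph::modularity(g, igraph::membership(comm))
  out
}

#' Network communicability
#'
#' The sum of all entries of the matrix exponential of the binary adjacency
#' matrix: a whole-network measure of communication capacity that counts
#' walks of all lengths with factorial damping. Always at least n, since the
#' diagonal of exp(A) is at least 1.
#'
#' @param net a \linkS4class{BinaryNetwork} or a plain symmetric 0/1 matrix.
#' @return a single nonnegative number.
#' @examples
#' communicability(binaryNetwork(matrix(0, 3, 3)))  # identity sum = 3
#' @export
communicability <- function(net) {
  a <- if (is(net, "BinaryNetwork")) adjacency(net) else net
  e <- eigen(a, symmetric = TRUE)
  colsum <- colSums(e$vectors)
  sum(exp(e$values) * colsum^2)
}
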