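## additive offset inside (m + eps)^gamma keeping zero-matching pairs reachable
.MATCH_EPS <- 1e-6

## d^eta with the 0^0 = 1 convention (eta = 0 disables the distance factor)
.dist_pow <- function(d, eta) {
  if (eta == 0) return(matrix(1, nrow(d), ncol(d)))
  offdiag <- d[row(d) != col(d)]
  if (eta < 0 && any(offdiag == 0))
    stop("zero distance between distinct nodes with a negative eta")
  p <- d^eta
  diag(p) <- 0
  p
}

## deterministic per-run seed stream: 32-bit mixing of (master, indices)
.derive_seed <- function(master, ...) {
  h <- as.double(master) %% 2147483647
  for (x in c(...)) h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

#' Wiring probabilities of the generative model
#'
#' For every unconnected pair (i < j) the wiring probability is proportional
#' to \eqn{d_{ij}^{\eta} (m_{ij} + \epsilon)^{\gamma}}: a distance penalty
#' (eta, typically negative) times a homophily preference on the matching
#' index (gamma, typically positive). A small offset epsilon keeps
#' zero-matching pairs reachable when gamma > 0, and 0^0 is taken as 1 so
#' that a zero exponent disables its factor.
#'
#' @param current the current \linkS4class{BinaryNetwork}.
#' @param dist distance matrix.
#' @param eta,gamma wiring exponents.
#' @param eps additive matching offset (default 1e-6).
#' @return data.frame with columns \code{i}, \code{j} (1-based, i < j, in
#'   column-major upper-triangle order) and \code{p}, summing to 1 over the
#'   eligible pairs.
#' @export
wiringProbabilities <- function(current, dist, eta, gamma,
                                eps = .MATCH_EPS) {
  a <- adjacency(current)
  n <- nrow(a)
  if (nrow(dist) != n) stop("distance matrix size mismatch")
  ut <- upper.tri(a)
  eligible <- which(a == 0 & ut)
  if (length(eligible) == 0) stop("network is complete: no eligible pairs")
  m <- matchingMatrix(current)
  w <- .dist_pow(dist, eta) * (m + eps)^gamma
  p <- w[eligible]
  if (!all(is.finite(p))) stop("non-finite wiring weights")
  p <- p / sum(p)
  j <- ((eligible - 1) %/% n) + 1L
  i <- eligible - (j - 1L) * n
  data.frame(i = as.integer(i), j = as.integer(j), p = p)
}

#' Grow a network with the generative model
#'
#' Starting from a fixed seed scaffold, edges are added one at a time, each
#' sampled from the wiring probabilities recomputed after every addition,
#' until \code{m_target} edges exist. Inside an optional noise window
#' (fractions of the final edge count, seed edges included in the count) the
#' next edge is instead drawn uniformly among eligible pairs, emulating a
#' temporary burst of developmental noise. Fully reproducible from
#' \code{rng_seed}.
#'
#' @param seed_net the seed \linkS4class{BinaryNetwork} (edges never removed).
#' @param dist distance matrix.
#' @param eta,gamma wiring exponents.
#' @param m_target final edge count (>= seed edges, <= n(n-1)/2).
#' @param rng_seed integer seed.
#' @param noise \code{NULL} or numeric \code{c(start, end)} fractions with
#'   0 <= start < end <= 1 (see \code{\link{noiseSchedule}}).
#' @param eps additive matching offset.
#' @return a \linkS4class{SimulationResult}.
#' @export
simulateNetwork <- function(seed_net, dist, eta, gamma, m_target, rng_seed,
                            noise = NULL, eps = .MATCH_EPS) {
  a <- adjacency(seed_net)
  n <- nrow(a)
  if (nrow(dist) != n) stop("distance matrix size mismatch")
  seed_edges <- which(a == 1 & upper.tri(a))
  sj <- ((seed_edges - 1) %/% n) + 1L
  si <- seed_edges - (sj - 1L) * n
  se <- cbind(as.integer(si), as.integer(sj))
  if (m_target < nrow(se)) stop("m_target below seed edge count")
  if (m_target > n * (n - 1) / 2) stop("m_target exceeds network capacity")
  if (!is.null(noise)) {
    stopifnot(length(noise) == 2, noise[1] >= 0, noise[2] <= 1,
              noise[1] <= noise[2])
    lo <- noise[1]; hi <- noise[2]
  } else {
    lo <- 0; hi <- -1
  }
  Deta <- .dist_pow(dist, eta)
  ord <- .with_seed(rng_seed,
    cpp_simulate(se, n, Deta, gamma, eps, as.integer(m_target), lo, hi))
  adj <- matrix(0, n, n)
  adj[ord] <- 1
  adj[ord[, c(2, 1), drop = FALSE]] <- 1
  new("SimulationResult",
      network = binaryNetwork(adj, geometry(seed_net)),
      edgeOrder = ord, eta = eta, gamma = gamma,
      rngSeed = as.numeric(rng_seed), noise = noise)
}

#' Repeated-runs sweep over the wiring parameter grid
#'
#' Runs \code{reps} seeded simulations at every (eta, gamma) grid cell and
#' records each run's five-metric topology profile and edge set. Per-run
#' seeds are derived deterministically from \code{master_seed} and the cell /
#' repetition indices, so the archive is bit-reproducible from its manifest.
#'
#' @param seed_net seed \linkS4class{BinaryNetwork}.
#' @param dist distance matrix.
#' @param eta_grid,gamma_grid numeric vectors of grid values (the reference
#'   protocol covers eta in [-4, 0], gamma in [0, 1]).
#' @param reps repetitions per cell (>= 2).
#' @param m_target stop criterion (edge count).
#' @param master_seed integer master seed.
#' @param noise optional noise window applied to every run.
#' @param mod_seed Louvain seed used for the modularity metric.
#' @param progress print a line per grid cell.
#' @return a \linkS4class{SweepArchive}.
#' @export
parameterSweep <- function(seed_net, dist, eta_grid, gamma_grid, reps,
                           m_target, master_seed, noise = NULL,
                           mod_seed = 42L, progress = FALSE) {
  stopifnot(length(eta_grid) >= 1, length(gamma_grid) >= 1, reps >= 2)
  n <- nNodes(seed_net)
  ncell <- length(eta_grid) * length(gamma_grid)
  nruns <- ncell * reps
  prof <- vector("list", nruns)
  esets <- vector("list", nruns)
  run <- 0L
  for (gi in seq_along(gamma_grid)) for (ei in seq_along(eta_grid)) {
    if (progress)
      message(sprintf("cell eta=%.3f gamma=%.3f", eta_grid[ei],
                      gamma_grid[gi]))
    for (r in seq_len(reps)) {
      run <- run + 1L
      s <- .derive_seed(master_seed, ei, gi, r)
      sim <- simulateNetwork(seed_net, dist, eta_grid[ei], gamma_grid[gi],
                             m_target, s, noise = noise)
      tp <- topologyProfile(sim@network, dist, mod_seed = mod_seed)
      prof[[run]] <- data.frame(eta = eta_grid[ei], gamma = gamma_grid[gi],
                                eta_idx = ei, gamma_idx = gi, rep = r,
                                seed = s, t(tp))
      esets[[run]] <- edgeIndices(sim@edgeOrder, n)
    }
  }
  profiles <- do.call(rbind, prof)
  rownames(profiles) <- NULL
  man <- list(eta_grid = eta_grid, gamma_grid = gamma_grid, reps = reps,
              n_nodes = n, m_target = m_target, master_seed = master_seed,
              noise = noise, mod_seed = mod_seed,
              eps = .MATCH_EPS, normalization = "global",
              package_version = as.character(utils::packageVersion("stochnet")))
  new("SweepArchive", eta = eta_grid, gamma = gamma_grid,
      reps = as.integer(reps), nNodes = as.integer(n),
      mTarget = as.integer(m_target), profiles = profiles,
      edgeSets = esets, manifest = man)
}

#' Persist / restore a sweep archive as plain text
#'
#' An archive directory holds \code{manifest.json}, \code{profiles.csv} and
#' \code{edge_sets.txt} (one space-separated line of edge codes per run).
#'
#' @param archive a \linkS4class{SweepArchive}.
#' @param dir directory to write (created if missing).
#' @export
saveArchive <- function(archive, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(archive@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(archive@profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  writeLines(vapply(archive@edgeSets, paste, "", collapse = " "),
             file.path(dir, "edge_sets.txt"))
  invisible(dir)
}

#' @param dir archive directory written by \code{saveArchive}.
#' @rdname saveArchive
#' @export
loadArchive <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  profiles <- utils::read.csv(file.path(dir, "profiles.csv"))
  lines <- readLines(file.path(dir, "edge_sets.txt"))
  esets <- lapply(strsplit(lines, " ", fixed = TRUE), as.integer)
  noise <- man$noise
  if (length(noise) == 0) noise <- NULL
  new("SweepArchive", eta = as.numeric(man$eta_grid),
      gamma = as.numeric(man$gamma_grid), reps = as.integer(man$reps),
      nNodes = as.integer(man$n_nodes), mTarget = as.integer(man$m_target),
      profiles = profiles, edgeSets = esets,
      manifest = c(man[setdiff(names(man), "noise")], list(noise = noise)))
}

.metric_cols <- c("clustering", "betweenness", "total_edge_length",
                  "efficiency", "modularity")
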