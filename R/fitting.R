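#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Maximum absolute difference between the empirical CDFs of two samples
#' (ties handled exactly); the building block of the model-fit energy.
#'
#' @param x,y numeric samples.
#' @return the KS statistic in [0, 1].
#' @export
ksStatistic <- function(x, y) cpp_ks(as.numeric(x), as.numeric(y))

.nodal_stat_list <- function(net) {
  a <- adjacency(net)
  n <- nrow(a)
  idx <- which(a == 1 & upper.tri(a))
  j <- ((idx - 1) %/% n) + 1L
  i <- idx - (j - 1L) * n
  st <- cpp_nodal_stats(cbind(as.integer(i), as.integer(j)), n)
  st$pairs <- cbind(i, j)
  st
}

#' Kolmogorov-Smirnov fit energy between two networks
#'
#' The maximum of the four two-sample KS statistics between the observed and
#' simulated distributions of nodal degree, nodal clustering, nodal
#' betweenness and edge Euclidean length — the standard fit measure of this
#' generative-model family. 0 for identical distributions; bounded by 1.
#'
#' @param observed,simulated \linkS4class{BinaryNetwork}s over the same n
#'   nodes.
#' @param dist distance matrix (for edge lengths).
#' @return energy in [0, 1].
#' @export
ksEnergy <- function(observed, simulated, dist) {
  if (nNodes(observed) != nNodes(simulated)) stop("networks differ in size")
  so <- .nodal_stat_list(observed)
  ss <- .nodal_stat_list(simulated)
  lo <- dist[so$pairs]
  ls <- dist[ss$pairs]
  max(ksStatistic(so$degree, ss$degree),
      ksStatistic(so$clustering, ss$clustering),
      ksStatistic(so$betweenness, ss$betweenness),
      ksStatistic(lo, ls))
}

#' Shared simulation landscapes for cohort fitting
#'
#' Simulates every grid cell up to \code{m_max} edges, \code{n_landscapes}
#' times with derived seeds, keeping the full edge-formation order so a
#' single landscape serves subjects with any edge count (each subject's fit
#' truncates the order at the subject's edge count). Landscapes are shared
#' across subjects and cohorts with the same inputs.
#'
#' @inheritParams parameterSweep
#' @param n_landscapes number of seeded landscape replicates (reference
#'   protocol: 50).
#' @param m_max maximum edge count any subject will need.
#' @return list with \code{eta_grid}, \code{gamma_grid}, \code{orders}
#'   (landscape x cell list of edge-order matrices) and metadata.
#' @export
buildLandscapes <- function(seed_net, dist, eta_grid, gamma_grid,
                            n_landscapes = 50, m_max, master_seed,
                            progress = FALSE) {
  cells <- expand.grid(ei = seq_along(eta_grid), gi = seq_along(gamma_grid))
  orders <- lapply(seq_len(n_landscapes), function(l) {
    if (progress) message("landscape ", l, "/", n_landscapes)
    lapply(seq_len(nrow(cells)), function(ci) {
      s <- .derive_seed(master_seed, l, cells$ei[ci], cells$gi[ci])
      simulateNetwork(seed_net, dist, eta_grid[cells$ei[ci]],
                      gamma_grid[cells$gi[ci]], m_max, s)@edgeOrder
    })
  })
  list(eta_grid = eta_grid, gamma_grid = gamma_grid, cells = cells,
       orders = orders, m_max = m_max, master_seed = master_seed,
       n_nodes = nNodes(seed_net))
}

#' Fit wiring parameters to one observed connectome
#'
#' For each landscape replicate, every grid cell's simulation is truncated to
#' the subject's edge count and the cell minimizing the KS energy against the
#' observed network is selected; the estimate is the mean best (eta, gamma)
#' across landscapes and the mean of the per-landscape best energies.
#'
#' @param observed a \linkS4class{BinaryNetwork}.
#' @param landscapes output of \code{\link{buildLandscapes}}.
#' @param dist distance matrix.
#' @return list with \code{eta_hat}, \code{gamma_hat}, \code{energy},
#'   \code{n_landscapes} and the per-landscape best table.
#' @export
fitSubject <- function(observed, landscapes, dist) {
  m_subj <- edgeCount(observed)
  if (m_subj > landscapes$m_max)
    stop("subject edge count exceeds landscape m_max")
  st <- .nodal_stat_list(observed)
  od <- sort(st$degree); oc <- sort(st$clustering); ob <- sort(st$betweenness)
  ol <- sort(dist[st$pairs])
  n <- landscapes$n_nodes
  cells <- landscapes$cells
  best <- lapply(seq_along(landscapes$orders), function(l) {
    en <- vapply(landscapes$orders[[l]], function(ord)
      cpp_fit_energy(ord, as.integer(m_subj), as.integer(n), dist,
                     od, oc, ob, ol), 0)
    k <- which.min(en)
    data.frame(landscape = l, eta = landscapes$eta_grid[cells$ei[k]],
               gamma = landscapes$gamma_grid[cells$gi[k]], energy = en[k])
  })
  best <- do.call(rbind, best)
  list(eta_hat = mean(best$eta), gamma_hat = mean(best$gamma),
       energy = mean(best$energy), n_landscapes = nrow(best),
       per_landscape = best)
}

#' Fit a whole cohort over shared landscapes
#'
#' @param networks list of observed \linkS4class{BinaryNetwork}s.
#' @param landscapes output of \code{\link{buildLandscapes}}.
#' @param dist distance matrix.
#' @param ids optional subject identifiers.
#' @return data.frame with one row per subject: \code{id}, \code{eta_hat},
#'   \code{gamma_hat}, \code{energy}, \code{edge_count},
#'   \code{n_landscapes}.
#' @export
fitCohort <- function(networks, landscapes, dist, ids = NULL) {
  if (is.null(ids)) ids <- paste0("s", seq_along(networks))
  out <- lapply(seq_along(networks), function(k) {
    f <- fitSubject(networks[[k]], landscapes, dist)
    data.frame(id = ids[k], eta_hat = f$eta_hat, gamma_hat = f$gamma_hat,
               energy = f$energy, edge_count = edgeCount(networks[[k]]),
               n_landscapes = f$n_landscapes)
  })
  do.call(rbind, out)
}

#' Median split on a deprivation score
#'
#' Subjects with deprivation strictly above the sample median form the
#' low-SES group; those at or below it (including ties at the median) form
#' the high-SES group.
#'
#' @param deprivation numeric scores, higher = more deprived.
#' @return factor with levels \code{"high"} and \code{"low"} (SES).
#' @export
medianSplit <- function(deprivation) {
  stopifnot(length(deprivation) >= 2)
  med <- stats::median(deprivation)
  if (all(deprivation == deprivation[1]))
    stop("all deprivation scores identical: no split possible")
  factor(ifelse(deprivation > med, "low", "high"), levels = c("high", "low"))
}

#' Two-sample group comparison with effect size
#'
#' Student's two-sample t-test (pooled variance; Welch via \code{welch =
#' TRUE}) and pooled-SD Cohen's d, signed as mean(high) - mean(low).
#'
#' @param values per-subject statistic.
#' @param groups factor with levels \code{"high"} and \code{"low"}.
#' @param welch use the Welch (unequal-variance) test.
#' @return list with \code{t}, \code{df}, \code{p_value}, \code{cohens_d},
#'   \code{mean_high}, \code{mean_low}.
#' @export
groupComparison <- function(values, groups, welch = FALSE) {
  groups <- factor(groups, levels = c("high", "low"))
  x <- values[groups == "high"]
  y <- values[groups == "low"]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 subjects per group")
  tt <- stats::t.test(x, y, var.equal = !welch)
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) /
             (length(x) + length(y) - 2))
  d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, cohens_d = d,
       mean_high = mean(x), mean_low = mean(y))
}

#' Permutation test of a group mean difference
#'
#' Null distribution of the absolute mean group difference under random
#' relabeling; the p-value is the rank position of the empirical value
#' (reported both as plain rank/n_perm and with +1 smoothing).
#'
#' @param values per-subject statistic.
#' @param groups two-level factor.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param rng_seed integer seed.
#' @return list with \code{p_perm} (rank form), \code{p_perm_smoothed},
#'   \code{observed} (absolute mean difference) and \code{null} (the null
#'   distribution).
#' @export
permutationTest <- function(values, groups, n_perm = 1000, rng_seed = 1) {
  stopifnot(n_perm >= 100)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  g1 <- groups == levels(groups)[1]
  if (sum(g1) == 0 || sum(!g1) == 0) stop("degenerate groups")
  obs <- abs(mean(values[g1]) - mean(values[!g1]))
  n1 <- sum(g1)
  null <- .with_seed(rng_seed, vapply(seq_len(n_perm), function(b) {
    sel <- sample.int(length(values), n1)
    abs(mean(values[sel]) - mean(values[-sel]))
  }, 0))
  ge <- sum(null >= obs)
  list(p_perm = max(ge, 1) / n_perm,
       p_perm_smoothed = (1 + ge) / (1 + n_perm),
       observed = obs, null = null)
}
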