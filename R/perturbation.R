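#' Canonical noise windows
#'
#' The three developmental stages at which a 5\%-of-edges burst of purely
#' random wiring is injected: early (5-10\% of network development), middle
#' (47.5-52.5\%) and late (90-95\%). Fractions count all edges including the
#' seed.
#'
#' @param timing \code{"early"}, \code{"middle"} or \code{"late"}.
#' @return numeric \code{c(start, end)} window.
#' @export
noiseSchedule <- function(timing = c("early", "middle", "late")) {
  timing <- match.arg(timing)
  switch(timing,
         early = c(0.05, 0.10),
         middle = c(0.475, 0.525),
         late = c(0.90, 0.95))
}

#' Timed noise-injection experiment
#'
#' Runs a baseline sweep plus one sweep per noise timing with matched grid,
#' repetitions and the SAME per-run seeds (common random numbers: a noise run
#' replays its baseline trajectory exactly until the noise window opens), and
#' returns per-cell change scores: the noise-condition dissimilarity minus
#' the matched baseline dissimilarity, for both the topological and the
#' embedding measure.
#'
#' @inheritParams parameterSweep
#' @param timings character vector of timings to test.
#' @return data.frame with columns \code{eta}, \code{gamma}, \code{timing},
#'   \code{delta_topo}, \code{delta_embed}, \code{topo_noise},
#'   \code{topo_base}, \code{embed_noise}, \code{embed_base}.
#' @export
noiseExperiment <- function(seed_net, dist, eta_grid, gamma_grid, reps,
                            m_target, master_seed,
                            timings = c("early", "middle", "late"),
                            progress = FALSE) {
  base <- parameterSweep(seed_net, dist, eta_grid, gamma_grid, reps,
                         m_target, master_seed, noise = NULL,
                         progress = progress)
  base_tab <- dissimilarityLandscape(base)
  out <- lapply(timings, function(tm) {
    sw <- parameterSweep(seed_net, dist, eta_grid, gamma_grid, reps,
                         m_target, master_seed,
                         noise = noiseSchedule(tm), progress = progress)
    tab <- dissimilarityLandscape(sw)
    data.frame(eta = tab$eta, gamma = tab$gamma, timing = tm,
               delta_topo = tab$topo_dissim - base_tab$topo_dissim,
               delta_embed = tab$embed_dissim - base_tab$embed_dissim,
               topo_noise = tab$topo_dissim, topo_base = base_tab$topo_dissim,
               embed_noise = tab$embed_dissim,
               embed_base = base_tab$embed_dissim)
  })
  do.call(rbind, out)
}

#' One-way ANOVA across noise timings
#'
#' Tests whether the per-cell change scores differ across the early / middle /
#' late timing groups. Change scores (noise minus matched baseline) are the
#' default response; raw noise-condition scores are available via
#' \code{raw = TRUE}.
#'
#' @param table output of \code{\link{noiseExperiment}}.
#' @param response \code{"delta_topo"} or \code{"delta_embed"}.
#' @param raw use the raw noise-condition score instead of the change score.
#' @return list with \code{F}, \code{df}, \code{p_value} and a
#'   \code{group_stats} data.frame (mean, SD, n per timing).
#' @export
timingAnova <- function(table, response = c("delta_topo", "delta_embed"),
                        raw = FALSE) {
  response <- match.arg(response)
  col <- if (raw) sub("delta_(topo|embed)", "\\1_noise", response) else response
  y <- table[[col]]
  g <- factor(table$timing)
  if (any(tabulate(g) < 2)) stop("need >= 2 cells per timing group")
  fit <- stats::aov(y ~ g)
  an <- stats::anova(fit)
  gs <- do.call(rbind, lapply(levels(g), function(l) {
    v <- y[g == l]
    data.frame(timing = l, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  list(F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
       p_value = an[1, "Pr(>F)"], group_stats = gs)
}

#' Attack trajectory of log-communicability
#'
#' Nodes are removed one at a time — in descending order of initial degree
#' (ties by ascending index) for the targeted regime, or in a seeded uniform
#' random order — by zeroing their connectivity, and ln(communicability) is
#' recorded at steps 0..n_steps. The ranking is computed once on the intact
#' network.
#'
#' @param net a \linkS4class{BinaryNetwork}.
#' @param regime \code{"targeted"} or \code{"random"}.
#' @param n_steps number of removals (< n); default 25\% of nodes.
#' @param rng_seed seed for the random regime.
#' @return list with \code{regime}, \code{order} (full removal ranking),
#'   \code{lnC} (length n_steps + 1) and \code{beta} (slope over the full
#'   recorded window, per removed node).
#' @export
attackTrajectory <- function(net, regime = c("targeted", "random"),
                             n_steps = NULL, rng_seed = 1) {
  regime <- match.arg(regime)
  a <- adjacency(net)
  n <- nrow(a)
  if (is.null(n_steps)) n_steps <- round(0.25 * n)
  stopifnot(n_steps >= 1, n_steps < n)
  ord <- if (regime == "targeted") {
    deg <- rowSums(a)
    order(-deg, seq_len(n))
  } else {
    .with_seed(rng_seed, sample.int(n))
  }
  lnC <- as.numeric(cpp_attack_lnC(a, as.integer(ord), as.integer(n_steps)))
  traj <- list(regime = regime, order = ord, lnC = lnC,
               beta = .ols_slope(0:n_steps, lnC))
  traj
}

.ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Robustness slope of an attack trajectory
#'
#' OLS slope of ln(communicability) on the number of removed nodes over steps
#' 0..window (intact network included). More negative = less robust.
#'
#' @param traj output of \code{\link{attackTrajectory}}.
#' @param window number of removals to fit over (default: all recorded).
#' @return the slope (per removed node).
#' @export
robustnessBeta <- function(traj, window = NULL) {
  if (is.null(window)) window <- length(traj$lnC) - 1
  stopifnot(window >= 2, window <= length(traj$lnC) - 1)
  .ols_slope(0:window, traj$lnC[1:(window + 1)])
}

#' Attack-robustness landscape over a sweep archive
#'
#' Mean robustness slope per grid cell. The random regime averages
#' \code{reps_random} seeded node orders per run. To bound cost on large
#' archives, at most \code{max_reps} runs per cell are used.
#'
#' @param archive a \linkS4class{SweepArchive}.
#' @param regime \code{"targeted"} or \code{"random"}.
#' @param window_frac fraction of nodes fitted over (default 0.25, i.e. 29
#'   nodes for a 116-node network).
#' @param reps_random random node orders per run in the random regime.
#' @param max_reps runs per cell entering the average (default: all).
#' @param rng_seed master seed for random orders.
#' @return data.frame with \code{eta}, \code{gamma}, \code{beta} and
#'   \code{lnC0} (mean intact log-communicability per cell).
#' @export
robustnessLandscape <- function(archive, regime = c("targeted", "random"),
                                window_frac = 0.25, reps_random = 25,
                                max_reps = NULL, rng_seed = 1) {
  regime <- match.arg(regime)
  n <- nNodes(archive)
  n_steps <- round(window_frac * n)
  prof <- profiles(archive)
  esets <- edgeSets(archive)
  if (is.null(max_reps)) max_reps <- archive@reps
  cells <- unique(prof[, c("eta", "gamma", "eta_idx", "gamma_idx")])
  out <- lapply(seq_len(nrow(cells)), function(ci) {
    sel <- which(prof$eta_idx == cells$eta_idx[ci] &
                 prof$gamma_idx == cells$gamma_idx[ci])
    sel <- sel[seq_len(min(max_reps, length(sel)))]
    betas <- lnC0 <- numeric(0)
    for (ri in sel) {
      net <- networkFromIndices(esets[[ri]], n)
      if (regime == "targeted") {
        tr <- attackTrajectory(net, "targeted", n_steps)
        betas <- c(betas, tr$beta)
        lnC0 <- c(lnC0, tr$lnC[1])
      } else {
        for (rr in seq_len(reps_random)) {
          tr <- attackTrajectory(net, "random", n_steps,
                                 rng_seed = .derive_seed(rng_seed, ci, ri, rr))
          betas <- c(betas, tr$beta)
          lnC0 <- c(lnC0, tr$lnC[1])
        }
      }
    }
    data.frame(eta = cells$eta[ci], gamma = cells$gamma[ci],
               beta = mean(betas), lnC0 = mean(lnC0))
  })
  do.call(rbind, out)
}
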