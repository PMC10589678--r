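#' Synthetic node geometries
#'
#' \code{"packaged-atlas"} returns the shipped 116-node brain-like centroid
#' geometry; \code{"random-box"} samples points uniformly inside a
#' 140 x 170 x 120 mm box (brain scale), reproducibly from the seed.
#'
#' @param n number of nodes (must be 116 for the packaged mode).
#' @param mode \code{"packaged-atlas"} or \code{"random-box"}.
#' @param rng_seed integer seed (random-box mode).
#' @return a \linkS4class{NodeGeometry}.
#' @export
synthGeometry <- function(n, mode = c("packaged-atlas", "random-box"),
                          rng_seed = 1) {
  mode <- match.arg(mode)
  if (mode == "packaged-atlas") {
    if (n != 116) stop("packaged-atlas mode requires n = 116")
    return(packagedAtlas(116))
  }
  stopifnot(n >= 2)
  co <- .with_seed(rng_seed,
    cbind(stats::runif(n, 0, 140), stats::runif(n, 0, 170),
          stats::runif(n, 0, 120)))
  nodeGeometry(co)
}

#' Synthetic neonatal-like cohort with a planted rich-club core
#'
#' Emulates the structure the consensus + rich-club pipeline is designed to
#' recover: a small set of core nodes that (a) are fully interconnected in
#' most subjects, and (b) act as hubs through consistent attachments to the
#' periphery, on top of a consistent population background graph plus
#' independent per-subject noise. The hub attachments give every core node
#' the same degree so that a single rich-club level isolates exactly the
#' planted core.
#'
#' @param n_subjects number of subjects.
#' @param n_nodes nodes per network (default 90; labels/coordinates from the
#'   cerebral subset of the packaged geometry when 90 or 116).
#' @param core_nodes indices of the planted core (default: the five default
#'   seed regions).
#' @param core_consistency fraction of subjects carrying the complete core
#'   (must exceed the consensus threshold used downstream); other subjects
#'   carry each core edge with probability 0.5.
#' @param background_density density of the population background graph among
#'   non-core pairs.
#' @param hub_attach consistent periphery attachments per core node.
#' @param background_consistency per-subject retention probability of each
#'   population background edge.
#' @param edge_noise per-subject flip probability of non-core node pairs.
#' @param rng_seed integer seed; the cohort is a pure function of it.
#' @return list of \linkS4class{BinaryNetwork}s.
#' @export
synthNeonatalCohort <- function(n_subjects = 40, n_nodes = 90,
                                core_nodes = NULL, core_consistency = 0.9,
                                background_density = 0.05, hub_attach = 12,
                                background_consistency = 0.9,
                                edge_noise = 0.01, rng_seed = 1) {
  geo <- if (n_nodes %in% c(90, 116)) packagedAtlas(n_nodes) else
    synthGeometry(n_nodes, "random-box", rng_seed)
  if (is.null(core_nodes)) {
    core <- c("Lingual_L", "Lingual_R", "Precuneus_L", "Occipital_Mid_L",
              "Fusiform_R")
    core_nodes <- match(core, nodeLabels(geo))
    if (any(is.na(core_nodes)))
      core_nodes <- seq_len(5)
  }
  nc <- length(core_nodes)
  if (nc > n_nodes) stop("core larger than the network")
  .with_seed(rng_seed, {
    periph <- setdiff(seq_len(n_nodes), core_nodes)
    ## population background among periphery pairs only, so that the core
    ## nodes keep identical consensus degrees (4 + hub_attach each) and a
    ## single rich-club level isolates exactly the planted core
    bg <- matrix(0, n_nodes, n_nodes)
    pp <- which(upper.tri(bg))
    jj <- ((pp - 1) %/% n_nodes) + 1L
    ii <- pp - (jj - 1L) * n_nodes
    is_core_pair <- ii %in% core_nodes & jj %in% core_nodes
    is_periph_pair <- !(ii %in% core_nodes) & !(jj %in% core_nodes)
    keep <- is_periph_pair & stats::runif(length(pp)) < background_density
    bg[pp[keep]] <- 1
    ## consistent hub attachments: equal extra degree for every core node
    for (v in core_nodes) {
      att <- sample(periph, hub_attach)
      bg[v, att] <- 1
      bg[att, v] <- 1
    }
    bg <- 1 * ((bg + t(bg)) > 0)
    core_adj <- matrix(0, n_nodes, n_nodes)
    core_adj[core_nodes, core_nodes] <- 1
    diag(core_adj) <- 0
    full_core <- sample(n_subjects) <= round(core_consistency * n_subjects)
    lapply(seq_len(n_subjects), function(s) {
      a <- matrix(0, n_nodes, n_nodes)
      ## background retention
      ut <- which(bg == 1 & upper.tri(bg))
      ret <- ut[stats::runif(length(ut)) < background_consistency]
      a[ret] <- 1
      ## core edges
      cut <- which(core_adj == 1 & upper.tri(core_adj))
      if (full_core[s]) a[cut] <- 1 else
        a[cut[stats::runif(length(cut)) < 0.5]] <- 1
      ## independent noise flips on non-core pairs
      flip <- pp[!is_core_pair & stats::runif(length(pp)) < edge_noise]
      a[flip] <- 1 - a[flip]
      a <- 1 * ((a + t(a)) > 0)
      a[lower.tri(a)] <- 0
      a <- a + t(a)
      binaryNetwork(a, geo)
    })
  })
}

#' Synthetic child cohort with known wiring parameters
#'
#' Generates per-subject connectomes from the generative model with known
#' (eta, gamma) so that parameter fitting and group statistics can be scored
#' against ground truth. Subjects split into two SES groups; the high-SES
#' group's eta magnitude is larger by \code{group_effect} pooled SDs. The
#' deprivation score is a monotone noisy transform of group membership (not
#' of eta itself), so detecting the planted effect requires the full
#' fit-and-compare pipeline.
#'
#' @param seed_net seed \linkS4class{BinaryNetwork}.
#' @param dist distance matrix.
#' @param n_subjects cohort size (split evenly between groups).
#' @param group_effect planted |eta| difference between SES groups, in units
#'   of the common eta SD.
#' @param eta_abs_mean,eta_sd magnitude distribution of eta in the low-SES
#'   group (the high-SES group mean is shifted by
#'   \code{group_effect * eta_sd}).
#' @param gamma_mean,gamma_sd gamma distribution (both groups).
#' @param edges_mean,edges_sd per-subject edge-count distribution (defaults
#'   mirror a 10\%-density child cohort at 116 nodes).
#' @param deprivation_gap,deprivation_sd location shift and noise of the
#'   deprivation score between groups.
#' @param rng_seed integer seed; the cohort (networks, covariates, truth
#'   table) is a pure function of it.
#' @return list with \code{networks} (list of \linkS4class{BinaryNetwork})
#'   and \code{truth}: data.frame of id, group, eta, gamma, edge_count,
#'   deprivation.
#' @export
synthChildCohort <- function(seed_net, dist, n_subjects = 40,
                             group_effect = 0.8, eta_abs_mean = 2.0,
                             eta_sd = 0.5, gamma_mean = 0.35,
                             gamma_sd = 0.1, edges_mean = 668,
                             edges_sd = 44, deprivation_gap = 2.4,
                             deprivation_sd = 1, rng_seed = 1) {
  n <- nNodes(seed_net)
  m_seed <- edgeCount(seed_net)
  m_cap <- n * (n - 1) / 2
  truth <- .with_seed(rng_seed, {
    group <- rep(c("high", "low"), length.out = n_subjects)
    absmu <- ifelse(group == "high", eta_abs_mean + group_effect * eta_sd,
                    eta_abs_mean)
    eta <- -pmax(stats::rnorm(n_subjects, absmu, eta_sd), 0)
    gamma <- pmax(stats::rnorm(n_subjects, gamma_mean, gamma_sd), 0)
    m <- round(stats::rnorm(n_subjects, edges_mean, edges_sd))
    m <- pmin(pmax(m, m_seed + 1), m_cap)
    depr <- stats::rnorm(n_subjects,
                         ifelse(group == "low", deprivation_gap / 2,
                                -deprivation_gap / 2), deprivation_sd)
    data.frame(id = sprintf("s%03d", seq_len(n_subjects)), group = group,
               eta = eta, gamma = gamma, edge_count = m, deprivation = depr,
               sim_seed = vapply(seq_len(n_subjects), function(k)
                 .derive_seed(rng_seed, 9000 + k), 0L))
  })
  networks <- lapply(seq_len(n_subjects), function(k)
    simulateNetwork(seed_net, dist, truth$eta[k], truth$gamma[k],
                    truth$edge_count[k], truth$sim_seed[k])@network)
  list(networks = networks, truth = truth)
}
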