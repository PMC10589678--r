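## stage schemas: required and optional config keys
.STAGE_SCHEMAS <- list(
  "synth-neonatal" = list(req = c("stage", "out_dir", "seed"),
    opt = c("n_subjects", "n_nodes", "core_consistency",
            "background_density", "hub_attach", "background_consistency",
            "edge_noise")),
  "seed-build" = list(req = c("stage", "out_dir", "cohort_dir", "seed"),
    opt = c("consensus", "nulls", "iters", "alpha", "max_edges")),
  "sweep" = list(req = c("stage", "out_dir", "seed"),
    opt = c("seed_network", "eta_range", "gamma_range", "grid_size", "reps",
            "edges", "noise")),
  "dissimilarity" = list(req = c("stage", "out_dir", "archive_dir"),
    opt = character()),
  "noise-experiment" = list(req = c("stage", "out_dir", "seed"),
    opt = c("seed_network", "eta_range", "gamma_range", "grid_size", "reps",
            "edges")),
  "robustness" = list(req = c("stage", "out_dir", "archive_dir"),
    opt = c("regime", "window_frac", "reps_random", "max_reps", "seed")),
  "equifinality" = list(req = c("stage", "out_dir", "archive_dir", "seed"),
    opt = c("features", "folds")),
  "fit-cohort" = list(req = c("stage", "out_dir", "seed"),
    opt = c("cohort_seed", "n_subjects", "group_effect", "grid_size",
            "landscapes", "seed_network")))

.validate_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (is.null(config$stage)) stop("config is missing the `stage` key")
  schema <- .STAGE_SCHEMAS[[config$stage]]
  if (is.null(schema))
    stop("unknown stage: ", config$stage)
  known <- c(schema$req, schema$opt)
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s) for stage ", config$stage, ": ",
         paste(extra, collapse = ", "))
  missing <- setdiff(schema$req, names(config))
  if (length(missing))
    stop("missing required key(s): ", paste(missing, collapse = ", "))
  config
}

## small deterministic string hash (djb2) for manifests
.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

.default_seed_net <- function(path = NULL) {
  if (!is.null(path)) {
    w <- readNetwork(path, "matrix-csv")
    geo <- packagedAtlas(116)
    return(binaryNetwork(1 * (adjacency(w) > 0), geo))
  }
  defaultSeedNetwork()
}

#' Run one pipeline stage from a validated configuration
#'
#' Validates the configuration against the stage schema (unknown keys are
#' rejected by name), runs the stage, writes its outputs into
#' \code{out_dir} together with a manifest (config, config hash, seeds,
#' package version, wall time) and cleans up partial outputs on failure.
#' Rerunning with the same config reproduces stochastic outputs exactly.
#'
#' @param config a named list or path to a YAML file.
#' @return (invisibly) the manifest list, with \code{outputs} naming the
#'   written artifact files.
#' @export
runStage <- function(config) {
  config <- .validate_config(config)
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE))
  outputs <- .run_stage_impl(config, out_dir)
  man <- list(stage = config$stage, config = config,
              config_hash = .config_hash(config),
              outputs = outputs,
              package_version = as.character(utils::packageVersion("stochnet")),
              wall_time_s = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ok <- TRUE
  invisible(man)
}

.grid_from_config <- function(config) {
  gs <- config$grid_size %||% 13
  er <- config$eta_range %||% c(-4, 0)
  gr <- config$gamma_range %||% c(0, 1)
  list(eta = seq(er[1], er[2], length.out = gs),
       gamma = seq(gr[1], gr[2], length.out = gs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_stage_impl <- function(config, out_dir) {
  switch(config$stage,
    "synth-neonatal" = {
      cohort <- synthNeonatalCohort(
        n_subjects = config$n_subjects %||% 40,
        n_nodes = config$n_nodes %||% 90,
        core_consistency = config$core_consistency %||% 0.9,
        background_density = config$background_density %||% 0.05,
        hub_attach = config$hub_attach %||% 12,
        background_consistency = config$background_consistency %||% 0.9,
        edge_noise = config$edge_noise %||% 0.01,
        rng_seed = config$seed)
      files <- vapply(seq_along(cohort), function(s) {
        f <- file.path(out_dir, sprintf("subject_%03d.csv", s))
        writeNetwork(cohort[[s]], f)
        basename(f)
      }, "")
      writeNetwork(cohort[[1]], file.path(out_dir, "subject_001.csv"),
                   coords_path = file.path(out_dir, "coords.csv"))
      c(files, "coords.csv")
    },
    "seed-build" = {
      files <- sort(list.files(config$cohort_dir, pattern = "^subject_.*csv$",
                               full.names = TRUE))
      geo <- readGeometry(file.path(config$cohort_dir, "coords.csv"))
      cohort <- lapply(files, function(f)
        binaryNetwork(1 * (adjacency(readNetwork(f, "matrix-csv")) > 0), geo))
      cons <- consensusNetwork(cohort, config$consensus %||% 0.70)
      curve <- richClubAnalysis(cons, n_nulls = config$nulls %||% 1000,
                                iters_per_edge = config$iters %||% 50,
                                rng_seed = config$seed)
      seed_net <- extractSeed(cons, curve, alpha = config$alpha %||% 0.05,
                              target_geometry = packagedAtlas(116),
                              max_edges = config$max_edges %||% 20)
      writeNetwork(seed_net, file.path(out_dir, "seed_network.csv"))
      utils::write.csv(curveTable(curve), file.path(out_dir, "richclub.csv"),
                       row.names = FALSE)
      c("seed_network.csv", "richclub.csv")
    },
    "sweep" = {
      sn <- .default_seed_net(config$seed_network)
      d <- distanceMatrix(geometry(sn))
      g <- .grid_from_config(config)
      noise <- if (!is.null(config$noise) && config$noise != "none")
        noiseSchedule(config$noise) else NULL
      arch <- parameterSweep(sn, d, g$eta, g$gamma,
                             reps = config$reps %||% 30,
                             m_target = config$edges %||% 400,
                             master_seed = config$seed, noise = noise)
      saveArchive(arch, file.path(out_dir, "archive"))
      "archive"
    },
    "dissimilarity" = {
      arch <- loadArchive(config$archive_dir)
      tab <- dissimilarityLandscape(arch)
      utils::write.csv(tab, file.path(out_dir, "dissimilarity.csv"),
                       row.names = FALSE)
      reg <- if (length(unique(tab$eta)) >= 3 &&
                 length(unique(tab$gamma)) >= 3) {
        list(gamma_topo = landscapeRegression(tab, "topo", "gamma"),
             eta_topo = landscapeRegression(tab, "topo", "eta"),
             eta_embed = landscapeRegression(tab, "embed", "eta"),
             gamma_embed = landscapeRegression(tab, "embed", "gamma"))
      } else list(note = "grid too small for landscape regressions")
      jsonlite::write_json(reg, file.path(out_dir, "regressions.json"),
                           auto_unbox = TRUE, digits = NA)
      c("dissimilarity.csv", "regressions.json")
    },
    "noise-experiment" = {
      sn <- .default_seed_net(config$seed_network)
      d <- distanceMatrix(geometry(sn))
      g <- .grid_from_config(config)
      tab <- noiseExperiment(sn, d, g$eta, g$gamma,
                             reps = config$reps %||% 30,
                             m_target = config$edges %||% 400,
                             master_seed = config$seed)
      utils::write.csv(tab, file.path(out_dir, "noise_effects.csv"),
                       row.names = FALSE)
      av <- list(delta_topo = timingAnova(tab, "delta_topo"),
                 delta_embed = timingAnova(tab, "delta_embed"))
      jsonlite::write_json(av, file.path(out_dir, "anova.json"),
                           auto_unbox = TRUE, digits = NA)
      c("noise_effects.csv", "anova.json")
    },
    "robustness" = {
      arch <- loadArchive(config$archive_dir)
      tab <- robustnessLandscape(arch, regime = config$regime %||% "targeted",
                                 window_frac = config$window_frac %||% 0.25,
                                 reps_random = config$reps_random %||% 25,
                                 max_reps = config$max_reps,
                                 rng_seed = config$seed %||% 1)
      utils::write.csv(tab, file.path(out_dir, "robustness.csv"),
                       row.names = FALSE)
      "robustness.csv"
    },
    "equifinality" = {
      arch <- loadArchive(config$archive_dir)
      eq <- equifinalityMatrix(arch,
                               feature_mode = config$features %||% "topology",
                               folds = config$folds %||% 10,
                               rng_seed = config$seed)
      utils::write.csv(eq$rate, file.path(out_dir, "rates.csv"),
                       row.names = FALSE)
      tab <- dissimilarityLandscape(arch)
      corr <- equifinalityCorrelates(eq, tab)
      corr$mean_rate <- NULL
      jsonlite::write_json(corr, file.path(out_dir, "correlates.json"),
                           auto_unbox = TRUE, digits = NA)
      c("rates.csv", "correlates.json")
    },
    "fit-cohort" = {
      sn <- .default_seed_net(config$seed_network)
      d <- distanceMatrix(geometry(sn))
      g <- .grid_from_config(config)
      cohort <- synthChildCohort(sn, d,
                                 n_subjects = config$n_subjects %||% 40,
                                 group_effect = config$group_effect %||% 0.8,
                                 rng_seed = config$cohort_seed %||%
                                   .derive_seed(config$seed, 77))
      ls <- buildLandscapes(sn, d, g$eta, g$gamma,
                            n_landscapes = config$landscapes %||% 50,
                            m_max = max(cohort$truth$edge_count),
                            master_seed = config$seed)
      fits <- fitCohort(cohort$networks, ls, d, ids = cohort$truth$id)
      fits$deprivation <- cohort$truth$deprivation
      utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                       row.names = FALSE)
      grp <- medianSplit(fits$deprivation)
      gc_ <- groupComparison(fits$eta_hat, grp)
      pt <- permutationTest(fits$eta_hat, grp,
                            rng_seed = .derive_seed(config$seed, 88))
      res <- list(group_comparison = gc_,
                  p_perm = pt$p_perm, p_perm_smoothed = pt$p_perm_smoothed)
      jsonlite::write_json(res, file.path(out_dir, "group_test.json"),
                           auto_unbox = TRUE, digits = NA)
      c("fits.csv", "group_test.json")
    },
    stop("unhandled stage"))
}

#' Demonstration protocol plan and runner
#'
#' The reduced protocol (13 x 13 grid, 30 repetitions, 400 edges) reproduces
#' all sign and ordering findings at desk scale; the full protocol (25 x 25
#' grid, 625 repetitions) is the cluster-scale reference configuration.
#' Without \code{execute} the function returns the plan only.
#'
#' @param scale \code{"reduced"} or \code{"full"}.
#' @param execute run the chained protocol (synth cohort, seed build, sweep,
#'   dissimilarity, noise, robustness, equifinality, fit) into
#'   \code{out_dir}.
#' @param out_dir output directory when executing.
#' @param seed master seed.
#' @param grid_size,reps overrides for smoke runs.
#' @return the plan (data.frame) if \code{execute = FALSE}; otherwise a list
#'   of stage manifests.
#' @export
demoProtocol <- function(scale = c("reduced", "full"), execute = FALSE,
                         out_dir = tempfile("stochnet_demo"), seed = 1,
                         grid_size = NULL, reps = NULL) {
  scale <- match.arg(scale)
  gs <- grid_size %||% if (scale == "reduced") 13 else 25
  rp <- reps %||% if (scale == "reduced") 30 else 625
  plan <- data.frame(
    stage = c("synth-neonatal", "seed-build", "sweep", "dissimilarity",
              "noise-experiment", "robustness", "equifinality",
              "fit-cohort"),
    runs = c(NA, NA, gs^2 * rp, NA, 4 * gs^2 * rp, NA,
             gs^2 * (gs^2 - 1) / 2, NA))
  attr(plan, "runs_per_protocol") <- gs^2 * rp
  if (!execute) return(plan)
  mans <- list()
  mans$synth <- runStage(list(stage = "synth-neonatal",
                              out_dir = file.path(out_dir, "cohort"),
                              seed = seed))
  mans$seed_build <- runStage(list(stage = "seed-build",
                                   out_dir = file.path(out_dir, "seed"),
                                   cohort_dir = file.path(out_dir, "cohort"),
                                   nulls = 200, seed = seed))
  seed_file <- file.path(out_dir, "seed", "seed_network.csv")
  mans$sweep <- runStage(list(stage = "sweep",
                              out_dir = file.path(out_dir, "sweep"),
                              seed_network = seed_file, grid_size = gs,
                              reps = rp, seed = seed))
  arch_dir <- file.path(out_dir, "sweep", "archive")
  mans$dissim <- runStage(list(stage = "dissimilarity",
                               out_dir = file.path(out_dir, "dissim"),
                               archive_dir = arch_dir))
  mans$noise <- runStage(list(stage = "noise-experiment",
                              out_dir = file.path(out_dir, "noise"),
                              grid_size = min(gs, 5), reps = rp,
                              seed_network = seed_file, seed = seed))
  mans$robust <- runStage(list(stage = "robustness",
                               out_dir = file.path(out_dir, "robust"),
                               archive_dir = arch_dir, max_reps = 5,
                               seed = seed))
  mans$equif <- runStage(list(stage = "equifinality",
                              out_dir = file.path(out_dir, "equif"),
                              archive_dir = arch_dir,
                              folds = min(10, rp), seed = seed))
  mans$fit <- runStage(list(stage = "fit-cohort",
                            out_dir = file.path(out_dir, "fit"),
                            grid_size = min(gs, 9), landscapes = 6,
                            seed_network = seed_file, seed = seed))
  mans
}
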