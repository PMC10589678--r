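#' Topological dissimilarity of a set of runs
#'
#' Each run's five-metric profile is min-max rescaled per metric (using the
#' supplied normalization context, or the profile set itself) and the
#' pairwise Euclidean distances in the normalized 5-D space are computed. The
#' headline scalar is the sum over the FULL distance matrix (off-diagonal
#' entries counted twice); the upper-triangle sum, exactly half, is also
#' returned. Zero-range metrics contribute 0 and are flagged.
#'
#' @param profiles numeric matrix (runs x 5 metrics) or data.frame containing
#'   the five metric columns.
#' @param context optional matrix/data.frame supplying the per-metric min and
#'   max (e.g. all runs of all cells of a landscape); defaults to
#'   \code{profiles} itself.
#' @return list with \code{matrix} (pairwise distances), \code{sum} (full
#'   matrix sum), \code{sum_upper}, and \code{flat_metrics} (names of
#'   zero-range metrics).
#' @export
topologicalDissimilarity <- function(profiles, context = NULL) {
  p <- as.matrix(as.data.frame(profiles)[, .metric_cols])
  if (nrow(p) < 2) stop("need at least two profiles")
  ctx <- if (is.null(context)) p else
    as.matrix(as.data.frame(context)[, .metric_cols])
  lo <- apply(ctx, 2, min)
  hi <- apply(ctx, 2, max)
  rng <- hi - lo
  flat <- .metric_cols[rng == 0]
  rng[rng == 0] <- 1  # zero-range metric: normalized column is constant 0
  z <- sweep(sweep(p, 2, lo), 2, rng, "/")
  dm <- as.matrix(stats::dist(z))
  dimnames(dm) <- NULL
  list(matrix = dm, sum = sum(dm), sum_upper = sum(dm[upper.tri(dm)]),
       flat_metrics = flat)
}

#' Embedding dissimilarity of equal-size edge sets
#'
#' Pairwise fraction of non-overlapping connections ("disconsistency"):
#' \eqn{1 - |E_a \cap E_b| / m} for edge sets of common size m. The scalar is
#' the mean over unordered pairs (the sum is also returned).
#'
#' @param edge_sets list of sorted integer edge-code vectors (see
#'   \code{\link{edgeIndices}}), all the same length.
#' @return list with \code{matrix}, \code{mean} and \code{sum} (over
#'   unordered pairs).
#' @export
embeddingDissimilarity <- function(edge_sets) {
  r <- length(edge_sets)
  stopifnot(r >= 2)
  m <- length(edge_sets[[1]])
  if (!all(lengths(edge_sets) == m))
    stop("edge sets must have equal cardinality")
  dm <- matrix(0, r, r)
  for (a in seq_len(r - 1)) for (b in (a + 1):r) {
    ov <- .overlap_sorted(edge_sets[[a]], edge_sets[[b]])
    dm[a, b] <- dm[b, a] <- 1 - ov / m
  }
  ut <- dm[upper.tri(dm)]
  list(matrix = dm, mean = mean(ut), sum = sum(ut))
}

## size of the intersection of two sorted integer vectors
.overlap_sorted <- function(x, y) sum(!is.na(match(x, y)))

#' Dissimilarity landscape of a sweep archive
#'
#' One row per grid cell with the summed topological dissimilarity (min-max
#' normalization computed GLOBALLY over all runs of all cells, so that
#' between-cell magnitude differences survive) and the mean pairwise
#' embedding dissimilarity across that cell's repetitions.
#'
#' @param archive a \linkS4class{SweepArchive} with reps >= 2.
#' @return data.frame with columns \code{eta}, \code{gamma},
#'   \code{topo_dissim}, \code{embed_dissim}.
#' @export
dissimilarityLandscape <- function(archive) {
  prof <- profiles(archive)
  esets <- edgeSets(archive)
  stopifnot(archive@reps >= 2)
  cells <- unique(prof[, c("eta", "gamma", "eta_idx", "gamma_idx")])
  out <- lapply(seq_len(nrow(cells)), function(ci) {
    sel <- prof$eta_idx == cells$eta_idx[ci] &
      prof$gamma_idx == cells$gamma_idx[ci]
    td <- topologicalDissimilarity(prof[sel, ], context = prof)
    ed <- embeddingDissimilarity(esets[sel])
    data.frame(eta = cells$eta[ci], gamma = cells$gamma[ci],
               topo_dissim = td$sum, embed_dissim = ed$mean)
  })
  do.call(rbind, out)
}

#' Univariate landscape regression
#'
#' Ordinary least squares of a dissimilarity landscape response on a single
#' wiring parameter across grid cells; used to ask which exponent drives
#' which kind of multifinality.
#'
#' @param table data.frame from \code{\link{dissimilarityLandscape}} (or any
#'   table with the needed columns).
#' @param response \code{"topo"} or \code{"embed"} (columns
#'   \code{topo_dissim} / \code{embed_dissim}), or a column name.
#' @param predictor \code{"eta"} or \code{"gamma"}.
#' @return list with \code{r2_percent}, \code{slope}, \code{p_value}.
#' @export
landscapeRegression <- function(table, response = c("topo", "embed"),
                                predictor = c("eta", "gamma")) {
  predictor <- match.arg(predictor, c("eta", "gamma"))
  rcol <- if (response[1] %in% c("topo", "embed"))
    paste0(match.arg(response), "_dissim") else response[1]
  x <- table[[predictor]]
  y <- table[[rcol]]
  if (length(unique(x)) < 3) stop("need >= 3 distinct predictor values")
  if (stats::var(y) == 0)
    return(list(r2_percent = 0, slope = 0, p_value = NA_real_))
  fit <- stats::lm(y ~ x)
  ## exact fits trip summary.lm's perfect-fit warning; R^2 is still defined
  sm <- suppressWarnings(summary(fit))
  pv <- if (sm$sigma == 0 || is.na(stats::coef(fit)[2])) NA_real_ else
    stats::coef(sm)[2, 4]
  list(r2_percent = 100 * sm$r.squared,
       slope = unname(stats::coef(fit)[2]),
       p_value = pv)
}
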