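#' Cross-validated pairwise misclassification rate
#'
#' Trains a soft-margin linear SVM (cost 1) to distinguish two classes of
#' feature vectors under stratified k-fold cross-validation, with features
#' standardized using training-fold statistics only, and returns the pooled
#' misclassification rate. A rate near 0.5 means the two generating processes
#' are statistically confusable (equifinality); near 0 means fully
#' distinguishable.
#'
#' @param features_a,features_b numeric matrices (samples x features), one
#'   per class, each with at least \code{folds} rows.
#' @param folds number of CV folds (default 10).
#' @param rng_seed seed for the stratified fold shuffle.
#' @param per_fold_mean return the mean of per-fold rates instead of the
#'   pooled rate (differs when fold sizes are unequal).
#' @param cost SVM regularization constant.
#' @return misclassification rate in [0, 1].
#' @export
pairwiseMisclassification <- function(features_a, features_b, folds = 10,
                                      rng_seed = 1, per_fold_mean = FALSE,
                                      cost = 1) {
  features_a <- as.matrix(features_a)
  features_b <- as.matrix(features_b)
  na <- nrow(features_a); nb <- nrow(features_b)
  if (na < folds || nb < folds) stop("need >= folds samples per class")
  x <- rbind(features_a, features_b)
  y <- factor(rep(c("a", "b"), c(na, nb)))
  fold <- integer(na + nb)
  fold[seq_len(na)] <- .with_seed(.derive_seed(rng_seed, 1),
    sample(rep_len(seq_len(folds), na)))
  fold[na + seq_len(nb)] <- .with_seed(.derive_seed(rng_seed, 2),
    sample(rep_len(seq_len(folds), nb)))
  errs <- integer(folds); tot <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = FALSE)
    pred <- stats::predict(fit, xs[!tr, , drop = FALSE])
    errs[f] <- sum(pred != y[!tr])
    tot[f] <- sum(!tr)
  }
  if (per_fold_mean) mean(errs / tot) else sum(errs) / sum(tot)
}

#' Pairwise equifinality matrix over a sweep archive
#'
#' For every unordered pair of grid cells, an SVM is trained to distinguish
#' the cells' repetitions and the cross-validated misclassification rate is
#' recorded. Features are either the five-metric topology profiles
#' (\code{"topology"}) or the vectorized upper-triangle edge indicators
#' (\code{"embedding"}).
#'
#' @param archive a \linkS4class{SweepArchive} with reps >= folds.
#' @param feature_mode \code{"topology"} or \code{"embedding"}.
#' @param folds CV folds (default 10).
#' @param rng_seed master seed (per-pair seeds derived from it).
#' @param cell_subset optional integer vector of cell indices (column-major
#'   over the eta x gamma grid) restricting the computation.
#' @param progress print progress every 1000 pairs.
#' @return list with \code{rate} (symmetric cells x cells matrix, NA
#'   diagonal), \code{cells} (data.frame of eta, gamma per cell) and
#'   \code{manifest} (kernel, cost, standardization, folds).
#' @export
equifinalityMatrix <- function(archive, feature_mode = c("topology",
                                                         "embedding"),
                               folds = 10, rng_seed = 1, cell_subset = NULL,
                               progress = FALSE) {
  feature_mode <- match.arg(feature_mode)
  prof <- profiles(archive)
  stopifnot(archive@reps >= folds)
  cells <- unique(prof[, c("eta", "gamma", "eta_idx", "gamma_idx")])
  rownames(cells) <- NULL
  if (is.null(cell_subset)) cell_subset <- seq_len(nrow(cells))
  cells <- cells[cell_subset, , drop = FALSE]
  nc <- nrow(cells)
  feats <- lapply(seq_len(nc), function(ci) {
    sel <- which(prof$eta_idx == cells$eta_idx[ci] &
                 prof$gamma_idx == cells$gamma_idx[ci])
    if (feature_mode == "topology") {
      as.matrix(prof[sel, .metric_cols])
    } else {
      es <- edgeSets(archive)[sel]
      cols <- sort(unique(unlist(es)))
      f <- matrix(0, length(sel), length(cols))
      for (k in seq_along(es)) f[k, match(es[[k]], cols)] <- 1
      attr(f, "cols") <- cols
      f
    }
  })
  rate <- matrix(NA_real_, nc, nc)
  done <- 0L
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
    fa <- feats[[a]]; fb <- feats[[b]]
    if (feature_mode == "embedding") {
      cols <- sort(union(attr(fa, "cols"), attr(fb, "cols")))
      ea <- matrix(0, nrow(fa), length(cols)); eb <- matrix(0, nrow(fb), length(cols))
      ea[, match(attr(fa, "cols"), cols)] <- fa
      eb[, match(attr(fb, "cols"), cols)] <- fb
      fa <- ea; fb <- eb
    }
    rate[a, b] <- rate[b, a] <- pairwiseMisclassification(
      fa, fb, folds = folds, rng_seed = .derive_seed(rng_seed, a, b))
    done <- done + 1L
    if (progress && done %% 1000 == 0)
      message(done, " pairs done")
  }
  list(rate = rate,
       cells = cells[, c("eta", "gamma")],
       manifest = list(feature_mode = feature_mode, kernel = "linear",
                       cost = 1, folds = folds, rng_seed = rng_seed,
                       standardization = "training-fold"))
}

#' Correlates of equifinality
#'
#' Two summary statistics of an equifinality matrix: the Pearson correlation
#' between pairwise misclassification rate and the distance between the two
#' cells' gamma values, and the percent variance in a cell's mean
#' misclassification rate explained by that cell's topological dissimilarity.
#'
#' @param eq output of \code{\link{equifinalityMatrix}}.
#' @param table matching \code{\link{dissimilarityLandscape}} table.
#' @return list with \code{r_gamma_distance}, \code{p_gamma_distance},
#'   \code{R2_stochasticity_percent}, \code{slope_stochasticity},
#'   \code{p_stochasticity} and \code{mean_rate} per cell.
#' @export
equifinalityCorrelates <- function(eq, table) {
  rate <- eq$rate
  cells <- eq$cells
  key <- paste(signif(cells$eta, 10), signif(cells$gamma, 10))
  tkey <- paste(signif(table$eta, 10), signif(table$gamma, 10))
  idx <- match(key, tkey)
  if (any(is.na(idx))) stop("equifinality matrix and table grids differ")
  ut <- upper.tri(rate)
  gd <- abs(outer(cells$gamma, cells$gamma, "-"))
  ct <- stats::cor.test(rate[ut], gd[ut])
  mean_rate <- rowMeans(rate, na.rm = TRUE)
  td <- table$topo_dissim[idx]
  fit <- stats::lm(mean_rate ~ td)
  sm <- summary(fit)
  list(r_gamma_distance = unname(ct$estimate),
       p_gamma_distance = ct$p.value,
       R2_stochasticity_percent = 100 * sm$r.squared,
       slope_stochasticity = unname(stats::coef(fit)[2]),
       p_stochasticity = stats::coef(sm)[2, 4],
       mean_rate = mean_rate)
}
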