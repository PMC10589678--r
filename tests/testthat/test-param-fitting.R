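test_that("the KS statistic matches reference implementations", {
  set.seed(1)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(ksStatistic(x, y),
               unname(suppressWarnings(stats::ks.test(x, y))$statistic),
               tolerance = 1e-12)
  ## tied/discrete data against a brute-force ECDF scan
  xd <- sample(1:5, 30, replace = TRUE)
  yd <- sample(2:6, 25, replace = TRUE)
  grid <- sort(unique(c(xd, yd)))
  oracle <- max(abs(vapply(grid, function(g) mean(xd <= g) - mean(yd <= g), 0)))
  expect_equal(ksStatistic(xd, yd), oracle, tolerance = 1e-12)
  expect_equal(ksStatistic(1:5, 1:5), 0)
})

test_that("KS energy compares the four graph-statistic distributions", {
  geo <- rand_geometry(20, 2)
  d <- distanceMatrix(geo)
  net1 <- er_network(20, 0.3, 3, geo)
  net2 <- er_network(20, 0.5, 4, geo)
  expect_equal(ksEnergy(net1, net1, d), 0)
  e <- ksEnergy(net1, net2, d)
  expect_true(e >= 0 && e <= 1)
  ## brute-force max-gap oracle per statistic
  stats_of <- function(net) {
    a <- adjacency(net)
    g <- igraph::graph_from_adjacency_matrix(a, "undirected")
    lens <- d[which(a == 1 & upper.tri(a))]
    list(deg = igraph::degree(g),
         clu = igraph::transitivity(g, "local", isolates = "zero"),
         btw = igraph::betweenness(g),
         len = lens)
  }
  ecdf_gap <- function(x, y) {
    g <- sort(unique(c(x, y)))
    max(abs(vapply(g, function(v) mean(x <= v) - mean(y <= v), 0)))
  }
  s1 <- stats_of(net1); s2 <- stats_of(net2)
  oracle <- max(ecdf_gap(s1$deg, s2$deg), ecdf_gap(s1$clu, s2$clu),
                ecdf_gap(s1$btw, s2$btw), ecdf_gap(s1$len, s2$len))
  expect_equal(e, oracle, tolerance = 1e-12)
  expect_error(ksEnergy(net1, er_network(10, .3, 1), d), "size")
})

test_that("C++ nodal statistics agree with igraph", {
  for (s in 1:20) {
    net <- er_network(25, runif(1, 0.1, 0.5), s + 70)
    a <- adjacency(net)
    idx <- which(a == 1 & upper.tri(a))
    if (!length(idx)) next
    j <- ((idx - 1) %/% 25) + 1L; i <- idx - (j - 1L) * 25
    st <- stochnet:::cpp_nodal_stats(cbind(i, j), 25L)
    g <- igraph::graph_from_adjacency_matrix(a, "undirected")
    expect_equal(st$degree, unname(igraph::degree(g)))
    expect_equal(st$clustering,
                 igraph::transitivity(g, "local", isolates = "zero"),
                 tolerance = 1e-12)
    expect_equal(st$betweenness, unname(igraph::betweenness(g)),
                 tolerance = 1e-9)
  }
})

test_that("landscape fitting recovers generating parameters", {
  geo <- packagedAtlas(116)
  sn <- defaultSeedNetwork(geo)
  d <- distanceMatrix(geo)
  eg <- seq(-4, 0, 1); gg <- seq(0, 1, 0.25)
  ls <- buildLandscapes(sn, d, eg, gg, n_landscapes = 4, m_max = 320,
                        master_seed = 13)
  truth <- list(c(-2, 0.5), c(-3, 0.25))
  for (tv in truth) {
    obs <- simulateNetwork(sn, d, tv[1], tv[2], 300, rng_seed = 555)@network
    fit <- fitSubject(obs, ls, d)
    expect_lte(abs(fit$eta_hat - tv[1]), 1)
    expect_lte(abs(fit$gamma_hat - tv[2]), 0.25)
    expect_true(fit$energy >= 0 && fit$energy <= 1)
    expect_equal(fit$n_landscapes, 4)
  }
  ## determinism of the whole fit
  obs <- simulateNetwork(sn, d, -2, 0.5, 300, rng_seed = 556)@network
  f1 <- fitSubject(obs, ls, d)
  ls2 <- buildLandscapes(sn, d, eg, gg, n_landscapes = 4, m_max = 320,
                         master_seed = 13)
  f2 <- fitSubject(obs, ls2, d)
  expect_identical(f1, f2)
})

test_that("median split assigns ties at the median to the high-SES group", {
  g <- medianSplit(1:10)
  expect_equal(table(g)[["high"]], 5)
  expect_equal(table(g)[["low"]], 5)
  ## odd n: the median subject itself goes to the high-SES (<=) group
  g2 <- medianSplit(c(1, 2, 3, 4, 5))
  expect_equal(as.character(g2[3]), "high")
  expect_equal(sum(g2 == "high"), 3)
  expect_error(medianSplit(rep(2, 6)), "identical")
})

test_that("group comparison matches hand-computed t and d", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- factor(rep(c("high", "low"), each = 3), levels = c("high", "low"))
  res <- groupComparison(vals, grp)
  sp <- sqrt((2 * var(c(1, 2, 3)) + 2 * var(c(4, 5, 6))) / 4)
  t_hand <- (2 - 5) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$cohens_d, -3, tolerance = 1e-10)
  expect_equal(res$df, 4)
  ## identical groups
  res0 <- groupComparison(rep(c(1, 2), 4), factor(rep(c("high", "low"), each = 4)))
  expect_equal(res0$cohens_d, 0)
  expect_equal(res0$t, 0)
})

test_that("the permutation test is calibrated and hits its floor", {
  ## null calibration: p values uniform across repeated experiments
  set.seed(3)
  pvals <- vapply(1:200, function(b) {
    v <- rnorm(20)
    g <- factor(rep(c("high", "low"), 10))
    permutationTest(v, g, n_perm = 199, rng_seed = b)$p_perm
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  ## huge planted separation: smallest attainable p
  set.seed(4)
  v <- c(rnorm(30, 0), rnorm(30, 2))
  g <- factor(rep(c("high", "low"), each = 30))
  pt <- permutationTest(v, g, n_perm = 500, rng_seed = 5)
  expect_equal(pt$p_perm, 1 / 500)
  expect_equal(pt$p_perm_smoothed, 1 / 501)
  expect_error(permutationTest(v, g, n_perm = 50), "n_perm")
})
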