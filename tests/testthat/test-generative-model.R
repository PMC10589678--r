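test_that("wiring probabilities follow the distance-homophily rule", {
  geo <- rand_geometry(4, 1)
  d <- distanceMatrix(geo)
  ## nearly complete graph: single eligible pair gets probability 1
  a <- 1 - diag(4); a[1, 2] <- a[2, 1] <- 0
  p <- wiringProbabilities(binaryNetwork(a), d, -2, 0.5)
  expect_equal(nrow(p), 1)
  expect_equal(p$p, 1)
  ## eta = gamma = 0: uniform over eligible pairs
  a2 <- matrix(0, 4, 4); a2[1, 2] <- a2[2, 1] <- 1
  p2 <- wiringProbabilities(binaryNetwork(a2), d, 0, 0)
  expect_equal(p2$p, rep(1 / 5, 5))
  ## hand-computed four-node state
  a3 <- matrix(0, 4, 4)
  a3[1, 2] <- a3[2, 3] <- 1; a3 <- a3 + t(a3)
  eta <- -1.5; gamma <- 0.7; eps <- 1e-6
  m <- matching_oracle(a3)
  w <- numeric(0); lab <- character(0)
  for (jj in 2:4) for (ii in 1:(jj - 1)) {
    if (a3[ii, jj] == 1) next
    w <- c(w, d[ii, jj]^eta * (m[ii, jj] + eps)^gamma)
    lab <- c(lab, paste(ii, jj))
  }
  p3 <- wiringProbabilities(binaryNetwork(a3), d, eta, gamma)
  expect_equal(paste(p3$i, p3$j), lab)
  expect_equal(p3$p, w / sum(w), tolerance = 1e-12)
  ## complete network: no eligible pairs
  expect_error(wiringProbabilities(binaryNetwork(1 - diag(4)), d, 0, 0),
               "eligible")
})

## reference implementation: recompute matching and weights from scratch at
## every step, replicating the sampler's single-uniform-draw walk
simulate_oracle <- function(seed_net, d, eta, gamma, m_target, rng_seed,
                            eps = 1e-6) {
  a <- adjacency(seed_net)
  n <- nrow(a)
  ord_idx <- which(a == 1 & upper.tri(a))
  set.seed(rng_seed)
  while (length(ord_idx) < m_target) {
    m <- matching_oracle(a)
    deta <- if (eta == 0) matrix(1, n, n) else d^eta
    w <- deta * (m + eps)^gamma
    elig <- which(a == 0 & upper.tri(a))
    wt <- w[elig]
    r <- runif(1) * sum(wt)
    hit <- which(cumsum(wt) >= r)
    pick <- elig[if (length(hit)) hit[1] else length(wt)]
    j <- ((pick - 1) %/% n) + 1; i <- pick - (j - 1) * n
    a[i, j] <- 1; a[j, i] <- 1
    ord_idx <- c(ord_idx, pick)
  }
  j <- ((ord_idx - 1) %/% n) + 1; i <- ord_idx - (j - 1) * n
  cbind(i = as.integer(i), j = as.integer(j))
}

test_that("the sampler matches a from-scratch reference implementation", {
  geo <- rand_geometry(10, 33)
  d <- distanceMatrix(geo)
  a <- matrix(0, 10, 10); a[1, 2] <- a[2, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  seed_net <- binaryNetwork(a, geo)
  cases <- list(c(0, 0), c(-2, 0.5), c(-8, 0), c(0, 1), c(-1, 0.25))
  for (cs in cases) for (s in 1:3) {
    sim <- simulateNetwork(seed_net, d, cs[1], cs[2], 20, rng_seed = s * 7)
    oracle <- simulate_oracle(seed_net, d, cs[1], cs[2], 20, rng_seed = s * 7)
    expect_equal(unname(sim@edgeOrder), unname(oracle))
  }
})

test_that("simulate honors the seed scaffold and stop criterion", {
  geo <- packagedAtlas(116)
  sn <- defaultSeedNetwork(geo)
  d <- distanceMatrix(geo)
  ## m_target equal to the seed returns the seed unchanged
  sim0 <- simulateNetwork(sn, d, -2, 0.3, 10, 5)
  expect_identical(adjacency(sim0@network), adjacency(sn))
  ## 10-edge seed grows to exactly 400 edges, seed edges first and kept
  sim <- simulateNetwork(sn, d, -2, 0.3, 400, 5)
  expect_equal(edgeCount(sim@network), 400)
  seed_idx <- edgeIndices(sim@edgeOrder[1:10, ], 116)
  expect_identical(seed_idx,
    sort(which(adjacency(sn) == 1 & upper.tri(adjacency(sn)))))
  expect_true(all(adjacency(sim@network)[adjacency(sn) == 1] == 1))
  ## reproducibility from the recorded seed
  sim2 <- simulateNetwork(sn, d, -2, 0.3, 400, 5)
  expect_identical(sim@edgeOrder, sim2@edgeOrder)
  ## bounds
  expect_error(simulateNetwork(sn, d, -2, 0.3, 5, 1), "below seed")
  expect_error(simulateNetwork(sn, d, -2, 0.3, 1e5, 1), "capacity")
})

test_that("a strong distance penalty shortens edges", {
  geo <- rand_geometry(30, 21)
  d <- distanceMatrix(geo)
  a <- matrix(0, 30, 30); a[1, 2] <- a[2, 1] <- 1; a[3, 4] <- a[4, 3] <- 1
  sn <- binaryNetwork(a, geo)
  mean_len <- function(eta, s) {
    sim <- simulateNetwork(sn, d, eta, 0, 80, s)
    mean(d[sim@edgeOrder])
  }
  lens <- vapply(1:20, function(s) c(mean_len(-8, s), mean_len(0, s + 1000)),
                 numeric(2))
  expect_lt(mean(lens[1, ]), mean(lens[2, ]))
})

test_that("a full-growth noise window reproduces unconstrained statistics", {
  geo <- rand_geometry(40, 77)
  d <- distanceMatrix(geo)
  a <- matrix(0, 40, 40); a[1, 2] <- a[2, 1] <- 1; a[2, 3] <- a[3, 2] <- 1
  sn <- binaryNetwork(a, geo)
  deg_noise <- unlist(lapply(1:50, function(s) {
    sim <- simulateNetwork(sn, d, -3, 0.8, 100, s, noise = c(0, 1))
    rowSums(adjacency(sim@network))
  }))
  deg_unif <- unlist(lapply(1:50, function(s) {
    sim <- simulateNetwork(sn, d, 0, 0, 100, s + 5000)
    rowSums(adjacency(sim@network))
  }))
  ks <- suppressWarnings(stats::ks.test(deg_noise, deg_unif))
  expect_gt(ks$p.value, 0.01)
})

test_that("sweeps are bit-reproducible and complete", {
  fx <- tiny_archive()
  arch <- fx$archive
  expect_equal(nrow(profiles(arch)), 2 * 2 * 5)
  expect_true(all(lengths(edgeSets(arch)) == 60))
  arch2 <- parameterSweep(fx$seed_net, fx$dist, c(-3, 0), c(0, 0.8),
                          reps = 5, m_target = 60, master_seed = 99)
  expect_identical(profiles(arch), profiles(arch2))
  expect_identical(edgeSets(arch), edgeSets(arch2))
  ## archive directory round trip
  dir <- withr::local_tempdir()
  saveArchive(arch, dir)
  back <- loadArchive(dir)
  expect_equal(profiles(back), profiles(arch))
  expect_identical(edgeSets(back), edgeSets(arch))
  expect_equal(manifest(back)$master_seed, 99)
})
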