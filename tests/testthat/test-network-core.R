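test_that("network I/O round-trips matrices and edge lists", {
  f <- withr::local_tempfile(fileext = ".csv")
  ## empty matrix
  writeLines(c("0,0,0", "0,0,0", "0,0,0"), f)
  net <- readNetwork(f, "matrix-csv")
  expect_equal(edgeCount(net), 0)
  ## edge list with 0-based indices
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 1 5.0", f2)
  net2 <- readNetwork(f2, "edge-list", n = 3)
  expect_equal(adjacency(net2)[1, 2], 5.0)
  expect_equal(adjacency(net2)[2, 1], 5.0)
  ## exact write -> read round trip of a random weighted network
  set.seed(7)
  a <- matrix(0, 10, 10)
  a[upper.tri(a)] <- rexp(45) * (runif(45) < 0.4)
  a <- a + t(a)
  geo <- rand_geometry(10, 3)
  w <- weightedNetwork(a, geo)
  f3 <- withr::local_tempfile(fileext = ".csv")
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeNetwork(w, f3, coords_path = f4)
  back <- readNetwork(f3, "matrix-csv", coords_path = f4)
  expect_identical(adjacency(back), a)
  expect_equal(coords(geometry(back)), coords(geo))
})

test_that("network reading rejects malformed input and symmetrizes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,0", "1,0,0"), f)  # non-square
  expect_error(readNetwork(f, "matrix-csv"), "square")
  writeLines(c("0,2,0", "1,0,0", "0,0,0"), f)  # asymmetric
  expect_warning(net <- readNetwork(f, "matrix-csv"), "symmetriz")
  expect_equal(adjacency(net)[1, 2], 2)
  writeLines(c("0,-1", "-1,0"), f)
  expect_error(readNetwork(f, "matrix-csv"), "negative")
  ## coordinate count mismatch
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("node,label,x,y,z", "0,a,0,0,0", "1,b,1,1,1"), f2)
  writeLines(c("0,0,0", "0,0,0", "0,0,0"), f)
  expect_error(readNetwork(f, "matrix-csv", coords_path = f2), "match")
})

test_that("binarize applies a >= threshold and keeps geometry", {
  geo <- rand_geometry(3, 5)
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 1529
  a[1, 3] <- a[3, 1] <- 1530
  a[2, 3] <- a[3, 2] <- 1531
  w <- weightedNetwork(a, geo)
  b <- binarize(w, 1530)
  expect_equal(edgeCount(b), 2)       # ties at the cutoff are kept
  expect_equal(adjacency(b)[1, 2], 0)
  expect_identical(geometry(b), geo)
  expect_equal(edgeCount(binarize(w, 1e6)), 0)
  ## threshold 0 keeps exactly the nonzero support
  b0 <- binarize(w, 0)
  expect_equal(edgeCount(b0), 3)
})

test_that("distanceMatrix is exact Euclidean distance", {
  geo <- nodeGeometry(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(distanceMatrix(geo)[1, 2], 5)
  geo2 <- rand_geometry(20, 11)
  d <- distanceMatrix(geo2)
  expect_true(all(diag(d) == 0))
  co <- coords(geo2)
  oracle <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20)
    oracle[i, j] <- sqrt(sum((co[i, ] - co[j, ])^2))
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("matching index follows the neighborhood-overlap definition", {
  ## triangle: every pair overlaps perfectly
  tri <- binaryNetwork(1 - diag(3))
  expect_true(all(matchingMatrix(tri)[upper.tri(diag(3))] == 1))
  ## path a-b-c-d: m(a, c) = |{b}| / |{b, d}|
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 3] <- a[3, 4] <- 1
  a <- a + t(a)
  expect_equal(matchingMatrix(binaryNetwork(a))[1, 3], 0.5)
  ## star: center vs leaf = 0 (leaf has no other neighbors)
  s <- matrix(0, 5, 5); s[1, 2:5] <- 1; s <- s + t(s)
  expect_equal(matchingMatrix(binaryNetwork(s))[1, 2], 0)
  ## exact agreement with set-enumeration oracle on random graphs
  for (k in 1:100) {
    net <- er_network(12, runif(1, 0.1, 0.6), k)
    expect_identical(matchingMatrix(net), matching_oracle(adjacency(net)))
  }
})

test_that("topology profile matches closed forms and brute force", {
  geo10 <- rand_geometry(10, 2)
  d10 <- distanceMatrix(geo10)
  empty <- binaryNetwork(matrix(0, 10, 10), geo10)
  expect_equal(unname(topologyProfile(empty, d10)), rep(0, 5))
  ## complete graph K5
  geo5 <- rand_geometry(5, 3)
  k5 <- binaryNetwork(1 - diag(5), geo5)
  p5 <- topologyProfile(k5, distanceMatrix(geo5))
  expect_equal(unname(p5["clustering"]), 1)
  expect_equal(unname(p5["efficiency"]), 1)
  expect_equal(unname(p5["betweenness"]), 0)
  ## 4-cycle on a unit square
  sq <- nodeGeometry(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 3] <- a[3, 4] <- a[4, 1] <- 1
  a <- a + t(a)
  p <- topologyProfile(binaryNetwork(a), distanceMatrix(sq))
  expect_equal(unname(p["clustering"]), 0)
  expect_equal(unname(p["efficiency"]), 5 / 6)
  expect_equal(unname(p["betweenness"]), mean(betweenness_oracle(a)))
  expect_equal(unname(p["total_edge_length"]), 4)
})

test_that("profile metrics match per-metric brute force on small graphs", {
  ## exhaustive on 4 nodes, random graphs on 5 and 6
  cases <- list()
  for (code in 0:63) {
    a <- matrix(0, 4, 4)
    a[upper.tri(a)] <- as.integer(intToBits(code))[1:6]
    cases[[length(cases) + 1]] <- a + t(a)
  }
  set.seed(42)
  for (k in 1:60) {
    n <- sample(5:6, 1)
    cases[[length(cases) + 1]] <- adjacency(er_network(n, runif(1, .2, .8), k + 500))
  }
  for (a in cases) {
    n <- nrow(a)
    geo <- rand_geometry(n, n)
    d <- distanceMatrix(geo)
    p <- topologyProfile(binaryNetwork(a), d)
    if (sum(a) == 0) {
      expect_equal(unname(p), rep(0, 5))
      next
    }
    expect_equal(unname(p["clustering"]), mean(clustering_oracle(a)))
    expect_equal(unname(p["betweenness"]), mean(betweenness_oracle(a)))
    expect_equal(unname(p["efficiency"]), efficiency_oracle(a))
    expect_equal(unname(p["total_edge_length"]),
                 sum(d[upper.tri(d)] * a[upper.tri(a)]))
    expect_true(p["modularity"] >= -1 && p["modularity"] <= 1)
  }
})

test_that("communicability matches closed forms and the power series", {
  expect_equal(communicability(binaryNetwork(matrix(0, 3, 3))), 3)
  k2 <- binaryNetwork(rbind(c(0, 1), c(1, 0)))
  expect_equal(communicability(k2), 2 * exp(1), tolerance = 1e-12)
  k2iso <- binaryNetwork(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(communicability(k2iso), 2 * exp(1) + 1, tolerance = 1e-12)
  ## truncated power series oracle on random graphs
  for (k in 1:10) {
    a <- adjacency(er_network(10, 0.3, k + 40))
    term <- diag(10); acc <- diag(10)
    for (i in 1:30) { term <- term %*% a / i; acc <- acc + term }
    expect_equal(communicability(binaryNetwork(a)), sum(acc),
                 tolerance = 1e-9)
  }
})

test_that("metrics are invariant under node permutation", {
  geo <- rand_geometry(15, 8)
  net <- er_network(15, 0.3, 9, geo)
  d <- distanceMatrix(geo)
  set.seed(10)
  pi <- sample(15)
  a2 <- adjacency(net)[pi, pi]
  geo2 <- nodeGeometry(coords(geo)[pi, ], nodeLabels(geo)[pi])
  net2 <- binaryNetwork(a2, geo2)
  d2 <- distanceMatrix(geo2)
  expect_equal(matchingMatrix(net2), matchingMatrix(net)[pi, pi])
  expect_equal(communicability(net2), communicability(net))
  p1 <- topologyProfile(net, d)
  p2 <- topologyProfile(net2, d2)
  expect_equal(p1[c(1, 2, 3, 4)], p2[c(1, 2, 3, 4)])
})

test_that("both density conventions are exposed", {
  ## 400 edges on 116 nodes: 3% under the directed-pair denominator
  set.seed(1)
  idx <- sample(116 * 115 / 2, 400)
  a <- matrix(0, 116, 116)
  ut <- which(upper.tri(a))
  a[ut[idx]] <- 1
  a <- a + t(a)
  net <- binaryNetwork(a)
  expect_equal(edgeDensity(net, "directed-denominator"), 400 / (116 * 115))
  expect_equal(round(edgeDensity(net, "directed-denominator"), 2), 0.03)
  expect_equal(edgeDensity(net, "standard"), 2 * 400 / (116 * 115))
  k5 <- binaryNetwork(1 - diag(5))
  expect_equal(edgeDensity(k5, "standard"), 1)
})
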