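test_that("consensus network counts shared edges with a >= cut", {
  base <- er_network(12, 0.3, 1)
  ## identical subjects reproduce the common graph at any threshold
  for (th in c(0.3, 0.7, 1)) {
    cons <- consensusNetwork(rep(list(base), 9), th)
    expect_identical(adjacency(cons), adjacency(base))
  }
  ## 69 of 100 subjects is below a 70% cut; 70 of 100 is at it
  n <- 6
  with_edge <- binaryNetwork({a <- matrix(0, n, n); a[1, 2] <- a[2, 1] <- 1; a})
  without <- binaryNetwork(matrix(0, n, n))
  cohort69 <- c(rep(list(with_edge), 69), rep(list(without), 31))
  cohort70 <- c(rep(list(with_edge), 70), rep(list(without), 30))
  expect_equal(edgeCount(consensusNetwork(cohort69, 0.70)), 0)
  expect_equal(edgeCount(consensusNetwork(cohort70, 0.70)), 1)
  ## brute-force per-edge counting oracle on 50 random subjects
  cohort <- lapply(1:50, function(s) er_network(12, 0.25, s + 10))
  cons <- consensusNetwork(cohort, 0.4)
  oracle <- matrix(0, 12, 12)
  for (i in 1:11) for (j in (i + 1):12) {
    cnt <- sum(vapply(cohort, function(net) adjacency(net)[i, j], 0))
    if (cnt >= 0.4 * 50) oracle[i, j] <- oracle[j, i] <- 1
  }
  expect_identical(adjacency(cons), oracle)
  ## monotone: raising the threshold never adds edges
  e_prev <- Inf
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    cons_th <- consensusNetwork(cohort, th)
    expect_true(all(adjacency(cons_th) <= adjacency(consensusNetwork(cohort, th - 0.1))))
    expect_lte(edgeCount(cons_th), e_prev)
    e_prev <- edgeCount(cons_th)
  }
  expect_error(consensusNetwork(list(base, er_network(5, .2, 2)), .5), "dimension")
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  for (s in 1:5) {
    net <- er_network(25, 0.2, s + 30)
    null <- rewiredNull(net, iters_per_edge = 50, rng_seed = s)
    expect_identical(sort(rowSums(adjacency(null))),
                     sort(rowSums(adjacency(net))))
    expect_identical(rowSums(adjacency(null)), rowSums(adjacency(net)))
    expect_equal(edgeCount(null), edgeCount(net))
    expect_true(all(diag(adjacency(null)) == 0))
  }
  ## complete graph is a fixed point
  k5 <- binaryNetwork(1 - diag(5))
  expect_identical(adjacency(rewiredNull(k5, 50, 3)), adjacency(k5))
  ## 50 iterations per edge is the default
  expect_equal(formals(rewiredNull)$iters_per_edge, 50)
})

test_that("rich-club coefficients match the subgraph-density definition", {
  ## K5: phi = 2*10/(5*4) = 1 at every defined level, phi_norm = 1
  k5 <- binaryNetwork(1 - diag(5))
  curve <- richClubAnalysis(k5, n_nulls = 100, rng_seed = 1)
  tab <- curveTable(curve)
  def <- tab[tab$defined, ]
  expect_true(all(def$phi == 1))
  expect_true(all(def$phi_norm == 1))
  expect_equal(def$phi[def$k == 3], 1)
  ## 15-node toy graph against a brute-force oracle at every k
  net <- er_network(15, 0.35, 77)
  a <- adjacency(net)
  tab2 <- curveTable(richClubAnalysis(net, n_nulls = 100, rng_seed = 2))
  deg <- rowSums(a)
  for (r in seq_len(nrow(tab2))) {
    k <- tab2$k[r]
    sel <- which(deg > k)
    if (length(sel) < 2) {
      expect_false(tab2$defined[r])
    } else {
      ek <- sum(a[sel, sel]) / 2
      expect_equal(tab2$phi[r], 2 * ek / (length(sel) * (length(sel) - 1)))
    }
  }
  ## p-values reproducible from the seed
  tab3 <- curveTable(richClubAnalysis(net, n_nulls = 100, rng_seed = 2))
  expect_identical(tab2, tab3)
})

test_that("random graphs show no spurious rich club", {
  frac_sig <- phi_norms <- c()
  for (s in 1:50) {
    net <- er_network(60, 0.15, s + 200)
    tab <- curveTable(richClubAnalysis(net, n_nulls = 100, rng_seed = s))
    def <- tab[tab$defined, ]
    phi_norms <- c(phi_norms, def$phi_norm)
    frac_sig <- c(frac_sig, def$p_perm < 0.05)
  }
  expect_equal(mean(phi_norms), 1, tolerance = 0.05)
  expect_lt(mean(frac_sig), 0.10)
})

test_that("seed extraction selects and re-embeds the rich club", {
  cohort <- synthNeonatalCohort(rng_seed = 5)
  cons <- consensusNetwork(cohort, 0.70)
  curve <- richClubAnalysis(cons, n_nulls = 200, rng_seed = 6)
  geo116 <- packagedAtlas(116)
  seed <- extractSeed(cons, curve, 0.05, geo116)
  expect_equal(edgeCount(seed), 10)
  on_nodes <- which(rowSums(adjacency(seed)) > 0)
  expect_equal(length(on_nodes), 5)
  ## identity map, same geometry: indices preserved
  seed_same <- extractSeed(cons, curve, 0.05, packagedAtlas(90))
  src <- which(rowSums(adjacency(seed_same)) > 0)
  expect_setequal(nodeLabels(geo116)[on_nodes], nodeLabels(cons)[src])
  ## the extracted subgraph is fully interconnected
  expect_identical(adjacency(seed)[on_nodes, on_nodes], 1 - diag(5))
  ## no significant level: explicit failure carrying the curve
  er <- er_network(40, 0.2, 301)
  curve_er <- richClubAnalysis(er, n_nulls = 100, rng_seed = 7)
  tab_er <- curveTable(curve_er)
  if (!any(tab_er$defined & tab_er$phi_norm > 1 & tab_er$p_perm < 0.05)) {
    err <- tryCatch(extractSeed(er, curve_er, 0.05, geo116,
                                labels = paste0("x", 1:40)),
                    error = function(e) e)
    expect_s3_class(err, "stochnet_no_richclub")
    expect_s4_class(err$curve, "RichClubCurve")
  }
  ## unmapped labels abort
  expect_error(extractSeed(cons, curve, 0.05, geo116,
                           label_map = c(Lingual_L = "nowhere")),
               "unmapped|absent")
})
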