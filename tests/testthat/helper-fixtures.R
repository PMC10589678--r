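# shared fixtures, built in code

# Erdos-Renyi binary network
er_network <- function(n, p, seed, geometry = NULL) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.numeric(runif(sum(ut)) < p)
  a <- a + t(a)
  binaryNetwork(a, geometry)
}

rand_geometry <- function(n, seed) synthGeometry(n, "random-box", seed)

# brute-force matching index straight from the set definition
matching_oracle <- function(a) {
  n <- nrow(a)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    gi <- setdiff(which(a[i, ] == 1), j)
    gj <- setdiff(which(a[j, ] == 1), i)
    u <- union(gi, gj)
    m[i, j] <- if (length(u) == 0) 0 else length(intersect(gi, gj)) / length(u)
  }
  m
}

# enumerate all simple paths between s and t (tiny graphs only)
all_simple_paths_r <- function(a, s, t) {
  res <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) { res[[length(res) + 1]] <<- path; return(invisible()) }
    for (w in which(a[v, ] == 1)) if (!(w %in% path)) rec(c(path, w))
  }
  rec(s)
  res
}

# brute-force nodal betweenness by exhaustive shortest-path enumeration
betweenness_oracle <- function(a) {
  n <- nrow(a)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_r(a, s, t)
    if (!length(paths)) next
    len <- vapply(paths, length, 0L)
    sp <- paths[len == min(len)]
    for (p in sp) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(sp)
    }
  }
  btw
}

# brute-force clustering / efficiency / shortest-path length (tiny graphs)
clustering_oracle <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, 0)
}

efficiency_oracle <- function(a) {
  n <- nrow(a)
  tot <- 0
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_r(a, s, t)
    if (length(paths)) tot <- tot + 1 / (min(vapply(paths, length, 0L)) - 1)
  }
  2 * tot / (n * (n - 1))
}

# truncated matrix-exponential power series (independent of eigen route)
expm_series <- function(a) {
  term <- diag(nrow(a)); acc <- diag(nrow(a))
  for (i in 1:40) { term <- term %*% a / i; acc <- acc + term }
  acc
}

# small shared sweep archive (built once per test run)
.fixture_env <- new.env()
tiny_archive <- function() {
  if (is.null(.fixture_env$tiny)) {
    geo <- rand_geometry(30, 404)
    seed_net <- er_network(30, 0, 1, geo)
    a <- adjacency(seed_net); a[1, 2] <- a[2, 1] <- 1; a[2, 3] <- a[3, 2] <- 1
    seed_net <- binaryNetwork(a, geo)
    d <- distanceMatrix(geo)
    .fixture_env$tiny <- list(
      archive = parameterSweep(seed_net, d, c(-3, 0), c(0, 0.8), reps = 5,
                               m_target = 60, master_seed = 99),
      seed_net = seed_net, dist = d, geo = geo)
  }
  .fixture_env$tiny
}
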