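# exact two-tailed p-value of a Pearson r under H0, used as the
# independent oracle for critical_r
p_of_r <- function(r, n) {
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
}

test_that("critical_r inverts the two-tailed Pearson test", {
  expect_lt(abs(critical_r(1e-4, 4800) - 0.0562), 1e-3)

  # bisection oracle on the exact p(r) function
  for (n in c(10, 100, 4800)) {
    lo <- 0
    hi <- 1 - 1e-12
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (p_of_r(mid, n) > 1e-4) lo <- mid else hi <- mid
    }
    expect_equal(critical_r(1e-4, n), (lo + hi) / 2, tolerance = 1e-9)
  }

  # smaller p demands a larger r
  expect_gt(critical_r(1e-4, 500), critical_r(1e-2, 500))
  expect_error(critical_r(1e-4, 3), "n_samples")
  expect_error(critical_r(0, 100), "in \\(0, 1\\)")
})

test_that("threshold_fc keeps only supra-threshold positive correlations", {
  fcv <- matrix(0.01, 4, 4)
  diag(fcv) <- 0
  fc <- connectivity_matrix(fcv, "functional")
  expect_true(all(threshold_fc(fc, 0.0562)$values == 0))

  m <- matrix(0, 4, 4)
  m[1, 2] <- 0.3
  m[3, 4] <- -0.3
  m <- m + t(m)
  fc2 <- connectivity_matrix(m, "functional")
  thr <- threshold_fc(fc2, 0.1)
  expect_equal(thr$values[1, 2], 0.3)   # kept with weight
  expect_equal(thr$values[3, 4], 0)     # negative dropped
  thr_abs <- threshold_fc(fc2, 0.1, absolute = TRUE)
  expect_equal(thr_abs$values[3, 4], -0.3)

  # counting oracle on random matrices
  for (seed in 1:20) {
    fc3 <- rand_fc(15, seed = seed)
    rc <- critical_r(1e-4, 4800)
    thr3 <- threshold_fc(fc3, rc)
    ut <- upper.tri(fc3$values)
    expect_equal(sum(thr3$values[ut] != 0), sum(fc3$values[ut] >= rc))
  }
  expect_error(threshold_fc(fc, 1.5), "r_crit")
})

test_that("degree centrality counts nonzero connections", {
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 3] <- 5
  path <- path + t(path)
  d <- degree_centrality(connectivity_matrix(path, "structural"))
  expect_equal(unname(d$values), c(1, 2, 1))

  empty <- connectivity_matrix(matrix(0, 4, 4), "functional")
  expect_equal(unname(degree_centrality(empty)$values), rep(0, 4))

  for (seed in 1:20) {
    m <- rand_sc(12, seed = seed)
    d2 <- degree_centrality(m)
    brute <- vapply(1:12, function(i) sum(m$values[i, -i] != 0), numeric(1))
    expect_equal(unname(d2$values), brute)
    expect_true(all(d2$values <= 11))
  }
})

test_that("eigenvector centrality matches dense eigendecomposition", {
  # complete graph: perfect symmetry, unit norm
  k4 <- connectivity_matrix(matrix(1, 4, 4) - diag(4), "structural")
  expect_equal(unname(eigenvector_centrality(k4)$values), rep(0.5, 4),
               tolerance = 1e-9)

  # star: centre strictly greatest, leaves equal (bipartite case)
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1
  star <- star + t(star)
  ev <- eigenvector_centrality(connectivity_matrix(star, "structural"))
  expect_gt(ev$values[1], max(ev$values[2:4]) + 0.1)
  expect_equal(stats::sd(ev$values[2:4]), 0, tolerance = 1e-9)

  for (seed in 1:20) {
    m <- rand_sc(20, seed = seed)
    for (weighted in c(FALSE, TRUE)) {
      ev2 <- eigenvector_centrality(m, weighted = weighted)
      a <- m$values
      if (!weighted) a <- (a != 0) * 1
      es <- eigen(a, symmetric = TRUE)
      ref <- abs(es$vectors[, which.max(es$values)])
      expect_lt(max(abs(unname(ev2$values) - ref)), 1e-8)
      expect_equal(sqrt(sum(ev2$values^2)), 1, tolerance = 1e-9)
    }
  }

  expect_error(eigenvector_centrality(
    connectivity_matrix(matrix(0, 3, 3), "structural")), "no edges")
})

test_that("pagerank centrality solves the damped random-walk fixed point", {
  two <- connectivity_matrix(matrix(c(0, 1, 1, 0), 2), "structural")
  expect_equal(unname(pagerank_centrality(two)$values), c(0.5, 0.5),
               tolerance = 1e-10)

  for (seed in 1:20) {
    m <- rand_sc(15, seed = seed)
    pr <- pagerank_centrality(m, damping = 0.85)
    expect_equal(sum(pr$values), 1, tolerance = 1e-10)
    # direct linear solve oracle: (I - d P^T) x = (1-d)/N
    a <- m$values
    p <- a / rowSums(a)
    x <- solve(diag(15) - 0.85 * t(p), rep(0.15 / 15, 15))
    expect_lt(max(abs(unname(pr$values) - x / sum(x))), 1e-8)
  }

  # dangling node: isolated region still receives teleport mass
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 1
  pr2 <- pagerank_centrality(connectivity_matrix(m2, "structural"))
  expect_equal(sum(pr2$values), 1, tolerance = 1e-10)
  expect_gt(pr2$values[3], 0)
})

test_that("standardize_rescale maps to [-1,1] and inverts exactly", {
  v <- centrality_vector(c(a = 0, b = 5, c = 10), "degree", "raw")
  s <- standardize_rescale(v)
  expect_equal(unname(s$values), c(-1, 0, 1))

  for (seed in 1:20) {
    set.seed(seed)
    raw <- stats::rnorm(30, 50, 12)
    s2 <- standardize_rescale(centrality_vector(raw, "pagerank", "raw"))
    expect_equal(min(s2$values), -1, tolerance = 1e-12)
    expect_equal(max(s2$values), 1, tolerance = 1e-12)
    back <- unstandardize(s2)
    expect_equal(unname(back$values), raw, tolerance = 1e-12)
  }

  # plain-vector interface mirrors the centrality interface
  sr <- standardize_rescale(c(0, 5, 10))
  expect_equal(sr$values, c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(unstandardize(c(-1, 0, 1), sr$standardization), c(0, 5, 10))

  # identity-like params leave input nearly unchanged
  idp <- list(mean = 0, sd = 1, post_z_min = -1, post_z_max = 1)
  expect_equal(unstandardize(c(-1, 0, 1), idp), c(-1, 0, 1))

  expect_error(standardize_rescale(centrality_vector(rep(2, 5), "degree",
                                                     "raw")), "constant")
  expect_error(unstandardize(centrality_vector(1:3 / 3, "degree", "raw")),
               "standardization")
})

test_that("centralities are permutation-equivariant", {
  for (seed in 1:10) {
    m <- rand_sc(14, seed = seed)
    set.seed(seed + 500)
    perm <- sample(14)
    mp <- connectivity_matrix(m$values[perm, perm], "structural")
    for (fn in list(degree_centrality,
                    function(x) eigenvector_centrality(x),
                    function(x) pagerank_centrality(x))) {
      v <- unname(fn(m)$values)
      vp <- unname(fn(mp)$values)
      expect_equal(vp, v[perm], tolerance = 1e-8)
    }
  }
})

test_that("centralities agree with an independent graph library", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    m <- rand_sc(16, seed = seed)
    g <- igraph::graph_from_adjacency_matrix(m$values, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(unname(degree_centrality(m)$values),
                 unname(igraph::degree(g)))
    ev <- unname(eigenvector_centrality(m, weighted = TRUE)$values)
    ev_ig <- unname(igraph::eigen_centrality(g)$vector)
    expect_equal(ev / max(ev), ev_ig / max(ev_ig), tolerance = 1e-6)
    pr <- unname(pagerank_centrality(m, weighted = TRUE)$values)
    pr_ig <- unname(igraph::page_rank(g, damping = 0.85)$vector)
    expect_equal(pr, pr_ig, tolerance = 1e-6)
  }
})
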