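test_that("encode_sc_as_graph builds two directed edges per connection", {
  m <- matrix(0, 2, 2)
  m[1, 2] <- m[2, 1] <- 5
  g <- encode_sc_as_graph(connectivity_matrix(m, "structural"))
  expect_equal(g$n_edges, 2)
  expect_setequal(paste(g$senders, g$receivers), c("1 2", "2 1"))

  sc <- rand_sc(9, seed = 2)
  g2 <- encode_sc_as_graph(sc, node_init = 1.0)
  expect_equal(g2$node_features, matrix(1, 9, 1))
  expect_equal(g2$n_edges, sum(sc$values != 0))   # counting oracle
  expect_true(all(g2$edge_features >= 0 & g2$edge_features <= 1))

  g3 <- encode_sc_as_graph(sc, transform = "none")
  expect_equal(sort(unique(as.numeric(g3$edge_features))),
               sort(unique(sc$values[sc$values != 0])))

  g4 <- encode_sc_as_graph(sc, all_pairs = TRUE)
  expect_equal(g4$n_edges, 9 * 8)

  expect_error(encode_sc_as_graph(
    connectivity_matrix(matrix(0, 3, 3), "structural")), "no edges")
})

test_that("mlp_forward computes the three-layer formula", {
  p0 <- sc2fc:::init_mlp(2, 3, 2, layernorm = FALSE)
  for (nm in names(p0)) p0[[nm]] <- p0[[nm]] * 0
  expect_equal(mlp_forward(c(1, 2), p0), matrix(0, 1, 2))

  # constructed pass-through: 1 -> 1 identity for positive input
  pid <- list(W1 = matrix(c(1, 0, 0), 3, 1), b1 = numeric(3),
              W2 = rbind(c(1, 0, 0), 0, 0), b2 = numeric(3),
              W3 = matrix(c(1, 0, 0), 1, 3), b3 = 0)
  for (x in c(0.5, 2, 7)) expect_equal(as.numeric(mlp_forward(x, pid)), x)

  # formula oracle with layer norm, random parameters
  set.seed(11)
  p <- sc2fc:::init_mlp(4, 6, 5, layernorm = TRUE)
  x <- matrix(stats::rnorm(12), 3, 4)
  out <- mlp_forward(x, p)
  for (r in 1:3) {
    h1 <- pmax(0, p$W1 %*% x[r, ] + p$b1)
    h2 <- pmax(0, p$W2 %*% h1 + p$b2)
    y <- as.numeric(p$W3 %*% h2 + p$b3)
    yc <- y - mean(y)
    s <- sqrt(mean(yc^2) + 1e-6)
    ref <- (yc / s) * p$ln_gain + p$ln_offset
    expect_equal(as.numeric(out[r, ]), ref, tolerance = 1e-12)
  }

  expect_error(mlp_forward(c(1, 2, 3), p0), "width")
})

test_that("edge_update, aggregate_edges and node_update match loop oracles", {
  set.seed(21)
  L <- 3
  nE <- 7
  nN <- 4
  p_e <- sc2fc:::init_mlp(3 * L, 5, L, layernorm = TRUE)
  e <- matrix(stats::rnorm(nE * L), nE)
  snd <- c(1, 2, 3, 4, 1, 2, 3)
  rcv <- c(2, 3, 4, 1, 3, 4, 1)
  vs <- matrix(stats::rnorm(nN * L), nN)
  out <- edge_update(e, vs[snd, ], vs[rcv, ], p_e)
  expect_equal(dim(out), c(nE, L))
  for (k in 1:nE) {
    ref <- mlp_forward(c(e[k, ], vs[snd[k], ], vs[rcv[k], ]), p_e)
    expect_equal(out[k, ], as.numeric(ref), tolerance = 1e-12)
  }

  agg <- aggregate_edges(matrix(c(1, 2, 3)), c(1, 1, 2), 3)
  expect_equal(agg, rbind(3, 3, 0))
  # permutation of edges leaves the sum unchanged
  ev <- matrix(stats::rnorm(nE * L), nE)
  a1 <- aggregate_edges(ev, rcv, nN)
  prm <- sample(nE)
  a2 <- aggregate_edges(ev[prm, ], rcv[prm], nN)
  expect_matrix_equal(a1, a2, 1e-12)
  for (i in 1:nN) {
    sel <- which(rcv == i)
    ref <- if (length(sel)) colSums(ev[sel, , drop = FALSE]) else rep(0, L)
    expect_equal(a1[i, ], ref, tolerance = 1e-12)
  }
  expect_error(aggregate_edges(ev, rep(9, nE), nN), "out of range")

  p_n <- sc2fc:::init_mlp(2 * L, 5, L, layernorm = TRUE)
  vout <- node_update(vs, a1, p_n)
  for (i in 1:nN) {
    expect_equal(vout[i, ], as.numeric(mlp_forward(c(vs[i, ], a1[i, ]), p_n)),
                 tolerance = 1e-12)
  }
})

test_that("gnn_forward is permutation-equivariant and deterministic", {
  sc <- rand_sc(8, seed = 5)
  fc <- rand_fc(8, seed = 15, atlas = sc$atlas)
  s <- subject_record("s", sc, fc)
  g <- make_edge_task(s)
  params <- tiny_params(n_steps = 4L)

  out1 <- gnn_forward(g, params)$per_step_outputs
  out2 <- gnn_forward(g, params)$per_step_outputs
  expect_identical(out1, out2)   # bit-identical rerun
  expect_length(out1, 4)

  for (seed in 1:5) {
    set.seed(seed + 900)
    perm <- sample(8)
    # relabel nodes: edge k (i -> j) becomes (perm[i] -> perm[j])
    gp <- graph_sample(g$node_features[order(perm), , drop = FALSE],
                       g$edge_features, perm[g$senders], perm[g$receivers],
                       edge_targets = g$edge_targets)
    op <- gnn_forward(gp, params, backend = "r")$per_step_outputs
    o0 <- gnn_forward(g, params, backend = "r")$per_step_outputs
    for (t in seq_along(o0)) expect_matrix_equal(op[[t]], o0[[t]], 1e-10)
  }
})

test_that("zero steps produce no outputs", {
  g <- make_edge_task(tiny_subject(6, seed = 2))
  p0 <- tiny_params(n_steps = 0L)
  expect_length(gnn_forward(g, p0)$per_step_outputs, 0)
})

test_that("isomorphic disconnected components get identical outputs", {
  # two copies of the same 4-node component in one graph
  m <- matrix(0, 4, 4)
  m[1, 2] <- 3; m[2, 3] <- 1; m[3, 4] <- 4; m[1, 4] <- 2
  m <- m + t(m)
  big <- matrix(0, 8, 8)
  big[1:4, 1:4] <- m
  big[5:8, 5:8] <- m
  g <- encode_sc_as_graph(connectivity_matrix(big, "structural"))
  params <- tiny_params(n_steps = 3L)
  out <- gnn_forward(g, params)$per_step_outputs[[3]]
  first <- g$senders <= 4
  # edges are enumerated identically within each block
  expect_matrix_equal(out[first, , drop = FALSE],
                      out[!first, , drop = FALSE], 1e-12)
})

test_that("compiled and reference passes agree to machine precision", {
  for (task in c("edge_prediction", "centrality_prediction")) {
    s <- tiny_subject(7, seed = 3, with_centralities = TRUE)
    g <- if (task == "edge_prediction") {
      make_edge_task(s)
    } else {
      make_centrality_task(s, "degree")
    }
    params <- tiny_params(task = task, L = 5L, n_steps = 4L)
    fr <- gnn_forward(g, params, backend = "r")$per_step_outputs
    fc_ <- gnn_forward(g, params, backend = "cpp")$per_step_outputs
    for (t in seq_along(fr)) expect_matrix_equal(fr[[t]], fc_[[t]], 1e-13)
    lr <- gnn_loss_and_grads(g, params, backend = "r")
    lc <- gnn_loss_and_grads(g, params, backend = "cpp")
    expect_equal(lr$loss, lc$loss, tolerance = 1e-13)
    for (mn in names(lr$grads)) {
      for (an in names(lr$grads[[mn]])) {
        expect_matrix_equal(lr$grads[[mn]][[an]], lc$grads[[mn]][[an]],
                            1e-12)
      }
    }
  }
})

test_that("analytic gradients match finite differences on a 5-node graph", {
  s <- tiny_subject(5, seed = 4, with_centralities = TRUE)
  g <- make_edge_task(s)
  err <- gradient_check(g, tiny_params(L = 4L, n_steps = 3L, seed = 7))
  expect_lt(as.numeric(err), 1e-5)

  gn <- make_centrality_task(s, "pagerank")
  errn <- gradient_check(gn, tiny_params(task = "centrality_prediction",
                                         L = 4L, n_steps = 3L, seed = 8))
  expect_lt(as.numeric(errn), 1e-5)
})

test_that("step-t outputs only see structure within t hops", {
  # path graph: perturbing the far end cannot reach edge (1,2) in 1 step
  n <- 8
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- 2
  m <- m + t(m)
  m2 <- m
  m2[n - 1, n] <- m2[n, n - 1] <- 9
  params <- tiny_params(n_steps = 3L)
  enc <- function(mm) {
    # fixed transform so the shared edges keep identical input features
    encode_sc_as_graph(connectivity_matrix(mm, "structural"),
                       transform = "none")
  }
  o1 <- gnn_forward(enc(m), params, backend = "r")$per_step_outputs
  o2 <- gnn_forward(enc(m2), params, backend = "r")$per_step_outputs
  near <- which(enc(m)$senders == 1 & enc(m)$receivers == 2)
  # one step: unaffected; three steps: still out of reach (distance > 3)
  expect_equal(o1[[1]][near, ], o2[[1]][near, ], tolerance = 1e-12)
  expect_equal(o1[[3]][near, ], o2[[3]][near, ], tolerance = 1e-12)
})

test_that("batch_graphs concatenates with offsets and equal subject weight", {
  g1 <- make_edge_task(tiny_subject(5, seed = 1))
  g2 <- make_edge_task(tiny_subject(7, seed = 2))
  bt <- batch_graphs(list(g1, g2))
  expect_equal(bt$graph$n_nodes, 12)
  expect_equal(bt$graph$n_edges, g1$n_edges + g2$n_edges)
  expect_true(all(bt$graph$senders[-(1:g1$n_edges)] > 5))
  expect_equal(sum(bt$row_weights[1:g1$n_edges]), 0.5, tolerance = 1e-12)
  expect_equal(sum(bt$row_weights), 1, tolerance = 1e-12)

  # batched loss is the mean of per-subject losses
  params <- tiny_params(n_steps = 2L)
  lb <- gnn_loss_and_grads(bt$graph, params, bt$row_weights)$loss
  l1 <- gnn_loss_and_grads(g1, params)$loss
  l2 <- gnn_loss_and_grads(g2, params)$loss
  expect_equal(lb, (l1 + l2) / 2, tolerance = 1e-12)
})
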