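#' Graph sample: directed-edge-list encoding of a connectome
#'
#' The network consumes graphs as flat arrays: an `n_nodes x d_v` node
#' feature matrix, an `n_edges x d_e` edge feature matrix and integer
#' sender/receiver indices.  A symmetric connectivity matrix is encoded
#' as two directed edges per nonzero off-diagonal pair; there are no
#' self-loops.
#'
#' @param node_features Numeric matrix, one row per node.
#' @param edge_features Numeric matrix, one row per directed edge.
#' @param senders,receivers 1-based integer vectors of length `n_edges`.
#' @param edge_targets,node_targets Optional target matrices aligned to
#'   the edge list / node list.
#' @param target_standardization Optional standardization constants for
#'   inverting targets or predictions back to raw space.
#' @return An object of class `graph_sample`.
#' @export
graph_sample <- function(node_features, edge_features, senders, receivers,
                         edge_targets = NULL, node_targets = NULL,
                         target_standardization = NULL) {
  node_features <- as.matrix(node_features)
  edge_features <- as.matrix(edge_features)
  n_nodes <- nrow(node_features)
  n_edges <- nrow(edge_features)
  senders <- as.integer(senders)
  receivers <- as.integer(receivers)
  if (length(senders) != n_edges || length(receivers) != n_edges) {
    stop("senders/receivers must have one entry per edge")
  }
  if (n_edges > 0) {
    if (min(senders, receivers) < 1L || max(senders, receivers) > n_nodes) {
      stop("edge indices out of range [1, n_nodes]")
    }
    if (any(senders == receivers)) stop("self-loop edges are not allowed")
  }
  if (!is.null(edge_targets)) {
    edge_targets <- as.matrix(edge_targets)
    stopifnot(nrow(edge_targets) == n_edges)
  }
  if (!is.null(node_targets)) {
    node_targets <- as.matrix(node_targets)
    stopifnot(nrow(node_targets) == n_nodes)
  }
  structure(list(node_features = node_features,
                 edge_features = edge_features,
                 senders = senders, receivers = receivers,
                 edge_targets = edge_targets, node_targets = node_targets,
                 target_standardization = target_standardization,
                 n_nodes = n_nodes, n_edges = n_edges),
            class = "graph_sample")
}

#' @export
print.graph_sample <- function(x, ...) {
  cat("<graph_sample> ", x$n_nodes, " nodes, ", x$n_edges,
      " directed edges\n", sep = "")
  invisible(x)
}

#' Encode a structural matrix as a directed graph sample
#'
#' One directed edge per ordered pair (i, j), i != j, with `sc[i, j] != 0`
#' (sparse mode, the default) or for every ordered pair (`all_pairs`).
#' Raw streamline counts are heavy-tailed, so the default edge-feature
#' transform is `log(1 + count)` followed by min-max rescaling to
#' `[0, 1]` within the subject; `transform = "none"` passes counts
#' through untouched.
#'
#' @param sc A structural `connectivity_matrix`.
#' @param node_init Scalar broadcast to all nodes, or an
#'   `n_nodes x d_v` matrix of node input features.
#' @param transform `"log1p_minmax"` or `"none"`.
#' @param all_pairs Include zero-weight edges (dense connectivity).
#' @return A `graph_sample` without targets.
#' @export
encode_sc_as_graph <- function(sc, node_init = 1.0,
                               transform = c("log1p_minmax", "none"),
                               all_pairs = FALSE) {
  stopifnot(inherits(sc, "connectivity_matrix"))
  transform <- match.arg(transform)
  a <- sc$values
  n <- nrow(a)
  off <- !diag(TRUE, n)
  keep <- if (all_pairs) off else off & (a != 0)
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("structural matrix has no edges")
  w <- a[keep]
  if (transform == "log1p_minmax") {
    w <- log1p(w)
    rng <- range(w)
    w <- if (rng[2] > rng[1]) (w - rng[1]) / (rng[2] - rng[1]) else w * 0 + 1
  }
  nf <- if (is.matrix(node_init)) {
    stopifnot(nrow(node_init) == n)
    node_init
  } else {
    matrix(node_init, n, 1)
  }
  graph_sample(node_features = nf,
               edge_features = matrix(w, ncol = 1),
               senders = idx[, 1], receivers = idx[, 2])
}

## ---- MLP primitives ---------------------------------------------------

LN_EPS <- 1e-6

init_mlp <- function(d_in, d_hidden, d_out, n_hidden = 2L,
                     layernorm = TRUE) {
  # variance scaling by fan-in; caller controls the RNG stream
  rnw <- function(dout, din) {
    matrix(stats::rnorm(dout * din, sd = sqrt(1 / din)), dout, din)
  }
  # hidden biases get a small random offset so no unit sits exactly on
  # the ReLU kink at initialization (keeps the loss differentiable at
  # the starting point, which finite-difference checks rely on)
  p <- list(W1 = rnw(d_hidden, d_in), b1 = stats::rnorm(d_hidden, sd = 0.01),
            W2 = rnw(d_hidden, d_hidden),
            b2 = stats::rnorm(d_hidden, sd = 0.01),
            W3 = rnw(d_out, d_hidden), b3 = numeric(d_out))
  if (layernorm) {
    p$ln_gain <- rep(1, d_out)
    p$ln_offset <- numeric(d_out)
  }
  p
}

addb <- function(m, b) m + rep(b, each = nrow(m))

#' Forward pass of a two-hidden-layer MLP
#'
#' `y = W3 relu(W2 relu(W1 x + b1) + b2) + b3`, applied row-wise to a
#' matrix of inputs, with optional layer normalization (over features,
#' per row) on the output.
#'
#' @param x Input matrix (rows are independent samples) or vector.
#' @param p MLP parameter list with `W1, b1, W2, b2, W3, b3` and
#'   optionally `ln_gain`, `ln_offset`.
#' @return Output matrix with `nrow(x)` rows.
#' @export
mlp_forward <- function(x, p) {
  mlp_forward_cached(x, p)$out
}

mlp_forward_cached <- function(x, p) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(p$W1)) {
    stop("MLP input width ", ncol(x), " != expected ", ncol(p$W1))
  }
  h1 <- addb(x %*% t(p$W1), p$b1)
  h1[h1 < 0] <- 0
  h2 <- addb(h1 %*% t(p$W2), p$b2)
  h2[h2 < 0] <- 0
  y <- addb(h2 %*% t(p$W3), p$b3)
  cache <- list(x = x, h1 = h1, h2 = h2)
  if (!is.null(p$ln_gain)) {
    mu <- rowMeans(y)
    yc <- y - mu
    s <- sqrt(rowMeans(yc^2) + LN_EPS)
    yhat <- yc / s
    out <- addb(yhat * rep(p$ln_gain, each = nrow(y)), p$ln_offset)
    cache$yhat <- yhat
    cache$s <- s
    list(out = out, cache = cache)
  } else {
    list(out = y, cache = cache)
  }
}

# returns list(dx, grads = list(W1,b1,...))
mlp_backward <- function(dout, p, cache) {
  g <- list()
  if (!is.null(p$ln_gain)) {
    yhat <- cache$yhat
    g$ln_gain <- colSums(dout * yhat)
    g$ln_offset <- colSums(dout)
    dyhat <- dout * rep(p$ln_gain, each = nrow(dout))
    m1 <- rowMeans(dyhat)
    m2 <- rowMeans(dyhat * yhat)
    dy <- (dyhat - m1 - yhat * m2) / cache$s
  } else {
    dy <- dout
  }
  g$W3 <- crossprod(dy, cache$h2)
  g$b3 <- colSums(dy)
  dh2 <- dy %*% p$W3
  dh2[cache$h2 <= 0] <- 0
  g$W2 <- crossprod(dh2, cache$h1)
  g$b2 <- colSums(dh2)
  dh1 <- dh2 %*% p$W2
  dh1[cache$h1 <= 0] <- 0
  g$W1 <- crossprod(dh1, cache$x)
  g$b1 <- colSums(dh1)
  list(dx = dh1 %*% p$W1, grads = g)
}

## ---- model parameters -------------------------------------------------

#' Initialize message-passing network parameters
#'
#' Encode-process-decode layout: independent edge and node encoders, a
#' recurrent core (edge update `phi^e` and node update `phi^v`) that
#' receives the concatenation of the encoder output and the current
#' latent (skip connection), and a linear-output decoder applied after
#' every message-passing step.  All update functions are MLPs with two
#' hidden layers of `latent_width` units; encoder and core outputs are
#' layer-normalized.
#'
#' @param d_edge_in,d_node_in Input feature widths.
#' @param d_out Decoder output width (1 for both tasks here).
#' @param task `"edge_prediction"` (decode edges) or
#'   `"centrality_prediction"` (decode nodes).
#' @param latent_width Latent and hidden width; default 16.
#' @param n_steps Message-passing steps; default 10.
#' @param aggregation `"sum"` (default) or `"mean"` incoming-edge
#'   aggregation.
#' @param seed Integer seed for the deterministic initialization.
#' @return An object of class `model_params`.
#' @export
init_model_params <- function(d_edge_in = 1L, d_node_in = 1L, d_out = 1L,
                              task = c("edge_prediction",
                                       "centrality_prediction"),
                              latent_width = 16L, n_steps = 10L,
                              aggregation = c("sum", "mean"),
                              seed = 1L) {
  task <- match.arg(task)
  aggregation <- match.arg(aggregation)
  L <- as.integer(latent_width)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  mlps <- list(
    edge_encoder = init_mlp(d_edge_in, L, L),
    node_encoder = init_mlp(d_node_in, L, L),
    core_edge = init_mlp(6L * L, L, L),
    core_node = init_mlp(3L * L, L, L),
    decoder = init_mlp(L, L, d_out, layernorm = FALSE))
  structure(list(mlps = mlps,
                 hyper = list(task = task, latent_width = L,
                              n_steps = as.integer(n_steps),
                              d_edge_in = as.integer(d_edge_in),
                              d_node_in = as.integer(d_node_in),
                              d_out = as.integer(d_out),
                              aggregation = aggregation)),
            class = "model_params")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.model_params <- function(x, ...) {
  h <- x$hyper
  cat("<model_params> ", h$task, ": ", h$n_steps, " steps, latent width ",
      h$latent_width, ", ", length(unlist(flatten_params(x))),
      " parameters\n", sep = "")
  invisible(x)
}

flatten_params <- function(params) {
  flat <- list()
  for (mn in names(params$mlps)) {
    p <- params$mlps[[mn]]
    for (an in names(p)) flat[[paste0(mn, ".", an)]] <- p[[an]]
  }
  flat
}

unflatten_params <- function(flat, hyper) {
  mlps <- list()
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    mlps[[parts[1]]][[parts[2]]] <- flat[[nm]]
  }
  structure(list(mlps = mlps, hyper = hyper), class = "model_params")
}

## ---- message passing --------------------------------------------------

#' Update every edge latent from its endpoints
#'
#' The edge update `phi^e`: each directed edge's new latent is the MLP
#' applied to the concatenation (edge, sender node, receiver node).
#'
#' @param e_k Edge latent matrix (`n_edges x d`).
#' @param v_sender,v_receiver Node latents gathered to the edges.
#' @param p MLP parameters.
#' @return Updated edge latents.
#' @export
edge_update <- function(e_k, v_sender, v_receiver, p) {
  mlp_forward(cbind(e_k, v_sender, v_receiver), p)
}

#' Sum incoming edge values per node
#'
#' The aggregation `rho^(e->v)`: row i of the result is the element-wise
#' sum (or mean) of `edge_values` over edges whose receiver is node i;
#' nodes with no incoming edges get a zero row.
#'
#' @param edge_values `n_edges x d` matrix.
#' @param receivers 1-based receiver index per edge.
#' @param n_nodes Number of nodes.
#' @param mode `"sum"` or `"mean"`.
#' @return `n_nodes x d` matrix.
#' @export
aggregate_edges <- function(edge_values, receivers, n_nodes,
                            mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  edge_values <- as.matrix(edge_values)
  receivers <- as.integer(receivers)
  if (length(receivers) && (min(receivers) < 1L || max(receivers) > n_nodes)) {
    stop("receiver index out of range")
  }
  out <- matrix(0, n_nodes, ncol(edge_values))
  if (length(receivers)) {
    rs <- rowsum(edge_values, receivers)
    rows <- as.integer(rownames(rs))
    if (mode == "mean") rs <- rs / as.numeric(table(receivers))
    out[rows, ] <- rs
  }
  out
}

#' Update every node latent from its aggregated incoming edges
#'
#' The node update `phi^v`: each node's new latent is the MLP applied to
#' the concatenation (node, aggregated incoming edges).
#'
#' @param v_i Node latent matrix (`n_nodes x d`).
#' @param agg_i Aggregated incoming-edge matrix.
#' @param p MLP parameters.
#' @return Updated node latents.
#' @export
node_update <- function(v_i, agg_i, p) {
  mlp_forward(cbind(v_i, agg_i), p)
}

# scatter-add `values` rows into acc at rows idx
scatter_add <- function(acc, idx, values) {
  rs <- rowsum(values, idx)
  rows <- as.integer(rownames(rs))
  acc[rows, ] <- acc[rows, , drop = FALSE] + rs
  acc
}

#' Run the message-passing network
#'
#' Encodes node and edge features to latents, then for each of `n_steps`
#' rounds: updates every edge from (encoder-output skip, current edge
#' latent, endpoint latents), sum-aggregates incoming edges per node,
#' updates every node, and decodes the current latents to the task
#' output.  Returns the decoded output of every step (training penalizes
#' all of them; prediction uses the last).
#'
#' @param g A `graph_sample`.
#' @param params A `model_params`.
#' @param with_cache Keep intermediate activations for backpropagation
#'   (forces the reference R path).
#' @param backend `"cpp"` (compiled fast path, the default) or `"r"`
#'   (reference implementation).  Both compute the identical
#'   architecture; their agreement is part of the test suite.
#' @return List with `per_step_outputs` (length `n_steps`) and, when
#'   requested, `cache`.
#' @export
gnn_forward <- function(g, params, with_cache = FALSE,
                        backend = getOption("sc2fc.backend", "cpp")) {
  stopifnot(inherits(g, "graph_sample"), inherits(params, "model_params"))
  if (!with_cache && backend == "cpp" && params$hyper$n_steps > 0) {
    h <- params$hyper
    res <- .gnn_pass_cpp(g$node_features, g$edge_features,
                         g$senders - 1L, g$receivers - 1L,
                         matrix(numeric(0), 0, 0),
                         h$task == "edge_prediction", h$n_steps,
                         h$aggregation == "mean", params$mlps,
                         numeric(0), FALSE)
    return(list(per_step_outputs = res$per_step_outputs))
  }
  h <- params$hyper
  mm <- params$mlps
  s <- g$senders
  r <- g$receivers
  enc_e <- mlp_forward_cached(g$edge_features, mm$edge_encoder)
  enc_v <- mlp_forward_cached(g$node_features, mm$node_encoder)
  E0 <- enc_e$out
  V0 <- enc_v$out
  e <- E0
  v <- V0
  outs <- vector("list", h$n_steps)
  steps <- if (with_cache) vector("list", h$n_steps) else NULL
  for (t in seq_len(h$n_steps)) {
    ein <- cbind(E0, e, V0[s, , drop = FALSE], v[s, , drop = FALSE],
                 V0[r, , drop = FALSE], v[r, , drop = FALSE])
    fe <- mlp_forward_cached(ein, mm$core_edge)
    e_new <- fe$out
    agg <- aggregate_edges(e_new, r, g$n_nodes, h$aggregation)
    nin <- cbind(V0, v, agg)
    fv <- mlp_forward_cached(nin, mm$core_node)
    v_new <- fv$out
    dec_in <- if (h$task == "edge_prediction") e_new else v_new
    fd <- mlp_forward_cached(dec_in, mm$decoder)
    outs[[t]] <- fd$out
    if (with_cache) {
      steps[[t]] <- list(edge = fe$cache, node = fv$cache, dec = fd$cache)
    }
    e <- e_new
    v <- v_new
  }
  res <- list(per_step_outputs = outs)
  if (with_cache) {
    res$cache <- list(enc_e = enc_e$cache, enc_v = enc_v$cache, steps = steps)
  }
  res
}

# Backward pass: given per-step output gradients, accumulate parameter
# gradients through the recurrent core and the encoders.
gnn_backward <- function(g, params, fwd, d_outs) {
  h <- params$hyper
  mm <- params$mlps
  L <- h$latent_width
  s <- g$senders
  r <- g$receivers
  nE <- g$n_edges
  nN <- g$n_nodes
  grads <- lapply(params$mlps, function(p) lapply(p, function(a) a * 0))
  acc <- function(mn, gl) {
    for (an in names(gl)) grads[[mn]][[an]] <<- grads[[mn]][[an]] + gl[[an]]
  }
  ge <- matrix(0, nE, L)   # grad wrt e_t
  gv <- matrix(0, nN, L)   # grad wrt v_t
  gE0 <- matrix(0, nE, L)
  gV0 <- matrix(0, nN, L)
  if (h$aggregation == "mean") {
    cnt <- as.numeric(table(factor(r, levels = seq_len(nN))))
    cnt[cnt == 0] <- 1
  }
  for (t in rev(seq_len(h$n_steps))) {
    st <- fwd$cache$steps[[t]]
    bd <- mlp_backward(d_outs[[t]], mm$decoder, st$dec)
    acc("decoder", bd$grads)
    if (h$task == "edge_prediction") ge <- ge + bd$dx else gv <- gv + bd$dx
    # node update
    bn <- mlp_backward(gv, mm$core_node, st$node)
    acc("core_node", bn$grads)
    gV0 <- gV0 + bn$dx[, 1:L, drop = FALSE]
    gv_prev <- bn$dx[, L + 1:L, drop = FALSE]
    dagg <- bn$dx[, 2 * L + 1:L, drop = FALSE]
    # aggregation: gather grad to contributing edges
    dagg_e <- dagg[r, , drop = FALSE]
    if (h$aggregation == "mean") dagg_e <- dagg_e / cnt[r]
    ge <- ge + dagg_e
    # edge update
    be <- mlp_backward(ge, mm$core_edge, st$edge)
    acc("core_edge", be$grads)
    dx <- be$dx
    gE0 <- gE0 + dx[, 1:L, drop = FALSE]
    ge_prev <- dx[, L + 1:L, drop = FALSE]
    gV0 <- scatter_add(gV0, s, dx[, 2 * L + 1:L, drop = FALSE])
    gv_prev <- scatter_add(gv_prev, s, dx[, 3 * L + 1:L, drop = FALSE])
    gV0 <- scatter_add(gV0, r, dx[, 4 * L + 1:L, drop = FALSE])
    gv_prev <- scatter_add(gv_prev, r, dx[, 5 * L + 1:L, drop = FALSE])
    ge <- ge_prev
    gv <- gv_prev
  }
  gE0 <- gE0 + ge  # latent before step 1 is the encoder output
  gV0 <- gV0 + gv
  bee <- mlp_backward(gE0, mm$edge_encoder, fwd$cache$enc_e)
  acc("edge_encoder", bee$grads)
  bev <- mlp_backward(gV0, mm$node_encoder, fwd$cache$enc_v)
  acc("node_encoder", bev$grads)
  grads
}

#' Loss and analytic gradients for one (possibly batched) graph
#'
#' Computes the multi-step mean-squared-error training loss (mean over
#' message-passing steps of the MSE over all target entries, weighted so
#' that each subject in a batched graph contributes equally) and its
#' exact gradient with respect to every parameter by backpropagation.
#'
#' @param g A `graph_sample` with targets matching the task.
#' @param params A `model_params`.
#' @param row_weights Optional per-row loss weights (used for batching;
#'   default: uniform over rows).
#' @param backend `"cpp"` (default) or `"r"`, see [gnn_forward()].
#' @return List with `loss` (scalar) and `grads` (mirrors `params$mlps`).
#' @export
gnn_loss_and_grads <- function(g, params, row_weights = NULL,
                               backend = getOption("sc2fc.backend", "cpp")) {
  h <- params$hyper
  target <- if (h$task == "edge_prediction") g$edge_targets else g$node_targets
  if (is.null(target)) stop("graph sample has no targets for task ", h$task)
  n_steps <- h$n_steps
  nr <- nrow(target)
  if (is.null(row_weights)) row_weights <- rep(1 / nr, nr)
  if (backend == "cpp" && n_steps > 0) {
    res <- .gnn_pass_cpp(g$node_features, g$edge_features,
                         g$senders - 1L, g$receivers - 1L, target,
                         h$task == "edge_prediction", n_steps,
                         h$aggregation == "mean", params$mlps,
                         row_weights, TRUE)
    # bias/layer-norm gradients come back as column matrices; match the
    # reference layout (matrices for W*, plain vectors for b*, ln_*)
    grads <- lapply(res$grads, function(gl) {
      lapply(stats::setNames(names(gl), names(gl)), function(an) {
        if (grepl("^W", an)) gl[[an]] else as.numeric(gl[[an]])
      })
    })
    return(list(loss = res$loss, grads = grads))
  }
  fwd <- gnn_forward(g, params, with_cache = TRUE)
  loss <- 0
  d_outs <- vector("list", n_steps)
  w <- row_weights / (n_steps * ncol(target))
  for (t in seq_len(n_steps)) {
    diff <- fwd$per_step_outputs[[t]] - target
    loss <- loss + sum(w * diff^2)
    d_outs[[t]] <- 2 * w * diff
  }
  grads <- gnn_backward(g, params, fwd, d_outs)
  list(loss = loss, grads = grads)
}

#' Verify analytic gradients against central finite differences
#'
#' Perturbs every parameter by `h` in both directions, recomputes the
#' loss, and compares the centered difference quotient with the
#' backpropagated gradient.  The reported error for each parameter is
#' `|num - ana| / max(1, |num|, |ana|)` (relative for large gradients,
#' absolute for vanishing ones, where finite-difference cancellation
#' noise dominates any ratio).
#'
#' The loss is piecewise smooth (ReLU hidden units), so a finite
#' difference that flips any unit's activation state straddles a kink
#' and does not estimate the one-sided gradient backpropagation
#' computes; such coordinates are detected by comparing activation
#' patterns and skipped (their count is reported as an attribute).
#'
#' @param g A `graph_sample` with targets.
#' @param params A `model_params`.
#' @param h Finite-difference step (default 1e-7, small enough that the
#'   quadratic truncation error of the centered quotient stays well
#'   below 1e-5 even where layer normalization curvature is large).
#' @return Maximum scaled error over all checked parameters, with
#'   attributes `n_checked` and `n_skipped`.
#' @export
gradient_check <- function(g, params, h = 1e-7) {
  lg <- gnn_loss_and_grads(g, params)
  base <- loss_and_pattern(g, params)
  flat <- flatten_params(params)
  flat_g <- list()
  for (mn in names(lg$grads)) {
    for (an in names(lg$grads[[mn]])) {
      flat_g[[paste0(mn, ".", an)]] <- lg$grads[[mn]][[an]]
    }
  }
  worst <- 0
  n_checked <- 0L
  n_skipped <- 0L
  for (nm in names(flat)) {
    a0 <- flat[[nm]]
    for (i in seq_along(a0)) {
      fp <- flat
      fp[[nm]][i] <- a0[i] + h
      up <- loss_and_pattern(g, unflatten_params(fp, params$hyper))
      fp[[nm]][i] <- a0[i] - h
      dn <- loss_and_pattern(g, unflatten_params(fp, params$hyper))
      if (!identical(up$pattern, base$pattern) ||
          !identical(dn$pattern, base$pattern)) {
        n_skipped <- n_skipped + 1L
        next
      }
      num <- (up$loss - dn$loss) / (2 * h)
      ana <- flat_g[[nm]][i]
      err <- abs(num - ana) / max(1, abs(num), abs(ana))
      if (err > worst) worst <- err
      n_checked <- n_checked + 1L
    }
  }
  structure(worst, n_checked = n_checked, n_skipped = n_skipped)
}

# loss plus the ReLU activation pattern of every hidden unit
loss_and_pattern <- function(g, params) {
  fwd <- gnn_forward(g, params, with_cache = TRUE)
  target <- if (params$hyper$task == "edge_prediction") {
    g$edge_targets
  } else {
    g$node_targets
  }
  pat <- function(cc) c(cc$h1 > 0, cc$h2 > 0)
  pattern <- c(pat(fwd$cache$enc_e), pat(fwd$cache$enc_v),
               unlist(lapply(fwd$cache$steps, function(st) {
                 c(pat(st$edge), pat(st$node), pat(st$dec))
               })))
  list(loss = multi_step_mse_loss(fwd$per_step_outputs, target),
       pattern = pattern)
}

#' Batch several graph samples into one disconnected graph
#'
#' Standard block-diagonal batching: nodes and edges are concatenated
#' with index offsets, so one forward/backward pass covers the whole
#' batch.  Row weights make each subject contribute equally to the loss
#' regardless of its edge count.
#'
#' @param graphs List of `graph_sample`s.
#' @return List with the merged `graph` and `row_weights`.
#' @export
batch_graphs <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  offs <- cumsum(c(0L, vapply(graphs, `[[`, integer(1), "n_nodes")))
  nf <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  ef <- do.call(rbind, lapply(graphs, `[[`, "edge_features"))
  snd <- unlist(lapply(seq_along(graphs),
                       function(i) graphs[[i]]$senders + offs[i]))
  rcv <- unlist(lapply(seq_along(graphs),
                       function(i) graphs[[i]]$receivers + offs[i]))
  et <- if (!is.null(graphs[[1]]$edge_targets)) {
    do.call(rbind, lapply(graphs, `[[`, "edge_targets"))
  }
  nt <- if (!is.null(graphs[[1]]$node_targets)) {
    do.call(rbind, lapply(graphs, `[[`, "node_targets"))
  }
  g <- graph_sample(nf, ef, snd, rcv, edge_targets = et, node_targets = nt)
  per <- if (!is.null(et)) {
    vapply(graphs, `[[`, integer(1), "n_edges")
  } else {
    vapply(graphs, `[[`, integer(1), "n_nodes")
  }
  rw <- unlist(lapply(per, function(k) rep(1 / (k * length(graphs)), k)))
  list(graph = g, row_weights = rw)
}
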