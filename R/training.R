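#' Training configuration
#'
#' Bundles the optimization and task settings.  Defaults follow common
#' deep-learning practice for this architecture: Adam with learning rate
#' 0.001, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7; batch size 32; a
#' 70/10/20 train/validation/test split; 10 message-passing steps.
#'
#' @param n_epochs Number of epochs to run.
#' @param task `"edge_prediction"` or `"centrality_prediction"`.
#' @param centrality_measure For the centrality task, which measure to
#'   predict (`"degree"`, `"eigenvector"`, `"pagerank"`).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @param batch_size Subjects per batch.
#' @param n_steps Message-passing steps.
#' @param latent_width Latent/hidden width of all update MLPs.
#' @param split_fractions Train/val/test fractions, summing to 1.
#' @param seed Root seed; all randomness (initialization, splits, epoch
#'   shuffles) derives from it.
#' @param all_measures Stack all three structural centralities as node
#'   input for the centrality task (default: single matching measure).
#' @return An object of class `train_config`.
#' @export
train_config <- function(n_epochs,
                         task = c("edge_prediction", "centrality_prediction"),
                         centrality_measure = NULL,
                         learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, batch_size = 32L, n_steps = 10L,
                         latent_width = 16L,
                         split_fractions = c(0.70, 0.10, 0.20),
                         seed = 1L, all_measures = FALSE) {
  task <- match.arg(task)
  if (abs(sum(split_fractions) - 1) > 1e-12) {
    stop("split_fractions must sum to 1")
  }
  stopifnot(learning_rate >= 0, batch_size >= 1, n_epochs >= 0, n_steps >= 0)
  if (task == "centrality_prediction" && is.null(centrality_measure) &&
      !all_measures) {
    stop("centrality task needs centrality_measure (or all_measures = TRUE)")
  }
  structure(list(n_epochs = as.integer(n_epochs), task = task,
                 centrality_measure = centrality_measure,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 n_steps = as.integer(n_steps),
                 latent_width = as.integer(latent_width),
                 split_fractions = split_fractions, seed = as.integer(seed),
                 all_measures = isTRUE(all_measures)),
            class = "train_config")
}

# deterministic per-purpose seed stream derived from one root seed
derive_seed <- function(root, purpose) {
  stopifnot(is.numeric(root))
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((as.numeric(root) * 48271 + h * 1009 + 12345) %% 2147483647)
}

#' Random train/validation/test partition
#'
#' Sizes are `train = floor(f_train * n)`, `val = floor(f_val * n)` and
#' the remainder to test, so a 998-subject cohort under the default
#' 70/10/20 fractions yields 698 training, 99 validation and 201 test
#' subjects.  Membership is random but fully determined by the seed.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return Character vector of `"train"/"val"/"test"` labels, length
#'   `n_subjects`, in subject order.
#' @export
split_cohort <- function(n_subjects, fractions = c(0.70, 0.10, 0.20),
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-12) stop("fractions must sum to 1")
  if (n_subjects < 10) stop("need at least 10 subjects to split")
  n_train <- floor(fractions[1] * n_subjects)
  n_val <- floor(fractions[2] * n_subjects)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  ord <- sample.int(n_subjects)
  labels <- character(n_subjects)
  labels[ord[seq_len(n_train)]] <- "train"
  labels[ord[n_train + seq_len(n_val)]] <- "val"
  labels[labels == ""] <- "test"
  labels
}

#' Batches per epoch
#'
#' `floor(n_train / batch_size)` batches of unique subjects sampled
#' without replacement (the ragged tail is dropped), so 698 training
#' subjects at batch size 32 give 21 batches per epoch.
#'
#' @param n_train Training-set size.
#' @param batch_size Batch size.
#' @return Integer batch count.
#' @export
batches_per_epoch <- function(n_train, batch_size) {
  if (n_train < batch_size) {
    stop("training set (", n_train, ") smaller than batch size (",
         batch_size, ")")
  }
  as.integer(floor(n_train / batch_size))
}

#' Multi-step mean-squared-error loss
#'
#' The training loss: the mean over message-passing steps of the MSE
#' between each step's decoded output and the target.
#'
#' @param per_step_outputs List of output matrices, one per step.
#' @param target Target matrix of the same shape.
#' @return Scalar loss.
#' @export
multi_step_mse_loss <- function(per_step_outputs, target) {
  target <- as.matrix(target)
  if (length(per_step_outputs) == 0) stop("no per-step outputs")
  mse <- vapply(per_step_outputs, function(o) {
    o <- as.matrix(o)
    if (!all(dim(o) == dim(target))) {
      stop("output shape ", paste(dim(o), collapse = "x"),
           " != target shape ", paste(dim(target), collapse = "x"))
    }
    mean((o - target)^2)
  }, numeric(1))
  mean(mse)
}

## ---- Adam -------------------------------------------------------------

#' Initialize Adam optimizer state
#'
#' @param params A `model_params`.
#' @return An `adam_state` with zeroed first/second moments and timestep 0.
#' @export
adam_init <- function(params) {
  flat <- flatten_params(params)
  structure(list(m = lapply(flat, function(a) a * 0),
                 v = lapply(flat, function(a) a * 0),
                 t = 0L),
            class = "adam_state")
}

#' One Adam update
#'
#' Standard bias-corrected Adam step applied to every parameter array.
#'
#' @param params A `model_params`.
#' @param grads Gradient list mirroring `params$mlps` (from
#'   [gnn_loss_and_grads()]).
#' @param state An `adam_state`.
#' @param config A `train_config` (supplies learning rate and betas).
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, config) {
  flat_g <- list()
  for (mn in names(grads)) {
    for (an in names(grads[[mn]])) {
      flat_g[[paste0(mn, ".", an)]] <- grads[[mn]][[an]]
    }
  }
  if (any(!vapply(flat_g, function(a) all(is.finite(a)), logical(1)))) {
    stop("non-finite gradient; aborting optimization")
  }
  flat_p <- flatten_params(params)
  state$t <- state$t + 1L
  b1 <- config$beta1
  b2 <- config$beta2
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(flat_p)) {
    g <- flat_g[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat_p[[nm]] <- flat_p[[nm]] -
      config$learning_rate * mhat / (sqrt(vhat) + config$epsilon)
  }
  list(params = unflatten_params(flat_p, params$hyper), state = state)
}

## ---- training loop ----------------------------------------------------

#' Train the message-passing network on a cohort
#'
#' Builds the task graphs for every subject, then runs
#' `n_epochs x batches_per_epoch` Adam updates of the multi-step MSE
#' loss.  Training ids are reshuffled each epoch and sampled without
#' replacement; the gradient is the mean of per-subject losses over the
#' batch (computed in one pass on a block-diagonal batched graph).
#' Validation loss is logged every epoch with the same loss formula;
#' test subjects are never touched.
#'
#' @param ch A `cohort` whose subjects carry the inputs the task needs
#'   (`fc` for edge prediction; standardized centralities for centrality
#'   prediction).
#' @param config A `train_config`.
#' @param params Optional warm-start `model_params`; by default
#'   initialized from the config seed.
#' @param log_every Record the log every this many epochs (always
#'   includes the final epoch).
#' @param state Optional `adam_state` to resume optimization (with
#'   `params` and `epoch_offset`, allows exact continuation of an
#'   earlier run in chunks, e.g. to evaluate between chunks).
#' @param epoch_offset Number of epochs already run (shifts the log and
#'   the epoch-shuffle RNG stream so chunked and unchunked runs match).
#' @return List with `params` (trained), `state` (Adam state), `log`
#'   (data.frame epoch, train_loss, val_loss) and `graphs` (the
#'   per-subject task graphs).
#' @export
train <- function(ch, config, params = NULL, log_every = 1L,
                  state = NULL, epoch_offset = 0L) {
  stopifnot(inherits(ch, "cohort"), inherits(config, "train_config"))
  graphs <- lapply(ch$subjects, function(s) make_task_graph(s, config))
  train_ids <- cohort_split_ids(ch, "train")
  val_ids <- cohort_split_ids(ch, "val")
  if (length(train_ids) == 0) stop("cohort has no training subjects")
  nb <- batches_per_epoch(length(train_ids), config$batch_size)
  d_node_in <- ncol(graphs[[1]]$node_features)
  if (is.null(params)) {
    params <- init_model_params(
      d_edge_in = ncol(graphs[[1]]$edge_features),
      d_node_in = d_node_in, d_out = 1L, task = config$task,
      latent_width = config$latent_width, n_steps = config$n_steps,
      seed = derive_seed(config$seed, "init"))
  }
  if (is.null(state)) state <- adam_init(params)
  val_batch <- if (length(val_ids)) batch_graphs(graphs[val_ids])
  log <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  for (ep in epoch_offset + seq_len(config$n_epochs)) {
    set.seed(derive_seed(config$seed, paste0("epoch", ep)))
    ids <- sample(train_ids)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      bids <- ids[(b - 1) * config$batch_size + seq_len(config$batch_size)]
      bt <- batch_graphs(graphs[bids])
      lg <- gnn_loss_and_grads(bt$graph, params, bt$row_weights)
      step <- adam_step(params, lg$grads, state, config)
      params <- step$params
      state <- step$state
      ep_loss <- ep_loss + lg$loss
    }
    if (ep %% log_every == 0 || ep == epoch_offset + config$n_epochs) {
      val_loss <- if (!is.null(val_batch)) {
        fwd <- gnn_forward(val_batch$graph, params)
        weighted_multi_step_loss(fwd$per_step_outputs, val_batch)
      } else {
        NA_real_
      }
      log[[length(log) + 1L]] <- data.frame(
        epoch = ep, train_loss = ep_loss / nb, val_loss = val_loss)
    }
  }
  list(params = params, state = state,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric()),
       graphs = graphs)
}

# loss of a batched graph with per-row weights (mean of per-subject losses)
weighted_multi_step_loss <- function(per_step_outputs, batch) {
  g <- batch$graph
  target <- if (!is.null(g$edge_targets)) g$edge_targets else g$node_targets
  w <- batch$row_weights / (length(per_step_outputs) * ncol(target))
  sum(vapply(per_step_outputs,
             function(o) sum(w * (o - target)^2), numeric(1)))
}
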