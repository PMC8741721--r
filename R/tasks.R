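#' Build the edge-prediction task graph for one subject
#'
#' Structural connectivity becomes the directed edge inputs
#' (log-transformed, min-max rescaled), every node input is initialized
#' to 1.0, and the targets are the subject's functional connectivity
#' values aligned to the directed edge list.  Targets are z-scored and
#' rescaled to `[-1, 1]` across the subject's edge set by default; the
#' constants are stored on the graph so predictions can be
#' unstandardized back to correlation units.
#'
#' @param subject A `subject_record` with both `sc` and `fc`.
#' @param standardize_targets Standardize FC targets (default) or keep
#'   raw correlations.
#' @param transform Edge-input transform, see [encode_sc_as_graph()].
#' @return A `graph_sample` with `edge_targets`.
#' @export
make_edge_task <- function(subject, standardize_targets = TRUE,
                           transform = "log1p_minmax") {
  stopifnot(inherits(subject, "subject_record"))
  if (is.null(subject$fc)) {
    stop("subject ", subject$subject_id, " has no functional connectivity")
  }
  g <- encode_sc_as_graph(subject$sc, node_init = 1.0, transform = transform)
  fc_vals <- subject$fc$values[cbind(g$senders, g$receivers)]
  std <- NULL
  if (standardize_targets) {
    sr <- standardize_rescale(fc_vals)
    fc_vals <- sr$values
    std <- sr$standardization
  }
  graph_sample(g$node_features, g$edge_features, g$senders, g$receivers,
               edge_targets = matrix(fc_vals, ncol = 1),
               target_standardization = std)
}

#' Build the centrality-prediction task graph for one subject
#'
#' Edges are the structural connectivity exactly as in the edge task;
#' node inputs are the subject's standardized structural centrality for
#' the requested measure (or all three measures stacked in the fixed
#' order degree, eigenvector, pagerank); node targets are the
#' standardized functional centrality for that measure.
#'
#' @param subject A `subject_record` with standardized structural and
#'   functional centralities computed.
#' @param measure `"degree"`, `"eigenvector"` or `"pagerank"`.
#' @param all_measures Stack all three structural measures as input.
#' @param transform Edge-input transform.
#' @return A `graph_sample` with `node_targets`.
#' @export
make_centrality_task <- function(subject, measure, all_measures = FALSE,
                                 transform = "log1p_minmax") {
  stopifnot(inherits(subject, "subject_record"))
  measures_in <- if (all_measures) {
    c("degree", "eigenvector", "pagerank")
  } else {
    measure
  }
  get_cv <- function(side, m) {
    cv <- subject[[side]][[m]]
    if (is.null(cv)) {
      stop("subject ", subject$subject_id, " is missing ", side, " ", m)
    }
    if (cv$space != "standardized") {
      stop(side, " ", m, " must be standardized for the centrality task")
    }
    cv
  }
  nf <- do.call(cbind, lapply(measures_in, function(m) {
    unname(get_cv("struct_centrality", m)$values)
  }))
  tgt <- get_cv("func_centrality", measure)
  g <- encode_sc_as_graph(subject$sc, node_init = 1.0, transform = transform)
  graph_sample(node_features = nf, edge_features = g$edge_features,
               senders = g$senders, receivers = g$receivers,
               node_targets = matrix(unname(tgt$values), ncol = 1),
               target_standardization = tgt$standardization)
}

# dispatcher used by train()
make_task_graph <- function(subject, config) {
  if (config$task == "edge_prediction") {
    make_edge_task(subject)
  } else {
    make_centrality_task(subject, config$centrality_measure,
                         all_measures = config$all_measures)
  }
}

#' Predict a subject's functional connectivity matrix
#'
#' Runs the trained edge model on the subject's structural graph, takes
#' the final message-passing step's decoded edge outputs, unstandardizes
#' them with the subject's stored constants, places them back into a
#' matrix, symmetrizes by averaging the two directed copies and zeroes
#' the diagonal.  Structural zero-pairs, which carry no edge in sparse
#' mode, predict 0.
#'
#' @param subject A `subject_record` with `sc` and `fc` (the latter
#'   supplies the target standardization constants).
#' @param params Trained edge-task `model_params`.
#' @return A functional `connectivity_matrix` of predicted correlations.
#' @export
predict_fc <- function(subject, params) {
  stopifnot(inherits(params, "model_params"))
  if (params$hyper$task != "edge_prediction") {
    stop("predict_fc needs edge-task parameters")
  }
  g <- make_edge_task(subject)
  fwd <- gnn_forward(g, params)
  pred <- fwd$per_step_outputs[[length(fwd$per_step_outputs)]][, 1]
  if (!is.null(g$target_standardization)) {
    pred <- unstandardize(pred, g$target_standardization)
  }
  n <- subject$sc$atlas$n_regions
  m <- matrix(0, n, n)
  m[cbind(g$senders, g$receivers)] <- pred
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  m[m < -1] <- -1
  diag(m) <- 0
  connectivity_matrix(m, "functional", subject$sc$atlas)
}

#' Predict a subject's functional centrality vector
#'
#' Final-step decoded node outputs of a trained centrality model, in
#' standardized space.
#'
#' @param subject A `subject_record` with the required centralities.
#' @param params Trained centrality-task `model_params`.
#' @param measure Measure the model was trained for.
#' @param all_measures Whether the model used stacked inputs.
#' @return Numeric vector of standardized predicted centrality.
#' @export
predict_centrality <- function(subject, params, measure,
                               all_measures = FALSE) {
  if (params$hyper$task != "centrality_prediction") {
    stop("predict_centrality needs centrality-task parameters")
  }
  g <- make_centrality_task(subject, measure, all_measures = all_measures)
  fwd <- gnn_forward(g, params)
  stats::setNames(fwd$per_step_outputs[[length(fwd$per_step_outputs)]][, 1],
                  subject$sc$atlas$names)
}

#' Centrality derived from a predicted functional matrix
#'
#' Applies the identical code path used for empirical functional
#' centralities: threshold at `r_crit`, then compute the requested
#' centrality.  Feeding the empirical FC through this path therefore
#' reproduces the empirical centrality exactly.
#'
#' @param predicted_fc A functional `connectivity_matrix` in raw
#'   correlation space (already unstandardized).
#' @param measure `"degree"`, `"eigenvector"` or `"pagerank"`.
#' @param r_crit Threshold from [critical_r()].
#' @return A raw-space `centrality_vector`.
#' @export
derived_centrality <- function(predicted_fc,
                               measure = c("degree", "eigenvector",
                                           "pagerank"),
                               r_crit) {
  measure <- match.arg(measure)
  thr <- threshold_fc(predicted_fc, r_crit)
  switch(measure,
         degree = degree_centrality(thr),
         eigenvector = eigenvector_centrality(thr),
         pagerank = pagerank_centrality(thr))
}
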