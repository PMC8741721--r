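#' Edge-model recovery benchmark on a synthetic cohort
#'
#' The package's standard end-to-end validation: generate a desk-scale
#' synthetic cohort (defaults: 30 regions, 200 subjects, the
#' direct-plus-indirect structure-to-function map, functional noise SD
#' 0.02), train the edge-prediction model in chunks, and evaluate on the
#' held-out test subjects after each chunk, stopping once the mean-level
#' R-squared reaches `target_r2` (or after `max_epochs`).  Also reports
#' the subject-blind baseline: the individual-level R-squared achieved
#' by predicting every test subject with the training-set mean
#' functional matrix.  A model that uses individual structure should
#' beat that baseline.
#'
#' @param seed Root seed for generation, initialization and training.
#' @param config A `sim_config`; defaults to the standard conditions.
#' @param max_epochs Training budget.
#' @param eval_every Chunk length between test-set evaluations.
#' @param target_r2 Mean-level stopping threshold.
#' @return List with `mean_level_r2`, `individual_level_r2`,
#'   `baseline_individual_r2`, `epochs_used`, `final_val_loss`.
#' @export
edge_recovery_benchmark <- function(seed, config = NULL, max_epochs = 300L,
                                    eval_every = 25L, target_r2 = 0.8) {
  if (is.null(config)) config <- sim_config(seed = seed)
  ch <- generate_cohort(config, centralities = FALSE)
  test <- ch$subjects[cohort_split_ids(ch, "test")]
  train_ids <- cohort_split_ids(ch, "train")
  mfc <- Reduce(`+`, lapply(ch$subjects[train_ids],
                            function(s) s$fc$values)) / length(train_ids)
  ut <- upper.tri(mfc)
  base_r2 <- r_squared(rep(mfc[ut], length(test)),
                       unlist(lapply(test, function(s) s$fc$values[ut])))
  tc <- train_config(n_epochs = eval_every, task = "edge_prediction",
                     seed = seed)
  params <- NULL
  state <- NULL
  done <- 0L
  r2m <- r2i <- NA_real_
  val <- NA_real_
  while (done < max_epochs) {
    fit <- train(ch, tc, params = params, state = state, epoch_offset = done)
    params <- fit$params
    state <- fit$state
    done <- done + eval_every
    val <- utils::tail(fit$log$val_loss, 1)
    r2m <- mean_level_eval(test, params, "edge_prediction")
    r2i <- individual_level_eval(test, params, "edge_prediction")
    if (r2m >= target_r2 && r2i > base_r2) break
  }
  list(mean_level_r2 = r2m, individual_level_r2 = r2i,
       baseline_individual_r2 = base_r2, epochs_used = done,
       final_val_loss = val, params = params, cohort = ch)
}

#' Virtual-lesion hub-recovery benchmark
#'
#' Generates a small planted-hub cohort (defaults: 20 regions, 3 hubs,
#' 50 subjects), trains the edge model briefly, runs the iterative
#' virtual-lesion analysis on the test subjects and reports the
#' correlation between per-region lesioned loss and group-mean
#' structural degree centrality, plus whether the planted hubs rank in
#' the top half of lesion importance.
#'
#' @param seed Root seed.
#' @param config A `sim_config`; defaults to the standard planted-hub
#'   conditions.
#' @param n_epochs Training length.
#' @param batch_size Training batch size (smaller than the package-wide
#'   default because the cohort is small).
#' @return List with `correlation_r`, `correlation_p`, `baseline_loss`,
#'   `hubs`, `hubs_above_median` (logical), `report` (the full
#'   `lesion_report`).
#' @export
hub_lesion_benchmark <- function(seed, config = NULL, n_epochs = 60L,
                                 batch_size = 16L) {
  if (is.null(config)) {
    config <- sim_config(n_subjects = 50L, n_regions = 20L,
                         planted_hubs = 3L, seed = seed)
  }
  ch <- generate_cohort(config, centralities = FALSE)
  tc <- train_config(n_epochs = n_epochs, task = "edge_prediction",
                     batch_size = batch_size, seed = seed)
  fit <- train(ch, tc)
  test <- ch$subjects[cohort_split_ids(ch, "test")]
  rep <- lesion_analysis(test, fit$params, "edge_prediction")
  hubs <- attr(ch, "hubs")
  ranks <- rank(rep$lesioned_loss)   # high rank = high importance
  list(correlation_r = rep$correlation_r,
       correlation_p = rep$correlation_p,
       baseline_loss = rep$baseline_loss,
       hubs = hubs,
       hubs_above_median = all(ranks[hubs] >
                                 length(ranks) / 2),
       report = rep)
}
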