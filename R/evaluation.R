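#' Variance explained as squared Pearson correlation
#'
#' R-squared of predicted versus empirical values, defined as the square
#' of their Pearson correlation (the convention used when plotting
#' predicted against empirical values).  Note this is sign-blind:
#' `pred = -emp` also gives 1.  Set `method = "cod"` for the
#' coefficient-of-determination alternative
#' `1 - SS_res / SS_tot`, which is not sign-blind and can be negative.
#'
#' @param pred,emp Numeric vectors of equal length (>= 3), both
#'   non-constant.
#' @param method `"pearson_sq"` (default) or `"cod"`.
#' @return Scalar in `[0, 1]` (`"pearson_sq"`) or `(-Inf, 1]` (`"cod"`).
#' @export
r_squared <- function(pred, emp, method = c("pearson_sq", "cod")) {
  method <- match.arg(method)
  if (length(pred) != length(emp)) stop("length mismatch")
  if (length(pred) < 3) stop("need at least 3 paired values")
  if (stats::sd(pred) == 0 || stats::sd(emp) == 0) {
    stop("r_squared undefined for a constant vector")
  }
  if (method == "pearson_sq") {
    stats::cor(pred, emp)^2
  } else {
    1 - sum((emp - pred)^2) / sum((emp - mean(emp))^2)
  }
}

# gather per-subject prediction/empirical vectors for a task
predict_pairs <- function(subjects, params, task,
                          measure = NULL, all_measures = FALSE) {
  lapply(subjects, function(s) {
    if (task == "edge_prediction") {
      pf <- predict_fc(s, params)
      ut <- upper.tri(pf$values)
      list(pred = pf$values[ut], emp = s$fc$values[ut])
    } else {
      pred <- predict_centrality(s, params, measure,
                                 all_measures = all_measures)
      emp <- s$func_centrality[[measure]]$values
      list(pred = unname(pred), emp = unname(emp))
    }
  })
}

#' Mean-level prediction accuracy
#'
#' Averages predictions element-wise across the test subjects and
#' empirical values likewise, then returns the R-squared between the two
#' mean vectors (edge values for the edge task, regional centralities
#' for the centrality task).
#'
#' @param subjects List of test `subject_record`s (>= 2).
#' @param params Trained `model_params`.
#' @param task `"edge_prediction"` or `"centrality_prediction"`.
#' @param measure Centrality measure for the centrality task.
#' @param all_measures Stacked-input centrality model.
#' @param method R-squared convention, see [r_squared()].
#' @return Scalar R-squared.
#' @export
mean_level_eval <- function(subjects, params,
                            task = c("edge_prediction",
                                     "centrality_prediction"),
                            measure = NULL, all_measures = FALSE,
                            method = "pearson_sq") {
  task <- match.arg(task)
  if (length(subjects) < 2) stop("mean-level evaluation needs >= 2 subjects")
  pairs <- predict_pairs(subjects, params, task, measure, all_measures)
  mp <- rowMeans(vapply(pairs, `[[`, numeric(length(pairs[[1]]$pred)),
                        "pred"))
  me <- rowMeans(vapply(pairs, `[[`, numeric(length(pairs[[1]]$emp)), "emp"))
  r_squared(mp, me, method)
}

#' Individual-level prediction accuracy
#'
#' Pools every per-subject (prediction, empirical) pair across the test
#' set and returns the R-squared on the pooled vectors.
#'
#' @inheritParams mean_level_eval
#' @return Scalar R-squared.
#' @export
individual_level_eval <- function(subjects, params,
                                  task = c("edge_prediction",
                                           "centrality_prediction"),
                                  measure = NULL, all_measures = FALSE,
                                  method = "pearson_sq") {
  task <- match.arg(task)
  if (length(subjects) < 1) stop("empty test set")
  pairs <- predict_pairs(subjects, params, task, measure, all_measures)
  r_squared(unlist(lapply(pairs, `[[`, "pred")),
            unlist(lapply(pairs, `[[`, "emp")), method)
}

#' Virtually lesion one region
#'
#' Returns a copy of the structural matrix with the region's row and
#' column set to zero: the region keeps its node but loses every
#' structural connection.
#'
#' @param sc A structural `connectivity_matrix`.
#' @param region_index 1-based region index.
#' @return The lesioned structural `connectivity_matrix`.
#' @export
lesion_region <- function(sc, region_index) {
  stopifnot(inherits(sc, "connectivity_matrix"))
  region_index <- as.integer(region_index)
  if (region_index < 1 || region_index > nrow(sc$values)) {
    stop("region index out of range")
  }
  v <- sc$values
  v[region_index, ] <- 0
  v[, region_index] <- 0
  connectivity_matrix(v, sc$kind, sc$atlas)
}

#' Iterative virtual-lesion analysis
#'
#' For each atlas region: zero that region's structural connections in
#' every test subject, rebuild the task graphs from the lesioned
#' matrices, and evaluate the trained model's multi-step MSE loss (no
#' retraining), averaged over test subjects.  The per-region lesioned
#' losses are then correlated with the group-mean structural degree
#' centrality across test subjects (Pearson r, df = n_regions - 2,
#' two-tailed p), testing whether hub regions matter more to the model.
#'
#' @param subjects List of test `subject_record`s.
#' @param params Trained `model_params`.
#' @param task `"edge_prediction"` or `"centrality_prediction"`.
#' @param measure,all_measures Centrality-task settings.
#' @param regions Region indices to lesion; default all.
#' @return A `lesion_report`: list with `lesioned_loss` (per region),
#'   `baseline_loss`, `degree` (group-mean structural degree),
#'   `correlation_r`, `correlation_df`, `correlation_p`.
#' @export
lesion_analysis <- function(subjects, params,
                            task = c("edge_prediction",
                                     "centrality_prediction"),
                            measure = NULL, all_measures = FALSE,
                            regions = NULL) {
  task <- match.arg(task)
  stopifnot(length(subjects) >= 1)
  n_regions <- subjects[[1]]$sc$atlas$n_regions
  if (is.null(regions)) regions <- seq_len(n_regions)
  cfg_like <- list(task = task, centrality_measure = measure,
                   all_measures = all_measures)
  subject_loss <- function(recs) {
    mean(vapply(recs, function(s) {
      g <- make_task_graph(s, cfg_like)
      fwd <- gnn_forward(g, params)
      tgt <- if (task == "edge_prediction") g$edge_targets else g$node_targets
      multi_step_mse_loss(fwd$per_step_outputs, tgt)
    }, numeric(1)))
  }
  baseline <- subject_loss(subjects)
  lesioned <- vapply(regions, function(ri) {
    recs <- lapply(subjects, function(s) {
      s2 <- s
      s2$sc <- lesion_region(s$sc, ri)
      s2
    })
    subject_loss(recs)
  }, numeric(1))
  if (length(regions) == 0) {
    return(structure(list(lesioned_loss = numeric(0),
                          baseline_loss = baseline,
                          degree = numeric(0), correlation_r = NA_real_,
                          correlation_df = NA_integer_,
                          correlation_p = NA_real_),
                     class = "lesion_report"))
  }
  deg <- rowMeans(vapply(subjects, function(s) {
    unname(degree_centrality(s$sc)$values)
  }, numeric(n_regions)))[regions]
  if (length(regions) < 3) {
    return(structure(list(lesioned_loss = stats::setNames(
                            lesioned,
                            subjects[[1]]$sc$atlas$names[regions]),
                          baseline_loss = baseline, degree = deg,
                          correlation_r = NA_real_,
                          correlation_df = NA_integer_,
                          correlation_p = NA_real_),
                     class = "lesion_report"))
  }
  ct <- stats::cor.test(lesioned, deg)
  structure(list(lesioned_loss = stats::setNames(
                   lesioned, subjects[[1]]$sc$atlas$names[regions]),
                 baseline_loss = baseline,
                 degree = deg,
                 correlation_r = unname(ct$estimate),
                 correlation_df = unname(ct$parameter),
                 correlation_p = ct$p.value),
            class = "lesion_report")
}

#' @export
print.lesion_report <- function(x, ...) {
  cat("<lesion_report> ", length(x$lesioned_loss), " regions lesioned\n",
      "  baseline loss ", format(x$baseline_loss, digits = 4),
      "; loss-vs-degree r = ", format(x$correlation_r, digits = 3),
      " (df = ", x$correlation_df, ", p = ",
      format.pval(x$correlation_p, digits = 3), ")\n", sep = "")
  invisible(x)
}
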