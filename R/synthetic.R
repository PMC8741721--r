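#' Synthetic cohort configuration
#'
#' Conditions for the synthetic structure-to-function cohorts used to
#' validate the whole pipeline: a shared structural template (geometric
#' backbone, lognormal streamline weights, a few planted hub regions),
#' per-subject structural jitter, and a smooth deterministic
#' structure-to-function mapping plus observation noise.
#'
#' @param n_subjects Number of subjects.
#' @param n_regions Number of atlas regions.
#' @param sc_density Target structural edge density in (0, 1).
#' @param sc_weight_scale Lognormal sigma of streamline-count weights.
#' @param subject_sc_jitter Subject-level variability: lognormal sigma of
#'   multiplicative weight noise, and (scaled down) the edge add/drop
#'   rate.
#' @param fc_map Ground-truth mapping family: `"direct_plus_indirect"`
#'   (squashed weighted sum of the normalized structural matrix and its
#'   square), `"communicability_tanh"` (squashed matrix exponential) or
#'   `"linear"`.
#' @param fc_noise_sd SD of additive Gaussian noise on functional edges.
#' @param planted_hubs Number of high-degree hub regions planted in the
#'   template.
#' @param n_fc_samples Nominal timepoint count behind each functional
#'   matrix; sets the critical correlation threshold (default 4800, four
#'   concatenated 1200-point sessions).
#' @param split_fractions Train/val/test fractions.
#' @param seed Root seed; every random draw derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 200L, n_regions = 30L,
                       sc_density = 0.3, sc_weight_scale = 1.0,
                       subject_sc_jitter = 0.1,
                       fc_map = c("direct_plus_indirect",
                                  "communicability_tanh", "linear"),
                       fc_noise_sd = 0.02, planted_hubs = 3L,
                       n_fc_samples = 4800L,
                       split_fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  fc_map <- match.arg(fc_map)
  stopifnot(n_subjects >= 1, n_regions >= 5,
            sc_density > 0, sc_density < 1,
            sc_weight_scale > 0, subject_sc_jitter >= 0,
            fc_noise_sd >= 0, planted_hubs >= 0,
            planted_hubs < n_regions, n_fc_samples >= 4)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 sc_density = sc_density, sc_weight_scale = sc_weight_scale,
                 subject_sc_jitter = subject_sc_jitter, fc_map = fc_map,
                 fc_noise_sd = fc_noise_sd,
                 planted_hubs = as.integer(planted_hubs),
                 n_fc_samples = as.integer(n_fc_samples),
                 split_fractions = split_fractions, seed = as.integer(seed)),
            class = "sim_config")
}

# connected components of a binary adjacency (simple BFS)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        u <- queue[1]
        queue <- queue[-1]
        nb <- which(adj[u, ] != 0 & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

#' Generate the template structural connectome
#'
#' Nodes are placed uniformly in the unit square; a minimum spanning
#' tree over Euclidean distances guarantees one connected component,
#' the shortest remaining pairs fill in up to the target density
#' (geometric backbone), and `planted_hubs` randomly chosen regions get
#' extra long-range connections until they reach about three quarters of
#' the maximum degree.  Weights are lognormal pseudo streamline counts.
#'
#' @param config A `sim_config`.
#' @return A structural `connectivity_matrix`.
#' @export
generate_template_sc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_regions
  m_target <- round(config$sc_density * n * (n - 1) / 2)
  if (m_target < n - 1) {
    stop("sc_density too low to connect ", n, " regions")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "template"))
  xy <- matrix(stats::runif(2 * n), n, 2)
  d <- as.matrix(stats::dist(xy))
  adj <- matrix(FALSE, n, n)
  # Prim's MST for guaranteed connectivity
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  while (!all(in_tree)) {
    dd <- d[in_tree, !in_tree, drop = FALSE]
    k <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    u <- which(in_tree)[k[1]]
    v <- which(!in_tree)[k[2]]
    adj[u, v] <- adj[v, u] <- TRUE
    in_tree[v] <- TRUE
  }
  # planted hubs: extra connections up to ~75% of the maximum degree
  hubs <- if (config$planted_hubs > 0) {
    sample.int(n, config$planted_hubs)
  } else {
    integer(0)
  }
  for (hb in hubs) {
    want <- round(0.75 * (n - 1))
    cand <- setdiff(which(!adj[hb, ] & seq_len(n) != hb), hb)
    extra <- min(max(0, want - sum(adj[hb, ])), length(cand))
    if (extra > 0) {
      nb <- sample(cand, extra)
      adj[hb, nb] <- adj[nb, hb] <- TRUE
    }
  }
  # fill with the geometrically shortest remaining pairs
  need <- m_target - sum(adj) / 2
  if (need > 0) {
    ut <- which(upper.tri(d) & !adj, arr.ind = TRUE)
    ord <- order(d[cbind(ut[, 1], ut[, 2])])
    take <- ut[ord[seq_len(min(need, nrow(ut)))], , drop = FALSE]
    adj[take] <- TRUE
    adj[take[, 2:1, drop = FALSE]] <- TRUE
  }
  m <- sum(adj) / 2
  w <- pmax(1, round(stats::rlnorm(m, meanlog = log(30),
                                   sdlog = config$sc_weight_scale)))
  sc <- matrix(0, n, n)
  ut_idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  sc[ut_idx] <- w
  sc <- sc + t(sc)
  cm <- connectivity_matrix(sc, "structural", default_atlas(n))
  attr(cm, "hubs") <- sort(hubs)
  cm
}

#' Perturb the template into one subject's structural matrix
#'
#' Existing edge weights get multiplicative lognormal noise with sigma
#' `jitter`; each existing edge is dropped with probability `jitter / 5`
#' and absent pairs are added at the rate that keeps the expected edge
#' count unchanged.  Dropped edges that would disconnect the network are
#' restored.
#'
#' @param template Structural `connectivity_matrix` from
#'   [generate_template_sc()].
#' @param jitter Subject variability level (>= 0; 0 returns the template
#'   unchanged).
#' @param seed Integer seed.
#' @return A structural `connectivity_matrix`.
#' @export
generate_subject_sc <- function(template, jitter, seed) {
  stopifnot(inherits(template, "connectivity_matrix"))
  if (jitter == 0) return(template)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(template$values)
  v <- template$values
  ut <- upper.tri(v)
  edges <- which(ut & v > 0)
  absent <- which(ut & v == 0)
  # multiplicative weight noise
  v[edges] <- pmax(1, round(v[edges] *
                              stats::rlnorm(length(edges), 0, jitter)))
  p_drop <- jitter / 5
  drop <- edges[stats::runif(length(edges)) < p_drop]
  p_add <- if (length(absent)) {
    p_drop * length(edges) / length(absent)
  } else {
    0
  }
  add <- absent[stats::runif(length(absent)) < p_add]
  v[drop] <- 0
  v[add] <- pmax(1, round(stats::rlnorm(length(add), meanlog = log(30),
                                        sdlog = 1)))
  v[lower.tri(v)] <- t(v)[lower.tri(v)]
  # restore dropped edges until connected again
  comp <- components_of(v)
  while (max(comp) > 1L && length(drop)) {
    ij <- arrayInd(drop[1], dim(v))
    if (comp[ij[1]] != comp[ij[2]]) {
      v[ij[1], ij[2]] <- v[ij[2], ij[1]] <- template$values[ij[1], ij[2]]
      comp <- components_of(v)
    }
    drop <- drop[-1]
  }
  connectivity_matrix(v, "structural", template$atlas)
}

# strength-normalized structural matrix D^{-1/2} S D^{-1/2}
normalize_sc <- function(s) {
  str <- rowSums(s)
  str[str == 0] <- 1
  d <- 1 / sqrt(str)
  s * outer(d, d)
}

#' Ground-truth functional connectivity from structure
#'
#' Deterministic structure-to-function mapping plus symmetric Gaussian
#' observation noise.  With `Shat` the strength-normalized structural
#' matrix, the families are: `linear`, proportional to `Shat`;
#' `direct_plus_indirect`, `tanh(4 Shat + 2 Shat^2)` (direct connections
#' plus one step of indirect paths); and `communicability_tanh`,
#' `tanh(2 expm(Shat))` off-diagonal (all walks, exponentially
#' down-weighted by length).  Noise is added to the upper triangle and
#' mirrored; values are clipped to `[-1, 1]` and the diagonal zeroed.
#'
#' @param sc A structural `connectivity_matrix`.
#' @param config A `sim_config` (supplies `fc_map`, `fc_noise_sd`).
#' @param seed Integer seed for the noise draw (ignored when
#'   `fc_noise_sd = 0`).
#' @return A functional `connectivity_matrix`.
#' @export
ground_truth_fc <- function(sc, config, seed = 1L) {
  stopifnot(inherits(sc, "connectivity_matrix"))
  shat <- normalize_sc(sc$values)
  fc <- switch(config$fc_map,
    linear = {
      mx <- max(abs(shat[upper.tri(shat)]))
      0.9 / mx * shat
    },
    direct_plus_indirect = tanh(4 * shat + 2 * (shat %*% shat)),
    communicability_tanh = tanh(2 * as.matrix(Matrix::expm(Matrix::Matrix(
      shat)))))
  if (config$fc_noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    n <- nrow(fc)
    noise <- matrix(0, n, n)
    noise[upper.tri(noise)] <- stats::rnorm(n * (n - 1) / 2,
                                            sd = config$fc_noise_sd)
    fc <- fc + noise + t(noise)
  }
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  diag(fc) <- 0
  connectivity_matrix(fc, "functional", sc$atlas)
}

#' Generate a full synthetic cohort
#'
#' Template structure, per-subject structural jitter, ground-truth
#' functional matrices, structural and (threshold-then-compute)
#' functional centralities with their standardizations, and a seeded
#' 70/10/20 partition.  Fully deterministic given the config seed.
#'
#' @param config A `sim_config`.
#' @param centralities Compute and attach centrality vectors (default
#'   TRUE; skipping them speeds up edge-task-only cohorts).
#' @return A `cohort`.  The planted hub indices are attached as
#'   attribute `"hubs"`.
#' @export
generate_cohort <- function(config, centralities = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  template <- generate_template_sc(config)
  rc <- critical_r(1e-4, config$n_fc_samples)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    sc <- generate_subject_sc(template, config$subject_sc_jitter,
                              derive_seed(config$seed,
                                          paste0("subject_sc", i)))
    fc <- ground_truth_fc(sc, config,
                          derive_seed(config$seed, paste0("fc_noise", i)))
    rec <- subject_record(sprintf("sub%04d", i), sc, fc)
    if (centralities) {
      rec$struct_centrality <- all_centralities(sc)
      rec$func_centrality <- all_centralities(threshold_fc(fc, rc))
    }
    rec
  })
  labels <- split_cohort(config$n_subjects, config$split_fractions,
                         derive_seed(config$seed, "split"))
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  ch <- cohort(subjects, stats::setNames(labels, ids))
  attr(ch, "hubs") <- attr(template, "hubs")
  attr(ch, "r_crit") <- rc
  ch
}
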