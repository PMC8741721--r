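# Shared fixture builders.  Everything is generated in code at test
# time; no data files.

# random connected symmetric structural matrix (path backbone + extras)
rand_sc <- function(n, density = 0.4, seed = 1, max_w = 20) {
  set.seed(seed)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- sample.int(max_w, 1)
  extra <- which(upper.tri(m) & m == 0)
  k <- max(0, round(density * n * (n - 1) / 2) - (n - 1))
  if (k > 0 && length(extra)) {
    pick <- sample(extra, min(k, length(extra)))
    m[pick] <- sample.int(max_w, length(pick), replace = TRUE)
  }
  m <- m + t(m)
  connectivity_matrix(m, "structural")
}

# random functional matrix with entries in [-r_max, r_max]
rand_fc <- function(n, seed = 1, r_max = 0.9, atlas = NULL) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, -r_max, r_max), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  connectivity_matrix(m, "functional", atlas)
}

# a small subject with sc, fc and (optionally) centralities attached
tiny_subject <- function(n = 6, seed = 1, with_centralities = FALSE,
                         r_crit = 0.1) {
  sc <- rand_sc(n, seed = seed)
  fc <- rand_fc(n, seed = seed + 100, atlas = sc$atlas)
  s <- subject_record(paste0("s", seed), sc, fc)
  if (with_centralities) {
    s$struct_centrality <- all_centralities(sc)
    s$func_centrality <- all_centralities(threshold_fc(fc, r_crit))
  }
  s
}

# quick small synthetic cohort
tiny_cohort <- function(n_subjects = 20, n_regions = 12, seed = 1, ...) {
  generate_cohort(sim_config(n_subjects = n_subjects, n_regions = n_regions,
                             seed = seed, planted_hubs = 1L, ...),
                  centralities = FALSE)
}

# small model params for fast GNN tests
tiny_params <- function(task = "edge_prediction", L = 4L, n_steps = 3L,
                        seed = 7, d_node_in = 1L) {
  init_model_params(d_edge_in = 1L, d_node_in = d_node_in, d_out = 1L,
                    task = task, latent_width = L, n_steps = n_steps,
                    seed = seed)
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
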