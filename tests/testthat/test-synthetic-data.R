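test_that("template structure hits density, symmetry and hub targets", {
  for (seed in 1:5) {
    cfg <- sim_config(n_regions = 30, sc_density = 0.3, seed = seed)
    sc <- generate_template_sc(cfg)
    v <- sc$values
    expect_matrix_equal(v, t(v), 1e-15)
    expect_equal(diag(v), rep(0, 30), ignore_attr = TRUE)
    expect_true(all(v >= 0))
    dens <- sum(v[upper.tri(v)] != 0) / (30 * 29 / 2)
    expect_gt(dens, 0.3 * 0.8)
    expect_lt(dens, 0.3 * 1.2)
    deg <- unname(degree_centrality(sc)$values)
    hubs <- attr(sc, "hubs")
    expect_length(hubs, 3)
    expect_true(all(deg[hubs] > stats::median(deg)))
  }
  expect_error(generate_template_sc(sim_config(n_regions = 30,
                                               sc_density = 0.02)),
               "too low")
})

test_that("subject matrices jitter around the template but stay close", {
  cfg <- sim_config(n_regions = 25, seed = 5)
  template <- generate_template_sc(cfg)
  expect_identical(generate_subject_sc(template, 0, seed = 1), template)
  for (seed in 1:5) {
    s <- generate_subject_sc(template, 0.1, seed = seed)
    expect_matrix_equal(s$values, t(s$values), 1e-15)
    expect_true(all(s$values >= 0))
    ut <- upper.tri(s$values)
    expect_gt(stats::cor(s$values[ut], template$values[ut]), 0.8)
    # still one connected component
    expect_equal(max(sc2fc:::components_of(s$values)), 1)
  }
})

test_that("ground-truth FC maps behave as documented", {
  cfg_lin <- sim_config(n_regions = 10, fc_map = "linear", fc_noise_sd = 0,
                        seed = 2)
  sc <- generate_template_sc(cfg_lin)
  fc <- ground_truth_fc(sc, cfg_lin)
  shat <- sc2fc:::normalize_sc(sc$values)
  ut <- upper.tri(shat)
  ratio <- fc$values[ut][shat[ut] > 0] / shat[ut][shat[ut] > 0]
  expect_lt(stats::sd(ratio), 1e-12)   # exactly proportional

  # 2-node closed form for the communicability map:
  # normalized SC is [[0,1],[1,0]], expm gives sinh(1) off-diagonal
  two <- connectivity_matrix(matrix(c(0, 7, 7, 0), 2), "structural")
  cfg_com <- sim_config(n_regions = 5, fc_map = "communicability_tanh",
                        fc_noise_sd = 0, seed = 3)
  fc2 <- ground_truth_fc(two, cfg_com)
  expect_equal(fc2$values[1, 2], tanh(2 * sinh(1)), tolerance = 1e-10)

  # functional network denser than the structural one
  cfg_d <- sim_config(n_regions = 30, seed = 4)
  scd <- generate_template_sc(cfg_d)
  fcd <- ground_truth_fc(scd, cfg_d, seed = 9)
  sc_dens <- mean(scd$values[ut <- upper.tri(scd$values)] != 0)
  fc_dens <- mean(abs(fcd$values[ut]) > 0.05)
  expect_gt(fc_dens, sc_dens)

  # noiseless maps are deterministic
  expect_identical(ground_truth_fc(scd, cfg_lin), ground_truth_fc(scd,
                                                                  cfg_lin))
})

test_that("generate_cohort is deterministic and internally consistent", {
  cfg <- sim_config(n_subjects = 14, n_regions = 12, seed = 21,
                    planted_hubs = 1L)
  ch1 <- generate_cohort(cfg)
  ch2 <- generate_cohort(cfg)
  expect_identical(ch1, ch2)
  for (s in ch1$subjects) {
    expect_matrix_equal(s$sc$values, t(s$sc$values), 1e-15)
    expect_true(all(abs(s$fc$values) <= 1))
    expect_equal(diag(s$fc$values), rep(0, 12), ignore_attr = TRUE)
    expect_named(s$struct_centrality,
                 c("degree", "eigenvector", "pagerank"))
    expect_equal(s$func_centrality$degree$space, "standardized")
  }
  # written cohorts reload identically
  d <- withr::local_tempdir()
  write_cohort(ch1, d)
  ch3 <- read_cohort(d)
  for (id in names(ch1$subjects)) {
    expect_matrix_equal(ch1$subjects[[id]]$sc$values,
                        ch3$subjects[[id]]$sc$values, 1e-12)
  }
})

test_that("a 998-subject cohort splits 698/99/201", {
  cfg <- sim_config(n_subjects = 998, n_regions = 10, sc_density = 0.4,
                    planted_hubs = 1L, seed = 30)
  ch <- generate_cohort(cfg, centralities = FALSE)
  tab <- table(factor(ch$partition, c("train", "val", "test")))
  expect_equal(as.numeric(tab), c(698, 99, 201))
})

test_that("individual-level accuracy degrades with FC noise", {
  # noise-ceiling behaviour, evaluated against the noiseless ground truth
  # mapping rather than a trained model (isolates the generator property)
  r2_at_noise <- function(sd) {
    cfg <- sim_config(n_subjects = 12, n_regions = 20, fc_noise_sd = sd,
                      seed = 41, planted_hubs = 1L)
    cfg0 <- sim_config(n_subjects = 12, n_regions = 20, fc_noise_sd = 0,
                       seed = 41, planted_hubs = 1L)
    ch <- generate_cohort(cfg, centralities = FALSE)
    ch0 <- generate_cohort(cfg0, centralities = FALSE)
    pred <- emp <- c()
    for (id in names(ch$subjects)) {
      ut <- upper.tri(ch$subjects[[id]]$fc$values)
      pred <- c(pred, ch0$subjects[[id]]$fc$values[ut])
      emp <- c(emp, ch$subjects[[id]]$fc$values[ut])
    }
    r_squared(pred, emp)
  }
  r2s <- vapply(c(0.01, 0.05, 0.15, 0.4), r2_at_noise, numeric(1))
  expect_identical(order(r2s, decreasing = TRUE), 1:4)
})
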