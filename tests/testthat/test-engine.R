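test_that("replicate seeds are pure, distinct and in the 32-bit range", {
  s1 <- replicate_seed(1, 3, 10)
  expect_identical(s1, replicate_seed(1, 3, 10))
  combos <- expand.grid(ms = c(0, 1, 2, 123456), sc = 1:8, rep = 1:50)
  seeds <- mapply(replicate_seed, combos$ms, combos$sc, combos$rep)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 1))
  expect_true(is.integer(seeds))
})

test_that("run_scenario aggregates with exact internal identities", {
  spec <- scenario_spec(0.5, 0.5, 1.28, 26)
  s <- run_scenario(spec, n_reps = 80, master_seed = 11)
  expect_s3_class(s, "scenario_summary")
  expect_identical(nrow(s), 1L)
  # paired bias equals the difference of the mean estimates
  expect_equal(s$bias_anova, s$mean_beta_ancova - s$mean_beta_anova,
               tolerance = 1e-12)
  expect_equal(s$bias_csa, s$mean_beta_ancova - s$mean_beta_csa,
               tolerance = 1e-12)
  # design-effect ratio identity, exact because ratios share the means
  expect_equal(s$de_ancova_csa, s$de_ancova_anova / s$de_csa_anova,
               tolerance = 1e-12)
  expect_true(all(s[, grep("^power", names(s))] >= 0 &
                    s[, grep("^power", names(s))] <= 1))
  expect_true(all(s[, grep("^mean_se", names(s))] > 0))
  # directional power can never exceed two-sided power
  expect_lte(s$power_pos_csa, s$power_csa)
})

test_that("run_scenario is deterministic and replicates are reconstructible", {
  spec <- scenario_spec(0.2, 0.1, -1.96, 64)
  a <- run_scenario(spec, 40, master_seed = 5, scenario_index = 3)
  b <- run_scenario(spec, 40, master_seed = 5, scenario_index = 3)
  expect_identical(a, b)
  d <- run_scenario(spec, 40, master_seed = 6, scenario_index = 3)
  expect_false(identical(a$mean_beta_anova, d$mean_beta_anova))
  # rebuilding replicate 17 in isolation matches what the run consumed
  tr <- generate_trial(spec, replicate_seed(5, 3, 17))
  expect_s3_class(tr, "trial_dataset")
})

test_that("build_grid crosses the factors with effect fastest, deviate slowest", {
  expect_identical(nrow(build_grid(grid_config())), 126L)
  one <- grid_config(deviates = 0, correlations = 0.5, effects = 0.5,
                     n_per_group = 64)
  expect_identical(nrow(build_grid(one)), 1L)
  small <- grid_config(deviates = c(-1, 1), correlations = c(0, 0.5),
                       effects = c(0.2, 0.8), n_per_group = c(394, 26))
  g <- build_grid(small)
  expect_identical(nrow(g), 8L)
  expect_identical(g$effect[1:2], c(0.2, 0.8))      # effect fastest
  expect_identical(g$deviate, rep(c(-1, 1), each = 4)) # deviate slowest
  expect_identical(g$n_per_group[g$effect == 0.8], rep(26L, 4)) # paired
  expect_error(grid_config(effects = c(0.2, 0.5), n_per_group = 64),
               "equal length")
  expect_error(grid_config(deviates = numeric(0)), "non-empty")
})

test_that("run_grid is deterministic and one-row-per-scenario", {
  cfg <- grid_config(deviates = c(-1.28, 1.28), correlations = c(0.1, 0.7),
                     effects = 0.8, n_per_group = 26, n_reps = 25,
                     master_seed = 2)
  g1 <- run_grid(cfg)
  g2 <- run_grid(cfg)
  expect_identical(g1, g2)
  expect_identical(nrow(g1), 4L)
  expect_identical(g1$scenario, 1:4)
  # a single replicate makes power degenerate at 0 or 1
  g3 <- run_grid(cfg, n_reps = 1)
  expect_true(all(unlist(g3[, c("power_anova", "power_csa", "power_ancova")])
                  %in% c(0, 1)))
})

test_that("grid configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("deviates: [-1.28, 0, 1.28]",
               "correlations: [0.1, 0.7]",
               "effects: [0.5]",
               "n_per_group: [64]",
               "n_reps: 200",
               "alpha: 0.01",
               "master_seed: 42"), path)
  cfg <- read_grid_config(path)
  expect_s3_class(cfg, "grid_config")
  expect_identical(cfg$n_reps, 200L)
  expect_identical(cfg$alpha, 0.01)
  expect_identical(nrow(build_grid(cfg)), 6L)
  # missing keys fall back to defaults
  writeLines("n_reps: 10", path)
  expect_identical(read_grid_config(path)$master_seed, 1L)
  expect_length(read_grid_config(path)$deviates, 7L)
  writeLines(c("n_reps: 10", "bogus_key: 3"), path)
  expect_error(read_grid_config(path), "unknown configuration keys: bogus")
})

test_that("run_grid surfaces scenario context on failure", {
  cfg <- grid_config(deviates = 0, correlations = c(0, 0.5), effects = 0.5,
                     n_per_group = 64)
  # n_reps = 0 is rejected inside run_scenario; context must be attached
  expect_error(run_grid(cfg, n_reps = 0), "scenario 1.*rho=0")
  cfg1 <- grid_config(deviates = 0, correlations = 0.5, effects = 0.5,
                      n_per_group = 64)
  expect_warning(g <- run_grid(cfg1, n_reps = 0, on_error = "continue"),
                 "scenario")
  expect_null(g)
})

test_that("mean estimates recover the generative means within Monte-Carlo error", {
  spec <- scenario_spec(0.5, 0.3, 1.96, 64)
  s <- run_scenario(spec, 600, master_seed = 77)
  dz <- absolute_imbalance(1.96, 64)
  expect_lt(abs(s$mean_beta_anova - 0.5), 3 * s$mc_se_beta_anova)
  expect_lt(abs(s$mean_beta_csa - (0.5 - dz)), 3 * s$mc_se_beta_csa)
  expect_lt(abs(s$mean_beta_ancova - (0.5 - 0.3 * dz)),
            3 * s$mc_se_beta_ancova)
  # and the paired Monte-Carlo biases agree with the closed forms
  th <- bias_closed_form(0.3, 1.96, 64)
  expect_lt(abs(s$bias_anova - th$bias_anova), 3 * s$mc_se_bias_anova)
  expect_lt(abs(s$bias_csa - th$bias_csa), 3 * s$mc_se_bias_csa)
})
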