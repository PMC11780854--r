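test_that("config validation rejects bad probabilities and warns on inversion", {
  st <- make_structure("..((....))..")
  expect_error(probing_config(st, p_mod_unpaired = 1.2),
               class = "probeval_validation_error")
  expect_error(probing_config(st, n_molecules = 0),
               class = "probeval_validation_error")
  expect_error(probing_config(st, stop_offset = 2L),
               class = "probeval_validation_error")
  expect_warning(probing_config(st, p_mod_unpaired = 0.01, p_mod_paired = 0.5),
                 "paired")
})

test_that("single-hit rescaling fixes the expected modifications per molecule", {
  st <- make_structure(strrep(".", 100))
  cfg <- probing_config(st, p_mod_unpaired = 0.2, p_mod_paired = 0.2,
                        target_mods_per_molecule = 0.5)
  expect_equal(sum(cfg$m), 0.5)
})

test_that("the null experiment produces zero events in both channels", {
  st <- make_structure("..((....))..")
  cfg <- probing_config(st, mode = "stop", p_mod_unpaired = 0,
                        p_mod_paired = 0, natural_stop_rate = 0,
                        n_molecules = 500L, rng_seed = 2L)
  sim <- simulate_experiment(cfg)
  expect_equal(sum(sim$plus$events), 0)
  expect_equal(sum(sim$minus$events), 0)
  expect_equal(sim$plus$depth, rep(500L, 12))  # every read runs full length
  expect_equal(sum(sim$truth$modifications), 0)
})

test_that("MaP rates concentrate on the per-position expectation", {
  st <- make_structure(strrep(".", 50))
  cfg <- probing_config(st, mode = "mutation", p_mod_unpaired = 0.1,
                        p_mod_paired = 0.1, mutation_detect_prob = 1,
                        n_molecules = 100000L, rng_seed = 12L)
  sim <- simulate_experiment(cfg)
  rate <- sim$plus$events / sim$plus$depth
  se <- sqrt(0.1 * 0.9 / 100000)
  expect_gte(mean(abs(rate - 0.1) <= 3 * se), 0.99)
  # ground truth equals recorded mutations when detection is perfect
  # and there are no sequencing errors
  expect_equal(sim$truth$modifications, sim$plus$events)
})

test_that("SEQ detection censors all but the 3'-most modification", {
  # positions 2 and 5 are always modified: every molecule stops at 5,
  # so position 2 yields no events and no coverage
  st <- make_structure(".......")
  m <- c(0, 1, 0, 0, 1, 0, 0)
  cfg <- probing_config(st, mode = "stop", p_mod_by_position = m,
                        n_molecules = 300L, rng_seed = 5L)
  sim <- simulate_experiment(cfg)
  expect_equal(sim$plus$events[5], 300L)
  expect_equal(sim$plus$events[2], 0L)
  expect_equal(sim$plus$depth[5:7], rep(300L, 3))
  expect_equal(sim$plus$depth[1:4], rep(0L, 4))
  # at most one modification-derived stop per molecule in total
  expect_lte(sum(sim$plus$events), cfg$n_molecules)
  # the censored modification at position 2 still exists in the truth
  expect_equal(sim$truth$modifications[2], 300L)
})

test_that("stop events can be recorded one position 3' of the adduct", {
  st <- make_structure(".....")
  m <- c(0, 0, 1, 0, 0)
  cfg <- probing_config(st, mode = "stop", p_mod_by_position = m,
                        stop_offset = 1L, n_molecules = 100L, rng_seed = 6L)
  sim <- simulate_experiment(cfg)
  expect_equal(sim$plus$events[4], 100L)
  expect_equal(sim$plus$events[3], 0L)
})

test_that("generated profiles always satisfy events <= depth", {
  set.seed(77)
  st <- make_structure("..(((....)))..((....))..")
  for (i in 1:8) {
    cfg <- probing_config(
      st, mode = sample(c("stop", "mutation"), 1),
      p_mod_unpaired = runif(1, 0, 0.3), p_mod_paired = runif(1, 0, 0.1),
      natural_stop_rate = runif(1, 0, 0.05),
      seq_error_rate = runif(1, 0, 0.01),
      mutation_detect_prob = runif(1, 0.5, 1),
      stop_offset = sample(0:1, 1),
      n_molecules = 2000L, rng_seed = i)
    sim <- simulate_experiment(cfg)
    expect_true(all(sim$plus$events <= sim$plus$depth))
    expect_true(all(sim$minus$events <= sim$minus$depth))
    expect_true(all(sim$truth$modifications <= cfg$n_molecules))
  }
})

test_that("empirical SEQ rates agree with the closed-form expectation", {
  st <- make_structure("((((....))))....((....))")
  m <- ifelse(st$paired, 0.01, 0.04)
  cfg <- probing_config(st, mode = "stop", p_mod_by_position = m,
                        natural_stop_rate = 0.01, n_molecules = 100000L,
                        rng_seed = 9L)
  exp_rate <- expected_rate_profile(cfg)$expected_rate
  # offset 0 closed form: combined per-position stop probability
  q <- 1 - (1 - m) * (1 - 0.01)
  expect_equal(exp_rate, q)
  sim <- simulate_experiment(cfg)
  obs <- sim$plus$events / sim$plus$depth
  se <- sqrt(exp_rate * (1 - exp_rate) / sim$plus$depth)
  expect_gte(mean(abs(obs - exp_rate) <= 3 * se), 0.95)

  # a single modifiable position cannot be censored: rate equals m
  m1 <- c(0, 0, 0, 0, 0.07, rep(0, 19))
  cfg1 <- probing_config(st, mode = "stop", p_mod_by_position = m1,
                         n_molecules = 50000L, rng_seed = 10L)
  expect_equal(expected_rate_profile(cfg1)$expected_rate[5], 0.07)
})

test_that("MaP expected rate composes detection and sequencing error", {
  st <- make_structure(".....")
  cfg <- probing_config(st, mode = "mutation", p_mod_unpaired = 0.05,
                        p_mod_paired = 0.05, mutation_detect_prob = 1,
                        seq_error_rate = 0, n_molecules = 10L)
  expect_equal(expected_rate_profile(cfg)$expected_rate, rep(0.05, 5))
  cfg2 <- probing_config(st, mode = "mutation", p_mod_unpaired = 0.05,
                         p_mod_paired = 0.05, mutation_detect_prob = 0.8,
                         seq_error_rate = 0.01, n_molecules = 10L)
  expect_equal(expected_rate_profile(cfg2)$expected_rate,
               rep(0.04 + 0.96 * 0.01, 5))
  expect_equal(expected_rate_profile(cfg2, channel = "minus")$expected_rate,
               rep(0.01, 5))
})

test_that("benchmark scenarios are named, seeded and reproducible", {
  expect_error(make_benchmark_scenario("no-such-scenario"),
               class = "probeval_validation_error")

  a <- simulate_experiment(make_benchmark_scenario("overlap", 3,
                                                   n_molecules = 5000L)$config)
  b <- simulate_experiment(make_benchmark_scenario("overlap", 3,
                                                   n_molecules = 5000L)$config)
  expect_identical(a$plus, b$plus)
  expect_identical(a$minus, b$minus)

  st <- make_benchmark_scenario("overlap", 1)$structure
  frac_unpaired <- mean(!st$paired)
  expect_gte(frac_unpaired, 0.38)
  expect_lte(frac_unpaired, 0.50)
})

test_that("the separable scenario is perfectly separable downstream", {
  sc <- make_benchmark_scenario("separable", 4, n_molecules = 20000L)
  sim <- simulate_experiment(sc$config)
  r <- mutation_rate(sim$plus)
  expect_equal(roc_auc(r, sc$structure)$auc, 1.0)
  expect_equal(top_fraction_unpaired(r, sc$structure, 10), 1.0)
})
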