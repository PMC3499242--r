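test_that("configs validate, reject unknown keys, and round-trip as YAML", {
  cfg <- sim_config(structure = "well_mixed", N = 6, generations = 10,
                    seed = 3)
  expect_identical(cfg$pop_size, 36L)
  expect_error(sim_config(N = 1), "N")
  expect_error(sim_config(mu = 2), "probability")
  expect_error(sim_config(generations = 0), "generations")
  expect_error(sim_config(init_A = matrix(1, 2, 2), N = 5), "init_A")
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back)[names(unclass(cfg))], unclass(cfg))
  # unknown keys are named in the error
  writeLines("structure: lattice\nnot_a_key: 1", path)
  expect_error(read_sim_config(path), "not_a_key")
})

test_that("communities initialise homogeneous with evaluated payoffs", {
  cfg <- sim_config(structure = "lattice", N = 4, generations = 1,
                    init_trait = 0.01, seed = 1)
  cm <- init_community(cfg)
  expect_equal(dim(cm$A), c(16, 2))
  expect_true(all(cm$A == 0.01) && all(cm$B == 0.01))
  want <- total_payoffs(c(0.01, 0.01), c(0.01, 0.01), test_params())
  expect_equal(cm$payoff_A, rep(want[["A"]], 16))
  # an all-defector start has exactly zero payoffs
  cm0 <- init_community(sim_config(structure = "lattice", N = 4,
                                   generations = 1, init_trait = 0,
                                   seed = 1))
  expect_true(all(cm0$payoff_A == 0) && all(cm0$payoff_B == 0))
})

test_that("partners are matched sites on lattices, uniform draws otherwise", {
  cfg <- sim_config(structure = "lattice", N = 3, generations = 1, seed = 1)
  cm <- init_community(cfg)
  expect_identical(pair_of(5, cm), 5L)
  expect_error(pair_of(10, cm), "range")
  wm <- init_community(sim_config(structure = "well_mixed", pop_size = 10,
                                  generations = 1, seed = 1))
  set.seed(42)
  draws <- replicate(1e5, pair_of(3, wm))
  expect_true(all(draws >= 1 & draws <= 10))
  # frequency tally: uniform marginal over the other guild
  expect_gt(chisq.test(table(factor(draws, levels = 1:10)))$p.value, 1e-4)
  # seeded draws are reproducible
  set.seed(99)
  d1 <- replicate(20, pair_of(1, wm))
  set.seed(99)
  expect_identical(replicate(20, pair_of(1, wm)), d1)
})

test_that("evaluate_payoff caches the matched-site interaction totals", {
  cfg <- sim_config(structure = "lattice", N = 3, generations = 1, seed = 2)
  cm <- init_community(cfg)
  cm$A[4, ] <- c(0.8, 0.2)
  cm$B[4, ] <- c(0.4, 0.6)
  p <- test_params()
  cm2 <- evaluate_payoff(4, cm, p, guild = "A")
  want <- total_payoffs(cm$A[4, ], cm$B[4, ], p)
  expect_equal(attr(cm2, "payoff"), want[["A"]])
  expect_equal(cm2$payoff_A[4], want[["A"]])
  expect_equal(cm2$payoff_B[4], want[["B"]])
})

test_that("best-takes-over picks the maximum and ties break uniformly", {
  expect_identical(best_takes_over(c(1, 3, 2)), 2L)
  expect_identical(best_takes_over(c(5, 3, 2)), 1L)
  set.seed(8)
  picks <- replicate(4000, best_takes_over(c(1, 1, 1)))
  expect_true(all(sort(unique(picks)) == 1:3))
  # roughly uniform among the tied maximisers
  expect_gt(chisq.test(table(picks))$p.value, 1e-4)
})

test_that("the Fermi rule gives the closed-form replacement probability", {
  expect_equal(fermi_probability(1, 1, 0.1), 0.5)
  expect_equal(fermi_probability(0, 0.4, 0.1), 1 / (1 + exp(-4)))
  p_hi <- fermi_probability(0, 0.4, 0.1)
  expect_equal(p_hi, 0.9820, tolerance = 1e-4)
  # Monte-Carlo frequency within 3 SE of the closed form
  set.seed(31)
  n <- 1e5
  wins <- sum(vapply(seq_len(n), function(i) {
    pairwise_comparison(0.2, 0.35, K_sel = 0.1) == "competitor"
  }, logical(1)))
  want <- fermi_probability(0.2, 0.35, 0.1)
  se <- sqrt(want * (1 - want) / n)
  expect_lt(abs(wins / n - want), 3 * se)
})

test_that("mutation schemes behave at zero and match their moments", {
  # zero is absorbing under constant CV
  expect_identical(mutate_trait(rep(0, 100), "constant_cv", 0.1, mu = 1),
                   rep(0, 100))
  # mu = 0 is the identity
  v <- runif(50)
  expect_identical(mutate_trait(v, "constant_sigma", 0.5, mu = 0), v)
  # constant-sigma sample moments (large trait value: truncation negligible)
  set.seed(12)
  out <- mutate_trait(rep(10, 1e5), "constant_sigma", 0.05, mu = 1)
  expect_lt(abs(sd(out) - 0.05) / 0.05, 0.05)
  expect_lt(abs(mean(out) - 10), 0.01)
  # constant-cv sd scales with the trait value
  set.seed(13)
  out2 <- mutate_trait(rep(10, 1e5), "constant_cv", 0.1, mu = 1)
  expect_lt(abs(sd(out2) - 1) / 1, 0.05)
})

test_that("a homogeneous community without mutation is a fixed point", {
  cfg <- sim_config(structure = "lattice", N = 5, generations = 1, mu = 0,
                    init_trait = 0.3, seed = 4)
  cm <- init_community(cfg)
  cm2 <- step_generation(cm, cfg, n_generations = 5)
  expect_equal(cm2$A, cm$A)
  expect_equal(cm2$B, cm$B)
})

test_that("a superior pair spreads into its Moore neighbourhood in one sweep", {
  N <- 7
  A <- matrix(0, N * N, 2)
  B <- matrix(0, N * N, 2)
  centre <- 3 * N + 4   # site (3, 3) 0-based -> row-major index
  A[centre, ] <- c(1, 0.5)
  B[centre, ] <- c(1, 0.5)
  cfg <- sim_config(structure = "lattice", N = N, generations = 1, mu = 0,
                    update_rule = "best_takes_over",
                    scheduling = "synchronous",
                    init_A = A, init_B = B, seed = 6)
  sim <- run_simulation(cfg)
  got <- sim$final$A[, 1] > 0
  # the 3 x 3 block around the centre adopted the superior strategy
  idx0 <- centre - 1L
  r0 <- idx0 %/% N; c0 <- idx0 %% N
  want <- rep(FALSE, N * N)
  for (dr in -1:1) for (dc in -1:1) {
    want[((r0 + dr) %% N) * N + ((c0 + dc) %% N) + 1L] <- TRUE
  }
  expect_identical(got, want)
  expect_identical(sim$final$B[, 1] > 0, want)
  # repeated application on the frozen payoff field is idempotent: the
  # winner set after one sweep does not change strategy values
  expect_true(all(sim$final$A[want, 1] == 1))
})

test_that("runs are bit-reproducible from the seed", {
  cfg <- sim_config(structure = "well_mixed", pop_size = 30,
                    generations = 30, mutation_scheme = "constant_sigma",
                    sigma = 0.05, seed = 123)
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$final$A, s2$final$A)
  # asynchronous and synchronous scheduling are both valid but distinct
  cfg_sync <- sim_config(structure = "well_mixed", pop_size = 30,
                         generations = 30,
                         mutation_scheme = "constant_sigma", sigma = 0.05,
                         scheduling = "synchronous", seed = 123)
  s3 <- run_simulation(cfg_sync)
  expect_false(identical(s1$summary, s3$summary))
})

test_that("a below-threshold defector start without mutation stays at zero", {
  cfg <- sim_config(structure = "well_mixed", pop_size = 25,
                    generations = 40, mu = 0, init_trait = 0, seed = 5)
  sim <- run_simulation(cfg)
  expect_true(all(sim$summary$mean_payoff == 0))
  expect_true(all(sim$summary$mean_offer == 0))
})

test_that("selection without mutation never invents new strategies", {
  set.seed(20)
  n <- 64
  A <- cbind(runif(n, 0, 1), runif(n, 0, 1))
  B <- cbind(runif(n, 0, 1), runif(n, 0, 1))
  cfg <- sim_config(structure = "lattice", N = 8, generations = 15, mu = 0,
                    update_rule = "best_takes_over",
                    init_A = A, init_B = B, seed = 21)
  sim <- run_simulation(cfg)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(sim$final$A) %in% key(A)))
  expect_true(all(key(sim$final$B) %in% key(B)))
  # population sizes constant, traits non-negative throughout
  expect_equal(nrow(sim$final$A), n)
  expect_true(all(sim$summary$mean_offer >= 0))
})

test_that("constant-CV mutation is absorbing at zero, constant-sigma escapes", {
  base <- list(structure = "well_mixed", pop_size = 20, generations = 20,
               mu = 0.5, init_trait = 0, seed = 30)
  cfg_cv <- do.call(sim_config, c(base, mutation_scheme = "constant_cv"))
  sim_cv <- run_simulation(cfg_cv)
  expect_true(all(sim_cv$final$A == 0) && all(sim_cv$final$B == 0))
  cfg_sg <- do.call(sim_config, c(base, mutation_scheme = "constant_sigma"))
  sim_sg <- run_simulation(cfg_sg)
  expect_gt(max(sim_sg$final$A, sim_sg$final$B), 0)
})
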