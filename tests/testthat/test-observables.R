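make_snapshot <- function(A, B, N, p = test_params()) {
  pay <- vapply(seq_len(N * N), function(i) {
    total_payoffs(A[i, ], B[i, ], p)
  }, numeric(2))
  structure(list(A = A, B = B, payoff_A = pay[1, ], payoff_B = pay[2, ],
                 structure = "lattice", N = N),
            class = "community")
}

test_that("bubble detection partitions the lattice exactly once", {
  N <- 6
  hom <- make_snapshot(matrix(0.5, N * N, 2), matrix(0.5, N * N, 2), N)
  bs <- detect_bubbles(hom, epsilon = 0.1)
  expect_equal(nrow(bs$bubbles), 1L)
  expect_equal(bs$bubbles$n_sites, N * N)
  expect_true(all(bs$membership == 1L))

  # half/half split with a gap larger than epsilon: exactly two bubbles
  colidx <- (seq_len(N * N) - 1L) %% N + 1L
  A <- matrix(0.1, N * N, 2)
  A[colidx > N / 2, ] <- 1.1
  two <- make_snapshot(A, A, N)
  bs2 <- detect_bubbles(two, epsilon = 0.5)
  expect_equal(nrow(bs2$bubbles), 2L)
  expect_setequal(bs2$bubbles$n_sites, c(18, 18))
  # every site in exactly one bubble
  expect_equal(sum(bs2$bubbles$n_sites), N * N)

  # checkerboard of two distant strategies: under Moore-8 adjacency the
  # diagonally-connected colour classes form exactly two bubbles
  r <- (seq_len(N * N) - 1L) %/% N
  cc <- (seq_len(N * N) - 1L) %% N
  chk <- matrix(0.1, N * N, 2)
  chk[(r + cc) %% 2 == 1, ] <- 2
  bs3 <- detect_bubbles(make_snapshot(chk, chk, N), epsilon = 0.5)
  expect_equal(nrow(bs3$bubbles), 2L)
  expect_setequal(bs3$bubbles$n_sites, c(18, 18))

  # when every site differs from all eight neighbours the partition is
  # all singletons (adjacency-enumeration oracle: no edge survives)
  uni <- cbind(seq_len(N * N) * 1.0, 0)
  bs4 <- detect_bubbles(make_snapshot(uni, uni, N), epsilon = 0.5)
  expect_equal(nrow(bs4$bubbles), N * N)
  expect_true(all(bs4$bubbles$n_sites == 1L))
})

test_that("interface classification covers the four replacement cases", {
  p <- test_params()
  # identical pairs: degenerate ties
  ic0 <- classify_interface(list(c(1, 0.5), c(1, 0.5)),
                            list(c(1, 0.5), c(1, 0.5)), p)
  expect_identical(ic0$label, "degenerate")
  # strictly dominant pair: unidirectional invasion
  ic1 <- classify_interface(list(c(1, 0.5), c(1, 0.5)),
                            list(c(0.2, 0.3), c(0.2, 0.3)), p)
  expect_identical(ic1$label, "unidirectional_invasion")
  expect_identical(ic1$predicted_outcome, "bubble1_wins")
  # relabelling invariance: swapping the bubbles mirrors the outcome
  ic1s <- classify_interface(list(c(0.2, 0.3), c(0.2, 0.3)),
                             list(c(1, 0.5), c(1, 0.5)), p)
  expect_identical(ic1s$label, "unidirectional_invasion")
  expect_identical(ic1s$predicted_outcome, "bubble2_wins")
  expect_true(ic1s$swapped)
  # the constructed duel suite reaches all four cases
  duels <- construct_duels(p, n_per = 2, seed = 7)
  expect_true(all(vapply(duels, length, integer(1)) >= 2))
  for (lab in names(duels)) {
    for (d in duels[[lab]]) {
      expect_identical(d$case$label, lab)
      # label invariant under relabelling of the input bubbles
      rev <- classify_interface(d$pair2, d$pair1, p)
      expect_identical(rev$label, lab)
    }
  }
})

test_that("the payoff table orders contexts as bubble1 / interface / bubble2", {
  p <- test_params()
  pair1 <- list(c(1, 0.5), c(1, 0.5))
  pair2 <- list(c(0.2, 0.3), c(0.2, 0.3))
  ic <- classify_interface(pair1, pair2, p)
  tab <- ic$payoff_table
  expect_identical(dim(tab), c(2L, 3L))
  h1 <- total_payoffs(pair1[[1]], pair1[[2]], p)
  h2 <- total_payoffs(pair2[[1]], pair2[[2]], p)
  expect_equal(unname(tab["A", "bubble1"]), h1[["A"]])
  expect_equal(unname(tab["B", "bubble2"]), h2[["B"]])
})

test_that("two-bubble experiments agree with the 1-D rehearsal", {
  p <- test_params()
  duels <- construct_duels(p, n_per = 1, seed = 7)
  for (lab in names(duels)) {
    d <- duels[[lab]][[1]]
    rh <- rehearse_interface(d$pair1, d$pair2, p, width = 20)
    tb <- two_bubble_experiment(d$pair1, d$pair2, p, N = 20,
                                generations = 100, seed = 1)
    expect_identical(tb$outcome, rh$outcome)
  }
  # identical pairs cannot displace each other
  tb0 <- two_bubble_experiment(list(c(1, 0.5), c(1, 0.5)),
                               list(c(1, 0.5), c(1, 0.5)), p,
                               N = 10, generations = 10, seed = 1)
  expect_identical(tb0$outcome, "coexistence")
})

test_that("phase distribution of a monomorphic community is a point mass", {
  n <- 9
  cm <- structure(list(A = matrix(c(0.2, 0.3), n, 2, byrow = TRUE),
                       B = matrix(c(0.2, 0.3), n, 2, byrow = TRUE),
                       payoff_A = numeric(n), payoff_B = numeric(n),
                       structure = "lattice", N = 3),
                  class = "community")
  pd <- phase_distribution(cm, test_params(), bin_width = 5)
  hA <- pd$histogram[pd$histogram$guild == "A", ]
  expect_identical(sum(hA$count > 0), 1L)
  expect_equal(sum(hA$count), n)
  expect_identical(unname(pd$n_undefined[["A"]]), 0L)
})

test_that("payoff symmetry statistics flag exploitation poles", {
  p <- test_params()
  n <- 4
  # symmetric interactions: relative difference 0
  cm <- structure(list(A = matrix(c(1, 0.3), n, 2, byrow = TRUE),
                       B = matrix(c(1, 0.3), n, 2, byrow = TRUE),
                       payoff_A = numeric(n), payoff_B = numeric(n),
                       structure = "lattice", N = 2),
                  class = "community")
  ps <- payoff_symmetry_stats(cm, p)
  expect_true(all(abs(ps$rel_diff) < 1e-12))
  expect_true(all(ps$payoff_sum > 0))
  # one-sided exploitation approaches d = 1: B offers, A only collects
  cm$A <- matrix(c(0, 0), n, 2, byrow = TRUE)
  cm$B <- matrix(c(1, 0), n, 2, byrow = TRUE)
  ps2 <- payoff_symmetry_stats(cm, p)
  dA <- benefit(1, p) * p$T            # A collects benefit, invests nothing
  dB <- -cost(1, p) * p$T              # B pays cost, receives nothing
  expect_equal(ps2$payoff_A, rep(dA, n))
  expect_equal(ps2$payoff_B, rep(dB, n))
  # the sum is positive so d is defined; it sits at/beyond the exploitation
  # pole d = 1 (beyond, because the exploited partner's payoff is negative)
  expect_equal(ps2$rel_diff, rep((dA - dB) / (dA + dB), n))
  expect_true(all(ps2$rel_diff >= 1))
})

test_that("CSV exports carry the documented columns", {
  p <- test_params()
  fl <- gradient_flow(list(c(0.01, 0.06), c(0.01, 0.06)), p,
                      step_size = 1e-3, n_steps = 50)
  path <- tempfile(fileext = ".csv")
  export_csv(fl, path)
  df <- read.csv(path)
  expect_true(all(c("step", "offer_A", "reward_A", "grad_offer_A",
                    "phase_A", "quadrant_A") %in% names(df)))
  cfg <- sim_config(structure = "lattice", N = 4, generations = 5, seed = 2)
  sim <- run_simulation(cfg)
  export_csv(sim, path)
  expect_true(all(c("generation", "guild", "mean_offer", "norm_payoff")
                  %in% names(read.csv(path))))
  export_csv(sim$final, path)
  df2 <- read.csv(path)
  expect_equal(nrow(df2), 16)
  expect_true(all(c("row", "col", "offer_A", "payoff_B") %in% names(df2)))
})
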