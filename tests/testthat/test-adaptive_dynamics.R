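test_that("phase angles follow the clockwise-from-reward-axis convention", {
  expect_equal(phase_of(1e-9, 1)$phase_angle, 0, tolerance = 1e-6)
  expect_equal(phase_of(1e-9, 1)$quadrant, "I")
  expect_equal(phase_of(1, -1)$phase_angle, 135)
  expect_equal(phase_of(1, -1)$quadrant, "II")
  expect_equal(phase_of(-1, 1)$phase_angle, 315)
  expect_equal(phase_of(-1, 1)$quadrant, "IV")
  expect_equal(phase_of(-1, -1)$quadrant, "III")
  expect_error(phase_of(0, 0), "undefined")
})

test_that("sign-based and angle-based quadrants agree on random gradients", {
  set.seed(11)
  n <- 10000
  go <- runif(n, -1, 1)
  gr <- runif(n, -1, 1)
  keep <- go != 0 & gr != 0
  for (i in which(keep)[1:2000]) {
    ph <- phase_of(go[i], gr[i])
    want <- if (go[i] > 0 && gr[i] > 0) "I" else if (go[i] > 0) "II"
            else if (gr[i] < 0) "III" else "IV"
    expect_identical(ph$quadrant, want)
    in_range <- switch(want, I = c(0, 90), II = c(90, 180),
                       III = c(180, 270), IV = c(270, 360))
    expect_true(ph$phase_angle >= in_range[1] && ph$phase_angle < in_range[2])
  }
})

test_that("phase asymmetry wraps into (-180, 180]", {
  expect_equal(phase_asymmetry(42, 42), 0)
  expect_equal(phase_asymmetry(10, 350), 20)
  expect_equal(phase_asymmetry(350, 10), -20)
  expect_equal(phase_asymmetry(200, 20), 180)
  set.seed(2)
  a <- runif(50, 0, 360); b <- runif(50, 0, 360)
  d <- phase_asymmetry(a, b)
  expect_true(all(d > -180 & d <= 180))
  # antisymmetric up to the wrap boundary
  expect_equal(phase_asymmetry(a, b)[abs(d) < 179],
               -phase_asymmetry(b, a)[abs(d) < 179])
})

test_that("monomorphic gradients match a polynomial-fit derivative oracle", {
  p <- test_params()
  focal <- c(0.3, 0.25)
  partner <- c(0.4, 0.15)
  rec <- selection_gradient(focal, partner, p, h = 1e-4)
  # quartic fit over a dense +-5h neighbourhood, differentiated at the centre
  poly_deriv <- function(dim) {
    hh <- seq(-5e-4, 5e-4, length.out = 11)
    pays <- vapply(hh, function(d) {
      s <- focal; s[dim] <- s[dim] + d
      total_payoffs(s, partner, p)[["A"]]
    }, numeric(1))
    fit <- lm(pays ~ poly(hh, 4, raw = TRUE))
    unname(coef(fit)[2])
  }
  expect_lt(abs(rec$grad_offer - poly_deriv(1)) / abs(poly_deriv(1)), 1e-3)
  expect_lt(abs(rec$grad_reward - poly_deriv(2)) / abs(poly_deriv(2)), 1e-3)
})

test_that("gradients at the no-investment corner never favour offering", {
  p <- test_params()
  rec <- selection_gradient(c(0, 0), c(0, 0), p)
  expect_lte(rec$grad_offer, 0)
  # just above the threshold with small offers: quadrant I
  beta <- reciprocation_threshold(p)
  rec2 <- selection_gradient(c(0.01, beta * 1.5), c(0.01, beta * 1.5), p)
  expect_identical(rec2$quadrant, "I")
})

test_that("polymorphic gradients reduce, add and average as they must", {
  p <- test_params()
  focal <- c(0.2, 0.3)
  partner <- c(0.5, 0.2)
  mono <- selection_gradient(focal, partner, p)
  poly1 <- selection_gradient_polymorphic(focal, partner, p)
  expect_equal(poly1$grad_offer, mono$grad_offer, tolerance = 1e-9)
  expect_equal(poly1$grad_reward, mono$grad_reward, tolerance = 1e-9)
  # two identical partners double the summed gradient
  poly2 <- selection_gradient_polymorphic(focal, rbind(partner, partner), p)
  expect_equal(poly2$grad_offer, 2 * mono$grad_offer, tolerance = 1e-9)
  # a mixed collection equals the sum of per-partner gradients
  set.seed(5)
  pop <- cbind(runif(6, 0, 1), runif(6, 0, 1))
  mix <- selection_gradient_polymorphic(focal, pop, p)
  per <- rowSums(vapply(seq_len(nrow(pop)), function(i) {
    g <- selection_gradient(focal, pop[i, ], p)
    c(g$grad_offer, g$grad_reward)
  }, numeric(2)))
  expect_equal(c(mix$grad_offer, mix$grad_reward), unname(per),
               tolerance = 1e-8)
  expect_error(selection_gradient_polymorphic(focal, pop[0, , drop = FALSE],
                                              p), "empty")
})

test_that("gradient flow reproduces the boom-and-bust investment cycle", {
  p <- test_params()
  beta <- reciprocation_threshold(p)
  fl <- gradient_flow(list(c(0.01, beta * 1.5), c(0.01, beta * 1.5)), p,
                      step_size = 1e-3, n_steps = 5000)
  tr <- fl$trajectory
  expect_gt(max(tr$offer_A), 10 * 0.01)
  expect_lt(max(abs(tail(tr[, c("offer_A", "reward_A",
                                "offer_B", "reward_B")], 1))), 1e-3)
  qs <- rle(tr$quadrant_A[tr$quadrant_A != "undefined"])$values
  expect_identical(qs[1:3], c("I", "II", "III"))
  # guild symmetry: symmetric starts give identical trajectories
  expect_equal(tr$offer_A, tr$offer_B, tolerance = 1e-12)
  expect_equal(tr$reward_A, tr$reward_B, tolerance = 1e-12)
})

test_that("below-threshold flows decay monotonically to no investment", {
  p <- test_params()
  beta <- reciprocation_threshold(p)
  fl <- gradient_flow(list(c(0.05, beta * 0.5), c(0.05, beta * 0.5)), p,
                      step_size = 1e-3, n_steps = 5000)
  tr <- fl$trajectory
  expect_true(all(diff(tr$offer_A) <= 1e-12))
  # offers vanish; selection on the reward rate itself scales with the
  # offers, so the reward freezes at or below its (sub-threshold) start
  expect_lt(tail(tr$offer_A, 1), 1e-3)
  expect_lt(tail(tr$offer_B, 1), 1e-3)
  expect_true(all(diff(tr$reward_A) <= 1e-12))
  expect_lte(tail(tr$reward_A, 1), beta * 0.5 + 1e-12)
})
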