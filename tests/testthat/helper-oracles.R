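# Independent reference implementations used as oracles. These deliberately
# re-derive the game from its definition with plain R loops and stay
# independent of the package's computational paths.

# straight-loop iterated game: round 1 invests the offer, later rounds
# max(0, offer + reward * previous own payoff); payoff = benefit of the
# partner's investment minus cost of one's own
reference_game <- function(sA, sB, B0, B1, K, T) {
  benefit <- function(x) B0 * (1 - exp(-B1 * x))
  iA <- sA[1]; iB <- sB[1]
  pA <- 0; pB <- 0
  invA <- invB <- payA <- payB <- numeric(T)
  for (t in seq_len(T)) {
    if (t > 1) {
      iA <- max(0, sA[1] + sA[2] * pA)
      iB <- max(0, sB[1] + sB[2] * pB)
    }
    pA <- benefit(iB) - K * iA
    pB <- benefit(iA) - K * iB
    invA[t] <- iA; invB[t] <- iB
    payA[t] <- pA; payB[t] <- pB
  }
  list(investments_A = invA, investments_B = invB,
       payoffs_A = payA, payoffs_B = payB,
       total_A = sum(payA), total_B = sum(payB))
}

# grid-search maximiser of T * (benefit - cost) over x in [0, 50/B1]
reference_max_potential <- function(B0, B1, K, T, resolution = 1e-4) {
  x <- seq(0, 50 / B1, by = resolution)
  max(0, max(B0 * (1 - exp(-B1 * x)) - K * x)) * T
}

random_strategy <- function(max_offer = 2, max_reward = 2) {
  c(runif(1, 0, max_offer), runif(1, 0, max_reward))
}

# small default parameterisation used across tests
test_params <- function(...) model_params(B0 = 5, B1 = 1, K = 1, T = 20, ...)

# deterministic duel-constructor: random search, classified by the package,
# collecting n_per duels of each of the four bubble-interface cases
construct_duels <- function(p, n_per = 5, seed = 7, max_tries = 8000) {
  labels <- c("unidirectional_invasion", "partner_swapping",
              "catalyzed_invasion", "insulating_boundary")
  found <- setNames(vector("list", length(labels)), labels)
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    pair1 <- list(random_strategy(1.5, 1), random_strategy(1.5, 1))
    pair2 <- list(random_strategy(1.5, 1), random_strategy(1.5, 1))
    ic <- classify_interface(pair1, pair2, p)
    lab <- ic$label
    if (lab %in% labels && length(found[[lab]]) < n_per) {
      found[[lab]] <- c(found[[lab]],
                        list(list(pair1 = pair1, pair2 = pair2, case = ic)))
    }
    if (all(vapply(found, length, integer(1)) >= n_per)) break
  }
  found
}
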