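#' Strategy-grid specification for numerical best responses
#'
#' Best responses are computed by exhaustively scanning a rectangular grid
#' over the two-dimensional strategy space. Both grids start exactly at 0.
#'
#' @param offer_max,reward_max Upper scan bounds (> 0).
#' @param n_offer,n_reward Number of grid points per axis (integer >= 2).
#' @return Object of class `"grid_spec"` with the two grid vectors.
#' @examples
#' grid_spec(5, 5, 51, 51)
#' @export
grid_spec <- function(offer_max = 5, reward_max = 5,
                      n_offer = 201, n_reward = 201) {
  if (offer_max <= 0 || reward_max <= 0) stop("grid bounds must be positive")
  if (n_offer < 2 || n_reward < 2) stop("grid resolutions must be >= 2")
  structure(list(
    offer_max = offer_max, reward_max = reward_max,
    n_offer = as.integer(n_offer), n_reward = as.integer(n_reward),
    offers = seq(0, offer_max, length.out = n_offer),
    rewards = seq(0, reward_max, length.out = n_reward)
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("strategy grid: %d x %d over [0, %g] x [0, %g]\n",
              x$n_offer, x$n_reward, x$offer_max, x$reward_max))
  invisible(x)
}

#' Numerical interspecific best response
#'
#' Scans the strategy grid for the responder strategy with the highest total
#' payoff against a fixed opponent from the other guild. Ties are broken
#' toward the smaller offer, then the smaller reward, so the result is
#' deterministic.
#'
#' @param opponent Opponent strategy (the partner guild's resident).
#' @param p A [model_params()] object (built-in benefit/cost family only).
#' @param g A [grid_spec()].
#' @return A [strategy()] with attributes `payoff` (the responder's total
#'   payoff) and `grid_index` (offer/reward grid indices).
#' @examples
#' p <- model_params()
#' best_response(strategy(0, 0), p, grid_spec(2, 2, 41, 41))
#' @export
best_response <- function(opponent, p, g = grid_spec()) {
  stopifnot(inherits(p, "model_params"), inherits(g, "grid_spec"))
  if (has_custom_fns(p)) {
    stop("grid best responses require the built-in benefit/cost family")
  }
  opp <- as_strategy(opponent, "opponent")
  res <- best_response_cpp(opp, p$B0, p$B1, p$K, p$T, g$offers, g$rewards)
  out <- strategy(res[["offer"]], res[["reward"]])
  attr(out, "payoff") <- res[["payoff"]]
  attr(out, "grid_index") <- c(offer = unname(res[["i_offer"]]),
                               reward = unname(res[["i_reward"]]))
  out
}

#' Alternating best-response dynamics
#'
#' Starting from a strategy pair, the guilds alternate in adopting the best
#' response to the other guild's current strategy. The walk stops at a fixed
#' point (both guilds repeat their grid point over a full A+B cycle) or
#' after `max_steps` responses.
#'
#' @param start List or pair of two strategies `(A, B)`.
#' @inheritParams best_response
#' @param max_steps Maximum number of single-guild responses (>= 1).
#' @param first Which guild responds first, `"A"` (default) or `"B"`.
#' @return Object of class `"br_dynamics"`: list with `trajectory` (data
#'   frame: step, guild, offer, reward, payoff), `converged`, `final`
#'   (list of the final A and B strategies) and `n_steps`.
#' @examples
#' p <- model_params()
#' d <- best_response_dynamics(list(strategy(0.3, 0.1), strategy(0.3, 0.1)),
#'                             p, grid_spec(2, 2, 41, 41))
#' d$converged
#' @export
best_response_dynamics <- function(start, p, g = grid_spec(),
                                   max_steps = 50, first = c("A", "B")) {
  stopifnot(inherits(p, "model_params"), inherits(g, "grid_spec"),
            max_steps >= 1)
  first <- match.arg(first)
  sA <- as_strategy(start[[1]], "start A")
  sB <- as_strategy(start[[2]], "start B")
  traj <- data.frame(step = 0L, guild = c("A", "B"),
                     offer = c(sA[1], sB[1]), reward = c(sA[2], sB[2]),
                     payoff = NA_real_)
  idx <- list(A = NULL, B = NULL)
  repeated <- c(A = FALSE, B = FALSE)
  responder <- first
  converged <- FALSE
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    br <- if (responder == "A") best_response(sB, p, g)
          else best_response(sA, p, g)
    gi <- attr(br, "grid_index")
    cur <- if (responder == "A") sA else sB
    repeated[responder] <- identical(gi, idx[[responder]]) ||
      (br[[1]] == cur[1] && br[[2]] == cur[2])
    idx[[responder]] <- gi
    if (responder == "A") sA <- unclass(br) else sB <- unclass(br)
    traj <- rbind(traj, data.frame(step = step, guild = responder,
                                   offer = br[[1]], reward = br[[2]],
                                   payoff = attr(br, "payoff")))
    # fixed point: both guilds repeated their own previous grid point on
    # their two most recent (consecutive same-guild) responses
    if (all(repeated)) {
      converged <- TRUE
      break
    }
    responder <- if (responder == "A") "B" else "A"
  }
  structure(list(trajectory = traj, converged = converged,
                 final = list(A = strategy(sA[1], sA[2]),
                              B = strategy(sB[1], sB[2])),
                 n_steps = step),
            class = "br_dynamics")
}

#' @export
print.br_dynamics <- function(x, ...) {
  cat(sprintf("best-response dynamics: %d responses, %s\n", x$n_steps,
              if (x$converged) "converged to a fixed point"
              else "stopped at max_steps (no fixed point reached)"))
  cat("final pair:\n  A: "); print(x$final$A)
  cat("  B: "); print(x$final$B)
  invisible(x)
}

#' @export
plot.br_dynamics <- function(x, ...) {
  tr <- x$trajectory
  plot(tr$offer, tr$reward, type = "n",
       xlab = "initial offer", ylab = "reward rate",
       main = "best-response dynamics", ...)
  for (gld in c("A", "B")) {
    sub <- tr[tr$guild == gld, ]
    lines(sub$offer, sub$reward, type = "o",
          col = if (gld == "A") "black" else "grey50", pch = 16)
  }
  legend("topright", legend = c("guild A", "guild B"),
         col = c("black", "grey50"), lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Reciprocation threshold of the linearised game
#'
#' For vanishing investments the game linearises: an extra unit of own
#' investment costs `C'(0) = K` and raises the partner's payoff by
#' `B'(0) = B0 * B1`; a payoff-reactive partner returns
#' `reward * B'(0)` extra investment, worth another factor `B'(0)` in
#' benefit. Reciprocation therefore pays when
#' `reward * B'(0)^2 > C'(0)`, i.e. above the threshold reward rate
#' \deqn{\beta^* = C'(0) / B'(0)^2 = K / (B_0 B_1)^2.}
#' Below this threshold both best-response dynamics and selection gradients
#' lead straight to the no-investment equilibrium; above it, investments
#' first rise (the start of the investment cycle). This is the
#' infinite-game, small-investment limit: in a finite game of `T` rounds the
#' last round's investment earns no return, shifting the measured
#' sign-change upward by a factor of roughly `1 + 2/T`.
#'
#' @param p A [model_params()] object.
#' @return The threshold reward rate `K / (B0 * B1)^2` (investment units per
#'   payoff unit).
#' @examples
#' reciprocation_threshold(model_params(B0 = 5, B1 = 1, K = 1))  # 0.04
#' @export
reciprocation_threshold <- function(p) {
  stopifnot(inherits(p, "model_params"))
  p$K / (p$B0 * p$B1)^2
}

#' Exhaustive scan for mutual best-response pairs
#'
#' Computes the (tie-broken, hence deterministic) best-response map on the
#' grid and returns every pair of strategies that are best responses to each
#' other. Because the two guilds are interchangeable in the game, a single
#' map serves both. Zero-payoff responses that are payoff-ties of the
#' no-investment strategy collapse onto it under the smaller-offer /
#' smaller-reward tie-break.
#'
#' A coarse grid can host spurious fixed points: wherever the true
#' best-response map moves a strategy by less than one grid step, the scan
#' sees a "mutual" pair. Candidate pairs are therefore verified on a finer
#' grid (`refine`): a pair is kept only if neither member can be strictly
#' improved upon there.
#'
#' @inheritParams best_response
#' @param refine A finer [grid_spec()] used to verify candidate pairs
#'   (`NULL` skips verification).
#' @return Data frame with one row per verified mutual pair: the two
#'   strategies' offers and rewards.
#' @examples
#' find_mutual_best_responses(model_params(), grid_spec(1, 1, 6, 6),
#'                            refine = grid_spec(1, 1, 51, 51))
#' @export
find_mutual_best_responses <- function(p, g = grid_spec(5, 5, 21, 21),
                                       refine = grid_spec()) {
  stopifnot(inherits(p, "model_params"), inherits(g, "grid_spec"))
  pts <- expand.grid(offer = g$offers, reward = g$rewards,
                     KEEP.OUT.ATTRS = FALSE)
  n <- nrow(pts)
  br_idx <- integer(n)
  for (i in seq_len(n)) {
    br <- best_response(c(pts$offer[i], pts$reward[i]), p, g)
    gi <- attr(br, "grid_index")
    br_idx[i] <- (gi[["reward"]] - 1L) * g$n_offer + gi[["offer"]]
  }
  # unordered pairs (i, j) with BR(i) = j and BR(j) = i, kept once
  mutual <- which(br_idx[br_idx] == seq_len(n) & br_idx >= seq_len(n))
  if (!is.null(refine) && length(mutual) > 0L) {
    ok <- vapply(mutual, function(i) {
      j <- br_idx[i]
      s_i <- c(pts$offer[i], pts$reward[i])
      s_j <- c(pts$offer[j], pts$reward[j])
      for (pair in list(list(s_i, s_j), list(s_j, s_i))) {
        held <- total_payoffs_cpp(pair[[2]], pair[[1]],
                                  p$B0, p$B1, p$K, p$T)[1]
        fine <- attr(best_response(pair[[1]], p, refine), "payoff")
        if (fine > held + 1e-9 * max(1, abs(held))) return(FALSE)
      }
      TRUE
    }, logical(1))
    mutual <- mutual[ok]
  }
  if (length(mutual) == 0L) {
    return(data.frame(offer_1 = numeric(0), reward_1 = numeric(0),
                      offer_2 = numeric(0), reward_2 = numeric(0)))
  }
  j <- br_idx[mutual]
  data.frame(offer_1 = pts$offer[mutual], reward_1 = pts$reward[mutual],
             offer_2 = pts$offer[j], reward_2 = pts$reward[j])
}
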