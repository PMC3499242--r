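#' Strategy of one guild member
#'
#' A strategy is the heritable pair of investment traits: the unconditional
#' initial offer (investment made in the first round, before any feedback)
#' and the reward rate (the slope with which the previous round's own net
#' payoff is translated into the next investment).
#'
#' @param offer Non-negative number, the initial offer (investment units).
#' @param reward Non-negative number, the reward rate (per payoff unit).
#'
#' @return An object of class `"strategy"`: a named numeric vector with
#'   elements `offer` and `reward`.
#' @examples
#' strategy(0.5, 1.2)
#' @export
strategy <- function(offer, reward) {
  if (!is.numeric(offer) || !is.numeric(reward) ||
      length(offer) != 1L || length(reward) != 1L ||
      is.na(offer) || is.na(reward)) {
    stop("`offer` and `reward` must be single non-missing numbers")
  }
  if (offer < 0 || reward < 0) {
    stop("strategy traits must be non-negative")
  }
  structure(c(offer = as.numeric(offer), reward = as.numeric(reward)),
            class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("strategy: offer = %g, reward = %g\n", x[[1]], x[[2]]))
  invisible(x)
}

# coerce a strategy / length-2 numeric to a plain c(offer, reward) double
as_strategy <- function(s, arg = "strategy") {
  if (inherits(s, "strategy")) return(unclass(s))
  if (is.numeric(s) && length(s) == 2L && !anyNA(s)) {
    if (any(s < 0)) stop(sprintf("`%s` has negative traits", arg))
    return(as.numeric(s))
  }
  stop(sprintf("`%s` must be a strategy() or a length-2 numeric vector", arg))
}

#' Model parameters of the investment game
#'
#' Collects the parameters of the benefit and cost functions and the number
#' of interaction rounds. The built-in benefit function is the saturating
#' exponential \eqn{B(x) = B_0 (1 - e^{-B_1 x})} and the cost function is
#' linear, \eqn{C(x) = K x}. The linearised benefit-to-cost ratio
#' \eqn{r_0 = B_0 B_1 / K} (the ratio of the two slopes at zero investment)
#' is an upper bound on the realised benefit-to-cost ratio of any positive
#' investment; mutualism can only be profitable when \eqn{r_0 > 1}.
#'
#' Alternative benefit/cost forms can be injected through `benefit_fn` and
#' `cost_fn`; these are honoured by the pure-R game ([play_interaction()])
#' and by [benefit()]/[cost()], while the grid scans and the individual-based
#' model always use the built-in parametric family.
#'
#' @param B0 Asymptotic benefit, payoff units (> 0).
#' @param B1 Saturation rate of the benefit, per investment unit (> 0).
#' @param K Cost slope, payoff units per investment unit (>= 0; `K = 0` is a
#'   degenerate costless limit useful only for analysis).
#' @param T Number of interaction rounds per pairing (integer >= 1).
#' @param benefit_fn,cost_fn Optional functions of a single non-negative
#'   investment returning payoff units; override the built-in forms.
#'
#' @return Object of class `"model_params"` with fields `B0`, `B1`, `K`, `T`
#'   and the derived slope ratio `r0`.
#' @examples
#' p <- model_params(B0 = 5, B1 = 1, K = 1, T = 20)
#' p$r0
#' @export
model_params <- function(B0 = 5, B1 = 1, K = 1, T = 20,
                         benefit_fn = NULL, cost_fn = NULL) {
  if (!is.numeric(B0) || B0 <= 0) stop("`B0` must be > 0")
  if (!is.numeric(B1) || B1 <= 0) stop("`B1` must be > 0")
  if (!is.numeric(K) || K < 0) stop("`K` must be >= 0")
  if (!is.numeric(T) || T < 1 || T != round(T)) {
    stop("`T` must be an integer >= 1")
  }
  if (!is.null(benefit_fn) && !is.function(benefit_fn)) {
    stop("`benefit_fn` must be a function")
  }
  if (!is.null(cost_fn) && !is.function(cost_fn)) {
    stop("`cost_fn` must be a function")
  }
  structure(list(B0 = as.numeric(B0), B1 = as.numeric(B1),
                 K = as.numeric(K), T = as.integer(T),
                 r0 = if (K > 0) B0 * B1 / K else Inf,
                 benefit_fn = benefit_fn, cost_fn = cost_fn),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("investment game: B0 = %g, B1 = %g, K = %g, T = %d rounds\n",
              x$B0, x$B1, x$K, x$T))
  cat(sprintf("  slope ratio r0 = B0*B1/K = %g", x$r0))
  cat(if (is.finite(x$r0) && x$r0 <= 1) "  (mutualism never profitable)\n"
      else "\n")
  if (!is.null(x$benefit_fn) || !is.null(x$cost_fn)) {
    cat("  custom benefit/cost functions supplied\n")
  }
  invisible(x)
}

has_custom_fns <- function(p) {
  !is.null(p$benefit_fn) || !is.null(p$cost_fn)
}

#' Benefit received from a partner's investment
#'
#' Saturating benefit \eqn{B(x) = B_0 (1 - e^{-B_1 x})}: zero at zero
#' investment, strictly increasing and concave, approaching `B0` for large
#' investments, with slope `B0 * B1` at the origin.
#'
#' @param x Non-negative investment (vectorised).
#' @param p A [model_params()] object.
#' @return Benefit in payoff units, in `[0, B0)`.
#' @examples
#' p <- model_params()
#' benefit(c(0, 1, 10), p)
#' @export
benefit <- function(x, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(x < 0)) stop("investment must be non-negative")
  if (!is.null(p$benefit_fn)) return(p$benefit_fn(x))
  p$B0 * (1 - exp(-p$B1 * x))
}

#' Cost of one's own investment
#'
#' Linear cost \eqn{C(x) = K x}.
#'
#' @inheritParams benefit
#' @return Cost in payoff units.
#' @examples
#' cost(2, model_params(K = 0.5))
#' @export
cost <- function(x, p) {
  stopifnot(inherits(p, "model_params"))
  if (any(x < 0)) stop("investment must be non-negative")
  if (!is.null(p$cost_fn)) return(p$cost_fn(x))
  p$K * x
}

#' Play one iterated interaction between an A- and a B-individual
#'
#' Runs the T-round reactive investment game. Both individuals invest their
#' offer in round 1; in every later round each invests
#' `max(0, offer + reward * previous own net payoff)`, where the net payoff
#' of a round is the benefit from the partner's investment minus the cost of
#' one's own. The game is deterministic.
#'
#' @param sA,sB Strategies ([strategy()] or length-2 numeric
#'   `c(offer, reward)`) of the A- and B-individual.
#' @param p A [model_params()] object.
#'
#' @return Object of class `"interaction"`: list with per-round
#'   `investments_A`, `investments_B`, `payoffs_A`, `payoffs_B` (length `T`)
#'   and the round sums `total_A`, `total_B`.
#' @examples
#' p <- model_params()
#' res <- play_interaction(strategy(0.5, 1), strategy(0.5, 1), p)
#' res$total_A
#' @export
play_interaction <- function(sA, sB, p) {
  stopifnot(inherits(p, "model_params"))
  a <- as_strategy(sA, "sA")
  b <- as_strategy(sB, "sB")
  if (!has_custom_fns(p)) {
    res <- play_interaction_cpp(a, b, p$B0, p$B1, p$K, p$T)
  } else {
    # pure-R path honouring injected benefit/cost functions
    T <- p$T
    invA <- invB <- payA <- payB <- numeric(T)
    iA <- a[1]; iB <- b[1]; pA <- 0; pB <- 0
    for (t in seq_len(T)) {
      if (t > 1) {
        iA <- max(0, a[1] + a[2] * pA)
        iB <- max(0, b[1] + b[2] * pB)
      }
      pA <- benefit(iB, p) - cost(iA, p)
      pB <- benefit(iA, p) - cost(iB, p)
      invA[t] <- iA; invB[t] <- iB; payA[t] <- pA; payB[t] <- pB
    }
    res <- list(investments_A = invA, investments_B = invB,
                payoffs_A = payA, payoffs_B = payB,
                total_A = sum(payA), total_B = sum(payB))
  }
  structure(res, class = "interaction")
}

#' @export
print.interaction <- function(x, ...) {
  T <- length(x$investments_A)
  cat(sprintf("iterated interaction over %d rounds\n", T))
  cat(sprintf("  total payoff A: %.4f   total payoff B: %.4f\n",
              x$total_A, x$total_B))
  k <- min(T, 5L)
  cat(sprintf("  first investments A: %s\n",
              paste(signif(x$investments_A[seq_len(k)], 4), collapse = " ")))
  cat(sprintf("  first investments B: %s\n",
              paste(signif(x$investments_B[seq_len(k)], 4), collapse = " ")))
  invisible(x)
}

#' Total payoffs of one pairing
#'
#' Fast path returning only the two round-summed payoffs of
#' [play_interaction()].
#'
#' @inheritParams play_interaction
#' @return Numeric vector `c(A = total_A, B = total_B)`.
#' @export
total_payoffs <- function(sA, sB, p) {
  stopifnot(inherits(p, "model_params"))
  if (has_custom_fns(p)) {
    res <- play_interaction(sA, sB, p)
    return(c(A = res$total_A, B = res$total_B))
  }
  out <- total_payoffs_cpp(as_strategy(sA, "sA"), as_strategy(sB, "sB"),
                           p$B0, p$B1, p$K, p$T)
  c(A = out[1], B = out[2])
}

#' Maximal potential payoff of an interaction
#'
#' The payoff a pair would accrue if both partners played the symmetric
#' investment maximising the per-round net gain:
#' `T * max_x (benefit(x) - cost(x))`, found by bounded scalar maximisation.
#' Used to normalise reported community payoffs onto `[0, 1]`. It is zero
#' exactly when the slope ratio `r0 <= 1` (mutualism never profitable).
#'
#' @param p A [model_params()] object.
#' @return Non-negative payoff in payoff units.
#' @examples
#' max_potential_payoff(model_params(B0 = 5, B1 = 1, K = 1, T = 20))
#' @export
max_potential_payoff <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$K == 0) return(p$T * p$B0)        # costless limit
  if (p$r0 <= 1) return(0)
  upper <- 50 / p$B1
  opt <- optimize(function(x) benefit(x, p) - cost(x, p),
                  interval = c(0, upper), maximum = TRUE)
  p$T * max(0, opt$objective)
}
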