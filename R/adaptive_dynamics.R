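#' Phase angle and quadrant of a selection-gradient vector
#'
#' The phase of the investment cycle is the direction of the selection
#' gradient `(grad_offer, grad_reward)`, measured clockwise from the
#' positive reward-rate axis (offer horizontal, reward vertical). The four
#' quadrants follow the narrated order of the cycle: I both traits increase,
#' II offer up / reward down, III both down, IV offer down / reward up.
#'
#' @param grad_offer,grad_reward Components of the selection gradient.
#' @return List with `phase_angle` (degrees in `[0, 360)`) and `quadrant`
#'   (`"I"`, `"II"`, `"III"` or `"IV"`).
#' @examples
#' phase_of(1, 1)   # 45 degrees, quadrant I
#' phase_of(-1, 1)  # 315 degrees, quadrant IV
#' @export
phase_of <- function(grad_offer, grad_reward) {
  if (grad_offer == 0 && grad_reward == 0) {
    stop("phase undefined for a zero gradient vector")
  }
  ang <- atan2(grad_offer, grad_reward) * 180 / pi   # clockwise from +reward
  if (ang < 0) ang <- ang + 360
  if (ang >= 360) ang <- 0
  quad <- if (ang < 90) "I" else if (ang < 180) "II"
          else if (ang < 270) "III" else "IV"
  list(phase_angle = ang, quadrant = quad)
}

#' Phase asymmetry between two interacting individuals
#'
#' Difference of cycle phases `phi_A - phi_B`, wrapped to `(-180, 180]` so
#' that symmetric interactions sit at 0 and the exploitation poles at +-180.
#'
#' @param phase_A,phase_B Phase angles in degrees.
#' @return Wrapped difference in degrees.
#' @examples
#' phase_asymmetry(10, 350)  # 20
#' @export
phase_asymmetry <- function(phase_A, phase_B) {
  d <- (phase_A - phase_B) %% 360
  ifelse(d > 180, d - 360, d)
}

phase_record <- function(g, h) {
  rec <- list(grad_offer = g[1], grad_reward = g[2],
              phase_angle = NA_real_, quadrant = "undefined", h = h)
  if (!(g[1] == 0 && g[2] == 0)) {
    ph <- phase_of(g[1], g[2])
    rec$phase_angle <- ph$phase_angle
    rec$quadrant <- ph$quadrant
  }
  class(rec) <- "phase_record"
  rec
}

#' @export
print.phase_record <- function(x, ...) {
  cat(sprintf("selection gradient: d offer = %.5g, d reward = %.5g\n",
              x$grad_offer, x$grad_reward))
  if (x$quadrant == "undefined") {
    cat("  phase: undefined (zero gradient)\n")
  } else {
    cat(sprintf("  phase: %.2f deg (quadrant %s)\n",
                x$phase_angle, x$quadrant))
  }
  invisible(x)
}

#' Monomorphic selection gradient
#'
#' Central finite-difference derivative of the focal guild's total payoff
#' with respect to its own two traits, with the partner guild's resident
#' held fixed; one-sided differences are used when a trait lies within `h`
#' of the zero boundary. Positive components mean mutants with a larger
#' trait value outperform the resident.
#'
#' @param resident_focal Resident strategy of the focal guild.
#' @param resident_partner Resident strategy of the partner guild.
#' @param p A [model_params()] object.
#' @param h Finite-difference step (> 0, default `1e-4`).
#' @return Object of class `"phase_record"`: gradient components, phase
#'   angle and quadrant (`"undefined"` if the gradient vanishes).
#' @examples
#' p <- model_params()
#' selection_gradient(strategy(0.01, 0.5), strategy(0.01, 0.5), p)
#' @export
selection_gradient <- function(resident_focal, resident_partner, p,
                               h = 1e-4) {
  stopifnot(inherits(p, "model_params"), h > 0)
  f <- as_strategy(resident_focal, "resident_focal")
  q <- as_strategy(resident_partner, "resident_partner")
  g <- sel_gradient_cpp(f, matrix(q, 1, 2), p$B0, p$B1, p$K, p$T, h)
  phase_record(g, h)
}

#' Polymorphic selection gradient
#'
#' Selection gradient experienced by a focal strategy whose mutants play
#' against every member of a polymorphic partner population (equivalently
#' the summed, or mean, payoff over the collection). Reduces to
#' [selection_gradient()] for a single partner.
#'
#' @param focal_strategy Focal strategy.
#' @param partner_population Matrix (n x 2) or data frame of partner
#'   strategies (columns offer, reward), or a single strategy.
#' @inheritParams selection_gradient
#' @param subsample Optional integer: evaluate against a random subsample of
#'   this many partners (for large populations).
#' @return A `"phase_record"` (gradient of the summed payoff).
#' @examples
#' p <- model_params()
#' pop <- rbind(c(0.5, 1), c(0.2, 2))
#' selection_gradient_polymorphic(strategy(0.3, 1), pop, p)
#' @export
selection_gradient_polymorphic <- function(focal_strategy,
                                           partner_population, p,
                                           h = 1e-4, subsample = NULL) {
  stopifnot(inherits(p, "model_params"), h > 0)
  f <- as_strategy(focal_strategy, "focal_strategy")
  pop <- partner_population
  if (inherits(pop, "strategy") ||
      (is.numeric(pop) && !is.matrix(pop) && length(pop) == 2L)) {
    pop <- matrix(as_strategy(pop, "partner_population"), 1, 2)
  }
  pop <- as.matrix(pop)
  if (nrow(pop) == 0L) stop("partner population is empty")
  if (ncol(pop) != 2L) stop("partner population must have two trait columns")
  if (!is.null(subsample) && subsample < nrow(pop)) {
    pop <- pop[sample.int(nrow(pop), subsample), , drop = FALSE]
  }
  g <- sel_gradient_cpp(f, pop, p$B0, p$B1, p$K, p$T, h)
  phase_record(g, h)
}

#' Gradient-flow trajectory of the coevolving trait pair
#'
#' Co-integrates both guilds' traits along their monomorphic selection
#' gradients by explicit Euler steps, clamping traits at the zero boundary
#' and capping them at `cap`. This deterministic flow reproduces the
#' investment cycle: started just above the reciprocation threshold, both
#' guilds' investments rise, pass a maximum and collapse back to zero.
#'
#' @param start List or pair of two strategies `(A, B)`.
#' @param p A [model_params()] object.
#' @param step_size Euler step (> 0); trait change per step is
#'   `step_size * gradient`.
#' @param n_steps Maximum number of Euler steps.
#' @param h Finite-difference step for the gradients.
#' @param cap Upper trait bound guarding against divergence.
#' @return Object of class `"gradient_flow"`: `trajectory` data frame (step,
#'   traits of both guilds, gradients, phase angle and quadrant per guild)
#'   and `n_steps` actually taken.
#' @examples
#' p <- model_params()
#' fl <- gradient_flow(list(strategy(0.01, 0.4), strategy(0.01, 0.4)), p,
#'                     step_size = 1e-3, n_steps = 500)
#' max(fl$trajectory$offer_A)
#' @export
gradient_flow <- function(start, p, step_size = 5e-4, n_steps = 20000,
                          h = 1e-4, cap = 50) {
  stopifnot(inherits(p, "model_params"), step_size > 0, n_steps >= 1)
  sA <- as_strategy(start[[1]], "start A")
  sB <- as_strategy(start[[2]], "start B")
  res <- gradient_flow_cpp(sA, sB, p$B0, p$B1, p$K, p$T,
                           h, step_size, as.integer(n_steps), cap)
  ns <- res$steps
  tr <- res$traits[seq_len(ns + 1L), , drop = FALSE]
  gr <- res$grads[seq_len(ns + 1L), , drop = FALSE]
  phase <- function(go, gre) {
    mapply(function(a, b) {
      if (a == 0 && b == 0) NA_real_ else phase_of(a, b)$phase_angle
    }, go, gre)
  }
  angA <- phase(gr[, 1], gr[, 2])
  angB <- phase(gr[, 3], gr[, 4])
  quad <- function(ang) {
    ifelse(is.na(ang), "undefined",
           ifelse(ang < 90, "I",
                  ifelse(ang < 180, "II", ifelse(ang < 270, "III", "IV"))))
  }
  traj <- data.frame(
    step = 0:ns,
    offer_A = tr[, 1], reward_A = tr[, 2],
    offer_B = tr[, 3], reward_B = tr[, 4],
    grad_offer_A = gr[, 1], grad_reward_A = gr[, 2],
    grad_offer_B = gr[, 3], grad_reward_B = gr[, 4],
    phase_A = angA, phase_B = angB,
    quadrant_A = quad(angA), quadrant_B = quad(angB)
  )
  structure(list(trajectory = traj, n_steps = ns, step_size = step_size,
                 params = p),
            class = "gradient_flow")
}

#' @export
print.gradient_flow <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("gradient-flow trajectory: %d Euler steps (step size %g)\n",
              x$n_steps, x$step_size))
  cat(sprintf("  peak offer A: %.4g   final traits (A): (%.3g, %.3g)\n",
              max(tr$offer_A), tr$offer_A[nrow(tr)], tr$reward_A[nrow(tr)]))
  qs <- rle(tr$quadrant_A[tr$quadrant_A != "undefined"])$values
  cat(sprintf("  phase sequence (A): %s\n", paste(qs, collapse = " -> ")))
  invisible(x)
}

#' @export
plot.gradient_flow <- function(x, ...) {
  tr <- x$trajectory
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(tr$offer_A, tr$reward_A, type = "l", xlab = "initial offer",
       ylab = "reward rate", main = "trait-space trajectory")
  abline(h = reciprocation_threshold(x$params), lty = 2, col = "grey50")
  plot(tr$step, tr$offer_A, type = "l", xlab = "Euler step",
       ylab = "trait value", main = "traits over time",
       ylim = range(tr[, c("offer_A", "reward_A")]))
  lines(tr$step, tr$reward_A, col = "grey50")
  legend("topright", legend = c("offer", "reward"),
         col = c("black", "grey50"), lty = 1, bty = "n")
  invisible(x)
}
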