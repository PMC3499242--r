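#' Configuration of an individual-based simulation run
#'
#' Collects every parameter of the stochastic two-guild model: game
#' parameters, population structure, competition and mutation settings, and
#' scheduling. All values are plain config keys; nothing is hard-coded in
#' the simulator.
#'
#' @param structure `"lattice"` (paired N x N square lattices, Moore-8
#'   neighbourhoods, toroidal wrap, matched-site partners) or
#'   `"well_mixed"` (random partner per payoff evaluation).
#' @param N Lattice width (lattice structure); each guild then has `N^2`
#'   individuals.
#' @param pop_size Guild size for well-mixed runs (default `N^2`).
#' @param generations Number of generations to run; one generation performs
#'   population-size updates (asynchronous) or one simultaneous sweep
#'   (synchronous).
#' @param B0,B1,K,T Game parameters, see [model_params()].
#' @param mu Per-update, per-trait mutation probability.
#' @param mutation_scheme `"constant_cv"` (mutational sd proportional to the
#'   current trait value, `sd = cv * value`; zero is absorbing) or
#'   `"constant_sigma"` (fixed sd; variation regenerates at zero).
#' @param sigma Mutational standard deviation for `"constant_sigma"`.
#' @param cv Mutational coefficient of variation for `"constant_cv"`.
#' @param update_rule `"best_takes_over"` (deterministic imitation of the
#'   highest-payoff contender, random tie-break) or `"pairwise_comparison"`
#'   (Fermi rule against one random competitor).
#' @param K_sel Selection scale of the Fermi rule.
#' @param n_competitors Number of random competitors drawn per update in
#'   well-mixed best-takes-over competition (lattice updates always use the
#'   Moore-8 neighbours).
#' @param scheduling `"asynchronous"` (random single-site updates, the
#'   model's default) or `"synchronous"` (whole-population sweeps on frozen
#'   payoffs).
#' @param payoff_refresh `"full"` (focal pair and all competitors get fresh
#'   payoffs before competition) or `"focal_only"` (competitors keep cached
#'   payoffs).
#' @param init_trait Initial value `eps0` given to all four traits of every
#'   individual (homogeneous start), unless explicit `init_A`/`init_B`
#'   matrices are supplied.
#' @param init_A,init_B Optional n x 2 matrices (offer, reward) of initial
#'   strategies per guild.
#' @param snapshot_every Save full trait/payoff snapshots every this many
#'   generations (0 = final state only).
#' @param seed Optional integer seed; fixed seeds make runs bit-reproducible.
#'
#' @return Object of class `"sim_config"` (a validated named list).
#' @examples
#' cfg <- sim_config(structure = "well_mixed", N = 10, generations = 50)
#' @export
sim_config <- function(structure = c("lattice", "well_mixed"),
                       N = 100, pop_size = NULL, generations = 10000,
                       B0 = 5, B1 = 1, K = 1, T = 20,
                       mu = 0.01,
                       mutation_scheme = c("constant_cv", "constant_sigma"),
                       sigma = 0.05, cv = 0.1,
                       update_rule = c("best_takes_over",
                                       "pairwise_comparison"),
                       K_sel = 0.1, n_competitors = 8,
                       scheduling = c("asynchronous", "synchronous"),
                       payoff_refresh = c("full", "focal_only"),
                       init_trait = 0.01, init_A = NULL, init_B = NULL,
                       snapshot_every = 0, seed = NULL) {
  structure_ <- match.arg(structure)
  mutation_scheme <- match.arg(mutation_scheme)
  update_rule <- match.arg(update_rule)
  scheduling <- match.arg(scheduling)
  payoff_refresh <- match.arg(payoff_refresh)
  if (structure_ == "lattice") {
    if (N < 2 || N != round(N)) stop("`N` must be an integer >= 2")
    n <- as.integer(N) * as.integer(N)
  } else {
    n <- if (is.null(pop_size)) as.integer(N) * as.integer(N)
         else as.integer(pop_size)
    if (n < 2) stop("population size must be >= 2")
  }
  if (generations < 1) stop("`generations` must be >= 1")
  if (mu < 0 || mu > 1) stop("`mu` must be a probability")
  if (sigma <= 0 || cv <= 0 || K_sel <= 0) {
    stop("`sigma`, `cv` and `K_sel` must be positive")
  }
  if (n_competitors < 1) stop("`n_competitors` must be >= 1")
  if (init_trait < 0) stop("`init_trait` must be >= 0")
  check_init <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 2L) {
      stop(sprintf("`%s` must be a %d x 2 matrix", nm, n))
    }
    if (any(m < 0)) stop(sprintf("`%s` has negative traits", nm))
    unname(m)
  }
  cfg <- list(structure = structure_, N = as.integer(N), pop_size = n,
              generations = as.integer(generations),
              B0 = B0, B1 = B1, K = K, T = as.integer(T),
              mu = mu, mutation_scheme = mutation_scheme,
              sigma = sigma, cv = cv,
              update_rule = update_rule, K_sel = K_sel,
              n_competitors = as.integer(n_competitors),
              scheduling = scheduling, payoff_refresh = payoff_refresh,
              init_trait = init_trait,
              init_A = check_init(init_A, "init_A"),
              init_B = check_init(init_B, "init_B"),
              snapshot_every = as.integer(snapshot_every),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  # validate the game parameters once
  model_params(B0 = B0, B1 = B1, K = K, T = T)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("simulation config: %s, %s individuals per guild, %d generations\n",
              x$structure,
              if (x$structure == "lattice")
                sprintf("%d x %d", x$N, x$N) else format(x$pop_size),
              x$generations))
  cat(sprintf("  game: B0 = %g, B1 = %g, K = %g, T = %d\n",
              x$B0, x$B1, x$K, x$T))
  cat(sprintf("  updating: %s, %s, payoff refresh %s\n",
              x$update_rule, x$scheduling, x$payoff_refresh))
  cat(sprintf("  mutation: mu = %g, %s (sigma = %g, cv = %g)\n",
              x$mu, x$mutation_scheme, x$sigma, x$cv))
  cat(sprintf("  init trait: %g, seed: %s\n", x$init_trait,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' Plain-text round trip of a [sim_config()]. Unknown keys raise an error
#' naming the key; missing keys fall back to the documented defaults.
#'
#' @param path File path of a YAML mapping of config keys.
#' @return `read_sim_config()` returns a `"sim_config"`;
#'   `write_sim_config()` invisibly returns `path`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must be a YAML mapping")
  known <- setdiff(names(formals(sim_config)), "...")
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  for (nm in c("init_A", "init_B")) {
    if (!is.null(vals[[nm]])) vals[[nm]] <- matrix(unlist(vals[[nm]]),
                                                   ncol = 2, byrow = TRUE)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  vals$pop_size <- NULL      # derived for lattice; kept for well-mixed
  if (config$structure == "well_mixed") vals$pop_size <- config$pop_size
  for (nm in c("init_A", "init_B")) {
    if (!is.null(vals[[nm]])) {
      vals[[nm]] <- apply(vals[[nm]], 1, function(r) as.list(r))
    }
  }
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

params_of <- function(config) {
  model_params(B0 = config$B0, B1 = config$B1, K = config$K, T = config$T)
}

init_matrices <- function(config) {
  n <- config$pop_size
  A <- if (is.null(config$init_A)) {
    matrix(config$init_trait, n, 2)
  } else config$init_A
  B <- if (is.null(config$init_B)) {
    matrix(config$init_trait, n, 2)
  } else config$init_B
  list(A = A, B = B)
}

new_community <- function(A, B, payoff_A, payoff_B, structure, N) {
  structure(list(A = A, B = B, payoff_A = payoff_A, payoff_B = payoff_B,
                 structure = structure, N = N),
            class = "community")
}

#' Initialise a two-guild community
#'
#' Builds both populations with the homogeneous initial strategy
#' `(init_trait, init_trait)` — or explicit `init_A`/`init_B` strategy
#' tables — and evaluates every individual's payoff once against its
#' initial partner.
#'
#' @param config A [sim_config()].
#' @return Object of class `"community"`: trait matrices `A`, `B`
#'   (`pop_size` x 2), cached payoff vectors `payoff_A`, `payoff_B`, the
#'   structure, and the lattice width `N` (NA for well-mixed).
#' @examples
#' cm <- init_community(sim_config(structure = "lattice", N = 5,
#'                                 generations = 1, seed = 1))
#' @export
init_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ini <- init_matrices(config)
  p <- params_of(config)
  n <- config$pop_size
  payA <- payB <- numeric(n)
  if (config$structure == "lattice") {
    for (i in seq_len(n)) {
      tot <- total_payoffs_cpp(ini$A[i, ], ini$B[i, ],
                               p$B0, p$B1, p$K, p$T)
      payA[i] <- tot[1]; payB[i] <- tot[2]
    }
  } else {
    for (i in seq_len(n)) {
      j <- sample.int(n, 1)
      payA[i] <- total_payoffs_cpp(ini$A[i, ], ini$B[j, ],
                                   p$B0, p$B1, p$K, p$T)[1]
    }
    for (i in seq_len(n)) {
      j <- sample.int(n, 1)
      payB[i] <- total_payoffs_cpp(ini$B[i, ], ini$A[j, ],
                                   p$B0, p$B1, p$K, p$T)[1]
    }
  }
  new_community(ini$A, ini$B, payA, payB, config$structure,
                if (config$structure == "lattice") config$N else NA_integer_)
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("community: %s, %d individuals per guild\n",
              if (x$structure == "lattice")
                sprintf("%d x %d lattice", x$N, x$N) else "well-mixed",
              nrow(x$A)))
  cat(sprintf("  guild A mean traits: offer %.4g, reward %.4g\n",
              mean(x$A[, 1]), mean(x$A[, 2])))
  cat(sprintf("  guild B mean traits: offer %.4g, reward %.4g\n",
              mean(x$B[, 1]), mean(x$B[, 2])))
  cat(sprintf("  mean payoffs: A %.4g, B %.4g\n",
              mean(x$payoff_A), mean(x$payoff_B)))
  invisible(x)
}

#' Partner of an individual
#'
#' On the lattice, partners occupy the matched site of the other guild's
#' lattice (fixed pairing); in well-mixed pools a uniform random partner is
#' drawn per evaluation.
#'
#' @param i Index of the focal individual (row-major site index on the
#'   lattice).
#' @param community A `"community"`.
#' @return The partner's index in the other guild.
#' @export
pair_of <- function(i, community) {
  stopifnot(inherits(community, "community"))
  n <- nrow(community$A)
  if (i < 1 || i > n) stop("index out of range")
  if (community$structure == "lattice") as.integer(i) else sample.int(n, 1)
}

#' Evaluate and cache the payoff of one interacting pair
#'
#' Plays the iterated game between individual `i` of guild A (or B) and its
#' partner, writing both totals back into the community's payoff cache.
#'
#' @param i Focal index.
#' @param community A `"community"`.
#' @param p A [model_params()] object.
#' @param guild `"A"` or `"B"`.
#' @return The community with refreshed payoffs; the focal individual's new
#'   payoff is attached as attribute `"payoff"`.
#' @export
evaluate_payoff <- function(i, community, p, guild = c("A", "B")) {
  guild <- match.arg(guild)
  j <- pair_of(i, community)
  if (guild == "A") {
    tot <- total_payoffs_cpp(community$A[i, ], community$B[j, ],
                             p$B0, p$B1, p$K, p$T)
    community$payoff_A[i] <- tot[1]
    community$payoff_B[j] <- tot[2]
    attr(community, "payoff") <- tot[1]
  } else {
    tot <- total_payoffs_cpp(community$B[i, ], community$A[j, ],
                             p$B0, p$B1, p$K, p$T)
    community$payoff_B[i] <- tot[1]
    community$payoff_A[j] <- tot[2]
    attr(community, "payoff") <- tot[1]
  }
  community
}

#' Best-takes-over competition
#'
#' The focal individual adopts the strategy of the highest-payoff contender
#' among itself and its competitors; exact payoff ties are resolved by a
#' uniform random choice among the maximisers.
#'
#' @param payoffs Named or plain numeric vector of contender payoffs; the
#'   first element is the focal individual.
#' @return Index (into `payoffs`) of the winning contender.
#' @examples
#' set.seed(1)
#' best_takes_over(c(focal = 1, a = 3, b = 2))  # 2 (the maximum)
#' @export
best_takes_over <- function(payoffs) {
  if (length(payoffs) < 1) stop("no contenders")
  winners <- which(payoffs == max(payoffs))
  if (length(winners) == 1L) winners else sample(winners, 1)
}

#' Fermi replacement probability and pairwise comparison
#'
#' With pairwise-comparison updating, a random competitor replaces the focal
#' individual with probability `1 / (1 + exp(-(P_c - P_f) / K_sel))`.
#'
#' @param p_focal,p_competitor Cached payoffs of the two individuals.
#' @param K_sel Selection scale (> 0).
#' @return `fermi_probability()` returns the replacement probability;
#'   `pairwise_comparison()` samples the outcome and returns `"competitor"`
#'   or `"focal"`.
#' @examples
#' fermi_probability(1, 1, 0.1)        # 0.5 at equal payoffs
#' @export
fermi_probability <- function(p_focal, p_competitor, K_sel = 0.1) {
  stopifnot(K_sel > 0)
  1 / (1 + exp(-(p_competitor - p_focal) / K_sel))
}

#' @rdname fermi_probability
#' @export
pairwise_comparison <- function(p_focal, p_competitor, K_sel = 0.1) {
  if (runif(1) < fermi_probability(p_focal, p_competitor, K_sel)) {
    "competitor"
  } else "focal"
}

#' Mutate a trait value
#'
#' With probability `mu` per trait the value is redrawn from a normal
#' distribution centred on the current value; the standard deviation is
#' `sigma_or_cv` under the constant-sigma scheme and
#' `sigma_or_cv * value` under the constant-CV scheme (so zero is absorbing
#' there). Negative draws are truncated to zero.
#'
#' @param value Current trait value (vectorised).
#' @param scheme `"constant_sigma"` or `"constant_cv"`.
#' @param sigma_or_cv The sd (constant-sigma) or CV (constant-cv).
#' @param mu Per-trait mutation probability.
#' @return Mutated trait value(s), non-negative.
#' @examples
#' set.seed(1)
#' mutate_trait(0.5, "constant_sigma", 0.05, mu = 1)
#' mutate_trait(0, "constant_cv", 0.1, mu = 1)  # stays exactly 0
#' @export
mutate_trait <- function(value, scheme = c("constant_sigma", "constant_cv"),
                         sigma_or_cv, mu) {
  scheme <- match.arg(scheme)
  stopifnot(sigma_or_cv > 0, mu >= 0, mu <= 1)
  out <- value
  hit <- runif(length(value)) < mu
  if (any(hit)) {
    sd <- if (scheme == "constant_sigma") {
      rep_len(sigma_or_cv, length(value))
    } else sigma_or_cv * value
    idx <- which(hit & sd > 0)
    if (length(idx) > 0) {
      out[idx] <- pmax(0, rnorm(length(idx), mean = value[idx],
                                sd = sd[idx]))
    }
  }
  out
}

run_cpp_on <- function(A, B, config, generations, snapshot_every) {
  ibm_run_cpp(A, B,
              structure = if (config$structure == "lattice") 0L else 1L,
              W = if (config$structure == "lattice") config$N else 0L,
              G = as.integer(generations),
              B0 = config$B0, B1 = config$B1, K = config$K, T = config$T,
              mu = config$mu,
              scheme = if (config$mutation_scheme == "constant_sigma")
                0L else 1L,
              sigma = config$sigma, cv = config$cv,
              rule = if (config$update_rule == "best_takes_over") 0L else 1L,
              Ksel = config$K_sel, k = config$n_competitors,
              sched = if (config$scheduling == "asynchronous") 0L else 1L,
              refresh = if (config$payoff_refresh == "full") 1L else 0L,
              snapshot_every = as.integer(snapshot_every))
}

#' Advance a community by whole generations
#'
#' Runs `n_generations` of the configured update process on an existing
#' community state. Asynchronous scheduling performs population-size random
#' single-site updates per generation (payoff refresh, competition on both
#' lattices at the site, mutation of the written strategies); synchronous
#' scheduling evaluates all payoffs on the frozen community and updates
#' every site simultaneously.
#'
#' @param community A `"community"`.
#' @param config The [sim_config()] governing the run.
#' @param n_generations Number of generations to advance (default 1).
#' @return The advanced `"community"`.
#' @export
step_generation <- function(community, config, n_generations = 1) {
  stopifnot(inherits(community, "community"), inherits(config, "sim_config"))
  res <- run_cpp_on(community$A, community$B, config,
                    generations = n_generations, snapshot_every = 0L)
  new_community(res$final_A, res$final_B,
                as.numeric(res$final_payoff_A),
                as.numeric(res$final_payoff_B),
                community$structure, community$N)
}

#' Run the individual-based simulation
#'
#' Full stochastic run: initialises the community, iterates generations,
#' and records per-generation guild means and variances of both traits,
#' mean payoffs, and mean payoffs normalised by the maximal potential
#' payoff of the parameterisation. Runs are bit-reproducible from the seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `"mutualism_sim"`: `summary` data frame (one row
#'   per generation and guild), `snapshots` (list of full trait/payoff
#'   states, see `snapshot_every`), `final` community, the resolved
#'   `config`, and `max_payoff` used for normalisation.
#' @examples
#' sim <- run_simulation(sim_config(structure = "well_mixed", N = 6,
#'                                  generations = 20, seed = 42))
#' head(sim$summary)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  ini <- init_matrices(config)
  res <- run_cpp_on(ini$A, ini$B, config, config$generations,
                    config$snapshot_every)
  p <- params_of(config)
  mp <- max_potential_payoff(p)
  # below the profitability boundary (r0 <= 1) the potential payoff is 0;
  # normalise by the costless upper bound T*B0 there so the column stays
  # defined (payoffs are then <= 0 and the normalised value is ~0)
  norm_base <- if (mp > 0) mp else p$T * p$B0
  sm <- res$summary
  G <- nrow(sm)
  summary_df <- data.frame(
    generation = rep(seq_len(G), 2L),
    guild = rep(c("A", "B"), each = G),
    mean_offer = c(sm[, 1], sm[, 5]),
    var_offer = c(sm[, 2], sm[, 6]),
    mean_reward = c(sm[, 3], sm[, 7]),
    var_reward = c(sm[, 4], sm[, 8]),
    mean_payoff = c(sm[, 9], sm[, 10]),
    norm_payoff = c(sm[, 9], sm[, 10]) / norm_base
  )
  snaps <- lapply(res$snapshots, function(s) {
    new_community(s$A, s$B, as.numeric(s$payoff_A), as.numeric(s$payoff_B),
                  config$structure,
                  if (config$structure == "lattice") config$N
                  else NA_integer_)
  })
  names(snaps) <- vapply(res$snapshots,
                         function(s) as.character(s$generation),
                         character(1))
  final <- new_community(res$final_A, res$final_B,
                         as.numeric(res$final_payoff_A),
                         as.numeric(res$final_payoff_B),
                         config$structure,
                         if (config$structure == "lattice") config$N
                         else NA_integer_)
  structure(list(summary = summary_df, snapshots = snaps, final = final,
                 config = config, max_payoff = mp),
            class = "mutualism_sim")
}

#' Long-run mean of a simulation statistic
#'
#' Mean of a per-generation summary column over the last `last_frac`
#' fraction of generations, averaged over both guilds.
#'
#' @param sim A `"mutualism_sim"`.
#' @param what Summary column (default `"norm_payoff"`).
#' @param last_frac Fraction of final generations to average over.
#' @return A single number.
#' @export
long_run_mean <- function(sim, what = "norm_payoff", last_frac = 0.25) {
  stopifnot(inherits(sim, "mutualism_sim"), last_frac > 0, last_frac <= 1)
  sm <- sim$summary
  G <- max(sm$generation)
  from <- max(1, ceiling((1 - last_frac) * G))
  mean(sm[[what]][sm$generation >= from])
}

#' @export
print.mutualism_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("mutualism IBM run: %s, %d per guild, %d generations\n",
              cfg$structure, cfg$pop_size, cfg$generations))
  cat(sprintf("  %s updating, %s scheduling, %s mutation\n",
              cfg$update_rule, cfg$scheduling, cfg$mutation_scheme))
  lr <- long_run_mean(x)
  cat(sprintf("  long-run normalised payoff (last 25%%): %.4f\n", lr))
  fin <- x$final
  cat(sprintf("  final mean traits A: (%.3g, %.3g)  B: (%.3g, %.3g)\n",
              mean(fin$A[, 1]), mean(fin$A[, 2]),
              mean(fin$B[, 1]), mean(fin$B[, 2])))
  invisible(x)
}

#' @export
summary.mutualism_sim <- function(object, ...) {
  sm <- object$summary
  agg <- aggregate(sm[, c("mean_offer", "mean_reward", "mean_payoff",
                          "norm_payoff")],
                   by = list(guild = sm$guild), FUN = mean)
  cat("per-guild means over the whole run:\n")
  print(agg, row.names = FALSE)
  cat(sprintf("long-run normalised payoff (last 25%%): %.4f\n",
              long_run_mean(object)))
  invisible(agg)
}

#' @export
plot.mutualism_sim <- function(x, ...) {
  sm <- x$summary
  a <- sm[sm$guild == "A", ]
  b <- sm[sm$guild == "B", ]
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(a$generation, a$mean_offer, type = "l", xlab = "generation",
       ylab = "mean trait", main = "trait means",
       ylim = range(sm[, c("mean_offer", "mean_reward")]))
  lines(a$generation, a$mean_reward, lty = 2)
  lines(b$generation, b$mean_offer, col = "grey50")
  lines(b$generation, b$mean_reward, col = "grey50", lty = 2)
  legend("topright", legend = c("A offer", "A reward", "B offer", "B reward"),
         col = c("black", "black", "grey50", "grey50"),
         lty = c(1, 2, 1, 2), bty = "n", cex = 0.8)
  if (all(is.finite(a$norm_payoff))) {
    plot(a$generation, a$norm_payoff, type = "l", xlab = "generation",
         ylab = "normalised mean payoff", main = "community payoff",
         ylim = range(c(0, sm$norm_payoff)))
    lines(b$generation, b$norm_payoff, col = "grey50")
  } else {
    plot(a$generation, a$mean_payoff, type = "l", xlab = "generation",
         ylab = "mean payoff", main = "community payoff")
    lines(b$generation, b$mean_payoff, col = "grey50")
  }
  invisible(x)
}
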