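#' Run a parameter sweep of the individual-based model
#'
#' Runs every combination of the supplied parameter values, `replicates`
#' times each, and reports the long-run community payoff (mean over the
#' last `last_frac` of generations, both guilds) normalised by the maximal
#' potential payoff of each cell's parameterisation. Per-run seeds are
#' drawn deterministically from `base_seed`, so the whole sweep is
#' reproducible.
#'
#' @param cells A data frame whose columns are [sim_config()] keys (e.g.
#'   `B0`, `K`, `structure`, `mutation_scheme`, `sigma`) and whose rows are
#'   the sweep cells, or a named list of value vectors to be crossed with
#'   `expand.grid()`.
#' @param base_config A [sim_config()] providing every key the cells do not
#'   override.
#' @param replicates Replicate runs per cell.
#' @param base_seed Integer seed from which all per-run seeds derive.
#' @param last_frac Fraction of final generations averaged into the
#'   long-run payoff.
#' @return Data frame in long format: one row per cell with the cell's
#'   parameter values, `norm_payoff` (replicate mean), `sd_payoff`
#'   (replicate sd) and `replicates`.
#' @examples
#' cfg <- sim_config(structure = "well_mixed", N = 5, generations = 20)
#' run_sweep(list(K = c(1, 6)), cfg, replicates = 2, base_seed = 1)
#' @export
run_sweep <- function(cells, base_config, replicates = 5, base_seed = 1,
                      last_frac = 0.25) {
  stopifnot(inherits(base_config, "sim_config"), replicates >= 1)
  if (!is.data.frame(cells)) {
    cells <- expand.grid(cells, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  }
  if (nrow(cells) < 1) stop("no sweep cells")
  known <- names(formals(sim_config))
  bad <- setdiff(names(cells), known)
  if (length(bad) > 0) {
    stop(sprintf("unknown config key(s) in sweep: %s",
                 paste(bad, collapse = ", ")))
  }
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      nrow(cells) * replicates)
  base_vals <- unclass(base_config)
  base_vals <- base_vals[setdiff(names(base_vals), "pop_size")]
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    vals <- base_vals
    for (nm in names(cells)) vals[[nm]] <- cells[[nm]][ci]
    lr <- numeric(replicates)
    for (r in seq_len(replicates)) {
      vals$seed <- seeds[(ci - 1) * replicates + r]
      cfg <- do.call(sim_config, vals[!vapply(vals, is.null, logical(1))])
      sim <- run_simulation(cfg)
      lr[r] <- long_run_mean(sim, "norm_payoff", last_frac)
    }
    row <- cells[ci, , drop = FALSE]
    row$norm_payoff <- mean(lr)
    row$sd_payoff <- if (replicates > 1) sd(lr) else NA_real_
    row$replicates <- replicates
    out[[ci]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @importFrom stats sd
NULL
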