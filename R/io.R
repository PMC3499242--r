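#' Export results as CSV
#'
#' Plain-text exports of the main result objects: per-generation run
#' summaries, full lattice snapshots (long format: site, row, column,
#' traits and payoff per guild), best-response trajectories and
#' gradient-flow trajectories.
#'
#' @param x Object to export (a `"mutualism_sim"`, `"community"`,
#'   `"br_dynamics"` or `"gradient_flow"`).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
export_csv <- function(x, path) {
  df <- if (inherits(x, "mutualism_sim")) {
    x$summary
  } else if (inherits(x, "community")) {
    n <- nrow(x$A)
    W <- if (!is.na(x$N)) x$N else NA_integer_
    data.frame(site = seq_len(n),
               row = if (!is.na(W)) (seq_len(n) - 1L) %/% W + 1L else NA,
               col = if (!is.na(W)) (seq_len(n) - 1L) %% W + 1L else NA,
               offer_A = x$A[, 1], reward_A = x$A[, 2],
               offer_B = x$B[, 1], reward_B = x$B[, 2],
               payoff_A = x$payoff_A, payoff_B = x$payoff_B)
  } else if (inherits(x, "br_dynamics") || inherits(x, "gradient_flow")) {
    x$trajectory
  } else {
    stop("no CSV export defined for this object")
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
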