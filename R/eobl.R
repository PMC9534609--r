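#' Elite opposition-based learning configuration
#'
#' @param enabled apply the opposition step each iteration (TRUE gives the
#'   EO-SSA, FALSE the plain SSA; useful for ablation).
#' @param eta_mode `"uniform01"` (default): the generalized coefficient
#'   eta is drawn uniformly in \[0, 1\] per individual per dimension;
#'   `"fixed1"`: eta = 1, the pure reflection through the dynamic bounds.
#' @return an `eobl_config` list.
#' @export
eobl_config <- function(enabled = TRUE,
                        eta_mode = c("uniform01", "fixed1")) {
  structure(list(enabled = enabled, eta_mode = match.arg(eta_mode)),
            class = "eobl_config")
}

#' Dynamic per-dimension bounds of a population
#'
#' @param positions n x d matrix of current positions.
#' @return list with vectors `da` (per-dimension minima) and `db`
#'   (per-dimension maxima).
#' @export
dynamic_bounds <- function(positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) == 0L) stop("empty population has no dynamic bounds")
  list(da = apply(positions, 2L, min), db = apply(positions, 2L, max))
}

#' Elite opposition solutions
#'
#' Reflects the elite (current best) individual through the dynamic
#' bounds: `x~_{i,j} = eta * (da_j + db_j) - x_e[j]`, one eta per
#' individual per dimension so the opposition individuals differ.
#' Coordinates falling outside `[da_j, db_j]` are reset to a uniform draw
#' inside that interval.
#'
#' @param x_e position vector of the elite individual.
#' @param positions current population positions (defines the bounds and
#'   the number of opposition individuals).
#' @param cfg an [eobl_config()].
#' @return a matrix of opposition positions, same shape as `positions`.
#' @export
elite_opposition <- function(x_e, positions, cfg = eobl_config()) {
  positions <- as.matrix(positions)
  n <- nrow(positions); d <- ncol(positions)
  b <- dynamic_bounds(positions)
  eta <- if (cfg$eta_mode == "fixed1") matrix(1, n, d) else
    matrix(stats::runif(n * d), n, d)
  opp <- sweep(sweep(eta, 2L, b$da + b$db, "*"), 2L, x_e, "-")
  out <- opp < matrix(b$da, n, d, byrow = TRUE) |
    opp > matrix(b$db, n, d, byrow = TRUE)
  if (any(out)) {
    ju <- col(opp)[out]
    opp[out] <- b$da[ju] + stats::runif(sum(out)) * (b$db[ju] - b$da[ju])
  }
  opp
}

#' Apply the elite opposition step
#'
#' Generates the opposition population from the current elite, evaluates
#' it, and keeps the best `n` individuals of the union of the current and
#' opposition populations (greedy selection), so the population size is
#' conserved and the best fitness can never worsen.
#'
#' @param state list with `positions` (n x d) and `fitness` (length n).
#' @param objective the cost function.
#' @param cfg an [eobl_config()].
#' @return the merged `state` (positions + fitness), same population size.
#' @export
apply_eobl <- function(state, objective, cfg = eobl_config()) {
  pos <- as.matrix(state$positions)
  fit <- state$fitness
  n <- nrow(pos)
  elite <- pos[which.min(fit), ]
  opp <- elite_opposition(elite, pos, cfg)
  opp_fit <- apply(opp, 1L, objective)
  all_pos <- rbind(pos, opp)
  all_fit <- c(fit, opp_fit)
  keep <- order(all_fit)[seq_len(n)]
  list(positions = all_pos[keep, , drop = FALSE], fitness = all_fit[keep])
}
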