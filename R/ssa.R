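#' Squirrel search algorithm configuration
#'
#' The squirrel search algorithm (SSA) is a population metaheuristic that
#' models flying squirrels gliding between food trees: the best individual
#' sits on the hickory tree, the next-best group on acorn trees, and the
#' rest on normal trees. Acorn squirrels glide toward the hickory squirrel
#' and normal squirrels toward a random acorn squirrel; a seasonal check
#' triggers Levy-flight relocation of normal squirrels when winter ends.
#'
#' The aerodynamic constants enter only through the gliding distance
#' `dg = hg / (tan(phi) * sf)` with `tan(phi) = C_D / C_L`, `C_L` drawn
#' uniformly from `c_l_range`, so `dg` always lies in
#' `[hg/((c_d/max CL)*sf), hg/((c_d/min CL)*sf)]` = \[0.5, 1.1111\] at the
#' defaults.
#'
#' @param n_pop population size (N).
#' @param dim search-space dimensionality (D).
#' @param lower,upper per-dimension bounds (scalars are recycled).
#' @param n_iter maximum number of iterations (T).
#' @param g_c gliding constant (1.9).
#' @param p_dp predator-appearance probability (0.1).
#' @param hg,sf gliding-distance constants (8 and 18).
#' @param rho air density, kg m^-3 (1.204).
#' @param v glide speed, m s^-1 (5.25).
#' @param s body surface, cm^2 (154).
#' @param c_d drag coefficient (0.6).
#' @param c_l_range lift-coefficient range (0.675 to 1.5).
#' @param levy_beta Levy-flight stability exponent (1.5).
#' @param n_hickory,n_acorn number of hickory-tree (best) and acorn-tree
#'   (next-best) squirrels; all others are normal.
#' @param sc_sqrt if TRUE use the Euclidean distance for the seasonal
#'   constant instead of the squared distance (default FALSE: the squared
#'   form, i.e. sum of squared coordinate differences).
#' @param include_normal_to_hickory if TRUE, a random half of the normal
#'   squirrels glide toward the hickory tree instead of an acorn tree
#'   (the original SSA's third update rule; off by default).
#' @param seed optional integer seed used by [ssa_optimize()].
#' @return an `ssa_config` list.
#' @export
ssa_config <- function(n_pop = 20, dim, lower = 0, upper = 1, n_iter = 100,
                       g_c = 1.9, p_dp = 0.1, hg = 8, sf = 18,
                       rho = 1.204, v = 5.25, s = 154, c_d = 0.6,
                       c_l_range = c(0.675, 1.5), levy_beta = 1.5,
                       n_hickory = 1, n_acorn = 3,
                       sc_sqrt = FALSE, include_normal_to_hickory = FALSE,
                       seed = NULL) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  if (any(lower >= upper)) stop("`lower` must be < `upper` elementwise")
  if (n_pop < n_hickory + n_acorn)
    stop("population must hold at least n_hickory + n_acorn squirrels")
  if (p_dp < 0 || p_dp > 1) stop("`p_dp` must lie in [0, 1]")
  stopifnot(g_c > 0, hg > 0, sf > 0, c_d > 0, levy_beta > 0,
            length(c_l_range) == 2, c_l_range[1] > 0,
            c_l_range[1] < c_l_range[2])
  structure(list(n_pop = n_pop, dim = dim, lower = lower, upper = upper,
                 n_iter = n_iter, g_c = g_c, p_dp = p_dp, hg = hg, sf = sf,
                 rho = rho, v = v, s = s, c_d = c_d, c_l_range = c_l_range,
                 levy_beta = levy_beta, n_hickory = n_hickory,
                 n_acorn = n_acorn, sc_sqrt = sc_sqrt,
                 include_normal_to_hickory = include_normal_to_hickory,
                 seed = seed),
            class = "ssa_config")
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# roles by fitness rank: best n_hickory -> "hickory", next n_acorn ->
# "acorn", remainder "normal"
assign_roles <- function(fitness, cfg) {
  roles <- rep("normal", length(fitness))
  ord <- order(fitness)
  roles[ord[seq_len(cfg$n_hickory)]] <- "hickory"
  roles[ord[cfg$n_hickory + seq_len(cfg$n_acorn)]] <- "acorn"
  roles
}

#' Initialize an SSA population
#'
#' Positions are drawn uniformly inside the bounds, fitnesses evaluated,
#' and tree roles assigned by fitness rank (lower fitness = better).
#'
#' @param cfg an [ssa_config()].
#' @param objective function mapping a position vector to a finite scalar
#'   cost (minimized).
#' @return a list with `positions` (n_pop x dim matrix), `fitness`, `roles`.
#' @export
ssa_init_population <- function(cfg, objective) {
  pos <- matrix(stats::runif(cfg$n_pop * cfg$dim), cfg$n_pop, cfg$dim)
  pos <- sweep(sweep(pos, 2L, cfg$upper - cfg$lower, "*"), 2L, cfg$lower, "+")
  fit <- apply(pos, 1L, objective)
  bad <- which(!is.finite(fit))
  if (length(bad))
    stop("objective returned a non-finite value at position (",
         paste(signif(pos[bad[1], ], 4), collapse = ", "), ")")
  list(positions = pos, fitness = fit, roles = assign_roles(fit, cfg))
}

#' Gliding distance
#'
#' Draws the lift coefficient `C_L` uniformly from its range and returns
#' `dg = hg / (tan(phi) * sf)` with `tan(phi) = C_D / C_L` (the drag and
#' lift forces share the factor `rho V^2 S / 2`, which cancels).
#'
#' @param cfg an [ssa_config()].
#' @param c_l optionally force the lift coefficient (used by tests).
#' @return the scalar gliding distance.
#' @export
gliding_distance <- function(cfg, c_l = NULL) {
  if (is.null(c_l))
    c_l <- stats::runif(1, cfg$c_l_range[1], cfg$c_l_range[2])
  tan_phi <- cfg$c_d / c_l
  cfg$hg / (tan_phi * cfg$sf)
}

# shared gliding update: glide toward `target` when no predator appears
# (r > p_dp), otherwise relocate uniformly at random. Returns the new
# position and whether a predator was met.
glide_update <- function(position, target, cfg) {
  r <- stats::runif(1)
  if (r > cfg$p_dp) {
    dg <- gliding_distance(cfg)
    newpos <- position + dg * cfg$g_c * (target - position)
    predator <- FALSE
  } else {
    newpos <- cfg$lower + stats::runif(cfg$dim) * (cfg$upper - cfg$lower)
    predator <- TRUE
  }
  list(position = clamp(newpos, cfg$lower, cfg$upper), predator = predator)
}

#' Acorn-squirrel update toward the hickory tree
#' @param position current position of an acorn squirrel.
#' @param hickory position of the hickory squirrel.
#' @param cfg an [ssa_config()].
#' @return list with the clamped new `position` and logical `predator`.
#' @export
update_toward_hickory <- function(position, hickory, cfg) {
  glide_update(position, hickory, cfg)
}

#' Normal-squirrel update toward an acorn tree
#' @param position current position of a normal squirrel.
#' @param acorn position of the (randomly chosen) acorn squirrel target.
#' @inheritParams update_toward_hickory
#' @export
update_toward_acorn <- function(position, acorn, cfg) {
  glide_update(position, acorn, cfg)
}

#' Seasonal constant
#'
#' Sum over dimensions of squared coordinate differences between an acorn
#' squirrel and the hickory squirrel (the squared Euclidean distance as
#' printed; set `sc_sqrt = TRUE` in the config for the square-root form).
#'
#' @param acorn,hickory position vectors.
#' @param sc_sqrt take the square root (Euclidean distance) if TRUE.
#' @return a non-negative scalar.
#' @export
seasonal_constant <- function(acorn, hickory, sc_sqrt = FALSE) {
  s <- sum((acorn - hickory)^2)
  if (sc_sqrt) sqrt(s) else s
}

#' Seasonal threshold
#'
#' `S_min(t) = 1e-5 / 365^(t / (T/2.5))`, strictly decreasing in the
#' iteration index so relocation becomes easier to trigger early and the
#' search settles later.
#'
#' @param t iteration index (0-based).
#' @param n_iter maximum number of iterations T.
#' @return the threshold value.
#' @export
seasonal_threshold <- function(t, n_iter) {
  if (n_iter <= 0) stop("`n_iter` must be positive")
  1e-5 / 365^(t / (n_iter / 2.5))
}

#' Levy-flight step vector
#'
#' Mantegna's algorithm: per coordinate, `0.01 * ra * sigma / |rb|^(1/beta)`
#' with `ra`, `rb` standard normal and
#' `sigma = (Gamma(1+b) sin(pi b/2) / (Gamma((1+b)/2) b 2^((b-1)/2)))^(1/b)`.
#' The resulting steps are heavy-tailed.
#'
#' @param dim number of coordinates.
#' @param beta stability exponent (1.5 by default).
#' @return a numeric vector of length `dim`.
#' @export
levy_step <- function(dim, beta = 1.5) {
  sigma <- levy_sigma(beta)
  ra <- stats::rnorm(dim)
  rb <- stats::rnorm(dim)
  0.01 * ra * sigma / abs(rb)^(1 / beta)
}

#' @rdname levy_step
#' @export
levy_sigma <- function(beta = 1.5) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Random Levy relocation
#'
#' Winter-to-summer relocation: `lower + levy * (upper - lower)`, clamped
#' to the bounds.
#'
#' @param cfg an [ssa_config()].
#' @return a position vector.
#' @export
relocate_random <- function(cfg) {
  pos <- cfg$lower + levy_step(cfg$dim, cfg$levy_beta) * (cfg$upper - cfg$lower)
  clamp(pos, cfg$lower, cfg$upper)
}

#' One SSA iteration
#'
#' Performs the gliding updates (acorn squirrels toward the hickory
#' squirrel, normal squirrels toward a random acorn squirrel),
#' re-evaluates fitness, optionally applies the elite opposition step,
#' re-ranks roles, and runs the seasonal check: if every acorn squirrel's
#' seasonal constant falls below the threshold, winter ends and each
#' normal squirrel that did not meet a predator this iteration is
#' relocated by a Levy flight.
#'
#' @param state population list from [ssa_init_population()] or a previous
#'   step.
#' @param t 0-based iteration index (drives the seasonal threshold).
#' @param cfg an [ssa_config()].
#' @param objective the cost function.
#' @param eobl_cfg an [eobl_config()] or NULL to disable opposition.
#' @return the updated population list.
#' @export
ssa_step <- function(state, t, cfg, objective, eobl_cfg = NULL) {
  pos <- state$positions
  fit <- state$fitness
  roles <- state$roles
  hickory_idx <- which(roles == "hickory")[1]
  acorn_idx <- which(roles == "acorn")
  normal_idx <- which(roles == "normal")
  predator_met <- logical(cfg$n_pop)

  for (i in acorn_idx) {
    upd <- update_toward_hickory(pos[i, ], pos[hickory_idx, ], cfg)
    pos[i, ] <- upd$position
    predator_met[i] <- upd$predator
  }
  to_hickory <- logical(length(normal_idx))
  if (cfg$include_normal_to_hickory && length(normal_idx))
    to_hickory <- stats::runif(length(normal_idx)) < 0.5
  for (k in seq_along(normal_idx)) {
    i <- normal_idx[k]
    target <- if (to_hickory[k]) pos[hickory_idx, ] else
      pos[sample_one(acorn_idx), ]
    upd <- update_toward_acorn(pos[i, ], target, cfg)
    pos[i, ] <- upd$position
    predator_met[i] <- upd$predator
  }
  moved <- c(acorn_idx, normal_idx)
  fit[moved] <- apply(pos[moved, , drop = FALSE], 1L, objective)

  if (!is.null(eobl_cfg) && isTRUE(eobl_cfg$enabled)) {
    merged <- apply_eobl(list(positions = pos, fitness = fit), objective,
                         eobl_cfg)
    pos <- merged$positions
    fit <- merged$fitness
  }
  roles <- assign_roles(fit, cfg)

  # seasonal monitoring (population starts each iteration in winter)
  hickory_idx <- which(roles == "hickory")[1]
  acorn_idx <- which(roles == "acorn")
  s_c <- vapply(acorn_idx, function(i)
    seasonal_constant(pos[i, ], pos[hickory_idx, ], cfg$sc_sqrt), numeric(1))
  if (all(s_c < seasonal_threshold(t, cfg$n_iter))) {
    for (i in which(roles == "normal"))
      if (!predator_met[i]) {
        pos[i, ] <- relocate_random(cfg)
        fit[i] <- objective(pos[i, ])
      }
    roles <- assign_roles(fit, cfg)
  }
  list(positions = pos, fitness = fit, roles = roles)
}

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Run the (EO-)SSA optimizer
#'
#' Initializes the population, runs `n_iter` iterations of [ssa_step()]
#' (with the elite opposition-based learning hook when `eobl_cfg` enables
#' it), and returns the elitist best-so-far solution together with the
#' per-iteration best-so-far trace.
#'
#' @param objective cost function over position vectors (minimized).
#' @param cfg an [ssa_config()].
#' @param eobl_cfg an [eobl_config()]; pass `eobl_config(enabled = FALSE)`
#'   for the plain SSA.
#' @return list with `par` (best position), `value` (best cost), and
#'   `trace` (length `n_iter + 1` non-increasing best-so-far costs).
#' @export
ssa_optimize <- function(objective, cfg, eobl_cfg = eobl_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  state <- ssa_init_population(cfg, objective)
  best_i <- which.min(state$fitness)
  best_par <- state$positions[best_i, ]
  best_val <- state$fitness[best_i]
  trace <- numeric(cfg$n_iter + 1L)
  trace[1L] <- best_val
  for (t in seq_len(cfg$n_iter)) {
    state <- ssa_step(state, t - 1L, cfg, objective, eobl_cfg)
    it_best <- which.min(state$fitness)
    if (state$fitness[it_best] < best_val) {
      best_val <- state$fitness[it_best]
      best_par <- state$positions[it_best, ]
    }
    trace[t + 1L] <- best_val
  }
  list(par = best_par, value = best_val, trace = trace)
}
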