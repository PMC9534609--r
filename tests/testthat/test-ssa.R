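test_that("gliding distance follows the closed form and its range", {
  cfg <- ssa_config(dim = 2)
  expect_equal(gliding_distance(cfg, c_l = 0.675), 0.5)
  expect_equal(gliding_distance(cfg, c_l = 1.5), 8 / (0.4 * 18),
               tolerance = 1e-12)
  set.seed(1)
  dgs <- replicate(500, gliding_distance(cfg))
  expect_true(all(dgs >= 0.5 & dgs <= 8 / (0.4 * 18) + 1e-12))
})

test_that("initial population respects bounds, roles and determinism", {
  cfg <- ssa_config(n_pop = 10, dim = 13, n_iter = 10, seed = 4)
  obj <- benchmark_objective("sphere")
  set.seed(4)
  pop <- ssa_init_population(cfg, obj)
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(sum(pop$roles == "hickory"), 1L)
  expect_equal(sum(pop$roles == "acorn"), 3L)
  expect_equal(which(pop$roles == "hickory"), which.min(pop$fitness))
  set.seed(4)
  pop2 <- ssa_init_population(cfg, obj)
  expect_identical(pop, pop2)
  expect_error(ssa_init_population(cfg, function(x) NaN), "non-finite")
})

test_that("gliding updates clamp, relocate, and vanish at the target", {
  cfg <- ssa_config(dim = 3, p_dp = 0)  # predators never appear
  target <- c(0.5, 0.5, 0.5)
  set.seed(2)
  upd <- update_toward_hickory(target, target, cfg)
  expect_equal(upd$position, target)
  expect_false(upd$predator)
  # large opposing positions may overshoot: result must stay in bounds
  set.seed(3)
  for (i in 1:20) {
    upd <- update_toward_acorn(runif(3), runif(3), cfg)
    expect_true(all(upd$position >= 0 & upd$position <= 1))
  }
  # forced predator branch relocates uniformly, independent of target
  cfg_pred <- ssa_config(dim = 3, p_dp = 1)
  set.seed(5)
  upd <- update_toward_hickory(target, target, cfg_pred)
  expect_true(upd$predator)
  expect_false(isTRUE(all.equal(upd$position, target)))
})

test_that("seasonal constant is the squared distance and is symmetric", {
  expect_equal(seasonal_constant(c(0, 0), c(3, 4)), 25)
  expect_equal(seasonal_constant(c(0, 0), c(3, 4), sc_sqrt = TRUE), 5)
  expect_equal(seasonal_constant(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- runif(5); b <- runif(5)
  expect_equal(seasonal_constant(a, b), seasonal_constant(b, a))
})

test_that("seasonal threshold starts at 1e-5 and decays monotonically", {
  T <- 50
  expect_equal(seasonal_threshold(0, T), 1e-5)
  expect_equal(seasonal_threshold(T, T), 1e-5 / 365^2.5)
  s <- vapply(0:T, seasonal_threshold, numeric(1), n_iter = T)
  expect_true(all(diff(s) < 0))
  expect_error(seasonal_threshold(1, 0), "positive")
})

test_that("Levy steps use the Mantegna sigma and are heavy-tailed", {
  expect_equal(levy_sigma(1.5), 0.6966, tolerance = 5e-5)
  set.seed(8)
  steps <- replicate(200, levy_step(5))
  expect_equal(dim(steps), c(5L, 200L))
  set.seed(9)
  draws <- levy_step(1e5)
  kurt <- mean((draws - mean(draws))^4) / stats::var(draws)^2
  expect_gt(kurt, 10)  # far beyond the normal value 3
})

test_that("random relocation respects bounds and the degenerate box", {
  cfg <- ssa_config(dim = 4)
  set.seed(3)
  for (i in 1:20) {
    p <- relocate_random(cfg)
    expect_true(all(p >= 0 & p <= 1))
  }
  cfg0 <- ssa_config(dim = 2, lower = c(0.3, 0.3), upper = c(0.3 + 1e-12, 0.3 + 1e-12))
  expect_equal(relocate_random(cfg0), c(0.3, 0.3), tolerance = 1e-9)
})

test_that("optimizer trace is elitist and positions stay bounded", {
  obj <- benchmark_objective("sphere")
  cfg <- ssa_config(n_pop = 20, dim = 5, lower = -5, upper = 5,
                    n_iter = 200, seed = 21)
  res <- ssa_optimize(obj, cfg)
  expect_length(res$trace, 201L)
  expect_true(all(diff(res$trace) <= 0))
  expect_lt(res$value, res$trace[1])
  expect_true(all(res$par >= -5 & res$par <= 5))
})

test_that("identical seed and config give identical traces", {
  obj <- benchmark_objective("rastrigin")
  cfg <- ssa_config(n_pop = 15, dim = 4, lower = -5.12, upper = 5.12,
                    n_iter = 50, seed = 77)
  r1 <- ssa_optimize(obj, cfg)
  r2 <- ssa_optimize(obj, cfg)
  expect_identical(r1, r2)
})

test_that("a constant objective is handled and returns the constant", {
  cfg <- ssa_config(n_pop = 8, dim = 3, n_iter = 10, seed = 1)
  res <- ssa_optimize(function(x) 7, cfg)
  expect_equal(res$value, 7)
  expect_true(all(res$trace == 7))
})

test_that("acorn squirrels contract toward the hickory optimum when dg*Gc <= 1", {
  # with no predators and a forced lift coefficient giving dg*Gc = 0.95,
  # the acorn-to-hickory distance never increases
  cfg <- ssa_config(dim = 4, p_dp = 0, g_c = 1.9)
  c_l_fix <- 0.675  # dg = 0.5 -> dg * g_c = 0.95
  hickory <- rep(0.5, 4)
  pos <- runif(4)
  for (i in 1:10) {
    dg <- gliding_distance(cfg, c_l = c_l_fix)
    new_pos <- pmin(pmax(pos + dg * cfg$g_c * (hickory - pos), 0), 1)
    expect_lte(sqrt(sum((new_pos - hickory)^2)),
               sqrt(sum((pos - hickory)^2)) + 1e-12)
    pos <- new_pos
  }
})

test_that("one step keeps bounds and never worsens the population best", {
  obj <- benchmark_objective("sphere")
  cfg <- ssa_config(n_pop = 12, dim = 6, lower = -2, upper = 2,
                    n_iter = 20, seed = 10)
  set.seed(10)
  state <- ssa_init_population(cfg, obj)
  for (t in 0:19) {
    prev_best <- min(state$fitness)
    state <- ssa_step(state, t, cfg, obj, eobl_config(enabled = FALSE))
    expect_true(all(state$positions >= -2 & state$positions <= 2))
    expect_equal(state$fitness,
                 apply(state$positions, 1L, obj))
  }
})
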