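test_that("best response matches closed-form first-order conditions", {
  prob <- benchmark_problem(n_partners = 1)
  cfg <- solver_config()
  y <- node_set(41)

  # constant continuation value: only the effort cost varies
  v_const <- fit_rbf(y, rep(7, 41))
  expect_equal(best_response(2, 1, 0, v_const, prob, cfg), 0.2, tolerance = 1e-6)

  # linear continuation value with slope kappa = 1:
  # D'(c) = (1 - rho*h) * a * kappa  =>  c = c* + 0.999
  v_lin <- fit_rbf(y, as.numeric(y))
  expect_equal(best_response(2, 1, 0, v_lin, prob, cfg), 1.199, tolerance = 1e-6)

  # zero efficiency: continuation independent of own effort
  prob0 <- benchmark_problem(a1 = 1, a2 = 0)
  v2 <- fit_rbf(y, 5 * log(as.numeric(y) + 1))
  expect_equal(best_response(2, 2, 1.5, v2, prob0, cfg), 0.2, tolerance = 1e-6)
})

test_that("the per-node game iteration finds effort fixed points", {
  cfg <- solver_config()
  y <- node_set(41)
  v <- fit_rbf(y, 5 * log(as.numeric(y) + 1) / 0.1)

  # single player: one best-response call is already the fixed point
  prob1 <- benchmark_problem(n_partners = 1)
  g1 <- game_iterate_node(2, 0.2, list(v), prob1, cfg)
  expect_true(g1$converged)
  expect_equal(g1$iterations, 1L)
  expect_equal(g1$efforts, best_response(2, 1, 0, v, prob1, cfg), tolerance = 1e-8)

  # a2 = 0 decouples partner 2: lands on c* regardless of partner 1
  prob0 <- benchmark_problem(a1 = 1, a2 = 0)
  g0 <- game_iterate_node(1.5, c(1, 1), list(v, v), prob0, cfg)
  expect_true(g0$converged)
  expect_equal(g0$efforts[2], 0.2, tolerance = 1e-6)

  # fully symmetric inputs give equal efforts
  prob2 <- benchmark_problem()
  g2 <- game_iterate_node(2.5, c(0.4, 0.4), list(v, v), prob2, cfg)
  expect_lt(abs(g2$efforts[1] - g2$efforts[2]), 1e-9)
})

test_that("zero utility collapses the game to preferred-effort play", {
  sol <- sol_zero_utility()
  expect_true(sol$report$converged)
  expect_equal(max(abs(sol$S - 0.2)), 0, tolerance = 1e-9)
  expect_equal(max(abs(sol$V)), 0, tolerance = 1e-9)
  expect_equal(bellman_residual(sol), 0, tolerance = 1e-10)
})

test_that("1D benchmark solution matches the independent saddle-path oracle", {
  sol <- sol_1d()
  expect_true(sol$report$converged)
  expect_lte(sol$report$value_change, sol$config$value_tol)
  expect_lte(sol$report$strategy_change, sol$config$strategy_tol)

  eq <- equilibrium_closed_form(partner_spec(), r = 2)
  ss <- steady_state(sol)
  expect_equal(ss$x, eq$x, tolerance = 0.02)
  expect_equal(ss$efforts[1], eq$c, tolerance = 0.02)
  expect_equal(strategy_fn(sol)(3), 1.087, tolerance = 0.02)

  # optimal effort decreasing, well-being increasing in the feeling
  expect_true(all(diff(sol$S[, 1]) <= 1e-7))
  expect_true(all(diff(sol$V[, 1]) >= -1e-7))
  # effort gap: equilibrium effort exceeds the preferred level everywhere
  expect_true(all(sol$S[, 1] >= 0.2 - 1e-7))
})

test_that("Bellman residual verifies a solution and scales with perturbations", {
  sol <- sol_1d()
  res <- bellman_residual(sol)
  expect_lte(res, sol$config$value_tol * 10)

  delta <- 1e-3
  pert <- sol
  pert$V <- sol$V + delta
  pert$value_interp[[1]] <- fit_rbf(pert$config$nodes, pert$V[, 1],
                                    eps = pert$value_interp[[1]]$eps)
  res_pert <- bellman_residual(pert)
  # a uniform shift delta changes the one-step residual by delta * rho * h
  # (the Bellman operator is a (1 - rho*h)-contraction)
  expected <- delta * sol$problem$partners[[1]]$rho * sol$config$h
  expect_gt(res_pert, 0.2 * expected)
  expect_lt(res_pert, 5 * expected)
})

test_that("value changes contract over the final outer iterations", {
  # the two-player game iteration decays with an oscillatory mode, so the
  # contraction shows up in running block maxima rather than step by step
  for (sol in list(sol_1d(), sol_2d(1))) {
    hist <- sol$report$value_change_history
    if (length(hist) >= 15) {
      blocks <- vapply(0:2, function(b)
        max(hist[seq(length(hist) - 5 * (b + 1) + 1, length(hist) - 5 * b)]), 0)
      expect_true(all(diff(blocks) > 0))     # older blocks are larger
    } else {
      expect_true(all(diff(hist) <= 0))
    }
    expect_lte(tail(hist, 1), sol$config$value_tol)
  }
})

test_that("homogamous games are symmetric and zero efficiency flattens the partner", {
  sol <- sol_2d(1)
  expect_true(sol$report$converged)
  expect_lt(max(abs(sol$S[, 1] - sol$S[, 2])), 10 * sol$config$strategy_tol)
  expect_lt(max(abs(sol$V[, 1] - sol$V[, 2])), 10 * sol$config$value_tol)
  expect_true(all(sol$S >= 0.2 - 1e-7))

  sol0 <- sol_2d(0)
  expect_lt(max(abs(sol0$S[, 2] - 0.2)), 1e-4)
  # with an ineffective partner 2, partner 1 carries the game and is worse off
  expect_true(all(sol0$V[, 1] < sol0$V[, 2]))
  # and partner 1's problem reduces to the 1-player benchmark
  expect_equal(steady_state(sol0)$x, steady_state(sol_1d())$x, tolerance = 1e-3)
})

test_that("steady_state handles boundary and missing-root cases", {
  sol0 <- sol_zero_utility(cstar = 0)   # S == 0: pure decay, rest point at 0
  ss <- steady_state(sol0)
  expect_equal(ss$x, 0)
  expect_equal(ss$efforts[1], 0, tolerance = 1e-9)
})

test_that("solver configuration guards are enforced", {
  expect_error(solve_hjb(benchmark_problem(), solver_config(h = 1)), "1 - r\\*h")
  expect_error(solve_hjb(couple_problem(partners = list(partner_spec(rho = 0))),
                         solver_config()), "undiscounted")
  expect_error(solver_config(damping = 0), "damping")
})
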