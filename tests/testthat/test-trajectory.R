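test_that("the itch shock fixture is twelve linearly spaced negative shocks", {
  sh <- make_itch_shocks()
  expect_length(sh$periods, 12)
  expect_equal(sh$periods[1], 85L)
  expect_equal(sh$periods, 85:96)
  expect_equal(sh$values, seq(-0.15, -0.05, length.out = 12))
  expect_equal(sum(sh$values), 12 * (-0.10))

  one <- make_itch_shocks(count = 1)
  expect_equal(one$values, -0.15)
  expect_error(make_itch_shocks(count = 0), "count")

  path <- withr::local_tempfile(fileext = ".json")
  write_shocks_json(sh, path)
  back <- read_shocks_json(path)
  expect_equal(back$periods, sh$periods)
  expect_equal(back$values, sh$values)
})

test_that("closed-loop simulation holds stationary states and zero-effort decay", {
  sol <- sol_1d()
  ss <- steady_state(sol)
  tr <- simulate_couple(sol, ss$x, n = 1000)
  expect_lt(max(abs(tr$x - ss$x)), 1e-3)

  # zero strategies: exact linear recursion x_k = x0 (1 - r h)^k
  sol0 <- sol_zero_utility(cstar = 0)
  tr0 <- simulate_couple(sol0, 3, n = 200)
  expect_equal(tr0$x, 3 * (1 - 2 * 0.01)^(0:200), tolerance = 1e-10)

  # benchmark run from x0 = 3: feeling decreasing, effort increasing
  tr3 <- simulate_couple(sol, 3, n = 400)
  expect_true(all(diff(tr3$x) < 0))
  expect_true(all(diff(tr3$c1) > 0))
  expect_equal(tail(tr3$x, 1), ss$x, tolerance = 0.01)
})

test_that("feeling stays non-negative under non-negative shocks", {
  sol <- sol_1d()
  up <- shock_sequence(periods = c(5L, 50L), values = c(0.4, 0.2), horizon = 300)
  for (x0 in c(0, 0.5, 4.5)) {
    tr <- simulate_with_shocks(sol, x0, up)
    expect_true(all(tr$x >= 0))
  }
})

test_that("stabilization with zero shocks is bitwise the unperturbed scheme", {
  sol <- sol_1d()
  base <- simulate_couple(sol, 3, n = 250)
  zs <- shock_sequence(horizon = 250)
  pert <- simulate_with_shocks(sol, 3, zs)
  expect_identical(pert$x, base$x)
  expect_identical(pert$c1, base$c1)
  expect_identical(pert$W1, base$W1)
})

test_that("the itch episode produces a U-shaped dip, extra effort, and recovery", {
  sol <- sol_1d()
  n <- 450
  base <- simulate_couple(sol, 3, n = n)
  pert <- simulate_with_shocks(sol, 3, make_itch_shocks(horizon = n))

  expect_lt(min(pert$x), min(base$x))
  mi <- which.min(pert$x)
  expect_gt(pert$k[mi], 85)                       # dip follows shock onset
  expect_equal(sum(pert$x == min(pert$x)), 1L)    # unique global minimum
  expect_true(all(diff(pert$x[mi:(n + 1)]) >= -1e-12))

  # returns within 1% of the unperturbed path after the shocks end
  rel_dev <- abs(pert$x - base$x) / pmax(base$x, 1e-9)
  expect_lt(tail(rel_dev, 1), 0.01)

  # stabilizing effort exceeds the unperturbed effort through the recovery
  rec_win <- pert$k >= 85 & pert$k <= 250
  expect_true(all(pert$c1[rec_win] >= base$c1[rec_win]))
})

test_that("discounted well-being matches geometric sums and the value function", {
  # truncated geometric sum for a constant payoff stream
  h <- 0.01; rho <- 0.1; p <- 2.5; n <- 400
  toy <- data.frame(k = 0:n, t = (0:n) * h, x = 1, c1 = 0.2,
                    payoff1 = p, W1 = 0, shocked = FALSE, clamped = FALSE)
  class(toy) <- c("couple_trajectory", "data.frame")
  got <- discounted_wellbeing(toy, 1, benchmark_problem(n_partners = 1),
                              solver_config())
  expect_equal(got, h * p * (1 - exp(-rho * h * (n + 1))) / (1 - exp(-rho * h)),
               tolerance = 1e-12)

  zeroed <- toy; zeroed$payoff1 <- 0
  expect_equal(discounted_wellbeing(zeroed, 1, benchmark_problem(n_partners = 1),
                                    solver_config()), 0)

  # long-horizon simulated well-being agrees with the solved value function
  sol <- sol_1d()
  tr <- simulate_couple(sol, 3, n = 8000)
  W <- discounted_wellbeing(tr, 1, sol$problem, sol$config)
  v3 <- value_fn(sol)(3)
  expect_equal(W, v3, tolerance = 0.02)
})

test_that("recovery time matches the linear closed-loop oracle", {
  sol <- sol_1d()
  ss <- steady_state(sol)
  calm <- simulate_couple(sol, ss$x, n = 300)
  expect_equal(as.integer(recovery_time(calm, ss$x)), 0L)

  # S == constant c0: deviation decays exactly as (1 - r h)^k
  solc <- sol_zero_utility(cstar = 1)        # S == 1, stationary x = 0.5
  r <- 2; h <- 0.01; s <- -0.2; base <- 0.5
  pert <- simulate_with_shocks(solc, base,
                               shock_sequence(periods = 1L, values = s,
                                              horizon = 1000))
  oracle <- 1 + ceiling(log(0.05 * base / abs(s)) / log(1 - r * h)) - 1
  got <- recovery_time(pert, baseline = base)
  expect_true(attr(got, "recovered"))
  expect_lte(abs(as.integer(got) - oracle), 1)
})

test_that("trajectories record breakdown and clamping", {
  sol <- sol_1d()
  big <- shock_sequence(periods = 5L, values = -4, horizon = 50)
  tr <- simulate_with_shocks(sol, 1, big)
  expect_true(attr(tr, "breakdown"))
  expect_true(any(tr$clamped))
  expect_true(all(tr$x >= 0))     # clamped at the domain floor, not negative

  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
})
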