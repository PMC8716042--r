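test_that("the phase field matches direct substitution", {
  p <- benchmark_partner()
  # at the closed-form equilibrium the field vanishes
  eq <- equilibrium_closed_form(p, r = 2)
  expect_lt(max(abs(phase_field(eq$x, eq$c, p, 2))), 1e-8)

  # at the preferred effort the effort dynamics push down (D' = 0, U' > 0)
  for (x in c(0, 1, 4)) {
    f <- phase_field(x, 0.2, p, 2)
    expect_equal(f[2], -p$utility$d1(x))
    expect_lt(f[2], 0)
  }

  # benchmark numbers at (3, 1.087)
  f3 <- phase_field(3, 1.087, p, 2)
  expect_equal(f3[1], -4.913, tolerance = 1e-12)
  expect_equal(f3[2], 2.1 * (1.087 - 0.2) - 5 / 4, tolerance = 1e-12)
  expect_equal(f3[2], 0.6127, tolerance = 1e-3)
})

test_that("the stationary equilibrium solves the quadratic stationarity system", {
  eq <- equilibrium_closed_form(benchmark_partner(), r = 2)
  # quadratic oracle: c^2 + 1.8 c - 5.161905 = 0, positive root
  croot <- (-1.8 + sqrt(1.8^2 + 4 * (0.4 + 10 / 2.1))) / 2
  expect_equal(eq$c, croot, tolerance = 1e-12)
  expect_equal(eq$x, croot / 2, tolerance = 1e-12)
  expect_equal(round(c(eq$x, eq$c), 2), c(0.77, 1.54))
  expect_lt(eq$residual, 1e-8)

  # zero preferred effort variant, solved by hand from the quadratic formula
  eq0 <- equilibrium_closed_form(partner_spec(cost = effort_cost(cstar = 0)), 2)
  expect_equal(eq0$c, (-2 + sqrt(4 + 4 * 5 / 1.05)) / 2, tolerance = 1e-10)
  expect_equal(eq0$x, eq0$c / 2, tolerance = 1e-10)

  # zero efficiency decouples: no feeling, preferred effort
  eqa0 <- equilibrium_closed_form(partner_spec(a = 0), 2)
  expect_equal(c(eqa0$x, eqa0$c), c(0, 0.2))

  # a generic smooth family goes through the bracketing root finder and
  # agrees with the log/quadratic closed form on the same inputs
  pgen <- partner_spec(
    utility = utility_curve(fn = function(x) 5 * log1p(x)),
    cost = effort_cost(cstar = 0.2, fn = function(c) 0.5 * (c - 0.2)^2))
  eqg <- equilibrium_closed_form(pgen, 2)
  expect_equal(eqg$x, eq$x, tolerance = 1e-5)
  expect_equal(eqg$c, eq$c, tolerance = 1e-5)
})

test_that("the equilibrium is always a saddle with the expected eigenstructure", {
  p <- benchmark_partner()
  eq <- equilibrium_closed_form(p, 2)
  expect_equal(eq$classification, "saddle")
  expect_equal(eq$eigenvalues, c(-2.3573, 2.4573), tolerance = 1e-4)
  cls <- classify_saddle(eq, p, 2)
  expect_equal(cls$stable_slope, -0.3573, tolerance = 1e-3)

  # triangular case a = 0: eigenvalues (-r, r + rho)
  p0 <- partner_spec(a = 0)
  eq0 <- equilibrium_closed_form(p0, 2)
  expect_equal(sort(eq0$eigenvalues), c(-2, 2.1))

  # saddle for any admissible concave-utility inputs
  for (alpha in c(1, 5, 20)) for (rr in c(0.5, 2, 4)) {
    pp <- partner_spec(a = 1.3, utility = utility_curve(alpha = alpha))
    ee <- equilibrium_closed_form(pp, rr)
    expect_equal(ee$classification, "saddle")
  }
})

test_that("RK4 integration is stationary at equilibrium and fourth order", {
  p <- benchmark_partner()
  eq <- equilibrium_closed_form(p, 2)
  path <- rk4_integrate(eq$x, eq$c, p, 2, step = 1e-3, n_steps = 1000)
  expect_lt(max(abs(path$x - eq$x)), 1e-6)
  expect_lt(max(abs(path$c - eq$c)), 1e-6)

  # a = 0 with c fixed at c*: x decays exponentially
  p0 <- partner_spec(a = 0)
  path0 <- rk4_integrate(1, 0.2, p0, 2, step = 1e-3, n_steps = 2000)
  expect_equal(path0$x, exp(-2 * path0$t), tolerance = 1e-10)

  # step halving cuts the endpoint error by about 2^4
  ref <- rk4_integrate(3, 1.2, p, 2, step = 1e-5, n_steps = 20000)
  endref <- unlist(ref[nrow(ref), c("x", "c")])
  err <- function(st) {
    pa <- rk4_integrate(3, 1.2, p, 2, step = st, n_steps = round(0.2 / st))
    max(abs(unlist(pa[nrow(pa), c("x", "c")]) - endref))
  }
  ratio <- err(0.02) / err(0.01)
  expect_gt(ratio, 8)
  expect_lt(ratio, 32)
})

test_that("stable-manifold shooting recovers the benchmark initial effort", {
  p <- benchmark_partner()
  eq <- equilibrium_closed_form(p, 2)

  sh_eq <- shoot_initial_effort(eq$x, p, 2)
  expect_equal(sh_eq$c0, eq$c, tolerance = 1e-3)

  sh3 <- shoot_initial_effort(3, p, 2)
  expect_equal(sh3$c0, 1.087, tolerance = 0.02)
  # the shot path is monotone between start and equilibrium
  expect_true(all(diff(sh3$path$x) <= 1e-10))
  expect_true(all(diff(sh3$path$c) >= -1e-6))

  c0s <- vapply(c(1, 2, 3), function(x0) shoot_initial_effort(x0, p, 2)$c0, 0)
  expect_true(all(diff(c0s) < 0))      # required initial effort falls with x0
})

test_that("the solved feedback map agrees with the saddle-path oracle", {
  sol <- sol_1d()
  p <- benchmark_partner()
  sh <- shoot_initial_effort(3, p, 2)

  # trajectory agreement within 2% of the feeling scale
  tr <- simulate_couple(sol, 3, n = 500)
  ora_x <- approx(sh$path$t, sh$path$x, xout = pmin(tr$t, max(sh$path$t)))$y
  scale <- diff(range(sol$problem$x_lo, sol$problem$x_hi))
  expect_lt(max(abs(tr$x - ora_x)), 0.02 * scale)

  # linearized feedback slope at the equilibrium within 15%
  eq <- equilibrium_closed_form(p, 2)
  cls <- classify_saddle(eq, p, 2)
  dS <- (strategy_fn(sol)(eq$x + 0.05) - strategy_fn(sol)(eq$x - 0.05)) / 0.1
  expect_lt(abs(dS - cls$stable_slope), 0.15 * abs(cls$stable_slope))
})
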