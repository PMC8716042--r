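# Shared lazily-computed solver fixtures. Solving the benchmark games is the
# expensive part of the suite, so each configuration is solved once and
# reused across test files (test_dir runs everything in one process).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) assign(key, fn(), .fixture_cache)
  get(key, .fixture_cache)
}

sol_1d <- function() cached("sol_1d", function()
  solve_hjb(benchmark_problem(n_partners = 1)))

sol_2d <- function(a2 = 1) cached(sprintf("sol_2d_%g", a2), function()
  solve_hjb(benchmark_problem(a2 = a2), solver_config(max_outer = 600)))

# U == 0 degenerate problem: optimal play is the zero-cost effort everywhere
zero_utility_problem <- function(cstar = 0.2, n_partners = 1) {
  U0 <- utility_curve(fn = function(x) rep(0, length(x)),
                      d1 = function(x) rep(0, length(x)),
                      d2 = function(x) rep(0, length(x)))
  ps <- replicate(n_partners,
                  partner_spec(utility = U0, cost = effort_cost(cstar = cstar)),
                  simplify = FALSE)
  couple_problem(r = 2, partners = ps)
}

sol_zero_utility <- function(cstar = 0.2) cached(sprintf("sol_u0_%g", cstar),
  function() solve_hjb(zero_utility_problem(cstar)))

benchmark_partner <- function() partner_spec()
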