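#' Solver configuration for the discrete HJB system
#'
#' Numerical knobs of the semi-Lagrangian / RBF-collocation solver.
#'
#' @param h time step of the discrete-time approximation (default 0.01; the
#'   one-step discount `1 - rho*h` and the Euler factor `1 - r*h` must both
#'   stay positive).
#' @param c_max upper control bound; the admissible effort set `[0, Inf)` is
#'   truncated to `[0, c_max]` and the solver asserts maximizers are
#'   interior (resolving with a doubled bound otherwise).
#' @param c_grid coarse control-grid resolution for the scalar maximization
#'   (default 501 points on `[0, c_max]`).
#' @param opt_tol bracket tolerance of the golden-section refinement.
#' @param value_tol sup-norm tolerance on the outer value-function change.
#' @param strategy_tol sup-norm tolerance on the outer strategy change.
#' @param game_tol inner game-iteration effort fixed-point tolerance.
#' @param damping damping factor in `(0, 1]` for the inner best-response
#'   sweeps.
#' @param max_outer,max_inner iteration caps for the double loop.
#' @param nodes a [node_set()] for the collocation.
#' @param kernel,eps,ridge,poly_tail RBF configuration, see [fit_rbf()].
#' @param verbose print per-iteration convergence diagnostics.
#' @param value_update `"policy"` (default) solves the frozen-strategy
#'   linear fixed point exactly each outer pass (Howard improvement, in RBF
#'   coefficient space); `"direct"` applies the one-step maximized
#'   right-hand side, the plain value-iteration update (slow for small
#'   `rho*h`, retained for cross-checks).
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(h = 0.01, c_max = 5, c_grid = 501,
                          opt_tol = 1e-10, value_tol = 1e-6, strategy_tol = 1e-8,
                          game_tol = 1e-9, damping = 0.5,
                          max_outer = 300, max_inner = 100,
                          nodes = node_set(41, c(0, 5)),
                          kernel = "gaussian", eps = NULL, ridge = 1e-12,
                          poly_tail = TRUE, verbose = FALSE,
                          value_update = c("policy", "direct")) {
  value_update <- match.arg(value_update)
  stopifnot(h > 0, c_max > 0, c_grid >= 11, opt_tol > 0, value_tol > 0,
            strategy_tol > 0, game_tol > 0, damping > 0, damping <= 1,
            max_outer >= 1, max_inner >= 1, inherits(nodes, "node_set"))
  structure(list(h = h, c_max = c_max, c_grid = c_grid, opt_tol = opt_tol,
                 value_tol = value_tol, strategy_tol = strategy_tol,
                 game_tol = game_tol, damping = damping,
                 max_outer = max_outer, max_inner = max_inner,
                 nodes = nodes, kernel = kernel, eps = eps, ridge = ridge,
                 poly_tail = poly_tail, verbose = verbose,
                 value_update = value_update),
            class = "solver_config")
}

check_config <- function(problem, config) {
  if (1 - problem$r * config$h <= 0)
    stop("time step too large: 1 - r*h must be positive")
  for (p in problem$partners) {
    if (p$rho <= 0)
      stop("undiscounted problem: rho must be positive to solve")
    if (1 - p$rho * config$h <= 0)
      stop("time step too large: 1 - rho*h must be positive")
  }
  rng <- attr(config$nodes, "range")
  if (rng[1] < problem$x_lo - 1e-12 || rng[2] > problem$x_hi + 1e-12)
    stop("node set extends beyond the problem domain")
  invisible(TRUE)
}

clamp_domain <- function(x, problem) pmin(pmax(x, problem$x_lo), problem$x_hi)

# Vectorized best response for partner i at the nodes `y` (one entry per
# node), given the opponent's efforts there and partner i's value
# interpolant. Coarse grid scan locates a one-cell bracket; where the
# analytic objective derivative changes sign across it (interior maximum)
# the bracket is resolved by derivative bisection, which is immune to the
# flat-top rounding noise of value comparisons (the objective's curvature
# in c carries a factor h); boundary/degenerate brackets fall back to
# golden-section on the h-rescaled objective. Ties break toward the
# smallest effort because the grid argmax takes the first maximizer.
br_nodes <- function(y, i, opp_effort, vinterp, problem, config, warm = NULL) {
  p <- problem$partners[[i]]
  h <- config$h
  disc <- 1 - p$rho * h
  a_i <- p$a
  a_opp <- if (length(problem$partners) == 2) problem$partners[[3 - i]]$a else 0
  drift0 <- -problem$r * y + a_opp * opp_effort
  Uy <- p$utility$fn(y)
  vy <- eval_rbf(vinterp, y)
  nQ <- length(y)
  cg <- seq(0, config$c_max, length.out = config$c_grid)
  cell <- cg[2] - cg[1]
  # h-rescaled objective: (U - D) + disc * (v(y#) - v(y)) / h; same argmax
  obj_sub <- function(cvec, idx) {
    yn <- clamp_domain(y[idx] + h * (drift0[idx] + a_i * cvec), problem)
    (Uy[idx] - p$cost$fn(cvec)) + disc * (eval_rbf(vinterp, yn) - vy[idx]) / h
  }
  dobj_sub <- function(cvec, idx) {     # derivative of obj_sub in c
    yn_raw <- y[idx] + h * (drift0[idx] + a_i * cvec)
    inside <- yn_raw > problem$x_lo & yn_raw < problem$x_hi
    -p$cost$d1(cvec) + disc * a_i * eval_rbf_d1(vinterp, yn_raw) * inside
  }
  coarse_bracket <- function(idx) {     # full grid scan for the given nodes
    yn <- clamp_domain(outer(y[idx] + h * drift0[idx], h * a_i * cg, "+"), problem)
    V <- matrix(eval_rbf(vinterp, as.vector(yn)), nrow = length(idx))
    O <- (Uy[idx] - disc * vy[idx] / h) -
      outer(rep(1, length(idx)), p$cost$fn(cg)) + disc * V / h
    if (!all(is.finite(O))) stop("non-finite Bellman objective encountered")
    ix <- max.col(O, ties.method = "first")       # first (smallest-c) argmax
    cbind(cg[pmax(ix - 1L, 1L)], cg[pmin(ix + 1L, length(cg))])
  }

  cbr <- numeric(nQ)
  todo <- seq_len(nQ)
  if (!is.null(warm)) {
    lo <- pmax(warm - 2 * cell, 0); hi <- pmin(warm + 2 * cell, config$c_max)
  } else {
    bk <- coarse_bracket(todo); lo <- bk[, 1]; hi <- bk[, 2]
  }
  for (pass in 1:2) {
    glo <- dobj_sub(lo, todo); ghi <- dobj_sub(hi, todo)
    interior <- is.finite(glo) & is.finite(ghi) & glo > 0 & ghi < 0
    # interior maxima: bisection on the derivative (immune to the flat-top
    # value-comparison noise, whose curvature carries a factor h)
    if (any(interior)) {
      idx <- todo[interior]
      blo <- lo[interior]; bhi <- hi[interior]
      n_bis <- ceiling(log2(max(max(bhi - blo) / config$opt_tol, 2)))
      for (k in seq_len(n_bis)) {
        mid <- (blo + bhi) / 2
        pos <- dobj_sub(mid, idx) > 0
        blo <- ifelse(pos, mid, blo)
        bhi <- ifelse(pos, bhi, mid)
      }
      cbr[idx] <- (blo + bhi) / 2
    }
    rest <- todo[!interior]
    if (!length(rest)) { todo <- integer(0); break }
    if (pass == 1 && !is.null(warm)) {
      # warm bracket failed for these nodes: rescan them fully
      todo <- rest
      bk <- coarse_bracket(todo); lo <- bk[, 1]; hi <- bk[, 2]
      next
    }
    # boundary / degenerate brackets: golden-section on the rescaled objective
    idx <- rest
    blo <- lo[!interior]; bhi <- hi[!interior]
    invphi <- (sqrt(5) - 1) / 2
    x1 <- bhi - invphi * (bhi - blo)
    x2 <- blo + invphi * (bhi - blo)
    f1 <- obj_sub(x1, idx); f2 <- obj_sub(x2, idx)
    wid <- max(max(bhi - blo), config$opt_tol)
    n_it <- ceiling(log(config$opt_tol / wid) / log(invphi))
    for (k in seq_len(max(n_it, 1))) {
      take1 <- f1 >= f2      # keep left interval on ties (smaller c)
      nlo <- ifelse(take1, blo, x1)
      nhi <- ifelse(take1, x2, bhi)
      nx1 <- ifelse(take1, nhi - invphi * (nhi - nlo), x2)
      nx2 <- ifelse(take1, x1, nlo + invphi * (nhi - nlo))
      fpt <- obj_sub(ifelse(take1, nx1, nx2), idx)
      nf1 <- ifelse(take1, fpt, f2)
      nf2 <- ifelse(take1, f1, fpt)
      blo <- nlo; bhi <- nhi; x1 <- nx1; x2 <- nx2; f1 <- nf1; f2 <- nf2
    }
    cbr[idx] <- (blo + bhi) / 2
    todo <- integer(0)
    break
  }
  # value on the original (unscaled) Bellman scale
  yn <- clamp_domain(y + h * (drift0 + a_i * cbr), problem)
  val <- h * (Uy - p$cost$fn(cbr)) + disc * eval_rbf(vinterp, yn)
  list(effort = cbr, value = val)
}

#' Best response of one partner at a feeling node
#'
#' Maximizes the discrete Bellman objective
#' `h*(U_i(y) - D_i(c)) + (1 - rho_i*h) * v_i(y + h*f(y, .))` over
#' `c` in `[0, c_max]`, with the Euler image clamped to the domain. A
#' coarse-grid scan locates the bracket; golden-section refinement resolves
#' it to `opt_tol`. Ties break toward the smallest effort.
#'
#' @param y feeling node (scalar, in the domain).
#' @param i partner index (1 or 2).
#' @param opponent_effort the other partner's effort at `y` (ignored for
#'   1-player problems).
#' @param v_i partner i's value interpolant ([fit_rbf()] result).
#' @param problem a [couple_problem()].
#' @param config a [solver_config()].
#' @return The maximizing effort (scalar).
#' @export
best_response <- function(y, i, opponent_effort, v_i, problem, config = solver_config()) {
  stopifnot(length(y) == 1, opponent_effort >= 0)
  br_nodes(y, i, opponent_effort, v_i, problem, config)$effort
}

#' Inner game iteration at one node
#'
#' Damped best-response sweeps at a single feeling node until the effort
#' pair stops moving (fixed point of the per-node game), or the iteration
#' cap is hit (then flagged, last iterate returned).
#'
#' @param y feeling node (scalar).
#' @param efforts initial effort vector (one entry per partner).
#' @param v_interps list of value interpolants, one per partner.
#' @param problem a [couple_problem()].
#' @param config a [solver_config()].
#' @return List with `efforts`, `iterations`, `converged`.
#' @export
game_iterate_node <- function(y, efforts, v_interps, problem, config = solver_config()) {
  np <- length(problem$partners)
  stopifnot(length(efforts) == np, all(efforts >= 0), all(efforts <= config$c_max))
  e <- efforts
  converged <- FALSE
  for (it in seq_len(config$max_inner)) {
    br <- vapply(seq_len(np), function(i) {
      opp <- if (np == 2) e[3 - i] else 0
      br_nodes(y, i, opp, v_interps[[i]], problem, config)$effort
    }, 0)
    enew <- if (np == 1) br else (1 - config$damping) * e + config$damping * br
    delta <- max(abs(enew - e))
    e <- enew
    if (delta < config$game_tol || np == 1) { converged <- np == 1 || delta < config$game_tol; break }
  }
  list(efforts = e, iterations = it, converged = converged)
}

#' Solve the discrete HJB system for feedback Nash equilibria
#'
#' The double loop: the outer pass refits the value interpolants from the
#' current node values, runs the inner game iteration (damped best-response
#' sweeps, vectorized over all nodes) to the per-node effort fixed point,
#' and updates the node values for the frozen strategies — by default
#' through an exact policy evaluation solved directly in RBF-coefficient
#' space, optionally by the one-step maximized right-hand side. Iteration
#' stops when both the value and the strategy sup-norm changes fall below
#' their tolerances. Values start at `U_i(y)/rho_i` (the value of a frozen
#' feeling at zero effort cost), strategies at the preferred efforts.
#'
#' @param problem a [couple_problem()].
#' @param config a [solver_config()].
#' @return An object of class `feedback_solution`: node tables `V` and `S`
#'   (one column per partner), value and strategy interpolants, and a
#'   convergence report.
#' @examples
#' \donttest{
#' sol <- solve_hjb(benchmark_problem(n_partners = 1))
#' steady_state(sol)
#' }
#' @export
solve_hjb <- function(problem, config = solver_config()) {
  stopifnot(inherits(problem, "couple_problem"))
  check_config(problem, config)
  np <- length(problem$partners)
  y <- as.numeric(config$nodes)
  Q <- length(y)
  h <- config$h

  # initial values / strategies, and one interpolant object per partner
  V <- vapply(problem$partners, function(p) p$utility$fn(y) / p$rho, numeric(Q))
  S <- vapply(problem$partners, function(p) rep(p$cost$cstar, Q), numeric(Q))
  vinterp <- lapply(seq_len(np), function(i)
    fit_rbf(config$nodes, V[, i], kernel = config$kernel, eps = config$eps,
            ridge = config$ridge, poly_tail = config$poly_tail))
  v0_norm <- max(1, max(abs(V)))

  # fixed pieces of the coefficient-space policy evaluation
  proto <- vinterp[[1]]
  Enode <- rbf_basis(y, proto)
  constraint_rows <- if (proto$poly_tail)
    cbind(t(cbind(1, y)), matrix(0, 2, 2)) else NULL

  cmax_try <- config$c_max
  repeat {
    cfg <- config; cfg$c_max <- cmax_try
    res <- hjb_outer_loop(problem, cfg, y, V, S, vinterp, Enode,
                          constraint_rows, v0_norm)
    if (max(res$S) < cmax_try - 10 * (cmax_try / (config$c_grid - 1))) break
    cmax_try <- cmax_try * 2   # maximizer hit the truncation bound: re-solve
    if (cmax_try > 64 * config$c_max)
      stop("effort maximizers keep hitting the control bound; problem appears unbounded")
    V <- res$V; S <- pmin(res$S, cmax_try); vinterp <- res$vinterp
  }
  V <- res$V; S <- res$S; vinterp <- res$vinterp

  sinterp <- lapply(seq_len(np), function(i)
    fit_rbf(config$nodes, S[, i], kernel = config$kernel, eps = config$eps,
            ridge = config$ridge, poly_tail = config$poly_tail))
  sol <- structure(
    list(problem = problem, config = config, c_max_used = cmax_try,
         nodes = y, V = V, S = S,
         value_interp = vinterp, strategy_interp = sinterp,
         report = res$report),
    class = "feedback_solution")
  sol$report$bellman_residual <- bellman_residual(sol)
  sol
}

# The double loop. The outer ("game") iteration updates each partner's
# strategy by a damped best-response step in strategy-function space; the
# inner ("value") iteration fully re-solves that partner's single-agent
# dynamic program against the opponent's frozen strategy, by policy
# iteration with exact policy evaluation in RBF-coefficient space.
# Alternating full single-agent solves keeps the scheme stable at strong
# effort coupling (a1*a2 large), where updating both value functions from
# a shared one-step strategy sweep diverges.
hjb_outer_loop <- function(problem, config, y, V, S, vinterp, Enode,
                           constraint_rows, v0_norm) {
  np <- length(problem$partners)
  Q <- length(y)
  h <- config$h
  a <- vapply(problem$partners, function(p) p$a, 0)
  dv <- dS <- Inf
  dv_hist <- numeric(0)
  inner_max_used <- 0L
  converged <- FALSE
  BRcache <- S

  # single-agent policy iteration for partner i with the opponent's node
  # efforts frozen; vinterp[[i]] is both warm start and output
  solve_single <- function(i, opp, warm) {
    p <- problem$partners[[i]]
    disc <- 1 - p$rho * h
    a_opp <- if (np == 2) a[3 - i] else 0
    Vi <- vinterp[[i]]$values
    Si <- warm
    iters <- 0L
    for (it in seq_len(config$max_inner)) {
      iters <- it
      bri <- br_nodes(y, i, opp, vinterp[[i]], problem, config, warm = Si)$effort
      yn <- clamp_domain(y + h * (-problem$r * y + a[i] * bri + a_opp * opp),
                         problem)
      b <- h * (p$utility$fn(y) - p$cost$fn(bri))
      if (config$value_update == "policy") {
        Eyn <- rbf_basis(yn, vinterp[[i]])
        LHS <- rbind(Enode - disc * Eyn, constraint_rows)
        rhs <- if (is.null(constraint_rows)) b else c(b, 0, 0)
        coef <- tryCatch(solve(LHS, rhs), error = function(e)
          stop("policy-evaluation system singular: ", conditionMessage(e)))
        vnew <- as.numeric(Enode %*% coef)
        vinterp[[i]]$coef <<- as.numeric(coef)
      } else {
        vnew <- b + disc * eval_rbf(vinterp[[i]], yn)
        vinterp[[i]] <<- rbf_refit(vinterp[[i]], vnew)
      }
      vinterp[[i]]$values <<- vnew
      dvi <- max(abs(vnew - Vi)); dsi <- max(abs(bri - Si))
      Vi <- vnew; Si <- bri
      if (dvi < 0.1 * config$value_tol && dsi < 0.1 * config$strategy_tol)
        break
    }
    list(S = Si, V = Vi, iters = iters)
  }

  for (outer in seq_len(config$max_outer)) {
    dS <- 0; dv <- 0
    for (i in seq_len(np)) {
      opp <- if (np == 2) S[, 3 - i] else rep(0, Q)
      res <- solve_single(i, opp, BRcache[, i])
      BRcache[, i] <- res$S
      inner_max_used <- max(inner_max_used, res$iters)
      snew_i <- if (np == 1) res$S else
        (1 - config$damping) * S[, i] + config$damping * res$S
      dS <- max(dS, max(abs(snew_i - S[, i])))
      dv <- max(dv, max(abs(res$V - V[, i])))
      S[, i] <- snew_i
      V[, i] <- res$V
    }
    dv_hist <- c(dv_hist, dv)
    if (isTRUE(config$verbose))
      message(sprintf("outer %d: dv %.3g dS %.3g inner %d", outer, dv, dS,
                      inner_max_used))
    if (max(abs(V)) > 1e6 * v0_norm)
      stop(sprintf("value iteration diverged (sup norm %.3g after %d outer iterations)",
                   max(abs(V)), outer))
    if (dv < config$value_tol && dS < config$strategy_tol) { converged <- TRUE; break }
  }
  report <- structure(
    list(outer_iterations = outer, inner_iterations_max = inner_max_used,
         value_change = dv, strategy_change = dS,
         value_change_history = dv_hist,
         bellman_residual = NA_real_, converged = converged),
    class = "convergence_report")
  list(V = V, S = S, vinterp = vinterp, report = report)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("<convergence_report> %s after %d outer iterations (inner max %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$outer_iterations, x$inner_iterations_max))
  cat(sprintf("  value change %.3g | strategy change %.3g | Bellman residual %.3g\n",
              x$value_change, x$strategy_change, x$bellman_residual))
  invisible(x)
}

#' @export
print.feedback_solution <- function(x, ...) {
  cat(sprintf("<feedback_solution> %d-player, Q = %d nodes on [%g, %g], h = %g\n",
              ncol(x$V), length(x$nodes), min(x$nodes), max(x$nodes), x$config$h))
  print(x$report)
  invisible(x)
}

#' Feedback strategy / value function accessors
#'
#' Return the solved effort feedback map `S_i(x)` or value function `v_i(x)`
#' of one partner as an ordinary R function of the feeling level (RBF
#' evaluation off-node, clamped to the domain).
#'
#' @param solution a [solve_hjb()] result.
#' @param i partner index.
#' @return A function of `x`.
#' @export
strategy_fn <- function(solution, i = 1) {
  stopifnot(inherits(solution, "feedback_solution"))
  interp <- solution$strategy_interp[[i]]
  function(x) eval_rbf(interp, x)
}

#' @rdname strategy_fn
#' @export
value_fn <- function(solution, i = 1) {
  stopifnot(inherits(solution, "feedback_solution"))
  interp <- solution$value_interp[[i]]
  function(x) eval_rbf(interp, x)
}

#' Bellman residual of a feedback solution
#'
#' Recomputes the maximized right-hand side of the collocated HJB equation
#' at every node, given the solution's strategies and value interpolants,
#' and returns the largest absolute discrepancy against the stored node
#' values (over nodes and partners).
#'
#' @param solution a [solve_hjb()] result.
#' @param problem,config default to those stored in the solution.
#' @return Scalar sup-norm residual.
#' @export
bellman_residual <- function(solution, problem = solution$problem,
                             config = solution$config) {
  stopifnot(inherits(solution, "feedback_solution"))
  y <- solution$nodes
  np <- length(problem$partners)
  res <- 0
  for (i in seq_len(np)) {
    opp <- if (np == 2) solution$S[, 3 - i] else rep(0, length(y))
    bv <- br_nodes(y, i, opp, solution$value_interp[[i]], problem, config)$value
    res <- max(res, max(abs(bv - solution$V[, i])))
  }
  res
}

#' Stationary state of the closed-loop feeling dynamics
#'
#' Root of the closed-loop drift `-r*x + sum_i a_i*S_i(x)` on the domain.
#' Returns the stationary feeling and the stationary efforts there.
#'
#' @param solution a [solve_hjb()] result.
#' @param problem defaults to the solution's problem.
#' @param tol root tolerance (default `1e-8`).
#' @return List with `x` (stationary feeling) and `efforts`.
#' @export
steady_state <- function(solution, problem = solution$problem, tol = 1e-8) {
  stopifnot(inherits(solution, "feedback_solution"))
  np <- length(problem$partners)
  a <- vapply(problem$partners, function(p) p$a, 0)
  g <- function(x) {
    s <- vapply(seq_len(np), function(i) eval_rbf(solution$strategy_interp[[i]], x), 0)
    -problem$r * x + sum(a * s)
  }
  glo <- g(problem$x_lo)
  if (abs(glo) < 1e-9 || all(a == 0)) {
    xbar <- problem$x_lo
  } else {
    if (glo * g(problem$x_hi) > 0)
      stop("no interior stationary state: closed-loop drift does not change sign on the domain")
    xbar <- stats::uniroot(g, c(problem$x_lo, problem$x_hi), tol = tol)$root
  }
  efforts <- vapply(seq_len(np), function(i)
    eval_rbf(solution$strategy_interp[[i]], xbar), 0)
  list(x = xbar, efforts = efforts)
}

#' Write a feedback solution to JSON and CSV
#'
#' JSON carries the nodes, per-node values and strategies, kernel
#' configuration and convergence diagnostics; the CSV is the node table
#' with columns `x, S1, S2, v1, v2` (`S2`/`v2` omitted for 1-player
#' problems).
#'
#' @param solution a [solve_hjb()] result.
#' @param json_path,csv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_solution <- function(solution, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(solution, "feedback_solution"))
  np <- ncol(solution$V)
  if (!is.null(json_path)) {
    obj <- list(
      nodes = solution$nodes,
      values = lapply(seq_len(np), function(i) solution$V[, i]),
      strategies = lapply(seq_len(np), function(i) solution$S[, i]),
      kernel = list(kernel = solution$value_interp[[1]]$kernel,
                    eps = solution$value_interp[[1]]$eps,
                    ridge = solution$value_interp[[1]]$ridge),
      h = solution$config$h,
      diagnostics = unclass(solution$report))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    df <- data.frame(x = solution$nodes, S1 = solution$S[, 1])
    if (np == 2) df$S2 <- solution$S[, 2]
    df$v1 <- solution$V[, 1]
    if (np == 2) df$v2 <- solution$V[, 2]
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
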