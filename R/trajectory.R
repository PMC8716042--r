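#' Sparse shock schedule
#'
#' Additive feeling perturbations indexed by simulation period. Periods not
#' listed carry a zero shock.
#'
#' @param periods positive integer period indices.
#' @param values shock sizes (feeling units), one per period.
#' @param horizon total number of simulation periods the schedule refers to.
#' @return An object of class `shock_sequence`.
#' @export
shock_sequence <- function(periods = integer(0), values = numeric(0), horizon = 300) {
  stopifnot(length(periods) == length(values), horizon >= 1)
  if (length(periods)) {
    stopifnot(all(periods == as.integer(periods)), all(periods >= 1),
              !anyDuplicated(periods))
    o <- order(periods)
    periods <- as.integer(periods[o]); values <- values[o]
  }
  structure(list(periods = as.integer(periods), values = as.numeric(values),
                 horizon = as.integer(horizon)),
            class = "shock_sequence")
}

#' @export
print.shock_sequence <- function(x, ...) {
  cat(sprintf("<shock_sequence> %d nonzero shocks over %d periods\n",
              length(x$periods), x$horizon))
  if (length(x$periods))
    cat(sprintf("  periods %d..%d, values in [%g, %g], total %g\n",
                min(x$periods), max(x$periods), min(x$values), max(x$values),
                sum(x$values)))
  invisible(x)
}

#' The "seven-year-itch" shock fixture
#'
#' A year-long stressful episode: `count` consecutive negative shocks
#' starting at period `start`, linearly spaced from `first` to `last`
#' (decreasing magnitude by default). With a month-long period the default
#' start (period 85) places the episode in the seventh year of the
#' relationship.
#'
#' @param start first shocked period.
#' @param count number of consecutive shocks, `>= 1`.
#' @param first,last first and last shock values.
#' @param horizon schedule horizon (default 300 periods).
#' @return A [shock_sequence()].
#' @examples
#' make_itch_shocks()   # 12 shocks at periods 85..96, -0.15 ... -0.05
#' @export
make_itch_shocks <- function(start = 85, count = 12, first = -0.15, last = -0.05,
                             horizon = 300) {
  if (count < 1) stop("count must be >= 1")
  values <- if (count == 1) first else seq(first, last, length.out = count)
  shock_sequence(periods = start + seq_len(count) - 1L, values = values,
                 horizon = max(horizon, start + count - 1L))
}

#' Read / write shock schedules as JSON
#' @param path file path.
#' @export
read_shocks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  shock_sequence(obj$periods, obj$values, obj$horizon)
}

#' @rdname read_shocks_json
#' @param shocks a [shock_sequence()].
#' @export
write_shocks_json <- function(shocks, path) {
  stopifnot(inherits(shocks, "shock_sequence"))
  jsonlite::write_json(unclass(shocks), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate the closed-loop relationship trajectory
#'
#' Iterates the feedback scheme: each period the efforts are read off the
#' solved feedback maps at the current feeling, and the feeling advances by
#' the first-order Euler step `x_{k+1} = x_k + h * f(x_k, c_{1,k}, c_{2,k})`.
#' States leaving the closed domain are clamped to its boundary and
#' flagged; a feeling below the viability threshold `x_min` sets the
#' breakdown flag (computation continues).
#'
#' @param solution a [solve_hjb()] result.
#' @param x0 initial feeling, in the domain.
#' @param n number of periods, `>= 1`.
#' @param problem,config default to those stored in the solution.
#' @return A data frame of class `couple_trajectory` with columns `k`, `t`,
#'   `x`, `c1` (`c2`), per-partner instantaneous payoffs, running
#'   discounted well-being sums `W1` (`W2`), `shocked` and `clamped` flags;
#'   attributes `breakdown` and `breakdown_period`.
#' @export
simulate_couple <- function(solution, x0, n = 300,
                            problem = solution$problem, config = solution$config) {
  simulate_engine(solution, x0, shock_sequence(horizon = n), problem, config)
}

#' Simulate with exogenous feeling shocks (feedback stabilization)
#'
#' Same closed-loop scheme as [simulate_couple()], but an additive shock
#' `sigma_{k+1}` perturbs each Euler update; efforts are recomputed from the
#' observed (perturbed) state every period, which is what a feedback
#' strategy permits. With an all-zero schedule the output is identical to
#' the unperturbed simulator.
#'
#' @param solution a [solve_hjb()] result.
#' @param x0 initial feeling.
#' @param shocks a [shock_sequence()]; its horizon sets the run length.
#' @param problem,config default to those stored in the solution.
#' @return A `couple_trajectory` data frame, see [simulate_couple()].
#' @export
simulate_with_shocks <- function(solution, x0, shocks,
                                 problem = solution$problem, config = solution$config) {
  stopifnot(inherits(shocks, "shock_sequence"))
  simulate_engine(solution, x0, shocks, problem, config)
}

simulate_engine <- function(solution, x0, shocks, problem, config) {
  stopifnot(inherits(solution, "feedback_solution"),
            x0 >= problem$x_lo, x0 <= problem$x_hi)
  n <- shocks$horizon
  stopifnot(n >= 1)
  np <- length(problem$partners)
  h <- config$h
  a <- vapply(problem$partners, function(p) p$a, 0)
  sigma <- numeric(n + 1)
  if (length(shocks$periods)) {
    keep <- shocks$periods <= n
    sigma[shocks$periods[keep] + 1L] <- shocks$values[keep]
  }
  x <- numeric(n + 1)
  C <- matrix(0, n + 1, np)
  clamped <- logical(n + 1)
  x[1] <- x0
  for (k in seq_len(n + 1)) {
    for (i in seq_len(np))
      C[k, i] <- eval_rbf(solution$strategy_interp[[i]], x[k])
    if (k <= n) {
      xn <- x[k] + h * (-problem$r * x[k] + sum(a * C[k, ])) + sigma[k + 1]
      xc <- clamp_domain(xn, problem)
      clamped[k + 1] <- xc != xn
      x[k + 1] <- xc
    }
  }
  kk <- 0:n
  tt <- kk * h
  df <- data.frame(k = kk, t = tt, x = x)
  pay <- matrix(0, n + 1, np)
  W <- matrix(0, n + 1, np)
  for (i in seq_len(np)) {
    p <- problem$partners[[i]]
    df[[paste0("c", i)]] <- C[, i]
    pay[, i] <- p$utility$fn(pmax(x, 0)) - p$cost$fn(C[, i])
    W[, i] <- cumsum(h * exp(-p$rho * tt) * pay[, i])
  }
  for (i in seq_len(np)) df[[paste0("payoff", i)]] <- pay[, i]
  for (i in seq_len(np)) df[[paste0("W", i)]] <- W[, i]
  df$shocked <- sigma != 0
  df$clamped <- clamped
  # breakdown: viability threshold crossed by the (pre-clamp equivalent) path
  below <- which(x < problem$x_min | (clamped & x <= problem$x_lo))
  attr(df, "breakdown") <- length(below) > 0
  attr(df, "breakdown_period") <- if (length(below)) kk[below[1]] else NA_integer_
  attr(df, "h") <- h
  class(df) <- c("couple_trajectory", "data.frame")
  df
}

#' Total discounted well-being along a trajectory
#'
#' The discrete happiness integral `h * sum_k exp(-rho t_k) * (U(x_k) -
#' D(c_k))` for one partner.
#'
#' @param traj a `couple_trajectory`.
#' @param partner partner index (1 or 2).
#' @param problem the [couple_problem()] the trajectory was simulated from.
#' @param config the [solver_config()] used (supplies `h`).
#' @return Scalar total discounted well-being.
#' @export
discounted_wellbeing <- function(traj, partner = 1, problem, config) {
  stopifnot(inherits(traj, "couple_trajectory"), nrow(traj) >= 1)
  p <- problem$partners[[partner]]
  h <- config$h
  pay <- traj[[paste0("payoff", partner)]]
  sum(h * exp(-p$rho * traj$t) * pay)
}

#' Periods needed to recover from a shock
#'
#' Counts periods from the first shocked period until the feeling first
#' returns to `fraction` of the baseline level. Returns 0 when the feeling
#' never drops below that threshold (or the trajectory has no shocks); when
#' recovery does not occur within the horizon the horizon is returned with
#' attribute `recovered = FALSE`.
#'
#' @param perturbed a shocked `couple_trajectory`.
#' @param baseline baseline feeling level, `> 0` (typically the pre-shock
#'   stationary level).
#' @param fraction recovery threshold as a fraction of baseline
#'   (default 0.95).
#' @return Integer period count with attribute `recovered`.
#' @export
recovery_time <- function(perturbed, baseline, fraction = 0.95) {
  stopifnot(inherits(perturbed, "couple_trajectory"), baseline > 0,
            fraction > 0, fraction <= 1)
  thr <- fraction * baseline
  k_shock <- which(perturbed$shocked)[1]
  if (is.na(k_shock)) return(structure(0L, recovered = TRUE))
  after <- perturbed$k >= perturbed$k[k_shock]
  if (all(perturbed$x[after] >= thr)) return(structure(0L, recovered = TRUE))
  k_below <- which(after & perturbed$x < thr)[1]
  rec <- which(perturbed$k > perturbed$k[k_below] & perturbed$x >= thr)
  if (!length(rec)) {
    out <- max(perturbed$k) - perturbed$k[k_shock]
    return(structure(as.integer(out), recovered = FALSE))
  }
  structure(as.integer(perturbed$k[rec[1]] - perturbed$k[k_shock]), recovered = TRUE)
}

#' Write a trajectory as CSV
#'
#' Columns: `k, t, x, c1, c2, payoff1, payoff2, W1, W2, shocked` (partner-2
#' columns only for 2-player problems).
#'
#' @param traj a `couple_trajectory`.
#' @param path output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "couple_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
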