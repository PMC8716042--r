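#' Heterogamy sweep over partner 2's effort efficiency
#'
#' Solves the dyadic game for each efficiency value `a2` (partner 1 fixed
#' at the base problem's `a1`), and summarizes each couple: stationary
#' feeling and efforts, and each partner's well-being at the stationary
#' feeling and at a reference initial feeling. A solver failure for one
#' value flags that row and the sweep continues.
#'
#' @param a2_values non-negative efficiencies for partner 2.
#' @param problem base 2-player [couple_problem()].
#' @param config a [solver_config()].
#' @param x0 reference initial feeling for the well-being columns.
#' @param solutions optional pre-computed list of [solve_hjb()] results,
#'   one per `a2` value (skips solving; used to share solves with
#'   [recovery_table()]).
#' @return A data frame keyed by the heterogamy gap `a2 - a1` with columns
#'   `a2, gap, xbar, cbar1, cbar2, v1_xbar, v2_xbar, v1_x0, v2_x0, ok`;
#'   the solutions are attached as attribute `"solutions"`.
#' @export
heterogamy_sweep <- function(a2_values, problem = benchmark_problem(),
                             config = solver_config(), x0 = 3,
                             solutions = NULL) {
  stopifnot(length(problem$partners) == 2, all(a2_values >= 0))
  a1 <- problem$partners[[1]]$a
  rows <- vector("list", length(a2_values))
  sols <- vector("list", length(a2_values))
  for (j in seq_along(a2_values)) {
    a2 <- a2_values[j]
    prob_j <- problem
    prob_j$partners[[2]]$a <- a2
    sol <- if (!is.null(solutions)) solutions[[j]] else
      tryCatch(solve_hjb(prob_j, config), error = function(e) e)
    if (inherits(sol, "error")) {
      rows[[j]] <- data.frame(a2 = a2, gap = a2 - a1, xbar = NA, cbar1 = NA,
                              cbar2 = NA, v1_xbar = NA, v2_xbar = NA,
                              v1_x0 = NA, v2_x0 = NA, ok = FALSE)
      next
    }
    sols[[j]] <- sol
    ss <- steady_state(sol, prob_j)
    rows[[j]] <- data.frame(
      a2 = a2, gap = a2 - a1, xbar = ss$x,
      cbar1 = ss$efforts[1], cbar2 = ss$efforts[2],
      v1_xbar = value_fn(sol, 1)(ss$x), v2_xbar = value_fn(sol, 2)(ss$x),
      v1_x0 = value_fn(sol, 1)(x0), v2_x0 = value_fn(sol, 2)(x0),
      ok = TRUE)
  }
  out <- do.call(rbind, rows)
  attr(out, "solutions") <- sols
  out
}

#' Post-shock recovery table across couples
#'
#' For each efficiency `a2`, solves the dyadic game, places the couple at
#' its stationary feeling, applies a one-period shock, and measures the
#' number of periods until the feeling recovers the given fraction of its
#' pre-shock level.
#'
#' @param a2_values efficiencies for partner 2.
#' @param shock one-period shock size (negative; default -0.2).
#' @param problem base 2-player [couple_problem()].
#' @param config a [solver_config()].
#' @param fraction recovery threshold (default 0.95).
#' @param horizon simulation horizon in periods.
#' @param solutions optional pre-computed solutions (as in
#'   [heterogamy_sweep()]).
#' @return Data frame with columns `a2, xbar, shock, rel_shock_pct,
#'   recovery_periods, recovered`.
#' @export
recovery_table <- function(a2_values, shock = -0.2, problem = benchmark_problem(),
                           config = solver_config(), fraction = 0.95,
                           horizon = 2000, solutions = NULL) {
  stopifnot(shock < 0, length(problem$partners) == 2)
  if (!length(a2_values))
    return(data.frame(a2 = numeric(0), xbar = numeric(0), shock = numeric(0),
                      rel_shock_pct = numeric(0), recovery_periods = integer(0),
                      recovered = logical(0)))
  rows <- vector("list", length(a2_values))
  for (j in seq_along(a2_values)) {
    a2 <- a2_values[j]
    prob_j <- problem
    prob_j$partners[[2]]$a <- a2
    sol <- if (!is.null(solutions)) solutions[[j]] else
      tryCatch(solve_hjb(prob_j, config), error = function(e) e)
    if (inherits(sol, "error")) {
      rows[[j]] <- data.frame(a2 = a2, xbar = NA, shock = shock,
                              rel_shock_pct = NA, recovery_periods = NA,
                              recovered = FALSE)
      next
    }
    ss <- steady_state(sol, prob_j)
    shocks <- shock_sequence(periods = 1L, values = shock, horizon = horizon)
    traj <- simulate_with_shocks(sol, ss$x, shocks, prob_j, config)
    rec <- recovery_time(traj, baseline = ss$x, fraction = fraction)
    rows[[j]] <- data.frame(a2 = a2, xbar = ss$x, shock = shock,
                            rel_shock_pct = 100 * abs(shock) / ss$x,
                            recovery_periods = as.integer(rec),
                            recovered = isTRUE(attr(rec, "recovered")))
  }
  do.call(rbind, rows)
}

#' Experiment specification
#'
#' A declarative description of one computational experiment: which canned
#' analysis to run (`feedback1d` 1-player feedback analysis with the
#' saddle-path cross-check, `stabilize1d` 1-player shock stabilization,
#' `heterogamy` the efficiency sweep with per-couple feedback curves,
#' `equilibria` the sweep summary of stationary levels versus the
#' efficiency gap, `stabilize2d` dyadic stabilization for three couples,
#' `recovery` the post-shock recovery analysis, or `custom`), with its
#' problem/solver configuration and output directory.
#'
#' @param tag experiment tag.
#' @param problem a [couple_problem()] (defaults depend on the tag).
#' @param config a [solver_config()].
#' @param a2_values sweep values (heterogamy/equilibria/recovery).
#' @param shocks a [shock_sequence()] (stabilize1d/stabilize2d).
#' @param x0 initial feeling for trajectory runs.
#' @param out_dir output directory.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(tag = c("feedback1d", "stabilize1d", "heterogamy",
                                    "equilibria", "stabilize2d", "recovery",
                                    "custom"),
                            problem = NULL, config = solver_config(),
                            a2_values = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75),
                            shocks = make_itch_shocks(),
                            x0 = 3, out_dir = tempfile("experiment")) {
  tag <- tryCatch(match.arg(tag), error = function(e)
    stop(sprintf("unknown experiment tag %s; valid tags: feedback1d, stabilize1d, heterogamy, equilibria, stabilize2d, recovery, custom",
                 deparse(tag[1])), call. = FALSE))
  if (is.null(problem))
    problem <- if (tag %in% c("feedback1d", "stabilize1d"))
      benchmark_problem(n_partners = 1) else benchmark_problem()
  stopifnot(inherits(problem, "couple_problem"), inherits(config, "solver_config"))
  structure(list(tag = tag, problem = problem, config = config,
                 a2_values = a2_values, shocks = shocks, x0 = x0,
                 out_dir = out_dir),
            class = "experiment_spec")
}

#' Run a canned experiment
#'
#' Executes the analysis named by the spec's tag and writes its artifacts
#' (CSV tables, JSON summaries) plus a manifest recording inputs, a config
#' hash and the output files with their checksums. Reruns of an identical
#' spec produce identical artifacts: the pipeline has no randomness.
#'
#' @param spec an [experiment_spec()].
#' @return The manifest (list), invisibly also written as
#'   `manifest.json` in the output directory.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
  outfile <- function(name) file.path(spec$out_dir, name)
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }

  grid <- seq(spec$problem$x_lo, spec$problem$x_hi, length.out = 201)
  tag <- spec$tag
  if (tag %in% c("feedback1d", "stabilize1d")) {
    sol <- solve_hjb(spec$problem, spec$config)
    curves <- data.frame(x = grid, S = strategy_fn(sol, 1)(grid),
                         v = value_fn(sol, 1)(grid))
    utils::write.csv(curves, emit(outfile("curves.csv")), row.names = FALSE)
    n <- spec$shocks$horizon
    base <- simulate_couple(sol, spec$x0, n = n)
    write_trajectory_csv(base, emit(outfile("trajectory.csv")))
    if (tag == "feedback1d") {
      sh <- shoot_initial_effort(spec$x0, spec$problem$partners[[1]], spec$problem$r)
      utils::write.csv(sh$path, emit(outfile("stable_manifold.csv")), row.names = FALSE)
      jsonlite::write_json(list(c0 = sh$c0, equilibrium = list(x = sh$equilibrium$x,
                                                               c = sh$equilibrium$c)),
                           emit(outfile("shooting.json")), auto_unbox = TRUE, digits = NA)
    } else {
      write_shocks_json(spec$shocks, emit(outfile("shocks.json")))
      pert <- simulate_with_shocks(sol, spec$x0, spec$shocks)
      write_trajectory_csv(pert, emit(outfile("trajectory_perturbed.csv")))
    }
  } else if (tag %in% c("heterogamy", "equilibria")) {
    sweep_tab <- heterogamy_sweep(spec$a2_values, spec$problem, spec$config,
                                  x0 = spec$x0)
    utils::write.csv(sweep_tab, emit(outfile("sweep.csv")), row.names = FALSE)
    sols <- attr(sweep_tab, "solutions")
    if (tag == "heterogamy") {
      for (j in seq_along(spec$a2_values)) {
        if (is.null(sols[[j]])) next
        cur <- data.frame(x = grid,
                          S1 = strategy_fn(sols[[j]], 1)(grid),
                          S2 = strategy_fn(sols[[j]], 2)(grid),
                          v1 = value_fn(sols[[j]], 1)(grid),
                          v2 = value_fn(sols[[j]], 2)(grid))
        utils::write.csv(cur, emit(outfile(sprintf("curves_a2_%g.csv", spec$a2_values[j]))),
                         row.names = FALSE)
      }
    }
  } else if (tag == "stabilize2d") {
    trio <- if (length(spec$a2_values) == 8) c(0.5, 1, 1.5) else spec$a2_values
    write_shocks_json(spec$shocks, emit(outfile("shocks.json")))
    for (a2 in trio) {
      prob <- spec$problem
      prob$partners[[2]]$a <- a2
      sol <- solve_hjb(prob, spec$config)
      base <- simulate_couple(sol, spec$x0, n = spec$shocks$horizon)
      pert <- simulate_with_shocks(sol, spec$x0, spec$shocks)
      write_trajectory_csv(base, emit(outfile(sprintf("trajectory_a2_%g.csv", a2))))
      write_trajectory_csv(pert, emit(outfile(sprintf("trajectory_perturbed_a2_%g.csv", a2))))
    }
  } else if (tag == "recovery") {
    a2s <- if (length(spec$a2_values) == 8) c(1.75, 1.5, 1, 0.75, 0.5) else spec$a2_values
    tab <- recovery_table(a2s, problem = spec$problem, config = spec$config)
    utils::write.csv(tab, emit(outfile("recovery.csv")), row.names = FALSE)
  } else {                               # custom: solve + emit curves only
    sol <- solve_hjb(spec$problem, spec$config)
    write_solution(sol, json_path = emit(outfile("solution.json")),
                   csv_path = emit(outfile("solution.csv")))
  }

  cfg_tmp <- tempfile(fileext = ".json")
  spec_desc <- list(tag = tag, x0 = spec$x0,
                    a2_values = spec$a2_values,
                    shocks = unclass(spec$shocks),
                    h = spec$config$h, Q = length(spec$config$nodes),
                    problem = couple_problem_digest(spec$problem))
  jsonlite::write_json(spec_desc, cfg_tmp, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tag = tag,
    spec = spec_desc,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    files = lapply(files, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

couple_problem_digest <- function(problem) {
  list(r = problem$r, x_lo = problem$x_lo, x_hi = problem$x_hi,
       x_min = problem$x_min,
       partners = lapply(problem$partners, function(p)
         list(rho = p$rho, a = p$a, utility = p$utility$family,
              alpha = p$utility$alpha, cost = p$cost$family,
              cstar = p$cost$cstar, w = p$cost$w)))
}

#' Write a set of tables as CSV files
#'
#' @param tables named list of data frames.
#' @param directory output directory (created if missing).
#' @return Character vector of written paths.
#' @export
write_outputs <- function(tables, directory) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(tables))
  for (j in seq_along(tables)) {
    paths[j] <- file.path(directory, paste0(names(tables)[j], ".csv"))
    utils::write.csv(tables[[j]], paths[j], row.names = FALSE)
  }
  paths
}
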