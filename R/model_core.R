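#' Utility-of-feeling curve
#'
#' Instantaneous utility a partner derives from the feeling level `x`.
#' The default family is logarithmic, `U(x) = alpha * log(x + 1)`, which is
#' increasing, strictly concave and satiating (`U'(x) -> 0` as `x` grows) —
#' the structural assumptions the model places on utility. A user-supplied
#' smooth function can be given instead; its first and second derivatives are
#' then taken by central differences unless supplied.
#'
#' @param alpha scale coefficient of the log family, in well-being units
#'   (default 5, the bundled benchmark configuration).
#' @param fn optional function of `x`; switches the curve to the `"custom"`
#'   family.
#' @param d1,d2 optional first and second derivative functions for a custom
#'   curve; finite differences are used when missing.
#' @return An object of class `utility_curve` with elements `family`,
#'   `alpha`, and evaluators `fn`, `d1`, `d2`.
#' @examples
#' U <- utility_curve(alpha = 5)
#' U$fn(3)        # 5 * log(4)
#' @export
utility_curve <- function(alpha = 5, fn = NULL, d1 = NULL, d2 = NULL) {
  if (is.null(fn)) {
    force(alpha)
    obj <- list(
      family = "log", alpha = alpha,
      fn = function(x) alpha * log1p(x),
      d1 = function(x) alpha / (x + 1),
      d2 = function(x) -alpha / (x + 1)^2
    )
  } else {
    stopifnot(is.function(fn))
    if (is.null(d1)) d1 <- function(x) (fn(x + 1e-5) - fn(x - 1e-5)) / 2e-5
    if (is.null(d2)) d2 <- function(x) (fn(x + 1e-4) - 2 * fn(x) + fn(x - 1e-4)) / 1e-8
    obj <- list(family = "custom", alpha = NA_real_, fn = fn, d1 = d1, d2 = d2)
  }
  structure(obj, class = "utility_curve")
}

#' Effort disutility curve
#'
#' Cost of exerting effort `c`. The default family is quadratic,
#' `D(c) = w/2 * (c - cstar)^2`: zero and flat at the preferred effort
#' `cstar`, strictly convex, so effort beyond the preferred level is
#' increasingly painful.
#'
#' @param cstar preferred effort level (effort units, `>= 0`).
#' @param w curvature weight (`> 0`).
#' @param fn optional custom smooth convex function of `c`.
#' @param d1,d2 optional derivatives of a custom curve.
#' @return An object of class `effort_cost`.
#' @examples
#' D <- effort_cost(cstar = 0.2)
#' D$fn(1.2)      # 0.5
#' @export
effort_cost <- function(cstar = 0.2, w = 1, fn = NULL, d1 = NULL, d2 = NULL) {
  stopifnot(cstar >= 0, w > 0)
  if (is.null(fn)) {
    force(cstar); force(w)
    obj <- list(
      family = "quadratic", cstar = cstar, w = w,
      fn = function(c) 0.5 * w * (c - cstar)^2,
      d1 = function(c) w * (c - cstar),
      d2 = function(c) rep(w, length(c))
    )
  } else {
    stopifnot(is.function(fn))
    if (is.null(d1)) d1 <- function(c) (fn(c + 1e-5) - fn(c - 1e-5)) / 2e-5
    if (is.null(d2)) d2 <- function(c) (fn(c + 1e-4) - 2 * fn(c) + fn(c - 1e-4)) / 1e-8
    obj <- list(family = "custom", cstar = cstar, w = w, fn = fn, d1 = d1, d2 = d2)
  }
  structure(obj, class = "effort_cost")
}

#' Partner specification
#'
#' Bundles one partner's preferences and dynamics coupling: the time
#' preference rate `rho` (per unit time), the effort efficiency `a`
#' (feeling units created per effort unit per unit time), the utility curve
#' and the effort cost.
#'
#' @param rho time-preference (discount) rate, `> 0`.
#' @param a effort efficiency, finite and `>= 0`.
#' @param utility a [utility_curve()].
#' @param cost an [effort_cost()].
#' @return An object of class `partner_spec`.
#' @export
partner_spec <- function(rho = 0.1, a = 1,
                         utility = utility_curve(), cost = effort_cost()) {
  # rho = 0 is constructible so validate_problem() can flag it; the solver
  # itself refuses undiscounted problems
  stopifnot(is.numeric(rho), length(rho) == 1, rho >= 0,
            is.numeric(a), length(a) == 1, is.finite(a), a >= 0,
            inherits(utility, "utility_curve"), inherits(cost, "effort_cost"))
  structure(list(rho = rho, a = a, utility = utility, cost = cost),
            class = "partner_spec")
}

#' Couple effort-game definition
#'
#' A full game: feeling decay rate `r`, one partner (the couple treated as a
#' unit, the 1D problem) or two partners (the 2D game), the feeling domain
#' and the viability threshold `x_min` below which the relationship is
#' considered no longer viable (it only sets a breakdown flag in simulated
#' trajectories; computation never halts).
#'
#' @param r feeling decay rate, `> 0` (per unit time).
#' @param partners a single [partner_spec()] or a list of one or two.
#' @param x_lo,x_hi feeling domain bounds.
#' @param x_min viability threshold, within the domain.
#' @return An object of class `couple_problem`.
#' @examples
#' prob <- couple_problem()          # benchmark 2-player configuration
#' prob1 <- benchmark_problem(n_partners = 1)
#' @export
couple_problem <- function(r = 2, partners = list(partner_spec(), partner_spec()),
                           x_lo = 0, x_hi = 5, x_min = 0) {
  if (inherits(partners, "partner_spec")) partners <- list(partners)
  stopifnot(is.numeric(r), length(r) == 1, r > 0,
            is.list(partners), length(partners) %in% c(1L, 2L),
            all(vapply(partners, inherits, TRUE, "partner_spec")),
            x_lo < x_hi, x_min >= x_lo, x_min <= x_hi)
  structure(list(r = r, partners = partners,
                 x_lo = x_lo, x_hi = x_hi, x_min = x_min),
            class = "couple_problem")
}

#' Benchmark problem configuration
#'
#' The bundled default configuration: `r = 2`, `rho_i = 0.1`, `a_i = 1`,
#' `U_i(x) = 5 log(x + 1)`, `D_i(c) = (c - 0.2)^2 / 2`, feeling domain
#' `[0, 5]`.
#'
#' @param n_partners 1 (couple-as-unit problem) or 2 (dyadic game).
#' @param a1,a2 effort efficiencies.
#' @return A [couple_problem()].
#' @export
benchmark_problem <- function(n_partners = 2, a1 = 1, a2 = 1) {
  ps <- list(partner_spec(a = a1))
  if (n_partners == 2) ps <- c(ps, list(partner_spec(a = a2)))
  couple_problem(r = 2, partners = ps)
}

#' @export
print.couple_problem <- function(x, ...) {
  np <- length(x$partners)
  cat(sprintf("<couple_problem> %d-player, r = %g, domain [%g, %g], x_min = %g\n",
              np, x$r, x$x_lo, x$x_hi, x$x_min))
  for (i in seq_len(np)) {
    p <- x$partners[[i]]
    cat(sprintf("  partner %d: rho = %g, a = %g, U = %s%s, D = %s (c* = %g, w = %g)\n",
                i, p$rho, p$a, p$utility$family,
                if (p$utility$family == "log") sprintf(" (alpha = %g)", p$utility$alpha) else "",
                p$cost$family, p$cost$cstar, p$cost$w))
  }
  invisible(x)
}

#' Feeling drift
#'
#' Rate of change of the feeling: `-r*x + a1*c1 + a2*c2` (or `-r*x + a*c`
#' for a single-partner problem). Effort counteracts the natural decay.
#'
#' @param x feeling level.
#' @param c1 effort of partner 1 (`>= 0`).
#' @param c2 effort of partner 2 (`>= 0`); ignored for 1-player problems.
#' @param problem a [couple_problem()].
#' @return Drift value(s), vectorized over the inputs.
#' @export
drift <- function(x, c1, c2 = NULL, problem = couple_problem()) {
  stopifnot(inherits(problem, "couple_problem"))
  if (any(c1 < 0)) stop("effort c1 must be non-negative")
  out <- -problem$r * x + problem$partners[[1]]$a * c1
  if (length(problem$partners) == 2) {
    if (is.null(c2)) stop("c2 required for a 2-player problem")
    if (any(c2 < 0)) stop("effort c2 must be non-negative")
    out <- out + problem$partners[[2]]$a * c2
  }
  out
}

#' Instantaneous well-being rate
#'
#' `U(x) - D(c)` for one partner: benefit of the current feeling minus the
#' cost of the current effort.
#'
#' @param x feeling level (`>= 0`).
#' @param c effort (`>= 0`).
#' @param partner a [partner_spec()].
#' @export
instantaneous_payoff <- function(x, c, partner = partner_spec()) {
  stopifnot(inherits(partner, "partner_spec"))
  if (any(x < 0)) stop("feeling x must be non-negative")
  if (any(c < 0)) stop("effort c must be non-negative")
  partner$utility$fn(x) - partner$cost$fn(c)
}

#' Validate the structural assumptions of a problem
#'
#' Checks each structural assumption of the model on sample grids —
#' utility increasing and concave with vanishing marginal utility, cost
#' convex with an interior minimum at the preferred effort, positive
#' discounting and decay, non-negative efficiencies, well-ordered domain —
#' and reports pass/fail per check. Failures are reported, never raised.
#'
#' @param problem a [couple_problem()].
#' @return A data frame of class `validation_report` with columns `check`,
#'   `partner`, `pass`, `detail`.
#' @export
validate_problem <- function(problem) {
  stopifnot(inherits(problem, "couple_problem"))
  rows <- list()
  add <- function(check, partner, pass, detail = "") {
    rows[[length(rows) + 1]] <<- data.frame(check = check, partner = partner,
                                            pass = pass, detail = detail,
                                            stringsAsFactors = FALSE)
  }
  add("decay rate r > 0", NA_integer_, problem$r > 0, sprintf("r = %g", problem$r))
  add("domain well-ordered", NA_integer_, problem$x_lo < problem$x_hi,
      sprintf("[%g, %g]", problem$x_lo, problem$x_hi))
  add("x_min within domain", NA_integer_,
      problem$x_min >= problem$x_lo && problem$x_min <= problem$x_hi,
      sprintf("x_min = %g", problem$x_min))
  xg <- seq(max(problem$x_lo, 0), max(problem$x_hi, 1), length.out = 101)
  for (i in seq_along(problem$partners)) {
    p <- problem$partners[[i]]
    add("discount rate rho > 0", i, p$rho > 0, sprintf("rho = %g", p$rho))
    add("efficiency a finite and >= 0", i, is.finite(p$a) && p$a >= 0,
        sprintf("a = %g", p$a))
    u <- p$utility$fn(xg)
    add("utility increasing (U' > 0)", i, all(diff(u) > 0))
    add("utility concave (U'' < 0)", i, all(diff(diff(u)) < 0))
    add("marginal utility vanishing", i,
        p$utility$d1(1e3) < p$utility$d1(10) &&
          abs(p$utility$d1(1e3)) < 0.1 * abs(p$utility$d1(0) + 1e-12))
    cg <- seq(0, max(2 * p$cost$cstar + 1, 5), length.out = 101)
    d <- p$cost$fn(cg)
    add("cost convex (D'' > 0)", i, all(diff(diff(d)) > 0))
    add("cost minimal and flat at c*", i,
        abs(p$cost$fn(p$cost$cstar)) < 1e-10 && abs(p$cost$d1(p$cost$cstar)) < 1e-8)
  }
  rep <- do.call(rbind, rows)
  class(rep) <- c("validation_report", "data.frame")
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  status <- ifelse(x$pass, "PASS", "FAIL")
  who <- ifelse(is.na(x$partner), "", sprintf(" [partner %d]", x$partner))
  cat(sprintf("%-34s%s: %s %s\n", x$check, who, status, x$detail), sep = "")
  cat(sprintf("%d/%d checks passed\n", sum(x$pass), nrow(x)))
  invisible(x)
}

#' Read a problem definition from a JSON config file
#'
#' Recognized fields: `r`, `a1`, `a2`, `rho1`, `rho2`, `cstar1`, `cstar2`,
#' `alpha1`, `alpha2`, `w1`, `w2`, `x_lo`, `x_hi`, `x_min`. A second partner
#' is created when any field ending in `2` is present (or `n_partners = 2`
#' is given). Missing fields fall back to the benchmark defaults.
#'
#' @param path path to a JSON file.
#' @return A [couple_problem()].
#' @seealso [write_problem_config()]
#' @export
read_problem_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- function(name, default) if (!is.null(cfg[[name]])) cfg[[name]] else default
  two <- isTRUE(g("n_partners", NA) == 2) ||
    any(c("a2", "rho2", "cstar2", "alpha2", "w2") %in% names(cfg))
  mk <- function(i) partner_spec(
    rho = g(paste0("rho", i), 0.1), a = g(paste0("a", i), 1),
    utility = utility_curve(alpha = g(paste0("alpha", i), 5)),
    cost = effort_cost(cstar = g(paste0("cstar", i), 0.2), w = g(paste0("w", i), 1))
  )
  partners <- if (two) list(mk(1), mk(2)) else list(mk(1))
  couple_problem(r = g("r", 2), partners = partners,
                 x_lo = g("x_lo", 0), x_hi = g("x_hi", 5), x_min = g("x_min", 0))
}

#' Write a problem definition to a JSON config file
#'
#' Inverse of [read_problem_config()] for problems using the log/quadratic
#' families.
#'
#' @param problem a [couple_problem()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_problem_config <- function(problem, path) {
  stopifnot(inherits(problem, "couple_problem"))
  cfg <- list(r = problem$r, x_lo = problem$x_lo, x_hi = problem$x_hi,
              x_min = problem$x_min, n_partners = length(problem$partners))
  for (i in seq_along(problem$partners)) {
    p <- problem$partners[[i]]
    if (p$utility$family != "log" || p$cost$family != "quadratic")
      stop("only log/quadratic problems are serializable to config files")
    cfg[[paste0("rho", i)]] <- p$rho
    cfg[[paste0("a", i)]] <- p$a
    cfg[[paste0("alpha", i)]] <- p$utility$alpha
    cfg[[paste0("cstar", i)]] <- p$cost$cstar
    cfg[[paste0("w", i)]] <- p$cost$w
  }
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
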