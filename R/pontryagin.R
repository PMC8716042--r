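#' Effort-feeling phase field of the 1D problem
#'
#' The two-dimensional vector field obtained from the maximum principle for
#' the couple-as-a-unit problem:
#' `dx/dt = -r*x + a*c`,
#' `dc/dt = (1/D''(c)) * ((r + rho) * D'(c) - a * U'(x))`.
#' Its unique rest point is the long-run equilibrium of the optimal
#' relationship; the optimal trajectory is the stable manifold through it.
#'
#' @param x feeling level (`> -1` for the log utility family).
#' @param c effort level.
#' @param partner a [partner_spec()].
#' @param r feeling decay rate.
#' @return Numeric `c(dx, dc)`.
#' @examples
#' phase_field(3, 1.087, partner_spec(), r = 2)   # ~ (-4.913, 0.6127)
#' @export
phase_field <- function(x, c, partner = partner_spec(), r = 2) {
  d2 <- partner$cost$d2(c)
  if (any(abs(d2) < 1e-14)) stop("D''(c) = 0: phase field undefined")
  dx <- -r * x + partner$a * c
  dc <- ((r + partner$rho) * partner$cost$d1(c) - partner$a * partner$utility$d1(x)) / d2
  c(dx, dc)
}

#' Fixed-step RK4 integration of the phase system
#'
#' Classical fourth-order Runge-Kutta path of the effort-feeling system,
#' integrated in chunks so that a trajectory escaping a bounding tube
#' around the start/equilibrium region (or going non-finite) is truncated
#' and flagged rather than propagated.
#'
#' @param x0,c0 initial feeling and effort.
#' @param partner a [partner_spec()].
#' @param r decay rate.
#' @param step RK4 step size (default `1e-3`).
#' @param n_steps number of steps.
#' @param tube truncate when `max(|x - x0|, |c - c0|)` exceeds this radius
#'   (default `Inf`: no truncation).
#' @return A data frame `t, x, c` with attribute `truncated`.
#' @export
rk4_integrate <- function(x0, c0, partner = partner_spec(), r = 2,
                          step = 1e-3, n_steps = 1000, tube = Inf) {
  stopifnot(step > 0, n_steps >= 1)
  field <- function(t, state, parms) {
    if (!all(is.finite(state)) || state[1] <= -1 + 1e-12)
      return(list(c(0, 0)))
    list(phase_field(state[1], state[2], partner, r))
  }
  chunk <- max(50L, min(n_steps, 500L))
  out <- matrix(NA_real_, n_steps + 1, 3,
                dimnames = list(NULL, c("t", "x", "c")))
  out[1, ] <- c(0, x0, c0)
  done <- 1L
  truncated <- FALSE
  while (done <= n_steps) {
    m <- min(chunk, n_steps - done + 1L)
    times <- (seq(0, m)) * step + out[done, "t"]
    seg <- deSolve::rk(y = c(x = unname(out[done, "x"]), c = unname(out[done, "c"])),
                       times = times, func = field, parms = NULL,
                       method = "rk4")
    rows <- done + seq_len(m)
    out[rows, "t"] <- seg[-1, "time"]
    out[rows, "x"] <- seg[-1, "x"]
    out[rows, "c"] <- seg[-1, "c"]
    bad <- !is.finite(out[rows, "x"]) | !is.finite(out[rows, "c"]) |
      pmax(abs(out[rows, "x"] - x0), abs(out[rows, "c"] - c0)) > tube |
      out[rows, "x"] <= -1 + 1e-9
    if (any(bad)) {
      cut <- rows[which(bad)[1]]
      out <- out[seq_len(cut), , drop = FALSE]
      truncated <- TRUE
      break
    }
    done <- done + m
  }
  df <- as.data.frame(out[stats::complete.cases(out), , drop = FALSE])
  attr(df, "truncated") <- truncated
  df
}

#' Stationary equilibrium of the 1D effort problem
#'
#' Solves the stationarity conditions `-r*x + a*c = 0` and
#' `(r + rho) * D'(c) = a * U'(x)`. For the log/quadratic family this
#' reduces to a single quadratic in `c` (solved in closed form, positive
#' root); other smooth families are handled by monotone root bracketing of
#' the reduced one-dimensional condition.
#'
#' @param partner a [partner_spec()].
#' @param r decay rate.
#' @return An object of class `equilibrium_1d`: `x`, `c`, `eigenvalues`,
#'   `classification`, `residual`.
#' @examples
#' eq <- equilibrium_closed_form(partner_spec(), r = 2)
#' c(eq$x, eq$c)    # ~ (0.7719, 1.5437)
#' @export
equilibrium_closed_form <- function(partner = partner_spec(), r = 2) {
  stopifnot(inherits(partner, "partner_spec"), r > 0)
  a <- partner$a; rho <- partner$rho
  if (a == 0) {
    cbar <- partner$cost$cstar
    xbar <- 0
  } else if (partner$utility$family == "log" && partner$cost$family == "quadratic") {
    alpha <- partner$utility$alpha
    cstar <- partner$cost$cstar
    w <- partner$cost$w
    # (r+rho) w (c - c*) (a c / r + 1) = a alpha  =>
    # (a/r) c^2 + (1 - a c*/r) c - c* - a alpha / ((r+rho) w) = 0
    A <- a / r
    B <- 1 - a * cstar / r
    Cc <- -cstar - a * alpha / ((r + rho) * w)
    disc <- B^2 - 4 * A * Cc
    if (disc < 0) stop("no real stationary effort")
    cbar <- (-B + sqrt(disc)) / (2 * A)
    if (cbar <= 0) stop("no positive stationary effort")
    xbar <- a * cbar / r
  } else {
    g <- function(cc) (r + rho) * partner$cost$d1(cc) -
      a * partner$utility$d1(a * cc / r)
    hi <- 1
    while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
    if (g(hi) < 0) stop("no positive stationary effort found")
    cbar <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
    xbar <- a * cbar / r
  }
  resid <- max(abs(phase_field(xbar, cbar, partner, r)))
  eq <- structure(list(x = xbar, c = cbar, residual = resid,
                       eigenvalues = NULL, classification = NULL),
                  class = "equilibrium_1d")
  cls <- classify_saddle(eq, partner, r)
  eq$eigenvalues <- cls$eigenvalues
  eq$classification <- cls$classification
  eq
}

#' @export
print.equilibrium_1d <- function(x, ...) {
  cat(sprintf("<equilibrium_1d> x = %.6f, c = %.6f (%s; eigenvalues %.4f, %.4f)\n",
              x$x, x$c, x$classification, x$eigenvalues[1], x$eigenvalues[2]))
  invisible(x)
}

#' Classify the 1D equilibrium
#'
#' Eigenvalues of the phase-system Jacobian
#' `[[-r, a], [-a*U''(x)/D''(c), r + rho]]` at the equilibrium. With a
#' concave utility the determinant is negative, so the rest point is a
#' saddle: the optimal path is the unique trajectory on its stable
#' manifold.
#'
#' @param eq an [equilibrium_closed_form()] result (or list with `x`, `c`).
#' @param partner a [partner_spec()].
#' @param r decay rate.
#' @return List with `eigenvalues` (ascending), `classification`
#'   (`"saddle"` or `"other"`), `jacobian`, and `stable_slope` — the
#'   `dc/dx` slope of the stable eigenvector (the linearized feedback
#'   slope at the equilibrium).
#' @export
classify_saddle <- function(eq, partner = partner_spec(), r = 2) {
  J <- rbind(c(-r, partner$a),
             c(-partner$a * partner$utility$d2(eq$x) / partner$cost$d2(eq$c),
               r + partner$rho))
  ev <- eigen(J, only.values = FALSE)
  ord <- order(Re(ev$values))
  lam <- ev$values[ord]
  saddle <- is.numeric(lam) && all(Im(lam) == 0) && Re(lam[1]) < 0 && Re(lam[2]) > 0
  vstable <- Re(ev$vectors[, ord[1]])
  slope <- if (abs(vstable[1]) > 1e-14) vstable[2] / vstable[1] else Inf
  list(eigenvalues = Re(lam),
       classification = if (saddle) "saddle" else "other",
       jacobian = J, stable_slope = slope)
}

#' Stable-manifold shooting for the initial effort
#'
#' Finds the initial effort `c(0)` whose phase trajectory stays in a
#' bounded tube and converges to the saddle equilibrium — i.e. lies on the
#' stable manifold. Bisection on `c(0)` classifies each trial path by the
#' sign of its component along the unstable eigen-direction once it leaves
#' a neighbourhood of the equilibrium (or at the end of the horizon).
#'
#' @param x0 initial feeling, `> 0`.
#' @param partner a [partner_spec()].
#' @param r decay rate.
#' @param c_bracket bisection bracket for `c(0)` (default `c(0, 5)`).
#' @param horizon integration horizon in time units (default 10).
#' @param step RK4 step (default `1e-3`).
#' @param tol bisection tolerance on `c(0)` (default `1e-6`).
#' @return List with `c0`, the shot `path` (data frame `t, x, c`), and the
#'   `equilibrium` used.
#' @examples
#' \donttest{
#' sh <- shoot_initial_effort(3)
#' sh$c0    # ~ 1.087
#' }
#' @export
shoot_initial_effort <- function(x0, partner = partner_spec(), r = 2,
                                 c_bracket = c(0, 5), horizon = 10,
                                 step = 1e-3, tol = 1e-6) {
  stopifnot(x0 > 0)
  eq <- equilibrium_closed_form(partner, r)
  if (eq$classification != "saddle")
    stop("equilibrium is not a saddle; shooting undefined")
  cls <- classify_saddle(eq, partner, r)
  J <- cls$jacobian
  evl <- eigen(t(J))
  iu <- which.max(Re(evl$values))
  lu <- Re(evl$vectors[, iu])            # left eigenvector of the unstable mode
  # orient so that raising c(0) raises the unstable coefficient
  if (lu[2] < 0) lu <- -lu
  tube <- 5 * (abs(x0) + abs(eq$x) + 1)
  n_steps <- ceiling(horizon / step)
  side <- function(c0) {
    path <- rk4_integrate(x0, c0, partner, r, step = step, n_steps = n_steps,
                          tube = tube)
    endx <- path$x[nrow(path)]; endc <- path$c[nrow(path)]
    s <- lu[1] * (endx - eq$x) + lu[2] * (endc - eq$c)
    sign(s)
  }
  lo <- c_bracket[1]; hi <- c_bracket[2]
  slo <- side(lo); shi <- side(hi)
  if (slo == shi)
    stop(sprintf("shooting bracket [%g, %g] does not straddle the stable manifold",
                 lo, hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (side(mid) == slo) lo <- mid else hi <- mid
  }
  c0 <- (lo + hi) / 2
  path <- rk4_integrate(x0, c0, partner, r, step = step, n_steps = n_steps,
                        tube = tube)
  # the residual unstable component eventually throws the shot path off the
  # manifold; truncate at the closest approach to the equilibrium
  d2 <- (path$x - eq$x)^2 + (path$c - eq$c)^2
  path <- path[seq_len(which.min(d2)), , drop = FALSE]
  list(c0 = c0, path = path, equilibrium = eq)
}
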