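#' Build the lattice transition-rate matrix from a free-energy landscape
#'
#' Discretizes the kinetic transition kernel
#' \deqn{W(x \leftarrow x') = \exp[-(x-x')^2/\Delta]\,
#'       \exp\{-(\beta/2)[F(x) - F(x')]\}}
#' on a uniform lattice. `W[i, j]` is the rate *from* lattice point `j`
#' *to* point `i` (column-generator layout, so propagation is a plain
#' matrix-vector product); diagonals are set to minus the column sums so
#' that every column sums to zero (gain-loss balance, hence exact
#' probability conservation). The kernel satisfies detailed balance with
#' respect to the Boltzmann distribution `exp(-beta * F)` by construction.
#'
#' Off-diagonal entries are kept within `cutoff` lattice neighbors; by
#' default the cutoff is where the Gaussian factor falls below `1e-12`.
#' Boundary columns simply have fewer neighbors (reflecting-by-truncation).
#'
#' @param landscape A [free_energy_landscape()].
#' @param xs Uniformly spaced lattice of state points, length `>= 3`.
#' @param Delta Spatial kernel width, `> 0` (state^2 units).
#' @param beta Inverse temperature, `> 0`.
#' @param cutoff Neighbor range in lattice units, integer `>= 1`, or
#'   `NULL` for the default rule.
#' @param gamma Anomalous exponent stored for propagation,
#'   `0 < gamma <= 1`.
#' @return An object of class `lattice_gme` with elements `xs`, `W`,
#'   `Delta`, `beta`, `gamma`, `F_lattice`.
#' @examples
#' g <- build_rate_matrix(landscape_quadratic(), xs = seq(-2, 2, 0.5),
#'                        Delta = 0.25, beta = 1)
#' colSums(g$W)   # all (numerically) zero
#' @export
build_rate_matrix <- function(landscape, xs, Delta, beta, cutoff = NULL,
                              gamma = 1) {
  if (!inherits(landscape, "free_energy_landscape"))
    tfk_domain_error("`landscape` must be a `free_energy_landscape`")
  if (!is.numeric(xs) || length(xs) < 3L)
    tfk_domain_error("`xs` must be a numeric lattice of length >= 3")
  dxs <- diff(xs)
  dx <- dxs[1]
  if (dx <= 0 || any(abs(dxs - dx) > 1e-9 * abs(dx)))
    tfk_domain_error("`xs` must be uniformly spaced and increasing")
  stopifnot_scalar(Delta, "Delta"); stopifnot_scalar(beta, "beta")
  stopifnot_scalar(gamma, "gamma")
  if (Delta <= 0) tfk_domain_error("`Delta` must be > 0")
  if (beta <= 0) tfk_domain_error("`beta` must be > 0")
  if (gamma <= 0 || gamma > 1)
    tfk_domain_error("`gamma` must lie in (0, 1]", gamma = gamma)
  N <- length(xs)
  Fx <- vapply(xs, landscape$f, numeric(1))
  if (any(!is.finite(Fx)))
    tfk_domain_error("free energy not finite on the lattice")
  if (is.null(cutoff)) {
    cutoff <- max(1L, sum(exp(-(dx * seq_len(N - 1L))^2 / Delta) >= 1e-12))
  }
  if (cutoff < 1L) tfk_domain_error("`cutoff` must be >= 1")
  W <- matrix(0, N, N)
  for (k in seq_len(min(cutoff, N - 1L))) {
    gk <- exp(-(dx * k)^2 / Delta)
    i <- seq_len(N - k)
    # j -> i transitions at lag k, both directions
    W[cbind(i, i + k)] <- gk * exp(-(beta / 2) * (Fx[i] - Fx[i + k]))
    W[cbind(i + k, i)] <- gk * exp(-(beta / 2) * (Fx[i + k] - Fx[i]))
  }
  diag(W) <- 0
  diag(W) <- -colSums(W)
  structure(list(xs = xs, W = W, Delta = Delta, beta = beta, gamma = gamma,
                 F_lattice = Fx, cutoff = as.integer(cutoff)),
            class = "lattice_gme")
}

#' @export
print.lattice_gme <- function(x, ...) {
  cat(sprintf(
    "Lattice GME: %d points on [%g, %g], Delta = %g, beta = %g, gamma = %g\n",
    length(x$xs), min(x$xs), max(x$xs), x$Delta, x$beta, x$gamma))
  cat(sprintf("  neighbor cutoff %d, max loss rate %g\n",
              x$cutoff, max(abs(diag(x$W)))))
  invisible(x)
}

#' Probability field on the lattice
#'
#' A probability mass vector over lattice points with a time stamp.
#' Validates non-negativity (to scheme-undershoot tolerance) and unit
#' total mass.
#'
#' @param values Probability masses, one per lattice point.
#' @param t Time stamp.
#' @return An object of class `probability_field`.
#' @export
probability_field <- function(values, t = 0) {
  if (!is.numeric(values) || any(!is.finite(values)))
    tfk_domain_error("`values` must be finite and numeric")
  if (any(values < -1e-12))
    tfk_domain_error("`values` must be >= 0 (within undershoot tolerance)")
  if (abs(sum(values) - 1) > 1e-10)
    tfk_domain_error("`values` must sum to 1 within 1e-10")
  structure(list(values = as.numeric(values), t = t),
            class = "probability_field")
}

#' @export
print.probability_field <- function(x, ...) {
  cat(sprintf("Probability field at t = %g over %d points (mass %.12f)\n",
              x$t, length(x$values), sum(x$values)))
  invisible(x)
}

#' Propagate the time-fractional lattice master equation
#'
#' Advances \eqn{\partial P/\partial t = D^{1-\gamma}[W P]} with the
#' explicit Grunwald-Letnikov discretization of the Riemann-Liouville
#' operator acting on the full history of `W P`:
#' \deqn{P^{m+1} = P^m + dt^{\gamma} \sum_{k=0}^{m} w_k^{(1-\gamma)}
#'       (W P)^{m-k}.}
#' Total mass is conserved exactly (columns of `W` sum to zero). For
#' `gamma = 1` the weights collapse to `(1, 0, 0, ...)` and the scheme is
#' the classical forward-Euler master-equation step.
#'
#' A stability guard warns when `dt^gamma * max|W_jj| > 0.5` and aborts
#' (with the maximal stable `dt` estimate in the message) if any
#' component of `P` exceeds 2 in magnitude.
#'
#' @param gme A [build_rate_matrix()] object.
#' @param p0 Initial [probability_field()] (or a bare numeric vector
#'   summing to 1).
#' @param grid A [uniform_grid()] with `t0 = 0`.
#' @return Object of class `gme_evolution`: list with `times` and an
#'   `(n_steps + 1) x N` matrix `P` of fields (rows are times).
#' @examples
#' g <- build_rate_matrix(landscape_flat(c(-5, 5)), xs = seq(-5, 5, 1),
#'                        Delta = 1, beta = 1, gamma = 0.5)
#' p0 <- replace(numeric(11), 6, 1)
#' ev <- propagate_gme(g, p0, uniform_grid(dt = 0.1, n_steps = 50))
#' @export
propagate_gme <- function(gme, p0, grid) {
  if (!inherits(gme, "lattice_gme"))
    tfk_domain_error("`gme` must be a `lattice_gme` object")
  if (inherits(p0, "probability_field")) p0 <- p0$values
  p0 <- probability_field(p0)$values     # validates
  if (!inherits(grid, "uniform_grid") || grid$t0 != 0)
    tfk_domain_error("`grid` must be a `uniform_grid` with t0 = 0")
  N <- length(gme$xs)
  if (length(p0) != N)
    tfk_domain_error("`p0` length must match the lattice")
  n <- grid$n_steps
  dt <- grid$dt
  g <- gme$gamma
  dtg <- dt^g
  maxloss <- max(abs(diag(gme$W)))
  if (dtg * maxloss > 0.5)
    warning(sprintf(
      "explicit GL step may be unstable: dt^gamma * max|W_jj| = %.3g > 0.5 (stable dt <= %.3g)",
      dtg * maxloss, (0.5 / maxloss)^(1 / g)))
  w <- gl_weights(1 - g, n)
  P <- matrix(0, n + 1L, N)
  P[1L, ] <- p0
  H <- matrix(0, N, n + 1L)              # history of W %*% P
  H[, 1L] <- gme$W %*% p0
  for (m in 0:(n - 1L)) {
    incr <- dtg * as.numeric(H[, (m + 1L):1L, drop = FALSE] %*% w[1:(m + 1L)])
    pn <- P[m + 1L, ] + incr
    if (any(abs(pn) > 2))
      tfk_eval_error(sprintf(
        "propagation unstable at step %d; reduce dt (estimated stable dt <= %.3g)",
        m + 1L, (0.5 / maxloss)^(1 / g)), step = m + 1L)
    P[m + 2L, ] <- pn
    H[, m + 2L] <- gme$W %*% pn
  }
  structure(list(times = grid_times(grid), P = P, xs = gme$xs,
                 gamma = g),
            class = "gme_evolution")
}

#' @export
print.gme_evolution <- function(x, ...) {
  cat(sprintf(
    "GME evolution: %d fields on %d lattice points, t in [%g, %g], gamma = %g\n",
    nrow(x$P), ncol(x$P), x$times[1], x$times[length(x$times)], x$gamma))
  invisible(x)
}

#' Stationary distribution of the lattice GME
#'
#' The normalized null vector of `W`, computed from the null space of the
#' rate matrix (smallest singular vector). Because the kernel satisfies
#' detailed balance, this equals the Boltzmann distribution
#' `exp(-beta * F)` normalized on the lattice; the anomalous exponent
#' does not enter (memory changes the approach, not the target).
#'
#' @param gme A [build_rate_matrix()] object.
#' @return A [probability_field()] (with `t = Inf`).
#' @export
stationary_distribution <- function(gme) {
  if (!inherits(gme, "lattice_gme"))
    tfk_domain_error("`gme` must be a `lattice_gme` object")
  sv <- svd(gme$W)
  d <- sv$d
  N <- length(d)
  scale <- max(d)
  if (N >= 2 && d[N - 1L] < 1e-10 * scale)
    tfk_stop("degenerate null space: lattice is not irreducible",
             "tfk_structure_error")
  v <- sv$v[, N]
  v <- v / sum(v)
  if (any(v < -1e-8))
    tfk_stop("null vector is not sign-definite", "tfk_structure_error")
  probability_field(pmax(v, 0) / sum(pmax(v, 0)), t = Inf)
}

#' Variance of a field sequence and its growth exponent
#'
#' `field_variance()` returns the variance of the lattice coordinate under
#' each field of a [propagate_gme()] result. `spreading_exponent()` fits
#' `log(variance)` against `log(t)` over a time window and returns the
#' slope — for free subdiffusion on a flat landscape the variance grows
#' like `t^gamma`.
#'
#' @param ev A `gme_evolution` object.
#' @param t_min,t_max Fit window (defaults: drop the first 2% of times).
#' @return `field_variance()`: numeric vector; `spreading_exponent()`: the
#'   fitted slope.
#' @export
field_variance <- function(ev) {
  if (!inherits(ev, "gme_evolution"))
    tfk_domain_error("`ev` must be a `gme_evolution` object")
  mu <- as.numeric(ev$P %*% ev$xs)
  m2 <- as.numeric(ev$P %*% ev$xs^2)
  m2 - mu^2
}

#' @rdname field_variance
#' @export
spreading_exponent <- function(ev, t_min = NULL, t_max = NULL) {
  v <- field_variance(ev)
  t <- ev$times
  if (is.null(t_min)) t_min <- stats::quantile(t[t > 0], 0.02)
  if (is.null(t_max)) t_max <- max(t)
  keep <- t >= t_min & t <= t_max & v > 0
  if (sum(keep) < 5)
    tfk_domain_error("not enough points in the fit window")
  unname(stats::coef(stats::lm(log(v[keep]) ~ log(t[keep])))[2])
}
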