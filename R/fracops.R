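#' Power-law memory kernel parameters
#'
#' The long-tailed waiting-time kernel of the generalized master equation
#' is parameterized by the anomalous exponent `gamma` and the macroscopic
#' relaxation time `tau`.
#'
#' @param gamma Anomalous exponent; `0 < gamma < 1` for genuinely
#'   non-Markovian memory. `gamma = 1` is accepted as the Markovian
#'   degenerate case (constant kernel).
#' @param tau Macroscopic relaxation parameter, `> 0`, in time units.
#' @return An object of class `memory_kernel_params`.
#' @export
memory_kernel_params <- function(gamma, tau = 1) {
  stopifnot_scalar(gamma, "gamma")
  stopifnot_scalar(tau, "tau")
  if (gamma <= 0 || gamma > 1)
    tfk_domain_error("`gamma` must lie in (0, 1]", gamma = gamma)
  if (tau <= 0) tfk_domain_error("`tau` must be > 0", tau = tau)
  structure(list(gamma = gamma, tau = tau), class = "memory_kernel_params")
}

#' @export
print.memory_kernel_params <- function(x, ...) {
  cat(sprintf("Power-law memory kernel: gamma = %g, tau = %g\n",
              x$gamma, x$tau))
  invisible(x)
}

#' Power-law memory kernel
#'
#' Evaluates \eqn{\Pi(t) = (t/\tau)^{\gamma-1} / \Gamma(\gamma)}, the
#' kernel of the non-Markovian master equation corresponding to a
#' long-tailed waiting-time distribution. It is positive, strictly
#' decreasing for `0 < gamma < 1`, and diverges (integrably) at `t = 0`.
#'
#' @param t Time(s), strictly positive (the kernel diverges at 0 for
#'   `gamma < 1`).
#' @param params A [memory_kernel_params()] object.
#' @return Kernel values, units `time^(gamma-1)`.
#' @export
memory_kernel <- function(t, params) {
  if (!inherits(params, "memory_kernel_params"))
    tfk_domain_error("`params` must be a `memory_kernel_params` object")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    tfk_domain_error("`t` must be > 0 (the kernel diverges at t = 0)")
  (t / params$tau)^(params$gamma - 1) / gamma(params$gamma)
}

#' Uniform time grid
#'
#' Grid points are `t_j = t0 + j * dt`, `j = 0..n_steps` (`n_steps + 1`
#' points). Fractional operators require `t0 = 0`, the lower limit of the
#' Riemann-Liouville integral.
#'
#' @param dt Time step, `> 0`.
#' @param n_steps Number of steps, `>= 1`.
#' @param t0 Start time (default 0).
#' @return An object of class `uniform_grid`.
#' @examples
#' g <- uniform_grid(dt = 0.1, n_steps = 10)
#' grid_times(g)
#' @export
uniform_grid <- function(dt, n_steps, t0 = 0) {
  stopifnot_scalar(dt, "dt")
  stopifnot_scalar(t0, "t0")
  if (dt <= 0) tfk_domain_error("`dt` must be > 0")
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1 ||
      n_steps != round(n_steps))
    tfk_domain_error("`n_steps` must be a positive integer")
  structure(list(dt = dt, n_steps = as.integer(n_steps), t0 = t0),
            class = "uniform_grid")
}

#' @rdname uniform_grid
#' @param grid A `uniform_grid` object.
#' @export
grid_times <- function(grid) {
  if (!inherits(grid, "uniform_grid"))
    tfk_domain_error("`grid` must be a `uniform_grid` object")
  grid$t0 + grid$dt * (0:grid$n_steps)
}

#' @export
print.uniform_grid <- function(x, ...) {
  cat(sprintf("Uniform grid: dt = %g, n_steps = %d, t in [%g, %g]\n",
              x$dt, x$n_steps, x$t0, x$t0 + x$dt * x$n_steps))
  invisible(x)
}

#' Grunwald-Letnikov convolution weights
#'
#' The signed binomial weights \eqn{w_k = (-1)^k \binom{\gamma}{k}} via the
#' stable recursion `w_0 = 1`, `w_k = w_{k-1} * (1 - (gamma + 1)/k)`. For
#' `0 < gamma < 1`: `w_0 > 0`, all later weights are negative, and the
#' weights sum to zero over `k = 0..Inf`.
#'
#' @param gamma Derivative order (any real).
#' @param n Highest index; returns `n + 1` weights.
#' @return Numeric vector `w_0..w_n`.
#' @examples
#' gl_weights(0.5, 4)
#' @export
gl_weights <- function(gamma, n) {
  stopifnot_scalar(gamma, "gamma")
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    tfk_domain_error("`n` must be a non-negative integer")
  if (n == 0) return(1)
  cumprod(c(1, 1 - (gamma + 1) / seq_len(n)))
}

# Linear convolution (full history) of weights w with series v via FFT;
# returns y_j = sum_{k=0..j} w[k+1] * v[j-k+1], length(v) values.
gl_convolve <- function(w, v) {
  n <- length(v)
  m <- stats::nextn(2L * n, 2)
  yw <- stats::fft(c(w[seq_len(n)], rep(0, m - n)))
  yv <- stats::fft(c(v, rep(0, m - n)))
  Re(stats::fft(yw * yv, inverse = TRUE))[seq_len(n)] / m
}

#' Riemann-Liouville fractional derivative on a uniform grid
#'
#' Grunwald-Letnikov approximation of the Riemann-Liouville derivative of
#' order `order` of a function sampled at `t_j = j * dt`:
#' \eqn{D^\mu f(t_j) \approx dt^{-\mu} \sum_{k=0}^{j} w_k f(t_{j-k})},
#' first-order accurate in `dt`. Note the Riemann-Liouville derivative of
#' a nonzero constant is not zero (it is `c * t^-mu / Gamma(1-mu)`).
#'
#' @param values Function samples at all grid points starting at `t = 0`.
#' @param order Derivative order in `(0, 1)`.
#' @param grid A [uniform_grid()] with `t0 = 0`, or pass `dt` directly.
#' @param dt Time step (used when `grid` is missing).
#' @return Numeric vector of the same length as `values`.
#' @examples
#' g <- uniform_grid(dt = 0.01, n_steps = 100)
#' d <- rl_derivative(grid_times(g), order = 0.5, grid = g)  # D^0.5 of t
#' @export
rl_derivative <- function(values, order, grid = NULL, dt = NULL) {
  if (!is.null(grid)) {
    if (!inherits(grid, "uniform_grid"))
      tfk_domain_error("`grid` must be a `uniform_grid` object")
    if (grid$t0 != 0)
      tfk_domain_error("fractional operators require t0 = 0")
    dt <- grid$dt
    if (length(values) != grid$n_steps + 1L)
      tfk_domain_error("`values` must be sampled at every grid point")
  }
  if (is.null(dt) || dt <= 0) tfk_domain_error("`dt` must be > 0")
  if (length(values) == 0) tfk_domain_error("`values` must be non-empty")
  if (order <= 0 || order >= 1)
    tfk_domain_error("`order` must lie in (0, 1)", order = order)
  w <- gl_weights(order, length(values) - 1L)
  dt^(-order) * gl_convolve(w, as.numeric(values))
}

#' Caputo fractional derivative on a uniform grid
#'
#' The Caputo derivative regularizes the Riemann-Liouville operator for
#' initial-value problems: it is the Riemann-Liouville derivative of the
#' increment `values - values[1]`, so it annihilates constants and agrees
#' with Riemann-Liouville exactly when `values[1] = 0`.
#'
#' @inheritParams rl_derivative
#' @return Numeric vector of the same length as `values`.
#' @export
caputo_derivative <- function(values, order, grid = NULL, dt = NULL) {
  if (length(values) == 0) tfk_domain_error("`values` must be non-empty")
  rl_derivative(as.numeric(values) - values[1], order, grid = grid, dt = dt)
}
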