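#' Kinetic solver configuration
#'
#' Parameters of the time-fractional kinetic equation
#' \eqn{D^\gamma x(t) = -\Gamma \beta \, \partial F/\partial x}. Time is
#' dimensionless (`tau = 1` convention); the composite rate constant the
#' user effectively controls is `Gamma_coef * beta` times the landscape
#' curvature.
#'
#' @param gamma Anomalous exponent, `0 < gamma <= 1` (`gamma = 1` is the
#'   classical Markovian limit).
#' @param Gamma_coef Kinetic coefficient \eqn{\Gamma}, `> 0`. Distinct from
#'   the Gamma *function*; see [gamma_from_delta()] for its relation to
#'   the spatial kernel width.
#' @param beta Inverse temperature, `> 0`.
#' @param x0 Initial state; must lie in the landscape domain interior.
#' @param grid A [uniform_grid()] with `t0 = 0`.
#' @param scheme `"abm"` (Adams-Bashforth-Moulton predictor-corrector, the
#'   default) or `"gl_implicit"` (implicit Grunwald-Letnikov, useful for
#'   stiff landscapes).
#' @param clamp_eps States leaving the domain are clamped this fraction of
#'   the domain width inside the boundary (logged, counted).
#' @return An object of class `kinetic_config`.
#' @export
kinetic_config <- function(gamma, Gamma_coef, beta, x0, grid,
                           scheme = c("abm", "gl_implicit"),
                           clamp_eps = 1e-12) {
  stopifnot_scalar(gamma, "gamma")
  stopifnot_scalar(Gamma_coef, "Gamma_coef")
  stopifnot_scalar(beta, "beta")
  stopifnot_scalar(x0, "x0")
  if (gamma <= 0 || gamma > 1)
    tfk_domain_error("`gamma` must lie in (0, 1]", gamma = gamma)
  if (Gamma_coef <= 0) tfk_domain_error("`Gamma_coef` must be > 0")
  if (beta <= 0) tfk_domain_error("`beta` must be > 0")
  if (!inherits(grid, "uniform_grid"))
    tfk_domain_error("`grid` must be a `uniform_grid` object")
  if (grid$t0 != 0)
    tfk_domain_error("fractional initial-value problems require t0 = 0")
  scheme <- match.arg(scheme)
  structure(list(gamma = gamma, Gamma_coef = Gamma_coef, beta = beta,
                 x0 = x0, grid = grid, scheme = scheme,
                 clamp_eps = clamp_eps),
            class = "kinetic_config")
}

#' @export
print.kinetic_config <- function(x, ...) {
  cat(sprintf(
    "Kinetic config: gamma = %g, Gamma = %g, beta = %g, x0 = %g, scheme = %s\n",
    x$gamma, x$Gamma_coef, x$beta, x$x0, x$scheme))
  print(x$grid)
  invisible(x)
}

#' Kinetic coefficient from the spatial kernel width
#'
#' The kinetic coefficient arises from Gaussian integrals over the jump
#' kernel of width `Delta`: \eqn{\Gamma = (2\pi\Delta)^{m/2} \Delta} in
#' `m` dimensions.
#'
#' @param Delta Kernel width, `> 0` (state^2 units).
#' @param m Dimension count, integer `>= 1`.
#' @return The kinetic coefficient.
#' @examples
#' gamma_from_delta(1 / (2 * pi), m = 2)  # 1/(2*pi)
#' @export
gamma_from_delta <- function(Delta, m = 1) {
  stopifnot_scalar(Delta, "Delta")
  if (Delta <= 0) tfk_domain_error("`Delta` must be > 0")
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    tfk_domain_error("`m` must be a positive integer")
  (2 * pi * Delta)^(m / 2) * Delta
}

#' Solve the time-fractional kinetic equation
#'
#' Integrates \eqn{D^\gamma x = -\Gamma \beta F'(x)} in the Caputo sense
#' from `x0` on a uniform grid. The default scheme is the fractional
#' Adams-Bashforth-Moulton predictor-corrector (one corrector pass); an
#' implicit Grunwald-Letnikov scheme is selectable for stiff drifts. Full
#' memory is kept (no short-memory truncation). For `gamma = 1` the ABM
#' scheme reduces to the classical (Heun-type) predictor-corrector.
#'
#' States that overshoot the landscape domain are clamped just inside the
#' boundary; the number of clamped steps is recorded in the trajectory
#' metadata and a warning is emitted, because overshoot would otherwise
#' poison the convolution history.
#'
#' @param landscape A [free_energy_landscape()].
#' @param config A [kinetic_config()].
#' @return A `tfk_trajectory`: list with `times`, `states`, and `meta`
#'   (the config, the scheme, and `n_clamped`).
#' @examples
#' quad <- landscape_quadratic(kappa = 1)
#' cfg <- kinetic_config(gamma = 0.6, Gamma_coef = 1, beta = 1, x0 = 1,
#'                       grid = uniform_grid(dt = 0.01, n_steps = 200))
#' traj <- solve_fractional_kinetic(quad, cfg)
#' @export
solve_fractional_kinetic <- function(landscape, config) {
  if (!inherits(landscape, "free_energy_landscape"))
    tfk_domain_error("`landscape` must be a `free_energy_landscape`")
  if (!inherits(config, "kinetic_config"))
    tfk_domain_error("`config` must be a `kinetic_config`")
  lo <- landscape$domain[1]; hi <- landscape$domain[2]
  if (config$x0 <= lo || config$x0 >= hi)
    tfk_domain_error("`x0` must lie in the landscape domain interior")
  rate <- config$Gamma_coef * config$beta
  drift <- function(x) -rate * landscape$fprime(x)
  out <- frac_ivp(drift, config$x0, config$gamma, config$grid,
                  scheme = config$scheme,
                  clamp = c(lo, hi), clamp_eps = config$clamp_eps)
  new_trajectory(grid_times(config$grid), out$states, config,
                 n_clamped = out$n_clamped)
}

# Caputo-sense fractional IVP integrator D^gamma x = f(x), shared by the
# kinetics solver and the channel simulator.
#
# ABM (Diethelm-Ford-Freed): with h = dt and F_j = f(x_j),
#   predictor: x_{n+1}^P = x0 + h^g/Gamma(g+1) * sum_j b_{n-j} F_j
#   corrector: x_{n+1} = x0 + h^g/Gamma(g+2) *
#              [ a0_n F_0 + sum_{j=1..n} a_{n-j} F_j + f(x^P_{n+1}) ]
# with lag weights b_l = (l+1)^g - l^g,
#   a_l = (l+2)^(g+1) + l^(g+1) - 2 (l+1)^(g+1), and
#   a0_n = n^(g+1) - (n-g)(n+1)^g.
frac_ivp <- function(f, x0, gamma, grid, scheme = "abm",
                     clamp = c(-Inf, Inf), clamp_eps = 1e-12) {
  n <- grid$n_steps
  h <- grid$dt
  g <- gamma
  lo <- clamp[1]; hi <- clamp[2]
  width <- if (is.finite(hi - lo)) hi - lo else 1
  eps <- clamp_eps * width
  x <- numeric(n + 1L)
  Fv <- numeric(n + 1L)
  x[1] <- x0
  Fv[1] <- f(x0)
  if (!is.finite(Fv[1]))
    tfk_eval_error("drift not finite at the initial state", step = 0L)
  n_clamped <- 0L
  ks <- 0:(n + 1L)
  bl <- diff(ks^g)                       # b_l, l = 0..n
  cg1 <- ks^(g + 1)
  al <- cg1[3:(n + 2L)] + cg1[1:n] - 2 * cg1[2:(n + 1L)]  # a_l, l = 0..n-1
  hg1 <- h^g / gamma(g + 1)
  hg2 <- h^g / gamma(g + 2)
  if (scheme == "abm") {
    for (m in 0:(n - 1L)) {
      j <- 0:m
      xp <- x0 + hg1 * sum(bl[m - j + 1L] * Fv[j + 1L])
      # keep the predictor a little further off the boundary than the
      # final clamp: drifts with boundary singularities (log terms) would
      # otherwise inject huge spikes into the corrector
      pe <- max(eps, 1e-6 * width)
      xp <- min(max(xp, lo + pe), hi - pe)
      a0 <- m^(g + 1) - (m - g) * (m + 1)^g
      hist <- a0 * Fv[1L]
      if (m >= 1L) {
        jj <- 1:m
        hist <- hist + sum(al[m - jj + 1L] * Fv[jj + 1L])
      }
      fp <- f(xp)
      if (!is.finite(fp))
        tfk_eval_error("drift overflowed during integration", step = m + 1L)
      xn <- x0 + hg2 * (hist + fp)
      if (xn <= lo || xn >= hi) {
        xn <- min(max(xn, lo + eps), hi - eps)
        n_clamped <- n_clamped + 1L
      }
      fx <- f(xn)
      if (!is.finite(fx))
        tfk_eval_error("drift overflowed during integration", step = m + 1L)
      x[m + 2L] <- xn
      Fv[m + 2L] <- fx
    }
  } else {  # implicit Grunwald-Letnikov: sum_k w_k (x_{j-k} - x0) = h^g f(x_j)
    w <- gl_weights(g, n)
    hg <- h^g
    for (m in 1:n) {
      k <- 1:m
      histterm <- sum(w[k + 1L] * (x[m - k + 1L] - x0))
      # solve x - x0 + histterm - h^g f(x) = 0 for x  (w_0 = 1)
      gfun <- function(xx) (xx - x0) + histterm - hg * f(xx)
      xprev <- x[m]
      # bracket around the previous state
      step_guess <- max(abs(hg * Fv[m]), 1e-8, abs(x[m] - x[max(m - 1L, 1L)]))
      a <- max(xprev - 10 * step_guess, lo + eps)
      b <- min(xprev + 10 * step_guess, hi - eps)
      fa <- gfun(a); fb <- gfun(b)
      tries <- 0L
      while (fa * fb > 0 && tries < 60L) {
        a <- max(a - (b - a), lo + eps)
        b <- min(b + (b - a), hi - eps)
        fa <- gfun(a); fb <- gfun(b)
        tries <- tries + 1L
      }
      if (fa * fb > 0)
        tfk_eval_error("implicit GL step failed to bracket a root",
                       step = m)
      xn <- stats::uniroot(gfun, c(a, b), tol = 1e-14)$root
      if (xn <= lo + eps || xn >= hi - eps) n_clamped <- n_clamped + 1L
      xn <- min(max(xn, lo + eps), hi - eps)
      x[m + 1L] <- xn
      Fv[m + 1L] <- f(xn)
    }
  }
  if (n_clamped > 0L)
    warning(sprintf("%d step(s) clamped to the landscape domain boundary",
                    n_clamped))
  list(states = x, n_clamped = n_clamped)
}

new_trajectory <- function(times, states, meta, n_clamped = 0L) {
  structure(list(times = times, states = states,
                 meta = c(list(n_clamped = n_clamped), list(config = meta))),
            class = "tfk_trajectory")
}

#' @export
print.tfk_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Trajectory: %d points, t in [%g, %g], x: %g -> %g\n",
              n, x$times[1], x$times[n], x$states[1], x$states[n]))
  if (x$meta$n_clamped > 0)
    cat(sprintf("  (%d clamped step(s))\n", x$meta$n_clamped))
  invisible(x)
}

#' @export
as.data.frame.tfk_trajectory <- function(x, ...) {
  data.frame(t = x$times, x = x$states)
}

#' Stationary state of the drift
#'
#' Finds `x*` with `F'(x*) = 0` near `x_guess` by bracket expansion and
#' bisection. The stationary state of the time-fractional kinetic
#' equation does not depend on the anomalous exponent; the memory kernel
#' changes the approach, not the target.
#'
#' @param landscape A [free_energy_landscape()].
#' @param x_guess Starting point inside the domain.
#' @return The root, with `|F'(x*)| < 1e-10`.
#' @examples
#' stationary_state(landscape_double_well(), 0.8)  # 1
#' @export
stationary_state <- function(landscape, x_guess) {
  if (!inherits(landscape, "free_energy_landscape"))
    tfk_domain_error("`landscape` must be a `free_energy_landscape`")
  lo <- landscape$domain[1]; hi <- landscape$domain[2]
  stopifnot_scalar(x_guess, "x_guess")
  if (x_guess <= lo || x_guess >= hi)
    tfk_domain_error("`x_guess` must lie in the domain interior")
  fp <- landscape$fprime
  pad <- 1e-9 * (hi - lo)
  r <- max(1e-4 * (hi - lo), 1e-8)
  a <- x_guess; b <- x_guess
  fa <- fp(a); fb <- fp(b)
  tries <- 0L
  while (fa * fb > 0 && tries < 200L) {
    a <- max(a - r, lo + pad); b <- min(b + r, hi - pad)
    fa <- fp(a); fb <- fp(b)
    r <- 2 * r
    tries <- tries + 1L
  }
  if (fa * fb > 0)
    tfk_stop("no sign change of F' found near `x_guess`", "tfk_root_error")
  root <- stats::uniroot(fp, c(a, b), tol = .Machine$double.eps^0.9)$root
  # polish with a couple of Newton steps (numeric slope) to push |F'| < 1e-10
  for (i in 1:3) {
    v <- fp(root)
    if (abs(v) < 1e-12) break
    h <- max(abs(root), 1) * 1e-7
    slope <- (fp(root + h) - fp(root - h)) / (2 * h)
    if (!is.finite(slope) || slope == 0) break
    cand <- root - v / slope
    if (cand > lo && cand < hi && abs(fp(cand)) < abs(v)) root <- cand
  }
  if (abs(fp(root)) >= 1e-10)
    tfk_stop("root refinement did not reach |F'| < 1e-10", "tfk_root_error")
  root
}
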