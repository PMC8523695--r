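#' Two-state voltage-gated channel parameters
#'
#' Thermodynamic and electrical parameters of the simplest voltage-gated
#' ion-channel model: `n` identical channels on the membrane, each closed
#' (energy `eps1`) or open (energy `eps2`), with `z` gating charges of
#' magnitude `e0` moved by the membrane voltage `V`. The open fraction
#' `x = n2/n` is the open probability. The threshold voltage
#' `V0 = -(eps1 - eps2)/(z * e0)` — the voltage at which half the
#' channels are open at equilibrium — is derived and stored.
#'
#' Defaults are reduced units: `e0 = 1`, energies in units of `1/beta`.
#' For physical units set `e0` to the elementary charge in coulombs,
#' `beta = 1/(kB T)` and `V` in volts.
#'
#' @param n Total channel count, `>= 1`.
#' @param eps1 Closed-state energy.
#' @param eps2 Open-state energy.
#' @param z Gating-charge valence, integer `>= 1`.
#' @param e0 Elementary charge (default 1, reduced units).
#' @param beta Inverse temperature, `> 0`.
#' @param V Membrane voltage.
#' @return An object of class `channel_params` with derived element `V0`.
#' @examples
#' p <- channel_params(eps1 = 1, eps2 = 3, V = 2)
#' p$V0                                # threshold voltage
#' equilibrium_open_probability(p)     # 0.5 at V = V0
#' @export
channel_params <- function(n = 1, eps1 = 0, eps2 = 0, z = 1, e0 = 1,
                           beta = 1, V = 0) {
  stopifnot_scalar(n, "n"); stopifnot_scalar(eps1, "eps1")
  stopifnot_scalar(eps2, "eps2"); stopifnot_scalar(e0, "e0")
  stopifnot_scalar(beta, "beta"); stopifnot_scalar(V, "V")
  if (n < 1) tfk_domain_error("`n` must be >= 1")
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z))
    tfk_domain_error("`z` must be an integer >= 1")
  if (e0 <= 0) tfk_domain_error("`e0` must be > 0")
  if (beta <= 0) tfk_domain_error("`beta` must be > 0")
  V0 <- -(eps1 - eps2) / (z * e0) + 0   # + 0 normalizes signed zero
  if (!is.finite(V0)) tfk_domain_error("derived threshold voltage not finite")
  structure(list(n = n, eps1 = eps1, eps2 = eps2, z = z, e0 = e0,
                 beta = beta, V = V, V0 = V0),
            class = "channel_params")
}

#' @export
print.channel_params <- function(x, ...) {
  cat(sprintf(
    "Two-state channel: n = %g, eps1 = %g, eps2 = %g, z = %d, e0 = %g\n",
    x$n, x$eps1, x$eps2, x$z, x$e0))
  cat(sprintf("  beta = %g, V = %g (threshold V0 = %g)\n", x$beta, x$V, x$V0))
  invisible(x)
}

#' Configurational entropy of the two-state channel population
#'
#' The log-count of microstates with open fraction `x`:
#' \eqn{\ln \Omega(x) = -n[(1-x)\ln(1-x) + x \ln x]}, the binomial mixing
#' entropy in the thermodynamic (Stirling) limit.
#'
#' @param x Open fraction(s), strictly in `(0, 1)`.
#' @param n Channel count.
#' @return Dimensionless entropy (log microstate count).
#' @examples
#' config_entropy(0.5)  # log(2)
#' @export
config_entropy <- function(x, n = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    tfk_domain_error("`x` must lie strictly in (0, 1)")
  stopifnot_scalar(n, "n")
  -n * ((1 - x) * log(1 - x) + x * log(x))
}

#' Helmholtz free energy of the channel population
#'
#' \deqn{F(x) = n[(1-x)\epsilon_1 + x\epsilon_2] + z e_0 n (1-x) V
#'       - \beta^{-1} \ln\Omega(x)}
#' combining the state energies, the electrical work of the gating charge
#' (carried by the closed fraction as printed), and the configurational
#' entropy. Its derivative is
#' \eqn{F'(x) = n z e_0 (V_0 - V) + n\beta^{-1}\ln[x/(1-x)]}, whose zero
#' is the equilibrium open probability.
#'
#' @inheritParams config_entropy
#' @param params A [channel_params()] object.
#' @return Free energy value(s).
#' @export
channel_free_energy <- function(x, params) {
  if (!inherits(params, "channel_params"))
    tfk_domain_error("`params` must be a `channel_params` object")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    tfk_domain_error("`x` must lie strictly in (0, 1)")
  p <- params
  p$n * ((1 - x) * p$eps1 + x * p$eps2) +
    p$z * p$e0 * p$n * (1 - x) * p$V -
    config_entropy(x, p$n) / p$beta
}

#' @rdname channel_free_energy
#' @export
channel_free_energy_deriv <- function(x, params) {
  if (!inherits(params, "channel_params"))
    tfk_domain_error("`params` must be a `channel_params` object")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x >= 1))
    tfk_domain_error("`x` must lie strictly in (0, 1)")
  p <- params
  p$n * p$z * p$e0 * (p$V0 - p$V) + p$n * log(x / (1 - x)) / p$beta
}

#' Channel free energy as a landscape object
#'
#' Wraps [channel_free_energy()] and its derivative as a
#' [free_energy_landscape()] on the open interval `(0, 1)` (trimmed by
#' `pad` because the entropy term's derivative diverges at the
#' boundaries).
#'
#' @param params A [channel_params()] object.
#' @param pad Distance from 0 and 1 at which the domain is truncated.
#' @return A [free_energy_landscape()].
#' @export
channel_landscape <- function(params, pad = 1e-9) {
  if (!inherits(params, "channel_params"))
    tfk_domain_error("`params` must be a `channel_params` object")
  free_energy_landscape(
    f = function(x) channel_free_energy(x, params),
    fprime = function(x) channel_free_energy_deriv(x, params),
    domain = c(pad, 1 - pad), name = "channel", check = FALSE)
}

#' Equilibrium open probability
#'
#' The Boltzmann sigmoid
#' \deqn{P_0 = \{1 + \exp[-\beta z e_0 (V - V_0)]\}^{-1}}
#' with threshold voltage \eqn{V_0 = -(\epsilon_1-\epsilon_2)/(z e_0)}.
#' At `V = V0` exactly half the channels are open; the value is strictly
#' increasing in `V`.
#'
#' @param params A [channel_params()] object.
#' @param V Optional voltage override (defaults to `params$V`).
#' @return Open probability strictly in `(0, 1)`.
#' @export
equilibrium_open_probability <- function(params, V = NULL) {
  if (!inherits(params, "channel_params"))
    tfk_domain_error("`params` must be a `channel_params` object")
  if (is.null(V)) V <- params$V
  stats::plogis(params$beta * params$z * params$e0 * (V - params$V0))
}

#' Drift of the time-fractional open-probability equation
#'
#' The right-hand side of the fractional relaxation law for the open
#' probability:
#' \deqn{D^\gamma P_0 = \frac{\Gamma}{n}\left\{\beta z e_0 (V - V_0)
#'       - \ln\frac{P_0}{1-P_0}\right\}}
#' Its unique zero is the equilibrium open probability, and it equals
#' \eqn{-(\Gamma/n^2)\,\beta\,F'(p)}: the free-energy gradient flow in
#' the open-channel count `n2 = n * p`.
#'
#' @param p Open fraction(s), strictly in `(0, 1)`.
#' @param params A [channel_params()] object.
#' @param Gamma_coef Kinetic coefficient, `> 0`.
#' @return Drift value(s), units `time^-gamma`.
#' @export
open_probability_drift <- function(p, params, Gamma_coef = 1) {
  if (!inherits(params, "channel_params"))
    tfk_domain_error("`params` must be a `channel_params` object")
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    tfk_domain_error("`p` must lie strictly in (0, 1)")
  stopifnot_scalar(Gamma_coef, "Gamma_coef")
  if (Gamma_coef <= 0) tfk_domain_error("`Gamma_coef` must be > 0")
  q <- params
  (Gamma_coef / q$n) *
    (q$beta * q$z * q$e0 * (q$V - q$V0) - log(p / (1 - p)))
}

#' Simulate the time-fractional open-probability relaxation
#'
#' Integrates the fractional open-probability equation in the Caputo
#' sense from `p0` with the same predictor-corrector machinery as
#' [solve_fractional_kinetic()]. Values stay in `(0, 1)`; overshoot is
#' clamped and counted.
#'
#' @param params A [channel_params()] object.
#' @param gamma Anomalous exponent, `0 < gamma <= 1`.
#' @param Gamma_coef Kinetic coefficient, `> 0`. The composite rate seen by
#'   the dynamics is `Gamma_coef / n`.
#' @param p0 Initial open fraction in `(0, 1)`; default 0.1 (a mostly
#'   closed, "deformed" population far from equilibrium).
#' @param grid A [uniform_grid()] with `t0 = 0`.
#' @param scheme Integration scheme, as in [kinetic_config()].
#' @return A `tfk_trajectory` of open probabilities.
#' @examples
#' p <- channel_params(V = 0)   # V at threshold
#' traj <- simulate_channel(p, gamma = 0.8, Gamma_coef = 1, p0 = 0.1,
#'                          grid = uniform_grid(dt = 0.01, n_steps = 500))
#' @export
simulate_channel <- function(params, gamma, Gamma_coef = 1, p0 = 0.1,
                             grid = uniform_grid(dt = 0.01, n_steps = 1000),
                             scheme = c("abm", "gl_implicit")) {
  if (!inherits(params, "channel_params"))
    tfk_domain_error("`params` must be a `channel_params` object")
  stopifnot_scalar(gamma, "gamma"); stopifnot_scalar(p0, "p0")
  if (gamma <= 0 || gamma > 1)
    tfk_domain_error("`gamma` must lie in (0, 1]", gamma = gamma)
  if (p0 <= 0 || p0 >= 1)
    tfk_domain_error("`p0` must lie strictly in (0, 1)")
  scheme <- match.arg(scheme)
  drift <- function(p) open_probability_drift(p, params, Gamma_coef)
  # clamp pad keeps log(p/(1-p)) finite
  out <- frac_ivp(drift, p0, gamma, grid, scheme = scheme,
                  clamp = c(0, 1), clamp_eps = 1e-12)
  meta_cfg <- list(params = params, gamma = gamma, Gamma_coef = Gamma_coef,
                   p0 = p0, grid = grid, scheme = scheme,
                   p_eq = equilibrium_open_probability(params))
  new_trajectory(grid_times(grid), out$states, meta_cfg,
                 n_clamped = out$n_clamped)
}
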