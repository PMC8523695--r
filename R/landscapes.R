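#' Free-energy landscape
#'
#' A one-dimensional free-energy landscape: the free energy `f(x)`, its
#' derivative `fprime(x)`, and the closed interval of valid states. The
#' constructor checks that `fprime` is consistent with `f` by central
#' differences at 20 interior probe points.
#'
#' @param f Function mapping state `x` to free energy.
#' @param fprime Function mapping `x` to `dF/dx`.
#' @param domain Numeric length-2 vector, the closed interval of valid `x`.
#' @param name Optional label used in printing and CLI output.
#' @param check If `TRUE` (default), run the derivative consistency check.
#' @return An object of class `free_energy_landscape`.
#' @examples
#' quad <- landscape_quadratic(kappa = 2)
#' quad$f(0.5); quad$fprime(0.5)
#' @export
free_energy_landscape <- function(f, fprime, domain, name = "custom",
                                  check = TRUE) {
  if (!is.function(f) || !is.function(fprime))
    tfk_domain_error("`f` and `fprime` must be functions")
  if (!is.numeric(domain) || length(domain) != 2L || domain[1] >= domain[2])
    tfk_domain_error("`domain` must be an increasing length-2 numeric vector")
  ls <- structure(list(f = f, fprime = fprime, domain = as.numeric(domain),
                       name = name),
                  class = "free_energy_landscape")
  if (check) {
    h <- 1e-5
    lo <- domain[1]; hi <- domain[2]
    pad <- 0.05 * (hi - lo)
    xs <- seq(lo + pad, hi - pad, length.out = 20)
    num <- (vapply(xs + h, f, numeric(1)) - vapply(xs - h, f, numeric(1))) / (2 * h)
    ana <- vapply(xs, fprime, numeric(1))
    if (any(!is.finite(num)) || any(!is.finite(ana)))
      tfk_domain_error("landscape not finite on the interior of its domain")
    scale <- pmax(abs(ana), 1)
    if (max(abs(num - ana) / scale) > 1e-4)
      tfk_domain_error("`fprime` is inconsistent with `f` (central-difference check failed)")
  }
  ls
}

#' @export
print.free_energy_landscape <- function(x, ...) {
  cat(sprintf("Free-energy landscape '%s' on [%g, %g]\n",
              x$name, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Built-in landscapes
#'
#' `landscape_quadratic()` is the harmonic well `F = kappa/2 * (x - center)^2`;
#' `landscape_double_well()` is the symmetric quartic `F = (x^2 - 1)^2 / 4`
#' with minima at `x = -1, 1`; `landscape_flat()` has `F = 0` everywhere
#' (free subdiffusion). The channel free energy is built by
#' [channel_landscape()].
#'
#' @param kappa Curvature (stiffness) of the harmonic well, `> 0`.
#' @param center Location of the harmonic minimum.
#' @param domain State interval.
#' @return A [free_energy_landscape()].
#' @export
landscape_quadratic <- function(kappa = 1, center = 0,
                                domain = center + c(-50, 50)) {
  stopifnot_scalar(kappa, "kappa")
  if (kappa <= 0) tfk_domain_error("`kappa` must be > 0")
  free_energy_landscape(
    f = function(x) 0.5 * kappa * (x - center)^2,
    fprime = function(x) kappa * (x - center),
    domain = domain, name = "quadratic", check = FALSE)
}

#' @rdname landscape_quadratic
#' @export
landscape_double_well <- function(domain = c(-3, 3)) {
  free_energy_landscape(
    f = function(x) (x^2 - 1)^2 / 4,
    fprime = function(x) x^3 - x,
    domain = domain, name = "double-well", check = FALSE)
}

#' @rdname landscape_quadratic
#' @export
landscape_flat <- function(domain = c(-100, 100)) {
  free_energy_landscape(
    f = function(x) 0 * x,
    fprime = function(x) 0 * x,
    domain = domain, name = "flat", check = FALSE)
}

# Resolve a landscape by name (CLI and fixtures).
builtin_landscape <- function(name, channel_params = NULL) {
  switch(name,
    quadratic = landscape_quadratic(),
    "double-well" = landscape_double_well(),
    flat = landscape_flat(),
    channel = channel_landscape(
      if (is.null(channel_params)) channel_params() else channel_params),
    tfk_domain_error(sprintf("unknown landscape '%s'", name)))
}
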