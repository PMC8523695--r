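test_that("rate matrix has the Gaussian-Boltzmann band structure", {
  # flat landscape: symmetric band with entries exp(-(dx k)^2 / Delta)
  fl <- landscape_flat(c(-5, 5))
  xs <- seq(-2, 2, 0.5)
  g <- build_rate_matrix(fl, xs, Delta = 1, beta = 1, cutoff = 3)
  expect_equal(g$W, t(g$W))
  for (k in 1:3) {
    expect_equal(unname(g$W[1, 1 + k]), exp(-(0.5 * k)^2 / 1),
                 tolerance = 1e-14)
  }
  expect_equal(unname(g$W[1, 6]), 0)   # beyond cutoff
  # columns sum to zero: probability conservation by construction
  expect_lt(max(abs(colSums(g$W))), 1e-14)
})

test_that("forward/backward rate ratios encode the free-energy difference", {
  quad <- landscape_quadratic(kappa = 1.4)
  xs <- seq(-2, 2, length.out = 11)
  g <- build_rate_matrix(quad, xs, Delta = 0.4, beta = 0.9)
  Fx <- g$F_lattice
  for (i in 1:10) {
    j <- i + 1
    expect_equal(g$W[i, j] / g$W[j, i],
                 exp(-0.9 * (Fx[i] - Fx[j])), tolerance = 1e-12)
  }
  # detailed balance against the Boltzmann weights, all pairs
  B <- exp(-0.9 * Fx)
  flux <- g$W * rep(B, each = length(B))     # W[i,j] * B[j]
  diag(flux) <- 0
  expect_equal(flux, t(flux), tolerance = 1e-12)
})

test_that("a 5-point rate matrix matches brute-force element evaluation", {
  quad <- landscape_quadratic(kappa = 1)
  xs <- seq(-1, 1, 0.5)
  dx <- 0.5
  g <- build_rate_matrix(quad, xs, Delta = dx^2, beta = 1, cutoff = 1)
  Fref <- 0.5 * xs^2
  Wref <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    if (i != j && abs(i - j) <= 1) {
      Wref[i, j] <- exp(-(xs[i] - xs[j])^2 / dx^2) *
        exp(-0.5 * (Fref[i] - Fref[j]))
    }
  }
  for (j in 1:5) Wref[j, j] <- -sum(Wref[-j, j])
  expect_equal(g$W, Wref, tolerance = 1e-14)
})

test_that("Markovian lattice propagation matches the matrix exponential", {
  quad <- landscape_quadratic(kappa = 1)
  xs <- seq(-2.5, 2.5, length.out = 21)
  g <- build_rate_matrix(quad, xs, Delta = diff(xs)[1]^2, beta = 1, gamma = 1)
  boltz <- exp(-g$F_lattice) / sum(exp(-g$F_lattice))
  p0 <- boltz * (1 + 0.3 * sin(3 * xs))
  p0 <- p0 / sum(p0)
  ev <- propagate_gme(g, p0, uniform_grid(dt = 2e-4, n_steps = 2500))
  ref <- expm_propagate(g, p0, 0.5)
  expect_lt(max(abs(ev$P[2501, ] - ref)), 1e-6)
  expect_lt(max(abs(rowSums(ev$P) - 1)), 1e-10)
})

test_that("a negligible jump kernel freezes the field", {
  fl <- landscape_flat(c(-5, 5))
  g <- build_rate_matrix(fl, seq(-2, 2, 1), Delta = 1e-4, beta = 1,
                         cutoff = 1)
  p0 <- c(0, 0.3, 0.4, 0.3, 0)
  ev <- propagate_gme(g, p0, uniform_grid(dt = 0.1, n_steps = 20))
  expect_equal(ev$P[21, ], p0, tolerance = 1e-12)
})

test_that("symmetric three-state chain relaxes to uniform at the spectral rate", {
  fl <- landscape_flat(c(-5, 5))
  xs <- c(0, 1, 2)
  g <- build_rate_matrix(fl, xs, Delta = 2, beta = 1, cutoff = 1, gamma = 1)
  w <- exp(-1 / 2)  # nearest-neighbor rate
  p0 <- c(1, 0, 0)
  dt <- 5e-4
  ev <- propagate_gme(g, p0, uniform_grid(dt, 4000))
  t <- ev$times
  # closed form from the eigenmodes of the 3-chain generator:
  # P_mid(t) = 1/3 - (1/3) exp(-3 w t)
  expect_lt(max(abs(ev$P[, 2] - (1 / 3 - exp(-3 * w * t) / 3))), 2e-3)
  expect_lt(max(abs(rowSums(ev$P) - 1)), 1e-10)
})

test_that("mass is conserved for all memory exponents", {
  quad <- landscape_quadratic(kappa = 1)
  xs <- seq(-2, 2, length.out = 15)
  for (g in c(0.5, 0.8, 1.0)) {
    gme <- build_rate_matrix(quad, xs, Delta = 0.3, beta = 1, gamma = g)
    p0 <- numeric(15); p0[8] <- 1
    ev <- propagate_gme(gme, p0, uniform_grid(dt = 0.04, n_steps = 400))
    expect_lt(max(abs(rowSums(ev$P) - 1)), 1e-10,
              label = sprintf("mass at gamma=%g", g))
    expect_true(all(ev$P > -1e-12))
  }
})

test_that("stationary distribution is the lattice Boltzmann measure", {
  fl <- landscape_flat(c(-5, 5))
  gf <- build_rate_matrix(fl, seq(-2, 2, 0.5), Delta = 0.5, beta = 1)
  sd <- stationary_distribution(gf)
  expect_equal(sd$values, rep(1 / 9, 9), tolerance = 1e-10)
  quad <- landscape_quadratic(kappa = 2)
  gq <- build_rate_matrix(quad, seq(-2, 2, 0.25), Delta = 0.25, beta = 1.3)
  sq <- stationary_distribution(gq)
  boltz <- exp(-1.3 * gq$F_lattice)
  boltz <- boltz / sum(boltz)
  expect_lt(0.5 * sum(abs(sq$values - boltz)), 1e-10)
  # channel landscape: stationary mode sits at the equilibrium open fraction
  cp <- channel_params(eps1 = 0, eps2 = -1, V = 0.2)  # V0 = -1
  ch <- channel_landscape(cp)
  xs <- seq(0.02, 0.98, length.out = 49)
  gc <- build_rate_matrix(ch, xs, Delta = 0.01, beta = 1)
  sc <- stationary_distribution(gc)
  peq <- equilibrium_open_probability(cp)
  expect_equal(which.max(sc$values), which.min(abs(xs - peq)))
})

test_that("long-time fields reach Boltzmann independently of the exponent", {
  # inexpensive form of the exponent-independence property: the gamma = 0.6
  # field heads to the same Boltzmann target as gamma = 1 (deep version in
  # the acceptance suite)
  quad <- landscape_quadratic(kappa = 1)
  xs <- seq(-2.5, 2.5, length.out = 21)
  boltzmann <- NULL
  for (g in c(0.6, 1)) {
    gme <- build_rate_matrix(quad, xs, Delta = 0.25, beta = 1, gamma = g)
    boltz <- exp(-gme$F_lattice) / sum(exp(-gme$F_lattice))
    p0 <- boltz * (1 + 0.2 * sin(3 * xs)); p0 <- p0 / sum(p0)
    ev <- propagate_gme(gme, p0, uniform_grid(dt = 0.06, n_steps = 1200))
    tv <- 0.5 * sum(abs(ev$P[1201, ] - boltz))
    expect_lt(tv, 2e-2, label = sprintf("approach at gamma=%g", g))
  }
})

test_that("subdiffusive spreading on a flat landscape scales as t^gamma", {
  fl <- landscape_flat(c(-100, 100))
  xs <- seq(-30, 30, 1)
  g <- build_rate_matrix(fl, xs, Delta = 1, beta = 1, gamma = 0.5)
  p0 <- numeric(61); p0[31] <- 1
  ev <- propagate_gme(g, p0, uniform_grid(dt = 0.4, n_steps = 1000))
  slope <- spreading_exponent(ev, t_min = 10, t_max = 400)
  expect_lt(abs(slope - 0.5), 0.1)
})

test_that("instability and degenerate structure are reported, not silent", {
  quad <- landscape_quadratic(kappa = 1)
  xs <- seq(-2, 2, length.out = 11)
  g <- build_rate_matrix(quad, xs, Delta = 1, beta = 1, gamma = 0.6)
  p0 <- numeric(11); p0[6] <- 1
  expect_warning(
    try(propagate_gme(g, p0, uniform_grid(dt = 5, n_steps = 200)),
        silent = TRUE),
    "unstable")
  expect_error(
    suppressWarnings(propagate_gme(g, p0, uniform_grid(dt = 5, n_steps = 200))),
    class = "tfk_eval_error")
  expect_error(probability_field(c(0.5, 0.4)), class = "tfk_domain_error")
  expect_error(probability_field(c(0.7, 0.4, -0.1)),
               class = "tfk_domain_error")
})
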