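# Independent oracles and small fixture builders used across the suite.

# Dense stiff ODE integration of dp/dt = K p, independent of the package's
# eigen-propagator.
odeOracle <- function(K, p0, times) {
  m <- unclass(K)
  t0 <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::ode(y = as.numeric(p0), times = t0,
                      func = function(t, y, parms) list(as.vector(m %*% y)),
                      method = "lsoda", rtol = 1e-10, atol = 1e-13)
  unname(sol[match(times, sol[, 1]), -1, drop = FALSE])
}

# Characteristic-polynomial eigenvalues of a 3x3 rate matrix via polyroot:
# lambda^3 + c2 lambda^2 + c1 lambda + c0.
charpolyTimeConstants <- function(K) {
  m <- unclass(K)
  stopifnot(nrow(m) == 3)
  c2 <- -sum(diag(m))
  minor <- function(i, j) m[i, i] * m[j, j] - m[i, j] * m[j, i]
  c1 <- minor(1, 2) + minor(1, 3) + minor(2, 3)
  c0 <- -det(m)
  ev <- polyroot(c(c0, c1, c2, 1))
  re <- Re(ev)[abs(Re(ev)) > 1e-9 * max(abs(Re(ev)))]
  sort(-1 / re)
}

# Random irreversible sequential chain with rates spanning several decades.
randomChainScheme <- function(nStates, seed) {
  rates <- withr::with_seed(seed, 10^stats::runif(nStates - 1, -5, 3))
  states <- c(paste0("S", seq_len(nStates - 1)), "ground")
  photocycleScheme(states,
                   data.frame(from = states[-nStates], to = states[-1],
                              rate = rates),
                   excitedFraction = 1)
}

# Noiseless single-exponential surface with a known amplitude spectrum.
oneExpSurface <- function(tau = 1e-3, nwl = 11) {
  times <- 10^seq(-5, 0, length.out = 60)
  wl <- seq(400, 600, length.out = nwl)
  amp <- sin(seq(0.3, 2.8, length.out = nwl))
  transientSurface(times, wl, outer(exp(-times / tau), amp))
}

# Sequential rise-and-decay trace of an intermediate: population
# a (e^{-t/tauDecay} - e^{-t/tauRise}) on a log time grid.
riseDecayTrace <- function(pH, tauRise, tauDecay, a = 0.02) {
  tt <- 10^seq(-5, 1, length.out = 80)
  list(pH = pH, time = tt,
       values = a * (exp(-tt / tauDecay) - exp(-tt / tauRise)))
}
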