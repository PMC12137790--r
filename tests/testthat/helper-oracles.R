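# Numeric oracles, independent of the closed-form implementation paths.

# brute-force extended Tofts: vp*Cp(t) + Ktrans * int_0^t Cp(tau) exp(-kep (t-tau)) dtau
# (adaptive quadrature on the exported AIF; kep in 1/min, t in s)
bruteTofts <- function(t_s, u, theta = AIFParameters()) {
  kepm <- kep(u)
  Kt <- ktrans(u)
  vapply(t_s, function(ts) {
    if (ts <= 0) return(0)
    conv <- stats::integrate(function(tau)
      aifConcentration(tau, theta) * exp(-kepm * (ts - tau) / 60),
      lower = 0, upper = ts, rel.tol = 1e-12, abs.tol = 1e-15,
      subdivisions = 1000L)$value / 60
    vp(u) * aifConcentration(ts, theta) + Kt * conv
  }, numeric(1))
}

# trapezoidal window mean of an arbitrary curve function, step in seconds
trapWindowMean <- function(f, center, dt, step = 0.001) {
  g <- seq(center - dt / 2, center + dt / 2, by = step)
  v <- f(g)
  sum((utils::head(v, -1) + utils::tail(v, -1)) / 2) * step / dt
}

refAIF <- function() AIFParameters()

# deterministic spread of tissue parameters covering the prior box
paramGrid <- function() {
  PKParameters(vp = c(0.001, 0.025, 0.1, 0.37, 0.05, 0.2),
               ve = c(0.05, 0.3, 0.9, 0.5, 0.7, 0.15),
               kep = c(0.1, 1, 2.8, 0.5, 1.7, 2.2))
}
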