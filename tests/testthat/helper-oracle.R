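# Independent propagation oracles, deliberately simple and separate from the
# package kernels: a hand-rolled fixed-step 4th-order Runge-Kutta integrator
# and a deSolve-based adaptive integrator for the same linear ODE dM/dt = G M.

rk4_propagate <- function(G, M0, T, dt = 1e-5) {
  n <- ceiling(T / dt)
  h <- T / n
  M <- M0
  for (i in seq_len(n)) {
    k1 <- G %*% M
    k2 <- G %*% (M + h / 2 * k1)
    k3 <- G %*% (M + h / 2 * k2)
    k4 <- G %*% (M + h * k3)
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  drop(M)
}

lsoda_propagate <- function(G, M0, T) {
  deriv <- function(t, y, parms) list(drop(G %*% y))
  out <- deSolve::lsoda(y = M0, times = c(0, T), func = deriv,
                        rtol = 1e-11, atol = 1e-12, maxsteps = 1e6)
  unname(out[2, -1])
}
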