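# Independent fixed-step 4th-order Runge-Kutta oracles for the two season
# phases, written directly from the within-season equations.  Specialised
# scalar loops (no closures) so a dt = 1e-5 phase stays fast enough to run
# in a loop over random parameter draws.

oracle_parasitoid <- function(p0, v_prev, E_t, tau, len, dt = 1e-5) {
  n <- ceiling(len / dt)
  dt <- len / n
  p <- p0; q <- 0
  for (i in seq_len(n)) {
    k1p <- -(v_prev - q) * p / tau;              k1q <- -E_t * k1p
    p2 <- p + dt / 2 * k1p; q2 <- q + dt / 2 * k1q
    k2p <- -(v_prev - q2) * p2 / tau;            k2q <- -E_t * k2p
    p3 <- p + dt / 2 * k2p; q3 <- q + dt / 2 * k2q
    k3p <- -(v_prev - q3) * p3 / tau;            k3q <- -E_t * k3p
    p4 <- p + dt * k3p; q4 <- q + dt * k3q
    k4p <- -(v_prev - q4) * p4 / tau;            k4q <- -E_t * k4p
    p <- p + dt / 6 * (k1p + 2 * k2p + 2 * k3p + k4p)
    q <- q + dt / 6 * (k1q + 2 * k2q + 2 * k3q + k4q)
  }
  list(p_end = p, q_end = q)
}

oracle_wasp <- function(emergence, E_d, mu, len, dt = 1e-5) {
  n <- ceiling(len / dt)
  dt <- len / n
  u <- 0; v <- 0
  for (i in seq_len(n)) {
    k1u <- -mu * (2 - v) * u + emergence;  k1v <- E_d * mu * (1 - v) * u
    u2 <- u + dt / 2 * k1u; v2 <- v + dt / 2 * k1v
    k2u <- -mu * (2 - v2) * u2 + emergence; k2v <- E_d * mu * (1 - v2) * u2
    u3 <- u + dt / 2 * k2u; v3 <- v + dt / 2 * k2v
    k3u <- -mu * (2 - v3) * u3 + emergence; k3v <- E_d * mu * (1 - v3) * u3
    u4 <- u + dt * k3u; v4 <- v + dt * k3v
    k4u <- -mu * (2 - v4) * u4 + emergence; k4v <- E_d * mu * (1 - v4) * u4
    u <- u + dt / 6 * (k1u + 2 * k2u + 2 * k3u + k4u)
    v <- v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
  }
  list(u_end = u, v_end = v)
}

# helper to build a season_series-shaped data frame for diagnostics tests
fake_series <- function(v, q = rep(0, length(v))) {
  n <- length(v)
  df <- data.frame(year = seq_len(n), v_end = v, q_end = q,
                   p_end = rep(NA_real_, n), u_end = rep(NA_real_, n),
                   clamped = rep(FALSE, n))
  class(df) <- c("season_series", "data.frame")
  df
}
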