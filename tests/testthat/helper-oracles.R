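# Independent oracles, coded directly from the model definitions and kept
# deliberately separate from the package implementation.

# Literal term-by-term transcription of the six sector equations.
oracle_proteome_rhs <- function(state, S, A, p) {
  Gamma <- state[["Gamma"]]; m_E <- state[["m_E"]]; m_R <- state[["m_R"]]
  E <- state[["E"]]; y <- state[["y"]]; R <- state[["R"]]
  u <- p$mu * (S * A) / (p$k + S * A)
  dGamma <- p$theta_b + p$theta_i * R / (1 + R) - p$delta_G * Gamma
  dm_E <- p$theta_E * (Gamma^p$n / (Gamma^p$n + p$omega^p$n)) +
    p$theta_hat_E * u - p$eta_E * m_E
  dm_R <- p$theta_R * (p$omega^p$n / (Gamma^p$n + p$omega^p$n)) +
    p$theta_hat_R * u - p$eta_R * m_R
  cap_E <- if (R < 1e-12) 1 else 1 - (E / R) * p$J_E
  cap_y <- if (R < 1e-12) 1 else 1 - (y / R) * p$J_E
  dE <- (1 - p$phi) * (p$kappa_E * m_E) * cap_E - p$delta_E * E
  dy <- p$phi * (p$kappa_E * m_E) * cap_y - p$delta_E * y
  dR <- p$kappa_R * m_R * (1 - p$J_R) - p$delta_R * R
  c(Gamma = dGamma, m_E = dm_E, m_R = dm_R, E = dE, y = dy, R = dR)
}

# Textbook bilinear interpolation on a rectilinear grid, with edge clamping.
oracle_bilinear <- function(xg, yg, Z, xq, yq) {
  xq <- min(max(xq, xg[1]), xg[length(xg)])
  yq <- min(max(yq, yg[1]), yg[length(yg)])
  i <- min(max(findInterval(xq, xg), 1), length(xg) - 1)
  j <- min(max(findInterval(yq, yg), 1), length(yg) - 1)
  tx <- (xq - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (yq - yg[j]) / (yg[j + 1] - yg[j])
  (1 - tx) * (1 - ty) * Z[i, j] + tx * (1 - ty) * Z[i + 1, j] +
    (1 - tx) * ty * Z[i, j + 1] + tx * ty * Z[i + 1, j + 1]
}

# Hand-built rate_surface with prescribed values, for interpolation tests.
fake_surface <- function(S_grid, A_grid, lambda, beta = lambda) {
  structure(list(S_grid = S_grid, A_grid = A_grid,
                 lambda = lambda, beta = beta, fingerprint = "fake"),
            class = "rate_surface")
}

# The standard surfaces used across test files; memoised in the package's
# session cache so each is built once per test run.
default_surface <- function() cached_rate_surface()
theta_surface <- function(theta_i) {
  cached_rate_surface(proteome_params(theta_i = theta_i))
}
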