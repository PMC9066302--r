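#' Saturating nutrient uptake
#'
#' Joint uptake of substrate (glucose, `S`) and the focal amino acid (`A`),
#' modelled as a single saturating function of their product:
#' `u(S, A) = mu * S * A / (k + S * A)`. Both nutrients are required: the
#' uptake flux vanishes whenever either concentration is zero, which is what
#' makes the strains behave as auxotrophs.
#'
#' @param S Substrate concentration(s), `>= 0`.
#' @param A Amino-acid concentration(s), `>= 0`.
#' @param params A [proteome_params()] object.
#' @return Uptake rate(s), bounded in `[0, mu)`, nondecreasing in `S` and `A`.
#' @examples
#' uptake(10, 5, proteome_params())  # S*A = k: half-saturation, mu/2
#' @export
uptake <- function(S, A, params = proteome_params()) {
  stopifnot(inherits(params, "proteome_params"))
  if (any(S < 0) || any(A < 0)) {
    stop("uptake: concentrations must be nonnegative", call. = FALSE)
  }
  params$mu * (S * A) / (params$k + S * A)
}

#' ppGpp synthesis-degradation balance
#'
#' Time derivative of the alarmone concentration: basal synthesis plus
#' ribosome-induced synthesis saturating in `R`, minus first-order
#' degradation: `theta_b + theta_i * R / (1 + R) - delta_G * Gamma`.
#' The fixed point at given `R` is
#' `(theta_b + theta_i * R / (1 + R)) / delta_G`.
#'
#' @param Gamma ppGpp concentration, `>= 0`.
#' @param R Ribosomal-sector protein concentration, `>= 0`.
#' @param params A [proteome_params()] object.
#' @return dGamma/dt.
#' @export
ppgpp_rhs <- function(Gamma, R, params = proteome_params()) {
  stopifnot(inherits(params, "proteome_params"))
  if (any(Gamma < 0) || any(R < 0)) {
    stop("ppgpp_rhs: Gamma and R must be nonnegative", call. = FALSE)
  }
  params$theta_b + params$theta_i * R / (1 + R) - params$delta_G * Gamma
}

proteome_state_names <- c("Gamma", "m_E", "m_R", "E", "y", "R")

as_proteome_state <- function(state) {
  state <- unlist(state)
  if (is.null(names(state)) || !all(proteome_state_names %in% names(state))) {
    if (length(state) != 6L) {
      stop("proteome state needs components ",
           paste(proteome_state_names, collapse = ", "), call. = FALSE)
    }
    names(state) <- proteome_state_names
  }
  state[proteome_state_names]
}

# Ribosome-capacity saturation of translation. Each sector's synthesis slows
# as its protein pool approaches the share of translating ribosomes; the
# guard at R < eps avoids 0/0 when no ribosomes exist yet.
capacity_terms <- function(E, y, R, params, eps = 1e-12) {
  if (R < eps) {
    c(E = 1, y = 1, R = 1 - params$J_R)
  } else {
    c(E = 1 - (E / R) * params$J_E,
      y = 1 - (y / R) * params$J_E,
      R = 1 - params$J_R)
  }
}

#' Right-hand side of the proteome-allocation ODEs
#'
#' The six coupled equations of the intracellular model: ppGpp balance
#' ([ppgpp_rhs()]); sector mRNAs transcribed at a ppGpp-gated Hill rate
#' (activating for E, repressing for R) plus an uptake-driven basal rate,
#' and degraded first-order; sector proteins translated at
#' `kappa * m * cap` with ribosome-capacity saturation `cap` (see Details)
#' and degraded first-order. The E-sector synthesis flux is split
#' `(1 - phi)` / `phi` between the catabolic pool `E` and the amino-acid
#' export sub-sector `y`.
#'
#' @details The capacity terms are `cap_E = 1 - (E/R) J_E`,
#' `cap_y = 1 - (y/R) J_E` and `cap_R = 1 - J_R`, with `cap = 1` substituted
#' when `R < 1e-12`. At any state with a zero component the corresponding
#' derivative is nonnegative, so trajectories started nonnegative remain so
#' (up to solver tolerance; see [proteome_trajectory()]).
#'
#' @param state Named numeric vector `(Gamma, m_E, m_R, E, y, R)`, `>= 0`.
#' @param S,A Substrate and amino-acid concentrations, `>= 0`.
#' @param params A [proteome_params()] object.
#' @return Named numeric vector of the six time derivatives.
#' @export
proteome_rhs <- function(state, S, A, params = proteome_params()) {
  stopifnot(inherits(params, "proteome_params"))
  state <- as_proteome_state(state)
  if (any(state < 0) || S < 0 || A < 0) {
    stop("proteome_rhs: state and environment must be nonnegative",
         call. = FALSE)
  }
  u <- uptake(S, A, params)
  Gamma <- state[["Gamma"]]
  hill_on <- Gamma^params$n / (Gamma^params$n + params$omega^params$n)
  hill_off <- params$omega^params$n / (Gamma^params$n + params$omega^params$n)
  cap <- capacity_terms(state[["E"]], state[["y"]], state[["R"]], params)
  c(Gamma = ppgpp_rhs(Gamma, state[["R"]], params),
    m_E = params$theta_E * hill_on + params$theta_hat_E * u -
      params$eta_E * state[["m_E"]],
    m_R = params$theta_R * hill_off + params$theta_hat_R * u -
      params$eta_R * state[["m_R"]],
    E = (1 - params$phi) * params$kappa_E * state[["m_E"]] * cap[["E"]] -
      params$delta_E * state[["E"]],
    y = params$phi * params$kappa_E * state[["m_E"]] * cap[["y"]] -
      params$delta_E * state[["y"]],
    R = params$kappa_R * state[["m_R"]] * cap[["R"]] -
      params$delta_R * state[["R"]])
}

default_proteome_init <- function() {
  c(Gamma = 0.1, m_E = 0.1, m_R = 0.1, E = 0.1, y = 0.01, R = 0.1)
}

proteome_desolve_rhs <- function(t, state, parms) {
  # deSolve adapter; negative excursions within solver steps are projected
  # back to the admissible region before evaluating the rhs
  state <- pmax(state, 0)
  list(proteome_rhs(state, parms$S, parms$A, parms$params))
}

#' Integrate the proteome model in time
#'
#' Solves the six-equation sector model at fixed nutrient concentrations with
#' a stiff-capable adaptive solver (`deSolve::lsoda`). Any negative component
#' produced by solver error is clamped to zero (projection onto the
#' admissible region).
#'
#' @param S,A Fixed substrate and amino-acid concentrations.
#' @param params A [proteome_params()] object.
#' @param times Output time points (strictly increasing, starting at the
#'   initial time).
#' @param init Initial state; defaults to the documented standard start
#'   `(0.1, 0.1, 0.1, 0.1, 0.01, 0.1)`.
#' @param rtol,atol Solver tolerances.
#' @return A data frame with columns `time, Gamma, m_E, m_R, E, y, R`.
#' @export
proteome_trajectory <- function(S, A, params = proteome_params(),
                                times = seq(0, 10, by = 0.05),
                                init = default_proteome_init(),
                                rtol = 1e-8, atol = 1e-10) {
  init <- as_proteome_state(init)
  if (any(init < 0)) stop("initial state must be nonnegative", call. = FALSE)
  out <- deSolve::lsoda(init, times, proteome_desolve_rhs,
                        parms = list(S = S, A = A, params = params),
                        rtol = rtol, atol = atol, maxsteps = 50000)
  df <- as.data.frame(out)
  names(df) <- c("time", proteome_state_names)
  df[proteome_state_names] <- lapply(df[proteome_state_names], pmax, 0)
  df
}

#' Write or read a proteome trajectory as CSV
#'
#' Long-format CSV with columns `time, Gamma, m_E, m_R, E, y, R`.
#'
#' @param trajectory A data frame from [proteome_trajectory()].
#' @param path File path.
#' @return `write_proteome_trajectory()` returns `path` invisibly;
#'   `read_proteome_trajectory()` returns the data frame.
#' @export
write_proteome_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_proteome_trajectory
#' @export
read_proteome_trajectory <- function(path) {
  utils::read.csv(path)
}

# Damped Newton polish of a candidate fixed point; finite-difference Jacobian.
newton_polish <- function(state, S, A, params, tol, max_iter = 25L) {
  f <- function(s) proteome_rhs(pmax(s, 0), S, A, params)
  s <- pmax(state, 0)
  res <- f(s)
  for (it in seq_len(max_iter)) {
    if (max(abs(res)) < tol) break
    J <- matrix(0, 6, 6)
    h <- pmax(abs(s), 1) * 1e-7
    for (j in 1:6) {
      sp <- s
      sp[j] <- sp[j] + h[j]
      J[, j] <- (f(sp) - res) / h[j]
    }
    step <- tryCatch(solve(J, -res), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      s_new <- pmax(s + lambda * step, 0)
      res_new <- f(s_new)
      if (max(abs(res_new)) < max(abs(res)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    s <- s_new
    res <- res_new
  }
  list(state = s, residual = max(abs(res)))
}

#' Steady state of the proteome model
#'
#' Locates the fixed point of the sector ODEs at fixed `(S, A)` by
#' integrating from the standard initial state to a long horizon, then
#' polishing with damped Newton iterations until the max-norm residual of
#' the right-hand side falls below `tol`. If the residual criterion is not
#' met the horizon is extended fivefold once before failing with an error
#' that reports the residual reached.
#'
#' The steady-state ribosomal pool `R*` is the model's growth-rate proxy
#' (ribosome concentration is proportional to growth rate) and the
#' steady-state export sub-sector `y*` is its amino-acid export proxy; they
#' are returned as `lambda` and `beta` and gridded by
#' [build_rate_surface()].
#'
#' @param S,A Nutrient concentrations, `>= 0`.
#' @param params A [proteome_params()] object.
#' @param tol Residual tolerance (max-norm of the rhs), `> 0`.
#' @param t_max Integration horizon before polishing.
#' @param init Initial state for the relaxation integration.
#' @return A list with components `state` (named steady state), `residual`,
#'   `lambda` (`R*`) and `beta` (`y*`).
#' @export
proteome_steady_state <- function(S, A, params = proteome_params(),
                                  tol = 1e-8, t_max = 200,
                                  init = default_proteome_init()) {
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  relax <- function(horizon, start) {
    out <- deSolve::lsoda(as_proteome_state(start), c(0, horizon),
                          proteome_desolve_rhs,
                          parms = list(S = S, A = A, params = params),
                          rtol = 1e-8, atol = 1e-8)
    pmax(out[nrow(out), -1], 0)
  }
  s <- relax(t_max, init)
  pol <- newton_polish(s, S, A, params, tol)
  if (pol$residual >= tol) {
    s <- relax(5 * t_max, pol$state)
    pol <- newton_polish(s, S, A, params, tol)
  }
  if (pol$residual >= tol) {
    stop(sprintf(
      "proteome_steady_state did not converge at (S = %g, A = %g): residual %.3e >= tol %.3e",
      S, A, pol$residual, tol), call. = FALSE)
  }
  state <- as_proteome_state(pol$state)
  list(state = state, residual = pol$residual,
       lambda = unname(state["R"]), beta = unname(state["y"]))
}

#' Proteome sector fractions
#'
#' Post-hoc sector fractions of a proteome state, reported relative to the
#' growth-linked proteome `E + y + R` (the housekeeping sector is constant
#' and not simulated).
#'
#' @param state A proteome state (named vector) or the `state` component of
#'   [proteome_steady_state()].
#' @return Named vector with fractions `E` (including y) and `R`.
#' @export
sector_fractions <- function(state) {
  state <- as_proteome_state(state)
  total <- state[["E"]] + state[["y"]] + state[["R"]]
  if (total <= 0) stop("sector fractions undefined for an empty proteome",
                       call. = FALSE)
  c(E = (state[["E"]] + state[["y"]]) / total, R = state[["R"]] / total)
}
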