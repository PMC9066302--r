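#' Population-level strain parameters
#'
#' Parameters coupling the intracellular rate proxies to the
#' consumer-resource model: the uptake-to-biomass conversion `c`, the growth
#' conversion `k1` (effective maximum growth rate is `k1 * lambda`), the
#' amino-acid conversion `k2`, and the Monod half-saturation `K` of glucose
#' uptake.
#'
#' `k2` is indexed by the amino acid, not the producer: the `k2` of strain
#' `B_x` converts export flux into amino acid X — the resource B_x consumes,
#' produced by its partner B_y. The defaults give the X pool half the
#' conversion of the Y pool, the asymmetry behind the parasitic regime at
#' intermediate supplementation.
#'
#' @param c Cell efficiency (uptake-to-biomass conversion).
#' @param k1 Growth conversion coefficient.
#' @param k2 Amino-acid conversion coefficient of this strain's resource.
#' @param K Monod half-saturation of glucose uptake. The default (40, same
#'   order as the cell-level uptake half-saturation) places the standard
#'   horizon `T = 180` in the growth-limited regime where cross-feeding
#'   matters; see the methods vignette.
#' @return An object of class `strain_params`.
#' @export
strain_params <- function(c = 13.95e9, k1 = 1e-11, k2 = 0.5e-9, K = 40) {
  vals <- c(c = c, k1 = k1, k2 = k2, K = K)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("strain_params fields must be finite and nonnegative", call. = FALSE)
  }
  if (K <= 0) stop("K must be positive", call. = FALSE)
  structure(as.list(vals), class = "strain_params")
}

#' Default cross-feeding strain pair
#'
#' The standard two-auxotroph parameterisation: identical cell efficiency,
#' growth conversion and Monod constant, with amino-acid conversion 0.5e-9
#' for the X pool (consumed by B_x) and 1e-9 for the Y pool (consumed by
#' B_y).
#'
#' @param K Monod half-saturation shared by both strains.
#' @return A list with `strain_params` components `x` and `y`.
#' @export
strain_pair <- function(K = 40) {
  list(x = strain_params(k2 = 0.5e-9, K = K),
       y = strain_params(k2 = 1e-9, K = K))
}

#' Monod glucose uptake
#'
#' `U(S) = lambda_hat * S / (K + S)`, the per-capita uptake rate of a strain
#' whose effective maximum rate `lambda_hat = k1 * lambda(S, A)` carries the
#' amino-acid dependence through the interpolated growth surface.
#'
#' @param S Substrate concentration, `>= 0`.
#' @param lambda_hat Effective maximum rate, `>= 0`.
#' @param K Half-saturation constant, `> 0`.
#' @return Uptake rate.
#' @examples
#' monod_uptake(40, 2e-10, 40)  # S = K: half of lambda_hat
#' @export
monod_uptake <- function(S, lambda_hat, K) {
  if (any(K <= 0)) stop("K must be positive", call. = FALSE)
  if (any(S < 0)) stop("S must be nonnegative", call. = FALSE)
  lambda_hat * S / (K + S)
}

community_state_names <- c("S", "X", "Y", "Bx", "By")

as_community_state <- function(state) {
  state <- unlist(state)
  if (is.null(names(state)) || !all(community_state_names %in% names(state))) {
    if (length(state) != 5L) {
      stop("community state needs components ",
           paste(community_state_names, collapse = ", "), call. = FALSE)
    }
    names(state) <- community_state_names
  }
  state[community_state_names]
}

#' Right-hand side of the cross-feeding community ODEs
#'
#' Two strains compete for glucose `S` and exchange amino acids: `X` is
#' consumed by `B_x` and produced by `B_y`, `Y` the reverse. With per-capita
#' uptake `U` and growth `G = c * U`:
#' `dS/dt = -(U_x B_x + U_y B_y) S`;
#' `dX/dt = beta_hat_x G_y B_y - U_x B_x`;
#' `dY/dt = beta_hat_y G_x B_x - U_y B_y`;
#' `dB/dt = G B` for each strain. The effective rates `lambda_hat` and
#' `beta_hat` are held constant between calls (they are refreshed from the
#' rate surface by [simulate_multiscale()]).
#'
#' @param state Named vector `(S, X, Y, Bx, By)`, `>= 0`.
#' @param rates List with `lambda_hat_x`, `lambda_hat_y`, `beta_hat_x`,
#'   `beta_hat_y`.
#' @param pair A [strain_pair()] list.
#' @return Named vector of time derivatives.
#' @export
community_rhs <- function(state, rates, pair = strain_pair()) {
  state <- as_community_state(state)
  if (any(state < 0)) {
    stop("community_rhs: state must be nonnegative", call. = FALSE)
  }
  S <- state[["S"]]
  Ux <- monod_uptake(S, rates$lambda_hat_x, pair$x$K)
  Uy <- monod_uptake(S, rates$lambda_hat_y, pair$y$K)
  Gx <- pair$x$c * Ux
  Gy <- pair$y$c * Uy
  c(S = -(Ux * state[["Bx"]] + Uy * state[["By"]]) * S,
    X = rates$beta_hat_x * Gy * state[["By"]] - Ux * state[["Bx"]],
    Y = rates$beta_hat_y * Gx * state[["Bx"]] - Uy * state[["By"]],
    Bx = Gx * state[["Bx"]],
    By = Gy * state[["By"]])
}

community_desolve_rhs <- function(t, state, parms) {
  list(unname(community_rhs(pmax(state, 0), parms$rates, parms$pair)))
}

#' Sequential multi-scale community simulation
#'
#' Integrates the community ODEs over `[0, T]` in sub-intervals of length
#' `dt`. At the start of each sub-interval the growth proxy `lambda` and
#' export proxy `beta` of each strain are interpolated from its rate surface
#' at the current nutrient concentrations — `(S, X)` for `B_x`, `(S, Y)` for
#' `B_y` — converted to effective rates (`lambda_hat = k1 * lambda`,
#' `beta_hat = k2 * beta`), frozen, and the population ODEs are integrated
#' across the sub-interval with `deSolve::lsoda`. Negative excursions are
#' clamped to zero at sub-interval boundaries.
#'
#' @param init Named initial state `(S, X, Y, Bx, By)`; defaults to a 50-50
#'   co-culture of 1e4 cells per strain in the standard low-resource
#'   environment.
#' @param surfaces A single `rate_surface` shared by both strains, or a list
#'   with components `x` and `y`.
#' @param pair A [strain_pair()] list.
#' @param T Total duration (model time units).
#' @param dt Coupling sub-interval length (`0 < dt <= T`).
#' @param rtol Relative solver tolerance.
#' @return An object of classes `community_trajectory` and `data.frame`:
#'   columns `time, S, X, Y, Bx, By, lambda_x, lambda_y, beta_x, beta_y`,
#'   one row per sub-interval boundary; the rate columns hold the effective
#'   surface values applied on the interval starting at that row's time (NA
#'   on the final row).
#' @export
simulate_multiscale <- function(init = community_init(),
                                surfaces = NULL,
                                pair = strain_pair(),
                                T = 180, dt = 1, rtol = 1e-8) {
  if (!(dt > 0 && dt <= T)) stop("need 0 < dt <= T", call. = FALSE)
  if (is.null(surfaces)) {
    surfaces <- cached_rate_surface()
  }
  if (inherits(surfaces, "rate_surface")) {
    surfaces <- list(x = surfaces, y = surfaces)
  }
  state <- as_community_state(init)
  if (any(state < 0)) stop("initial state must be nonnegative", call. = FALSE)
  n_steps <- ceiling(T / dt - 1e-9)
  out <- matrix(NA_real_, n_steps + 1L, 10L)
  colnames(out) <- c("time", community_state_names,
                     "lambda_x", "lambda_y", "beta_x", "beta_y")
  atol <- c(1e-14, 1e-14, 1e-14, 1e-4, 1e-4)
  t_now <- 0
  for (step in seq_len(n_steps)) {
    rx <- interpolate_rates(surfaces$x, state[["S"]], state[["X"]])
    ry <- interpolate_rates(surfaces$y, state[["S"]], state[["Y"]])
    rates <- list(lambda_hat_x = pair$x$k1 * rx$lambda,
                  lambda_hat_y = pair$y$k1 * ry$lambda,
                  beta_hat_x = pair$x$k2 * ry$beta,
                  beta_hat_y = pair$y$k2 * rx$beta)
    out[step, ] <- c(t_now, state, rx$lambda, ry$lambda, rx$beta, ry$beta)
    h <- min(dt, T - t_now)
    sol <- tryCatch(
      deSolve::lsoda(state, c(0, h), community_desolve_rhs,
                     parms = list(rates = rates, pair = pair),
                     rtol = rtol, atol = atol),
      error = function(e) {
        stop(sprintf("community integration failed on [%g, %g]: %s",
                     t_now, t_now + h, conditionMessage(e)), call. = FALSE)
      })
    state <- pmax(as_community_state(sol[nrow(sol), -1]), 0)
    t_now <- t_now + h
  }
  out[n_steps + 1L, 1:6] <- c(t_now, state)
  df <- as.data.frame(out)
  class(df) <- c("community_trajectory", "data.frame")
  df
}

#' Standard community initial state
#'
#' @param S0,X0,Y0 Initial glucose and amino-acid concentrations.
#' @param Bx0,By0 Initial strain densities (cells per volume).
#' @return Named numeric state vector.
#' @export
community_init <- function(S0 = 1, X0 = 1, Y0 = 1, Bx0 = 1e4, By0 = 1e4) {
  c(S = S0, X = X0, Y = Y0, Bx = Bx0, By = By0)
}

#' Monoculture simulation
#'
#' Runs [simulate_multiscale()] with the partner strain absent (density
#' fixed at zero). For interaction comparisons the standard monoculture
#' inoculum equals the strain's co-culture share, so the contrast isolates
#' the partner's effect rather than the inoculum's.
#'
#' @param strain Which strain is present, `"x"` or `"y"`.
#' @param init Initial state; the partner's density is overwritten with 0.
#' @inheritParams simulate_multiscale
#' @return A `community_trajectory`.
#' @export
simulate_monoculture <- function(strain = c("x", "y"),
                                 init = community_init(),
                                 surfaces = NULL, pair = strain_pair(),
                                 T = 180, dt = 1, rtol = 1e-8) {
  strain <- match.arg(strain)
  init <- as_community_state(init)
  init[[if (strain == "x") "By" else "Bx"]] <- 0
  simulate_multiscale(init, surfaces, pair, T = T, dt = dt, rtol = rtol)
}

#' Final state of a community trajectory
#'
#' @param trajectory A `community_trajectory`.
#' @return Named vector `(S, X, Y, Bx, By)` at the last time point.
#' @export
final_state <- function(trajectory) {
  stopifnot(inherits(trajectory, "community_trajectory"))
  as_community_state(trajectory[nrow(trajectory), community_state_names])
}

#' Write a community trajectory as long-format CSV
#'
#' @param trajectory A `community_trajectory`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_community_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
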