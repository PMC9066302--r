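#' Computational amino-acid checkerboard
#'
#' For every combination of initial amino-acid concentrations `(X0, Y0)`,
#' runs a 50-50 co-culture and both share-inoculum monocultures of the
#' cross-feeding pair under identical conditions and records the relative
#' density (community total minus the sum of the independent monoculture
#' yields, see [interaction_assay()]) and the
#' mutualism/parasitism/competition classification. Monoculture runs are
#' shared across the grid (a `B_x` monoculture is unaffected by `Y0` and
#' vice versa), so an n-by-m board costs `n*m + n + m` simulations.
#' Deterministic.
#'
#' @param X0_values,Y0_values Nonnegative axis concentrations (model units).
#' @param S0 Initial glucose concentration.
#' @param total_inoculum Total initial density (split 50-50 between the
#'   co-culture strains and between the two monocultures).
#' @param surfaces,pair,T,dt Passed to [simulate_multiscale()].
#' @param tol Classification tolerance.
#' @return An object of classes `checkerboard_grid` and `data.frame` with
#'   one row per cell: `X0, Y0, co_Bx, co_By, mono_Bx, mono_By,
#'   relative_density, class`.
#' @export
checkerboard_sweep <- function(X0_values = seq(0, 2, length.out = 9),
                               Y0_values = seq(0, 2, length.out = 9),
                               S0 = 1, total_inoculum = 2e4,
                               surfaces = NULL, pair = strain_pair(),
                               T = 180, dt = 1, tol = 1e-3) {
  if (any(X0_values < 0) || any(Y0_values < 0)) {
    stop("checkerboard axes must be nonnegative", call. = FALSE)
  }
  if (is.null(surfaces)) surfaces <- cached_rate_surface()
  run_cell <- function(fun, X0, Y0) {
    tryCatch(fun(), error = function(e) {
      stop(sprintf("checkerboard cell (X0 = %g, Y0 = %g) failed: %s",
                   X0, Y0, conditionMessage(e)), call. = FALSE)
    })
  }
  mono_x <- vapply(X0_values, function(X0) {
    run_cell(function() final_state(simulate_monoculture(
      "x", community_init(S0, X0, 0, Bx0 = total_inoculum / 2, By0 = 0),
      surfaces, pair, T = T, dt = dt))[["Bx"]], X0, NA)
  }, numeric(1))
  mono_y <- vapply(Y0_values, function(Y0) {
    run_cell(function() final_state(simulate_monoculture(
      "y", community_init(S0, 0, Y0, Bx0 = 0, By0 = total_inoculum / 2),
      surfaces, pair, T = T, dt = dt))[["By"]], NA, Y0)
  }, numeric(1))
  grid <- expand.grid(X0 = X0_values, Y0 = Y0_values)
  res <- mapply(function(X0, Y0) {
    co <- run_cell(function() final_state(simulate_multiscale(
      community_init(S0, X0, Y0,
                     Bx0 = total_inoculum / 2, By0 = total_inoculum / 2),
      surfaces, pair, T = T, dt = dt)), X0, Y0)
    c(co[["Bx"]], co[["By"]])
  }, grid$X0, grid$Y0)
  grid$co_Bx <- res[1, ]
  grid$co_By <- res[2, ]
  grid$mono_Bx <- mono_x[match(grid$X0, X0_values)]
  grid$mono_By <- mono_y[match(grid$Y0, Y0_values)]
  grid$relative_density <- (grid$co_Bx + grid$co_By) -
    (grid$mono_Bx + grid$mono_By)
  grid$class <- classify_interaction(grid$co_Bx, grid$co_By,
                                     grid$mono_Bx, grid$mono_By, tol = tol)
  class(grid) <- c("checkerboard_grid", "data.frame")
  grid
}

#' @export
print.checkerboard_grid <- function(x, ...) {
  counts <- table(factor(x$class,
                         levels = c("mutualism", "parasitism", "competition")))
  cat(sprintf("<checkerboard_grid> %d cells: %s\n", nrow(x),
              paste(names(counts), counts, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Stringent-response sweep
#'
#' Varies the ribosome-induced ppGpp synthesis rate `theta_i`, rebuilding
#' the steady-state rate surface for each value (through the surface cache)
#' and running the 50-50 co-culture vs monoculture comparison in a fixed
#' environment. Returns the relative density and interaction class per
#' `theta_i`, the computational probe of how dynamic proteome allocation
#' shapes cooperative growth.
#'
#' @param theta_values Nonnegative `theta_i` values.
#' @param S0,X0,Y0 Environment of the comparison.
#' @param params Baseline [proteome_params()]; `theta_i` is overridden per
#'   sweep point.
#' @param pair,T,dt,total_inoculum,tol As in [checkerboard_sweep()].
#' @param S_grid,A_grid Surface grids for the rebuilds.
#' @param cache_dir Optional on-disk surface cache.
#' @return A data frame with columns `theta_i, co_Bx, co_By, mono_Bx,
#'   mono_By, relative_density, class`.
#' @export
theta_sweep <- function(theta_values, S0 = 1, X0 = 1, Y0 = 1,
                        params = proteome_params(), pair = strain_pair(),
                        T = 180, dt = 1, total_inoculum = 2e4, tol = 1e-3,
                        S_grid = default_S_grid(), A_grid = default_A_grid(),
                        cache_dir = NULL) {
  if (any(theta_values < 0)) {
    stop("theta_i values must be nonnegative", call. = FALSE)
  }
  rows <- lapply(theta_values, function(th) {
    pars <- do.call(proteome_params, utils::modifyList(unclass(params),
                                                       list(theta_i = th)))
    surf <- cached_rate_surface(pars, S_grid, A_grid, cache_dir = cache_dir)
    res <- interaction_assay(S0, X0, Y0, fraction = 0.5,
                             total_inoculum = total_inoculum,
                             surfaces = surf, pair = pair, T = T, dt = dt,
                             tol = tol)
    data.frame(theta_i = th,
               co_Bx = res$co[["Bx"]], co_By = res$co[["By"]],
               mono_Bx = res$mono_x, mono_By = res$mono_y,
               relative_density = res$relative_density,
               class = res$class)
  })
  do.call(rbind, rows)
}
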