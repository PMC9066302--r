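#' Default nutrient grids for rate surfaces
#'
#' Grids spanning the concentration ranges the community simulations explore:
#' glucose from 0 to 2 (initial substrate is 1 in all standard runs) and
#' amino acid from 0 to 4 (checkerboards span 0 to 2 in model units, with
#' headroom for cross-feeding excursions; experimentally amino acids are
#' supplemented up to 4x basal). Both grids contain the exact zero boundary —
#' uptake vanishes there, which is where auxotrophy bites — followed by
#' logarithmically spaced points. Queries outside the hull are clamped to the
#' nearest edge, so the surface extent also defines where the model's
#' growth-rate response saturates.
#'
#' @param n Number of grid points per axis (including the zero point).
#' @return Numeric vector of strictly increasing concentrations.
#' @export
default_S_grid <- function(n = 25) c(0, 10^seq(-2, log10(2), length.out = n - 1))

#' @rdname default_S_grid
#' @export
default_A_grid <- function(n = 25) c(0, 10^seq(-2, log10(4), length.out = n - 1))

#' Precompute steady-state growth and export surfaces
#'
#' Evaluates [proteome_steady_state()] on a rectangular nutrient grid,
#' storing the growth-rate proxy `lambda = R*` and the export proxy
#' `beta = y*` for later interpolation by the population model. Deterministic
#' given the parameters and grids.
#'
#' @param S_grid,A_grid Strictly increasing nonnegative coordinates
#'   (length `>= 2`).
#' @param params A [proteome_params()] object.
#' @param tol Steady-state residual tolerance.
#' @return An object of class `rate_surface`: list with `S_grid`, `A_grid`,
#'   matrices `lambda` and `beta` (rows index `S_grid`, columns `A_grid`),
#'   and `fingerprint` of the generating parameters.
#' @seealso [interpolate_rates()], [cached_rate_surface()]
#' @export
build_rate_surface <- function(S_grid = default_S_grid(),
                               A_grid = default_A_grid(),
                               params = proteome_params(),
                               tol = 1e-8) {
  check_grid <- function(g, nm) {
    if (length(g) < 2 || any(g < 0) || any(diff(g) <= 0)) {
      stop(nm, " must be strictly increasing and nonnegative with length >= 2",
           call. = FALSE)
    }
  }
  check_grid(S_grid, "S_grid")
  check_grid(A_grid, "A_grid")
  lam <- matrix(NA_real_, length(S_grid), length(A_grid))
  bet <- lam
  for (i in seq_along(S_grid)) {
    for (j in seq_along(A_grid)) {
      ss <- tryCatch(
        proteome_steady_state(S_grid[i], A_grid[j], params, tol = tol),
        error = function(e) {
          stop(sprintf("surface cell (S = %g, A = %g) failed: %s",
                       S_grid[i], A_grid[j], conditionMessage(e)),
               call. = FALSE)
        })
      lam[i, j] <- ss$lambda
      bet[i, j] <- ss$beta
    }
  }
  structure(list(S_grid = S_grid, A_grid = A_grid,
                 lambda = lam, beta = bet,
                 fingerprint = params_fingerprint(params)),
            class = "rate_surface")
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf("<rate_surface> %d x %d grid, S in [%g, %g], A in [%g, %g]\n",
              length(x$S_grid), length(x$A_grid),
              min(x$S_grid), max(x$S_grid), min(x$A_grid), max(x$A_grid)))
  cat(sprintf("  lambda in [%.3g, %.3g], beta in [%.3g, %.3g], params %s\n",
              min(x$lambda), max(x$lambda), min(x$beta), max(x$beta),
              substr(x$fingerprint, 1, 8)))
  invisible(x)
}

#' Bilinear interpolation of a rate surface
#'
#' Evaluates the gridded `lambda` and `beta` surfaces at arbitrary
#' nonnegative nutrient concentrations. Inside the grid hull the
#' interpolation is bilinear (exact on nodes, bounded by the surrounding
#' corner values); queries outside the hull are clamped to the nearest edge
#' rather than extrapolated, preserving nonnegativity when population
#' trajectories transiently leave the grid.
#'
#' @param surface A [build_rate_surface()] object.
#' @param S,A Query concentrations (vectors of equal length, `>= 0`).
#' @return A list with numeric vectors `lambda` and `beta`.
#' @export
interpolate_rates <- function(surface, S, A) {
  if (!inherits(surface, "rate_surface")) {
    stop("surface must be a rate_surface", call. = FALSE)
  }
  if (length(surface$S_grid) < 2 || length(surface$A_grid) < 2) {
    stop("degenerate surface: grids need length >= 2", call. = FALSE)
  }
  if (any(S < 0) || any(A < 0)) {
    stop("interpolate_rates: concentrations must be nonnegative", call. = FALSE)
  }
  Sq <- pmin(pmax(S, min(surface$S_grid)), max(surface$S_grid))
  Aq <- pmin(pmax(A, min(surface$A_grid)), max(surface$A_grid))
  # interp2 takes x along columns of Z; our matrices are [S x A]
  list(lambda = pracma::interp2(surface$A_grid, surface$S_grid,
                                surface$lambda, Aq, Sq, method = "linear"),
       beta = pracma::interp2(surface$A_grid, surface$S_grid,
                              surface$beta, Aq, Sq, method = "linear"))
}

#' Serialize a rate surface
#'
#' Writes the surface as a CSV of `(S, A, lambda, beta)` triplets plus a
#' YAML sidecar (`<path>.yml`) holding the grids and the parameter
#' fingerprint; `read_rate_surface()` restores the object.
#'
#' @param surface A `rate_surface`.
#' @param path CSV file path.
#' @return `write_rate_surface()` returns `path` invisibly;
#'   `read_rate_surface()` returns the restored `rate_surface`.
#' @export
write_rate_surface <- function(surface, path) {
  stopifnot(inherits(surface, "rate_surface"))
  grid <- expand.grid(S = surface$S_grid, A = surface$A_grid)
  grid$lambda <- as.vector(surface$lambda)
  grid$beta <- as.vector(surface$beta)
  utils::write.csv(grid, path, row.names = FALSE)
  yaml::write_yaml(list(S_grid = surface$S_grid, A_grid = surface$A_grid,
                        fingerprint = surface$fingerprint),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_rate_surface
#' @export
read_rate_surface <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yml"))
  grid <- utils::read.csv(path)
  nS <- length(side$S_grid)
  nA <- length(side$A_grid)
  structure(list(S_grid = as.numeric(side$S_grid),
                 A_grid = as.numeric(side$A_grid),
                 lambda = matrix(grid$lambda, nS, nA),
                 beta = matrix(grid$beta, nS, nA),
                 fingerprint = side$fingerprint),
            class = "rate_surface")
}

.surface_cache <- new.env(parent = emptyenv())

#' Cached surface construction
#'
#' Memoised [build_rate_surface()]: surfaces are cached in memory for the
#' session, keyed by the parameter fingerprint and the grids, and optionally
#' persisted to `cache_dir` as CSV + YAML. Checkerboard and
#' stringent-response sweeps re-use surfaces through this cache.
#'
#' @inheritParams build_rate_surface
#' @param cache_dir Optional directory for on-disk persistence.
#' @return A `rate_surface`.
#' @export
cached_rate_surface <- function(params = proteome_params(),
                                S_grid = default_S_grid(),
                                A_grid = default_A_grid(),
                                tol = 1e-8, cache_dir = NULL) {
  key <- rlang::hash(list(params_fingerprint(params), S_grid, A_grid, tol))
  if (!is.null(.surface_cache[[key]])) return(.surface_cache[[key]])
  if (!is.null(cache_dir)) {
    file <- file.path(cache_dir, paste0("surface-", key, ".csv"))
    if (file.exists(file) && file.exists(paste0(file, ".yml"))) {
      surf <- read_rate_surface(file)
      .surface_cache[[key]] <- surf
      return(surf)
    }
  }
  surf <- build_rate_surface(S_grid, A_grid, params, tol = tol)
  .surface_cache[[key]] <- surf
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    write_rate_surface(surf, file.path(cache_dir, paste0("surface-", key, ".csv")))
  }
  surf
}
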