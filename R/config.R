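#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a full model run and validates it
#' against the schema below, applying the standard defaults (the published
#' parameter table, the default grids and the standard simulation
#' conditions) for anything unset. Unknown keys are rejected with their key
#' path, so typos fail loudly instead of silently running defaults.
#'
#' Schema (all sections optional):
#' \preformatted{
#' proteome:     any field of proteome_params(), e.g. theta_i: 1.5
#' strains:
#'   x:          c, k1, k2, K
#'   y:          c, k1, k2, K
#' surface:      S_grid, A_grid (explicit numeric grids)
#' simulation:   S0, X0, Y0, Bx0, By0, T, dt
#' checkerboard: X0_values, Y0_values
#' seed:         integer
#' }
#'
#' @param path Path to a YAML file. An empty file yields the full default
#'   configuration.
#' @return An object of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_sections <- c("proteome", "strains", "surface", "simulation",
                      "checkerboard", "seed")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  check_keys <- function(section, allowed, where) {
    bad <- setdiff(names(section), allowed)
    if (length(bad) > 0) {
      stop("unknown config key(s): ",
           paste(paste0(where, ".", bad), collapse = ", "), call. = FALSE)
    }
  }
  check_keys(raw$proteome, proteome_param_names(), "proteome")
  params <- do.call(proteome_params, as.list(raw$proteome))

  strain_fields <- c("c", "k1", "k2", "K")
  # YAML 1.1 parses a bare `y` key as boolean; map it back to the strain name
  if (!is.null(raw$strains)) {
    names(raw$strains)[names(raw$strains) == "TRUE"] <- "y"
  }
  check_keys(raw$strains, c("x", "y"), "strains")
  pair <- strain_pair()
  for (s in c("x", "y")) {
    check_keys(raw$strains[[s]], strain_fields, paste0("strains.", s))
    if (!is.null(raw$strains[[s]])) {
      pair[[s]] <- do.call(strain_params,
                           utils::modifyList(unclass(pair[[s]]),
                                             as.list(raw$strains[[s]])))
    }
  }

  check_keys(raw$surface, c("S_grid", "A_grid"), "surface")
  S_grid <- if (is.null(raw$surface$S_grid)) default_S_grid() else
    as.numeric(raw$surface$S_grid)
  A_grid <- if (is.null(raw$surface$A_grid)) default_A_grid() else
    as.numeric(raw$surface$A_grid)

  sim_fields <- c("S0", "X0", "Y0", "Bx0", "By0", "T", "dt")
  check_keys(raw$simulation, sim_fields, "simulation")
  sim <- utils::modifyList(list(S0 = 1, X0 = 1, Y0 = 1,
                                Bx0 = 1e4, By0 = 1e4, T = 180, dt = 1),
                           as.list(raw$simulation))
  if (!(sim$dt > 0 && sim$dt <= sim$T)) {
    stop("simulation requires 0 < dt <= T", call. = FALSE)
  }

  check_keys(raw$checkerboard, c("X0_values", "Y0_values"), "checkerboard")
  board <- if (is.null(raw$checkerboard)) NULL else
    list(X0_values = as.numeric(raw$checkerboard$X0_values),
         Y0_values = as.numeric(raw$checkerboard$Y0_values))

  structure(list(proteome = params, strains = pair,
                 S_grid = S_grid, A_grid = A_grid,
                 simulation = sim, checkerboard = board,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)),
            class = "run_config")
}

#' Run the modelling pipeline from a configuration
#'
#' Executes the requested stages against a validated configuration and
#' writes plain-text artifacts to `out_dir`:
#' \describe{
#'   \item{surface}{builds (or fetches from cache) the steady-state rate
#'     surface and writes `surface.csv` (+ YAML sidecar).}
#'   \item{simulate}{runs the configured co-culture and writes
#'     `trajectory.csv`.}
#'   \item{analyze}{runs the co-culture vs monoculture comparison in the
#'     configured environment and writes `analysis.csv` (final densities,
#'     relative density, interaction class); if the config has a
#'     checkerboard section, also sweeps it and writes `checkerboard.csv`.}
#' }
#' A `run_log.yml` capturing the parameter fingerprint, seed, grids and
#' package version is always written, so deterministic stages can be
#' reproduced bit-for-bit from the log and config.
#'
#' @param config A [load_run_config()] object.
#' @param stages Subset of `c("surface", "simulate", "analyze")`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config, stages = c("surface", "simulate", "analyze"),
                         out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  surf <- cached_rate_surface(config$proteome, config$S_grid, config$A_grid)
  if ("surface" %in% stages) {
    p <- file.path(out_dir, "surface.csv")
    write_rate_surface(surf, p)
    artifacts$surface <- p
  }
  sim <- config$simulation
  if ("simulate" %in% stages) {
    traj <- simulate_multiscale(
      community_init(sim$S0, sim$X0, sim$Y0, sim$Bx0, sim$By0),
      surf, config$strains, T = sim$T, dt = sim$dt)
    p <- file.path(out_dir, "trajectory.csv")
    write_community_trajectory(traj, p)
    artifacts$trajectory <- p
  }
  if ("analyze" %in% stages) {
    res <- interaction_assay(sim$S0, sim$X0, sim$Y0,
                             total_inoculum = sim$Bx0 + sim$By0,
                             surfaces = surf, pair = config$strains,
                             T = sim$T, dt = sim$dt)
    p <- file.path(out_dir, "analysis.csv")
    utils::write.csv(data.frame(
      S0 = sim$S0, X0 = sim$X0, Y0 = sim$Y0,
      co_Bx = res$co[["Bx"]], co_By = res$co[["By"]],
      mono_Bx = res$mono_x, mono_By = res$mono_y,
      relative_density = res$relative_density, class = res$class),
      p, row.names = FALSE)
    artifacts$analysis <- p
    if (!is.null(config$checkerboard)) {
      board <- checkerboard_sweep(config$checkerboard$X0_values,
                                  config$checkerboard$Y0_values,
                                  S0 = sim$S0,
                                  total_inoculum = sim$Bx0 + sim$By0,
                                  surfaces = surf, pair = config$strains,
                                  T = sim$T, dt = sim$dt)
      p <- file.path(out_dir, "checkerboard.csv")
      utils::write.csv(as.data.frame(board), p, row.names = FALSE)
      artifacts$checkerboard <- p
    }
  }
  log_path <- file.path(out_dir, "run_log.yml")
  yaml::write_yaml(list(
    package = "syntrophr",
    version = as.character(utils::packageVersion("syntrophr")),
    params_fingerprint = params_fingerprint(config$proteome),
    seed = config$seed,
    stages = stages,
    S_grid = config$S_grid, A_grid = config$A_grid,
    simulation = config$simulation), log_path)
  artifacts$run_log <- log_path
  invisible(artifacts)
}
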