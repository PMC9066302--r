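#' Plate layout for synthetic experiments
#'
#' Describes a set of wells (condition per well: initial fraction of strain
#' `B_x`, nutrient concentrations, replicate index) and the sampling time
#' points shared by all wells. Fraction 1 or 0 denotes a monoculture well.
#'
#' @param conditions Data frame with columns `well`, `fraction`, `S0`, `X0`,
#'   `Y0`, `replicate`, and optionally `inoculum` (total initial density of
#'   the well, overriding the generator's default). Well identifiers must
#'   be unique.
#' @param timepoints Strictly increasing sampling times (model time units).
#'   The default mirrors a plate reader's 20-minute cycle over a day mapped
#'   onto the 180-unit model horizon (73 reads).
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(conditions,
                         timepoints = seq(0, 180, length.out = 73)) {
  need <- c("well", "fraction", "S0", "X0", "Y0", "replicate")
  if (!is.data.frame(conditions) || !all(need %in% names(conditions))) {
    stop("conditions needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(conditions$well)) {
    stop("well identifiers must be unique", call. = FALSE)
  }
  if (any(conditions$fraction < 0 | conditions$fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  structure(list(conditions = conditions, timepoints = timepoints),
            class = "plate_layout")
}

#' Standard frequency-sweep layout
#'
#' One well per initial fraction and replicate in a fixed environment; the
#' fraction sweep includes the monoculture endpoints.
#'
#' @param fractions Initial fractions of `B_x`.
#' @param replicates Number of replicate wells per fraction.
#' @param S0,X0,Y0 Shared nutrient environment.
#' @return A [plate_layout()].
#' @export
layout_frequency_sweep <- function(fractions = seq(0, 1, by = 0.1),
                                   replicates = 1L,
                                   S0 = 1, X0 = 1, Y0 = 1) {
  grid <- expand.grid(fraction = fractions, replicate = seq_len(replicates))
  grid$well <- sprintf("W%02d", seq_len(nrow(grid)))
  grid$S0 <- S0
  grid$X0 <- X0
  grid$Y0 <- Y0
  plate_layout(grid[c("well", "fraction", "S0", "X0", "Y0", "replicate")])
}

#' Co-culture-versus-monoculture layout
#'
#' Three wells — a 50-50 co-culture and both share-inoculum monocultures —
#' in one environment: the design behind the interaction classification
#' (see [interaction_assay()]).
#'
#' @inheritParams layout_frequency_sweep
#' @param total_inoculum Co-culture total; each monoculture well receives
#'   half of it, its strain's co-culture share.
#' @return A [plate_layout()].
#' @export
layout_interaction_assay <- function(S0 = 1, X0 = 1, Y0 = 1,
                                     total_inoculum = 2e4) {
  plate_layout(data.frame(
    well = c("co", "mono_x", "mono_y"),
    fraction = c(0.5, 1, 0),
    S0 = S0, X0 = X0, Y0 = Y0, replicate = 1L,
    inoculum = c(total_inoculum, total_inoculum / 2, total_inoculum / 2)))
}

#' Generate a synthetic plate-reader dataset
#'
#' Simulates each well of a layout with the multi-scale model, converts
#' densities to an optical-density-like signal (`OD = (Bx + By) / c`, using
#' the cell-efficiency scale so simulated ODs land in the familiar 0.1-1
#' range) and to two fluorescence channels (CFP reports strain `B_x`,
#' mCherry strain `B_y`, linear gain per OD-equivalent plus a blank
#' offset), then applies multiplicative measurement noise. Noise is
#' lognormal by default (plate-reader coefficients of variation scale with
#' signal); the noiseless values are kept in a truth sidecar and the whole
#' dataset is reproducible from the seed.
#'
#' @param layout A [plate_layout()].
#' @param surfaces,pair Model configuration passed to
#'   [simulate_multiscale()].
#' @param noise Named numeric: `sigma_od` and `sigma_fl`, relative standard
#'   deviations (`>= 0`).
#' @param seed Integer seed; same seed, same dataset.
#' @param total_inoculum Default total initial density per well; overridden
#'   by the layout's `inoculum` column where present.
#' @param gain Fluorescence gain per OD-equivalent, per channel
#'   (`cfp`, `mcherry`).
#' @param blank Reader blank per channel.
#' @param noise_model `"lognormal"` (default) or `"gaussian"` (additive,
#'   sd relative to signal).
#' @param dt Coupling interval of the underlying simulations.
#' @param truth Optional truth sidecar from a previous call with the same
#'   layout and model configuration; when supplied, the simulations are
#'   skipped and only fresh measurement noise is drawn (useful for
#'   noise-replicate Monte Carlo).
#' @return An object of class `plate_dataset`: list with `records`
#'   (long-format data frame `well, time, OD630, CFP, mCherry`), `truth`
#'   (noiseless `well, time, Bx, By, OD630, CFP, mCherry`), `layout`,
#'   `noise`, `seed`, `gain`, `blank`.
#' @export
generate_plate_dataset <- function(layout,
                                   surfaces = NULL, pair = strain_pair(),
                                   noise = c(sigma_od = 0.02, sigma_fl = 0.02),
                                   seed = 1L,
                                   total_inoculum = 2e4,
                                   gain = c(cfp = 1000, mcherry = 1000),
                                   blank = c(cfp = 50, mcherry = 50),
                                   noise_model = c("lognormal", "gaussian"),
                                   dt = 1, truth = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  noise_model <- match.arg(noise_model)
  if (any(noise < 0)) stop("noise sigmas must be nonnegative", call. = FALSE)
  if (is.null(surfaces)) surfaces <- cached_rate_surface()
  cond <- layout$conditions
  tp <- layout$timepoints
  if (is.null(truth)) {
    truth <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
      w <- cond[i, ]
      tot_w <- if (is.null(w$inoculum)) total_inoculum else w$inoculum
      traj <- simulate_multiscale(
        community_init(w$S0, w$X0, w$Y0,
                       Bx0 = w$fraction * tot_w,
                       By0 = (1 - w$fraction) * tot_w),
        surfaces, pair, T = max(tp), dt = dt)
      Bx <- stats::approx(traj$time, traj$Bx, tp)$y
      By <- stats::approx(traj$time, traj$By, tp)$y
      od <- (Bx + By) / pair$x$c
      data.frame(well = w$well, time = tp, Bx = Bx, By = By,
                 OD630 = od,
                 CFP = blank[["cfp"]] + gain[["cfp"]] * Bx / pair$x$c,
                 mCherry = blank[["mcherry"]] +
                   gain[["mcherry"]] * By / pair$y$c)
    }))
    rownames(truth) <- NULL
  }
  seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- nrow(truth)
  jitter <- function(x, sigma) {
    if (sigma == 0) return(x)
    if (noise_model == "lognormal") x * exp(stats::rnorm(n, 0, sigma))
    else pmax(x * (1 + stats::rnorm(n, 0, sigma)), 0)
  }
  records <- data.frame(
    well = truth$well, time = truth$time,
    OD630 = jitter(truth$OD630, noise[["sigma_od"]]),
    CFP = blank[["cfp"]] +
      jitter(truth$CFP - blank[["cfp"]], noise[["sigma_fl"]]),
    mCherry = blank[["mcherry"]] +
      jitter(truth$mCherry - blank[["mcherry"]], noise[["sigma_fl"]]))
  structure(list(records = records, truth = truth, layout = layout,
                 noise = noise, seed = seed, gain = gain, blank = blank),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("<plate_dataset> %d wells x %d timepoints, sigma_od = %g, sigma_fl = %g, seed = %d\n",
              nrow(x$layout$conditions), length(x$layout$timepoints),
              x$noise[["sigma_od"]], x$noise[["sigma_fl"]], x$seed))
  invisible(x)
}

#' Per-strain final densities from a plate dataset
#'
#' Inverts the fluorescence model at the last time point of each well:
#' blank-subtracts each channel and divides by its gain and the cell
#' efficiency to recover per-strain densities. Negative estimates (possible
#' under noise) are clamped to zero.
#'
#' @param dataset A [generate_plate_dataset()] result.
#' @param pair The [strain_pair()] used for generation.
#' @return Data frame `well, Bx_hat, By_hat`.
#' @export
dataset_final_densities <- function(dataset, pair = strain_pair()) {
  stopifnot(inherits(dataset, "plate_dataset"))
  rec <- dataset$records
  last <- rec[rec$time == max(rec$time), ]
  data.frame(
    well = last$well,
    Bx_hat = pmax(last$CFP - dataset$blank[["cfp"]], 0) /
      dataset$gain[["cfp"]] * pair$x$c,
    By_hat = pmax(last$mCherry - dataset$blank[["mcherry"]], 0) /
      dataset$gain[["mcherry"]] * pair$y$c)
}

#' Write plate-reader records as CSV
#'
#' The same long-format dialect the analysis functions consume:
#' `well, time, OD630, CFP, mCherry`.
#'
#' @param dataset A `plate_dataset`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_plate_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "plate_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  invisible(path)
}

#' Packaged pair-wise interaction summary
#'
#' The printed summary of the 36 pair-wise auxotroph co-cultures: mean
#' monoculture OD630, mean 50-50 co-culture OD630, relative optical density,
#' quadratic interaction coefficient `alpha` and its R-squared, for every
#' pair of the nine single-gene amino-acid auxotrophs (glyA, hisB, ilvA,
#' leuB, metA, pheA, thrC, trpC, tyrA; keys use one letter per strain).
#' Values are verbatim from the published table.
#'
#' @return A data frame with 36 rows and columns `key, strain_1, strain_2,
#'   mono_mean, co_mean, delta_od, alpha, r_squared`.
#' @examples
#' tab <- table2_fixture()
#' subset(tab, key == "FG")$delta_od  # 0.079
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_interactions.csv",
                      package = "syntrophr", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
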