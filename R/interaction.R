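#' Line of additivity
#'
#' Expected co-culture yield under no interaction: the linear interpolation
#' of the two monoculture yields across the initial fraction `x` of the
#' focal strain, `x * mono_focal + (1 - x) * mono_partner`.
#'
#' @param x Initial fraction of the focal strain, in `[0, 1]`.
#' @param mono_focal,mono_partner Monoculture final densities (the `x = 1`
#'   and `x = 0` endpoints).
#' @return Expected density under additivity.
#' @export
additive_expectation <- function(x, mono_focal, mono_partner) {
  if (any(x < 0 | x > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  x * mono_focal + (1 - x) * mono_partner
}

#' Relative density
#'
#' Observed co-culture yield minus the line of additivity; the population
#' analogue of the plate-reader relative optical density. Positive values
#' indicate cooperative benefit. At `x = 0.5` this is the co-culture yield
#' minus the mean of the two monocultures.
#'
#' @param co_final Observed co-culture final density.
#' @inheritParams additive_expectation
#' @return Signed density difference.
#' @examples
#' relative_density(0.5417, 0.5, 0.46, 0.4654)  # co-culture above additivity
#' @export
relative_density <- function(co_final, x, mono_focal, mono_partner) {
  co_final - additive_expectation(x, mono_focal, mono_partner)
}

#' Interaction profile across initial frequencies
#'
#' Container for a frequency-sweep experiment: the final density of the
#' community at a series of initial fractions of the focal strain, with the
#' two monocultures as the `x = 1` and `x = 0` endpoints. Replicates are
#' kept; summaries average over them.
#'
#' @param fraction Initial fraction of the focal strain per observation.
#' @param density Final density (or OD) per observation.
#' @param replicate Replicate index per observation.
#' @return An object of class `frequency_profile`: a data frame with
#'   attributes `mono_focal` and `mono_partner` (means over replicates at
#'   the endpoints).
#' @export
frequency_profile <- function(fraction, density, replicate = 1L) {
  if (length(fraction) != length(density)) {
    stop("fraction and density must have equal length", call. = FALSE)
  }
  if (any(fraction < 0 | fraction > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!any(fraction == 1) || !any(fraction == 0)) {
    stop("profile needs monoculture endpoints at fractions 0 and 1",
         call. = FALSE)
  }
  df <- data.frame(fraction = fraction, density = density,
                   replicate = rep_len(replicate, length(fraction)))
  df <- df[order(df$fraction, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "mono_focal") <- mean(df$density[df$fraction == 1])
  attr(df, "mono_partner") <- mean(df$density[df$fraction == 0])
  class(df) <- c("frequency_profile", "data.frame")
  df
}

profile_delta <- function(profile) {
  relative_density(profile$density, profile$fraction,
                   attr(profile, "mono_focal"), attr(profile, "mono_partner"))
}

#' Quadratic interaction fit
#'
#' Ordinary least squares of the through-origin model `y = alpha x^2 +
#' beta x` on an interaction profile. The default response is the relative
#' density (observed minus the line of additivity, zero by construction at
#' both endpoints); `response = "raw"` fits the raw final densities instead.
#' The quadratic coefficient `alpha` quantifies the curvature of the
#' interaction profile. `r_squared` is the uncentered coefficient of
#' determination of the through-origin fit, guaranteed in `[0, 1]`.
#'
#' @param profile A [frequency_profile()].
#' @param response `"delta"` (default) or `"raw"`.
#' @return An object of class `interaction_fit`: list with `alpha`,
#'   `beta_fit`, `r_squared`, `response`.
#' @export
fit_interaction_curve <- function(profile, response = c("delta", "raw")) {
  stopifnot(inherits(profile, "frequency_profile"))
  response <- match.arg(response)
  x <- profile$fraction
  if (length(unique(x)) < 3) {
    stop("need at least 3 distinct fractions for a quadratic fit",
         call. = FALSE)
  }
  y <- if (response == "delta") profile_delta(profile) else profile$density
  fit <- stats::lm(y ~ 0 + I(x^2) + x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum(y^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  structure(list(alpha = unname(stats::coef(fit)[1]),
                 beta_fit = unname(stats::coef(fit)[2]),
                 r_squared = min(max(r2, 0), 1),
                 response = response),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("<interaction_fit> alpha = %.4g, beta = %.4g, R^2 = %.3f (%s response)\n",
              x$alpha, x$beta_fit, x$r_squared, x$response))
  invisible(x)
}

#' Optimal initial frequency
#'
#' The tested initial fraction of the focal strain that maximises the mean
#' final density of the community. Ties break to the lowest fraction. The
#' across-replicate standard deviation at the optimum is attached as
#' attribute `dispersion`.
#'
#' @param profile A [frequency_profile()].
#' @return The optimal fraction (numeric scalar) with attribute
#'   `dispersion`.
#' @export
optimal_initial_frequency <- function(profile) {
  stopifnot(inherits(profile, "frequency_profile"))
  if (nrow(profile) == 0) stop("empty profile", call. = FALSE)
  means <- tapply(profile$density, profile$fraction, mean)
  fracs <- as.numeric(names(means))
  best <- fracs[which.max(means)]  # which.max takes the first (lowest) tie
  disp <- stats::sd(profile$density[profile$fraction == best])
  structure(best, dispersion = unname(disp))
}

#' Strain composition from dual-fluorescence readout
#'
#' Blank-subtracts each channel, normalises by its monoculture maximum and
#' rescales the two normalised intensities to sum to one, giving the
#' relative abundance of the CFP-tagged and mCherry-tagged strains.
#'
#' @param cfp,mcherry Measured intensities (scalars or equal-length
#'   vectors), at or above their blanks.
#' @param blank Length-2 numeric, blank intensity of each channel
#'   (`cfp`, `mcherry`).
#' @param mono_max Length-2 numeric, blank-subtracted monoculture maximum of
#'   each channel, `> 0`.
#' @return A data frame with columns `cfp_fraction` and `mcherry_fraction`
#'   summing to 1 per row.
#' @export
abundance_from_fluorescence <- function(cfp, mcherry,
                                        blank = c(cfp = 0, mcherry = 0),
                                        mono_max = c(cfp = 1, mcherry = 1)) {
  if (any(cfp < blank[[1]]) || any(mcherry < blank[[2]])) {
    stop("intensities must be at or above their blanks", call. = FALSE)
  }
  if (any(mono_max <= 0)) stop("mono_max must be positive", call. = FALSE)
  nc <- (cfp - blank[[1]]) / mono_max[[1]]
  nm <- (mcherry - blank[[2]]) / mono_max[[2]]
  total <- nc + nm
  if (any(total == 0)) {
    stop("composition undefined: both channels at blank", call. = FALSE)
  }
  data.frame(cfp_fraction = nc / total, mcherry_fraction = nm / total)
}

#' Classify a pair-wise interaction
#'
#' Compares each strain's co-culture density with its monoculture density:
#' *mutualism* when both strains do better together, *competition* when
#' both do strictly worse, *parasitism* otherwise (one better, one
#' worse-or-equal). Comparisons use a relative tolerance to avoid
#' float-equality artifacts.
#'
#' @param co_focal,co_partner Final densities of the strains in co-culture.
#' @param mono_focal,mono_partner Final densities of the corresponding
#'   monocultures.
#' @param tol Relative tolerance of the better/worse comparisons.
#' @return A character vector with values in
#'   `c("mutualism", "parasitism", "competition")`.
#' @examples
#' classify_interaction(0.2, 0.2, 0.1, 0.1)   # both better: mutualism
#' classify_interaction(0.2, 0.05, 0.1, 0.1)  # one better: parasitism
#' @export
classify_interaction <- function(co_focal, co_partner,
                                 mono_focal, mono_partner, tol = 1e-3) {
  if (any(c(co_focal, co_partner, mono_focal, mono_partner) < 0)) {
    stop("densities must be nonnegative", call. = FALSE)
  }
  focal_better <- co_focal > mono_focal * (1 + tol)
  partner_better <- co_partner > mono_partner * (1 + tol)
  focal_worse <- co_focal < mono_focal * (1 - tol)
  partner_worse <- co_partner < mono_partner * (1 - tol)
  ifelse(focal_better & partner_better, "mutualism",
         ifelse(focal_worse & partner_worse, "competition", "parasitism"))
}

#' Simulated interaction assay: co-culture vs monocultures
#'
#' Runs the multi-scale model for a co-culture at the given initial fraction
#' and for both monocultures under identical environmental conditions, and
#' summarises the interaction: per-strain final densities, relative density
#' of the community against the no-interaction expectation, and the
#' mutualism/parasitism/competition classification.
#'
#' Each monoculture is inoculated at the strain's co-culture share
#' (`fraction * total_inoculum` for `B_x`), so the comparison isolates the
#' effect of the partner's presence. The simulated no-interaction
#' expectation is the sum of the two share-inoculum monoculture yields —
#' the community total had the strains grown independently. (For saturated
#' plate-reader yields, which are inoculum-insensitive, this reduces to the
#' fraction-interpolated line of additivity used on tabular data by
#' [relative_density()].) Resource competition alone drives the co-culture
#' below this expectation; cross-feeding can push it above.
#'
#' @param S0,X0,Y0 Initial nutrient concentrations.
#' @param fraction Initial fraction of strain `B_x` in the co-culture.
#' @param total_inoculum Total initial density, split by `fraction` in
#'   co-culture and between the share-inoculum monocultures.
#' @param surfaces,pair,T,dt Passed to [simulate_multiscale()].
#' @param tol Classification tolerance.
#' @return A list with `co` (final co-culture state), `mono_x`, `mono_y`
#'   (share-inoculum monoculture final densities), `relative_density`
#'   and `class`.
#' @export
interaction_assay <- function(S0 = 1, X0 = 1, Y0 = 1, fraction = 0.5,
                              total_inoculum = 2e4,
                              surfaces = NULL, pair = strain_pair(),
                              T = 180, dt = 1, tol = 1e-3) {
  co <- final_state(simulate_multiscale(
    community_init(S0, X0, Y0,
                   Bx0 = fraction * total_inoculum,
                   By0 = (1 - fraction) * total_inoculum),
    surfaces, pair, T = T, dt = dt))
  mono_x <- final_state(simulate_monoculture(
    "x", community_init(S0, X0, Y0,
                        Bx0 = fraction * total_inoculum, By0 = 0),
    surfaces, pair, T = T, dt = dt))[["Bx"]]
  mono_y <- final_state(simulate_monoculture(
    "y", community_init(S0, X0, Y0, Bx0 = 0,
                        By0 = (1 - fraction) * total_inoculum),
    surfaces, pair, T = T, dt = dt))[["By"]]
  list(co = co, mono_x = mono_x, mono_y = mono_y,
       relative_density = (co[["Bx"]] + co[["By"]]) - (mono_x + mono_y),
       class = classify_interaction(co[["Bx"]], co[["By"]], mono_x, mono_y,
                                    tol = tol))
}

#' Simulate a full frequency profile
#'
#' Runs co-cultures at a sweep of initial fractions of `B_x` (monocultures
#' at the endpoints) and returns the resulting [frequency_profile()] of
#' total final densities.
#'
#' @param fractions Initial fractions of `B_x`, must include 0 and 1.
#' @inheritParams interaction_assay
#' @return A `frequency_profile` of total final density against initial
#'   fraction.
#' @export
simulate_frequency_profile <- function(fractions = seq(0, 1, by = 0.1),
                                       S0 = 1, X0 = 1, Y0 = 1,
                                       total_inoculum = 2e4,
                                       surfaces = NULL, pair = strain_pair(),
                                       T = 180, dt = 1) {
  totals <- vapply(fractions, function(f) {
    fin <- final_state(simulate_multiscale(
      community_init(S0, X0, Y0,
                     Bx0 = f * total_inoculum,
                     By0 = (1 - f) * total_inoculum),
      surfaces, pair, T = T, dt = dt))
    fin[["Bx"]] + fin[["By"]]
  }, numeric(1))
  frequency_profile(fractions, totals)
}
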