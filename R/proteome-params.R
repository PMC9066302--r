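#' Parameters of the proteome-allocation model
#'
#' Constructs the parameter set of the coarse-grained intracellular model: a
#' saturating nutrient-uptake function feeding ppGpp-regulated transcription of
#' two proteome sectors (metabolic E, with an amino-acid-export sub-sector y,
#' and ribosomal R), translation limited by the share of actively translating
#' ribosomes, and first-order degradation throughout. Defaults are the values
#' used for the numerical experiments on the cross-feeding *E. coli* pair;
#' both strains share one proteome parameterisation.
#'
#' Units are arbitrary but mutually consistent: concentrations in model
#' concentration units, rates per model time unit.
#'
#' @param mu Maximum nutrient uptake rate (scales the substrate-by-amino-acid
#'   saturating uptake).
#' @param k Half-saturation constant of uptake, on the product `S * A`.
#' @param theta_hat_E,theta_hat_R Basal maximum transcription rates of sectors
#'   E and R; these multiply the uptake flux.
#' @param theta_E,theta_R ppGpp-inducible transcription rates of sectors E
#'   and R.
#' @param n Hill coefficient of the ppGpp-promoter interaction (`n >= 1`).
#' @param omega ppGpp activity threshold of the Hill terms.
#' @param kappa_E,kappa_R Maximum translation rates of the sector mRNAs.
#' @param eta_E,eta_R mRNA degradation rates.
#' @param delta_E,delta_R Protein degradation rates (the export sub-sector y
#'   degrades at `delta_E`, like the rest of sector E).
#' @param delta_G ppGpp degradation rate.
#' @param J_E,J_R Fractions of ribosomes actively translating each sector's
#'   mRNAs (in `[0, 1]`).
#' @param theta_b Basal ppGpp synthesis rate.
#' @param theta_i Ribosome-induced ppGpp synthesis rate; the stringent-response
#'   knob swept in [theta_sweep()].
#' @param phi Fraction of E-sector synthesis allocated to the amino-acid
#'   export sub-sector y (in `[0, 1]`).
#'
#' @return An object of class `proteome_params`: a validated named list.
#' @seealso [proteome_rhs()], [proteome_steady_state()], [build_rate_surface()]
#' @examples
#' p <- proteome_params()
#' p_low_ppgpp <- proteome_params(theta_i = 1.5)
#' @export
proteome_params <- function(mu = 1e3, k = 50,
                            theta_hat_E = 0.020, theta_hat_R = 0.08,
                            theta_E = 20, theta_R = 20,
                            n = 2, omega = 5.1,
                            kappa_E = 60, kappa_R = 60,
                            eta_E = 2.4, eta_R = 2.4,
                            delta_E = 1.7, delta_R = 1.7, delta_G = 0.8,
                            J_E = 0.5, J_R = 0.5,
                            theta_b = 0.05, theta_i = 15.2,
                            phi = 0.01) {
  p <- list(mu = mu, k = k,
            theta_hat_E = theta_hat_E, theta_hat_R = theta_hat_R,
            theta_E = theta_E, theta_R = theta_R,
            n = n, omega = omega,
            kappa_E = kappa_E, kappa_R = kappa_R,
            eta_E = eta_E, eta_R = eta_R,
            delta_E = delta_E, delta_R = delta_R, delta_G = delta_G,
            J_E = J_E, J_R = J_R,
            theta_b = theta_b, theta_i = theta_i,
            phi = phi)
  validate_proteome_params(p)
  structure(p, class = "proteome_params")
}

validate_proteome_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("proteome_params fields must be finite numeric scalars: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  neg <- vapply(p, function(x) x < 0, logical(1))
  if (any(neg)) {
    stop("proteome_params fields must be nonnegative: ",
         paste(names(p)[neg], collapse = ", "), call. = FALSE)
  }
  if (p$phi > 1) stop("phi must lie in [0, 1]", call. = FALSE)
  if (p$J_E > 1 || p$J_R > 1) stop("J_E and J_R must lie in [0, 1]", call. = FALSE)
  if (p$n < 1) stop("Hill coefficient n must be >= 1", call. = FALSE)
  invisible(p)
}

#' @export
print.proteome_params <- function(x, ...) {
  cat("<proteome_params>\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals), width = 12), " ",
             format(vals, trim = TRUE)), sep = "\n")
  invisible(x)
}

proteome_param_names <- function() names(proteome_params())

#' Read or write proteome parameters
#'
#' Flat YAML or JSON mapping of parameter names to numbers. The format is
#' chosen from the file extension (`.yml`/`.yaml` or `.json`). Unknown keys
#' are rejected; missing keys fall back to the defaults of
#' [proteome_params()].
#'
#' @param path File path.
#' @param params A `proteome_params` object (for writing).
#' @return `read_proteome_params()` returns a `proteome_params` object;
#'   `write_proteome_params()` returns `path` invisibly.
#' @export
read_proteome_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), proteome_param_names())
  if (length(unknown) > 0) {
    stop("unknown proteome parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(proteome_params, vals)
}

#' @rdname read_proteome_params
#' @export
write_proteome_params <- function(params, path) {
  stopifnot(inherits(params, "proteome_params"))
  vals <- lapply(unclass(params), identity)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' Fingerprint of a parameter set
#'
#' Stable hash of a `proteome_params` object, used to key cached rate
#' surfaces and to stamp run logs.
#'
#' @param params A `proteome_params` object.
#' @return A character scalar.
#' @export
params_fingerprint <- function(params) {
  stopifnot(inherits(params, "proteome_params"))
  rlang::hash(unlist(unclass(params)))
}
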