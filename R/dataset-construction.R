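## Dataset construction: acceptance-angle models, missing-angle corrections,
## and the closure rules that make the compiled channel set self-consistent.

#' Detector acceptance model
#'
#' Transmission-measured total cross sections undercount forward-scattered
#' electrons.  Two acceptance geometries are supported: a fixed geometric
#' acceptance angle (aperture-limited beam spectrometers, typically ~5 deg)
#' and a confinement-linked acceptance, where the magnetically confined
#' apparatus cannot distinguish a scattered electron whose axial-energy
#' decrement is smaller than the energy resolution, giving
#' `theta_acc = acos(sqrt(1 - dE_res / E))`.
#'
#' @param kind `"fixed_angle"` or `"energy_resolution_linked"`.
#' @param theta_fixed_rad fixed acceptance half-angle, radians (fixed kind).
#' @param delta_E_res_eV energy resolution, eV (linked kind).
#' @return object of class `acceptance_model`.
#' @export
acceptance_model <- function(kind = c("fixed_angle", "energy_resolution_linked"),
                             theta_fixed_rad = 5 * pi / 180,
                             delta_E_res_eV = 0.45) {
  kind <- match.arg(kind)
  if (kind == "fixed_angle")
    stopifnot(theta_fixed_rad > 0, theta_fixed_rad <= pi / 2)
  else
    stopifnot(delta_E_res_eV > 0)
  structure(list(kind = kind, theta_fixed_rad = theta_fixed_rad,
                 delta_E_res_eV = delta_E_res_eV),
            class = "acceptance_model")
}

#' Acceptance half-angle at a given energy
#'
#' For the fixed kind, the geometric angle independent of energy; for the
#' confinement-linked kind, the pitch angle whose axial-energy decrement
#' equals the energy resolution.  When `E <= dE_res` discrimination is
#' impossible and the full forward hemisphere (`pi/2`) is returned.
#'
#' @param model an [acceptance_model].
#' @param E incident energy, eV (vectorized).
#' @return acceptance half-angle, radians.
#' @export
acceptance_angle <- function(model, E) {
  stopifnot(inherits(model, "acceptance_model"))
  if (model$kind == "fixed_angle") return(rep(model$theta_fixed_rad, length(E)))
  r <- model$delta_E_res_eV / E
  ifelse(r >= 1, pi / 2, acos(sqrt(1 - r)))
}

#' Cross section scattered into the missing angles
#'
#' Integrates a differential cross section over the forward acceptance cone,
#' `delta_sigma = 2*pi * integral_0^theta_acc dcs(theta) sin(theta) dtheta`,
#' by adaptive quadrature (relative tolerance 1e-8).  Forward-peaked
#' integrands are handled by splitting the domain at `theta_acc / 10`.
#'
#' @param dcs function of `theta` (radians) returning the differential cross
#'   section in 1e-20 m^2/sr, normalized so its full-sphere integral equals
#'   the channel's integral cross section at the energy of interest.
#' @param theta_acc acceptance half-angle, radians, in \[0, pi\].
#' @return the missing-angle correction, 1e-20 m^2.
#' @export
missing_angle_correction <- function(dcs, theta_acc) {
  stopifnot(is.function(dcs), theta_acc >= 0, theta_acc <= pi)
  if (theta_acc == 0) return(0)
  f <- function(th) {
    y <- dcs(th) * sin(th)
    if (any(!is.finite(y))) stop("non-finite DCS inside the acceptance cone")
    y
  }
  split <- theta_acc / 10
  i1 <- stats::integrate(f, 0, split, rel.tol = 1e-8, abs.tol = 0,
                         subdivisions = 200L)
  i2 <- stats::integrate(f, split, theta_acc, rel.tol = 1e-8, abs.tol = 0,
                         subdivisions = 200L)
  2 * pi * (i1$value + i2$value)
}

#' Correct a transmission-measured total cross section
#'
#' Adds back the elastic (and optionally rotational) cross section scattered
#' into the detector's acceptance cone.
#'
#' @param tcs measured total cross section, 1e-20 m^2.
#' @param E incident energy, eV.
#' @param model an [acceptance_model].
#' @param elastic_dcs_fun function of `theta` giving the elastic DCS at `E`
#'   (full-sphere normalized to the elastic ICS).
#' @param rotational_dcs_fun optional; same for the rotational channel.
#' @return a one-row data frame: `E`, `theta_acc_rad`, `delta_sigma_el`,
#'   `delta_sigma_rot`, `corrected_tcs`.
#' @export
correct_tcs <- function(tcs, E, model, elastic_dcs_fun,
                        rotational_dcs_fun = NULL) {
  th <- acceptance_angle(model, E)
  d_el <- missing_angle_correction(elastic_dcs_fun, th)
  d_rot <- if (is.null(rotational_dcs_fun)) 0 else
    missing_angle_correction(rotational_dcs_fun, th)
  data.frame(E = E, theta_acc_rad = th, delta_sigma_el = d_el,
             delta_sigma_rot = d_rot, corrected_tcs = tcs + d_el + d_rot)
}

#' Vibrational cross section by closure
#'
#' The compiled set is made self-consistent by attributing to vibrational
#' excitation whatever part of the reference total cross section (which
#' excludes rotational excitation) is not accounted for by the elastic,
#' electronic, ionization and attachment channels.  A negative remainder
#' signals an inconsistency: it is floored at zero with a warning.
#'
#' @param tcs_ref reference total cross section (rotation excluded), 1e-20 m^2.
#' @param iecs integral elastic cross section.
#' @param electronic,ionization,attachment the other channel cross sections.
#' @return vibrational cross section, 1e-20 m^2 (>= 0).
#' @export
close_vibrational <- function(tcs_ref, iecs, electronic = 0, ionization = 0,
                              attachment = 0) {
  stopifnot(all(c(tcs_ref, iecs, electronic, ionization, attachment) >= 0))
  rem <- tcs_ref - (iecs + electronic + ionization + attachment)
  neg <- rem < 0
  if (any(neg))
    warning(sprintf("negative closure remainder (%.4g) floored to 0: channel sum exceeds reference TCS",
                    min(rem)))
  rem[neg] <- 0
  rem
}

#' Split a total inelastic cross section into ionization and electronic parts
#'
#' Uses the theoretical ratio of ionization to electronic-excitation cross
#' sections: `electronic = total / (1 + ratio)`,
#' `ionization = total * ratio / (1 + ratio)`; the two parts sum to the input
#' exactly.
#'
#' @param total_inelastic total inelastic cross section, 1e-20 m^2.
#' @param ratio_ion_over_elec ionization / electronic ratio (>= 0).
#' @return named list with `ionization` and `electronic`.
#' @export
split_inelastic <- function(total_inelastic, ratio_ion_over_elec) {
  stopifnot(total_inelastic >= 0, ratio_ion_over_elec >= 0)
  electronic <- total_inelastic / (1 + ratio_ion_over_elec)
  list(ionization = total_inelastic - electronic, electronic = electronic)
}
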