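## Per-channel energy-loss distribution functions and samplers.

#' Default per-channel energy-loss models
#'
#' Builds the set of energy-loss samplers used by the transport engine:
#' \describe{
#'   \item{rotational}{fixed loss of 0.00109 eV (mean rotational excitation
#'     energy at 300 K); no secondary.}
#'   \item{elastic}{recoil only, computed from the scattering angle by
#'     two-body kinematics ([elastic_recoil()]); handled by the engine.}
#'   \item{vibrational}{discrete mixture at 0.1, 0.2, 0.4 eV with weights
#'     0.5, 0.3, 0.2 (parametric stand-in for the measured loss spectra).}
#'   \item{electronic}{Gaussian mixture with means 4.8 and 7.0 eV,
#'     sd 0.5 eV, truncated to (0, E).}
#'   \item{ionization}{loss `B + W`: binding energy `B` plus the secondary
#'     electron energy `W`, drawn from a Lorentzian-tailed density
#'     proportional to `1/(W^2 + w^2)` truncated to `[0, (E - B)/2]` (the
#'     slower outgoing electron is the secondary).}
#'   \item{attachment}{dissociative attachment absorbs the electron: the
#'     whole kinetic energy is deposited.}
#' }
#' The parametric vibrational/electronic defaults are stand-ins for measured
#' angle-averaged loss spectra; [spectrum_to_channel_models()] replaces them
#' with empirical samplers from a two-column spectrum file.
#'
#' @param vib_losses,vib_weights discrete vibrational losses (eV)/weights.
#' @param elec_means,elec_sd,elec_weights electronic Gaussian mixture (eV).
#' @param B_eV ionization binding energy (inside the tabulated onset
#'   bracket, default 9.6 eV).
#' @param w_eV secondary-spectrum width parameter, eV.
#' @return a named list of `energy_loss_model` objects, one per channel.
#' @export
energy_loss_models <- function(vib_losses = c(0.1, 0.2, 0.4),
                               vib_weights = c(0.5, 0.3, 0.2),
                               elec_means = c(4.8, 7.0), elec_sd = 0.5,
                               elec_weights = c(0.5, 0.5),
                               B_eV = 9.6, w_eV = 10) {
  stopifnot(all(vib_losses > 0), all(vib_weights > 0),
            length(vib_losses) == length(vib_weights),
            all(elec_means > 0), elec_sd > 0, B_eV > 0, w_eV > 0)
  mk <- function(channel, kind, pars)
    structure(c(list(channel = channel, kind = kind), pars),
              class = "energy_loss_model")
  list(
    rotational = mk("rotational", "fixed", list(loss = 0.00109)),
    elastic    = mk("elastic", "recoil", list()),
    vibrational = mk("vibrational", "discrete_mixture",
                     list(losses = vib_losses,
                          weights = vib_weights / sum(vib_weights))),
    electronic = mk("electronic", "gaussian_mixture",
                    list(means = elec_means, sd = elec_sd,
                         weights = elec_weights / sum(elec_weights))),
    ionization = mk("ionization", "ionization_partition",
                    list(B = B_eV, w = w_eV)),
    attachment = mk("attachment", "absorb", list())
  )
}

#' @export
print.energy_loss_model <- function(x, ...) {
  cat("<energy_loss_model> ", x$channel, " (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' Sample the energy loss of one inelastic collision
#'
#' Returns the primary electron's energy decrement `loss` and, for
#' ionization, the kinetic energy `secondary` carried away by the ejected
#' electron (`loss = B + secondary`; the locally deposited energy is
#' `loss - secondary`).  For attachment the whole incident energy is
#' deposited and the primary is terminated.  Vibrational and electronic
#' draws are truncated so the loss never reaches the incident energy.
#'
#' @param model one `energy_loss_model` from [energy_loss_models()] (or from
#'   [spectrum_to_channel_models()]).
#' @param E incident energy, eV.
#' @return list with `loss` (eV) and `secondary` (eV, `NA` if none).
#' @export
sample_energy_loss <- function(model, E) {
  stopifnot(inherits(model, "energy_loss_model"), E > 0)
  switch(model$kind,
    fixed = {
      if (E <= model$loss) stop("rotational channel closed at E = ", E)
      list(loss = model$loss, secondary = NA_real_)
    },
    recoil = stop("elastic recoil is angle-dependent; use elastic_recoil()"),
    discrete_mixture = {
      open <- model$losses < E
      if (!any(open)) stop(model$channel, " channel closed at E = ", E)
      i <- sample.int(sum(open), 1L, prob = model$weights[open])
      list(loss = model$losses[open][i], secondary = NA_real_)
    },
    gaussian_mixture = {
      if (E <= min(model$means) - 3 * model$sd)
        stop(model$channel, " channel closed at E = ", E)
      repeat {
        i <- sample.int(length(model$means), 1L, prob = model$weights)
        x <- stats::rnorm(1L, model$means[i], model$sd)
        if (x > 0 && x < E) return(list(loss = x, secondary = NA_real_))
      }
    },
    spectrum = {
      open <- model$losses < E
      if (!any(open)) stop(model$channel, " channel closed at E = ", E)
      i <- sample.int(sum(open), 1L, prob = model$weights[open])
      list(loss = model$losses[open][i], secondary = NA_real_)
    },
    spectrum_ionization = {
      ## empirical total-loss draw; the secondary gets loss - B, capped so the
      ## secondary is the slower outgoing electron
      open <- model$losses >= model$B &
        (model$losses - model$B) <= (E - model$B) / 2
      if (!any(open)) stop("ionization channel closed at E = ", E)
      i <- sample.int(sum(open), 1L, prob = model$weights[open])
      loss <- model$losses[open][i]
      list(loss = loss, secondary = loss - model$B)
    },
    ionization_partition = {
      if (E <= model$B) stop("ionization channel closed at E = ", E)
      Wmax <- (E - model$B) / 2
      ## inverse CDF of 1/(W^2 + w^2) truncated to [0, Wmax]
      W <- model$w * tan(stats::runif(1L) * atan(Wmax / model$w))
      list(loss = model$B + W, secondary = W)
    },
    absorb = list(loss = E, secondary = NA_real_),
    stop("unknown energy-loss kind: ", model$kind)
  )
}

#' Elastic recoil energy transfer
#'
#' Two-body kinematics for an electron scattering elastically off a molecule
#' of mass `M`: `dE = [4 me M / (me + M)^2] * E * (1 - cos(theta)) / 2`,
#' which reduces to `(2 me / M) E (1 - cos(theta))` for `M >> me`.
#'
#' @param E incident energy, eV.
#' @param theta scattering angle, radians.
#' @param M_amu target mass, atomic mass units (79 for pyridine).
#' @return recoil energy transferred to the molecule, eV.
#' @export
elastic_recoil <- function(E, theta, M_amu = 79) {
  stopifnot(all(theta >= 0 & theta <= pi), M_amu > 0)
  frac <- 4 * .me_amu * M_amu / (.me_amu + M_amu)^2
  frac * E * (1 - cos(theta)) / 2
}

#' Read a two-column energy-loss spectrum
#'
#' @param path CSV file with columns `loss_eV` and `intensity` (arbitrary
#'   units); `#` comment lines allowed.
#' @param incident_E_eV incident energy the spectrum was measured at
#'   (metadata).
#' @return object of class `spectrum_table`.
#' @export
load_spectrum <- function(path, incident_E_eV = NA_real_) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("loss_eV", "intensity") %in% names(df)))
    stop("spectrum file needs columns loss_eV, intensity")
  if (nrow(df) == 0) stop("empty spectrum file")
  if (any(df$intensity < 0)) stop("negative intensity in spectrum file")
  if (any(diff(df$loss_eV) <= 0)) stop("loss grid must be strictly ascending")
  structure(list(loss_eV = df$loss_eV, intensity = df$intensity,
                 incident_E_eV = incident_E_eV),
            class = "spectrum_table")
}

#' Split a measured loss spectrum into per-channel samplers
#'
#' Partitions the spectrum at the channel loss boundaries (defaults: the
#' electronic-excitation onset 3.5 eV and the ionization binding energy) and
#' returns normalized empirical samplers for the vibrational, electronic and
#' ionization bands, together with each band's share of the spectrum mass.
#' The ionization band sampler draws the total loss directly from the
#' spectrum; losses below the binding energy are excluded from that band.
#'
#' @param spec a [spectrum_table].
#' @param electronic_onset_eV vibrational/electronic boundary, eV.
#' @param B_eV electronic/ionization boundary (binding energy), eV.
#' @return list with per-channel `energy_loss_model`s (`vibrational`,
#'   `electronic`, `ionization`; absent bands dropped) and `band_mass`.
#' @export
spectrum_to_channel_models <- function(spec, electronic_onset_eV = 3.5,
                                       B_eV = 9.6) {
  stopifnot(inherits(spec, "spectrum_table"))
  bands <- list(
    vibrational = spec$loss_eV < electronic_onset_eV,
    electronic = spec$loss_eV >= electronic_onset_eV & spec$loss_eV < B_eV,
    ionization = spec$loss_eV >= B_eV)
  mass <- vapply(bands, function(i) sum(spec$intensity[i]), numeric(1))
  models <- list()
  for (ch in names(bands)) {
    i <- bands[[ch]] & spec$intensity > 0
    if (!any(i)) next
    m <- structure(list(channel = ch, kind = "spectrum",
                        losses = spec$loss_eV[i],
                        weights = spec$intensity[i] / sum(spec$intensity[i])),
                   class = "energy_loss_model")
    if (ch == "ionization") { m$kind <- "spectrum_ionization"; m$B <- B_eV }
    models[[ch]] <- m
  }
  c(models, list(band_mass = mass / sum(mass)))
}
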