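## Event-by-event Monte Carlo electron transport through a gas cell, with
## the magnetic-confinement axial-energy observable (RPA transmission curve)
## and a virtual attenuation measurement of the total cross section.

#' Simulation configuration
#'
#' @param gas a [gas_conditions] object.
#' @param E0_eV nominal beam energy, eV.
#' @param fwhm_eV Gaussian energy spread of the beam (FWHM), eV.  The
#'   confined source's natural spread is 0.4-0.5 eV; default 0.45.  Draws
#'   are truncated below at the 0.1 eV transport cull.
#' @param n_electrons number of primary electrons.
#' @param seed RNG seed (integer) for full reproducibility.
#' @param confinement magnetic-confinement mode: transverse motion is frozen
#'   to the (negligible) gyro-scale and scattering manifests purely as loss
#'   of axial energy.
#' @param track_secondaries transport ionization secondaries with the same
#'   physics?
#' @param max_generation secondary generation cap (primary = 0).
#' @param backscatter_policy electrons leaving through the entrance plane:
#'   `"lost"` (removed and logged) or `"reflected"` (specular return at the
#'   source plane).
#' @param record_events keep the per-collision event log?
#' @return object of class `sim_config`.
#' @export
sim_config <- function(gas, E0_eV, fwhm_eV = 0.45, n_electrons = 1000L,
                       seed = 1L, confinement = TRUE,
                       track_secondaries = TRUE, max_generation = 3L,
                       backscatter_policy = c("lost", "reflected"),
                       record_events = TRUE) {
  stopifnot(inherits(gas, "gas_conditions"), E0_eV > 0, fwhm_eV >= 0,
            n_electrons >= 1)
  backscatter_policy <- match.arg(backscatter_policy)
  structure(list(gas = gas, E0_eV = E0_eV, fwhm_eV = fwhm_eV,
                 n_electrons = as.integer(n_electrons), seed = as.integer(seed),
                 confinement = confinement,
                 track_secondaries = track_secondaries,
                 max_generation = as.integer(max_generation),
                 backscatter_policy = backscatter_policy,
                 record_events = record_events),
            class = "sim_config")
}

## Rotate unit vector d by polar angle theta (about d) and azimuth phi.
.rotate_direction <- function(d, theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  ## orthonormal basis (e1, e2, d)
  if (abs(d[3]) < 0.99) ref <- c(0, 0, 1) else ref <- c(1, 0, 0)
  e1 <- c(d[2] * ref[3] - d[3] * ref[2],
          d[3] * ref[1] - d[1] * ref[3],
          d[1] * ref[2] - d[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  v <- ct * d + st * (cos(phi) * e1 + sin(phi) * e2)
  v / sqrt(sum(v^2))
}

## Draw one scattering polar angle for a channel (closed-form samplers for
## the screened-Rutherford family; grid sampler for tabulated elastic DCS).
.draw_theta <- function(channel, E, dE, ctx) {
  if (channel == "rotational") {
    kin <- .rot_kinematics(E, ctx$rot_model$eps_rot_eV)
    return(acos(.sample_u_rot(kin$b, kin$c)))
  }
  if (ctx$el_model$kind == "screened_rutherford") {
    a <- 1 + 2 * ctx$el_model$eta0 / E
    if (channel == "elastic") return(acos(.sample_u_sr(a)))
    p <- .inel_power(ctx$inel_params, dE / E)
    return(acos(.sample_u_srpow(a, p)))
  }
  ## tabulated elastic model: generic grid sampler
  pdf <- if (channel == "elastic")
    function(th) elastic_dcs(ctx$el_model, E, th)
  else
    function(th) inelastic_ddcs(ctx$el_model, ctx$inel_params, E, dE, th)
  sample_theta(pdf, 1L)
}

#' Run an electron beam through the gas cell
#'
#' Event-by-event Monte Carlo transport: free paths are sampled from the
#' local mean free path, the interaction channel from the per-channel cross
#' sections, the scattering angle from the channel's angular model and the
#' energy loss from the channel's loss model; ionization spawns secondaries
#' that are transported with the same physics.  Electrons are followed until
#' they leave the cell, are absorbed (attachment), or fall below the 0.1 eV
#' cull (their residual energy is deposited locally).  Fully reproducible
#' under the configured seed.
#'
#' @param config a [sim_config].
#' @param xs a [xs_set].
#' @param angular optional list with `elastic` ([elastic_dcs_model]),
#'   `rotational` ([rotational_dcs_model]) and `inelastic`
#'   ([inelastic_angular_params]); defaults built from `xs`.
#' @param eloss optional per-channel energy-loss models
#'   ([energy_loss_models()] defaults).
#' @return object of class `beam_run`: `exits` data frame (one row per
#'   terminated electron: id, generation, fate, energy, direction cosine,
#'   axial energy, collision count), `events` data frame (per-collision
#'   ledger: z, channel, loss, deposit, theta, secondary flag), and `ledger`
#'   (energy bookkeeping totals).
#' @export
run_beam <- function(config, xs, angular = NULL, eloss = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(xs, "xs_set"))
  if (is.null(angular))
    angular <- list(elastic = elastic_dcs_model(xs),
                    rotational = rotational_dcs_model(xs),
                    inelastic = inelastic_angular_params())
  if (is.null(eloss)) eloss <- energy_loss_models()
  if (config$E0_eV < xs$energy_range[1] || config$E0_eV > xs$energy_range[2])
    stop("beam energy outside the data set's energy range")
  ctx <- list(el_model = angular$elastic, rot_model = angular$rotational,
              inel_params = angular$inelastic)
  g <- config$gas
  n_dens <- pressure_to_density(g)
  L <- g$cell_length_m
  cull_E <- 0.1
  set.seed(config$seed)

  n <- config$n_electrons
  ## beam energies: Gaussian, truncated at the transport cull
  draw_E0 <- function(m) {
    if (config$fwhm_eV == 0) return(rep(config$E0_eV, m))
    sd <- config$fwhm_eV / (2 * sqrt(2 * log(2)))
    e <- stats::rnorm(m, config$E0_eV, sd)
    while (any(bad <- e < cull_E))
      e[bad] <- stats::rnorm(sum(bad), config$E0_eV, sd)
    e
  }
  primaries_E <- draw_E0(n)

  ## result accumulators (grown geometrically)
  ex_n <- 0L
  ex_cap <- n + 16L
  exits <- list(id = integer(ex_cap), generation = integer(ex_cap),
                fate = character(ex_cap), energy = numeric(ex_cap),
                dz = numeric(ex_cap), axial = numeric(ex_cap),
                ncoll = integer(ex_cap))
  ev_n <- 0L
  ev_cap <- 4L * n + 16L
  events <- list(id = integer(ev_cap), generation = integer(ev_cap),
                 z = numeric(ev_cap), channel = character(ev_cap),
                 loss = numeric(ev_cap), deposit = numeric(ev_cap),
                 theta = numeric(ev_cap), secondary = logical(ev_cap))
  push_exit <- function(id, gen, fate, E, dz, ncoll) {
    if (ex_n == ex_cap) {
      ex_cap <<- ex_cap * 2L
      exits <<- lapply(exits, function(v) { length(v) <- ex_cap; v })
    }
    ex_n <<- ex_n + 1L
    exits$id[ex_n] <<- id; exits$generation[ex_n] <<- gen
    exits$fate[ex_n] <<- fate; exits$energy[ex_n] <<- E
    exits$dz[ex_n] <<- dz; exits$axial[ex_n] <<- E * dz^2
    exits$ncoll[ex_n] <<- ncoll
  }
  push_event <- function(id, gen, z, ch, loss, dep, th, sec) {
    if (ev_n == ev_cap) {
      ev_cap <<- ev_cap * 2L
      events <<- lapply(events, function(v) { length(v) <- ev_cap; v })
    }
    ev_n <<- ev_n + 1L
    events$id[ev_n] <<- id; events$generation[ev_n] <<- gen
    events$z[ev_n] <<- z; events$channel[ev_n] <<- ch
    events$loss[ev_n] <<- loss; events$deposit[ev_n] <<- dep
    events$theta[ev_n] <<- th; events$secondary[ev_n] <<- sec
  }

  deposited <- 0; culled <- 0; exited_E <- 0; backscattered_E <- 0
  injected <- sum(primaries_E)
  M <- g$molar_mass_amu
  record <- config$record_events

  ## stack of electrons to transport: each is list(id, gen, z, dir, E)
  for (ip in seq_len(n)) {
    stack <- list(list(id = ip, gen = 0L, z = 0, dir = c(0, 0, 1),
                       E = primaries_E[ip]))
    while (length(stack)) {
      el <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      z <- el$z; dir <- el$dir; E <- el$E
      ncoll <- 0L
      repeat {
        sig_tot <- xs_total(xs, E)
        lambda <- mean_free_path(sig_tot, n_dens)
        s <- if (is.finite(lambda)) -lambda * log(stats::runif(1L)) else Inf
        dz_step <- s * dir[3]
        if (!is.finite(s) ||
            (dir[3] > 0 && z + dz_step >= L) ||
            (dir[3] < 0 && z + dz_step <= 0) ||
            dir[3] == 0) {
          ## leaves the cell before colliding (dir[3]==0: never reaches an
          ## axial plane; logged with the backscatter losses)
          if (dir[3] > 0 || (!is.finite(s) && dir[3] >= 0)) {
            push_exit(el$id, el$gen, "transmitted", E, dir[3], ncoll)
            exited_E <- exited_E + E
            break
          }
          if (dir[3] < 0 && config$backscatter_policy == "reflected") {
            ## free paths are memoryless: advance to the source plane and
            ## return specularly, then resample
            z <- 0
            dir[3] <- -dir[3]
            next
          }
          push_exit(el$id, el$gen, "backscattered", E, dir[3], ncoll)
          backscattered_E <- backscattered_E + E
          break
        }
        ## collision inside the cell
        z <- z + dz_step
        ncoll <- ncoll + 1L
        res <- .collide(el$id, el$gen, z, dir, E, xs, ctx, eloss, M,
                        cull_E, record, push_event)
        deposited <- deposited + res$deposit
        culled <- culled + res$culled
        if (!is.null(res$secondary)) {
          if (config$track_secondaries && el$gen < config$max_generation)
            stack[[length(stack) + 1L]] <- c(res$secondary,
                                             list(id = el$id,
                                                  gen = el$gen + 1L))
          else
            deposited <- deposited + res$secondary$E
        }
        if (!res$alive) break
        dir <- res$dir; E <- res$E
      }
    }
  }

  exits <- as.data.frame(lapply(exits, function(v) v[seq_len(ex_n)]))
  events <- if (record)
    as.data.frame(lapply(events, function(v) v[seq_len(ev_n)]))
  else NULL
  structure(list(
    exits = exits, events = events,
    ledger = list(injected = injected, exited = exited_E,
                  backscattered = backscattered_E,
                  deposited = deposited, culled = culled),
    config = config, n_density = n_dens),
    class = "beam_run")
}

## One collision: sample channel, angle, loss; returns the updated state and
## the locally deposited / culled energy bookkeeping for this event.
.collide <- function(id, gen, z, dir, E, xs, ctx, eloss, M, cull_E,
                     record, push_event) {
  pr <- xs_channel_probs(xs, E)
  channel <- sample(names(pr), 1L, prob = pr)
  secondary <- NULL
  deposit <- 0; culled <- 0; alive <- TRUE
  if (channel == "attachment") {
    deposit <- E
    if (record) push_event(id, gen, z, channel, E, E, NA_real_, FALSE)
    return(list(alive = FALSE, deposit = deposit, culled = 0,
                secondary = NULL))
  }
  if (channel == "elastic") {
    theta <- .draw_theta("elastic", E, 0, ctx)
    loss <- elastic_recoil(E, theta, M)
    deposit <- loss
  } else if (channel == "rotational") {
    sl <- sample_energy_loss(eloss$rotational, E)
    loss <- sl$loss
    theta <- .draw_theta("rotational", E, loss, ctx)
    deposit <- loss
  } else {
    sl <- sample_energy_loss(eloss[[channel]], E)
    loss <- sl$loss
    theta <- .draw_theta(channel, E, loss, ctx)
    if (!is.na(sl$secondary)) {
      deposit <- loss - sl$secondary
      secondary <- list(z = z, dir = .iso_direction(), E = sl$secondary)
      if (secondary$E < cull_E) {  # sub-cull secondary: deposit locally
        deposit <- loss
        secondary <- NULL
      }
    } else {
      deposit <- loss
    }
  }
  E_new <- E - loss
  if (record) push_event(id, gen, z, channel, loss, deposit, theta,
                         !is.null(secondary))
  if (E_new < cull_E) {
    culled <- E_new
    alive <- FALSE
    dir_new <- dir
  } else {
    dir_new <- .rotate_direction(dir, theta, stats::runif(1L) * 2 * pi)
  }
  list(alive = alive, deposit = deposit, culled = culled,
       secondary = secondary, dir = dir_new, E = E_new)
}

.iso_direction <- function() {
  u <- 2 * stats::runif(1L) - 1
  phi <- 2 * pi * stats::runif(1L)
  s <- sqrt(1 - u^2)
  c(s * cos(phi), s * sin(phi), u)
}

#' @export
print.beam_run <- function(x, ...) {
  l <- x$ledger
  cat("<beam_run> ", x$config$n_electrons, " primaries at ",
      x$config$E0_eV, " eV, ", x$config$gas$pressure_mTorr, " mTorr\n",
      sep = "")
  cat(sprintf("  transmitted %d, backscattered %d, primaries absorbed/culled %d, secondary exits %d\n",
              sum(x$exits$fate == "transmitted"),
              sum(x$exits$fate == "backscattered"),
              x$config$n_electrons - sum(x$exits$generation == 0L),
              sum(x$exits$generation > 0L)))
  cat(sprintf("  energy (eV): injected %.4g = exited %.4g + backscattered %.4g + deposited %.4g + culled %.4g\n",
              l$injected, l$exited, l$backscattered, l$deposited, l$culled))
  invisible(x)
}

#' Axial kinetic energy of an electron
#'
#' Under strong magnetic confinement, scattering converts polar deflection
#' into loss of axial kinetic energy: `E_par = E * dz^2` where `dz` is the
#' axial direction cosine.  This is the quantity a retarding potential
#' analyzer discriminates on.
#'
#' @param E kinetic energy, eV.
#' @param dz axial direction cosine.
#' @return axial kinetic energy, eV.
#' @export
axial_energy <- function(E, dz) E * dz^2

#' Retarding-potential transmission curve
#'
#' Fraction of incident electrons whose axial kinetic energy at the exit
#' exceeds the retarding barrier, as a function of the barrier height:
#' `counts(V) = #{transmitted exits with E_par >= e*V} / n_incident`.
#' Non-increasing in `V`; at `V = 0` it equals the transmitted fraction.
#'
#' @param run a [beam_run] (confinement mode).
#' @param V_grid retarding potentials, volts.
#' @return object of class `transmission_curve`: data frame with columns
#'   `V_volts`, `intensity`.
#' @export
rpa_curve <- function(run, V_grid) {
  stopifnot(inherits(run, "beam_run"))
  tr <- run$exits[run$exits$fate == "transmitted", ]
  n0 <- run$config$n_electrons
  if (nrow(tr) == 0) warning("no transmitted electrons: all-zero curve")
  counts <- vapply(V_grid, function(v) sum(tr$axial >= v) / n0, numeric(1))
  structure(data.frame(V_volts = V_grid, intensity = counts),
            class = c("transmission_curve", "data.frame"))
}

#' Virtual total-cross-section attenuation measurement
#'
#' Runs a monoenergetic beam through a thin target and recovers an effective
#' total cross section from the Beer-Lambert attenuation,
#' `sigma_eff = ln(I0 / I) / (n L)`, where `I` counts the transmitted
#' electrons the detector cannot distinguish from unscattered ones.  With
#' perfect discrimination (`acceptance = NULL`) only collision-free
#' electrons count and `sigma_eff` estimates the full total cross section;
#' with a finite acceptance angle, electrons whose final polar angle lies
#' inside the cone are also counted, so `sigma_eff` is reduced by the
#' missing-angle contribution.
#'
#' @param config a [sim_config] (use `fwhm_eV = 0`; thin target,
#'   `n * sigma * L < 0.5`, recommended).
#' @param xs a [xs_set].
#' @param acceptance `NULL` for perfect discrimination, or an
#'   [acceptance_model] whose angle at the beam energy defines the cone of
#'   undetected scattering.
#' @param ... passed to [run_beam()].
#' @return list: `sigma_eff` (1e-20 m^2), `I0`, `I`, `run`.
#' @export
virtual_tcs <- function(config, xs, acceptance = NULL, ...) {
  run <- run_beam(config, xs, ...)
  ## only primaries enter the attenuation count: a collision-free secondary
  ## is not an unscattered beam electron
  tr <- run$exits[run$exits$fate == "transmitted" &
                    run$exits$generation == 0L, ]
  I0 <- config$n_electrons
  if (is.null(acceptance)) {
    I <- sum(tr$ncoll == 0L)
  } else {
    th_acc <- acceptance_angle(acceptance, config$E0_eV)
    I <- sum(tr$ncoll == 0L | acos(pmin(1, pmax(-1, tr$dz))) <= th_acc)
  }
  if (I == 0) stop("no transmitted electrons within acceptance (opaque target)")
  n_dens <- pressure_to_density(config$gas)
  sigma_eff <- log(I0 / I) / (n_dens * config$gas$cell_length_m) / .xs_unit
  list(sigma_eff = sigma_eff, I0 = I0, I = I, run = run)
}
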