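## Angular distribution models: parametric elastic DCS, dipole-Born
## rotational shape, the semi-empirical inelastic DDCS, and angle sampling.

#' Elastic differential cross-section model
#'
#' Either a screened-Rutherford parametric shape,
#' `dcs(E, theta) = C(E) / (1 + 2*eta(E) - cos(theta))^2` with screening
#' `eta(E) = eta0 / E` and `C(E)` fixed so that the full-sphere integral
#' equals the elastic integral cross section of the data set, or a tabulated
#' (E, theta) grid supplied by the user (e.g. digitized ab initio curves),
#' bilinearly interpolated and renormalized to the same ICS.
#'
#' @param set a [xs_set] providing the elastic ICS normalization.
#' @param kind `"screened_rutherford"` or `"tabulated"`.
#' @param eta0 screening scale (dimensionless * eV); `eta = eta0 / E`.  The
#'   default 0.5 makes the 10 eV shape strongly forward peaked
#'   (forward/backward ratio ~440).
#' @param table for the tabulated kind, a data frame with columns `E_eV`,
#'   `theta_deg`, `dcs` (relative or absolute; it is renormalized).
#' @return object of class `elastic_dcs_model`.
#' @export
elastic_dcs_model <- function(set, kind = c("screened_rutherford", "tabulated"),
                              eta0 = 0.5, table = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(set, "xs_set"))
  if (kind == "screened_rutherford" && eta0 <= 0)
    stop("screening parameter eta0 must be positive")
  if (kind == "tabulated") {
    if (is.null(table) || !all(c("E_eV", "theta_deg", "dcs") %in% names(table)))
      stop("tabulated kind needs a table with columns E_eV, theta_deg, dcs")
    if (any(table$dcs < 0)) stop("tabulated DCS values must be >= 0")
  }
  structure(list(kind = kind, eta0 = eta0, table = table, set = set),
            class = "elastic_dcs_model")
}

## Full-sphere integral of 1/(a - cos theta)^2 over solid angle, a = 1 + 2 eta:
## 2*pi * [1/(a-1) - 1/(a+1)] = pi / (eta * (1 + eta))
.sr_norm <- function(eta) pi / (eta * (1 + eta))

#' Evaluate the elastic differential cross section
#'
#' @param model an [elastic_dcs_model].
#' @param E incident energy, eV (scalar).
#' @param theta scattering angles, radians, in \[0, pi\] (vectorized).
#' @return DCS in 1e-20 m^2/sr, full-sphere normalized to the elastic ICS.
#' @export
elastic_dcs <- function(model, E, theta) {
  stopifnot(inherits(model, "elastic_dcs_model"),
            all(theta >= 0 & theta <= pi))
  ics <- xs_sigma(model$set, "elastic", E)
  if (model$kind == "screened_rutherford") {
    eta <- model$eta0 / E
    C <- ics / .sr_norm(eta)
    C / (1 + 2 * eta - cos(theta))^2
  } else {
    shape <- .tab_dcs_shape(model$table, E, theta)
    ## renormalize the interpolated shape to the dataset ICS
    th <- seq(0, pi, length.out = 4096L)
    w <- .tab_dcs_shape(model$table, E, th) * sin(th)
    I <- 2 * pi * sum((w[-1] + w[-length(w)]) / 2 * diff(th))
    shape * ics / I
  }
}

## Bilinear interpolation of a (E, theta) DCS table
.tab_dcs_shape <- function(tab, E, theta) {
  Es <- sort(unique(tab$E_eV))
  iE <- findInterval(E, Es, all.inside = TRUE)
  e1 <- Es[iE]; e2 <- Es[min(iE + 1L, length(Es))]
  tE <- if (e2 > e1) (E - e1) / (e2 - e1) else 0
  interp_at <- function(e) {
    sub <- tab[tab$E_eV == e, ]
    sub <- sub[order(sub$theta_deg), ]
    stats::approx(sub$theta_deg * pi / 180, sub$dcs, xout = theta,
                  rule = 2)$y
  }
  (1 - tE) * interp_at(e1) + tE * interp_at(e2)
}

#' Dipole-Born rotational differential cross-section model
#'
#' Rotational excitation of a polar molecule is strongly forward peaked;
#' in the dipole-Born approximation the angular shape is `1/K^2` with
#' momentum transfer `K^2 = k^2 + k'^2 - 2 k k' cos(theta)`, where `k`, `k'`
#' are the incident and outgoing momenta for the (tiny) mean rotational
#' excitation energy.  The magnitude is set by normalizing the full-sphere
#' integral to the data set's rotational integral cross section, which
#' reproduces the characteristic 1/E fall-off of the dipole-Born curves.
#'
#' @param set a [xs_set] providing the rotational ICS.
#' @param dipole_moment_D permanent dipole moment, debye (metadata; 2.2 for
#'   pyridine).
#' @param eps_rot_eV mean rotational excitation energy at 300 K, eV.
#' @return object of class `rotational_dcs_model`.
#' @export
rotational_dcs_model <- function(set, dipole_moment_D = 2.2,
                                 eps_rot_eV = 0.00109) {
  stopifnot(inherits(set, "xs_set"), dipole_moment_D > 0, eps_rot_eV > 0)
  structure(list(set = set, dipole_moment_D = dipole_moment_D,
                 eps_rot_eV = eps_rot_eV),
            class = "rotational_dcs_model")
}

## Nonrelativistic momenta in sqrt(eV) units (common factors cancel)
.rot_kinematics <- function(E, eps) {
  if (E <= eps) stop("incident energy at or below the rotational excitation energy")
  k <- sqrt(E); kp <- sqrt(E - eps)
  list(b = k^2 + kp^2, c = 2 * k * kp)
}

## Full-sphere integral of 1/(b - c*cos theta): (2*pi/c) * log((b+c)/(b-c))
.rot_norm <- function(b, c) (2 * pi / c) * log((b + c) / (b - c))

#' Evaluate the rotational differential cross section
#'
#' @param model a [rotational_dcs_model].
#' @param E incident energy, eV (scalar, > the rotational excitation energy).
#' @param theta angles, radians (vectorized).
#' @return DCS in 1e-20 m^2/sr, normalized to the rotational ICS at `E`.
#' @export
rotational_dcs <- function(model, E, theta) {
  stopifnot(inherits(model, "rotational_dcs_model"),
            all(theta >= 0 & theta <= pi))
  kin <- .rot_kinematics(E, model$eps_rot_eV)
  ics <- xs_sigma(model$set, "rotational", E)
  C <- ics / .rot_norm(kin$b, kin$c)
  C / (kin$b - kin$c * cos(theta))
}

#' Semi-empirical inelastic angular-distribution parameters
#'
#' The inelastic double-differential cross section is modelled as the
#' elastic DCS raised to a power that decreases with the fractional energy
#' loss: `p = 1 - dE/E` for the original formula (`"eq1"`), and
#' `p = (1 - dE/E)^k` for the improved formula (`"eq2"`), whose best-fit
#' exponent against measured ionization DDCS is `k = 1.3`.  At `dE = 0`
#' both reduce to the elastic shape; larger `dE` flattens the distribution,
#' the improved form more strongly for `k > 1`.
#'
#' @param k flattening exponent (> 0), default 1.3.
#' @param formula `"eq2"` (improved, default) or `"eq1"` (original).
#' @return object of class `inelastic_angular_params`.
#' @export
inelastic_angular_params <- function(k = 1.3, formula = c("eq2", "eq1")) {
  formula <- match.arg(formula)
  stopifnot(k > 0)
  structure(list(k = k, formula = formula),
            class = "inelastic_angular_params")
}

## The DCS exponent for a fractional energy loss f = dE/E
.inel_power <- function(params, f) {
  if (params$formula == "eq1") 1 - f else (1 - f)^params$k
}

#' Semi-empirical inelastic double-differential cross section (relative)
#'
#' `ddcs(E, dE, theta) = elastic_dcs(E, theta) ^ p`, with
#' `p = 1 - dE/E` (`"eq1"`) or `p = (1 - dE/E)^k` (`"eq2"`).  The result is
#' a relative shape; the transport code normalizes it as an angular PDF.
#'
#' @param elastic_model an [elastic_dcs_model].
#' @param params an [inelastic_angular_params].
#' @param E incident energy, eV.
#' @param dE energy loss, eV, with `0 <= dE < E`.
#' @param theta angles, radians (vectorized).
#' @return unnormalized relative DDCS values.
#' @export
inelastic_ddcs <- function(elastic_model, params, E, dE, theta) {
  stopifnot(inherits(params, "inelastic_angular_params"))
  if (dE < 0 || dE >= E) stop("energy loss must satisfy 0 <= dE < E")
  p <- .inel_power(params, dE / E)
  elastic_dcs(elastic_model, E, theta)^p
}

#' Sample scattering polar angles from an angular PDF
#'
#' Draws polar angles distributed as `pdf(theta) * sin(theta)` (normalized)
#' by inverse-CDF sampling on a dense theta grid with linear interpolation.
#' The azimuth is sampled uniformly on `[0, 2*pi)` by the caller.
#' Deterministic under a fixed RNG seed.
#'
#' @param pdf function of theta (radians) returning non-negative relative
#'   density over solid angle (without the `sin(theta)` Jacobian).
#' @param n number of draws.
#' @param grid_n resolution of the discretization grid.
#' @return `n` polar angles in radians.
#' @export
sample_theta <- function(pdf, n, grid_n = 4096L) {
  th <- seq(0, pi, length.out = grid_n)
  w <- pdf(th) * sin(th)
  if (any(!is.finite(w) | w < 0)) stop("pdf must be non-negative and finite")
  ## trapezoid cumulative integral
  seg <- (w[-1] + w[-grid_n]) / 2 * diff(th)
  if (sum(seg) <= 0) stop("all-zero pdf: cannot sample")
  cdf <- c(0, cumsum(seg)) / sum(seg)
  ## de-duplicate flat CDF stretches for approx()
  keep <- c(TRUE, diff(cdf) > 0)
  stats::approx(cdf[keep], th[keep], xout = stats::runif(n),
                rule = 2)$y
}

## ---- closed-form inverse-CDF samplers used by the transport engine ----
## (exact draws for the screened-Rutherford family; u = cos theta)

## density prop. 1/(a - u)^2 on [-1, 1]
.sample_u_sr <- function(a, nr = 1L) {
  lo <- 1 / (a + 1); hi <- 1 / (a - 1)
  a - 1 / (lo + stats::runif(nr) * (hi - lo))
}

## density prop. (a - u)^(-2p) on [-1, 1]
.sample_u_srpow <- function(a, p, nr = 1L) {
  q <- 1 - 2 * p
  if (abs(q) < 1e-9) {  # p ~ 1/2: log case
    r <- stats::runif(nr)
    return(a - (a + 1)^(1 - r) * (a - 1)^r)
  }
  g1 <- (a + 1)^q; g0 <- (a - 1)^q
  a - ((g1 + stats::runif(nr) * (g0 - g1)))^(1 / q)
}

## density prop. 1/(b - c*u) on [-1, 1]
.sample_u_rot <- function(b, c, nr = 1L) {
  r <- stats::runif(nr)
  (b - (b + c) * ((b - c) / (b + c))^r) / c
}
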