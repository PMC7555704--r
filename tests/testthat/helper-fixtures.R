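# Shared fixtures: the packaged sets are loaded once per test run.
xs_rec <- load_pyridine_xs("recommended")
xs_smc <- load_pyridine_xs("smc")

# A minimal single-channel gas: constant elastic cross section, every other
# channel identically zero.  Used for analytically solvable transport checks.
toy_xs_set <- function(elastic_value = 10) {
  grids <- list()
  for (ch in pyrxs:::.channels) {
    v <- if (ch == "elastic") c(elastic_value, elastic_value) else c(0, 0)
    grids[[ch]] <- channel_grid(ch, c(0.1, 100), v, source = "toy")
  }
  set <- structure(list(grids = grids, elastic_variant = "recommended",
                        energy_range = c(0.1, 100)),
                   class = "xs_set")
  set$interp <- lapply(grids, pyrxs:::.make_interpolator,
                       range = set$energy_range)
  set
}

# An isotropic elastic angular model on a tabulated grid (constant DCS).
iso_elastic_model <- function(set) {
  tab <- expand.grid(E_eV = c(0.1, 100), theta_deg = c(0, 90, 180))
  tab$dcs <- 1
  elastic_dcs_model(set, kind = "tabulated", table = tab)
}

# Full-sphere quadrature of a DCS shape, 2*pi * int f(theta) sin(theta).
sphere_integral <- function(f) {
  2 * pi * stats::integrate(function(th) f(th) * sin(th), 0, pi,
                            rel.tol = 1e-8, subdivisions = 400L)$value
}
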