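## Integral cross-section data set: load, validate, interpolate, query.

#' Construct a per-channel cross-section grid
#'
#' A `channel_grid` holds the tabulated integral cross section of one
#' scattering channel on a strictly ascending energy grid, together with the
#' interpolation windows in which linear (rather than log-log) interpolation
#' is used, and a flag marking values that were printed only as an upper
#' bound (`"<0.1"`, encoded as the interval midpoint 0.05).
#'
#' @param channel one of `"elastic"`, `"rotational"`, `"vibrational"`,
#'   `"electronic"`, `"ionization"`, `"attachment"`.
#' @param energies incident energies in eV, strictly ascending, all positive.
#' @param values integral cross sections in 1e-20 m^2, same length, all >= 0.
#' @param bound logical vector: `TRUE` where the printed cell was an upper
#'   bound.
#' @param linear_windows two-column matrix of energy windows (eV) inside
#'   which interpolation is linear-linear; elsewhere it is log-log.
#' @param below_threshold_policy `"zero"` (threshold channels return 0 below
#'   the first grid energy) or `"error"`.
#' @param source free-text provenance tag.
#' @param labels optional character vector of the printed table cells
#'   (retained for character-exact re-serialization).
#' @return an object of class `channel_grid`.
#' @export
channel_grid <- function(channel, energies, values,
                         bound = rep(FALSE, length(values)),
                         linear_windows = NULL,
                         below_threshold_policy = c("zero", "error"),
                         source = "", labels = NULL) {
  channel <- match.arg(channel, .channels)
  below_threshold_policy <- match.arg(below_threshold_policy)
  energies <- as.numeric(energies)
  values <- as.numeric(values)
  if (length(energies) != length(values))
    stop("energies and values must have equal length for channel '",
         channel, "'")
  if (any(!is.finite(energies)) || any(energies <= 0))
    stop("channel '", channel, "': energies must be positive and finite")
  if (any(diff(energies) <= 0)) {
    i <- which(diff(energies) <= 0)[1]
    stop("channel '", channel, "': energies not strictly increasing at row ",
         i + 1, " (E = ", energies[i + 1], " eV)")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    i <- which(!is.finite(values) | values < 0)[1]
    stop("channel '", channel, "': negative or non-finite cross section at E = ",
         energies[i], " eV")
  }
  structure(list(channel = channel, energies = energies, values = values,
                 bound = as.logical(bound),
                 linear_windows = linear_windows,
                 below_threshold_policy = below_threshold_policy,
                 source = source, labels = labels),
            class = "channel_grid")
}

#' @export
print.channel_grid <- function(x, ...) {
  cat("<channel_grid> ", x$channel, ": ", length(x$energies),
      " points, ", min(x$energies), "-", max(x$energies), " eV",
      if (any(x$bound)) sprintf(" (%d upper-bound cells)", sum(x$bound)),
      "\n", sep = "")
  invisible(x)
}

## Parse one CSV cell: "" -> NA, "<0.1" -> 0.05 with bound flag.
.parse_cell <- function(x) {
  x <- trimws(x)
  val <- rep(NA_real_, length(x))
  bnd <- rep(FALSE, length(x))
  lt <- grepl("^<", x)
  val[lt] <- as.numeric(sub("^<", "", x[lt])) / 2
  bnd[lt] <- TRUE
  plain <- !lt & nzchar(x)
  val[plain] <- suppressWarnings(as.numeric(x[plain]))
  if (any(plain & is.na(val)))
    stop("unparseable cross-section cell: '", x[plain & is.na(val)][1], "'")
  list(value = val, bound = bnd)
}

.read_xs_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", colClasses = "character",
                  check.names = FALSE)
}

## Attachment resonance windows and the SMC 0.9 eV spike window: sharply
## structured regions tabulated densely, interpolated linearly to preserve
## peak shape.
.attachment_windows <- rbind(c(0.71, 0.935), c(1.01, 1.2))
.smc_spike_window <- rbind(c(0.8, 1.0))

#' Load the packaged pyridine cross-section set
#'
#' Reads the packaged machine-readable twins of the recommended integral
#' cross-section compilation (all six channels, 0.1-100 eV) and of the
#' Schwinger-multichannel integral elastic cross sections (0.1-20 eV), and
#' assembles a [xs_set] ready for querying with [xs_sigma()].
#'
#' @param elastic_variant `"recommended"` uses the compiled elastic column
#'   (R-matrix below 10 eV, IAM-SCAR above) throughout; `"smc"` substitutes
#'   the Schwinger-multichannel elastic values up to 20 eV (keeping the
#'   recommended values above 20 eV), for sensitivity studies of the elastic
#'   channel.
#' @return an object of class `xs_set`.
#' @examples
#' xs <- load_pyridine_xs()
#' xs_sigma(xs, "elastic", 20)     # 42.28
#' xs_sigma(xs, "attachment", 1.11) # 36.67
#' @export
load_pyridine_xs <- function(elastic_variant = c("recommended", "smc")) {
  elastic_variant <- match.arg(elastic_variant)
  f1 <- system.file("extdata", "table1_recommended.csv", package = "pyrxs",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "table2_smc.csv", package = "pyrxs",
                    mustWork = TRUE)
  t1 <- .read_xs_csv(f1)
  t2 <- .read_xs_csv(f2)
  E1 <- as.numeric(t1$E_eV)
  grids <- list()
  src1 <- c(elastic = "R-matrix (<10 eV) / IAM-SCAR compilation",
            rotational = "dipole-Born calculation",
            vibrational = "closure remainder of reference TCS",
            electronic = "IAM-SCAR ratio split of total inelastic",
            ionization = "average of experimental TICS",
            attachment = "R-matrix shape resonances")
  for (ch in .channels) {
    cells <- .parse_cell(t1[[ch]])
    keep <- !is.na(cells$value)
    win <- if (ch == "attachment") .attachment_windows else NULL
    grids[[ch]] <- channel_grid(ch, E1[keep], cells$value[keep],
                                bound = cells$bound[keep],
                                linear_windows = win,
                                source = src1[[ch]],
                                labels = trimws(t1[[ch]][keep]))
  }
  if (elastic_variant == "smc") {
    E2 <- as.numeric(t2$E_eV)
    v2 <- .parse_cell(t2$elastic)
    hi <- grids$elastic$energies > 20
    grids$elastic <- channel_grid(
      "elastic",
      c(E2, grids$elastic$energies[hi]),
      c(v2$value, grids$elastic$values[hi]),
      bound = c(v2$bound, grids$elastic$bound[hi]),
      linear_windows = .smc_spike_window,
      source = "SMC (<=20 eV) / IAM-SCAR compilation (>20 eV)",
      labels = c(trimws(t2$elastic), grids$elastic$labels[hi]))
  }
  set <- structure(list(grids = grids, elastic_variant = elastic_variant,
                        energy_range = c(0.1, 100)),
                   class = "xs_set")
  set$interp <- lapply(grids, .make_interpolator, range = set$energy_range)
  set
}

#' @export
print.xs_set <- function(x, ...) {
  cat("<xs_set> pyridine integral cross sections, ",
      x$energy_range[1], "-", x$energy_range[2], " eV (elastic variant: ",
      x$elastic_variant, ")\n", sep = "")
  for (g in x$grids) print(g)
  invisible(x)
}

## Build a fast vectorized interpolator over one channel grid.
## Log-log linear between grid points by default; linear-linear inside the
## grid's declared windows. Threshold channels: 0 outside [first, last] grid
## energy; elastic/rotational: clamped to the first grid value below it (the
## recommended grids start at 0.11 eV while the set's range starts at 0.1).
.make_interpolator <- function(grid, range) {
  E <- grid$energies
  V <- grid$values
  threshold <- grid$channel %in% .threshold_channels
  ## per-segment flag: TRUE -> linear interpolation
  nseg <- length(E) - 1L
  lin <- rep(FALSE, nseg)
  if (!is.null(grid$linear_windows)) {
    mid <- (E[-1] + E[-length(E)]) / 2
    for (r in seq_len(nrow(grid$linear_windows))) {
      w <- grid$linear_windows[r, ]
      lin <- lin | (mid >= w[1] & mid <= w[2])
    }
  }
  ## log-log needs positive values; fall back to linear where a value is 0
  lin <- lin | (V[-1] <= 0) | (V[-length(V)] <= 0)
  logE <- log(E)
  logV <- suppressWarnings(log(V))
  policy <- grid$below_threshold_policy
  function(x) {
    x <- as.numeric(x)
    out <- numeric(length(x))
    bad <- x < range[1] - 1e-12 | x > range[2] + 1e-12
    if (any(bad))
      stop("energy out of range [", range[1], ", ", range[2], "] eV: ",
           x[bad][1])
    below <- x < E[1]
    above <- x > E[length(E)]
    if (any(below) && !threshold) out[below] <- V[1]
    if (any(below) && threshold && policy == "error")
      stop("query below ", grid$channel, " onset (", E[1], " eV)")
    inside <- !below & !above
    if (any(inside)) {
      xi <- x[inside]
      i <- findInterval(xi, E, rightmost.closed = TRUE)
      i[i < 1L] <- 1L
      hi_node <- xi == E[i + 1L] & i + 1L <= length(E)
      i[hi_node] <- i[hi_node] + 1L
      at_node <- xi == E[i]
      res <- numeric(length(xi))
      res[at_node] <- V[i[at_node]]
      if (any(!at_node)) {
        j <- i[!at_node]
        xx <- xi[!at_node]
        use_lin <- lin[j]
        r <- numeric(length(xx))
        if (any(use_lin)) {
          jj <- j[use_lin]
          t <- (xx[use_lin] - E[jj]) / (E[jj + 1L] - E[jj])
          r[use_lin] <- V[jj] + t * (V[jj + 1L] - V[jj])
        }
        if (any(!use_lin)) {
          jj <- j[!use_lin]
          t <- (log(xx[!use_lin]) - logE[jj]) / (logE[jj + 1L] - logE[jj])
          r[!use_lin] <- exp(logV[jj] + t * (logV[jj + 1L] - logV[jj]))
        }
        res[!at_node] <- r
      }
      out[inside] <- res
    }
    ## above the last grid point: elastic/rotational grids end at 100 eV (the
    ## range max) so this only triggers for threshold channels -> 0
    out
  }
}

#' Query an integral cross section
#'
#' Interpolates the tabulated integral cross section of one channel at the
#' requested incident energies.  At tabulated energies the printed value is
#' returned exactly; between grid points interpolation is log-log linear,
#' except inside documented resonance windows where it is linear; outside a
#' channel's tabulated support (below onset, or above the last tabulated
#' energy of a threshold channel) the result is 0.  Energies outside
#' 0.1-100 eV raise an error: the set is never extrapolated.
#'
#' @param set a [xs_set] from [load_pyridine_xs()].
#' @param channel channel name.
#' @param E incident energies, eV (vectorized).
#' @return cross sections in 1e-20 m^2.
#' @export
xs_sigma <- function(set, channel, E) {
  stopifnot(inherits(set, "xs_set"))
  channel <- match.arg(channel, .channels)
  set$interp[[channel]](E)
}

#' Total scattering cross section
#'
#' Sum of all open channels at each energy.  The transmission-experiment
#' reference values exclude rotational excitation, hence the flag.
#'
#' @inheritParams xs_sigma
#' @param include_rotational include the rotational channel in the sum?
#' @return total cross sections, 1e-20 m^2.
#' @export
xs_total <- function(set, E, include_rotational = TRUE) {
  stopifnot(inherits(set, "xs_set"))
  chans <- if (include_rotational) .channels else
    setdiff(.channels, "rotational")
  Reduce(`+`, lapply(chans, function(ch) set$interp[[ch]](E)))
}

#' Per-channel collision probabilities
#'
#' The probability that a collision at energy `E` proceeds through each
#' channel: each channel's cross section divided by the total.
#'
#' @inheritParams xs_sigma
#' @param E a single incident energy, eV.
#' @return named numeric vector over the six channels, summing to 1.
#' @export
xs_channel_probs <- function(set, E) {
  stopifnot(inherits(set, "xs_set"), length(E) == 1L)
  s <- vapply(.channels, function(ch) set$interp[[ch]](E), numeric(1))
  tot <- sum(s)
  if (tot <= 0) stop("zero total cross section at E = ", E, " eV")
  s / tot
}

#' Gas-cell conditions
#'
#' Pressure, temperatures, cell length and target molar mass of a gas cell.
#' The effective gas temperature is the geometric mean of the scattering
#' chamber temperature (thermocouple) and the capacitance-gauge operating
#' temperature, `T = sqrt(T_C * T_m)`, the standard thermal-transpiration
#' correction for such gauges.
#'
#' @param pressure_mTorr gas pressure, mTorr (>= 0).
#' @param T_chamber_K scattering-chamber temperature, K.
#' @param T_gauge_K gauge operating temperature, K.
#' @param cell_length_m absorption length of the cell, m (default 0.05, the
#'   linear spectrometer cell).
#' @param molar_mass_amu target molar mass (79 for pyridine).
#' @return object of class `gas_conditions`.
#' @export
gas_conditions <- function(pressure_mTorr, T_chamber_K = 300,
                           T_gauge_K = 300, cell_length_m = 0.05,
                           molar_mass_amu = 79) {
  stopifnot(pressure_mTorr >= 0, T_chamber_K > 0, T_gauge_K > 0,
            cell_length_m > 0, molar_mass_amu > 0)
  structure(list(pressure_mTorr = pressure_mTorr,
                 T_chamber_K = T_chamber_K, T_gauge_K = T_gauge_K,
                 T_eff_K = sqrt(T_chamber_K * T_gauge_K),
                 cell_length_m = cell_length_m,
                 molar_mass_amu = molar_mass_amu),
            class = "gas_conditions")
}

#' @export
print.gas_conditions <- function(x, ...) {
  cat(sprintf("<gas_conditions> %.4g mTorr, T_eff = %.2f K, L = %g m, M = %g amu\n",
              x$pressure_mTorr, x$T_eff_K, x$cell_length_m, x$molar_mass_amu))
  invisible(x)
}

#' Number density of the target gas
#'
#' Ideal-gas number density `n = P / (kB * T_eff)` with the pressure converted
#' from mTorr to Pa and `T_eff = sqrt(T_C * T_m)`.
#'
#' @param g a [gas_conditions] object.
#' @return number density, m^-3.
#' @export
pressure_to_density <- function(g) {
  stopifnot(inherits(g, "gas_conditions"))
  (g$pressure_mTorr * .mTorr_Pa) / (.kB * g$T_eff_K)
}

#' Mean free path
#'
#' `lambda = 1 / (n * sigma)` with the cross section converted to SI.
#' Zero density or zero cross section give an infinite path (vacuum).
#'
#' @param sigma_xs total cross section in 1e-20 m^2.
#' @param n number density, m^-3.
#' @return mean free path, m (`Inf` when `n * sigma` is 0).
#' @export
mean_free_path <- function(sigma_xs, n) {
  stopifnot(sigma_xs >= 0, n >= 0)
  denom <- n * sigma_xs * .xs_unit
  ifelse(denom > 0, 1 / denom, Inf)
}

#' Serialize a cross-section set back to the packaged CSV dialect
#'
#' Writes the recommended-compilation grids in the same column layout as the
#' packaged file, restoring `"<0.1"` for upper-bound cells and blanks for
#' absent grid points, so that a load/serialize round trip reproduces every
#' printed cell character-exactly.
#'
#' @param set a [xs_set] (recommended variant).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xs_csv <- function(set, path) {
  stopifnot(inherits(set, "xs_set"))
  allE <- sort(unique(unlist(lapply(set$grids, `[[`, "energies"))))
  cols <- lapply(set$grids[.channels], function(g) {
    cell <- rep("", length(allE))
    i <- match(g$energies, allE)
    if (!is.null(g$labels)) {
      cell[i] <- g$labels
    } else {
      v <- format(g$values, trim = TRUE, scientific = FALSE,
                  drop0trailing = TRUE)
      ## restore printed upper bounds
      v[g$bound] <- paste0("<", format(g$values[g$bound] * 2, trim = TRUE,
                                       drop0trailing = TRUE))
      cell[i] <- v
    }
    cell
  })
  df <- data.frame(E_eV = format(allE, trim = TRUE, drop0trailing = TRUE),
                   cols, check.names = FALSE)
  names(df) <- c("E_eV", .channels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
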