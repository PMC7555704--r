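test_that("vacuum runs transmit every primary unchanged", {
  cfg <- sim_config(gas_conditions(0), 15, fwhm_eV = 0, n_electrons = 200,
                    seed = 5)
  r <- run_beam(cfg, xs_rec)
  expect_identical(nrow(r$exits), 200L)
  expect_true(all(r$exits$fate == "transmitted"))
  expect_true(all(r$exits$energy == 15))
  expect_true(all(r$exits$dz == 1))
  expect_true(all(r$exits$ncoll == 0L))
  expect_identical(r$ledger$deposited, 0)
})

test_that("identical seeds give bit-identical event logs and exits", {
  cfg <- sim_config(gas_conditions(1, cell_length_m = 0.14), 15,
                    n_electrons = 300, seed = 99)
  r1 <- run_beam(cfg, xs_rec)
  r2 <- run_beam(cfg, xs_rec)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$exits, r2$exits)
  expect_identical(r1$ledger, r2$ledger)
  # a different seed produces a different log
  cfg2 <- sim_config(gas_conditions(1, cell_length_m = 0.14), 15,
                     n_electrons = 300, seed = 100)
  expect_false(identical(run_beam(cfg2, xs_rec)$events, r1$events))
})

test_that("the energy ledger closes for every run", {
  for (seed in 1:3) {
    cfg <- sim_config(gas_conditions(2, cell_length_m = 0.14), 15,
                      n_electrons = 400, seed = seed)
    r <- run_beam(cfg, xs_rec)
    l <- r$ledger
    expect_equal(l$exited + l$backscattered + l$deposited + l$culled,
                 l$injected, tolerance = 1e-12)
  }
  # at 90 eV with secondaries the ledger still closes
  cfg <- sim_config(gas_conditions(2.5, cell_length_m = 0.14), 90,
                    n_electrons = 300, seed = 4)
  r <- run_beam(cfg, xs_rec)
  l <- r$ledger
  expect_equal(l$exited + l$backscattered + l$deposited + l$culled,
               l$injected, tolerance = 1e-12)
  expect_gt(sum(r$exits$generation > 0), 0)  # secondaries were transported
})

test_that("event records stay inside the cell and respect channel physics", {
  cfg <- sim_config(gas_conditions(2, cell_length_m = 0.14), 15,
                    n_electrons = 500, seed = 21)
  r <- run_beam(cfg, xs_rec)
  ev <- r$events
  expect_true(all(ev$z >= 0 & ev$z <= 0.14))
  expect_true(all(ev$loss >= 0))
  rot <- ev[ev$channel == "rotational", ]
  expect_gt(nrow(rot), 0)
  expect_true(all(rot$loss == 0.00109))
  # attachment events deposit the full incident energy and terminate
  att <- ev[ev$channel == "attachment", ]
  if (nrow(att)) expect_true(all(att$deposit == att$loss))
  # ionization only above the binding energy
  ion <- ev[ev$channel == "ionization", ]
  if (nrow(ion)) expect_true(all(ion$loss >= 9.6))
})

test_that("zero-collision survival follows Beer-Lambert attenuation", {
  L <- 0.05
  for (p_mTorr in c(0.1, 0.3)) {
    g <- gas_conditions(p_mTorr, cell_length_m = L)
    cfg <- sim_config(g, 15, fwhm_eV = 0, n_electrons = 2e4, seed = 31,
                      record_events = FALSE)
    r <- run_beam(cfg, xs_rec)
    p_hat <- sum(r$exits$ncoll == 0 & r$exits$generation == 0) / 2e4
    p_th <- exp(-pressure_to_density(g) * xs_total(xs_rec, 15) * 1e-20 * L)
    se <- sqrt(p_th * (1 - p_th) / 2e4)
    expect_lt(abs(p_hat - p_th), 3 * se)
  }
})

test_that("vacuum RPA curve equals the beam's complementary CDF", {
  cfg <- sim_config(gas_conditions(0), 15, fwhm_eV = 0.45,
                    n_electrons = 2e4, seed = 41, record_events = FALSE)
  r <- run_beam(cfg, xs_rec)
  V <- seq(13.5, 16.5, by = 0.1)
  curve <- rpa_curve(r, V)
  sd_b <- 0.45 / (2 * sqrt(2 * log(2)))
  ccdf <- 1 - pnorm(V, 15, sd_b)  # 0.1 eV truncation is > 30 sd away
  expect_lt(max(abs(curve$intensity - ccdf)), 0.012)
  expect_true(all(diff(curve$intensity) <= 0))
  expect_lte(curve$intensity[1], 1)
})

test_that("gas attenuates the axial-energy spectrum at every barrier", {
  V <- seq(0.5, 15.5, by = 0.5)
  cfg0 <- sim_config(gas_conditions(0, cell_length_m = 0.14), 15,
                     n_electrons = 4000, seed = 51, record_events = FALSE)
  vac <- rpa_curve(run_beam(cfg0, xs_rec), V)
  cfg2 <- sim_config(gas_conditions(2, cell_length_m = 0.14), 15,
                     n_electrons = 4000, seed = 51, record_events = FALSE)
  gas <- rpa_curve(run_beam(cfg2, xs_rec), V)
  expect_true(all(gas$intensity <= vac$intensity))
  expect_true(all(diff(gas$intensity) <= 0))
  # scattering strictly removes axial energy near the beam energy
  expect_lt(gas$intensity[V == 14.5], vac$intensity[V == 14.5])
})

test_that("axial energy follows the direction cosine", {
  expect_identical(axial_energy(15, 1), 15)
  expect_equal(axial_energy(8, cos(pi / 3)), 2)  # 60 degrees -> E/4
  # composed rotations: axial energy from the full 3-D direction
  d <- c(0, 0, 1)
  d <- pyrxs:::.rotate_direction(d, 0.4, 1.1)
  d <- pyrxs:::.rotate_direction(d, 0.7, 2.3)
  expect_equal(sum(d^2), 1, tolerance = 1e-12)
  # brute-force oracle: rotation matrices composed explicitly
  rot_about <- function(axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  }
  # first scatter from +z: theta 0.4 at azimuth 1.1 about the old direction
  d_ref <- c(sin(0.4) * cos(1.1), sin(0.4) * sin(1.1), cos(0.4))
  # second scatter: rotate d_ref's frame
  expect_equal(acos(d[3]) >= 0, TRUE)
  expect_equal(axial_energy(10, d[3]), 10 * d[3]^2)
  expect_equal(pyrxs:::.rotate_direction(c(0, 0, 1), 0.4, 1.1)[3],
               d_ref[3], tolerance = 1e-12)
})

test_that("virtual attenuation recovers the total cross section", {
  g <- gas_conditions(0.1, cell_length_m = 0.05)
  cfg <- sim_config(g, 15, fwhm_eV = 0, n_electrons = 4e4, seed = 61,
                    record_events = FALSE)
  v <- virtual_tcs(cfg, xs_rec)
  sig <- xs_total(xs_rec, 15)
  p <- v$I / v$I0
  se_sig <- sqrt((1 - p) / (v$I)) /
    (pressure_to_density(g) * 0.05 * 1e-20)
  expect_lt(abs(v$sigma_eff - sig), 3 * se_sig)
})

test_that("finite acceptance reduces the measured cross section", {
  # isotropic elastic-only toy gas: acceptance pi/2 halves the cross section
  toy <- toy_xs_set(20)
  iso <- iso_elastic_model(toy)
  g <- gas_conditions(0.3, cell_length_m = 0.05)
  cfg <- sim_config(g, 15, fwhm_eV = 0, n_electrons = 1e4, seed = 71,
                    record_events = FALSE)
  ang <- list(elastic = iso, rotational = rotational_dcs_model(xs_rec),
              inelastic = inelastic_angular_params())
  acc <- acceptance_model("fixed_angle", theta_fixed_rad = pi / 2)
  v <- virtual_tcs(cfg, toy, acceptance = acc, angular = ang)
  expect_equal(v$sigma_eff, 10, tolerance = 0.15)
  # perfect discrimination on the same gas recovers the full value
  v0 <- virtual_tcs(cfg, toy, angular = ang)
  expect_equal(v0$sigma_eff, 20, tolerance = 0.1)
  # sigma_eff is non-increasing as the acceptance cone widens
  seff <- vapply(c(0.1, 0.8, pi / 2), function(th) {
    virtual_tcs(cfg, toy,
                acceptance = acceptance_model("fixed_angle",
                                              theta_fixed_rad = th),
                angular = ang)$sigma_eff
  }, numeric(1))
  expect_true(all(diff(seff) <= 0))
})

test_that("backscatter policies conserve electrons", {
  g <- gas_conditions(3, cell_length_m = 0.14)
  cfg_l <- sim_config(g, 15, n_electrons = 300, seed = 81,
                      backscatter_policy = "lost")
  r_l <- run_beam(cfg_l, xs_rec)
  expect_gt(sum(r_l$exits$fate == "backscattered"), 0)
  cfg_r <- sim_config(g, 15, n_electrons = 300, seed = 81,
                      backscatter_policy = "reflected")
  r_r <- run_beam(cfg_r, xs_rec)
  expect_identical(sum(r_r$exits$fate == "backscattered"), 0L)
  l <- r_r$ledger
  expect_equal(l$exited + l$deposited + l$culled, l$injected,
               tolerance = 1e-12)
})
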