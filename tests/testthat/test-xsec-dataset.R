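test_that("packaged grids reproduce the printed table cells exactly", {
  cells <- list(
    list("elastic", 20, 42.28), list("elastic", 15, 40.6),
    list("elastic", 0.11, 423), list("rotational", 0.16, 984.4),
    list("attachment", 1.11, 36.67), list("vibrational", 2.8, 4.71),
    list("electronic", 7, 17.40), list("ionization", 100, 12.26),
    list("ionization", 12, 0.18), list("rotational", 100, 3.173))
  for (c3 in cells)
    expect_identical(xs_sigma(xs_rec, c3[[1]], c3[[2]]), c3[[3]])
  expect_identical(xs_sigma(xs_smc, "elastic", 0.1), 172.4)
  expect_identical(xs_sigma(xs_smc, "elastic", 1.33), 64.7)
  expect_identical(xs_sigma(xs_smc, "elastic", 0.9), 81.96)
  # above 20 eV the SMC variant falls back to the recommended column
  expect_identical(xs_sigma(xs_smc, "elastic", 30), 35.56)
})

test_that("upper-bound cells are encoded as the interval midpoint and flagged", {
  g <- xs_rec$grids$attachment
  i <- which(g$energies == 0.71)
  expect_equal(g$values[i], 0.05)
  expect_true(g$bound[i])
  expect_equal(xs_sigma(xs_rec, "ionization", 10), 0.05)
  expect_false(any(g$bound[g$energies == 1.11]))
})

test_that("queries outside a channel's tabulated support return zero", {
  expect_identical(xs_sigma(xs_rec, "ionization", 5), 0)
  expect_identical(xs_sigma(xs_rec, "attachment", 0.5), 0)
  expect_identical(xs_sigma(xs_rec, "vibrational", 50), 0)  # blank above 3.2 eV
  expect_identical(xs_sigma(xs_rec, "electronic", 1), 0)
  # non-threshold channels clamp below their first grid energy
  expect_identical(xs_sigma(xs_rec, "elastic", 0.1), 423)
})

test_that("interpolation is log-log between smooth grid points and exact at nodes", {
  # frozen hand-computed oracle: ln-ln interpolation between (15, 40.6) and
  # (20, 42.28) at 17.5 eV
  lo <- exp(log(40.6) + (log(17.5) - log(15)) / (log(20) - log(15)) *
              (log(42.28) - log(40.6)))
  expect_equal(xs_sigma(xs_rec, "elastic", 17.5), lo, tolerance = 1e-12)
  expect_equal(lo, 41.49173, tolerance = 1e-6)
  # passes through every grid point exactly
  for (ch in c("elastic", "rotational", "ionization")) {
    g <- xs_rec$grids[[ch]]
    expect_identical(xs_sigma(xs_rec, ch, g$energies), g$values)
  }
})

test_that("attachment resonances interpolate linearly inside their windows", {
  # midpoint of the 0.76-0.785 segment, inside the first resonance window
  expect_equal(xs_sigma(xs_rec, "attachment", 0.7725), (18.25 + 29.47) / 2)
  # SMC spike window 0.8-1.0 is linear too
  expect_equal(xs_sigma(xs_smc, "elastic", 0.85), (32.47 + 81.96) / 2)
})

test_that("interpolant is bounded by neighbours on monotone segments", {
  g <- xs_rec$grids$rotational
  mids <- (g$energies[-1] + g$energies[-length(g$energies)]) / 2
  v <- xs_sigma(xs_rec, "rotational", mids)
  lo <- pmin(g$values[-1], g$values[-length(g$values)])
  hi <- pmax(g$values[-1], g$values[-length(g$values)])
  expect_true(all(v >= lo - 1e-12 & v <= hi + 1e-12))
})

test_that("energies outside 0.1-100 eV are refused", {
  expect_error(xs_sigma(xs_rec, "elastic", 0.05), "out of range")
  expect_error(xs_sigma(xs_rec, "elastic", 101), "out of range")
  expect_error(xs_total(xs_rec, 150), "out of range")
})

test_that("grid validation names the offending data", {
  expect_error(channel_grid("elastic", c(1, 2, 2), c(1, 1, 1)),
               "not strictly increasing")
  expect_error(channel_grid("elastic", c(1, 2), c(1, -1)), "negative")
  expect_error(channel_grid("elastic", c(-1, 2), c(1, 1)), "positive")
})

test_that("total cross section decomposes over channels", {
  # 100 eV row: elastic + electronic + ionization (others blank)
  expect_equal(xs_total(xs_rec, 100, include_rotational = FALSE),
               21.42 + 3.96 + 12.26)
  E <- c(0.5, 2.5, 8, 20, 60)
  expect_equal(xs_total(xs_rec, E, TRUE) - xs_total(xs_rec, E, FALSE),
               xs_sigma(xs_rec, "rotational", E))
  expect_true(all(xs_total(xs_rec, E) >= xs_sigma(xs_rec, "elastic", E)))
})

test_that("channel probabilities are a distribution at random energies", {
  set.seed(42)
  E <- exp(runif(1000, log(0.1), log(100)))
  for (e in E[1:25]) {  # exact node + off-node energies below
    p <- xs_channel_probs(xs_rec, e)
    expect_true(all(p >= 0 & p <= 1))
  }
  sums <- vapply(E, function(e) sum(xs_channel_probs(xs_rec, e)), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
  # at 0.31 eV only elastic and rotational are open
  p <- xs_channel_probs(xs_rec, 0.31)
  expect_identical(sum(p > 0), 2L)
  expect_equal(unname(p[["elastic"]]), 144.8 / (144.8 + 546))
  # 100 eV row probabilities equal printed cells over the row sum
  p <- xs_channel_probs(xs_rec, 100)
  tot <- 21.42 + 3.96 + 12.26 + 3.173
  expect_equal(unname(p[["ionization"]]), 12.26 / tot)
})

test_that("load/serialize round trip restores the printed cells", {
  f <- tempfile(fileext = ".csv")
  write_xs_csv(xs_rec, f)
  out <- read.csv(f, colClasses = "character", check.names = FALSE)
  src <- read.csv(system.file("extdata", "table1_recommended.csv",
                              package = "pyrxs"),
                  comment.char = "#", colClasses = "character",
                  check.names = FALSE)
  for (ch in c("elastic", "attachment", "electronic", "vibrational",
               "ionization", "rotational")) {
    expect_identical(trimws(out[[ch]]), trimws(src[[ch]]))
  }
})

test_that("gas conditions convert to number density and mean free path", {
  g <- gas_conditions(2, 300, 300)
  expect_equal(g$T_eff_K, 300)
  # frozen arithmetic oracle: 2 mTorr at 300 K
  expect_equal(pressure_to_density(g),
               2 * 0.13332237 / (1.380649e-23 * 300), tolerance = 1e-12)
  expect_equal(pressure_to_density(g), 6.4377e19, tolerance = 1e-4)
  expect_identical(pressure_to_density(gas_conditions(0)), 0)
  # geometric-mean temperature
  g2 <- gas_conditions(1, 400, 225)
  expect_equal(g2$T_eff_K, 300)
  expect_equal(mean_free_path(40, 1e20), 0.025)
  expect_equal(mean_free_path(40, 2e20), 0.0125)
  expect_identical(mean_free_path(40, 0), Inf)
  # chained oracle: mean free path at 2 mTorr/300 K for the 100 eV total
  lam <- mean_free_path(xs_total(xs_rec, 100, FALSE), pressure_to_density(g))
  expect_equal(lam, 1 / (6.437667e19 * 37.64e-20), tolerance = 1e-6)
})
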