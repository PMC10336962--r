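test_that("screening parameters follow the closed forms", {
  expect_equal(debye_parameters(0)$inverse_debye_length, 0)
  d <- debye_parameters(150, 298, 78.4)
  expect_equal(d$bjerrum_length, 7.1, tolerance = 0.01)
  expect_equal(1 / d$inverse_debye_length, 7.9, tolerance = 0.01)
  expect_error(debye_parameters(150, relative_permittivity = -2),
               "permittivity")
})

test_that("pair energies reproduce the model's defining values", {
  cfg <- bn_config()
  # uncharged ion pair beyond contact: no interaction at all
  expect_equal(pair_energy(c(4, 6, 50), 0, 0, "ion_ion", cfg), c(0, 0, 0))
  # chain-chain at closest contact: the calibrated -0.6 kT
  expect_equal(pair_energy(4, 0, 0, "chain_chain", cfg), -0.6)
  # hard-core overlap
  expect_equal(pair_energy(3.9, 0, 0, "chain_chain", cfg), Inf)
  # zero salt, point-like particles: bare Coulomb lB/r
  tiny <- bn_config(bead_radius = 1e-6, ion_radius = 1e-6, salt_mM = 0)
  lB <- debye_parameters(0)$bjerrum_length
  r <- c(5, 10, 40)
  u <- pair_energy(r, 1, 1, "chain_ion", tiny)
  expect_equal(u, lB / r, tolerance = 1e-5)
})

test_that("bond energy is harmonic with the converted force constant", {
  cfg <- bn_config()
  expect_equal(bond_energy(4.1, cfg), 0)
  expect_equal(bond_energy(5.1, cfg), 0.486, tolerance = 0.001)
  delta <- c(0.3, 0.9, 1.7)
  expect_equal(bond_energy(4.1 + delta, cfg), bond_energy(4.1 - delta, cfg))
})

test_that("Metropolis rule accepts downhill always and uphill at exp(-dU)", {
  expect_true(all(metropolis_accept(rep(0, 100))))
  expect_true(all(metropolis_accept(rep(-3, 100))))
  expect_false(any(metropolis_accept(rep(Inf, 100))))
  set.seed(12)
  n <- 1e5
  p_hat <- mean(metropolis_accept(rep(1, n)))
  sigma <- sqrt(exp(-1) * (1 - exp(-1)) / n)
  expect_lt(abs(p_hat - exp(-1)), 3 * sigma)
})

test_that("compiled incremental energies match the brute-force oracle", {
  ca <- assign_charges(hst5_sequence())
  tr <- run_bead_necklace(ca, short_config(salt_mM = 150), seed = 4)
  expect_gte(length(tr$frames), 10L)
  for (f in tr$frames) {
    st <- list(chain = f$chain, ions = f$ions,
               bead_charge = tr$bead_charge, ion_charge = tr$ion_charge)
    expect_equal(f$energy, total_energy(st, tr$config), tolerance = 1e-8)
  }
  # accumulated-increment drift against full recomputation at run end
  expect_lt(abs(tr$energy_drift), 1e-6)
})

test_that("runs are deterministic, hard-core-respecting and electroneutral", {
  ca <- assign_charges("GKKDDAAAKG")
  cfg <- short_config(salt_mM = 50)
  t1 <- run_bead_necklace(ca, cfg, seed = 99)
  t2 <- run_bead_necklace(ca, cfg, seed = 99)
  expect_identical(t1$rg_series, t2$rg_series)
  expect_identical(t1$energy_series, t2$energy_series)
  t3 <- run_bead_necklace(ca, cfg, seed = 100)
  expect_false(identical(t1$rg_series, t3$rg_series))

  # one counterion per chain charge, of opposite sign: exact neutrality
  expect_equal(length(t1$ion_charge), sum(t1$bead_charge != 0))
  expect_equal(sum(t1$bead_charge) + sum(t1$ion_charge), 0L)

  # no sampled pair closer than the 4 Angstrom contact distance
  expect_gte(t1$min_pair_distance, 4)

  # acceptance fractions are proper frequencies
  expect_true(all(t1$acceptance$fraction >= 0 & t1$acceptance$fraction <= 1,
                  na.rm = TRUE))
})

test_that("degenerate chains and undersized boxes are rejected", {
  expect_error(run_bead_necklace(integer(1), short_config()), "at least 2")
  expect_error(run_bead_necklace(rep(0L, 20),
                                 short_config(box_side = 30)),
               "contour")
  # a 2-bead chain runs with pivot/slither weights redistributed
  t2 <- run_bead_necklace(rep(0L, 2), short_config(box_side = 60), seed = 1)
  expect_gt(length(t2$rg_series), 0L)
  expect_equal(sum(t2$acceptance$attempted[
    t2$acceptance$move_type %in% c("pivot", "slither")]), 0)
})

test_that("zero-interaction limit reproduces phantom-chain statistics", {
  # neutral chain, no attraction, vanishing hard core: bonds decouple and
  # <Ree^2> = (N-1) <b^2> with <b^2> from quadrature
  cfg <- bn_config(bead_radius = 0.01, ion_radius = 0.01,
                   attraction_contact = 0, salt_mM = 0, box_side = 200,
                   n_equil_cycles = 5000, n_prod_cycles = 150000,
                   sample_interval = 25)
  tr <- run_bead_necklace(rep(0L, 10), cfg, seed = 7)
  target <- 9 * phantom_bond_moments()$mean_sq
  expect_equal(mean(tr$ree2_series), target, tolerance = 0.05)
})

test_that("counterion distributions are excluded from the core and sign-sorted", {
  # net-negative chain with charges of both signs
  charges <- c(rep(-1L, 8), rep(1L, 2), rep(0L, 10))
  tr <- run_bead_necklace(charges,
                          short_config(salt_mM = 20, n_prod_cycles = 6000,
                                       n_store_frames = 40),
                          seed = 21)
  rdf <- counterion_rdf(tr, bin_width = 1)
  # occupancy conservation before normalization
  expect_equal(sum(rdf$counts), length(tr$ion_charge) * length(tr$frames))
  expect_equal(rdf$n_observations, sum(rdf$counts))
  # hard-sphere exclusion below bead-ion contact
  expect_equal(sum(rdf$counts[rdf$mids < 4]), 0)
  expect_equal(sum(rdf$density * diff(rdf$breaks)), 1)
  # positive counterions of a net-negative chain sit closer than co-ions
  expect_lt(rdf$mean_min_distance_positive, rdf$mean_min_distance_negative)

  neutral <- run_bead_necklace(rep(0L, 5), short_config(box_side = 100),
                               seed = 1)
  expect_error(counterion_rdf(neutral), "no counterions")
})

test_that("RDF of identical frames equals the single-frame histogram", {
  tr <- run_bead_necklace(c(1L, -1L, rep(0L, 4)),
                          short_config(n_prod_cycles = 2000,
                                       n_store_frames = 15),
                          seed = 2)
  frozen <- tr
  frozen$frames <- rep(tr$frames[1], 12)
  single <- tr
  single$frames <- rep(tr$frames[1], 10)   # minimum frame count
  a <- counterion_rdf(frozen, bin_width = 2)
  b <- counterion_rdf(single, bin_width = 2)
  expect_equal(a$density, b$density)
})

test_that("convergence diagnostics flag discordant replicates", {
  const <- rep(5, 1000)
  rep_const <- convergence_report(list(const, const))
  expect_equal(rep_const$pooled_se, 0)
  expect_false(any(rep_const$replicates$flagged))

  set.seed(31)
  base <- rnorm(2000, 10, 0.5)
  off <- rnorm(2000, 10 + 10 * 0.5, 0.5)
  rep_off <- convergence_report(list(base, off))
  expect_true(any(rep_off$replicates$flagged))
})

test_that("statistical inefficiency recovers the AR(1) closed form", {
  set.seed(5)
  for (phi in c(0.5, 0.8)) {
    x <- as.numeric(stats::arima.sim(list(ar = phi), 100000))
    g <- statistical_inefficiency(x)
    expect_equal(g, (1 + phi) / (1 - phi), tolerance = 0.2)
  }
  expect_equal(statistical_inefficiency(rep(3, 100)), 1)
})

test_that("trajectory files round-trip the sampled series", {
  tr <- run_bead_necklace(c(1L, 0L, -1L, 0L, 0L),
                          short_config(n_prod_cycles = 1000),
                          seed = 3)
  prefix <- tempfile()
  paths <- write_trajectory(tr, prefix)
  expect_true(all(file.exists(paths)))
  side <- read.csv(paths[["csv"]])
  expect_equal(side$rg, tr$rg_series, tolerance = 1e-12)
  xyz <- readLines(paths[["xyz"]])
  expect_equal(as.integer(xyz[1]),
               length(tr$bead_charge) + length(tr$ion_charge))
  cfg <- yaml::read_yaml(paths[["yaml"]])
  expect_equal(cfg$seed, 3)
})
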