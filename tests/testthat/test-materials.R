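test_that("packaged materials have the right densities and compositions", {
  cw <- make_material("cell_water")
  expect_equal(cw$density, 1.10)
  w <- make_material("water")
  expect_equal(w$density, 1.0)
  expect_equal(unname(w$fractions[["H"]]), 0.1119, tolerance = 1e-3)
  expect_equal(sum(w$fractions), 1, tolerance = 1e-6)
  broth <- make_material("davis_broth_water")
  expect_equal(sum(broth$fractions), 1, tolerance = 1e-6)
  # potassium from 7 g/L K2HPO4 + 2 g/L KH2PO4
  K_gL <- broth$fractions[["K"]] * broth$density * 1000
  expect_equal(unname(K_gL), 3.72, tolerance = 0.01)
  pp <- make_material("polypropylene")
  expect_equal(pp$density, 0.905)
  expect_error(make_material("granite"))
})

test_that("photon attenuation reproduces water benchmarks and process physics", {
  mu <- photon_mu(1.25e6, "water")
  expect_equal(mu$total, 0.063, tolerance = 0.05)
  expect_equal(photon_mu(1.0e6, "water")$pair, 0)  # below the 2 me c^2 threshold
  expect_gt(photon_mu(2e6, "water")$pair, 0)       # above it
  # Compton share grows from the photoelectric- to the Compton-dominated regime
  E <- c(2e3, 1e4, 5e4, 1e5, 5e5, 1e6)
  frac <- photon_mu(E, "water")
  share <- frac$compton / frac$total
  expect_true(all(diff(share) > 0))
  expect_equal(photon_mu(662e3, "water")$total, 0.0857, tolerance = 0.05)
  expect_error(photon_mu(5e2, "water"), "grid")
  expect_error(photon_mu(2e7, "water"), "grid")
})

test_that("Compton sampling respects Klein-Nishina kinematics", {
  set.seed(12)
  cs <- sample_compton(1.25e6, n = 5e4)
  # energy conserved exactly
  expect_equal(cs$electron_energy + cs$photon_energy, rep(1.25e6, 5e4),
               tolerance = 1e-12)
  # backscatter bound 2E^2/(me + 2E)
  Emax <- 2 * 1.25e6^2 / (510998.95 + 2 * 1.25e6)
  expect_lte(max(cs$electron_energy), Emax)
  expect_gt(max(cs$electron_energy), 0.99 * Emax)
  # forward scatter deposits nothing
  expect_lt(min(cs$electron_energy[cs$cos_theta_photon > 0.9999]), 1e3)

  # mean sampled energy vs numeric integration of the KN differential
  # cross-section in eps = E'/E
  k <- 662e3 / 510998.95
  kn <- function(eps) (1 / eps + eps) * (1 - eps * ((1 - eps) / (k * eps)) *
                        (2 - (1 - eps) / (k * eps)) / (1 + eps^2))
  eps_min <- 1 / (1 + 2 * k)
  norm <- integrate(kn, eps_min, 1)$value
  mean_eps <- integrate(function(e) e * kn(e), eps_min, 1)$value / norm
  set.seed(13)
  cs2 <- sample_compton(662e3, n = 2e5)
  se <- sd(cs2$photon_energy) / sqrt(2e5)
  expect_lt(abs(mean(cs2$photon_energy) - mean_eps * 662e3), 4 * se)
})

test_that("stopping powers and ranges match the printed anchors", {
  expect_equal(stopping_and_range("electron", 511e3)$S, 2.04, tolerance = 0.02)
  expect_equal(stopping_and_range("electron", 1e5)$R_csda * 1e4, 140,
               tolerance = 0.05)
  expect_equal(stopping_and_range("muon_minus", 14e9)$S, 2.55, tolerance = 0.05)
  # range is the integral of 1/S (independent numeric quadrature)
  R10 <- stopping_and_range("electron", 1e4)$R_csda
  R100 <- stopping_and_range("electron", 1e5)$R_csda
  iq <- integrate(function(E) 1e-6 / stopping_and_range("electron", E)$S,
                  1e4, 1e5, subdivisions = 400)$value
  expect_equal(R100 - R10, iq, tolerance = 0.02)
  # monotone range
  E <- c(1e4, 1e5, 1e6, 1e7)
  expect_true(all(diff(stopping_and_range("electron", E)$R_csda) > 0))
  expect_error(stopping_and_range("electron", 10), "grid")
})

test_that("chord deposits have the right mean, bounds and density scaling", {
  expect_equal(sample_deposit("electron", 2e5, 0), 0)
  set.seed(21)
  d <- sample_deposit("electron", 2e5, 0.889, material = "water", n = 2e4)
  S_chord <- stopping_and_range("electron", 2e5)$S * 100 * 0.889
  expect_within(mean(d), S_chord, 0.10, "mean water deposit")
  expect_true(all(d <= 2e5))
  # clamped by the available kinetic energy
  dlow <- sample_deposit("electron", 500, 10, n = 200)
  expect_true(all(dlow <= 500))
  # 1.10 density scaling, deterministic mode
  dw <- sample_deposit("electron", 2e5, 1, material = "water", straggling = FALSE)
  dc <- sample_deposit("electron", 2e5, 1, material = "cell_water", straggling = FALSE)
  expect_equal(dc / dw, 1.10, tolerance = 0.01)
  # straggled means keep the same ratio (rare large knock-on transfers make
  # the mean heavy-tailed, so use a large sample)
  set.seed(22)
  d2 <- sample_deposit("electron", 2e5, 0.889, material = "water", n = 2e5)
  dc2 <- sample_deposit("electron", 2e5, 0.889, material = "cell_water", n = 2e5)
  expect_within(mean(dc2) / mean(d2), 1.10, 0.05, "density scaling of means")
})

test_that("restricted stopping and knock-on rates behave at the thresholds", {
  S <- stopping_and_range("electron", 2e5)$S
  Sres <- restricted_stopping("electron", 2e5, 1000)
  expect_lt(Sres, S)
  expect_gt(Sres, 0)
  expect_gt(delta_rate("electron", 2e5, 1000), 0)
  # no knock-ons when Tmax = E/2 is below the threshold
  expect_equal(delta_rate("electron", 1500, 1000), 0)
})

test_that("neutron elastic recoils follow two-body kinematics", {
  # A = 1: maximum transfer is the full neutron energy, flat spectrum
  set.seed(33)
  rh <- neutron_elastic_recoil(2e6, "H", n = 2e5)
  expect_true(all(rh$species == "proton"))
  expect_lte(max(rh$energy), 2e6)
  expect_gt(max(rh$energy), 0.999 * 2e6)
  se <- sd(rh$energy) / sqrt(2e5)
  expect_lt(abs(mean(rh$energy) - 1e6), 3 * se)
  # A = 16: E_max/E_n = 4*16/17^2
  ro <- neutron_elastic_recoil(2e6, "O", n = 2e5)
  expect_true(all(ro$species == "ion_O16"))
  expect_equal(max(ro$energy) / 2e6, 4 * 16 / 17^2, tolerance = 1e-3)
  expect_true(all(ro$cos_theta >= 0 & ro$cos_theta <= 1))
})
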