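# Materials and interaction physics: compositions, photon attenuation,
# charged-particle stopping powers / CSDA ranges, energy-loss straggling,
# and simplified neutron elastic kinematics.

# Element lookup (Z, A) for everything appearing in the packaged recipes.
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "K"),
  Z = c(1, 6, 7, 8, 11, 12, 15, 16, 19),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06, 39.098),
  stringsAsFactors = FALSE
)

# Davis minimal broth recipe [g/L] (dipotassium phosphate, monopotassium
# phosphate, ammonium sulfate, sodium citrate, magnesium sulfate heptahydrate)
# plus the glucose enrichment used in the growth protocol.
.davis_recipe <- c(
  K2HPO4 = 7, KH2PO4 = 2, NH4_2SO4 = 1, Na3Citrate = 0.5,
  MgSO4_7H2O = 0.1, glucose = 0.25
)

# Elemental mass fractions of each solute
.solute_fractions <- list(
  K2HPO4     = c(K = 78.196 / 174.176, H = 1.008 / 174.176, P = 30.974 / 174.176, O = 63.996 / 174.176),
  KH2PO4     = c(K = 39.098 / 136.086, H = 2.016 / 136.086, P = 30.974 / 136.086, O = 63.996 / 136.086),
  NH4_2SO4   = c(N = 28.014 / 132.140, H = 8.064 / 132.140, S = 32.060 / 132.140, O = 63.996 / 132.140),
  Na3Citrate = c(Na = 68.970 / 258.069, C = 72.066 / 258.069, H = 5.040 / 258.069, O = 111.993 / 258.069),
  MgSO4_7H2O = c(Mg = 24.305 / 246.475, S = 32.060 / 246.475, O = 175.989 / 246.475, H = 14.112 / 246.475),
  glucose    = c(C = 72.066 / 180.156, H = 12.096 / 180.156, O = 95.994 / 180.156)
)

#' Construct a packaged material
#'
#' Returns one of the four materials of the experiment model: pure water,
#' Davis-minimal-broth-enriched water (the well liquid), high-density cell
#' water (1.10 g/cm^3, the intracellular medium) or polypropylene (the plate).
#'
#' @param name one of `"water"`, `"davis_broth_water"`, `"cell_water"`,
#'   `"polypropylene"`.
#' @return An object of class `material`: a list with `name`, `density`
#'   (g/cm^3), `fractions` (named elemental mass fractions summing to 1),
#'   `electrons_per_gram`, and `Zeff` (photoelectric-weighted effective
#'   atomic number).
#' @examples
#' make_material("cell_water")$density   # 1.10
#' make_material("water")$fractions[["H"]]
#' @export
make_material <- function(name) {
  name <- match.arg(name, c("water", "davis_broth_water", "cell_water", "polypropylene"))
  water_frac <- c(H = 2 * 1.008 / 18.015, O = 15.999 / 18.015)
  if (name == "water") {
    frac <- water_frac; density <- 1.0
  } else if (name == "cell_water") {
    frac <- water_frac; density <- 1.10
  } else if (name == "polypropylene") {
    frac <- c(C = 12.011 / 14.027, H = 2.016 / 14.027); density <- 0.905
  } else { # davis_broth_water: 1 L water + solutes
    grams <- c(setNames(rep(0, nrow(.elements)), .elements$symbol))
    grams["H"] <- 1000 * water_frac[["H"]]
    grams["O"] <- 1000 * water_frac[["O"]]
    for (s in names(.davis_recipe)) {
      f <- .solute_fractions[[s]]
      grams[names(f)] <- grams[names(f)] + .davis_recipe[[s]] * f
    }
    total <- sum(grams)
    frac <- grams[grams > 0] / total
    density <- total / 1000  # ~1.010; solutes add mass at ~constant volume
  }
  frac <- frac / sum(frac)
  idx <- match(names(frac), .elements$symbol)
  epg <- .const$N_A * sum(frac * .elements$Z[idx] / .elements$A[idx])
  # photoelectric-weighted effective Z (electron-fraction weighted Z^2.94)
  efrac <- frac * .elements$Z[idx] / .elements$A[idx]
  efrac <- efrac / sum(efrac)
  zeff <- sum(efrac * .elements$Z[idx]^2.94)^(1 / 2.94)
  structure(list(name = name, density = density, fractions = frac,
                 electrons_per_gram = epg, Zeff = zeff),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  rho = %.4g g/cm^3  Zeff = %.3g\n", x$name, x$density, x$Zeff))
  print(round(x$fractions, 5))
  invisible(x)
}

#' Total Klein-Nishina cross section per electron
#'
#' Closed-form total cross section for Compton scattering of a photon on a
#' free electron.
#'
#' @param E photon energy [eV] (vectorized).
#' @return cross section [cm^2] per electron.
#' @export
klein_nishina_total <- function(E) {
  k <- E / .const$me_c2_eV
  re2 <- .const$re_cm^2
  2 * pi * re2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
                    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

# Water photoelectric mass attenuation [cm^2/g], anchored piecewise power law
.mu_pe_water <- function(E) {
  E10 <- E / 1e4
  ifelse(E10 < 1, 4.944 * E10^(-2.92), 4.944 * E10^(-3.25))
}

#' Photon attenuation coefficients by process
#'
#' Linear attenuation coefficients for the photoelectric effect, (incoherent)
#' Compton scattering and pair production. Compton is the exact Klein-Nishina
#' total per electron times the electron density; photoelectric and pair are
#' anchored power-law parameterizations scaled by electron density and
#' effective atomic number. Valid from 1 keV to 10 MeV.
#'
#' @param E photon energy [eV] (vectorized).
#' @param material a `material` object or material name.
#' @return data.frame with columns `photoelectric`, `compton`, `pair`,
#'   `total` [cm^-1].
#' @export
photon_mu <- function(E, material = "water") {
  if (is.character(material)) material <- make_material(material)
  if (any(E < 1e3 * (1 - 1e-9)) || any(E > 1e7 * (1 + 1e-9)))
    stop("photon energy outside the packaged grid (1 keV - 10 MeV)")
  ne_cm3 <- material$electrons_per_gram * material$density
  compton <- ne_cm3 * klein_nishina_total(E)
  # scale water anchor by electron density and (Zeff/Zeff_water)^3
  zw <- make_material("water")$Zeff
  pe <- .mu_pe_water(E) * material$density *
    (material$electrons_per_gram / 3.343e23) * (material$Zeff / zw)^3
  pair <- ifelse(E > 1.022e6,
                 5.0e-3 * ((E - 1.022e6) / 8.978e6)^1.63 * material$density *
                   (material$electrons_per_gram / 3.343e23) * (material$Zeff / zw),
                 0)
  data.frame(photoelectric = pe, compton = compton, pair = pair,
             total = pe + compton + pair)
}

#' Sample Compton scattering kinematics
#'
#' Samples the scattered-photon energy from the Klein-Nishina differential
#' cross section on a free electron (Kahn-style rejection) and returns the
#' full kinematics. Energy is conserved exactly.
#'
#' @param E_gamma incident photon energy [eV].
#' @param n number of samples.
#' @return data.frame with `electron_energy`, `photon_energy` [eV],
#'   `cos_theta_photon`, `cos_theta_electron` (relative to the incident
#'   direction).
#' @export
sample_compton <- function(E_gamma, n = 1) {
  k <- E_gamma / .const$me_c2_eV
  eps_min <- 1 / (1 + 2 * k)
  out <- numeric(0)
  # rejection: propose eps ~ mix of 1/eps and uniform, accept on KN weight
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    a1 <- -log(eps_min); a2 <- (1 - eps_min^2) / 2
    use_log <- runif(m) < a1 / (a1 + a2)
    eps <- ifelse(use_log, eps_min * exp(a1 * runif(m)), sqrt(eps_min^2 + (1 - eps_min^2) * runif(m)))
    t1 <- (1 - eps) / (k * eps)
    sin2 <- t1 * (2 - t1)
    accept <- runif(m) < 1 - eps * sin2 / (1 + eps^2)
    out <- c(out, eps[accept])
  }
  eps <- out[seq_len(n)]
  cos_th <- 1 - (1 - eps) / (k * eps)
  E_prime <- eps * E_gamma
  E_e <- E_gamma - E_prime
  # electron direction from momentum conservation
  p_g <- E_gamma; p_gp <- E_prime
  p_e <- sqrt(E_e * (E_e + 2 * .const$me_c2_eV))
  cos_e <- ifelse(p_e > 0, (p_g - p_gp * cos_th) / p_e, 1)
  cos_e <- pmin(1, pmax(-1, cos_e))
  data.frame(electron_energy = E_e, photon_energy = E_prime,
             cos_theta_photon = cos_th, cos_theta_electron = cos_e)
}

## ---- stopping powers ------------------------------------------------------

# Sternheimer density-effect correction for water
.delta_sternheimer <- function(beta_gamma) {
  x <- log10(pmax(beta_gamma, 1e-12))
  C <- 3.5017; a <- 0.09116; m <- 3.4773; x0 <- 0.2400; x1 <- 2.8004
  d <- ifelse(x < x0, 0,
              ifelse(x < x1, 4.6052 * x - C + a * (x1 - x)^m, 4.6052 * x - C))
  pmax(d, 0)
}

# Berger-Seltzer electron collision stopping power in water [MeV cm^2/g]
.S_col_electron <- function(E_eV) {
  me <- .const$me_c2_eV
  tau <- E_eV / me
  beta2 <- 1 - 1 / (1 + tau)^2
  I_ratio2 <- (.const$I_water_eV / me)^2
  Fterm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  delta <- .delta_sternheimer(sqrt(tau * (tau + 2)))
  brack <- log(tau^2 * (tau + 2) / (2 * I_ratio2)) + Fterm - delta
  pmax(.const$xi_coef * .const$ZA_water / beta2 * brack, 1e-3)
}

# Approximate radiative stopping power (bremsstrahlung), water
.S_rad_electron <- function(E_eV, S_col) {
  S_col * (E_eV / 1e6) * 7.5 / 800
}

# Bethe stopping power for heavy charged particles in water [MeV cm^2/g]
.S_heavy <- function(E_eV, mass_eV, z2) {
  me <- .const$me_c2_eV
  gamma <- 1 + E_eV / mass_eV
  beta2 <- 1 - 1 / gamma^2
  bg2 <- beta2 * gamma^2
  Tmax <- 2 * me * bg2 / (1 + 2 * gamma * me / mass_eV + (me / mass_eV)^2)
  I <- .const$I_water_eV
  delta <- .delta_sternheimer(sqrt(bg2))
  brack <- 0.5 * log(2 * me * bg2 * Tmax / I^2) - beta2 - delta / 2
  pmax(.const$K_bethe * z2 * .const$ZA_water / beta2 * brack, 1e-3)
}

# Build a stopping/range table on a uniform log-energy grid (water, rho = 1)
.build_table <- function(species) {
  npts <- 400L
  if (species %in% c("electron", "positron")) {
    Emin <- 100; Emax <- 1e8
    E <- exp(seq(log(Emin), log(Emax), length.out = npts))
    S <- .S_col_electron(E)
    S <- S + .S_rad_electron(E, S)
  } else if (species %in% c("muon_minus", "muon_plus")) {
    Emin <- 1e6; Emax <- 1e11
    E <- exp(seq(log(Emin), log(Emax), length.out = npts))
    S <- .S_heavy(E, .const$mmu_c2_eV, 1)
  } else if (species == "proton") {
    Emin <- 1e4; Emax <- 1e9
    E <- exp(seq(log(Emin), log(Emax), length.out = npts))
    S <- .S_heavy(E, .const$mp_c2_eV, 1)
    # Bethe is invalid at low proton energies: splice a velocity-scaling
    # approximation below 1 MeV (S ~ E^-0.5 down to the Bragg peak at
    # ~80 keV, then S ~ E^0.5), continuous at the splice point.
    S1 <- .S_heavy(1e6, .const$mp_c2_eV, 1)
    low <- E < 1e6
    Sl <- ifelse(E >= 8e4, S1 * (E / 1e6)^(-0.5),
                 S1 * (8e4 / 1e6)^(-0.5) * (E / 8e4)^(0.5))
    S[low] <- Sl[low]
  } else if (species %in% c("alpha", "ion_O16")) {
    # proton velocity scaling with effective charge
    mass <- if (species == "alpha") .const$malpha_c2_eV else .const$mO16_c2_eV
    z <- if (species == "alpha") 2 else 8
    Emin <- 1e4 * mass / .const$mp_c2_eV; Emax <- 1e9 * mass / .const$mp_c2_eV
    E <- exp(seq(log(Emin), log(Emax), length.out = npts))
    pt <- .build_table("proton")
    Ep <- E * .const$mp_c2_eV / mass
    Sp <- exp(approx(pt$logE, log(pt$S_mass), xout = log(Ep), rule = 2)$y)
    gamma <- 1 + E / mass
    beta <- sqrt(1 - 1 / gamma^2)
    zeff_f <- 1 - exp(-125 * beta / z^(2 / 3))
    S <- z^2 * zeff_f^2 * Sp
  } else stop("no stopping table for species ", species)
  # CSDA range by cumulative trapezoid of 1/S [g/cm^2 -> cm at rho = 1]
  invS <- 1 / S
  dR <- c(0, diff(E) * (head(invS, -1) + tail(invS, -1)) / 2) * 1e-6 # eV->MeV
  R <- cumsum(dR) + E[1] * invS[1] * 1e-6  # residual range below grid
  list(species = species, logE = log(E), E = E, S_mass = S, R = R,
       dlog = diff(log(E))[1])
}

.tbl_env <- new.env(parent = emptyenv())

.get_table <- function(species) {
  if (is.null(.tbl_env[[species]])) .tbl_env[[species]] <- .build_table(species)
  .tbl_env[[species]]
}

#' Stopping power and CSDA range
#'
#' Interpolated (total) stopping power and continuous-slowing-down range for
#' charged particles, generated from closed-form parameterizations
#' (Berger-Seltzer collision + approximate radiative stopping for electrons
#' and positrons; Bethe with Sternheimer density correction for muons and
#' protons; proton velocity scaling with effective charge for alphas and 16O
#' ions). For water-like media the stopping power scales with density.
#'
#' @param species one of `"electron"`, `"positron"`, `"muon_minus"`,
#'   `"muon_plus"`, `"proton"`, `"alpha"`, `"ion_O16"`.
#' @param E kinetic energy [eV] (vectorized).
#' @param material a `material` or name (density scaling for water-like media).
#' @return list with `S` [MeV/cm] and `R_csda` [cm] in the given material.
#' @examples
#' stopping_and_range("electron", 511e3)$S        # ~2.04 MeV/cm
#' stopping_and_range("electron", 100e3)$R_csda   # ~0.014 cm
#' @export
stopping_and_range <- function(species, E, material = "water") {
  if (is.character(material)) material <- make_material(material)
  tb <- .get_table(species)
  if (any(E < tb$E[1] * (1 - 1e-9)) || any(E > tb$E[length(tb$E)] * (1 + 1e-9)))
    stop(sprintf("energy outside the %s stopping grid [%.3g, %.3g] eV",
                 species, tb$E[1], tb$E[length(tb$E)]))
  lE <- log(E)
  S <- exp(approx(tb$logE, log(tb$S_mass), xout = lE, rule = 2)$y)
  R <- exp(approx(tb$logE, log(tb$R), xout = lE, rule = 2)$y)
  rho_scale <- material$density *
    (sum(material$fractions * .elements$Z[match(names(material$fractions), .elements$symbol)] /
           .elements$A[match(names(material$fractions), .elements$symbol)]) / .const$ZA_water)
  list(S = S * rho_scale, R_csda = R / rho_scale)
}

# Maximum energy transfer to an atomic electron [eV]
.Tmax_eV <- function(species, E) {
  if (species == "electron") return(E / 2)
  if (species == "positron") return(E)
  mass <- switch(species,
                 muon_minus = , muon_plus = .const$mmu_c2_eV,
                 proton = .const$mp_c2_eV, alpha = .const$malpha_c2_eV,
                 ion_O16 = .const$mO16_c2_eV)
  me <- .const$me_c2_eV
  gamma <- 1 + E / mass
  bg2 <- (gamma^2 - 1)
  2 * me * bg2 / (1 + 2 * gamma * me / mass + (me / mass)^2)
}

.beta2 <- function(species, E) {
  mass <- switch(species, electron = , positron = .const$me_c2_eV,
                 muon_minus = , muon_plus = .const$mmu_c2_eV,
                 proton = .const$mp_c2_eV, alpha = .const$malpha_c2_eV,
                 ion_O16 = .const$mO16_c2_eV)
  gamma <- 1 + E / mass
  1 - 1 / gamma^2
}

# Straggling parameter xi per unit water-equivalent path [eV/um]
.xi_per_um <- function(species, E) {
  z2 <- species_z2(species_code(species))
  # 0.1535356 MeV cm^2/g * (Z/A) * rho(1) / beta^2, converted to eV/um
  0.1535356 * .const$ZA_water * z2 / .beta2(species, E) * 100
}

#' Restricted stopping power
#'
#' Collision stopping power excluding discrete energy transfers above
#' `delta` (the knock-on electron production threshold): the continuous
#' energy-loss rate used between explicitly generated delta rays.
#'
#' @param species particle species.
#' @param E kinetic energy [eV].
#' @param delta production threshold [eV].
#' @return restricted stopping power [MeV/cm] in water.
#' @export
restricted_stopping <- function(species, E, delta = 1000) {
  S <- stopping_and_range(species, E)$S
  Tmax <- .Tmax_eV(species, E)
  xi <- .xi_per_um(species, E)  # eV/um
  loss <- ifelse(Tmax > delta, xi * log(Tmax / delta) * 1e-2, 0)  # MeV/cm
  pmax(S - loss, 0.10 * S)
}

#' Knock-on (delta-ray) production rate
#'
#' Expected number of discrete energy transfers above `delta` per micrometre
#' of water path, from the asymptotic 1/T^2 knock-on spectrum.
#'
#' @inheritParams restricted_stopping
#' @return rate [um^-1].
#' @export
delta_rate <- function(species, E, delta = 1000) {
  Tmax <- .Tmax_eV(species, E)
  xi <- .xi_per_um(species, E)
  ifelse(Tmax > delta, xi * (1 / delta - 1 / Tmax), 0)
}

#' Sample an energy deposit along a chord
#'
#' Draws the energy deposited by a charged particle crossing a cell along a
#' chord, from a Landau-type straggling model: a smooth component with
#' Moyal-shaped fluctuation of width xi around the mean restricted to
#' transfers below `discrete_min`, plus Poisson-sampled discrete knock-on
#' transfers above `discrete_min` from the asymptotic 1/T^2 spectrum
#' (deposited locally, as their residual ranges are below the cell size).
#' The expectation equals the unrestricted stopping power times the chord;
#' the discrete component reproduces the Landau tail and the low-deposit
#' mode near the sub-threshold restricted loss. The deposit is clamped to
#' [0, E]; a zero-length chord deposits nothing.
#'
#' @param species particle species.
#' @param E kinetic energy at entry [eV].
#' @param chord chord length [um].
#' @param material a `material` or name (default the 1.10 g/cm^3 cell interior).
#' @param straggling if FALSE, returns the deterministic mean S(E) * chord.
#' @param discrete_min threshold [eV] above which energy transfers are
#'   sampled discretely (default the 100 eV production threshold).
#' @param n number of samples.
#' @return energy deposits [eV].
#' @export
sample_deposit <- function(species, E, chord, material = "cell_water",
                           straggling = TRUE, discrete_min = 100, n = 1) {
  if (is.character(material)) material <- make_material(material)
  if (chord <= 0) return(rep(0, n))
  weq <- chord * material$density  # water-equivalent path [um]
  S <- stopping_and_range(species, E)$S * 100  # MeV/cm -> eV/um at rho=1
  if (!straggling) return(rep(min(S * weq, E), n))
  Tmax <- .Tmax_eV(species, E)
  xi <- .xi_per_um(species, E) * weq  # eV
  Sres <- restricted_stopping(species, E, discrete_min) * 100  # -> eV/um
  moyal <- -2 * log(abs(rnorm(n)))
  smooth <- pmax(Sres * weq + xi * (moyal - 1.2704), 0)
  disc <- 0
  if (Tmax > discrete_min) {
    nu <- xi * (1 / discrete_min - 1 / Tmax)
    k <- rpois(n, nu)
    disc <- vapply(k, function(ki) {
      if (ki == 0) return(0)
      u <- runif(ki)
      sum(discrete_min / (1 - u * (1 - discrete_min / Tmax)))
    }, numeric(1))
  }
  pmin(smooth + disc, E)
}

#' Neutron elastic recoil kinematics
#'
#' Isotropic centre-of-mass elastic scattering of a neutron on hydrogen or
#' oxygen; the lab recoil energy is uniform on [0, E_max] with
#' E_max = 4A/(1+A)^2 E_n.
#'
#' @param E_n neutron kinetic energy [eV].
#' @param nucleus `"H"` or `"O"`.
#' @param n number of samples.
#' @return data.frame with `species`, `energy` [eV] and `cos_theta` of the
#'   recoil relative to the incident neutron.
#' @export
neutron_elastic_recoil <- function(E_n, nucleus = c("H", "O"), n = 1) {
  nucleus <- match.arg(nucleus)
  A <- if (nucleus == "H") 1 else 16
  Emax <- 4 * A / (1 + A)^2 * E_n
  Er <- Emax * runif(n)
  cos_r <- pmin(1, (1 + A) / (2 * sqrt(A)) * sqrt(Er / E_n))
  data.frame(species = if (nucleus == "H") "proton" else "ion_O16",
             energy = Er, cos_theta = cos_r, stringsAsFactors = FALSE)
}
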