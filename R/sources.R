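# Background radiation sources: spectra, emitter geometries and real-time
# normalization for the terrestrial gamma background, 40K beta decay in the
# growth medium, cosmic neutrons and cosmic muons.

.new_source <- function(kind, spectrum, emitter, strength_per_day,
                        calibration, env_scale = 1, label = kind,
                        extra = list()) {
  structure(c(list(kind = kind, spectrum = spectrum, emitter = emitter,
                   strength_per_day = strength_per_day,
                   calibration = calibration, env_scale = env_scale,
                   label = label), extra),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %s  strength %.4g primaries/day  (%s calibration)\n",
              x$label, x$strength_per_day, x$calibration))
  invisible(x)
}

# sample energies [eV] from a binned spectrum data.frame(lo, hi, w) in keV
.sample_binned <- function(bins, n) {
  i <- sample.int(nrow(bins), n, replace = TRUE, prob = bins$w)
  (bins$lo[i] + runif(n) * (bins$hi[i] - bins$lo[i])) * 1e3
}

.load_gamma_spectrum <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "terrestrial_gamma_spectrum.txt",
                        package = "microdosim")
  df <- read.table(path, col.names = c("lo", "hi", "w"))
  df$w <- df$w / sum(df$w)
  df
}

#' Terrestrial gamma background source
#'
#' Isotropic gamma emission from an r = 3 cm sphere around the sensitive
#' well, with a packaged binned terrestrial spectrum (K/U/Th lines plus
#' scattered continuum, 0.05-2.7 MeV). The strength uses the printed
#' normalization (1e8 primaries represent 10.8 days underground); the
#' surface environment is 6.4 times stronger.
#'
#' @param environment `"LSM_underground"` or `"LPC_surface"`.
#' @param spectrum_file optional path to a substitute spectrum (two-column
#'   bin-edge/intensity text file).
#' @return a `source_model`.
#' @export
gamma_background_source <- function(environment = c("LPC_surface", "LSM_underground"),
                                    spectrum_file = NULL) {
  environment <- match.arg(environment)
  scale <- if (environment == "LPC_surface") 6.4 else 1
  strength_lsm <- 1e8 / 10.8  # printed normalization [primaries/day]
  .new_source("gamma_background", .load_gamma_spectrum(spectrum_file),
              emitter = list(type = "sphere", r_cm = 3,
                             center_mm = c(0, 0, -12.5)),
              strength_per_day = strength_lsm * scale,
              calibration = "printed-normalization", env_scale = scale,
              label = paste0("gamma_background/", environment),
              extra = list(environment = environment, species = "photon"))
}

## ---- 40K beta spectrum ----------------------------------------------------

# Numeric 40K beta- spectrum: endpoint 1.311 MeV, third-forbidden-unique
# shape factor, nonrelativistic Fermi Coulomb correction (daughter Z = 20).
.k40_spectrum_tbl <- function() {
  if (!is.null(.tbl_env$k40sp)) return(.tbl_env$k40sp)
  W0 <- 1 + 1.311e6 / .const$me_c2_eV   # total energy, units of me c^2
  W <- seq(1 + 1e-5, W0 - 1e-6, length.out = 2000)
  p <- sqrt(W^2 - 1)
  q <- W0 - W                            # neutrino momentum (massless)
  beta <- p / W
  eta <- (1 / 137.036) * 20 / beta
  fermi <- 2 * pi * eta / (1 - exp(-2 * pi * eta))
  shape <- p^6 + 7 * p^4 * q^2 + 7 * p^2 * q^4 + q^6
  f <- p * W * q^2 * fermi * shape
  f <- f / sum(f)
  E_eV <- (W - 1) * .const$me_c2_eV
  .tbl_env$k40sp <- list(E = E_eV, pdf = f, cdf = cumsum(f),
                         mean_eV = sum(E_eV * f), endpoint_eV = 1.311e6)
  .tbl_env$k40sp
}

#' Sample 40K beta-decay electron energies
#' @param n number of samples.
#' @return energies [eV], bounded by the 1.311 MeV endpoint.
#' @export
sample_k40_beta <- function(n) {
  sp <- .k40_spectrum_tbl()
  idx <- findInterval(runif(n), sp$cdf) + 1
  idx[idx > length(sp$E)] <- length(sp$E)
  sp$E[idx]
}

#' Beta activity of natural potassium
#'
#' 40K abundance 0.0117 atom-%, half-life 1.248e9 yr, beta-minus branching
#' 89.3 %.
#'
#' @param potassium_g grams of natural potassium.
#' @return beta-decay rate [Bq].
#' @export
k40_activity <- function(potassium_g) {
  atoms_K <- potassium_g / 39.0983 * .const$N_A
  atoms_40K <- atoms_K * 1.17e-4
  lambda <- log(2) / (1.248e9 * .const$year_s)
  atoms_40K * lambda * 0.893
}

#' 40K nutritive background source
#'
#' Beta electrons emitted uniformly in the sensitive well and its six
#' closest filled neighbors, with the 40K beta spectrum. The strength is
#' either the printed normalization (1e7 decays represent 105 days) or
#' derived from the broth potassium content (7 g/L K2HPO4 + 2 g/L KH2PO4
#' give 3.72 g/L potassium; `k40_activity()` then fixes the decay rate).
#'
#' @param calibration `"activity-derived"` (default) or
#'   `"printed-normalization"`.
#' @param n_wells number of source wells (default 7).
#' @param well_volume_ml liquid volume per well [mL] (default 1.5).
#' @param potassium_g_per_L potassium mass concentration of the broth.
#' @return a `source_model`.
#' @export
k40_source <- function(calibration = c("activity-derived", "printed-normalization"),
                       n_wells = 7, well_volume_ml = 1.5,
                       potassium_g_per_L = 3.7172) {
  calibration <- match.arg(calibration)
  if (n_wells < 1 || well_volume_ml <= 0) stop("need >= 1 source well with positive volume")
  if (calibration == "activity-derived") {
    if (potassium_g_per_L <= 0)
      stop("zero potassium content: cannot derive the 40K activity")
    bq <- k40_activity(potassium_g_per_L * well_volume_ml / 1000 * n_wells)
    strength <- bq * .const$sec_per_day
  } else {
    strength <- 1e7 / 105
  }
  .new_source("k40_beta", spectrum = "k40_beta",
              emitter = list(type = "wells", n_wells = n_wells,
                             well_volume_ml = well_volume_ml),
              strength_per_day = strength, calibration = calibration,
              extra = list(species = "electron",
                           potassium_g_per_L = potassium_g_per_L))
}

## ---- cosmic neutrons ------------------------------------------------------

# Sea-level neutron lethargy spectrum on 0.1-500 MeV: evaporation peak near
# 2 MeV plus the high-energy (~100 MeV) bump, renormalized so the integral
# equals the printed 5.96e-3 cm^-2 s^-1.
.neutron_spectrum_tbl <- function() {
  if (!is.null(.tbl_env$nsp)) return(.tbl_env$nsp)
  lnE <- seq(log(0.1), log(500), length.out = 400)  # MeV
  shape <- 0.65 * exp(-0.5 * ((lnE - log(2)) / 1.0)^2) +
    0.35 * exp(-0.5 * ((lnE - log(100)) / 0.6)^2)
  pdf <- shape / sum(shape)
  .tbl_env$nsp <- list(lnE = lnE, pdf = pdf, cdf = cumsum(pdf),
                       flux_cm2_s = 5.96e-3)
  .tbl_env$nsp
}

#' Sample cosmic-neutron energies
#' @param n number of samples.
#' @return energies [eV] on the 0.1-500 MeV support.
#' @export
sample_neutron_energy <- function(n) {
  sp <- .neutron_spectrum_tbl()
  idx <- findInterval(runif(n), sp$cdf) + 1
  idx[idx > length(sp$lnE)] <- length(sp$lnE)
  exp(sp$lnE[idx]) * 1e6
}

#' Cosmic neutron background source
#'
#' Neutrons emitted isotropically (downward hemisphere) from a disc of
#' radius 10 cm located 30 mm above the microplate; energies from the
#' packaged sea-level spectrum on 0.1-500 MeV whose integral flux is
#' 5.96e-3 cm^-2 s^-1. Printed normalization: 1e8 primaries represent
#' 98.4 days.
#'
#' @return a `source_model`.
#' @export
neutron_source <- function() {
  .new_source("cosmic_neutron", .neutron_spectrum_tbl(),
              emitter = list(type = "disc", r_cm = 10, z_mm = 30),
              strength_per_day = 1e8 / 98.4,
              calibration = "printed-normalization",
              extra = list(species = "neutron",
                           flux_cm2_s = 5.96e-3))
}

## ---- cosmic muons ---------------------------------------------------------

# Gaisser-type sea-level muon intensity, renormalized over the packaged
# momentum range; adequate here because results are normalization- and
# geometry-dominated at these energies.
.gaisser_intensity <- function(p_GeV, cos_th) {
  E <- sqrt(p_GeV^2 + 0.1056^2)
  0.14 * E^(-2.7) * (1 / (1 + 1.1 * E * cos_th / 115) +
                       0.054 / (1 + 1.1 * E * cos_th / 850))
}

.muon_sampler_tbl <- function() {
  if (!is.null(.tbl_env$musp)) return(.tbl_env$musp)
  p_edges <- exp(seq(log(0.1), log(50), length.out = 61))
  c_edges <- seq(0.1, 1, length.out = 21)
  pm <- sqrt(p_edges[-1] * p_edges[-61])
  cm <- (c_edges[-1] + c_edges[-21]) / 2
  g <- expand.grid(p = pm, c = cm)
  dp <- rep(diff(p_edges), times = 20)
  dc <- rep(diff(c_edges), each = 60)
  # arrival rate through a horizontal surface ~ I(p, theta) cos(theta)
  w <- .gaisser_intensity(g$p, g$c) * g$c * dp * dc
  .tbl_env$musp <- list(grid = g, w = w / sum(w), p_edges = p_edges,
                        c_edges = c_edges, dp = dp, dc = dc)
  .tbl_env$musp
}

#' Sample cosmic-muon momentum, zenith angle and charge
#'
#' @param n number of samples.
#' @return data.frame with `p_GeV` (0.1-50 GeV/c), `cos_theta` (zenith),
#'   `charge` (+1 with probability 0.54, else -1), `energy` kinetic [eV].
#' @export
sample_muons <- function(n) {
  sp <- .muon_sampler_tbl()
  i <- sample.int(nrow(sp$grid), n, replace = TRUE, prob = sp$w)
  # uniform within the (log-p, cos) bin
  p <- sp$grid$p[i] * exp((runif(n) - 0.5) * log(sp$p_edges[2] / sp$p_edges[1]))
  p <- pmin(pmax(p, 0.1), 50)
  cth <- pmin(pmax(sp$grid$c[i] + (runif(n) - 0.5) * (sp$c_edges[2] - sp$c_edges[1]), 0.05), 1)
  charge <- ifelse(runif(n) < 0.54, 1L, -1L)
  m <- .const$mmu_c2_eV / 1e9  # GeV
  Ekin <- (sqrt(p^2 + m^2) - m) * 1e9
  data.frame(p_GeV = p, cos_theta = cth, charge = charge, energy = Ekin)
}

#' Cosmic muon background source
#'
#' Muons sampled from a Gaisser-type momentum-zenith parameterization on
#' 0.1-50 GeV/c (54 % mu+), emitted from random positions on an r = 15 cm
#' disc 3 cm above the microplate. The integrated flux in this range is
#' 3.4e-2 cm^-2 s^-1; printed normalization: 1e8 primaries represent
#' 48.7 days.
#'
#' @return a `source_model`.
#' @export
muon_source <- function() {
  .new_source("cosmic_muon", "gaisser",
              emitter = list(type = "disc", r_cm = 15, z_mm = 30),
              strength_per_day = 1e8 / 48.7,
              calibration = "printed-normalization",
              extra = list(species = "muon", flux_cm2_s = 3.4e-2,
                           mu_plus_fraction = 0.54))
}

#' Monoenergetic gamma-line source calibrated to a dose rate
#'
#' Isotropic monoenergetic emission from the r = 3 cm sphere, with the
#' strength calibrated ("dose-anchored") so the macroscopic dose tally in
#' the sensitive well equals `dose_rate_target`.
#'
#' @param energy photon energy [eV].
#' @param dose_rate_target target dose rate [nGy/hr], > 0.
#' @param plate a [plate_model()] used for the calibration transport run.
#' @param n_calibration primaries for the calibration run.
#' @param seed calibration seed.
#' @return a `source_model` with `dose_per_primary_nGy` attached.
#' @export
gamma_line_source <- function(energy, dose_rate_target,
                              plate = plate_model(),
                              n_calibration = 2e5, seed = 1L) {
  if (energy <= 0) stop("energy must be > 0")
  if (dose_rate_target <= 0) stop("dose target must be > 0")
  src <- .new_source("gamma_line",
                     data.frame(lo = energy / 1e3, hi = energy / 1e3, w = 1),
                     emitter = list(type = "sphere", r_cm = 3,
                                    center_mm = c(0, 0, -12.5)),
                     strength_per_day = 1,  # provisional
                     calibration = "dose-anchored",
                     extra = list(species = "photon", energy = energy))
  cal <- run_macro(src, plate, n_primaries = n_calibration, seed = seed)
  dose_nGy <- cal$tally$E_dep_eV * .const$eV_to_J / (cal$tally$mass_g * 1e-3) * 1e9
  dose_per_primary <- dose_nGy / n_calibration
  if (dose_per_primary <= 0) stop("calibration run deposited no dose")
  src$strength_per_day <- dose_rate_target * 24 / dose_per_primary
  src$dose_per_primary_nGy <- dose_per_primary
  src$dose_rate_target <- dose_rate_target
  src
}

#' Real time represented by a number of primaries
#'
#' @param source a `source_model`.
#' @param n_primaries number of primaries (> 0).
#' @return days of real time; propagated into every downstream rate.
#' @examples
#' represented_time(gamma_background_source("LSM_underground"), 1e8)  # 10.8
#' @export
represented_time <- function(source, n_primaries) {
  stopifnot(inherits(source, "source_model"), n_primaries > 0)
  n_primaries / source$strength_per_day
}

#' Sample primary particles from a source's emitter geometry
#'
#' Positions [mm, well frame], unit directions and energies [eV] for
#' `n` primaries. Gamma sources emit from the sphere surface into the
#' inward hemisphere (uniform in solid angle); disc sources emit downward
#' (isotropic hemisphere for neutrons, the momentum-zenith sampler for
#' muons); 40K well emission requires the plate geometry.
#'
#' @param source a `source_model`.
#' @param n number of primaries.
#' @param plate a [plate_model()] (needed for `k40_beta`).
#' @return data.frame with `species`, `energy`, `x`, `y`, `z`,
#'   `dx`, `dy`, `dz`, `created_in_well`.
#' @export
sample_primaries <- function(source, n, plate = NULL) {
  n <- as.integer(n)
  kind <- source$kind
  if (kind %in% c("gamma_background", "gamma_line")) {
    E <- .sample_binned(source$spectrum, n)
    ctr <- source$emitter$center_mm
    r_mm <- source$emitter$r_cm * 10
    u <- 2 * runif(n) - 1; ph <- 2 * pi * runif(n)
    st <- sqrt(pmax(0, 1 - u^2))
    nx <- st * cos(ph); ny <- st * sin(ph); nz <- u   # outward normal
    x <- ctr[1] + r_mm * nx; y <- ctr[2] + r_mm * ny; z <- ctr[3] + r_mm * nz
    v <- 2 * runif(n) - 1; ph2 <- 2 * pi * runif(n)
    st2 <- sqrt(pmax(0, 1 - v^2))
    dx <- st2 * cos(ph2); dy <- st2 * sin(ph2); dz <- v
    flip <- (dx * nx + dy * ny + dz * nz) > 0   # keep inward hemisphere
    dx[flip] <- -dx[flip]; dy[flip] <- -dy[flip]; dz[flip] <- -dz[flip]
    return(data.frame(species = "photon", energy = E, x = x, y = y, z = z,
                      dx = dx, dy = dy, dz = dz, created_in_well = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (kind == "k40_beta") {
    if (is.null(plate)) stop("k40_beta emission requires the plate geometry")
    offs <- plate$k40_source_wells       # well-center offsets [mm]
    wi <- sample.int(nrow(offs), n, replace = TRUE)
    hx <- plate$inner_half
    x <- offs[wi, 1] + runif(n, -hx, hx)
    y <- offs[wi, 2] + runif(n, -hx, hx)
    z <- runif(n, plate$liq_zlo, plate$liq_zhi)
    u <- 2 * runif(n) - 1; ph <- 2 * pi * runif(n)
    st <- sqrt(pmax(0, 1 - u^2))
    return(data.frame(species = "electron", energy = sample_k40_beta(n),
                      x = x, y = y, z = z,
                      dx = st * cos(ph), dy = st * sin(ph), dz = u,
                      created_in_well = wi == 1, stringsAsFactors = FALSE))
  }
  if (kind %in% c("cosmic_neutron", "cosmic_muon")) {
    r_mm <- source$emitter$r_cm * 10
    rr <- r_mm * sqrt(runif(n)); ph <- 2 * pi * runif(n)
    x <- rr * cos(ph); y <- rr * sin(ph); z <- rep(source$emitter$z_mm, n)
    if (kind == "cosmic_neutron") {
      u <- runif(n); ph2 <- 2 * pi * runif(n)   # isotropic downward
      cz <- -u
      st <- sqrt(pmax(0, 1 - cz^2))
      df <- data.frame(species = "neutron", energy = sample_neutron_energy(n),
                       x = x, y = y, z = z,
                       dx = st * cos(ph2), dy = st * sin(ph2), dz = cz,
                       created_in_well = FALSE, stringsAsFactors = FALSE)
      return(df)
    }
    mu <- sample_muons(n)
    ph2 <- 2 * pi * runif(n)
    st <- sqrt(pmax(0, 1 - mu$cos_theta^2))
    data.frame(species = ifelse(mu$charge > 0, "muon_plus", "muon_minus"),
               energy = mu$energy, x = x, y = y, z = z,
               dx = st * cos(ph2), dy = st * sin(ph2), dz = -mu$cos_theta,
               created_in_well = FALSE, stringsAsFactors = FALSE)
  } else stop("unknown source kind: ", kind)
}
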