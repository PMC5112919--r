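# Macroscopic level: transport primaries through the 96-well microplate
# model, tally dose in the sensitive central well, and record the charged
# particle phase space per the recording rule.

#' 96-well microplate model
#'
#' Simplified plate: a polypropylene block with a 12 x 8 grid of square
#' 1 x 1 cm cavities (1 mm walls, 2 cm deep), 24 of which are filled with
#' Davis-broth water to a depth of 1.5 cm. The sensitive well is centered
#' at the origin; its liquid occupies x, y in [-5, 5] mm, z in [-20, -5] mm.
#'
#' @param filled_block integer vector `c(ix_lo, ix_hi, iy_lo, iy_hi)` of the
#'   filled 6 x 4 well block (0-based column/row indices; default
#'   `c(3, 8, 2, 5)` = 24 wells around the sensitive well at (5, 3)).
#' @return object of class `plate_model`.
#' @export
plate_model <- function(filled_block = c(3, 8, 2, 5)) {
  ncol <- 12L; nrow <- 8L
  filled <- integer(ncol * nrow)
  for (ix in filled_block[1]:filled_block[2])
    for (iy in filled_block[3]:filled_block[4])
      filled[ix * nrow + iy + 1] <- 1L
  sens <- c(5L, 3L)
  if (filled[sens[1] * nrow + sens[2] + 1] != 1L)
    stop("the sensitive well must be a filled well")
  broth <- make_material("davis_broth_water")
  # sensitive well + its six closest filled neighbours (well-center offsets, mm)
  k40_wells <- rbind(c(0, 0), c(11, 0), c(-11, 0), c(0, 11), c(0, -11),
                     c(11, 11), c(-11, -11))
  structure(list(
    pitch = 11, inner_half = 5, wall_zlo = -20, wall_zhi = 0,
    liq_zlo = -20, liq_zhi = -5, ncol = ncol, nrow = nrow,
    ix_off = sens[1], iy_off = sens[2], filled = filled,
    world = c(-120, 120, -120, 120, -80, 80),
    k40_source_wells = k40_wells,
    liquid_volume_cm3 = 1.5, broth = broth,
    mass_g = 1.5 * broth$density), class = "plate_model")
}

#' @export
print.plate_model <- function(x, ...) {
  cat(sprintf("<plate_model> %d filled wells of %d; sensitive well %.3g cm^3 (%.3g g)\n",
              sum(x$filled), length(x$filled), x$liquid_volume_cm3, x$mass_g))
  invisible(x)
}

.plate_cpp_list <- function(plate) {
  plate[c("pitch", "inner_half", "wall_zlo", "wall_zhi", "liq_zlo", "liq_zhi",
          "ncol", "nrow", "ix_off", "iy_off", "filled", "world")]
}

# water-equivalent stopping scale per macro material (air, poly, broth)
.mat_scales <- function(plate) {
  poly <- make_material("polypropylene")
  za <- function(m) sum(m$fractions * .elements$Z[match(names(m$fractions), .elements$symbol)] /
                          .elements$A[match(names(m$fractions), .elements$symbol)])
  c(air = 1.205e-3 * 0.499 / .const$ZA_water,
    poly = poly$density * za(poly) / .const$ZA_water,
    broth = plate$broth$density * za(plate$broth) / .const$ZA_water)
}

# photon attenuation tables per macro material on a shared log grid
.macro_mu_tables <- function(plate) {
  if (!is.null(.tbl_env$macro_mu)) return(.tbl_env$macro_mu)
  E <- exp(seq(log(1e3), log(1e7), length.out = 160))
  water <- photon_mu(E, "water")
  scales <- .mat_scales(plate)
  poly <- photon_mu(E, "polypropylene")
  broth <- photon_mu(E, plate$broth)
  air <- list(pe = water$photoelectric * scales[["air"]],
              co = water$compton * scales[["air"]],
              pa = water$pair * scales[["air"]])
  tabs <- list(air,
               list(pe = poly$photoelectric, co = poly$compton, pa = poly$pair),
               list(pe = broth$photoelectric, co = broth$compton, pa = broth$pair))
  major <- pmax(air$pe + air$co + air$pa,
                poly$total, broth$total) * 1.05
  .tbl_env$macro_mu <- list(tables = tabs, major = major,
                            logE0 = log(1e3), dlog = diff(log(E))[1])
  .tbl_env$macro_mu
}

# slab intersection of a ray with the sensitive liquid box; returns chord [mm]
.sens_box_chord <- function(x, y, z, dx, dy, dz) {
  lo <- c(-5, -5, -20); hi <- c(5, 5, -5)
  t0 <- rep(-Inf, length(x)); t1 <- rep(Inf, length(x))
  P <- cbind(x, y, z); D <- cbind(dx, dy, dz)
  for (k in 1:3) {
    pk <- P[, k]; dk <- D[, k]
    para <- abs(dk) < 1e-12
    ta <- (lo[k] - pk) / dk; tb <- (hi[k] - pk) / dk
    tlo <- pmin(ta, tb); thi <- pmax(ta, tb)
    t0 <- ifelse(para, ifelse(pk >= lo[k] & pk <= hi[k], t0, Inf), pmax(t0, tlo))
    t1 <- ifelse(para, ifelse(pk >= lo[k] & pk <= hi[k], t1, -Inf), pmin(t1, thi))
  }
  t0 <- pmax(t0, 0)
  data.frame(t0 = t0, t1 = t1, chord = pmax(t1 - t0, 0))
}

# kinetic energy after a water-equivalent path [cm] (0 when the particle stops)
.E_after_path <- function(species, E, path_cm) {
  tb <- .get_table(species)
  R <- exp(approx(tb$logE, log(tb$R), xout = log(pmin(pmax(E, tb$E[1]), tb$E[length(tb$E)])), rule = 2)$y)
  r_new <- R - path_cm
  out <- numeric(length(E))
  ok <- r_new > tb$R[1]
  if (any(ok)) {
    logE_new <- approx(log(tb$R), tb$logE, xout = log(r_new[ok]), rule = 2)$y
    out[ok] <- exp(logE_new)
  }
  out
}

# microscopic neutron cross sections [barn] on a coarse energy grid [MeV]
.sigma_n <- function(E_MeV, nucleus) {
  if (nucleus == "H") {
    Eg <- c(0.1, 0.5, 1, 2, 5, 10, 14, 20, 50, 100, 300, 500)
    sg <- c(12.8, 6.1, 4.26, 2.9, 1.5, 0.94, 0.69, 0.48, 0.17, 0.075, 0.035, 0.033)
  } else {
    Eg <- c(0.1, 0.5, 1, 2, 5, 10, 14, 20, 50, 100, 300, 500)
    sg <- c(3.6, 3.2, 3.2, 2.0, 1.1, 1.0, 1.6, 1.4, 0.7, 0.45, 0.3, 0.3)
  }
  exp(approx(log(Eg), log(sg), xout = log(pmin(pmax(E_MeV, 0.1), 500)), rule = 2)$y)
}

# single-collision neutron transport (neutrons contribute ~2% of the total
# hit rate; see the methods vignette for the fidelity argument)
.run_macro_neutrons <- function(source, plate, n_primaries, seed,
                                absorption_multiplier = 1.10) {
  prim <- sample_primaries(source, n_primaries)
  bc <- .sens_box_chord(prim$x, prim$y, prim$z, prim$dx, prim$dy, prim$dz)
  L_cm <- bc$chord / 10
  E_MeV <- prim$energy / 1e6
  rho <- plate$broth$density
  n_H <- rho * plate$broth$fractions[["H"]] / 1.008 * .const$N_A * 1e-24  # per barn cm
  n_O <- rho * plate$broth$fractions[["O"]] / 15.999 * .const$N_A * 1e-24
  Sig_H <- n_H * .sigma_n(E_MeV, "H")
  Sig_O <- n_O * .sigma_n(E_MeV, "O")
  Sig_el <- Sig_H + Sig_O
  Sig_tot <- Sig_el * absorption_multiplier
  p_int <- 1 - exp(-Sig_tot * L_cm)
  hit <- runif(n_primaries) < p_int & L_cm > 0
  idx <- which(hit)
  rec <- list(); dep <- 0
  for (i in idx) {
    # collision point along the chord (truncated exponential)
    u <- runif(1)
    s <- -log(1 - u * (1 - exp(-Sig_tot[i] * L_cm[i]))) / Sig_tot[i]  # cm
    px <- prim$x[i] + prim$dx[i] * (bc$t0[i] + 10 * s)
    py <- prim$y[i] + prim$dy[i] * (bc$t0[i] + 10 * s)
    pz <- prim$z[i] + prim$dz[i] * (bc$t0[i] + 10 * s)
    ch <- runif(1) * Sig_tot[i]
    if (ch < Sig_H[i]) {
      rc <- neutron_elastic_recoil(prim$energy[i], "H", n = 1)
    } else if (ch < Sig_el[i]) {
      # oxygen: elastic recoil, or a crude (n, alpha) channel at high energy
      if (E_MeV[i] > 10 && runif(1) < 0.10) {
        rc <- data.frame(species = "alpha",
                         energy = runif(1) * (prim$energy[i] - 2.35e6) / 2,
                         cos_theta = 2 * runif(1) - 1)
      } else {
        rc <- neutron_elastic_recoil(prim$energy[i], "O", n = 1)
      }
    } else next  # absorbed (capture photons not followed)
    if (rc$energy <= 100) next
    d <- c(prim$dx[i], prim$dy[i], prim$dz[i])
    dd <- .rotate_dir(d, acos(pmin(1, pmax(-1, rc$cos_theta))), 2 * pi * runif(1))
    rec[[length(rec) + 1]] <- data.frame(
      species = rc$species, energy = rc$energy, x = px, y = py, z = pz,
      dx = dd[1], dy = dd[2], dz = dd[3], weight = 1, tag = "created",
      stringsAsFactors = FALSE)
    # dose: recoil energy minus what escapes through the box wall
    ex <- .sens_box_chord(px, py, pz, dd[1], dd[2], dd[3])
    tb_ok <- rc$species %in% c("proton", "alpha", "ion_O16")
    if (tb_ok) {
      E_exit <- .E_after_path(rc$species, rc$energy, ex$t1 / 10 * rho)
      dep <- dep + (rc$energy - E_exit)
    } else dep <- dep + rc$energy
  }
  records <- if (length(rec)) do.call(rbind, rec) else
    data.frame(species = character(0), energy = numeric(0), x = numeric(0),
               y = numeric(0), z = numeric(0), dx = numeric(0),
               dy = numeric(0), dz = numeric(0), weight = numeric(0),
               tag = character(0), stringsAsFactors = FALSE)
  list(records = records, dose_eV = dep,
       log = list(n_interactions = length(idx)))
}

.rotate_dir <- function(d, theta, phi) {
  if (abs(d[3]) < 0.99) u <- c(-d[2], d[1], 0) else u <- c(0, -d[3], d[2])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2], d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  ct <- cos(theta); st <- sin(theta)
  w <- ct * d + st * (cos(phi) * u + sin(phi) * v)
  w / sqrt(sum(w^2))
}

#' Run the macroscopic simulation level
#'
#' Transports `n_primaries` source particles through the microplate model,
#' tallies the dose in the sensitive well, and records the charged-particle
#' phase space: every charged particle created inside the sensitive well by
#' a neutral particle, emitted inside it, or entering it from outside, with
#' its species, position, direction and kinetic energy at creation/entry.
#' Children of recorded charged particles are not separately recorded;
#' recorded particles are still tracked for the dose tally.
#'
#' @param source a `source_model`.
#' @param plate a [plate_model()].
#' @param n_primaries number of primaries (>= 1).
#' @param seed integer seed.
#' @return list with `phsp` (a [phase_space_set()]), `tally` (a dose tally:
#'   `E_dep_eV`, `mass_g`, `represented_days`, `n_primaries`,
#'   `n_deposit_events`) and `log`.
#' @export
run_macro <- function(source, plate = plate_model(), n_primaries, seed = 1L) {
  stopifnot(inherits(source, "source_model"), n_primaries >= 1)
  n_primaries <- as.integer(round(n_primaries))
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed)
  days <- represented_time(source, n_primaries)
  kind <- source$kind
  lg <- list()
  if (kind %in% c("gamma_background", "gamma_line")) {
    prim <- sample_primaries(source, n_primaries)
    mu <- .macro_mu_tables(plate)
    res <- macro_photons_cpp(prim$energy,
                             as.matrix(prim[, c("x", "y", "z")]),
                             as.matrix(prim[, c("dx", "dy", "dz")]),
                             .plate_cpp_list(plate), mu$tables, mu$major,
                             mu$logE0, mu$dlog, .cpp_tables(1000),
                             .mat_scales(plate), 537, 0.1, 1000,
                             as.numeric(seed))
    records <- .macro_records_df(res$records)
    dose <- res$dose_eV
    lg <- res[c("n_compton", "n_pe", "n_pair", "n_primaries_interacted")]
  } else if (kind == "k40_beta") {
    prim <- sample_primaries(source, n_primaries, plate)
    res <- macro_charged_cpp(rep(species_code("electron"), n_primaries),
                             prim$energy, as.matrix(prim[, c("x", "y", "z")]),
                             as.matrix(prim[, c("dx", "dy", "dz")]),
                             prim$created_in_well, .plate_cpp_list(plate),
                             .cpp_tables(1000), .mat_scales(plate), 0.1, 1000)
    records <- .macro_records_df(res$records)
    dose <- res$dose_eV
  } else if (kind == "cosmic_muon") {
    prim <- sample_primaries(source, n_primaries)
    res <- macro_charged_cpp(species_code(prim$species), prim$energy,
                             as.matrix(prim[, c("x", "y", "z")]),
                             as.matrix(prim[, c("dx", "dy", "dz")]),
                             rep(FALSE, n_primaries), .plate_cpp_list(plate),
                             .cpp_tables(1000), .mat_scales(plate), 0.5, 1.1e6)
    records <- .macro_records_df(res$records)
    dose <- res$dose_eV
  } else if (kind == "cosmic_neutron") {
    res <- .run_macro_neutrons(source, plate, n_primaries, seed)
    records <- res$records
    dose <- res$dose_eV
    lg <- res$log
  } else stop("unknown source kind: ", kind)

  if (nrow(records) == 0)
    warning("empty phase space: no charged particles recorded in the sensitive well")
  phsp <- phase_space_set(records, source$label, n_primaries, days)
  tally <- structure(list(E_dep_eV = dose, mass_g = plate$mass_g,
                          represented_days = days, n_primaries = n_primaries,
                          n_deposit_events = max(nrow(records), 1L)),
                     class = "dose_tally")
  list(phsp = phsp, tally = tally,
       log = c(list(source = source$label, n_primaries = n_primaries,
                    represented_days = days, seed = seed,
                    calibration = source$calibration), lg))
}

.macro_records_df <- function(m) {
  if (nrow(m) == 0)
    return(data.frame(species = character(0), energy = numeric(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      dx = numeric(0), dy = numeric(0), dz = numeric(0),
                      weight = numeric(0), tag = character(0),
                      stringsAsFactors = FALSE))
  data.frame(species = species_name(as.integer(m[, 1])), energy = m[, 2],
             x = m[, 3], y = m[, 4], z = m[, 5],
             dx = m[, 6], dy = m[, 7], dz = m[, 8], weight = 1,
             tag = ifelse(m[, 9] == 1, "created", "entered"),
             stringsAsFactors = FALSE)
}

#' Dose rate of a macroscopic tally
#'
#' Unit-converted dose rate in the sensitive well with an approximate
#' Monte Carlo standard error (Poisson scaling on the number of depositing
#' particles).
#'
#' @param tally the `tally` element of a [run_macro()] result.
#' @return list with `nGy_hr`, `se_nGy_hr`, `dose_nGy`, `days`.
#' @export
dose_rate <- function(tally) {
  if (tally$represented_days <= 0) stop("represented time must be > 0")
  dose_nGy <- tally$E_dep_eV * .const$eV_to_J / (tally$mass_g * 1e-3) * 1e9
  rate <- dose_nGy / (tally$represented_days * 24)
  list(nGy_hr = rate,
       se_nGy_hr = rate / sqrt(max(tally$n_deposit_events, 1)),
       dose_nGy = dose_nGy, days = tally$represented_days)
}
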