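# Scenario configuration, presets, the full two-level pipeline, and the
# deterministic fixture generator.

.table2_reference <- data.frame(
  source = c("gamma", "k40", "muon", "neutron"),
  dose_nGy_hr = c(150, 26, 45, 4.4),
  hit_frequency = c(3.6e-5, 8.2e-6, 1.6e-5, 1.4e-7),
  stringsAsFactors = FALSE)

#' Scenario presets
#'
#' Fully specified configurations reproducing the study computations at a
#' configurable scale: the surface laboratory (all four background
#' sources), the underground laboratory (gamma scaled down 6.4-fold plus
#' the nutritive 40K background), the low-background D. radiodurans
#' exposure (1.5 um spheres, a 1.46 MeV gamma line at 71.3 nGy/hr plus
#' internal 40K at 7.2 nGy/hr), and the 200 keV electron physics benchmark.
#'
#' @param name one of `"lpc_surface"`, `"lsm_underground"`,
#'   `"castillo_wipp"`, `"table1_physics_check"`.
#' @param scale event-count scale relative to the full study runs (default
#'   0.01; 1 reproduces the full primary counts).
#' @param seed integer seed.
#' @return a scenario configuration list.
#' @export
preset <- function(name = c("lpc_surface", "lsm_underground", "castillo_wipp",
                            "table1_physics_check"),
                   scale = 0.01, seed = 1L) {
  name <- match.arg(name)
  base <- list(
    name = name, scale = scale, seed = as.integer(seed),
    plate = list(filled_block = c(3, 8, 2, 5)),
    domain = list(n_cells = 4000, edge = 200,
                  shape = list(kind = "capsule", radius = 0.5, cylinder_length = 2),
                  overlap_policy = "reject"),
    physics = list(cutoff = 100, delta_threshold = 1000, straggling = TRUE,
                   msc = TRUE, deltas = TRUE, cell_density = 1.10))
  n_macro_full <- c(gamma = 1e8, k40 = 1e7, neutron = 1e8, muon = 1e8)
  n_micro_full <- c(gamma = 2e6, k40 = 1e6, neutron = 1e6, muon = 1e6)
  if (name == "lpc_surface") {
    base$environment <- "LPC_surface"
    base$sources <- list(
      gamma = list(enabled = TRUE, calibration = "printed-normalization"),
      k40 = list(enabled = TRUE, calibration = "activity-derived"),
      neutron = list(enabled = TRUE, calibration = "printed-normalization"),
      muon = list(enabled = TRUE, calibration = "printed-normalization"))
  } else if (name == "lsm_underground") {
    base$environment <- "LSM_underground"
    base$sources <- list(
      gamma = list(enabled = TRUE, calibration = "printed-normalization"),
      k40 = list(enabled = TRUE, calibration = "activity-derived"),
      neutron = list(enabled = FALSE), muon = list(enabled = FALSE))
  } else if (name == "castillo_wipp") {
    base$environment <- "custom"
    base$domain$shape <- list(kind = "sphere", radius = 1.5, cylinder_length = 0)
    base$sources <- list(
      gamma_line = list(enabled = TRUE, calibration = "dose-anchored",
                        energy_eV = 1.46e6, dose_rate_nGy_hr = 71.3),
      k40 = list(enabled = TRUE, calibration = "dose-anchored",
                 dose_rate_nGy_hr = 7.2),
      neutron = list(enabled = FALSE), muon = list(enabled = FALSE))
  } else {  # table1_physics_check
    base$environment <- "custom"
    base$sources <- list(
      electron_beam = list(enabled = TRUE, energy_eV = 2e5, n = 1e6 * scale))
    base$kill_outside_well <- FALSE
  }
  base$n_macro <- as.list(pmax(round(n_macro_full * scale), 1000))
  base$n_micro <- as.list(pmax(round(n_micro_full * scale), 1000))
  base
}

#' Re-anchor a source strength to a target dose rate
#'
#' Runs a macroscopic calibration transport and rescales the source
#' strength so the sensitive-well dose rate equals the target
#' ("dose-anchored" calibration mode).
#'
#' @param source a `source_model`.
#' @param dose_rate_target target [nGy/hr].
#' @param plate a [plate_model()].
#' @param n_calibration calibration primaries.
#' @param seed calibration seed.
#' @return the source with rescaled `strength_per_day`.
#' @export
anchor_to_dose <- function(source, dose_rate_target, plate = plate_model(),
                           n_calibration = 1e5, seed = 1L) {
  if (dose_rate_target <= 0) stop("dose target must be > 0")
  cal <- run_macro(source, plate, n_primaries = n_calibration, seed = seed)
  dr <- dose_rate(cal$tally)
  if (dr$nGy_hr <= 0) stop("calibration run deposited no dose")
  source$strength_per_day <- source$strength_per_day * dose_rate_target / dr$nGy_hr
  source$calibration <- "dose-anchored"
  source$dose_rate_target <- dose_rate_target
  source
}

.build_domain <- function(cfg, seed) {
  sh <- cfg$domain$shape
  place_cells(cfg$domain$n_cells, cfg$domain$edge,
              cell_shape(sh$kind, sh$radius, sh$cylinder_length),
              seed = seed, overlap_policy = cfg$domain$overlap_policy)
}

.build_source <- function(key, scfg, cfg, plate, seed) {
  if (key == "gamma") {
    gamma_background_source(if (identical(cfg$environment, "LSM_underground"))
      "LSM_underground" else "LPC_surface")
  } else if (key == "gamma_line") {
    gamma_line_source(scfg$energy_eV, scfg$dose_rate_nGy_hr, plate,
                      n_calibration = 5e4, seed = seed)
  } else if (key == "k40") {
    src <- k40_source(if (identical(scfg$calibration, "printed-normalization"))
      "printed-normalization" else "activity-derived")
    if (identical(scfg$calibration, "dose-anchored"))
      src <- anchor_to_dose(src, scfg$dose_rate_nGy_hr, plate,
                            n_calibration = 2e4, seed = seed)
    src
  } else if (key == "neutron") {
    neutron_source()
  } else if (key == "muon") {
    muon_source()
  } else stop("unknown source key: ", key)
}

#' Run the full two-level pipeline for a scenario
#'
#' For each enabled source: macroscopic transport, phase-space subset draw,
#' microscopic replay, and rate analysis; returns per-source rate summaries
#' under both the source's own calibration and (where a reference dose rate
#' exists) the dose-anchored normalization, plus a discrepancy report.
#' Fully reproducible from the configuration and seed.
#'
#' @param config a scenario configuration from [preset()].
#' @param out_dir optional directory for artifacts (config copy, phase
#'   space files, hit lists, summary tables).
#' @param verbose print stage logs.
#' @return object of class `pipeline_result`: list with `summary`
#'   (data.frame), `per_source` (detailed per-source results), `report`
#'   (character), `config`, `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  seed <- config$seed
  plate <- plate_model(config$plate$filled_block)
  domain <- .build_domain(config, seed)
  physics <- do.call(micro_physics, config$physics)
  per_source <- list()
  rows <- list()
  report <- c(sprintf("scenario %s (scale %.3g, seed %d)", config$name,
                      config$scale, seed))

  if (config$name == "table1_physics_check") {
    sb <- config$sources$electron_beam
    fx <- make_fixtures("monoenergetic_beam", seed = seed,
                        n = sb$n, energy = sb$energy_eV,
                        edge = config$domain$edge)
    run <- run_micro(fx$phsp, domain, physics, seed = seed + 1,
                     kill_outside_well = FALSE)
    per_source$electron_beam <- list(run = run)
    st <- deposit_statistics(run)
    rows[["electron_beam"]] <- data.frame(
      source = "electron_beam", n_events = run$n_events,
      cells_hit = count_hits(run), median_dep_eV = st$percentiles[["p50"]],
      stringsAsFactors = FALSE)
    summary <- do.call(rbind, rows)
    out <- structure(list(summary = summary, per_source = per_source,
                          report = report, config = config,
                          config_hash = .cfg_hash(config), seed = seed),
                     class = "pipeline_result")
    if (!is.null(out_dir)) .write_artifacts(out, out_dir)
    return(out)
  }

  ref <- .table2_reference
  keys <- names(config$sources)
  for (i in seq_along(keys)) {
    key <- keys[i]
    scfg <- config$sources[[key]]
    if (!isTRUE(scfg$enabled)) next
    if (verbose) message("source: ", key)
    src <- .build_source(key, scfg, config, plate, seed + 10 * i)
    n_mac <- config$n_macro[[if (key %in% names(config$n_macro)) key else "gamma"]]
    mac <- run_macro(src, plate, n_primaries = n_mac, seed = seed + 10 * i + 1)
    N <- nrow(mac$phsp$records)
    run <- NULL
    if (N > 0) {
      k <- min(config$n_micro[[if (key %in% names(config$n_micro)) key else "gamma"]], N)
      sub <- draw_subset(mac$phsp, k, seed = seed + 10 * i + 2)
      run <- run_micro(sub, domain, physics, seed = seed + 10 * i + 3)
    }
    dr <- dose_rate(mac$tally)
    rs <- if (!is.null(run)) rate_summary(src$label, run, dr, src$calibration) else NULL
    ref_row <- ref[ref$source == sub_key(key), , drop = FALSE]
    hf <- if (!is.null(rs)) rs$hit_frequency else 0
    hfe <- if (!is.null(rs)) rs$hit_frequency_events else 0
    anchor <- if (nrow(ref_row) && dr$nGy_hr > 0)
      ref_row$dose_nGy_hr / dr$nGy_hr else NA_real_
    rows[[key]] <- data.frame(
      source = key, n_macro = n_mac, n_phsp = N,
      n_micro = if (!is.null(run)) run$n_events else 0,
      represented_days = if (!is.null(run)) run$represented_days else NA_real_,
      dose_rate_nGy_hr = dr$nGy_hr,
      hit_frequency = hf,
      hit_frequency_se = if (!is.null(rs)) rs$hit_frequency_se else NA_real_,
      hit_frequency_events = hfe,
      hit_frequency_dose_anchored = hf * anchor,
      hit_frequency_events_dose_anchored = hfe * anchor,
      hits_per_nGy = if (!is.null(rs)) rs$hits_per_nGy else NA_real_,
      median_dep_eV = if (!is.null(rs) && !is.null(rs$deposit_percentiles))
        rs$deposit_percentiles[["p50"]] else NA_real_,
      stringsAsFactors = FALSE)
    per_source[[key]] <- list(source = src, macro_log = mac$log,
                              tally = mac$tally, dose = dr, run = run,
                              summary = rs)
    if (nrow(ref_row)) {
      cases <- list(`crossings/own-calibration` = hf,
                    `crossings/dose-anchored` = hf * anchor,
                    `track-events/own-calibration` = hfe,
                    `track-events/dose-anchored` = hfe * anchor)
      for (mode in names(cases)) {
        v <- cases[[mode]]
        if (is.finite(v) && v > 0)
          report <- c(report, sprintf(
            "%s [%s]: %.3g day^-1 vs reference %.3g (ratio %.2f)",
            key, mode, v, ref_row$hit_frequency, v / ref_row$hit_frequency))
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(summary) && nrow(summary) > 1) {
    tot <- colSums(summary[, c("hit_frequency", "hit_frequency_events",
                               "hit_frequency_events_dose_anchored",
                               "dose_rate_nGy_hr")], na.rm = TRUE)
    report <- c(report, sprintf(
      "total: %.3g day^-1 (crossings) / %.3g (track-events) / %.3g (track-events, dose-anchored); dose %.3g nGy/hr",
      tot[1], tot[2], tot[3], tot[4]),
      "note: cell-crossing counts track the chord-count oracle n*sigma_bar*track-length;",
      "track-event counts (events hitting >= 1 cell) reproduce the printed per-source rows,",
      "which sit ~4x below the crossing-based expectation for the 40K and muon sources.")
  }
  out <- structure(list(summary = summary, per_source = per_source,
                        report = report, config = config,
                        config_hash = .cfg_hash(config), seed = seed),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_artifacts(out, out_dir)
  out
}

# map config source keys onto reference-table keys
sub_key <- function(key) {
  if (key == "gamma_line") "gamma" else key
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  if (!is.null(x$summary)) print(x$summary, digits = 3)
  invisible(x)
}

# polynomial hash of the serialized configuration
.cfg_hash <- function(config) {
  raw <- as.integer(serialize(config, NULL, version = 2))
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_scenario_config(res$config, file.path(out_dir, "config.yaml"))
  writeLines(c(res$report, paste0("config_hash ", res$config_hash),
               paste0("seed ", res$seed)),
             file.path(out_dir, "report.txt"))
  if (!is.null(res$summary))
    write.table(res$summary, file.path(out_dir, "summary.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  for (key in names(res$per_source)) {
    run <- res$per_source[[key]]$run
    if (!is.null(run) && nrow(run$hits) > 0)
      write.table(run$hits, file.path(out_dir, paste0("hits_", key, ".csv")),
                  sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' Write / read a scenario configuration (YAML)
#'
#' Serialization is idempotent: serialize - parse - serialize yields the
#' same document.
#'
#' @param config a scenario configuration.
#' @param path file path.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  yaml::read_yaml(path)
}

#' Deterministic test fixtures
#'
#' Generates phase-space and microdomain fixtures with analytically known
#' hit counts and deposits, plus a manifest of expected values.
#'
#' `known_chord_set`: one capsule cell at the domain center, electrons aimed
#' perpendicularly through its cylinder mid-point (chord exactly 2r).
#' `monoenergetic_beam`: electrons of one energy at uniform positions and
#' isotropic directions (expected crossings from the chord-count oracle
#' `n_density * mean_projected_area * R_csda`).
#' `constant_let_stub`: high-energy muons as straight, effectively
#' constant-LET tracks of known path length.
#'
#' @param kind fixture kind.
#' @param seed integer seed.
#' @param n number of particles.
#' @param energy kinetic energy [eV].
#' @param edge domain edge [um].
#' @param dir optional directory; when given, the phase space (and domain,
#'   for `known_chord_set`) are also written as text files.
#' @return list with `phsp`, optionally `domain`, and `manifest`.
#' @export
make_fixtures <- function(kind = c("monoenergetic_beam", "known_chord_set",
                                   "constant_let_stub"),
                          seed = 1L, n = 1000, energy = 2e5, edge = 200,
                          dir = NULL) {
  kind <- match.arg(kind)
  old <- .Random.seed_safe(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (kind == "known_chord_set") {
    shape <- cell_shape("capsule", 0.5, 2)
    # confine the virtual well to one tile so each track crosses the cell once
    dom <- structure(list(edge = edge, n = 1L,
                          centers = matrix(edge / 2, 1, 3),
                          orientations = matrix(c(0, 0, 1), 1, 3),
                          shape = shape,
                          well_extent = list(min = c(0, 0, 0),
                                             max = rep(edge, 3))),
                     class = "microdomain")
    start_gap <- 10  # um upstream of the cell center
    rec <- data.frame(species = "electron", energy = energy,
                      x = rep(1e-3 * (edge / 2 - start_gap), n),
                      y = 1e-3 * edge / 2, z = 1e-3 * edge / 2,
                      dx = 1, dy = 0, dz = 0, weight = 1, tag = "created",
                      stringsAsFactors = FALSE)
    phsp <- phase_space_set(rec, "fixture/known_chord_set", n, 1)
    # kinetic energy at the cell surface after the upstream medium path
    E_entry <- energy
    for (i in seq_len(100))
      E_entry <- E_entry - stopping_and_range("electron", E_entry)$S * 100 *
        (start_gap - shape$radius) / 100
    manifest <- list(expected_hits = n, chord_um = 2 * shape$radius,
                     entry_energy_eV = E_entry,
                     deposit_no_straggle_eV =
                       stopping_and_range("electron", E_entry)$S * 100 *
                       2 * shape$radius * 1.10)
    out <- list(phsp = phsp, domain = dom, manifest = manifest)
  } else if (kind == "monoenergetic_beam") {
    u <- 2 * runif(n) - 1; ph <- 2 * pi * runif(n)
    st <- sqrt(pmax(0, 1 - u^2))
    rec <- data.frame(species = rep("electron", n), energy = rep(energy, n),
                      x = runif(n, 0, edge) * 1e-3,
                      y = runif(n, 0, edge) * 1e-3,
                      z = runif(n, 0, edge) * 1e-3,
                      dx = st * cos(ph), dy = st * sin(ph), dz = u,
                      weight = rep(1, n), tag = rep("created", n),
                      stringsAsFactors = FALSE)
    phsp <- phase_space_set(rec, "fixture/monoenergetic_beam", n, 1)
    sigma <- shape_properties(cell_shape("capsule", 0.5, 2))$mean_projected_area
    R_um <- stopping_and_range("electron", energy)$R_csda * 1e4
    manifest <- list(expected_crossings_per_particle =
                       (4000 / 200^3) * sigma * R_um,
                     R_csda_um = R_um)
    out <- list(phsp = phsp, manifest = manifest)
  } else {  # constant_let_stub
    rec <- data.frame(species = rep("muon_minus", n), energy = rep(energy, n),
                      x = runif(n, 0, edge) * 1e-3,
                      y = runif(n, 0, edge) * 1e-3,
                      z = runif(n, 0, edge) * 1e-3,
                      dx = rep(1, n), dy = rep(0, n), dz = rep(0, n),
                      weight = rep(1, n), tag = rep("created", n),
                      stringsAsFactors = FALSE)
    phsp <- phase_space_set(rec, "fixture/constant_let_stub", n, 1)
    manifest <- list(S_eV_per_um = stopping_and_range("muon_minus",
                                                      max(energy, 1e6))$S * 100)
    out <- list(phsp = phsp, manifest = manifest)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_phsp(out$phsp, file.path(dir, paste0(kind, ".phsp")))
    if (!is.null(out$domain))
      write_microdomain(out$domain, file.path(dir, paste0(kind, "_domain.txt")))
    writeLines(paste(names(out$manifest),
                     vapply(out$manifest, function(x) sprintf("%.8g", x), ""),
                     sep = " "),
               file.path(dir, paste0(kind, "_manifest.txt")))
  }
  out
}
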