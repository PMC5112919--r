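det_physics <- function() micro_physics(straggling = FALSE, msc = FALSE,
                                        deltas = FALSE)

test_that("a known chord gives exactly one hit with the deterministic deposit", {
  fx <- make_fixtures("known_chord_set", n = 10, seed = 1)
  run <- run_micro(fx$phsp, fx$domain, det_physics(), seed = 2)
  expect_equal(nrow(run$hits), 10)
  expect_equal(unique(run$hits$cell), 1L)
  expect_equal(run$hits$deposit, rep(fx$manifest$deposit_no_straggle_eV, 10),
               tolerance = 0.01)
  expect_equal(run$hits$entry_energy, rep(fx$manifest$entry_energy_eV, 10),
               tolerance = 0.01)
})

test_that("fixed seeds give identical hit lists; different seeds differ", {
  bench <- benchmark_run()
  dom <- place_cells(300, 100, seed = 4)
  fx <- make_fixtures("monoenergetic_beam", seed = 3, n = 2000, energy = 1e5,
                      edge = 100)
  r1 <- run_micro(fx$phsp, dom, micro_physics(), seed = 5, kill_outside_well = FALSE)
  r2 <- run_micro(fx$phsp, dom, micro_physics(), seed = 5, kill_outside_well = FALSE)
  expect_identical(r1$hits, r2$hits)
  r3 <- run_micro(fx$phsp, dom, micro_physics(), seed = 6, kill_outside_well = FALSE)
  expect_false(identical(r1$hits, r3$hits))
})

test_that("particles starting outside the virtual well are killed with zero hits", {
  dom <- place_cells(200, 100, seed = 8)
  rec <- data.frame(species = "electron", energy = 2e5,
                    x = 50, y = 0, z = 0,  # 50 mm: far outside the well box
                    dx = 1, dy = 0, dz = 0, weight = 1, tag = "created",
                    stringsAsFactors = FALSE)
  phsp <- phase_space_set(rec, "outside", 1, 1)
  run <- run_micro(phsp, dom, micro_physics(), seed = 1,
                   well_extent = list(min = c(-5000, -5000, -5000),
                                      max = c(5000, 5000, 5000)))
  expect_equal(nrow(run$hits), 0)
  led <- energy_ledger(run)
  expect_equal(led$E_escaped, 2e5)
  expect_equal(led$E_deposited_cells, 0)
})

test_that("the energy ledger balances and respects the volume-fraction expectation", {
  dom <- place_cells(4000, 200, seed = 10)
  fx <- make_fixtures("monoenergetic_beam", seed = 11, n = 3000, energy = 1e5)
  run <- run_micro(fx$phsp, dom, micro_physics(), seed = 12,
                   kill_outside_well = FALSE)
  led <- energy_ledger(run)
  expect_equal(led$E_escaped, 0)                 # unbounded tiling: no escape
  expect_lt(led$relative_imbalance, 1e-6)
  expect_equal(led$E_in, 3000 * 1e5)
  # energy fraction ending in cells ~ density-weighted volume fraction
  vf <- 4000 * shape_properties(dom$shape)$volume / 200^3 * 1.10
  frac <- led$E_deposited_cells / led$E_in
  expect_gt(frac, vf / 1.5)
  expect_lt(frac, vf * 1.5)

  # empty phase space: all-zero ledger with a warning
  empty <- phase_space_set(data.frame(species = character(0), energy = numeric(0),
                                      x = numeric(0), y = numeric(0), z = numeric(0),
                                      dx = numeric(0), dy = numeric(0), dz = numeric(0),
                                      weight = numeric(0), tag = character(0)),
                           "none", 1, 1)
  expect_warning(r0 <- run_micro(empty, dom, micro_physics(), seed = 1), "no trackable")
  expect_equal(energy_ledger(r0)$E_in, 0)
})

test_that("constant-LET straight tracks match the brute-force geometric oracle exactly", {
  dom <- place_cells(50, 50, seed = 20)
  n_tr <- 40
  set.seed(21)
  starts <- cbind(runif(n_tr, 0, 50), runif(n_tr, 0, 50), runif(n_tr, 0, 50))
  u <- 2 * runif(n_tr) - 1; ph <- 2 * pi * runif(n_tr)
  dirs <- cbind(sqrt(1 - u^2) * cos(ph), sqrt(1 - u^2) * sin(ph), u)
  L <- 400
  rec <- data.frame(species = "muon_minus", energy = 1e10,
                    x = starts[, 1] / 1000, y = starts[, 2] / 1000,
                    z = starts[, 3] / 1000,
                    dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                    weight = 1, tag = "created", stringsAsFactors = FALSE)
  phsp <- phase_space_set(rec, "stub", n_tr, 1)
  # kill each track after exactly L um of straight flight via a well slab
  # along its own direction is not expressible; instead use an energy budget:
  # 10 GeV muons lose ~0.2 keV/um, so clip tracks with a tight global box
  run <- run_micro(phsp, dom, det_physics(), seed = 22,
                   well_extent = list(min = apply(starts, 2, min) - L,
                                      max = apply(starts, 2, max) + L))
  # oracle: count crossings for the same tracks until they leave that box
  box_lo <- apply(starts, 2, min) - L
  box_hi <- apply(starts, 2, max) + L
  exit_len <- sapply(seq_len(n_tr), function(i) {
    tt <- c((box_hi - starts[i, ]) / dirs[i, ], (box_lo - starts[i, ]) / dirs[i, ])
    min(tt[tt > 0])
  })
  oracle <- sum(sapply(seq_len(n_tr), function(i) {
    brute_crossings(dom, starts[i, , drop = FALSE], dirs[i, , drop = FALSE],
                    exit_len[i])$total
  }))
  expect_equal(nrow(run$hits), oracle)
})

test_that("straight-track hit rate matches the L * n * sigma_bar prediction", {
  dom <- place_cells(50, 50, seed = 30)
  n_mu <- 600
  set.seed(31)
  rec <- data.frame(species = "muon_minus", energy = 1e10,
                    x = 0, y = runif(n_mu, 0, 50) / 1000,
                    z = runif(n_mu, 0, 50) / 1000,
                    dx = 1, dy = 0, dz = 0, weight = 1, tag = "created",
                    stringsAsFactors = FALSE)
  phsp <- phase_space_set(rec, "stub", n_mu, 1)
  L <- 2000
  run <- run_micro(phsp, dom, det_physics(), seed = 32,
                   well_extent = list(min = c(0, -1e9, -1e9),
                                      max = c(L, 1e9, 1e9)))
  expected <- n_mu * L * (50 / 50^3) *
    shape_properties(dom$shape)$mean_projected_area
  per_track <- tabulate(run$hits$event, nbins = n_mu)
  se_emp <- sd(per_track) * sqrt(n_mu)
  expect_lt(abs(nrow(run$hits) - expected), 3 * se_emp)
})

test_that("statistics are invariant under lattice translation of the cell positions", {
  dom <- place_cells(100, 60, seed = 40)
  fx <- make_fixtures("monoenergetic_beam", seed = 41, n = 800, energy = 1e5,
                      edge = 60)
  r1 <- run_micro(fx$phsp, dom, det_physics(), seed = 42, kill_outside_well = FALSE)
  dom2 <- dom
  dom2$centers <- ((dom$centers + 60) %% 60)  # translate by one lattice vector
  r2 <- run_micro(fx$phsp, dom2, det_physics(), seed = 42, kill_outside_well = FALSE)
  expect_equal(nrow(r1$hits), nrow(r2$hits))
  expect_equal(sort(r1$hits$deposit), sort(r2$hits$deposit), tolerance = 1e-9)
})

test_that("periodic transport equals an explicitly tiled 3x3x3 replica", {
  domA <- place_cells(40, 50, seed = 50)
  # explicit 27-fold replica in a 150 um box
  offs <- as.matrix(expand.grid(0:2, 0:2, 0:2)) * 50
  centersB <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    sweep(domA$centers, 2, offs[i, ], "+")))
  domB <- structure(list(edge = 150, n = 40L * 27L, centers = centersB,
                         orientations = do.call(rbind,
                           rep(list(domA$orientations), 27)),
                         shape = domA$shape, well_extent = NULL),
                    class = "microdomain")
  # 50 keV electrons (range ~43 um) started inside the central replica never
  # leave the 150 um box, so the two descriptions are geometrically identical
  set.seed(51)
  n <- 500
  u <- 2 * runif(n) - 1; ph <- 2 * pi * runif(n)
  rec <- data.frame(species = "electron", energy = 5e4,
                    x = runif(n, 50, 100) / 1000, y = runif(n, 50, 100) / 1000,
                    z = runif(n, 50, 100) / 1000,
                    dx = sqrt(1 - u^2) * cos(ph), dy = sqrt(1 - u^2) * sin(ph),
                    dz = u, weight = 1, tag = "created", stringsAsFactors = FALSE)
  phsp <- phase_space_set(rec, "tiling", n, 1)
  rA <- run_micro(phsp, domA, det_physics(), seed = 52, kill_outside_well = FALSE)
  rB <- run_micro(phsp, domB, det_physics(), seed = 52, kill_outside_well = FALSE)
  expect_lte(abs(nrow(rA$hits) - nrow(rB$hits)), 2)
  expect_equal(sum(rA$hits$deposit), sum(rB$hits$deposit), tolerance = 0.02)
})

test_that("raising the tracking cutoff never increases the hit count", {
  dom <- place_cells(4000, 200, seed = 60)
  fx <- make_fixtures("monoenergetic_beam", seed = 61, n = 2000, energy = 1e5)
  r100 <- run_micro(fx$phsp, dom, det_physics(), seed = 62, kill_outside_well = FALSE)
  p1k <- det_physics(); p1k$cutoff <- 1000
  r1k <- run_micro(fx$phsp, dom, p1k, seed = 62, kill_outside_well = FALSE)
  expect_lte(nrow(r1k$hits), nrow(r100$hits))
})

test_that("per-event summaries count distinct cell-tile pairs", {
  fx <- make_fixtures("known_chord_set", n = 4, seed = 1)
  run <- run_micro(fx$phsp, fx$domain, det_physics(), seed = 2)
  es <- event_summaries(run)
  expect_equal(nrow(es), 4)
  expect_equal(es$cells_hit, rep(1L, 4))
  expect_equal(count_hits(run, "events"), 4)
  expect_equal(count_hits(run, "crossings"), 4)
})
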