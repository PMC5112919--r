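make_records <- function(n, energy = 1e5) {
  set.seed(77)
  u <- 2 * runif(n) - 1; ph <- 2 * pi * runif(n)
  st <- sqrt(pmax(0, 1 - u^2))
  data.frame(species = rep("electron", n), energy = rep(energy, n),
             x = runif(n, -5, 5), y = runif(n, -5, 5), z = runif(n, -20, -5),
             dx = st * cos(ph), dy = st * sin(ph), dz = u,
             weight = rep(1, n), tag = rep("created", n),
             stringsAsFactors = FALSE)
}

# rate and empirical standard error from per-event (weighted) hit counts;
# axis-aligned stub tracks cluster their crossings, so the Poisson error
# underestimates the spread
rate_emp <- function(run, n_cells, days) {
  n_ev <- run$n_events
  per <- rep(0, n_ev)
  if (nrow(run$hits) > 0) {
    agg <- tapply(run$hits$weight, run$hits$event, sum)
    per[as.integer(names(agg))] <- agg
  }
  denom <- n_cells * days
  list(rate = sum(per) / denom, se = sd(per) * sqrt(n_ev) / denom)
}

test_that("phase-space files round-trip losslessly with a validated header", {
  set1 <- phase_space_set(make_records(50), "test_source", 1234, 2.5)
  path <- tempfile(fileext = ".phsp")
  write_phsp(set1, path)
  back <- read_phsp(path)
  expect_equal(back$records$energy, set1$records$energy, tolerance = 1e-10)
  expect_equal(back$records$x, set1$records$x, tolerance = 1e-10)
  expect_equal(back$records$dx, set1$records$dx, tolerance = 1e-10)
  expect_identical(back$records$species, set1$records$species)
  expect_identical(back$records$tag, set1$records$tag)
  expect_equal(back$represented_days, 2.5)
  expect_equal(back$n_primaries, 1234)
  expect_equal(back$source, "test_source")

  # empty set: valid file with intact metadata
  empty <- phase_space_set(make_records(0), "empty", 10, 1)
  p2 <- tempfile()
  write_phsp(empty, p2)
  back2 <- read_phsp(p2)
  expect_equal(nrow(back2$records), 0)
  expect_equal(back2$represented_days, 1)

  # malformed headers rejected
  p3 <- tempfile()
  writeLines(c("no header", "at all", "x", "y", "z", "w"), p3)
  expect_error(read_phsp(p3), "header")
  lines <- readLines(path)
  lines[2] <- "# units keV cm"
  p4 <- tempfile()
  writeLines(lines, p4)
  expect_error(read_phsp(p4), "units")
})

test_that("phase-space construction enforces its invariants", {
  r <- make_records(5)
  r$energy[3] <- -1
  expect_error(phase_space_set(r, "x", 5, 1), "energies")
  r <- make_records(5); r$weight[1] <- 0
  expect_error(phase_space_set(r, "x", 5, 1), "weights")
  r <- make_records(5); r$dx[2] <- 5
  expect_error(phase_space_set(r, "x", 5, 1), "unit")
  expect_error(phase_space_set(make_records(5), "x", 5, 0), "represented_days")
})

test_that("subset draws keep the represented-time bookkeeping consistent", {
  full <- phase_space_set(make_records(1000), "sub", 1e6, 100)
  # without replacement: time scales with the kept fraction
  sub <- draw_subset(full, 100, seed = 1)
  expect_equal(sub$represented_days, 10)
  expect_equal(nrow(sub$records), 100)
  expect_equal(unique(sub$records$weight), 1)
  # with replacement: weights rescale, total represented time preserved
  over <- draw_subset(full, 2000, seed = 2, replace = TRUE)
  expect_equal(over$represented_days, 100)
  expect_equal(unique(over$records$weight), 0.5)
  expect_equal(sum(over$records$weight), 1000)
  # determinism and bounds
  expect_identical(draw_subset(full, 100, seed = 7)$records,
                   draw_subset(full, 100, seed = 7)$records)
  expect_error(draw_subset(full, 2000, seed = 1, replace = FALSE), "replace")
})

test_that("downstream rates are invariant under subset sampling", {
  # straight constant-LET tracks with an analytically known hit rate
  dom <- place_cells(50, 50, seed = 9)
  dom$well_extent <- list(min = c(-1e9, -1e9, -1e9), max = c(2000, 1e9, 1e9))
  fx <- make_fixtures("constant_let_stub", seed = 5, n = 1500, energy = 1e10,
                      edge = 50)
  phys <- micro_physics(straggling = FALSE, msc = FALSE, deltas = FALSE)
  full_run <- run_micro(fx$phsp, dom, phys, seed = 3)
  r_full <- rate_emp(full_run, 50, 1)

  sub <- draw_subset(fx$phsp, 500, seed = 4)
  sub_run <- run_micro(sub, dom, phys, seed = 3)
  r_sub <- rate_emp(sub_run, 50, sub$represented_days)
  expect_lt(abs(r_sub$rate - r_full$rate), 4 * sqrt(r_sub$se^2 + r_full$se^2))

  over <- draw_subset(fx$phsp, 3000, seed = 4, replace = TRUE)
  over_run <- run_micro(over, dom, phys, seed = 3)
  r_over <- rate_emp(over_run, 50, over$represented_days)
  expect_lt(abs(r_over$rate - r_full$rate), 4 * sqrt(r_over$se^2 + r_full$se^2))
})
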