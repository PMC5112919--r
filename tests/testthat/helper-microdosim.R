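# Shared fixtures and independent brute-force oracles for the test suite.

.helper_env <- new.env(parent = emptyenv())

# The 200 keV electron microdomain benchmark (computed once, reused by
# several tests): 2.5e5 monoenergetic electrons through the default domain
# with the periodic tiling continued indefinitely.
benchmark_run <- function() {
  if (!is.null(.helper_env$bench)) return(.helper_env$bench)
  dom <- place_cells(4000, 200, seed = 42)
  fx <- make_fixtures("monoenergetic_beam", seed = 7, n = 2.5e5, energy = 2e5)
  run <- run_micro(fx$phsp, dom, micro_physics(), seed = 101,
                   kill_outside_well = FALSE)
  .helper_env$bench <- list(run = run, fixture = fx, n = 2.5e5)
  .helper_env$bench
}

# Brute-force crossing counter: intersects every cell of every overlapped
# periodic tile with each straight track, independently of the transport
# grid walk. Tracks are (global start [um], unit direction, length L [um]);
# a crossing counts when the entry parameter lies in [0, L) with a positive
# chord.
brute_crossings <- function(domain, starts, dirs, L) {
  edge <- domain$edge
  sh <- domain$shape
  reach <- sh$radius + sh$cylinder_length / 2
  total <- 0L
  per_track <- integer(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    p <- starts[i, ]; d <- dirs[i, ]
    ends <- rbind(p, p + d * L)
    lo <- floor((apply(ends, 2, min) - reach) / edge)
    hi <- floor((apply(ends, 2, max) + reach) / edge)
    cnt <- 0L
    for (tx in lo[1]:hi[1]) for (ty in lo[2]:hi[2]) for (tz in lo[3]:hi[3]) {
      off <- c(tx, ty, tz) * edge
      for (ci in seq_len(domain$n)) {
        tt <- microdosim:::ray_capsule_cpp(p, d, domain$centers[ci, ] + off,
                                           domain$orientations[ci, ],
                                           sh$radius, sh$cylinder_length / 2)
        if (tt[1] <= tt[2] && tt[2] > 1e-6 && tt[1] < L &&
            (tt[2] - max(tt[1], 0)) > 1e-9)
          cnt <- cnt + 1L
      }
    }
    per_track[i] <- cnt
    total <- total + cnt
  }
  list(total = total, per_track = per_track)
}

# analytic projected area of a capsule along a direction at angle theta to
# its axis: a rectangle 2r * L sin(theta) plus a full disc pi r^2
capsule_projected_area <- function(theta, r, L) {
  2 * r * L * sin(theta) + pi * r^2
}

expect_within <- function(value, target, rel_tol, label = NULL) {
  expect_true(abs(value - target) <= rel_tol * abs(target),
              info = sprintf("%s: %g not within %g%% of %g",
                             label %||% "value", value, 100 * rel_tol, target))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
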