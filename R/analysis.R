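# Analysis: per-cell per-day hit frequencies, per-nGy interaction rates,
# energy-deposit statistics, distribution comparisons, and the
# mutation-rate context arithmetic.

#' Per-cell per-day hit frequency
#'
#' Count of deposit-positive cell crossings divided by the number of cells
#' considered and the represented time, with a Poisson standard error. The
#' cells considered are all cells the periodic tiling represents in the
#' well (`cells_considered()`), which the represented-time bookkeeping
#' makes equivalent to normalizing by the simulated cells only.
#'
#' @param run a `micro_run`, or a numeric hit count.
#' @param n_cells number of cells considered (required when `run` is a
#'   count; defaults to `cells_considered(run$domain)`).
#' @param represented_days represented time [days] (defaults to the run's).
#' @param convention hit-counting convention, see [count_hits()].
#' @return list with `rate` [day^-1 cell^-1], `se`, `n_hits`, `upper95`
#'   (upper confidence bound, reported when the count is zero).
#' @export
hit_frequency <- function(run, n_cells = NULL, represented_days = NULL,
                          convention = "unique_pairs") {
  if (inherits(run, "micro_run")) {
    n_hits <- count_hits(run, convention)
    if (is.null(n_cells)) n_cells <- cells_considered(run$domain)
    if (is.null(represented_days)) represented_days <- run$represented_days
  } else {
    n_hits <- as.numeric(run)
    if (is.null(n_cells) || is.null(represented_days))
      stop("n_cells and represented_days are required with a raw count")
  }
  if (represented_days <= 0) stop("represented time must be > 0")
  if (n_cells < 1) stop("n_cells must be >= 1")
  denom <- n_cells * represented_days
  list(rate = n_hits / denom, se = sqrt(max(n_hits, 1)) / denom,
       n_hits = n_hits, upper95 = if (n_hits == 0) 3 / denom else NA_real_)
}

#' Expected interactions per cell per nanogray
#'
#' @param hit_freq hit frequency [day^-1 cell^-1] or a `rate_summary`.
#' @param dose_rate_nGy_hr dose rate [nGy/hr], > 0.
#' @return rate [nGy^-1].
#' @examples
#' per_nGy(3.6e-5, 150)   # 1.0e-8
#' @export
per_nGy <- function(hit_freq, dose_rate_nGy_hr = NULL) {
  if (inherits(hit_freq, "rate_summary")) {
    dose_rate_nGy_hr <- hit_freq$dose_rate_nGy_hr
    hit_freq <- hit_freq$hit_frequency
  }
  if (is.null(dose_rate_nGy_hr) || dose_rate_nGy_hr <= 0)
    stop("dose rate must be > 0")
  hit_freq / (dose_rate_nGy_hr * 24)
}

#' Energy-deposit statistics
#'
#' Order statistics (25/50/75th percentiles) of per-crossing deposits, the
#' modal deposit from a log-binned histogram (20 bins per decade over
#' 10 eV - 100 keV, declared in the output), and the histogram itself. The
#' per-crossing deposit spectrum is Landau-like, so percentiles rather than
#' a mean summarize it.
#'
#' @param deposits numeric deposits [eV], or a `micro_run`.
#' @param bins_per_decade histogram binning (default 20).
#' @return list with `percentiles` (named, eV), `mode` (bin center, eV),
#'   `histogram` (data.frame `lo`, `hi`, `count`), `n`, `binning`.
#' @export
deposit_statistics <- function(deposits, bins_per_decade = 20) {
  if (inherits(deposits, "micro_run")) deposits <- deposits$hits$deposit
  deposits <- deposits[is.finite(deposits) & deposits > 0]
  if (length(deposits) == 0) stop("no deposits to summarize")
  qs <- quantile(deposits, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  edges <- 10^seq(1, 5, by = 1 / bins_per_decade)
  cut_d <- pmin(pmax(deposits, edges[1] * 1.0000001), edges[length(edges)])
  idx <- findInterval(cut_d, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  imax <- which.max(counts)
  hist <- data.frame(lo = edges[-length(edges)], hi = edges[-1], count = counts)
  list(percentiles = c(p25 = qs[1], p50 = qs[2], p75 = qs[3]),
       mode = sqrt(edges[imax] * edges[imax + 1]),
       histogram = hist, n = length(deposits),
       binning = sprintf("%d log bins per decade, 10 eV - 100 keV", bins_per_decade))
}

#' Two-sample Kolmogorov-Smirnov comparison of deposit distributions
#'
#' @param a,b numeric samples (e.g. deposits from two physics models).
#' @return list with `D` (KS statistic), `p_value` and `z_equivalent`
#'   (two-sided normal z-score equivalent of the p-value).
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty input sample")
  ks <- suppressWarnings(stats::ks.test(a, b))
  p <- max(ks$p.value, .Machine$double.xmin)
  list(D = unname(ks$statistic), p_value = p,
       z_equivalent = abs(stats::qnorm(p / 2)))
}

#' Mutation-rate context
#'
#' The daily spontaneous point-mutation bound (mutations per generation
#' times generations per day) and its ratio to the radiation hit rate.
#'
#' @param hit_rate radiation hit frequency [day^-1 cell^-1], > 0.
#' @param mu_per_generation point mutation rate bound per generation
#'   (default 7.4e-4).
#' @param generations_per_day growth rate (default 8.23).
#' @return list with `mutations_per_day` and `hit_to_mutation_ratio`
#'   (mutations per day / hit rate).
#' @examples
#' mutation_comparison(6.0e-5)   # ~6.1e-3 per day, ratio ~102
#' @export
mutation_comparison <- function(hit_rate, mu_per_generation = 7.4e-4,
                                generations_per_day = 8.23) {
  stopifnot(mu_per_generation > 0, generations_per_day > 0)
  if (is.null(hit_rate) || !is.finite(hit_rate) || hit_rate <= 0)
    stop("hit rate must be > 0 (ratio undefined otherwise)")
  mpd <- mu_per_generation * generations_per_day
  list(mutations_per_day = mpd, hit_to_mutation_ratio = mpd / hit_rate)
}

#' Dose rate needed to reach a target hit rate
#'
#' Inverts the per-nGy interaction rate: the dose rate at which the cell
#' hit frequency would equal `target_rate`. Order-of-magnitude by nature,
#' since the per-nGy rate is source-spectrum dependent.
#'
#' @param target_rate target hit frequency [day^-1 cell^-1].
#' @param per_nGy_rate interactions per cell per nGy, > 0.
#' @return dose rate [uGy/hr].
#' @examples
#' dose_to_match(6.1e-3, 1.0e-8)   # ~25 uGy/hr
#' @export
dose_to_match <- function(target_rate, per_nGy_rate) {
  if (per_nGy_rate <= 0) stop("per-nGy rate must be > 0")
  target_rate / (per_nGy_rate * 24) / 1000   # nGy/hr -> uGy/hr
}

#' Geometric hit-rate scaling between two cell shapes
#'
#' By Cauchy's formula the isotropic-track interaction cross section of a
#' convex cell is surface/4, so hit rates scale as surface areas.
#'
#' @param shape_a,shape_b [cell_shape()] objects.
#' @return ratio of mean projected areas (a over b).
#' @examples
#' geometry_scaling(cell_shape("sphere", 15), cell_shape("sphere", 0.5)) # 900
#' @export
geometry_scaling <- function(shape_a, shape_b) {
  shape_properties(shape_a)$mean_projected_area /
    shape_properties(shape_b)$mean_projected_area
}

#' Assemble a rate summary for one source
#'
#' Bundles the hit frequency, dose rate, per-nGy rate and deposit
#' statistics with the normalization chain used. The identity
#' `hits_per_nGy * dose_rate * 24 == hit_frequency` holds by construction.
#'
#' @param source source label.
#' @param run a `micro_run`.
#' @param dose a [dose_rate()] result.
#' @param normalization description of the calibration chain.
#' @return object of class `rate_summary`.
#' @export
rate_summary <- function(source, run, dose, normalization = "printed-normalization") {
  hf <- hit_frequency(run)
  hfe <- hit_frequency(run, convention = "events")
  dep <- if (nrow(run$hits) > 0) deposit_statistics(run) else NULL
  structure(list(
    source = source,
    hit_frequency = hf$rate, hit_frequency_se = hf$se, n_hits = hf$n_hits,
    hit_frequency_events = hfe$rate, hit_frequency_events_se = hfe$se,
    dose_rate_nGy_hr = dose$nGy_hr, dose_rate_se = dose$se_nGy_hr,
    hits_per_nGy = if (dose$nGy_hr > 0) hf$rate / (dose$nGy_hr * 24) else NA_real_,
    deposit_percentiles = dep$percentiles, deposit_mode = dep$mode,
    normalization = normalization), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("<rate_summary> %s [%s]\n", x$source, x$normalization))
  cat(sprintf("  hit frequency : %.3g +/- %.2g day^-1 cell^-1 (%.4g hits)\n",
              x$hit_frequency, x$hit_frequency_se, x$n_hits))
  cat(sprintf("  track events : %.3g +/- %.2g day^-1 cell^-1\n",
              x$hit_frequency_events, x$hit_frequency_events_se))
  cat(sprintf("  dose rate     : %.3g nGy/hr\n", x$dose_rate_nGy_hr))
  cat(sprintf("  per nGy       : %.3g\n", x$hits_per_nGy))
  if (!is.null(x$deposit_percentiles))
    cat(sprintf("  deposit 25/50/75: %.3g / %.3g / %.3g eV (mode %.3g)\n",
                x$deposit_percentiles[1], x$deposit_percentiles[2],
                x$deposit_percentiles[3], x$deposit_mode))
  invisible(x)
}
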