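# Phase-space sets: the contract between the macroscopic and microscopic
# simulation levels, with explicit represented-time bookkeeping.

#' Construct a phase-space set
#'
#' A phase-space set holds the charged particles recorded at the macroscopic
#' level (species, kinetic energy, position in the well frame, direction,
#' statistical weight) together with the real time their parent primaries
#' represent. Every downstream rate inherits this normalization.
#'
#' @param records data.frame with columns `species` (character), `energy`
#'   [eV], `x`, `y`, `z` [mm, well frame], `dx`, `dy`, `dz` (unit vector),
#'   `weight` (> 0), and optionally `tag` (`"created"` or `"entered"`).
#' @param source character label of the generating source.
#' @param n_primaries number of primaries run at the macroscopic level.
#' @param represented_days real time represented by those primaries [days].
#' @return object of class `phase_space_set`.
#' @export
phase_space_set <- function(records, source = "unknown", n_primaries = NA_real_,
                            represented_days) {
  need <- c("species", "energy", "x", "y", "z", "dx", "dy", "dz", "weight")
  if (!all(need %in% names(records)))
    stop("phase-space records must have columns: ", paste(need, collapse = ", "))
  if (nrow(records) > 0) {
    if (any(records$energy <= 0)) stop("phase-space energies must be > 0")
    if (any(records$weight <= 0)) stop("phase-space weights must be > 0")
    nrm <- sqrt(records$dx^2 + records$dy^2 + records$dz^2)
    if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  }
  if (!is.numeric(represented_days) || represented_days <= 0)
    stop("represented_days must be > 0")
  if (is.null(records$tag)) records$tag <- "created"
  structure(list(records = records, source = source,
                 n_primaries = n_primaries,
                 represented_days = represented_days),
            class = "phase_space_set")
}

#' @export
print.phase_space_set <- function(x, ...) {
  cat(sprintf("<phase_space_set> %d records from '%s' (%s primaries, %.4g days)\n",
              nrow(x$records), x$source,
              format(x$n_primaries, big.mark = ","), x$represented_days))
  if (nrow(x$records) > 0) print(table(x$records$species))
  invisible(x)
}

.phsp_version <- "microdosim phsp v1"

#' Write a phase-space set to a columnar text file
#'
#' Versioned header (units eV / mm, source descriptor, normalization
#' metadata) followed by one record per row. Lossless round trip via
#' [read_phsp()].
#'
#' @param set a `phase_space_set`.
#' @param path output path.
#' @export
write_phsp <- function(set, path) {
  stopifnot(inherits(set, "phase_space_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ", .phsp_version),
    "# units eV mm",
    paste0("# source ", set$source),
    sprintf("# n_primaries %.9g", set$n_primaries),
    sprintf("# represented_days %.12g", set$represented_days),
    "# columns species energy x y z dx dy dz weight tag"), con)
  if (nrow(set$records) > 0) {
    df <- set$records[, c("species", "energy", "x", "y", "z",
                          "dx", "dy", "dz", "weight", "tag")]
    write.table(format(df, digits = 12, trim = TRUE), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a phase-space set written by [write_phsp()]
#'
#' Rejects files without the versioned header or with malformed unit
#' declarations.
#'
#' @param path input path.
#' @export
read_phsp <- function(path) {
  hdr <- readLines(path, n = 6)
  if (length(hdr) < 6 || !identical(hdr[1], paste0("# ", .phsp_version)))
    stop("not a recognized phase-space file (missing/old header): ", path)
  if (!identical(hdr[2], "# units eV mm"))
    stop("phase-space file declares unexpected units: ", hdr[2])
  source <- sub("^# source ", "", hdr[3])
  n_primaries <- as.numeric(sub("^# n_primaries ", "", hdr[4]))
  days <- as.numeric(sub("^# represented_days ", "", hdr[5]))
  nl <- length(readLines(path))
  if (nl > 6) {
    df <- read.table(path, skip = 6, col.names = c(
      "species", "energy", "x", "y", "z", "dx", "dy", "dz", "weight", "tag"),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(species = character(0), energy = numeric(0),
                     x = numeric(0), y = numeric(0), z = numeric(0),
                     dx = numeric(0), dy = numeric(0), dz = numeric(0),
                     weight = numeric(0), tag = character(0),
                     stringsAsFactors = FALSE)
  }
  phase_space_set(df, source, n_primaries, days)
}

#' Draw a subset of a phase-space set
#'
#' Random subset with represented-time bookkeeping: drawing `k` of `N`
#' records without replacement represents `k/N` of the original time;
#' drawing with replacement preserves the represented time by rescaling the
#' per-record weights by `N/k` (so oversampling a set leaves every
#' downstream rate unbiased).
#'
#' @param set a `phase_space_set`.
#' @param k number of records to draw (>= 1).
#' @param seed integer seed.
#' @param replace draw with replacement (required when `k > N`).
#' @return a new `phase_space_set`.
#' @export
draw_subset <- function(set, k, seed = 1L, replace = FALSE) {
  stopifnot(inherits(set, "phase_space_set"), k >= 1)
  N <- nrow(set$records)
  if (N == 0) stop("cannot subsample an empty phase-space set")
  if (!replace && k > N)
    stop(sprintf("k = %d exceeds the %d available records; use replace = TRUE", k, N))
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  idx <- sample.int(N, size = k, replace = replace)
  rec <- set$records[idx, , drop = FALSE]
  rownames(rec) <- NULL
  if (replace) {
    rec$weight <- rec$weight * (N / k)
    days <- set$represented_days
  } else {
    days <- set$represented_days * k / N
  }
  phase_space_set(rec, set$source, set$n_primaries, days)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
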