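#' Minimal metadata for an MEA recording
#'
#' Construct the metadata block stored under `/meta` in a recording file.
#' The vocabulary is deliberately minimal: a study key, the species, the
#' postnatal age, the genotype and the recording condition.
#'
#' @param key Study identifier, conventionally first-author surname plus
#'   year of the main paper (e.g. `"Wong1993"`).
#' @param species Species name (e.g. `"mouse"`, `"ferret"`).
#' @param age Integer postnatal age in days.  Day of birth is 0; embryonic
#'   ages may be negative; the sentinel value 500 denotes an adult animal.
#' @param genotype Genotype label; default `"wt"` (wild type).
#' @param cond Recording condition; default `"ctl"` (control).  Free text
#'   such as drug applications (`"bic"`) or rearing (`"dr"`) is allowed.
#'
#' @return A list of class `mea_metadata` with elements `key`, `species`,
#'   `age`, `genotype`, `cond`.
#' @examples
#' mea_metadata("Wong1993", "ferret", age = 0)
#' @export
mea_metadata <- function(key, species, age, genotype = "wt", cond = "ctl") {
  stopifnot(is.character(key), length(key) == 1L,
            is.character(species), length(species) == 1L,
            length(age) == 1L, is.numeric(age))
  if (!nzchar(key)) stop("'key' must be a non-empty string")
  if (!nzchar(species)) stop("'species' must be a non-empty string")
  if (!is.finite(age) || age != round(age))
    stop("'age' must be an integer number of postnatal days")
  structure(list(key = key, species = species, age = as.integer(age),
                 genotype = as.character(genotype), cond = as.character(cond)),
            class = "mea_metadata")
}

#' In-memory MEA recording
#'
#' Build a recording object mirroring the on-disk HDF5 schema: unit
#' positions, per-unit spike counts, all spike times concatenated unit by
#' unit, the array layout label, optional unit names, metadata, and a
#' summary block (recomputed here unless supplied).
#'
#' @param epos Numeric N x 2 matrix of unit (x, y) positions in micrometres.
#' @param spikes Numeric vector of spike times in seconds; the trains of
#'   all units concatenated in unit order, each train sorted ascending.
#' @param sCount Integer vector of length N; `sCount[i]` is the number of
#'   spikes of unit i, so `sum(sCount) == length(spikes)`.
#' @param array String label of the MEA layout (see [make_layout()] for
#'   the standard vocabulary; the set is open).
#' @param meta An [mea_metadata()] object.
#' @param names Optional character vector of length N of unit names.
#' @param summary Optional precomputed summary block; if `NULL` it is
#'   computed with [compute_summary()].
#'
#' @return An object of class `mea_recording`: a list with fields `epos`,
#'   `spikes`, `sCount`, `array`, `names`, `meta`, `summary`.
#' @seealso [read_mea_h5()], [write_mea_h5()], [validate_mea()]
#' @examples
#' rec <- mea_recording(
#'   epos   = cbind(x = c(0, 100), y = c(0, 0)),
#'   spikes = c(0.5, 1.2, 8.3, 0.9),
#'   sCount = c(3, 1),
#'   array  = "MCS_8x8_100um",
#'   meta   = mea_metadata("demo", "mouse", age = 5))
#' rec$summary$duration
#' @export
mea_recording <- function(epos, spikes, sCount, array, meta,
                          names = NULL, summary = NULL) {
  epos <- as.matrix(epos)
  storage.mode(epos) <- "double"
  if (ncol(epos) != 2L)
    stop("'epos' must be an N x 2 matrix of (x, y) positions")
  dimnames(epos) <- list(NULL, c("x", "y"))
  sCount <- as.integer(round(sCount))
  spikes <- as.double(spikes)
  if (!inherits(meta, "mea_metadata"))
    meta <- do.call(mea_metadata, as.list(meta))
  rec <- structure(
    list(epos = epos, spikes = spikes, sCount = sCount,
         array = as.character(array)[1L],
         names = if (!is.null(names)) as.character(names),
         meta = meta, summary = summary),
    class = "mea_recording")
  if (is.null(summary)) rec$summary <- compute_summary(rec)
  rec
}

#' @export
print.mea_recording <- function(x, ...) {
  s <- x$summary
  cat(sprintf("MEA recording: %d units on '%s' array\n", n_units(x), x$array))
  cat(sprintf("  meta: key=%s species=%s age=%d genotype=%s cond=%s\n",
              x$meta$key, x$meta$species, x$meta$age,
              x$meta$genotype, x$meta$cond))
  if (!is.null(s))
    cat(sprintf("  %d spikes over %d s (mean rate %.3g Hz/unit)\n",
                s$totalspikes, s$duration, mean(s$frate)))
  invisible(x)
}

#' Number of units in a recording
#' @param rec An `mea_recording`.
#' @return Integer unit count N.
#' @export
n_units <- function(rec) length(rec$sCount)

#' Element range of one unit's spikes in the concatenated vector
#'
#' The concatenated spike vector stores the spikes of unit j in elements
#' a to b (1-based, inclusive), where a is one past the cumulative count
#' of the preceding units and `b = a + sCount[j] - 1`.  A unit with no
#' spikes yields `b < a`, denoting an empty range.
#'
#' @param sCount Integer vector of per-unit spike counts.
#' @param j Unit index in `1..length(sCount)`.
#' @return Integer vector `c(a, b)`.
#' @examples
#' unit_slice(c(2, 3, 1), 2)  # c(3, 5)
#' @export
unit_slice <- function(sCount, j) {
  n <- length(sCount)
  if (length(j) != 1L || is.na(j) || j < 1L || j > n)
    stop(sprintf("unit index j=%s out of range 1..%d", format(j), n))
  j <- as.integer(j)
  a <- 1L + if (j > 1L) sum(as.integer(sCount[seq_len(j - 1L)])) else 0L
  b <- a + as.integer(sCount[j]) - 1L
  c(a = a, b = b)
}

#' Extract the spike train of one unit
#'
#' @param rec An `mea_recording`.
#' @param j Unit index.
#' @return Numeric vector of that unit's spike times (possibly empty),
#'   sorted ascending.
#' @examples
#' rec <- mea_recording(cbind(0:1, 0), c(0.1, 0.9, 0.2, 0.4, 0.8), c(2, 3),
#'                      "MCS_8x8_100um", mea_metadata("demo", "mouse", 5))
#' unit_spikes(rec, 2)
#' @export
unit_spikes <- function(rec, j) {
  ab <- unit_slice(rec$sCount, j)
  if (ab[2L] < ab[1L]) return(numeric(0))
  rec$spikes[ab[1L]:ab[2L]]
}

#' Compute the summary cache of a recording
#'
#' The summary block mirrors the `/summary` group of the file format: the
#' number of spike trains `N`, the recording `duration` in whole seconds
#' (maximum spike time rounded up to the nearest second), the per-unit
#' firing rates `frate` in Hz (`sCount / duration`), and `totalspikes`,
#' the total number of spikes.
#'
#' A recording with no spikes (or whose only spike is at time 0) has no
#' well-defined duration; supply `duration` explicitly or an error is
#' raised.
#'
#' @param rec An `mea_recording` (its `summary` field is ignored).
#' @param duration Optional duration override in whole seconds.
#' @return A list of class `mea_summary` with `N`, `duration`, `frate`,
#'   `totalspikes`.
#' @examples
#' rec <- mea_recording(cbind(0, 0), c(1.0, 9.2), 2, "MCS_8x8_100um",
#'                      mea_metadata("demo", "mouse", 5))
#' compute_summary(rec)$duration  # ceiling(9.2) = 10
#' @export
compute_summary <- function(rec, duration = NULL) {
  N <- n_units(rec)
  total <- sum(rec$sCount)
  if (is.null(duration)) {
    if (total == 0L)
      stop("recording has no spikes: duration is undefined; ",
           "pass an explicit 'duration'")
    duration <- as.integer(ceiling(max(rec$spikes)))
    if (duration <= 0L)
      stop("maximum spike time is 0: duration is undefined; ",
           "pass an explicit 'duration'")
  } else {
    duration <- as.integer(duration)
    if (duration <= 0L) stop("'duration' must be a positive whole number")
  }
  structure(list(N = N, duration = duration,
                 frate = as.double(rec$sCount) / duration,
                 totalspikes = as.integer(total)),
            class = "mea_summary")
}

#' Per-unit firing rates
#'
#' Recomputes `sCount / duration` from the raw fields, as a cross-check of
#' the stored `/summary/frate` cache.
#'
#' @param rec An `mea_recording` with a summary block.
#' @return Numeric vector of length N, in Hz.
#' @export
unit_firing_rates <- function(rec) {
  as.double(rec$sCount) / rec$summary$duration
}
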