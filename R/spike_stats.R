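#' Count near-coincident spikes between two trains
#'
#' Number of ordered spike pairs (s from `a`, t from `b`) with
#' `|s - t| <= dt` (window closed at both ends).  Computed by a linear
#' two-pointer sweep over the two sorted trains.
#'
#' @param a,b Sorted numeric vectors of spike times in seconds.
#' @param dt Half-width of the coincidence window, in seconds; must be
#'   positive.
#' @param check Verify that inputs are sorted (default).  Set `FALSE` to
#'   skip the check in tight loops over pre-validated trains.
#' @return Number of coincident pairs (a non-negative count).
#' @examples
#' coincident_count(c(0.1, 0.2, 0.3), c(0.12, 0.5), dt = 0.05)  # 1
#' @export
coincident_count <- function(a, b, dt, check = TRUE) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number")
  a <- as.double(a); b <- as.double(b)
  if (check && (is.unsorted(a) || is.unsorted(b)))
    stop("spike trains must be sorted ascending")
  .coincident_count_cpp(a, b, dt)
}

#' Correlation index of two spike trains
#'
#' The classic coincidence-within-a-window statistic for developing-retina
#' recordings: the observed number of spike pairs of the two trains within
#' `dt` of each other, divided by the number expected if the trains were
#' independent homogeneous processes over a recording of length `T`:
#'
#' \deqn{CI = \frac{N_{ab}(\pm dt) \, T}{N_a N_b \, 2 dt}}
#'
#' Independent trains give CI about 1; correlated firing gives CI > 1.
#' If either train is empty the index is undefined and `NaN` is returned.
#'
#' @inheritParams coincident_count
#' @param T Recording duration in seconds (conventionally the `/summary`
#'   duration); must be positive.
#' @return The correlation index (dimensionless), or `NaN`.
#' @examples
#' correlation_index(c(0.1, 0.2, 0.3), c(0.12, 0.5), dt = 0.05, T = 1)
#' @export
correlation_index <- function(a, b, dt, T, check = TRUE) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("'T' must be a single positive number")
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) return(NaN)
  coincident_count(a, b, dt, check = check) * T / (na * nb * 2 * dt)
}

#' All pairwise correlation indices of a recording
#'
#' Computes the correlation index for every unordered unit pair, together
#' with the Euclidean inter-unit distance in the electrode plane.  Pairs
#' of units assigned the same position (distance 0) are included; pairs
#' involving an empty spike train carry `ci = NaN`.  The recording
#' duration `T` is taken from the summary block.
#'
#' @param rec A valid [mea_recording()] with at least two units.
#' @param dt Coincidence half-window in seconds (default 0.05, i.e. the
#'   conventional 50 ms).
#' @return A data frame with one row per pair: `i`, `j` (unit indices,
#'   `i < j`), `distance` (micrometres) and `ci`.
#' @seealso [bin_ci_by_distance()], [correlation_index()]
#' @export
ci_map <- function(rec, dt = 0.05) {
  N <- n_units(rec)
  if (N < 2L) stop("need at least 2 units to form pairs")
  T <- rec$summary$duration
  trains <- lapply(seq_len(N), unit_spikes, rec = rec)
  idx <- which(upper.tri(matrix(NA_integer_, N, N)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  d <- sqrt((rec$epos[i, 1L] - rec$epos[j, 1L])^2 +
            (rec$epos[i, 2L] - rec$epos[j, 2L])^2)
  ci <- vapply(seq_along(i), function(k)
    correlation_index(trains[[i[k]]], trains[[j[k]]], dt, T, check = FALSE),
    numeric(1L))
  ord <- order(i, j)
  data.frame(i = i, j = j, distance = d, ci = ci)[ord, , drop = FALSE]
}

#' Bin pairwise correlation indices by inter-unit distance
#'
#' Groups pairs into contiguous left-closed distance bins
#' `[k*width, (k+1)*width)` and averages the correlation index within
#' each bin, skipping `NaN` pairs.  Bins containing no pairs are omitted.
#'
#' @param pairs Data frame from [ci_map()] (columns `distance`, `ci`).
#' @param width Bin width in micrometres (default 100).
#' @return A data frame with one row per occupied bin: `left` (bin left
#'   edge), `centre`, `mean_ci`, `n_pairs` (count of non-`NaN` pairs).
#' @export
bin_ci_by_distance <- function(pairs, width = 100) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("'width' must be a single positive number")
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("'pairs' must contain at least one pair")
  ok <- is.finite(pairs$ci)
  bin <- floor(pairs$distance / width)
  bins <- sort(unique(bin[ok]))
  out <- do.call(rbind, lapply(bins, function(k) {
    sel <- ok & bin == k
    data.frame(left = k * width, centre = (k + 0.5) * width,
               mean_ci = mean(pairs$ci[sel]), n_pairs = sum(sel))
  }))
  if (is.null(out))
    out <- data.frame(left = numeric(), centre = numeric(),
                      mean_ci = numeric(), n_pairs = integer())
  rownames(out) <- NULL
  out
}

#' Array-averaged population firing rate
#'
#' Firing rate in consecutive time bins, averaged over all units: spikes
#' falling in each bin, divided by `N * binwidth`.  Bins cover
#' `[0, duration)`; a spike exactly at the duration (possible because the
#' duration is the ceiling of the last spike time) is counted in the last
#' bin.
#'
#' @param rec A valid [mea_recording()].
#' @param binwidth Bin width in seconds (default 1).
#' @return A data frame with `time` (bin left edge, s) and `rate`
#'   (Hz per unit).
#' @export
population_rate <- function(rec, binwidth = 1) {
  if (!is.numeric(binwidth) || length(binwidth) != 1L || binwidth <= 0)
    stop("'binwidth' must be a single positive number")
  dur <- rec$summary$duration
  nbin <- as.integer(ceiling(dur / binwidth))
  bin <- pmin(floor(rec$spikes / binwidth), nbin - 1L) + 1L
  counts <- tabulate(bin, nbins = nbin)
  data.frame(time = (seq_len(nbin) - 1L) * binwidth,
             rate = counts / (n_units(rec) * binwidth))
}
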