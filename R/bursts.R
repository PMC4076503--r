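#' Burst-detection parameters
#'
#' Parameters of the fixed-threshold interspike-interval (ISI) burst
#' detector: a burst is a maximal run of consecutive spikes whose ISIs do
#' not exceed `max_isi`, kept only if it contains at least `min_spikes`
#' spikes; accepted runs separated by less than `merge_interval` are
#' merged into one burst.
#'
#' Defaults (`max_isi` 0.3 s, `min_spikes` 3, `merge_interval` 0.5 s) are
#' chosen to recover wave-driven bursts in developing retina, where units
#' fire dense volleys as a wave passes and are nearly silent in between.
#' All parameters are exposed so other ISI-threshold definitions from the
#' literature can be emulated.
#'
#' @param max_isi Maximum within-burst interspike interval, seconds.
#' @param min_spikes Minimum spikes per burst (at least 2).
#' @param merge_interval Runs closer than this (offset to next onset,
#'   seconds) are merged.
#' @return A list of class `burst_params`.
#' @export
burst_params <- function(max_isi = 0.3, min_spikes = 3, merge_interval = 0.5) {
  stopifnot(is.numeric(max_isi), max_isi > 0,
            is.numeric(merge_interval), merge_interval > 0,
            is.numeric(min_spikes), min_spikes >= 2)
  structure(list(max_isi = max_isi, min_spikes = as.integer(min_spikes),
                 merge_interval = merge_interval),
            class = "burst_params")
}

.empty_bursts <- function() {
  data.frame(unit = integer(), onset = numeric(), offset = numeric(),
             n_spikes = integer(), duration = numeric())
}

#' Detect bursts in one spike train
#'
#' Applies the ISI-threshold detector of [burst_params()] to a single
#' sorted spike train.
#'
#' @param train Sorted numeric vector of spike times, seconds.
#' @param params A [burst_params()] object.
#' @return A data frame with one row per burst: `onset`, `offset`
#'   (first/last spike time, s), `n_spikes`, and
#'   `duration = offset - onset`.
#' @examples
#' train <- c(0, 0.02, 0.04, 0.06, 0.08, 5, 5.02, 5.04, 5.06, 5.08)
#' detect_bursts(train, burst_params())
#' @export
detect_bursts <- function(train, params = burst_params()) {
  stopifnot(inherits(params, "burst_params"))
  train <- as.double(train)
  n <- length(train)
  out0 <- .empty_bursts()[, -1L]  # per-train result has no unit column
  if (n == 0L) return(out0)
  if (is.unsorted(train)) stop("spike train must be sorted ascending")

  # maximal runs with ISI <= max_isi
  grp <- cumsum(c(1L, as.integer(diff(train) > params$max_isi)))
  first <- which(!duplicated(grp))
  last <- c(first[-1L] - 1L, n)
  len <- last - first + 1L
  keep <- len >= params$min_spikes
  first <- first[keep]; last <- last[keep]
  if (!length(first)) return(out0)

  # merge accepted runs separated by < merge_interval
  onset <- train[first]; offset <- train[last]
  m_first <- first[1L]; m_last <- last[1L]
  res_first <- integer(); res_last <- integer()
  if (length(first) > 1L) {
    for (k in 2L:length(first)) {
      if (onset[k] - train[m_last] < params$merge_interval) {
        m_last <- last[k]
      } else {
        res_first <- c(res_first, m_first); res_last <- c(res_last, m_last)
        m_first <- first[k]; m_last <- last[k]
      }
    }
  }
  res_first <- c(res_first, m_first); res_last <- c(res_last, m_last)

  # merged bursts span every spike between their first and last member
  data.frame(onset = train[res_first], offset = train[res_last],
             n_spikes = res_last - res_first + 1L,
             duration = train[res_last] - train[res_first])
}

#' Detect bursts in every unit of a recording
#'
#' @param rec A valid [mea_recording()].
#' @param params A [burst_params()] object.
#' @return A data frame with one row per burst and columns `unit`,
#'   `onset`, `offset`, `n_spikes`, `duration`, ordered by unit then
#'   onset.
#' @export
detect_bursts_recording <- function(rec, params = burst_params()) {
  per_unit <- lapply(seq_len(n_units(rec)), function(j) {
    b <- detect_bursts(unit_spikes(rec, j), params)
    if (nrow(b)) cbind(unit = j, b) else NULL
  })
  per_unit <- per_unit[!vapply(per_unit, is.null, logical(1L))]
  if (!length(per_unit)) return(.empty_bursts())
  out <- do.call(rbind, per_unit)
  rownames(out) <- NULL
  out
}

#' Empirical CDF of burst durations per group
#'
#' Builds the cumulative distribution of burst durations for each labelled
#' group of bursts (typically one group per recording or per laboratory),
#' in a form suitable for step-plot rendering or CSV export.
#'
#' @param bursts_by_group Named list mapping a label to either a burst
#'   data frame (from [detect_bursts_recording()]) or a numeric vector of
#'   durations.  Every group must contain at least one burst.
#' @return A data frame with columns `label`, `duration` (sorted within
#'   label) and `cdf` (`k/n`, reaching exactly 1 at each group's longest
#'   burst).
#' @export
duration_cdf <- function(bursts_by_group) {
  if (!is.list(bursts_by_group) || !length(bursts_by_group) ||
      is.null(names(bursts_by_group)) || any(!nzchar(names(bursts_by_group))))
    stop("'bursts_by_group' must be a non-empty named list")
  out <- lapply(names(bursts_by_group), function(lab) {
    x <- bursts_by_group[[lab]]
    d <- if (is.data.frame(x)) x$duration else as.numeric(x)
    if (!length(d)) stop("group '", lab, "' contains no bursts")
    d <- sort(d)
    data.frame(label = lab, duration = d, cdf = seq_along(d) / length(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
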