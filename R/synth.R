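# Synthetic recordings: standard array layouts, a propagating-wave
# generative model, and homogeneous Poisson null controls.  Everything is
# seeded and leaves the caller's RNG untouched.

.layout_names <- c("MCS_8x8_100um", "MCS_8x8_200um", "APS_64x64_42um",
                   "hex_60um_61", "hex_60um_512")

.square_layout <- function(n, spacing, drop_corners = FALSE) {
  g <- expand.grid(col = seq_len(n) - 1L, row = seq_len(n) - 1L)
  if (drop_corners) {
    corner <- (g$col %in% c(0L, n - 1L)) & (g$row %in% c(0L, n - 1L))
    g <- g[!corner, , drop = FALSE]
  }
  cbind(x = g$col * spacing, y = g$row * spacing)
}

# Triangular lattice with given nearest-neighbour spacing; sites ranked by
# distance from the patch centre (ties broken by angle then coordinates)
# and trimmed to n_sites.
.hex_layout <- function(n_sites, spacing = 60) {
  k <- 1L
  while (1L + 3L * k * (k + 1L) < n_sites) k <- k + 1L
  qr <- expand.grid(q = -k:k, r = -k:k)
  qr <- qr[abs(qr$q + qr$r) <= k, , drop = FALSE]
  x <- spacing * (qr$q + qr$r / 2)
  y <- spacing * (sqrt(3) / 2) * qr$r
  d <- sqrt(x^2 + y^2)
  ord <- order(round(d, 9), round(atan2(y, x), 9), x, y)
  sel <- ord[seq_len(n_sites)]
  cbind(x = x[sel] - min(x[sel]), y = y[sel] - min(y[sel]))
}

#' Electrode positions of a standard MEA layout
#'
#' Generates the electrode coordinates of the array layouts used in the
#' repository: the two Multi Channel Systems 8 x 8 lattices (60 sites,
#' corners missing, 100 or 200 micrometre pitch), the high-density
#' 64 x 64 active-pixel sensor array (4096 sites, 42 micrometre pitch),
#' and hexagonal (triangular-lattice) arrays with 60 micrometre
#' nearest-neighbour spacing trimmed to 61 or 512 sites.
#'
#' @param name One of `"MCS_8x8_100um"`, `"MCS_8x8_200um"`,
#'   `"APS_64x64_42um"`, `"hex_60um_61"`, `"hex_60um_512"`.
#' @return A numeric matrix with columns `x`, `y` (micrometres), one row
#'   per electrode.
#' @examples
#' nrow(make_layout("MCS_8x8_100um"))   # 60
#' nrow(make_layout("APS_64x64_42um"))  # 4096
#' @export
make_layout <- function(name) {
  switch(name,
    MCS_8x8_100um = .square_layout(8L, 100, drop_corners = TRUE),
    MCS_8x8_200um = .square_layout(8L, 200, drop_corners = TRUE),
    APS_64x64_42um = .square_layout(64L, 42),
    hex_60um_61 = .hex_layout(61L),
    hex_60um_512 = .hex_layout(512L),
    stop("unknown layout '", name, "'; supported: ",
         paste(.layout_names, collapse = ", ")))
}

#' Parameters of the retinal-wave simulator
#'
#' @param layout Array layout name (see [make_layout()]).
#' @param duration Recording length T, seconds.
#' @param wave_rate Wave initiation rate (waves/s); initiation is Poisson
#'   in time and uniform in space over the array bounding box.
#' @param speed Wavefront propagation speed, micrometres/s.
#' @param burst_rate Within-burst firing rate of a unit swept by a wave,
#'   Hz.
#' @param burst_duration Length of the wave-evoked burst at one unit,
#'   seconds.
#' @param bg_rate Background (between-wave) firing rate per unit, Hz.
#' @param refractory Minimum interval between successive wave-evoked
#'   bursts at one unit, seconds; wavefront arrivals during this window
#'   do not trigger a burst.
#' @param seed Mandatory RNG seed.
#' @return A list of class `wave_sim_params`.
#' @seealso [simulate_waves()]
#' @export
wave_sim_params <- function(layout = "MCS_8x8_100um", duration = 1800,
                            wave_rate = 0.02, speed = 200, burst_rate = 30,
                            burst_duration = 1, bg_rate = 0.05,
                            refractory = 5, seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  for (p in c("duration", "wave_rate", "speed", "burst_rate",
              "burst_duration", "bg_rate", "refractory")) {
    val <- get(p)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0)
      stop("'", p, "' must be a single non-negative number")
  }
  if (duration <= 0) stop("'duration' must be positive")
  if (speed <= 0) stop("'speed' must be positive")
  structure(list(layout = layout, duration = duration, wave_rate = wave_rate,
                 speed = speed, burst_rate = burst_rate,
                 burst_duration = burst_duration, bg_rate = bg_rate,
                 refractory = refractory, seed = seed),
            class = "wave_sim_params")
}

.synth_meta <- function() mea_metadata("synthetic", "synthetic", age = 0L)

.build_synth_recording <- function(trains, epos, array) {
  trains <- lapply(trains, function(t) sort(as.double(t)))
  mea_recording(epos = epos,
                spikes = unlist(trains, use.names = FALSE),
                sCount = lengths(trains),
                array = array, meta = .synth_meta())
}

#' Simulate a propagating-wave recording
#'
#' Event-level generative model of retinal waves on an MEA: wave origins
#' arise as a Poisson process in time (rate `wave_rate`), uniformly
#' placed over the array bounding box; a circular wavefront expands at
#' constant `speed`, and when it reaches a unit the unit emits a Poisson
#' burst (`burst_rate` Hz for `burst_duration` s) unless it is within
#' `refractory` s of its previous wave response.  Independent background
#' spiking at `bg_rate` Hz is superimposed throughout.  Spike times are
#' truncated to `[0, duration)` and sorted per unit.
#'
#' The result is periodic array-wide elevations in population rate
#' separated by near-silence, and pairwise correlation indices that decay
#' with inter-unit distance — the statistical signature of retinal waves.
#'
#' @param params A [wave_sim_params()] object (the seed is mandatory).
#' @return A valid [mea_recording()] with metadata
#'   `key = "synthetic"`, `species = "synthetic"`, `age = 0`.
#' @examples
#' rec <- simulate_waves(wave_sim_params(duration = 300, seed = 1))
#' rec$summary$N
#' @export
simulate_waves <- function(params) {
  stopifnot(inherits(params, "wave_sim_params"))
  epos <- make_layout(params$layout)
  N <- nrow(epos)
  T <- params$duration
  with_seed(params$seed, {
    n_waves <- rpois(1L, params$wave_rate * T)
    wave_t <- sort(runif(n_waves, 0, T))
    wave_x <- runif(n_waves, min(epos[, 1L]), max(epos[, 1L]))
    wave_y <- runif(n_waves, min(epos[, 2L]), max(epos[, 2L]))
    trains <- vector("list", N)
    for (u in seq_len(N)) {
      spk <- if (params$bg_rate > 0)
        runif(rpois(1L, params$bg_rate * T), 0, T) else numeric(0)
      if (n_waves > 0L) {
        arrive <- wave_t + sqrt((wave_x - epos[u, 1L])^2 +
                                (wave_y - epos[u, 2L])^2) / params$speed
        last <- -Inf
        for (t0 in arrive) {        # arrivals are already time-ordered
          if (t0 - last < params$refractory) next
          last <- t0
          nb <- rpois(1L, params$burst_rate * params$burst_duration)
          if (nb > 0L)
            spk <- c(spk, t0 + runif(nb, 0, params$burst_duration))
        }
      }
      trains[[u]] <- spk[spk >= 0 & spk < T]
    }
    .build_synth_recording(trains, epos, params$layout)
  })
}

#' Simulate independent homogeneous Poisson trains
#'
#' Null control: every unit fires as an independent homogeneous Poisson
#' process at the same rate, with no spatial structure.  Pairwise
#' correlation indices have expectation 1.
#'
#' @param rate Firing rate per unit, Hz (non-negative).
#' @param duration Recording length, seconds.
#' @param layout Array layout name (see [make_layout()]).
#' @param seed Mandatory RNG seed.
#' @return A valid [mea_recording()].  With `rate = 0` no spikes are
#'   generated and the summary duration is undefined, so an error is
#'   raised.
#' @export
simulate_poisson <- function(rate, duration, layout = "MCS_8x8_100um",
                             seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0,
            is.numeric(duration), length(duration) == 1L, duration > 0)
  epos <- make_layout(layout)
  with_seed(seed, {
    trains <- lapply(seq_len(nrow(epos)), function(u)
      runif(rpois(1L, rate * duration), 0, duration))
    .build_synth_recording(trains, epos, layout)
  })
}
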