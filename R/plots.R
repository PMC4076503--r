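# Diagnostic figures.  Every figure has a machine-readable companion: the
# *_data() functions return exactly the numbers drawn, so tests and
# exports never depend on the rendering backend.

.open_device <- function(file, width = 8, height = 8) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    png = grDevices::png(file, width = width, height = height,
                         units = "in", res = 150),
    pdf = grDevices::pdf(file, width = width, height = height),
    svg = grDevices::svg(file, width = width, height = height),
    stop("unsupported image format '.", ext, "'; use .png, .pdf or .svg"))
}

# On a log axis zero CI values cannot be drawn; place them at half the
# smallest positive value and flag them.
.floor_log_zeros <- function(ci) {
  pos <- ci[is.finite(ci) & ci > 0]
  floor_val <- if (length(pos)) min(pos) / 2 else NA_real_
  floored <- is.finite(ci) & ci == 0
  list(y = ifelse(floored, floor_val, ci), floored = floored)
}

#' Panel data of the four-panel recording overview
#'
#' Computes the numbers behind each panel of [fourplot()]: unit
#' positions, the 1-s-binned population rate, the raster (every spike
#' with its unit index) and the pairwise correlation-index-vs-distance
#' scatter.  With fewer than two units the correlation panel is `NULL`.
#'
#' @param rec A valid [mea_recording()].
#' @param dt Coincidence half-window for the correlation panel, seconds.
#' @return A list with elements `title`, `positions`, `poprate`,
#'   `raster` and `ci` (possibly `NULL`).
#' @export
fourplot_data <- function(rec, dt = 0.05) {
  N <- n_units(rec)
  raster <- data.frame(
    unit = rep.int(seq_len(N), rec$sCount),
    time = rec$spikes)
  ci <- if (N >= 2L) ci_map(rec, dt = dt)
  list(title = rec$meta$key,
       positions = data.frame(unit = seq_len(N),
                              x = rec$epos[, 1L], y = rec$epos[, 2L]),
       poprate = population_rate(rec, binwidth = 1),
       raster = raster,
       ci = ci)
}

#' Four-panel quality-control overview of one recording
#'
#' The one-page summary plot used to screen a recording: (A) estimated
#' unit positions labelled by unit number — overlapping numbers mean
#' several units share a position; (B) population firing rate in 1 s
#' bins averaged across the array, where periodic elevations separated by
#' silence are the signature of retinal waves; (C) the spike raster,
#' unit 1 at the bottom; (D) correlation index against inter-unit
#' distance on a logarithmic y axis.  With fewer than two units, panel D
#' is annotated as unavailable.
#'
#' @param rec A valid [mea_recording()].
#' @param file Output image path (`.png`, `.pdf` or `.svg`); `NULL` draws
#'   on the current device.
#' @param dt Coincidence half-window for panel D, seconds.
#' @param title Plot title; defaults to the recording's metadata key.
#' @param export Optional path of a JSON export of the plotted numbers.
#' @return The [fourplot_data()] list, invisibly.
#' @export
fourplot <- function(rec, file = NULL, dt = 0.05, title = NULL,
                     export = NULL) {
  dat <- fourplot_data(rec, dt = dt)
  if (!is.null(title)) dat$title <- title
  if (!is.null(export))
    jsonlite::write_json(dat, export, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (!is.null(file)) {
    .open_device(file)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1),
                      oma = c(0, 0, 2, 0))
  on.exit(graphics::par(op), add = TRUE)

  p <- dat$positions
  graphics::plot(p$x, p$y, type = "n", xlab = "x (um)", ylab = "y (um)",
                 main = "A: unit positions", asp = 1)
  graphics::text(p$x, p$y, labels = p$unit, cex = 0.6)

  graphics::plot(dat$poprate$time, dat$poprate$rate, type = "l",
                 xlab = "time (s)", ylab = "rate (Hz/unit)",
                 main = "B: population rate (1 s bins)")

  graphics::plot(dat$raster$time, dat$raster$unit, pch = ".",
                 xlab = "time (s)", ylab = "unit",
                 main = "C: raster", ylim = c(0.5, n_units(rec) + 0.5))

  if (!is.null(dat$ci) && any(is.finite(dat$ci$ci))) {
    fl <- .floor_log_zeros(dat$ci$ci)
    ok <- is.finite(fl$y) & fl$y > 0
    graphics::plot(dat$ci$distance[ok], fl$y[ok], log = "y",
                   xlab = "distance (um)", ylab = "correlation index",
                   main = "D: correlation index", pch = 20, cex = 0.5)
  } else {
    graphics::plot.new()
    graphics::title(main = "D: correlation index")
    graphics::text(0.5, 0.5, "unavailable (fewer than 2 active units)")
  }
  graphics::mtext(dat$title, outer = TRUE, cex = 1.1)
  invisible(dat)
}

#' Flatten grouped binned-CI curves to a long table
#'
#' @param groups Named list mapping a group label to one binned-CI data
#'   frame (from [bin_ci_by_distance()]) or to a list of them (one per
#'   recording).
#' @return Long data frame: `group`, `recording`, `left`, `centre`,
#'   `mean_ci`, `n_pairs`, `plot_y` (CI with zeros floored for the log
#'   axis) and `floored`.
#' @export
ci_family_data <- function(groups) {
  if (!is.list(groups) || !length(groups) || is.null(names(groups)))
    stop("'groups' must be a non-empty named list")
  rows <- list()
  for (g in names(groups)) {
    el <- groups[[g]]
    curves <- if (is.data.frame(el)) list(el) else el
    for (k in seq_along(curves)) {
      cur <- curves[[k]]
      id <- names(curves)[k]
      if (is.null(id) || !nzchar(id)) id <- sprintf("%s_%d", g, k)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, recording = id, left = cur$left, centre = cur$centre,
        mean_ci = cur$mean_ci, n_pairs = cur$n_pairs)
    }
  }
  out <- do.call(rbind, rows)
  fl <- .floor_log_zeros(out$mean_ci)
  out$plot_y <- fl$y
  out$floored <- fl$floored
  rownames(out) <- NULL
  out
}

#' Family of binned correlation-index curves
#'
#' Draws one line per recording — mean correlation index in fixed-width
#' distance bins — coloured by group label (e.g. genotype), with a
#' logarithmic y axis.  Used to compare the spatial range of correlated
#' activity across genotypes or conditions.
#'
#' @inheritParams ci_family_data
#' @param file Output image path (`.png`, `.pdf`, `.svg`); `NULL` draws
#'   on the current device.
#' @param export Optional CSV path for the plotted numbers.
#' @return The [ci_family_data()] long data frame, invisibly.
#' @export
ci_family_plot <- function(groups, file = NULL, export = NULL) {
  dat <- ci_family_data(groups)
  if (!is.null(export))
    utils::write.csv(dat, export, row.names = FALSE)
  if (!is.null(file)) {
    .open_device(file, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  labs <- unique(dat$group)
  cols <- grDevices::hcl.colors(max(2L, length(labs)), "Dark 2")
  ok <- is.finite(dat$plot_y) & dat$plot_y > 0
  graphics::plot(range(dat$centre), range(dat$plot_y[ok]), type = "n",
                 log = "y", xlab = "distance (um)",
                 ylab = "mean correlation index",
                 main = "Correlation index vs distance")
  for (id in unique(dat$recording)) {
    sub <- dat[dat$recording == id & ok, , drop = FALSE]
    graphics::lines(sub$centre, sub$plot_y,
                    col = cols[match(sub$group[1L], labs)])
  }
  graphics::legend("topright", legend = labs,
                   col = cols[seq_along(labs)], lty = 1, bty = "n")
  invisible(dat)
}
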