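#' Catalogue a directory of recordings
#'
#' Recursively scans a directory for `*.h5` files and builds the
#' repository inventory: one row per readable recording with its path,
#' metadata, array label and summary figures.  Summaries are taken from
#' the `/summary` cache (recomputed by the reader when absent); missing
#' `genotype`/`cond` metadata appear as their defaults.
#'
#' @param dir Directory to scan.
#' @param on_error `"skip"` (default): unreadable files are dropped with
#'   a warning; `"fail"`: the first unreadable file raises an error.
#' @return A data frame with columns `path`, `key`, `species`, `age`,
#'   `genotype`, `cond`, `array`, `N`, `duration`, `totalspikes`,
#'   `mean_rate` (Hz) and `bytes`, ordered lexicographically by path.
#' @seealso [count_recordings()], [overview_stats()]
#' @export
scan_mea_directory <- function(dir, on_error = c("skip", "fail")) {
  on_error <- match.arg(on_error)
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- sort(list.files(dir, pattern = "\\.h5$", recursive = TRUE,
                           full.names = TRUE))
  rows <- lapply(files, function(f) {
    rec <- tryCatch(read_mea_h5(f), error = function(e) e)
    if (inherits(rec, "error")) {
      if (on_error == "fail")
        stop("failed to read ", f, ": ", conditionMessage(rec))
      warning("skipping unreadable file ", f, ": ",
              conditionMessage(rec), call. = FALSE)
      return(NULL)
    }
    s <- rec$summary
    data.frame(path = f, key = rec$meta$key, species = rec$meta$species,
               age = rec$meta$age, genotype = rec$meta$genotype,
               cond = rec$meta$cond, array = rec$array, N = s$N,
               duration = s$duration, totalspikes = s$totalspikes,
               mean_rate = mean(s$frate), bytes = file.size(f),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows))
    return(data.frame(path = character(), key = character(),
                      species = character(), age = integer(),
                      genotype = character(), cond = character(),
                      array = character(), N = integer(),
                      duration = integer(), totalspikes = integer(),
                      mean_rate = numeric(), bytes = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.catalog_fields <- c("key", "species", "age", "genotype", "cond", "array")

#' Contingency table of recordings over metadata fields
#'
#' Counts catalogue rows for each unique combination of the requested
#' metadata fields — the repository inventory tables (recordings per
#' species, per study and age, per genotype, per condition).  Age levels
#' sort ascending numerically, which places the adult sentinel (500)
#' last.
#'
#' @param rows Catalogue data frame from [scan_mea_directory()].
#' @param by Character vector of one or more field names among
#'   `key`, `species`, `age`, `genotype`, `cond`, `array`.
#' @return A `table` with one dimension per field; cell counts sum to
#'   `nrow(rows)`.
#' @examples \dontrun{
#' rows <- scan_mea_directory("repository/")
#' count_recordings(rows, "species")
#' count_recordings(rows, c("key", "age"))
#' }
#' @export
count_recordings <- function(rows, by) {
  bad <- setdiff(by, .catalog_fields)
  if (length(bad))
    stop("unknown field(s): ", paste(bad, collapse = ", "),
         "; choose from ", paste(.catalog_fields, collapse = ", "))
  if (!length(by)) stop("'by' must name at least one field")
  cols <- lapply(by, function(f) {
    v <- rows[[f]]
    if (f == "age") factor(v, levels = sort(unique(v))) else factor(v)
  })
  names(cols) <- by
  table(cols)
}

#' Repository overview statistics
#'
#' Per-recording (number of spike trains, duration) pairs — the scatter
#' data of the repository overview figure, plotted on log axes — plus the
#' total number of recordings and total bytes on disc.
#'
#' @param rows Catalogue data frame from [scan_mea_directory()]; must be
#'   non-empty.
#' @return A list with `points` (data frame `path`, `N`, `duration`,
#'   `key`), `n_recordings` and `total_bytes`.
#' @export
overview_stats <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L)
    stop("'rows' must contain at least one recording")
  list(points = rows[, c("path", "N", "duration", "key")],
       n_recordings = nrow(rows),
       total_bytes = sum(rows$bytes))
}
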