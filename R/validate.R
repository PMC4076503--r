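# Known vocabulary, seeded from the repository's inventory tables.  These
# are open sets: unseen labels are reported as warnings, never errors.
.known_arrays <- c(
  "MCS_8x8_100um", "MCS_8x8_200um", "APS_64x64_42um",
  "litke_hex_60um", "EJC1_hex_60um", "stanford_hex_60um",
  "hex_60um_61", "hex_60um_512")
.known_species <- c("mouse", "ferret", "synthetic")

.violation <- function(code, message, severity = "error") {
  data.frame(code = code, severity = severity, message = message,
             stringsAsFactors = FALSE)
}

.no_violations <- function() {
  data.frame(code = character(), severity = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a recording against the schema invariants
#'
#' Checks every invariant of the container format: shape and finiteness of
#' the position matrix, consistency of `sCount` with the concatenated
#' spike vector, per-train sort order, non-negative finite spike times,
#' metadata presence and types, and agreement of the `/summary` cache
#' with the raw data.  Unrecognised `array` or `species` labels produce
#' warnings (the vocabulary is an open set), never errors.
#'
#' @param x An [mea_recording()] object, or the path of an HDF5 file.
#'   When a path is given, missing required datasets are reported as
#'   `SCHEMA_MISSING` violations; an unreadable or non-HDF5 file raises an
#'   ordinary error instead.
#' @return A data frame of violations with columns `code`, `severity`
#'   (`"error"` or `"warning"`) and `message`; zero rows when the
#'   recording is fully conformant.
#' @examples
#' rec <- mea_recording(cbind(0, 0), c(1, 2.5), 2, "MCS_8x8_100um",
#'                      mea_metadata("demo", "mouse", 5))
#' validate_mea(rec)            # no violations
#' rec$sCount <- 3L             # break the length invariant
#' validate_mea(rec)$code
#' @export
validate_mea <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("file not found: ", x)
    if (!rhdf5::H5Fis_hdf5(x)) stop("not an HDF5 file: ", x)
    rec <- tryCatch(read_mea_h5(x), error = function(e) e)
    if (inherits(rec, "error")) {
      msg <- conditionMessage(rec)
      if (grepl("schema error", msg))
        return(.violation("SCHEMA_MISSING", msg))
      stop(rec)
    }
    return(validate_mea(rec))
  }
  rec <- x
  v <- .no_violations()
  add <- function(code, message, severity = "error")
    v <<- rbind(v, .violation(code, message, severity))

  N <- length(rec$sCount)
  epos <- rec$epos
  if (!is.matrix(epos) || ncol(epos) != 2L || nrow(epos) != N)
    add("EPOS_SHAPE", sprintf(
      "epos must be an N x 2 matrix with N = length(sCount) = %d", N))
  else if (!all(is.finite(epos)))
    add("EPOS_NONFINITE", "epos contains non-finite positions")

  if (any(is.na(rec$sCount)) || any(rec$sCount < 0L))
    add("SCOUNT_NEGATIVE", "sCount entries must be >= 0")
  else if (length(rec$spikes) != sum(rec$sCount))
    add("SPIKES_LEN_MISMATCH", sprintf(
      "length(spikes) = %d but sum(sCount) = %d",
      length(rec$spikes), sum(rec$sCount)))
  else {
    if (!all(is.finite(rec$spikes)))
      add("SPIKES_NONFINITE", "spike times must be finite")
    else {
      if (any(rec$spikes < 0))
        add("SPIKES_NEGATIVE", "spike times must be >= 0")
      unsorted <- which(vapply(seq_len(N), function(j)
        is.unsorted(unit_spikes(rec, j)), logical(1L)))
      if (length(unsorted))
        add("TRAIN_UNSORTED", paste0(
          "spike times not sorted within unit(s) ",
          paste(unsorted, collapse = ", ")))
    }
  }

  if (!is.null(rec$names) && length(rec$names) != N)
    add("NAMES_LEN_MISMATCH", sprintf(
      "names has length %d, expected N = %d", length(rec$names), N))

  m <- rec$meta
  if (is.null(m$key) || !nzchar(m$key))
    add("META_MISSING_KEY", "/meta/key must be a non-empty string")
  if (is.null(m$species) || !nzchar(m$species))
    add("META_MISSING_SPECIES", "/meta/species must be a non-empty string")
  else if (!tolower(m$species) %in% .known_species)
    add("META_SPECIES_UNSEEN", sprintf(
      "species '%s' not in the known vocabulary", m$species), "warning")
  if (is.null(m$age) || !is.finite(m$age) || m$age != round(m$age))
    add("META_AGE_NOT_INTEGER", "/meta/age must be an integer day count")

  if (is.null(rec$array) || !nzchar(rec$array))
    add("ARRAY_MISSING", "array label must be a non-empty string")
  else if (!rec$array %in% .known_arrays)
    add("ARRAY_UNSEEN", sprintf(
      "array '%s' not in the known vocabulary", rec$array), "warning")

  s <- rec$summary
  if (is.null(s)) {
    add("SUMMARY_MISSING", "summary block absent")
  } else if (length(rec$spikes) == sum(rec$sCount) &&
             all(is.finite(rec$spikes))) {
    if (s$N != N)
      add("SUMMARY_N_WRONG", sprintf(
        "/summary/N = %d but recording has %d units", s$N, N))
    if (sum(rec$sCount) == 0L) {
      add("NO_SPIKES", "recording has no spikes; duration is undefined")
    } else {
      want <- as.integer(ceiling(max(rec$spikes)))
      if (s$duration != want)
        add("SUMMARY_DURATION_WRONG", sprintf(
          "/summary/duration = %d but ceiling(max spike time) = %d",
          s$duration, want))
      if (s$totalspikes != sum(rec$sCount))
        add("SUMMARY_TOTALSPIKES_WRONG", sprintf(
          "/summary/totalspikes = %d but sum(sCount) = %d",
          s$totalspikes, sum(rec$sCount)))
      if (length(s$frate) != N ||
          !isTRUE(all.equal(s$frate * s$duration, as.double(rec$sCount),
                            tolerance = 1e-9)))
        add("SUMMARY_FRATE_WRONG",
            "/summary/frate inconsistent with sCount / duration")
    }
  }
  v
}

#' Does a recording pass validation?
#'
#' @param x Recording or file path, as in [validate_mea()].
#' @return `TRUE` iff [validate_mea()] reports no `"error"`-severity
#'   violations (warnings about unseen vocabulary are allowed).
#' @export
is_valid_mea <- function(x) {
  v <- validate_mea(x)
  !any(v$severity == "error")
}
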