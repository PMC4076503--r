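# HDF5 schema for one recording.  Root datasets: epos (N x 2), sCount,
# spikes, array, optional names.  Groups: /meta/{key,species,age,genotype,
# cond} and /summary/{N,duration,frate,totalspikes}.  Spike times and
# firing rates are 64-bit IEEE floats, counts and ages 64-bit integers,
# strings variable-length UTF-8.

.meta_required <- c("key", "species", "age")
.root_required <- c("epos", "sCount", "spikes", "array")

.h5_names <- function(path) {
  ls <- rhdf5::h5ls(path)
  ifelse(ls$group == "/", ls$name,
         paste(sub("^/", "", ls$group), ls$name, sep = "/"))
}

.h5_scalar <- function(path, name) {
  x <- rhdf5::h5read(path, name, bit64conversion = "double")
  as.vector(x)[1L]
}

#' Read a recording from an HDF5 file
#'
#' Loads the root datasets and the `/meta` and `/summary` groups.  Absent
#' `genotype`/`cond` metadata materialise as their defaults (`"wt"`,
#' `"ctl"`); an absent `/summary` group is recomputed from the spike
#' trains.  `epos` stored as 2 x N (files written from row-major
#' environments) is transposed to N x 2 on load; an ambiguous 2 x 2 matrix
#' is taken as-is.
#'
#' @param path Path to an HDF5 recording file.
#' @return An [mea_recording()] object.
#' @seealso [write_mea_h5()], [validate_mea()]
#' @export
read_mea_h5 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!rhdf5::H5Fis_hdf5(path)) stop("not an HDF5 file: ", path)
  present <- .h5_names(path)
  need <- c(.root_required, paste0("meta/", .meta_required))
  miss <- setdiff(need, present)
  if (length(miss))
    stop("schema error: missing dataset(s) ", paste(miss, collapse = ", "),
         " in ", path)

  epos <- rhdf5::h5read(path, "epos")
  epos <- as.matrix(epos)
  storage.mode(epos) <- "double"
  if (ncol(epos) != 2L) {
    if (nrow(epos) == 2L) epos <- t(epos)
    else stop("schema error: epos has shape ", nrow(epos), " x ", ncol(epos),
              ", expected N x 2")
  }

  sCount <- as.integer(rhdf5::h5read(path, "sCount",
                                     bit64conversion = "double"))
  spikes <- as.double(rhdf5::h5read(path, "spikes"))
  array <- .h5_scalar(path, "array")
  nms <- if ("names" %in% present)
    as.character(rhdf5::h5read(path, "names"))

  meta <- mea_metadata(
    key = .h5_scalar(path, "meta/key"),
    species = .h5_scalar(path, "meta/species"),
    age = .h5_scalar(path, "meta/age"),
    genotype = if ("meta/genotype" %in% present)
      .h5_scalar(path, "meta/genotype") else "wt",
    cond = if ("meta/cond" %in% present)
      .h5_scalar(path, "meta/cond") else "ctl")

  summary <- if (all(paste0("summary/", c("N", "duration", "frate",
                                          "totalspikes")) %in% present)) {
    structure(list(
      N = as.integer(.h5_scalar(path, "summary/N")),
      duration = as.integer(.h5_scalar(path, "summary/duration")),
      frate = as.double(rhdf5::h5read(path, "summary/frate")),
      totalspikes = as.integer(.h5_scalar(path, "summary/totalspikes"))),
      class = "mea_summary")
  }

  mea_recording(epos = epos, spikes = spikes, sCount = sCount,
                array = array, meta = meta, names = nms, summary = summary)
}

.h5_write_string <- function(x, file, name) {
  rhdf5::h5write(as.character(x), file, name,
                 variableLengthString = TRUE, encoding = "UTF-8")
}

.h5_write_int64 <- function(x, file, name) {
  rhdf5::h5createDataset(file, name, dims = length(x),
                         H5type = "H5T_STD_I64LE")
  rhdf5::h5write(as.integer(x), file, name)
}

#' Write a recording to an HDF5 file
#'
#' Serialises a recording into the container schema.  The recording is
#' validated first and writing is refused (with the violations in the
#' error message) if any invariant fails.  The `names` dataset is only
#' written when unit names are present.
#'
#' @param rec An [mea_recording()] object.
#' @param path Output file path; overwritten if it exists.
#' @return `path`, invisibly.
#' @seealso [read_mea_h5()]
#' @export
write_mea_h5 <- function(rec, path) {
  v <- validate_mea(rec)
  bad <- v[v$severity == "error", , drop = FALSE]
  if (nrow(bad))
    stop("refusing to write invalid recording:\n  ",
         paste(sprintf("[%s] %s", bad$code, bad$message), collapse = "\n  "))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  rhdf5::h5write(rec$epos, path, "epos")
  .h5_write_int64(rec$sCount, path, "sCount")
  rhdf5::h5write(as.double(rec$spikes), path, "spikes")
  .h5_write_string(rec$array, path, "array")
  if (!is.null(rec$names)) .h5_write_string(rec$names, path, "names")

  rhdf5::h5createGroup(path, "meta")
  .h5_write_string(rec$meta$key, path, "meta/key")
  .h5_write_string(rec$meta$species, path, "meta/species")
  .h5_write_int64(rec$meta$age, path, "meta/age")
  .h5_write_string(rec$meta$genotype, path, "meta/genotype")
  .h5_write_string(rec$meta$cond, path, "meta/cond")

  s <- rec$summary
  rhdf5::h5createGroup(path, "summary")
  .h5_write_int64(s$N, path, "summary/N")
  .h5_write_int64(s$duration, path, "summary/duration")
  rhdf5::h5write(as.double(s$frate), path, "summary/frate")
  .h5_write_int64(s$totalspikes, path, "summary/totalspikes")
  invisible(path)
}
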