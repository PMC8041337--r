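#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti preserving the voxel-to-world affine
#' exactly and the data within float32 on a round trip.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti` returns a `volume_image`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("failed to parse NIfTI file ", path, ": ", conditionMessage(e)))
  aff <- structure(RNifti::xform(img), class = NULL)
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  volume_image(arr, matrix(aff, 4, 4))
}

#' @rdname read_nifti
#' @param img A `volume_image`.
#' @param datatype NIfTI storage type (default `"float"`; use `"int32"`
#'   for count images).
#' @export
write_nifti <- function(img, path, datatype = "float") {
  stopifnot(inherits(img, "volume_image"))
  dat <- img$data
  if (datatype %in% c("int32", "int16")) {
    dat[is.na(dat)] <- 0
    storage.mode(dat) <- "integer"
  }
  nim <- RNifti::asNifti(dat)
  nim <- RNifti::`sform<-`(nim, structure(img$affine, code = 2L))
  RNifti::writeNifti(nim, path, datatype = datatype)
  invisible(path)
}

#' Read / write TRK (TrackVis) streamline files
#'
#' Minimal TRK v2 reader/writer. Vertices are stored in the file's
#' "voxmm" convention and converted to world mm through the header's
#' voxel-to-RAS matrix the same way nibabel does:
#' `world = A %*% (voxmm / voxel_size - 0.5)`.
#'
#' @param path File path.
#' @return `read_trk` returns a `streamline_set` (world mm).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 5))
  invisible(readBin(con, "raw", 1))
  if (magic != "TRACK") stop("not a TRK file: ", path)
  dim_ <- readBin(con, "integer", 3, size = 2)
  voxel_size <- readBin(con, "numeric", 3, size = 4)
  origin <- readBin(con, "numeric", 3, size = 4)
  n_scalars <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  n_properties <- readBin(con, "integer", 1, size = 2)
  invisible(readBin(con, "raw", 200))
  vox2ras <- matrix(readBin(con, "numeric", 16, size = 4), 4, 4, byrow = TRUE)
  invisible(readBin(con, "raw", 444))
  invisible(readBin(con, "raw", 4))   # voxel_order
  invisible(readBin(con, "raw", 4))
  invisible(readBin(con, "numeric", 6, size = 4))
  invisible(readBin(con, "raw", 8))
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr_size <- readBin(con, "integer", 1, size = 4)
  if (hdr_size != 1000L) stop("malformed TRK header (hdr_size != 1000)")
  if (all(vox2ras == 0)) { vox2ras <- diag(4); vox2ras[1:3, 4] <- 0.5 }
  lines <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4)
    if (length(np) == 0) break
    vals <- readBin(con, "numeric", np * (3 + n_scalars) + n_properties,
                    size = 4)
    if (length(vals) < np * (3 + n_scalars) + n_properties)
      stop("truncated TRK stream in ", path)
    m <- matrix(vals[seq_len(np * (3 + n_scalars))],
                ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2, voxel_size, "/") - 0.5
    w <- cbind(vox, 1) %*% t(vox2ras)
    lines[[length(lines) + 1L]] <- w[, 1:3, drop = FALSE]
  }
  if (n_count > 0 && length(lines) != n_count)
    stop(sprintf("TRK stream count mismatch: header %d, found %d",
                 n_count, length(lines)))
  streamline_set(lines)
}

#' @rdname read_trk
#' @param s A `streamline_set` (world mm coordinates).
#' @export
write_trk <- function(s, path) {
  stopifnot(inherits(s, "streamline_set"))
  # unit voxels and A = [I | 0.5]: world = voxmm - 0.5 + 0.5 = voxmm,
  # so vertices are stored as-is and any reader honoring the affine
  # recovers world mm exactly
  vox2ras <- diag(4)
  vox2ras[1:3, 4] <- 0.5
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), as.raw(0)), con)
  writeBin(as.integer(c(1, 1, 1)), con, size = 2)
  writeBin(as.numeric(c(1, 1, 1)), con, size = 4)
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4)
  writeBin(0L, con, size = 2)
  writeBin(raw(200), con)
  writeBin(0L, con, size = 2)
  writeBin(raw(200), con)
  writeBin(as.numeric(t(vox2ras)), con, size = 4)
  writeBin(raw(444), con)
  writeBin(c(charToRaw("LPS"), as.raw(0)), con)
  writeBin(raw(4), con)
  writeBin(as.numeric(rep(0, 6)), con, size = 4)
  writeBin(raw(8), con)
  writeBin(length(s$streamlines), con, size = 4)
  writeBin(2L, con, size = 4)
  writeBin(1000L, con, size = 4)
  for (m in s$streamlines) {
    writeBin(nrow(m), con, size = 4)
    writeBin(as.numeric(t(m)), con, size = 4)
  }
  invisible(path)
}

#' Read a pipeline configuration
#'
#' Plain-text hierarchical key-value (YAML) configuration for
#' [run_pipeline()]. Referenced paths are checked at validation time.
#'
#' @param path YAML file path.
#' @return Named list of class `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg Named list of configuration values.
#' @export
validate_config <- function(cfg) {
  req <- c("output_dir", "seed")
  miss <- setdiff(req, names(cfg))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  if (!is.numeric(cfg$seed)) stop("seed must be an integer")
  defaults <- list(n_subjects = 5, n_hemispheres = 2, duration_s = 60,
                   fs = 300, sensor_snr = 1, grid_spacing = 5,
                   voxel_size = 2, brain_radius = 28, regularization = 0.05,
                   forming_p = 0.01, n_perm = 500, n_sensors = 24,
                   seed_radius = 3, band = "low_beta")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  for (k in c("recordings", "streamlines", "mask"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("config path does not exist: ", k, " = ", cfg[[k]])
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
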