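#' Intensity volume container
#'
#' A 3D scalar grid with an isotropic voxel size in micrometers. This is the
#' raw tomographic image on which all downstream analysis operates.
#'
#' @param data 3D numeric array of intensities.
#' @param voxel_size_um Positive scalar, isotropic voxel edge length (um).
#' @return An object of class `intensity_volume`: a list with elements
#'   `data` (the array) and `voxel_size_um`.
#' @export
intensity_volume <- function(data, voxel_size_um) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number")
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um)),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_volume> %d x %d x %d voxels @ %g um (range %g..%g)\n",
              d[1], d[2], d[3], x$voxel_size_um,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.intensity_volume <- function(x) dim(x$data)

is_intensity_volume <- function(x) inherits(x, "intensity_volume")

#' Read a volume from disk
#'
#' Supported formats: the package's native chunked store (a directory of flat
#' float64 chunk files plus JSON metadata), single-file NIfTI-1, and a
#' directory of single-slice TIFF files (read-only; slice order is the sorted
#' file name order, one slice per z index).
#'
#' The pipeline assumes isotropic voxels; a NIfTI header with anisotropic
#' pixdim is rejected rather than silently collapsed. TIFF stacks carry no
#' trustworthy voxel-size metadata, so `voxel_size_um` is required for them.
#'
#' @param path File (NIfTI) or directory (chunked store, TIFF stack).
#' @param format One of `"auto"`, `"chunked"`, `"nifti"`, `"tiff"`.
#' @param voxel_size_um Voxel size override; required for TIFF, optional
#'   elsewhere (must then agree with stored metadata).
#' @return An [intensity_volume()].
#' @export
read_volume <- function(path, format = c("auto", "chunked", "nifti", "tiff"),
                        voxel_size_um = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    chunked = read_chunked_store(path, voxel_size_um),
    nifti   = read_nifti_volume(path, voxel_size_um),
    tiff    = read_tiff_stack(path, voxel_size_um))
}

#' Write a volume to disk
#'
#' @param vol An [intensity_volume()].
#' @param path Destination file (NIfTI) or directory (chunked store).
#' @param format `"chunked"` or `"nifti"`.
#' @param chunk_shape For the chunked store, voxel counts per chunk
#'   (default 64^3, clipped to the volume extent).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("chunked", "nifti"),
                         chunk_shape = c(64L, 64L, 64L)) {
  stopifnot(is_intensity_volume(vol))
  format <- match.arg(format)
  if (format == "chunked") write_chunked_store(vol, path, chunk_shape)
  else write_nifti_volume(vol, path)
  invisible(path)
}

guess_format <- function(path) {
  if (dir.exists(path)) {
    if (file.exists(file.path(path, "meta.json"))) return("chunked")
    return("tiff")
  }
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  stop("cannot guess volume format for ", path,
       "; pass `format` explicitly")
}

## --- native chunked store -------------------------------------------------
## Directory layout: meta.json {shape, chunk_shape, voxel_size_um, dtype,
## order:"F"} + one little-endian float64 file per chunk, named
## "c_<i>_<j>_<k>.bin" with 0-based chunk-grid indices. Border chunks are
## stored at their clipped (smaller) extent so the chunk grid tiles the
## volume exactly.

write_chunked_store <- function(vol, path, chunk_shape) {
  d <- dim(vol$data)
  chunk_shape <- pmin(as.integer(chunk_shape), d)
  if (any(chunk_shape < 1L)) stop("chunk_shape must be positive")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta <- list(shape = d, chunk_shape = chunk_shape,
               voxel_size_um = vol$voxel_size_um,
               dtype = "float64", order = "F")
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  grid <- chunk_grid(d, chunk_shape)
  for (ck in grid) {
    sub <- vol$data[ck$lo[1]:ck$hi[1], ck$lo[2]:ck$hi[2], ck$lo[3]:ck$hi[3],
                    drop = FALSE]
    f <- file.path(path, sprintf("c_%d_%d_%d.bin",
                                 ck$idx[1] - 1L, ck$idx[2] - 1L, ck$idx[3] - 1L))
    con <- file(f, "wb")
    writeBin(as.numeric(sub), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

read_chunked_store <- function(path, voxel_size_um = NULL) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("not a chunked store (no meta.json): ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  vs <- meta$voxel_size_um
  if (is.null(vs)) {
    if (is.null(voxel_size_um))
      stop("chunked store at ", path, " has no voxel_size_um; pass it explicitly")
    vs <- voxel_size_um
  }
  arr <- array(NA_real_, dim = d)
  grid <- chunk_grid(d, as.integer(meta$chunk_shape))
  for (ck in grid) {
    f <- file.path(path, sprintf("c_%d_%d_%d.bin",
                                 ck$idx[1] - 1L, ck$idx[2] - 1L, ck$idx[3] - 1L))
    n <- prod(ck$hi - ck$lo + 1L)
    con <- file(f, "rb")
    v <- readBin(con, "double", n = n, size = 8L, endian = "little")
    close(con)
    arr[ck$lo[1]:ck$hi[1], ck$lo[2]:ck$hi[2], ck$lo[3]:ck$hi[3]] <-
      array(v, dim = ck$hi - ck$lo + 1L)
  }
  intensity_volume(arr, vs)
}

## --- NIfTI ----------------------------------------------------------------

write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- rep(vol$voxel_size_um, 3L)
  RNifti::pixunits(img) <- c("um", "s")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

read_nifti_volume <- function(path, voxel_size_um = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop header attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L) stop("NIfTI image at ", path, " is not 3D")
  pd <- RNifti::pixdim(img)[1:3]
  un <- tryCatch(RNifti::pixunits(img)[1], error = function(e) "unknown")
  if (max(pd) - min(pd) > 1e-6 * max(pd))
    stop("anisotropic voxel size ", paste(signif(pd, 6), collapse = " x "),
         " in ", path, ": the pipeline assumes isotropic voxels")
  vs <- switch(un, um = pd[1], mm = pd[1] * 1000, pd[1])
  if (!is.null(voxel_size_um)) vs <- voxel_size_um
  if (!is.finite(vs) || vs <= 0)
    stop("missing or invalid voxel size in ", path,
         "; pass `voxel_size_um` explicitly")
  intensity_volume(arr, vs)
}

## --- TIFF stack (read-only) -----------------------------------------------

read_tiff_stack <- function(path, voxel_size_um = NULL) {
  if (is.null(voxel_size_um))
    stop("TIFF stacks carry no voxel-size metadata; `voxel_size_um` is required")
  files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no TIFF files found under ", path)
  slices <- lapply(files, function(f) {
    s <- tiff::readTIFF(f, info = TRUE)
    bps <- attr(s, "bits.per.sample")
    # integer TIFFs keep native values; 32-bit float reads natively already
    if (!is.null(bps) && bps <= 16L) s <- tiff::readTIFF(f, as.is = TRUE)
    attributes(s) <- list(dim = dim(s))
    if (length(dim(s)) == 3L) s <- s[, , 1]  # first channel
    s
  })
  d2 <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), d2), logical(1))))
    stop("TIFF slices under ", path, " have inconsistent dimensions")
  arr <- array(0, dim = c(d2[1], d2[2], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  intensity_volume(arr, voxel_size_um)
}
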