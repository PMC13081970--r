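#' Chunked processing plan
#'
#' Describes how a volume is tiled into chunks for out-of-core style
#' processing, and how much overlap (halo) each chunk is loaded with so that
#' filter-based operations on chunks equal their dense counterparts. The halo
#' must cover the support radius of the operation (for a Gaussian of standard
#' deviation s truncated at `truncate` standard deviations the support radius
#' is `ceiling(truncate * s)`; composed filters add their radii). The padding
#' is discarded after the per-chunk computation, before assembly.
#'
#' @param chunk_shape Integer vector of 3 voxel counts per chunk.
#' @param halo Nonnegative per-axis voxel margin (scalar or length 3).
#' @param boundary_mode Handling of positions outside the *volume*:
#'   `"reflect"` (default; symmetric, edge voxel repeated), `"nearest"`, or
#'   `"constant"`.
#' @param constant_value Fill value for `boundary_mode = "constant"`.
#' @return An object of class `chunk_plan`.
#' @export
chunk_plan <- function(chunk_shape, halo,
                       boundary_mode = c("reflect", "nearest", "constant"),
                       constant_value = 0) {
  boundary_mode <- match.arg(boundary_mode)
  chunk_shape <- as.integer(rep_len(chunk_shape, 3L))
  halo <- as.integer(rep_len(halo, 3L))
  if (any(chunk_shape < 1L)) stop("chunk_shape must be positive")
  if (any(halo < 0L)) stop("halo must be nonnegative")
  structure(list(chunk_shape = chunk_shape, halo = halo,
                 boundary_mode = boundary_mode,
                 constant_value = constant_value),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("<chunk_plan> chunks %s, halo %s, boundary %s\n",
              paste(x$chunk_shape, collapse = "x"),
              paste(x$halo, collapse = "x"), x$boundary_mode))
  invisible(x)
}

# Tile `dim` exactly with chunks of `chunk_shape`; border chunks are smaller.
chunk_grid <- function(dim, chunk_shape) {
  chunk_shape <- pmin(as.integer(chunk_shape), as.integer(dim))
  starts <- lapply(1:3, function(a) seq(1L, dim[a], by = chunk_shape[a]))
  grid <- list()
  for (k in seq_along(starts[[3]]))
    for (j in seq_along(starts[[2]]))
      for (i in seq_along(starts[[1]])) {
        lo <- c(starts[[1]][i], starts[[2]][j], starts[[3]][k])
        hi <- pmin(lo + chunk_shape - 1L, dim)
        grid[[length(grid) + 1L]] <- list(idx = c(i, j, k), lo = lo, hi = hi)
      }
  grid
}

# Map possibly out-of-range 1-based indices into 1..n per boundary mode.
# Returns NA for "constant" out-of-range positions (caller fills the value).
map_boundary_indices <- function(idx, n, mode) {
  out <- idx
  if (mode == "constant") {
    out[idx < 1L | idx > n] <- NA_integer_
    return(out)
  }
  if (mode == "nearest") return(pmin(pmax(idx, 1L), n))
  # symmetric reflect; iterate for halos larger than the extent
  bad <- which(out < 1L | out > n)
  while (length(bad)) {
    out[bad] <- ifelse(out[bad] < 1L, 1L - out[bad], 2L * n + 1L - out[bad])
    bad <- which(out < 1L | out > n)
  }
  out
}

# Extract the chunk [lo, hi] expanded by `halo`, with out-of-volume positions
# resolved per the plan's boundary mode. Returns the padded array plus the
# per-axis mapped full-volume index vectors (so callers can extract
# co-registered companion arrays, e.g. a vessel mask, identically).
extract_padded_chunk <- function(arr, lo, hi, plan) {
  d <- dim(arr)
  idx <- lapply(1:3, function(a)
    map_boundary_indices((lo[a] - plan$halo[a]):(hi[a] + plan$halo[a]),
                         d[a], plan$boundary_mode))
  sub <- extract_by_mapped_indices(arr, idx, plan$constant_value)
  list(data = sub, index = idx)
}

extract_by_mapped_indices <- function(arr, idx, constant_value = 0) {
  has_na <- any(vapply(idx, anyNA, logical(1)))
  if (!has_na) return(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE])
  safe <- lapply(seq_along(idx), function(a) {
    v <- idx[[a]]; v[is.na(v)] <- 1L; v
  })
  sub <- arr[safe[[1]], safe[[2]], safe[[3]], drop = FALSE]
  for (a in 1:3) {
    na_pos <- which(is.na(idx[[a]]))
    if (length(na_pos)) {
      if (a == 1L) sub[na_pos, , ] <- constant_value
      else if (a == 2L) sub[, na_pos, ] <- constant_value
      else sub[, , na_pos] <- constant_value
    }
  }
  sub
}

#' Apply an operation chunk-wise with halo padding
#'
#' Runs `op` on each halo-padded chunk of the volume, discards the halo of
#' each result, and reassembles the full output. Provided the halo covers the
#' operation's support radius, the result equals applying `op` to the whole
#' volume in memory (up to float accumulation order). A halo smaller than the
#' declared support is refused outright: silent edge artifacts at chunk seams
#' are exactly the failure mode this interface exists to prevent.
#'
#' @param vol An [intensity_volume()] (or plain 3D array).
#' @param plan A [chunk_plan()].
#' @param op Function `(padded_array, chunk_info)` returning an array whose
#'   first three dimensions equal `dim(padded_array)`; trailing dimensions
#'   (e.g. vector/tensor channels) are preserved. `chunk_info` has elements
#'   `lo`, `hi` (chunk bounds in volume coordinates) and `index` (per-axis
#'   mapped full-volume indices of the padded block).
#' @param support Per-axis support radius of `op` in voxels (scalar or
#'   length 3). Must not exceed `plan$halo`.
#' @return Array of the volume's shape, with any trailing channel dimensions
#'   produced by `op`.
#' @export
map_with_halo <- function(vol, plan, op, support) {
  arr <- if (is_intensity_volume(vol)) vol$data else vol
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  support <- as.integer(rep_len(support, 3L))
  if (any(plan$halo < support))
    stop(sprintf(paste0("halo (%s) smaller than the operation's support ",
                        "radius (%s): refusing to run, chunk seams would be ",
                        "silently corrupted"),
                 paste(plan$halo, collapse = ","),
                 paste(support, collapse = ",")))
  d <- dim(arr)
  grid <- chunk_grid(d, plan$chunk_shape)
  out <- NULL
  for (ck in grid) {
    padded <- extract_padded_chunk(arr, ck$lo, ck$hi, plan)
    res <- op(padded$data, list(lo = ck$lo, hi = ck$hi, index = padded$index))
    rd <- dim(res)
    if (is.null(rd)) rd <- length(res)
    pd <- dim(padded$data)
    if (length(rd) < 3L || !all(rd[1:3] == pd))
      stop("op returned an array whose leading dims do not match the padded chunk")
    nchan <- if (length(rd) > 3L) prod(rd[-(1:3)]) else 1L
    if (is.null(out)) {
      out_dim <- if (length(rd) > 3L) c(d, rd[-(1:3)]) else d
      out <- array(NA_real_, dim = out_dim)
      dim(out) <- c(d, nchan)  # channel-flattened view for assembly
      final_dim <- out_dim
    }
    keep <- lapply(1:3, function(a)
      (plan$halo[a] + 1L):(plan$halo[a] + (ck$hi[a] - ck$lo[a] + 1L)))
    dim(res) <- c(pd, nchan)
    out[ck$lo[1]:ck$hi[1], ck$lo[2]:ck$hi[2], ck$lo[3]:ck$hi[3], ] <-
      res[keep[[1]], keep[[2]], keep[[3]], , drop = FALSE]
  }
  dim(out) <- final_dim
  out
}
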