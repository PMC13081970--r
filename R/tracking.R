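## Probabilistic streamline tractography driven by the supervoxel fODF field.

#' Tractography configuration
#'
#' Defaults follow the pipeline's standard operating point: seeding where the
#' structure-tensor FA exceeds 0.42 (a threshold separating coherent
#' anisotropic white matter from more isotropic surroundings), stopping where
#' fODF GFA falls below 0.7 (GFA stays high in crossing regions, so tracking
#' survives complex configurations), a step of a quarter supervoxel edge, and
#' a 30 degree maximum turning angle between steps.
#'
#' @param fa_seed_threshold Seed where supervoxel-mean FA exceeds this
#'   (default 0.42).
#' @param gfa_stop_threshold Terminate below this GFA (default 0.7).
#' @param step_size_um Step length; `NULL` = supervoxel edge / 4.
#' @param max_turn_deg Maximum turning angle per step, in (0, 90).
#' @param pmf_threshold Relative amplitude threshold for direction sampling:
#'   fODF amplitudes below this fraction of the supervoxel's maximum are
#'   excluded from the sampling mass (default 0.1, the convention of
#'   probabilistic ODF trackers; suppresses side-lobe ringing of the
#'   band-limited fODF).
#' @param seeds_per_voxel Seeds per qualifying supervoxel (default 1).
#' @param jitter Jitter seed positions uniformly within the supervoxel
#'   (default FALSE: supervoxel centers).
#' @param min_steps Minimum half-track-combined step count for a streamline
#'   to be kept (default 4; suppresses seed-noise stubs).
#' @param max_length_um Maximum streamline length (default 100000).
#' @param rng_seed Integer RNG seed; fixed seed gives bitwise-identical
#'   tractograms.
#' @return Object of class `tracking_config`.
#' @export
tracking_config <- function(fa_seed_threshold = 0.42, gfa_stop_threshold = 0.7,
                            step_size_um = NULL, max_turn_deg = 30,
                            pmf_threshold = 0.1, seeds_per_voxel = 1L,
                            jitter = FALSE, min_steps = 4L,
                            max_length_um = 1e5, rng_seed = 1L) {
  if (fa_seed_threshold < 0 || fa_seed_threshold > 1 ||
      gfa_stop_threshold < 0 || gfa_stop_threshold > 1)
    stop("thresholds must lie in [0, 1]")
  if (!is.null(step_size_um) && step_size_um <= 0)
    stop("step_size_um must be positive")
  if (max_turn_deg <= 0 || max_turn_deg >= 90)
    stop("max_turn_deg must lie strictly between 0 and 90")
  if (pmf_threshold < 0 || pmf_threshold >= 1)
    stop("pmf_threshold must lie in [0, 1)")
  if (seeds_per_voxel < 1L) stop("seeds_per_voxel must be >= 1")
  structure(list(fa_seed_threshold = fa_seed_threshold,
                 gfa_stop_threshold = gfa_stop_threshold,
                 step_size_um = step_size_um, max_turn_deg = max_turn_deg,
                 pmf_threshold = pmf_threshold,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 jitter = jitter, min_steps = as.integer(min_steps),
                 max_length_um = max_length_um,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_config")
}

#' Supervoxel-mean FA map
#'
#' Averages the fine-voxel FA over each supervoxel block (border supervoxels
#' truncated, in step with the fODF grid) for seeding decisions.
#'
#' @param fa 3D fine-voxel FA array.
#' @param edge_vox Supervoxel edge in fine voxels.
#' @return 3D array on the supervoxel grid.
#' @export
supervoxel_mean_fa <- function(fa, edge_vox) {
  d <- dim(fa)
  edge_vox <- as.integer(edge_vox)
  nsv <- d %/% edge_vox
  out <- array(0, dim = nsv)
  for (k in seq_len(nsv[3])) for (j in seq_len(nsv[2])) for (i in seq_len(nsv[1]))
    out[i, j, k] <- mean(fa[((i - 1L) * edge_vox + 1L):(i * edge_vox),
                            ((j - 1L) * edge_vox + 1L):(j * edge_vox),
                            ((k - 1L) * edge_vox + 1L):(k * edge_vox)])
  out
}

#' Seed points from a supervoxel FA map
#'
#' Emits `seeds_per_voxel` seed points (physical um coordinates) in every
#' supervoxel whose FA exceeds the seed threshold, at the supervoxel center
#' or jittered uniformly within it. Deterministic for a fixed `rng_seed`.
#'
#' @param fa_sv Supervoxel-scale FA array (e.g. [supervoxel_mean_fa()]).
#' @param cfg A [tracking_config()].
#' @param supervoxel_edge_um Supervoxel edge length (um).
#' @return Matrix `n x 3` of seed coordinates (um) with attribute
#'   `sv_index` (linear supervoxel index per seed); zero rows (with a
#'   warning) if no supervoxel qualifies.
#' @export
seed_streamlines <- function(fa_sv, cfg, supervoxel_edge_um) {
  stopifnot(inherits(cfg, "tracking_config"))
  qual <- which(fa_sv > cfg$fa_seed_threshold)
  if (!length(qual)) {
    warning("no supervoxel exceeds the FA seed threshold; empty tractogram")
    out <- matrix(numeric(0), ncol = 3L)
    attr(out, "sv_index") <- integer(0)
    return(out)
  }
  set.seed(cfg$rng_seed)
  e <- supervoxel_edge_um
  seeds <- matrix(0, nrow = length(qual) * cfg$seeds_per_voxel, ncol = 3L)
  svi <- integer(nrow(seeds))
  r <- 1L
  for (q in qual) {
    idx <- arrayInd(q, dim(fa_sv))
    lo <- (idx - 1) * e
    for (s in seq_len(cfg$seeds_per_voxel)) {
      seeds[r, ] <- if (cfg$jitter) lo + stats::runif(3) * e else lo + e / 2
      svi[r] <- q
      r <- r + 1L
    }
  }
  attr(seeds, "sv_index") <- svi
  seeds
}

# Linear supervoxel index of a physical position; NA outside the grid.
pos_to_sv <- function(pos, edge_um, sv_dim) {
  idx <- floor(pos / edge_um) + 1
  if (any(idx < 1) || any(idx > sv_dim)) return(NA_integer_)
  as.integer(idx[1] + (idx[2] - 1) * sv_dim[1] + (idx[3] - 1) * sv_dim[1] * sv_dim[2])
}

# Cache of clipped, PMF-thresholded fODF amplitudes on the sampling set.
make_amplitude_cache <- function(sh, dirs, pmf_threshold = 0) {
  B <- sh_basis(acos(pmin(pmax(dirs[, 3], -1), 1)),
                atan2(dirs[, 2], dirs[, 1]), sh$lmax, sh$even_only)
  cache <- new.env(parent = emptyenv())
  function(sv) {
    key <- as.character(sv)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cf <- sh$coeffs[sv, ]
    a <- if (anyNA(cf)) NULL else {
      v <- as.numeric(B %*% cf)
      v[v < 0] <- 0
      if (pmf_threshold > 0) v[v < pmf_threshold * max(v)] <- 0
      v
    }
    cache[[key]] <- a
    a
  }
}

# One half-track from `seed` with initial incoming direction `dir0`
# (NULL = unrestricted first draw from the full fODF).
propagate_half <- function(seed, dir0, sh, cfg, dirs, amp_of, step_um,
                           max_steps) {
  cos_turn <- cos(cfg$max_turn_deg * pi / 180)
  pts <- matrix(NA_real_, nrow = max_steps + 1L, ncol = 3L)
  pts[1L, ] <- seed
  pos <- seed
  incoming <- dir0
  n <- 1L
  reason <- "max_length"
  first_dir <- NULL
  while (n <= max_steps) {
    sv <- pos_to_sv(pos, sh$supervoxel_edge_um, sh$sv_dim)
    if (is.na(sv)) { reason <- "volume_exit"; break }
    g <- sh$gfa[sv]
    if (is.na(g) || g < cfg$gfa_stop_threshold) { reason <- "low_gfa"; break }
    amp <- amp_of(sv)
    if (is.null(amp)) { reason <- "empty_fodf"; break }
    w <- amp
    if (!is.null(incoming)) {
      cosang <- as.numeric(dirs %*% incoming)
      w <- ifelse(cosang >= cos_turn, w, 0)
    }
    tot <- sum(w)
    if (tot <= 0) { reason <- "no_cone_mass"; break }
    k <- sample.int(length(w), 1L, prob = w)
    stepdir <- dirs[k, ]
    if (is.null(first_dir)) first_dir <- stepdir
    pos <- pos + step_um * stepdir
    n <- n + 1L
    pts[n, ] <- pos
    incoming <- stepdir
  }
  # a half-track that stepped outside keeps only in-volume points
  if (reason == "volume_exit" && n > 1L) n <- n - 1L
  pts <- pts[seq_len(n), , drop = FALSE]
  list(points = pts, reason = reason, first_dir = first_dir)
}

#' Propagate a single streamline
#'
#' Bidirectional probabilistic propagation from one seed: at each step a
#' direction is drawn from the local clipped fODF (nearest supervoxel),
#' restricted to the cone of `max_turn_deg` around the incoming direction;
#' the first draw is unrestricted and the second half-track starts along its
#' antipode. Propagation stops on GFA below threshold, volume exit, zero
#' fODF mass within the cone, or maximum length.
#'
#' @param seed Length-3 position (um); must lie inside the supervoxel grid.
#' @param sh An `sh_field` (with its `gfa` map).
#' @param cfg A [tracking_config()].
#' @param dirs Direction sampling set (default [symmetric_sphere_set()]).
#' @return List with `points` (n x 3 matrix, um), `reasons` (termination
#'   reason of each half-track).
#' @export
propagate <- function(seed, sh, cfg, dirs = symmetric_sphere_set(724L)) {
  stopifnot(inherits(sh, "sh_field"), inherits(cfg, "tracking_config"))
  if (is.na(pos_to_sv(seed, sh$supervoxel_edge_um, sh$sv_dim)))
    stop("seed lies outside the volume")
  amp_of <- make_amplitude_cache(sh, dirs, cfg$pmf_threshold)
  step_um <- if (is.null(cfg$step_size_um)) sh$supervoxel_edge_um / 4
             else cfg$step_size_um
  max_steps <- max(1L, floor(cfg$max_length_um / step_um / 2))
  h1 <- propagate_half(seed, NULL, sh, cfg, dirs, amp_of, step_um, max_steps)
  if (is.null(h1$first_dir))
    return(list(points = matrix(seed, 1L), reasons = c(h1$reason, h1$reason)))
  h2 <- propagate_half(seed, -h1$first_dir, sh, cfg, dirs, amp_of, step_um,
                       max_steps)
  pts <- rbind(h2$points[rev(seq_len(nrow(h2$points))), , drop = FALSE],
               h1$points[-1L, , drop = FALSE])
  list(points = pts, reasons = c(backward = h2$reason, forward = h1$reason))
}

#' Run whole-field probabilistic tractography
#'
#' Seeds per [seed_streamlines()], propagates every seed bidirectionally per
#' [propagate()], and drops streamlines shorter than `min_steps` steps.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param sh An `sh_field`.
#' @param fa_sv Supervoxel-scale FA map, same grid as `sh`.
#' @param cfg A [tracking_config()].
#' @param dirs Direction sampling set.
#' @return Object of class `tractogram`: `streamlines` (list of n x 3
#'   matrices, um), `seed_index`, `reasons`, `step_size_um`, `config`.
#' @export
run_tractography <- function(sh, fa_sv, cfg = tracking_config(),
                             dirs = symmetric_sphere_set(724L)) {
  stopifnot(inherits(sh, "sh_field"))
  if (!identical(dim(fa_sv), sh$sv_dim))
    stop("FA map grid does not match the fODF supervoxel grid")
  seeds <- seed_streamlines(fa_sv, cfg, sh$supervoxel_edge_um)
  step_um <- if (is.null(cfg$step_size_um)) sh$supervoxel_edge_um / 4
             else cfg$step_size_um
  amp_of <- make_amplitude_cache(sh, dirs, cfg$pmf_threshold)
  max_steps <- max(1L, floor(cfg$max_length_um / step_um / 2))
  streamlines <- list(); seed_index <- integer(0); reasons <- list()
  set.seed(cfg$rng_seed)
  for (i in seq_len(nrow(seeds))) {
    h1 <- propagate_half(seeds[i, ], NULL, sh, cfg, dirs, amp_of, step_um,
                         max_steps)
    if (is.null(h1$first_dir)) next
    h2 <- propagate_half(seeds[i, ], -h1$first_dir, sh, cfg, dirs, amp_of,
                         step_um, max_steps)
    pts <- rbind(h2$points[rev(seq_len(nrow(h2$points))), , drop = FALSE],
                 h1$points[-1L, , drop = FALSE])
    if (nrow(pts) - 1L < cfg$min_steps) next
    streamlines[[length(streamlines) + 1L]] <- pts
    seed_index <- c(seed_index, i)
    reasons[[length(reasons) + 1L]] <- c(backward = h2$reason,
                                         forward = h1$reason)
  }
  structure(list(streamlines = streamlines, seed_index = seed_index,
                 reasons = reasons, step_size_um = step_um,
                 seeds = seeds, config = cfg),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  ns <- length(x$streamlines)
  npts <- if (ns) vapply(x$streamlines, nrow, integer(1)) else integer(0)
  cat(sprintf("<tractogram> %d streamlines (median %g points), step %g um\n",
              ns, if (ns) stats::median(npts) else 0, x$step_size_um))
  invisible(x)
}

#' Write a tractogram in MRtrix TCK format
#'
#' Coordinates are converted from micrometers to millimeters for format
#' compliance. Streamlines are separated by NaN triplets and the file is
#' terminated by an Inf triplet, float32 little-endian.
#'
#' @param tract A `tractogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tract, path) {
  stopifnot(inherits(tract, "tractogram"))
  ns <- length(tract$streamlines)
  header <- paste0("mrtrix tracks\n",
                   "datatype: Float32LE\n",
                   sprintf("count: %d\n", ns),
                   "fibrect_step_size_mm: ",
                   format(tract$step_size_um / 1000), "\n")
  offset_line <- "file: . %d\n"
  # two-pass: compute the header size including the offset line and END
  probe <- paste0(header, sprintf(offset_line, 0), "END\n")
  off <- nchar(probe, type = "bytes")
  # widen until self-consistent (offset digits can change the length)
  repeat {
    hdr <- paste0(header, sprintf(offset_line, off), "END\n")
    n2 <- nchar(hdr, type = "bytes")
    if (n2 == off) break
    off <- n2
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in tract$streamlines) {
    writeBin(as.numeric(t(s / 1000)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}
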