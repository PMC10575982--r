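#' Unit conversion constants for oxDNA reduced units
#'
#' Community-standard conversion factors: 0.8518 nm per oxDNA length unit
#' and 3.03 ps per oxDNA time unit.
#' @name oxdna_units
#' @export
OXDNA_LENGTH_NM <- 0.8518

#' @rdname oxdna_units
#' @export
OXDNA_TIME_PS <- 3.03

#' Coarse-grained trajectory container
#'
#' @param positions 3D array `[frame, entity, 3]` of coordinates in nm.
#' @param time_ps frame times (ps), non-decreasing, one per frame.
#' @return an object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(positions, time_ps) {
  if (length(dim(positions)) != 3 || dim(positions)[3] != 3)
    stop("positions must be a [frame, entity, 3] array")
  if (dim(positions)[1] < 1) stop("need at least one frame")
  if (length(time_ps) != dim(positions)[1])
    stop("one time per frame required")
  if (is.unsorted(time_ps)) stop("times must be non-decreasing")
  structure(list(positions = positions, time_ps = as.numeric(time_ps)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$positions)
  cat(sprintf("Coarse-grained trajectory: %d frames x %d entities, %.4g-%.4g ns\n",
              d[1], d[2], x$time_ps[1] / 1e3, x$time_ps[d[1]] / 1e3))
  invisible(x)
}

#' Read an oxDNA topology / configuration pair
#'
#' Parses the standard oxDNA text formats: the topology's first line gives
#' the nucleotide and strand counts; each configuration frame starts with
#' three header lines (`t = ...`, `b = ...`, `E = ...`) followed by one row
#' of 15 whitespace-separated floats per nucleotide (position, backbone-base
#' versor, normal versor, velocity, angular velocity).  Only positions are
#' kept.  Lengths are converted at `OXDNA_LENGTH_NM` nm and times at
#' `OXDNA_TIME_PS` ps per oxDNA unit.
#'
#' @param topology path to the `.top` file.
#' @param configuration path to the `.conf` / `.dat` trajectory file.
#' @param length_unit,time_unit conversion factors, configurable.
#' @return a [cg_trajectory()].
#' @export
read_oxdna <- function(topology, configuration,
                       length_unit = OXDNA_LENGTH_NM,
                       time_unit = OXDNA_TIME_PS) {
  top <- readLines(topology, warn = FALSE)
  hdr <- strsplit(trimws(top[1]), "\\s+")[[1]]
  n_nt <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(n_nt) || n_nt < 1)
    stop("malformed topology header: ", top[1])
  if (length(top) - 1 < n_nt)
    stop("topology lists fewer nucleotides than its header declares")
  lines <- readLines(configuration, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  frames <- list()
  times <- numeric(0)
  fr <- 0L
  while (i <= length(lines)) {
    fr <- fr + 1L
    if (!grepl("^\\s*t\\s*=", lines[i]))
      stop(sprintf("line %d: expected 't = ...' frame header", i))
    tval <- as.numeric(sub("^\\s*t\\s*=\\s*", "", lines[i]))
    if (is.na(tval)) stop(sprintf("line %d: unparseable time", i))
    if (i + 2 > length(lines) ||
        !grepl("^\\s*b\\s*=", lines[i + 1]) ||
        !grepl("^\\s*E\\s*=", lines[i + 2]))
      stop(sprintf("frame %d: missing 'b =' / 'E =' header lines", fr))
    i <- i + 3L
    if (i + n_nt - 1L > length(lines))
      stop(sprintf("truncated frame %d: expected %d nucleotide rows", fr,
                   n_nt))
    block <- lines[i:(i + n_nt - 1L)]
    vals <- strsplit(trimws(block), "\\s+")
    nc <- lengths(vals)
    if (any(nc != 15L))
      stop(sprintf("line %d: expected 15 columns, found %d",
                   i + which(nc != 15L)[1] - 1L, nc[nc != 15L][1]))
    num <- matrix(as.numeric(unlist(vals)), ncol = 15, byrow = TRUE)
    if (anyNA(num))
      stop(sprintf("frame %d: non-numeric configuration value", fr))
    frames[[fr]] <- num[, 1:3, drop = FALSE] * length_unit
    times[fr] <- tval * time_unit
    i <- i + n_nt
  }
  if (fr == 0L) stop("configuration file contains no frames")
  pos <- array(0, dim = c(fr, n_nt, 3))
  for (k in seq_len(fr)) pos[k, , ] <- frames[[k]]
  cg_trajectory(pos, times)
}

#' Write a trajectory in oxDNA topology / configuration format
#'
#' Inverse of [read_oxdna()] for round-trip testing: positions are written
#' in oxDNA length units, times in oxDNA time units; orientation versors
#' are written as the canonical frame and velocities as zero.  All entities
#' are emitted as one poly-A strand in the topology.
#'
#' @param traj a [cg_trajectory()].
#' @param topology,configuration output paths.
#' @inheritParams read_oxdna
#' @return invisibly, a list of the two paths.
#' @export
write_oxdna <- function(traj, topology, configuration,
                        length_unit = OXDNA_LENGTH_NM,
                        time_unit = OXDNA_TIME_PS) {
  stopifnot(inherits(traj, "cg_trajectory"))
  d <- dim(traj$positions)
  n <- d[2]
  top <- c(sprintf("%d 1", n),
           sprintf("1 A %d %d", c(-1L, seq_len(n - 1) - 1L),
                   c(seq_len(n - 1), -1L)))
  writeLines(top, topology)
  con <- file(configuration, "w"); on.exit(close(con))
  for (k in seq_len(d[1])) {
    writeLines(c(sprintf("t = %.10g", traj$time_ps[k] / time_unit),
                 "b = 50 50 50", "E = 0 0 0"), con)
    p <- traj$positions[k, , , drop = FALSE] / length_unit
    rows <- sprintf(
      "%.10g %.10g %.10g 1 0 0 0 1 0 0 0 0 0 0 0",
      p[1, , 1], p[1, , 2], p[1, , 3])
    writeLines(rows, con)
  }
  invisible(list(topology = topology, configuration = configuration))
}

#' Root-mean-square deviation from the initial frame
#'
#' For each frame, the squared distance from the position in the first
#' frame is computed per entity and the root of the mean over entities is
#' reported.  No rigid-body superposition is applied, so a uniform
#' translation of all entities by `d` yields RMSD exactly `d` (the measure
#' doubles as an equilibration index).
#'
#' @param traj a [cg_trajectory()] with at least 2 frames.
#' @param align if TRUE, remove the centroid displacement of each frame
#'   before computing distances (off by default).
#' @return a `data.frame` with columns `time_ps`, `rmsd_nm`; first value 0.
#' @export
rmsd_trace <- function(traj, align = FALSE) {
  stopifnot(inherits(traj, "cg_trajectory"))
  p <- traj$positions
  if (dim(p)[1] < 2) stop("need at least 2 frames")
  ref <- matrix(p[1, , ], ncol = 3)
  rmsd <- vapply(seq_len(dim(p)[1]), function(k) {
    cur <- matrix(p[k, , ], ncol = 3)
    if (align) {
      cur <- sweep(cur, 2, colMeans(cur) - colMeans(ref))
    }
    sqrt(mean(rowSums((cur - ref)^2)))
  }, numeric(1))
  data.frame(time_ps = traj$time_ps, rmsd_nm = rmsd)
}

#' Per-entity root-mean-square fluctuation
#'
#' For every entity, the RMSF is the root of the mean squared distance from
#' its window-averaged position, over the frames of the analysis window.
#' The default window spans 2000 to 3000 ns, which selects exactly 100
#' frames on a 10 ns-spaced trajectory (frames with
#' `window_ns[1] < t <= window_ns[2]`); if the trajectory does not reach
#' the window, all frames are used.
#'
#' @param traj a [cg_trajectory()].
#' @param window_ns analysis window `c(lo, hi)` in ns.
#' @return numeric vector of per-entity RMSF values (nm).
#' @export
rmsf <- function(traj, window_ns = c(2000, 3000)) {
  stopifnot(inherits(traj, "cg_trajectory"))
  t_ns <- traj$time_ps / 1e3
  sel <- which(t_ns > window_ns[1] & t_ns <= window_ns[2])
  if (length(sel) == 0) sel <- seq_along(t_ns)
  if (length(sel) < 2) stop("analysis window selects fewer than 2 frames")
  p <- traj$positions[sel, , , drop = FALSE]
  ref <- apply(p, c(2, 3), mean)
  dev2 <- sweep(p, c(2, 3), ref)^2
  sqrt(apply(dev2, 2, sum) / dim(p)[1])
}

#' Average paired entities into guide points
#'
#' Reduces paired entities (e.g. 26 nucleotides picked along a backbone or
#' pier) to the midpoints of each pair (13 guide coordinates), preserving
#' the order along the structure.
#'
#' @param frame matrix `entities x 3` of coordinates (nm), e.g.
#'   `traj$positions[k, , ]`.
#' @param index_pairs 2-column matrix (or list of length-2 vectors) of
#'   entity indices, ordered along the structure.
#' @return a matrix of midpoints (one row per pair), usable as a 3D
#'   polyline for [fit_helix()].
#' @export
average_guide_points <- function(frame, index_pairs) {
  frame <- as.matrix(frame)
  if (is.list(index_pairs)) index_pairs <- do.call(rbind, index_pairs)
  index_pairs <- as.matrix(index_pairs)
  if (ncol(index_pairs) != 2) stop("index_pairs must have two columns")
  if (any(index_pairs < 1) || any(index_pairs > nrow(frame)))
    stop("entity index out of range")
  (frame[index_pairs[, 1], , drop = FALSE] +
     frame[index_pairs[, 2], , drop = FALSE]) / 2
}
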