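#' Trajectory containers and I/O
#'
#' Trajectories are stored as an `ion_trajectory`: an atoms x 3 x frames
#' coordinate array with atom `labels`, optional `roles`, and the frame time
#' step `dt` (ns). [write_xyz_trajectory()] serializes to multi-frame XYZ
#' with a JSON sidecar naming the atoms; [read_xyz_trajectory()] reads the
#' pair back. Periodic boundary conditions are not represented: all distance
#' operations are plain Euclidean, appropriate for intra-site distances far
#' smaller than any simulation box.
#'
#' @param traj an `ion_trajectory`.
#' @param path multi-frame XYZ file.
#' @param sidecar JSON sidecar path; defaults to `paste0(path, ".json")`.
#' @return `write_xyz_trajectory` returns `path` invisibly;
#'   `read_xyz_trajectory` an `ion_trajectory`.
#' @export
write_xyz_trajectory <- function(traj, path, sidecar = paste0(path, ".json")) {
  n <- dim(traj$frames)[1]; nf <- dim(traj$frames)[3]
  el <- toupper(substr(gsub("[0-9]", "", traj$labels), 1, 2))
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_len(nf)) {
    writeLines(c(as.character(n), sprintf("frame %d time_ns %.6f", k,
                                          (k - 1) * traj$dt)), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", el,
                       traj$frames[, 1, k], traj$frames[, 2, k],
                       traj$frames[, 3, k]), con)
  }
  jsonlite::write_json(list(labels = traj$labels, roles = traj$roles,
                            dt = traj$dt), sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @export
read_xyz_trajectory <- function(path, sidecar = paste0(path, ".json")) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  block <- n + 2L
  nf <- length(ln) %/% block
  frames <- array(NA_real_, c(n, 3L, nf))
  for (k in seq_len(nf)) {
    rows <- ln[((k - 1) * block + 3):((k - 1) * block + 2 + n)]
    m <- matrix(as.numeric(unlist(lapply(strsplit(trimws(rows), "\\s+"),
                                         `[`, 2:4))), ncol = 3, byrow = TRUE)
    frames[, , k] <- m
  }
  labels <- paste0("A", seq_len(n)); roles <- rep("atom", n); dt <- 1
  if (!is.null(sidecar) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    labels <- side$labels; roles <- side$roles; dt <- side$dt
  }
  structure(list(frames = frames, labels = labels, roles = roles, dt = dt,
                 ground_truth = list(dissociation_frame = NULL)),
            class = "ion_trajectory")
}

resolve_atoms <- function(traj, which, arg = "selection") {
  if (is.numeric(which)) {
    idx <- as.integer(which)
    if (any(idx < 1L | idx > dim(traj$frames)[1]))
      stop(arg, " index out of range (1..", dim(traj$frames)[1], ")")
    return(idx)
  }
  idx <- match(which, traj$labels)
  if (anyNA(idx))
    stop(arg, " atom(s) not found: ", paste(which[is.na(idx)], collapse = ", "),
         "; available: ", paste(utils::head(traj$labels, 25), collapse = ", "))
  idx
}

new_distance_series <- function(times, values, label) {
  stopifnot(length(times) == length(values), !is.unsorted(times))
  structure(list(times = times, values = values, label = label),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s: %d frames, mean %.3f A (range %.3f-%.3f)\n",
              x$label, length(x$values), mean(x$values), min(x$values),
              max(x$values)))
  invisible(x)
}

#' Per-frame distance between two atoms
#'
#' @param traj an `ion_trajectory`.
#' @param atom_a,atom_b atom labels or indices.
#' @return A `distance_series` (fields `times` in ns, `values` in Angstrom,
#'   `label`).
#' @export
pair_distance_series <- function(traj, atom_a, atom_b) {
  ia <- resolve_atoms(traj, atom_a, "atom_a")[1]
  ib <- resolve_atoms(traj, atom_b, "atom_b")[1]
  d <- sqrt(colSums((traj$frames[ia, , ] - traj$frames[ib, , ])^2))
  nf <- dim(traj$frames)[3]
  new_distance_series((seq_len(nf) - 1) * traj$dt, d,
                      paste0(traj$labels[ia], "-", traj$labels[ib]))
}

#' Per-frame distance from a probe atom to the nearest of a selection
#'
#' @param traj an `ion_trajectory`.
#' @param probe_atom probe atom label or index.
#' @param selection labels or indices of the candidate atoms (nonempty).
#' @return A `distance_series` of per-frame minima.
#' @export
nearest_distance_series <- function(traj, probe_atom, selection) {
  if (length(selection) == 0L) stop("selection is empty")
  ip <- resolve_atoms(traj, probe_atom, "probe_atom")[1]
  sel <- resolve_atoms(traj, selection)
  nf <- dim(traj$frames)[3]
  d2 <- matrix(0, length(sel), nf)
  for (ax in 1:3) {
    m <- matrix(traj$frames[sel, ax, , drop = FALSE], length(sel), nf)
    d2 <- d2 + sweep(m, 2, traj$frames[ip, ax, ])^2
  }
  dmin <- sqrt(apply(d2, 2, min))
  new_distance_series((seq_len(nf) - 1) * traj$dt, dmin,
                      paste0(traj$labels[ip], "-nearest(", length(sel), ")"))
}

#' Distance from each frame's probe position to a fixed point
#'
#' Convenience series used for site-occupancy checks: the Euclidean distance
#' of one atom to a fixed reference point, per frame.
#'
#' @param traj an `ion_trajectory`.
#' @param atom atom label or index.
#' @param point 3-vector, Angstrom.
#' @return A `distance_series`.
#' @export
point_distance_series <- function(traj, atom, point) {
  ia <- resolve_atoms(traj, atom, "atom")[1]
  d <- sqrt(colSums((traj$frames[ia, , ] - as.numeric(point))^2))
  nf <- dim(traj$frames)[3]
  new_distance_series((seq_len(nf) - 1) * traj$dt, d,
                      paste0(traj$labels[ia], "-site"))
}

#' Density-normalized histogram of a scalar series
#'
#' Bins are half-open `[lo, hi)` with the last bin closed; densities are
#' probability per Angstrom so that `sum(density * bin_width) == 1`.
#'
#' @param series a `distance_series` or numeric vector.
#' @param bin_width bin width (default 0.1); ignored when `n_bins` given.
#' @param n_bins alternative to `bin_width`.
#' @param range length-2 range; defaults to the data range padded to whole
#'   bins.
#' @return list of class `histogram_result`: `bin_edges`, `densities`,
#'   `counts`, `n_samples`.
#' @export
histogram <- function(series, bin_width = 0.1, n_bins = NULL, range = NULL) {
  v <- if (inherits(series, "distance_series")) series$values else
    as.numeric(series)
  if (length(v) == 0L) stop("series is empty")
  if (is.null(range)) {
    lo <- floor(min(v) / bin_width) * bin_width
    hi <- ceiling(max(v) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    range <- c(lo, hi)
  }
  if (diff(range) <= 0) stop("histogram range has zero width")
  edges <- if (!is.null(n_bins)) seq(range[1], range[2], length.out = n_bins + 1L)
           else seq(range[1], range[2] + bin_width / 2, by = bin_width)
  if (edges[length(edges)] < max(v)) edges <- c(edges, max(v) + bin_width)
  h <- graphics::hist(v, breaks = edges, right = FALSE,
                      include.lowest = TRUE, plot = FALSE)
  widths <- diff(h$breaks)
  structure(list(bin_edges = h$breaks,
                 densities = h$counts / (sum(h$counts) * widths),
                 counts = h$counts, n_samples = length(v)),
            class = "histogram_result")
}

#' @export
print.histogram_result <- function(x, ...) {
  cat(sprintf("<histogram_result> %d bins over [%.3g, %.3g], n = %d\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              x$n_samples))
  invisible(x)
}

#' Detect a sustained dissociation event in a distance series
#'
#' Returns the earliest frame `f` such that the series stays strictly above
#' `threshold` for at least `dwell_frames` consecutive frames starting at
#' `f`; transient single-frame excursions shorter than the dwell are ignored.
#' The event is flagged `irreversible` when the series never drops back below
#' the threshold after the event frame.
#'
#' @param series a `distance_series` or numeric vector, Angstrom.
#' @param threshold Angstrom; default 8, well beyond any direct-coordination
#'   distance.
#' @param dwell_frames minimum sustained excursion, frames (default 100).
#' @return list of class `dissociation_event`: `event_frame` (1-based, or
#'   `NULL`), `threshold`, `dwell_frames`, `irreversible`.
#' @export
detect_dissociation <- function(series, threshold = 8, dwell_frames = 100) {
  if (dwell_frames < 1) stop("dwell_frames must be >= 1")
  v <- if (inherits(series, "distance_series")) series$values else
    as.numeric(series)
  above <- v > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= dwell_frames)
  if (length(ok) == 0L)
    return(structure(list(event_frame = NULL, threshold = threshold,
                          dwell_frames = dwell_frames, irreversible = FALSE),
                     class = "dissociation_event"))
  f <- starts[ok[1]]
  irrev <- all(above[f:length(above)])
  structure(list(event_frame = f, threshold = threshold,
                 dwell_frames = dwell_frames, irreversible = irrev),
            class = "dissociation_event")
}

#' @export
print.dissociation_event <- function(x, ...) {
  if (is.null(x$event_frame))
    cat(sprintf("<dissociation_event> none (threshold %g A, dwell %d)\n",
                x$threshold, x$dwell_frames))
  else
    cat(sprintf("<dissociation_event> frame %d (threshold %g A, dwell %d%s)\n",
                x$event_frame, x$threshold, x$dwell_frames,
                if (x$irreversible) ", irreversible" else ""))
  invisible(x)
}

#' Spatial occupancy grid of selected atoms over a trajectory
#'
#' Optionally superposes every frame onto a reference frame by least-squares
#' rigid-body fit over an alignment selection (via [bio3d::fit.xyz()]), then
#' bins the selected atoms' positions into cubic voxels and normalizes the
#' counts by the number of frames. Equivalent subunits can be pooled by
#' calling this once per subunit with per-subunit alignment selections and
#' summing the counts. Before normalization the total count equals
#' frames x selection size (atoms falling outside an explicit grid are
#' dropped with a warning and counted in `n_dropped`).
#'
#' @param traj an `ion_trajectory`.
#' @param selection labels or indices of atoms to accumulate (nonempty).
#' @param spacing voxel edge, Angstrom (> 0).
#' @param grid_spec optional list with `origin` (3-vector) and `dims`
#'   (3 integers); default covers the selection's reference-frame bounding
#'   box padded by `pad`.
#' @param align_to optional list with `frame` (reference frame index,
#'   default 1) and `selection` (alignment atoms; at least 3, non-collinear).
#' @param pad padding of the automatic bounding box, Angstrom.
#' @return list of class `occupancy_grid`: `origin`, `spacing`, `dims`,
#'   `counts` (3-d array), `density` (counts / n_frames), `n_frames`,
#'   `n_dropped`.
#' @export
occupancy_grid <- function(traj, selection, spacing = 0.5, grid_spec = NULL,
                           align_to = NULL, pad = 3) {
  if (length(selection) == 0L) stop("selection is empty")
  if (spacing <= 0) stop("spacing must be positive")
  sel <- resolve_atoms(traj, selection)
  frames <- traj$frames
  nf <- dim(frames)[3]
  if (!is.null(align_to)) {
    ref_frame <- if (is.null(align_to$frame)) 1L else align_to$frame
    aln <- resolve_atoms(traj, align_to$selection, "alignment selection")
    if (length(aln) < 3L)
      stop("alignment selection needs at least 3 atoms")
    ref_aln <- frames[aln, , ref_frame, drop = FALSE][, , 1]
    cen <- sweep(ref_aln, 2, colMeans(ref_aln))
    if (qr(cen)$rank < 2L)
      stop("alignment selection is collinear; superposition is degenerate")
    natoms <- dim(frames)[1]
    mobile <- t(apply(frames, 3, function(m) as.vector(t(m))))  # nf x 3N
    fixed <- as.vector(t(frames[, , ref_frame]))
    inds <- bio3d::atom2xyz(aln)
    fitted <- bio3d::fit.xyz(fixed, mobile, fixed.inds = inds,
                             mobile.inds = inds)
    for (k in seq_len(nf))
      frames[, , k] <- matrix(fitted[k, ], ncol = 3, byrow = TRUE)
  }
  ref_for_box <- frames[sel, , 1, drop = FALSE][, , 1, drop = TRUE]
  if (length(sel) == 1L) ref_for_box <- matrix(ref_for_box, 1L)
  if (is.null(grid_spec)) {
    lo <- apply(ref_for_box, 2, min) - pad
    hi <- apply(ref_for_box, 2, max) + pad
    origin <- lo
    dims <- pmax(ceiling((hi - lo) / spacing), 1L)
  } else {
    origin <- grid_spec$origin
    dims <- as.integer(grid_spec$dims)
  }
  counts <- array(0L, dims)
  dropped <- 0L
  pts <- matrix(aperm(frames[sel, , , drop = FALSE], c(1, 3, 2)), ncol = 3)
  ix <- floor(sweep(pts, 2, origin) / spacing) + 1L
  inside <- ix[, 1] >= 1 & ix[, 1] <= dims[1] &
            ix[, 2] >= 1 & ix[, 2] <= dims[2] &
            ix[, 3] >= 1 & ix[, 3] <= dims[3]
  dropped <- sum(!inside)
  if (dropped > 0L)
    warning(dropped, " selection positions fell outside the grid")
  ix <- ix[inside, , drop = FALSE]
  if (nrow(ix) > 0L) {
    lin <- (ix[, 3] - 1L) * dims[1] * dims[2] + (ix[, 2] - 1L) * dims[1] +
      ix[, 1]
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(tab, dims)
  }
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 counts = counts, density = counts / nf, n_frames = nf,
                 n_dropped = dropped),
            class = "occupancy_grid")
}

#' Write an occupancy grid as an OpenDX scalar field
#'
#' @param grid an [occupancy_grid()].
#' @param path output `.dx` file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: z fastest
  vals <- as.vector(aperm(grid$density, c(3, 2, 1)))
  idx <- seq(1, length(vals), by = 3)
  writeLines(vapply(idx, function(i)
    paste(format(vals[i:min(i + 2, length(vals))], trim = TRUE),
          collapse = " "), ""), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Write a distance series or histogram as TSV
#'
#' @param x a `distance_series` or `histogram_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(x, path) {
  if (inherits(x, "distance_series")) {
    utils::write.table(data.frame(time_ns = x$times, distance_A = x$values),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "histogram_result")) {
    n <- length(x$counts)
    utils::write.table(data.frame(bin_lo_A = x$bin_edges[-(n + 1)],
                                  bin_hi_A = x$bin_edges[-1],
                                  density_per_A = x$densities,
                                  count = x$counts),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
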