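#' Molecular geometries for rigid-dimer energy scans
#'
#' A `molecule_geometry` is an ordered set of atoms, each with a name, a
#' force-field atom type, an element symbol and Cartesian coordinates in
#' Angstrom. Geometries are rigid: no bonded energy terms are ever evaluated,
#' and scans move only the probe ion.
#'
#' @param atoms data frame with columns `name`, `type`, `element`,
#'   `x`, `y`, `z` (Angstrom).
#' @param label free-text molecule label, used to look up partial charges in a
#'   [parameter_set()] (e.g. `"methylthioethane"`).
#' @return An object of class `molecule_geometry`.
#' @export
molecule_geometry <- function(atoms, label) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  need <- c("name", "type", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom positions must be finite")
  if (any(!nzchar(atoms$element))) stop("element symbols must be non-empty")
  if (nrow(atoms) > 1L) {
    d <- as.matrix(stats::dist(xyz))
    diag(d) <- Inf
    if (min(d) < 0.5)
      stop("atoms closer than 0.5 Angstrom: geometry rejected")
  }
  structure(list(atoms = atoms, label = label), class = "molecule_geometry")
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat("<molecule_geometry> ", x$label, ": ", nrow(x$atoms), " atoms (",
      paste(unique(x$atoms$element), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

## Internal-coordinate (z-matrix style) construction of idealized geometries.
## row i places atom i at distance r from atom `b`, angle a (deg) w.r.t. atom
## `ang`, dihedral d (deg) w.r.t. atom `dih`.
place_zmat <- function(zm) {
  n <- nrow(zm)
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (i == 1L) next
    r <- zm$r[i]
    if (i == 2L) { xyz[2, ] <- c(r, 0, 0); next }
    b <- xyz[zm$b[i], ]; a <- xyz[zm$ang[i], ]
    ang <- zm$a[i] * pi / 180
    if (i == 3L) {
      u <- (a - b); u <- u / sqrt(sum(u^2))
      # any perpendicular in the xy-plane
      perp <- c(-u[2], u[1], 0)
      if (sum(perp^2) < 1e-12) perp <- c(0, 1, 0)
      perp <- perp / sqrt(sum(perp^2))
      xyz[3, ] <- b + r * (cos(ang) * u + sin(ang) * perp)
      next
    }
    d <- xyz[zm$dih[i], ]
    tor <- zm$d[i] * pi / 180
    # standard NeRF-style placement
    bc <- b - a; bc <- bc / sqrt(sum(bc^2))       # note: along chain dih->ang->b
    ab <- a - d
    nvec <- pracma_cross(ab, bc)
    nvec <- nvec / sqrt(sum(nvec^2))
    m <- pracma_cross(nvec, bc)
    d2 <- c(-r * cos(ang), r * sin(ang) * cos(tor), r * sin(ang) * sin(tor))
    xyz[i, ] <- b + d2[1] * bc + d2[2] * m + d2[3] * nvec
  }
  xyz
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Idealized thioether / thiol analog geometries
#'
#' Builds rigid, idealized geometries of the methionine side-chain analog
#' methylthioethane (CH3-S-CH2-CH3) or the cysteine analog methanethiol
#' (CH3-SH), with standard bond lengths (C-S 1.81, C-C 1.53, C-H 1.09,
#' S-H 1.34 Angstrom) and near-tetrahedral angles. The sulfur atom is named
#' `SD` (methylthioethane) or `SG` (methanethiol) and serves as the anchor of
#' approach scans. Copies of these geometries ship as XYZ files under
#' `inst/extdata`.
#'
#' @param which `"methylthioethane"` or `"methanethiol"`.
#' @return A [molecule_geometry()].
#' @export
analog_geometry <- function(which = c("methylthioethane", "methanethiol")) {
  which <- match.arg(which)
  if (which == "methylthioethane") {
    # order: SD, C3 (S-methyl), C2 (methylene), C1 (terminal methyl), 8 H
    zm <- data.frame(
      b   = c(NA, 1, 1, 3, 2, 2, 2, 3, 3, 4, 4, 4),
      r   = c(NA, 1.81, 1.81, 1.53, 1.09, 1.09, 1.09, 1.09, 1.09, 1.09, 1.09, 1.09),
      ang = c(NA, NA, 2, 1, 1, 1, 1, 1, 1, 3, 3, 3),
      a   = c(NA, NA, 98.9, 114, 110, 110, 110, 110, 110, 110, 110, 110),
      dih = c(NA, NA, NA, 2, 3, 3, 3, 2, 2, 1, 1, 1),
      d   = c(NA, NA, NA, 180, 60, 180, 300, 120, 240, 60, 180, 300)
    )
    xyz <- place_zmat(zm)
    atoms <- data.frame(
      name = c("SD", "C3", "C2", "C1", "H31", "H32", "H33", "H21", "H22",
               "H11", "H12", "H13"),
      type = c("S", "CT3", "CT2", "CT3", rep("HA", 8)),
      element = c("S", "C", "C", "C", rep("H", 8)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  } else {
    # order: SG, C, HS (on S), 3 H on C
    zm <- data.frame(
      b   = c(NA, 1, 1, 2, 2, 2),
      r   = c(NA, 1.81, 1.34, 1.09, 1.09, 1.09),
      ang = c(NA, NA, 2, 1, 1, 1),
      a   = c(NA, NA, 96, 110, 110, 110),
      dih = c(NA, NA, NA, 3, 3, 3),
      d   = c(NA, NA, NA, 60, 180, 300)
    )
    xyz <- place_zmat(zm)
    atoms <- data.frame(
      name = c("SG", "C1", "HG", "H11", "H12", "H13"),
      type = c("S", "CT3", "HS", rep("HA", 3)),
      element = c("S", "C", "H", rep("H", 3)),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
  }
  molecule_geometry(atoms, which)
}

#' Read a molecule geometry from an (extended) XYZ file
#'
#' Accepts plain XYZ (`element x y z`) or the extended form written by
#' [write_xyz()] with two trailing columns (`name type`). For plain XYZ the
#' atom name defaults to `element` + index and the type to the element symbol.
#' The comment line, if non-empty, is used as the molecule label unless
#' `label` is given.
#'
#' @param path file path.
#' @param label optional molecule label overriding the comment line.
#' @return A [molecule_geometry()].
#' @export
read_xyz <- function(path, label = NULL) {
  ln <- readLines(path)
  if (length(ln) < 3L) stop("not an XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(ln[1])))
  if (is.na(n)) stop("XYZ count line unreadable in ", path)
  comment <- trimws(ln[2])
  rows <- ln[3:(2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  el <- vapply(parts, `[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  nm <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 5L) parts[[i]][5L] else paste0(el[i], i)
  }, "")
  ty <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 6L) parts[[i]][6L] else el[i]
  }, "")
  if (is.null(label)) label <- if (nzchar(comment)) comment else basename(path)
  molecule_geometry(data.frame(name = nm, type = ty, element = el,
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                    label)
}

#' Write a molecule geometry as extended XYZ
#'
#' @param mol a [molecule_geometry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path) {
  a <- mol$atoms
  lines <- c(nrow(a), mol$label,
             sprintf("%-2s %12.6f %12.6f %12.6f  %-4s %-4s",
                     a$element, a$x, a$y, a$z, a$name, a$type))
  writeLines(lines, path)
  invisible(path)
}

#' Build the ion positions of a sulfur-approach distance scan
#'
#' Generates the rigid-dimer configurations of a potential-energy scan: the
#' molecule is held fixed and the ion is placed at exact anchor-ion distances
#' `r_start + k * step` along a single approach direction. The direction is
#' the unit vector opposite the normalized sum of bond vectors from the anchor
#' sulfur to its covalently bonded neighbours (atoms within `bond_cutoff`),
#' i.e. an approximation to the sulfur lone-pair bisector. The default bounds
#' (2 to 7 Angstrom in 0.1 steps) yield 51 configurations.
#'
#' @param mol a [molecule_geometry()].
#' @param r_start,r_end,step scan bounds and increment, Angstrom.
#' @param anchor_atom name of the anchor atom (the sulfur); defaults to the
#'   first atom whose element is `S`.
#' @param bond_cutoff neighbour-detection distance, Angstrom.
#' @return data frame with columns `distance`, `x`, `y`, `z` (ion positions).
#' @export
build_approach_series <- function(mol, r_start = 2.0, r_end = 7.0, step = 0.1,
                                  anchor_atom = NULL, bond_cutoff = 2.0) {
  if (r_start >= r_end) stop("r_start must be smaller than r_end")
  if (step <= 0) stop("step must be positive")
  a <- mol$atoms
  if (is.null(anchor_atom)) {
    i <- which(a$element == "S")[1]
    if (is.na(i)) stop("no sulfur atom found; supply anchor_atom")
  } else {
    i <- match(anchor_atom, a$name)
    if (is.na(i)) stop("anchor atom '", anchor_atom, "' not in geometry (",
                       paste(a$name, collapse = ", "), ")")
  }
  xyz <- coords(mol)
  anchor <- xyz[i, ]
  dvec <- sqrt(rowSums(sweep(xyz, 2, anchor)^2))
  nb <- which(dvec > 1e-6 & dvec <= bond_cutoff)
  if (length(nb) == 0L) stop("anchor atom has no bonded neighbours within ",
                             bond_cutoff, " Angstrom")
  bonds <- sweep(xyz[nb, , drop = FALSE], 2, anchor)
  bonds <- bonds / sqrt(rowSums(bonds^2))
  v <- colSums(bonds)
  if (sqrt(sum(v^2)) < 1e-8) stop("bond vectors cancel; approach direction undefined")
  dir <- -v / sqrt(sum(v^2))
  r <- seq(r_start, r_end, by = step)
  pos <- t(anchor + t(outer(r, dir)))
  data.frame(distance = r, x = pos[, 1], y = pos[, 2], z = pos[, 3])
}
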