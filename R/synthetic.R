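#' Parameters of the synthetic reference-curve model
#'
#' The reference model stands in for an ab initio ion-thioether scan. It is a
#' fixed-charge dimer energy plus an ion-induced-dipole induction term:
#' `E(r) = Coulomb(charges) + LJ(base_well_depth, base_rmin at the anchor) -
#' induction_B / r^4`, evaluated on the rigid analog geometry along the
#' approach path. The induction term is the minimal physics-motivated model
#' of sulfur polarizability: it deepens and slightly shifts the well the way
#' an electronically polarizable sulfur would, which the fixed-charge force
#' field must then absorb into an effective pair override. The defaults are
#' calibrated once so that the demonstration curve has its minimum near
#' 2.8 Angstrom, the contact distance characteristic of thioether-Na+
#' coordination.
#'
#' @param base_well_depth kcal/mol, positive magnitude of the anchor-ion LJ
#'   well before induction.
#' @param base_rmin Angstrom, anchor-ion LJ minimum position before induction.
#' @param charges named per-atom charge vector (elementary units), or `NULL`
#'   to use the packaged analog charges from [default_parameter_set()].
#' @param induction_B kcal*Angstrom^4/mol, ion-induced-dipole strength
#'   (>= 0; 0 switches induction off).
#' @param seed integer, recorded for provenance (the model is deterministic).
#' @return list of class `ref_model_params`.
#' @export
ref_model_params <- function(base_well_depth = 6.0, base_rmin = 2.9,
                             charges = NULL, induction_B = 160, seed = 1L) {
  if (base_rmin <= 0) stop("base_rmin must be positive")
  if (induction_B < 0) stop("induction_B must be non-negative")
  structure(list(base_well_depth = base_well_depth, base_rmin = base_rmin,
                 charges = charges, induction_B = induction_B,
                 seed = as.integer(seed)),
            class = "ref_model_params")
}

#' Generate a synthetic reference energy curve
#'
#' Evaluates the reference model of [ref_model_params()] on the approach path
#' of `mol` (same path convention as [build_approach_series()]): Coulomb over
#' all atoms with the given charges, a single anchor-ion Lennard-Jones term
#' with the base parameters, and the attractive induction term
#' `-induction_B / r^4`. With `induction_B > 0` the curve minimum is strictly
#' deeper than with `induction_B = 0`. With zero charges and
#' `induction_B = 0` the curve reduces exactly to the pure LJ curve.
#'
#' @param p a [ref_model_params()].
#' @param distances ascending anchor-ion distances, Angstrom.
#' @param mol analog geometry; default [analog_geometry()]`("methylthioethane")`.
#' @param ion_charge ion charge, elementary units.
#' @param coulomb_constant kcal*Angstrom/(mol*e^2).
#' @return An [as_energy_curve()] labelled `"reference"`.
#' @export
make_reference_curve <- function(p, distances = seq(2, 7, by = 0.1),
                                 mol = analog_geometry("methylthioethane"),
                                 ion_charge = 1,
                                 coulomb_constant = 332.0636) {
  stopifnot(inherits(p, "ref_model_params"))
  if (any(diff(distances) <= 0)) stop("distances must be ascending")
  q <- p$charges
  if (is.null(q)) {
    ps <- default_parameter_set()
    q <- vapply(mol$atoms$name,
                function(nm) lookup_charge(ps, mol$label, nm), numeric(1))
  } else {
    q <- q[mol$atoms$name]
    if (anyNA(q)) stop("charges must be named for every atom of the geometry")
  }
  cfg <- approach_at(mol, distances)
  xyz <- coords(mol)
  ion <- as.matrix(cfg[, c("x", "y", "z")])
  rmat <- sqrt(outer(rowSums(xyz^2), rep(1, nrow(ion))) +
               outer(rep(1, nrow(xyz)), rowSums(ion^2)) -
               2 * xyz %*% t(ion))
  coul <- colSums(coulomb_constant * q * ion_charge / rmat)
  x6 <- (p$base_rmin / distances)^6
  lj <- p$base_well_depth * (x6^2 - 2 * x6)
  e <- coul + lj - p$induction_B / distances^4
  as_energy_curve(distances, e, "reference")
}

#' Distance-dependent polarized charge model
#'
#' A qualitative stand-in for population-analysis charges of an ion-polarized
#' thioether: as the ion approaches, charge is transferred from the sulfur's
#' neighbours to the sulfur through a sigmoidal switch, making the sulfur
#' monotonically more negative and its flanking atoms more positive at
#' shorter distances. Total charge is conserved exactly at every distance.
#' The model is deliberately uncalibrated: its testable content is
#' conservation and monotonicity, not particular charge values.
#'
#' @param base_charges named numeric vector of unpolarized charges.
#' @param distance ion-sulfur distance, Angstrom.
#' @param polarization_scale total charge (e) transferred in the
#'   close-contact limit (>= 0).
#' @param sulfur name of the sulfur entry in `base_charges` (default: the
#'   first name starting with `S`).
#' @param midpoint,width sigmoid midpoint and width, Angstrom.
#' @return list with `distance` and `charges` (named, same sum as
#'   `base_charges`).
#' @export
make_polarized_charges <- function(base_charges, distance,
                                   polarization_scale = 0.3,
                                   sulfur = NULL, midpoint = 4, width = 0.8) {
  if (polarization_scale < 0) stop("polarization_scale must be >= 0")
  if (is.null(sulfur)) sulfur <- grep("^S", names(base_charges), value = TRUE)[1]
  if (is.na(sulfur) || !sulfur %in% names(base_charges))
    stop("sulfur atom not found in base_charges")
  t <- polarization_scale / (1 + exp((distance - midpoint) / width))
  q <- base_charges
  others <- setdiff(names(q), sulfur)
  q[sulfur] <- q[sulfur] - t
  q[others] <- q[others] + t / length(others)
  list(distance = distance, charges = q)
}

## --- structure fixtures -----------------------------------------------------

met_template <- function() {
  data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "SD", "CE"),
    element = c("N", "C", "C", "O", "C", "C", "S", "C"),
    x = c(0.0, 1.46, 2.0, 1.3, 2.0, 3.5, 4.2, 6.0),
    y = c(0.0, 0.0, 1.42, 2.4, -0.77, -0.77, -0.8, -0.8),
    z = c(0.0, 0.0, 0.0, 0.0, 1.2, 1.3, 2.9, 2.7)
  )
}

cys_template <- function() {
  data.frame(
    name = c("N", "CA", "C", "O", "CB", "SG"),
    element = c("N", "C", "C", "O", "C", "S"),
    x = c(0.0, 1.46, 2.0, 1.3, 2.0, 3.3),
    y = c(0.0, 0.0, 1.42, 2.4, -0.77, -0.9),
    z = c(0.0, 0.0, 0.0, 0.0, 1.2, 2.3)
  )
}

pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                          x, y, z, element) {
  name4 <- if (nchar(element) == 2L) sprintf("%-4s", name)
           else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, resname, chain, resno, x, y, z, 1.00, 0.00,
          toupper(element))
}

#' Write a minimal structure fixture with known ion-sulfur contacts
#'
#' Emits a single-model PDB-format structure containing one methionine or
#' cysteine residue per requested contact, each with a sodium ion placed at
#' the exact requested distance from the side-chain sulfur, and the requested
#' resolution recorded on a `REMARK 2` line. Residues are spaced 25 Angstrom
#' apart so that each ion's only sub-cutoff sulfur is its own. Intended as
#' constructed ground truth for testing the contact scan; files written by
#' this generator are synthetic fixtures, not deposited structures.
#'
#' @param contacts data frame with columns `residue_kind` (`"MET"` or
#'   `"CYS"`) and `distance` (Angstrom, > 1.5); optional `chain` (default
#'   A, B, ...) and `resno` (default 314).
#' @param resolution Angstrom, recorded in the header.
#' @param structure_id four-character id written on the HEADER line.
#' @param path optional output file; when given, lines are written there.
#' @return character vector of PDB lines (invisibly when `path` is given).
#' @export
make_fixture_structure <- function(contacts, resolution = 2.0,
                                   structure_id = "SYNT", path = NULL) {
  stopifnot(is.data.frame(contacts), nrow(contacts) >= 1L)
  if (any(contacts$distance <= 1.5))
    stop("contact distances must exceed 1.5 Angstrom")
  if (is.null(contacts$chain)) contacts$chain <- LETTERS[seq_len(nrow(contacts))]
  if (is.null(contacts$resno)) contacts$resno <- 314L
  lines <- c(sprintf("HEADER    SYNTHETIC FIXTURE                       01-JAN-20   %s", structure_id),
             sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", resolution))
  serial <- 0L
  ion_lines <- character(0)
  for (i in seq_len(nrow(contacts))) {
    kind <- toupper(contacts$residue_kind[i])
    tmpl <- switch(kind, MET = met_template(), CYS = cys_template(),
                   stop("residue_kind must be MET or CYS"))
    off <- c(25 * (i - 1), 0, 0)
    for (j in seq_len(nrow(tmpl))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("ATOM", serial, tmpl$name[j], kind,
                                      contacts$chain[i], contacts$resno[i],
                                      tmpl$x[j] + off[1], tmpl$y[j] + off[2],
                                      tmpl$z[j] + off[3], tmpl$element[j]))
    }
    s <- tmpl[tmpl$element == "S", ]
    ion <- c(s$x + off[1], s$y + off[2], s$z + off[3] + contacts$distance[i])
    serial <- serial + 1L
    ion_lines <- c(ion_lines,
                   pdb_atom_line("HETATM", serial, "NA", "NA",
                                 contacts$chain[i], 500L + i,
                                 ion[1], ion[2], ion[3], "NA"))
  }
  lines <- c(lines, "TER", ion_lines, "END")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

## --- synthetic trajectories -------------------------------------------------

#' Generate a synthetic binding-site trajectory with known ground truth
#'
#' Emulates the distance phenomenology of an ion bound at a coordination
#' site: the tracked ion (atom `NA1`, always first) fluctuates isotropically
#' (Gaussian, `bound_sigma`) around `site_center` until `t_off_frame`, then
#' performs a biased random walk outward along a fixed random direction with
#' drift `escape_rate` per frame (default 0.1 Angstrom/frame, fast relative to the bound fluctuation) and small step jitter. Optional water atoms
#' fluctuate around fixed stations drawn uniformly in a box around the site.
#' The true dissociation frame is recorded in `ground_truth`; identical seeds
#' give bit-identical trajectories.
#'
#' @param n_frames number of frames (> 0).
#' @param dt time per frame, ns.
#' @param site_center 3-vector, Angstrom.
#' @param bound_sigma per-axis fluctuation of the bound ion, Angstrom (> 0).
#' @param t_off_frame 1-based frame at which dissociation starts, or `NULL`;
#'   values beyond `n_frames` mean the ion never dissociates.
#' @param escape_rate outward drift per frame after dissociation, Angstrom.
#' @param n_waters number of water oxygen stations.
#' @param water_sigma per-axis water fluctuation, Angstrom.
#' @param water_box edge of the water-station box, Angstrom.
#' @param seed integer RNG seed.
#' @return An object of class `ion_trajectory`: list with `frames`
#'   (atoms x 3 x frames array), `labels`, `roles`, `dt`, `site_center`,
#'   `bound_sigma`, `ground_truth` (list with `dissociation_frame` or `NULL`).
#' @export
make_synthetic_trajectory <- function(n_frames, dt = 0.1,
                                      site_center = c(0, 0, 0),
                                      bound_sigma = 0.5, t_off_frame = NULL,
                                      escape_rate = 0.1, n_waters = 0,
                                      water_sigma = 0.3, water_box = 8,
                                      seed = 1L) {
  if (n_frames <= 0) stop("n_frames must be positive")
  if (bound_sigma <= 0) stop("bound_sigma must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (!is.null(t_off_frame) && t_off_frame >= n_frames) t_off_frame <- NULL
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n_atoms <- 1L + n_waters
  frames <- array(NA_real_, c(n_atoms, 3L, n_frames))
  t_off <- t_off_frame
  n_bound <- if (is.null(t_off)) n_frames else t_off - 1L
  if (n_bound > 0)
    frames[1L, , seq_len(n_bound)] <-
      site_center + matrix(stats::rnorm(3 * n_bound, sd = bound_sigma), 3)
  if (!is.null(t_off)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    pos <- site_center
    for (k in t_off:n_frames) {
      pos <- pos + escape_rate * u +
        stats::rnorm(3, sd = bound_sigma * 0.2)
      frames[1L, , k] <- pos
    }
  }
  labels <- "NA1"; roles <- "ion"
  if (n_waters > 0) {
    stations <- matrix(stats::runif(3 * n_waters, -water_box / 2,
                                    water_box / 2), n_waters) +
      matrix(site_center, n_waters, 3, byrow = TRUE)
    for (w in seq_len(n_waters))
      frames[1L + w, , ] <- stations[w, ] +
        matrix(stats::rnorm(3 * n_frames, sd = water_sigma), 3)
    labels <- c(labels, paste0("W", seq_len(n_waters)))
    roles <- c(roles, rep("water", n_waters))
  }
  structure(list(frames = frames, labels = labels, roles = roles, dt = dt,
                 site_center = site_center, bound_sigma = bound_sigma,
                 ground_truth = list(dissociation_frame = t_off)),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  gt <- x$ground_truth$dissociation_frame
  cat(sprintf("<ion_trajectory> %d atoms x %d frames, dt = %g ns%s\n",
              dim(x$frames)[1], dim(x$frames)[3], x$dt,
              if (is.null(gt)) "" else sprintf(", dissociation at frame %d", gt)))
  invisible(x)
}
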