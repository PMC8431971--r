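# Shared fixtures, built in code at test time.

# A minimal "bare dimer" system: one neutral sulfur-like site and an ion
# type, no charges anywhere. The MM curve of this system is a pure LJ curve,
# which makes analytic expectations exact.
minimal_params <- function(eps_s = 0.45, rmin_half_s = 2.0,
                           eps_ion = 0.0469, rmin_half_ion = 1.41075) {
  parameter_set(
    lj_types = data.frame(type = c("S", "SOD"),
                          well_depth = c(eps_s, eps_ion),
                          rmin_half = c(rmin_half_s, rmin_half_ion)),
    charges = data.frame(molecule = "onesite", atom = "S1", charge = 0))
}

one_site_molecule <- function() {
  # a sulfur with a dummy neighbour to define the approach direction
  molecule_geometry(
    data.frame(name = c("S1", "C1"), type = c("S", "CT3"),
               element = c("S", "C"),
               x = c(0, 0), y = c(0, 0), z = c(0, 1.81)),
    "onesite")
}

one_site_params <- function(...) {
  p <- minimal_params(...)
  parameter_set(
    lj_types = rbind(p$lj_types,
                     data.frame(type = "CT3", well_depth = 0, rmin_half = 1)),
    charges = data.frame(molecule = "onesite", atom = c("S1", "C1"),
                         charge = c(0, 0)))
}

# Reference curve produced by the package's own MM model with a known
# override installed; used for parameter-recovery tests.
mm_generated_reference <- function(eps, rmin, mol = analog_geometry("methylthioethane"),
                                   params = default_parameter_set()) {
  ov <- data.frame(type_a = "S", type_b = "SOD",
                   well_depth = eps, rmin = rmin)
  cfg <- build_approach_series(mol)
  curve <- energy_curve(cfg, mol,
                        parameter_set(params$lj_types, params$charges, ov,
                                      params$coulomb_constant))
  curve$source_label <- "reference"
  curve
}

# Independent brute-force oracle for the dimer energy: explicit per-pair
# loop with no shared code path (combination rule and LJ form restated).
brute_force_energy <- function(mol, ion_pos, params, ion_type = "SOD",
                               ion_charge = 1) {
  total <- 0
  lj <- params$lj_types
  for (i in seq_len(nrow(mol$atoms))) {
    a <- mol$atoms[i, ]
    r <- sqrt((a$x - ion_pos[1])^2 + (a$y - ion_pos[2])^2 +
              (a$z - ion_pos[3])^2)
    q <- params$charges$charge[params$charges$molecule == mol$label &
                               params$charges$atom == a$name][1]
    ov <- params$overrides
    hit <- ov[(ov$type_a == a$type & ov$type_b == ion_type) |
              (ov$type_a == ion_type & ov$type_b == a$type), ]
    if (nrow(hit) > 0) {
      eps <- hit$well_depth[1]; rmin <- hit$rmin[1]
    } else {
      eps <- sqrt(lj$well_depth[lj$type == a$type] *
                  lj$well_depth[lj$type == ion_type])
      rmin <- lj$rmin_half[lj$type == a$type] +
        lj$rmin_half[lj$type == ion_type]
    }
    total <- total + params$coulomb_constant * q * ion_charge / r +
      eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  total
}

# Independent brute-force oracle for structure contacts: parse ATOM/HETATM
# records directly from the fixed-width columns and compute all ion-sulfur
# distances, no shared code with scan_structure().
oracle_contacts <- function(path, cutoff = 3.5) {
  ln <- grep("^(ATOM|HETATM)", readLines(path), value = TRUE)
  f <- function(l, a, b) trimws(substr(l, a, b))
  tab <- data.frame(
    name = vapply(ln, f, "", 13, 16),
    resname = vapply(ln, f, "", 18, 20),
    x = as.numeric(vapply(ln, f, "", 31, 38)),
    y = as.numeric(vapply(ln, f, "", 39, 46)),
    z = as.numeric(vapply(ln, f, "", 47, 54)), row.names = NULL)
  ions <- tab[tab$resname == "NA", ]
  sulf <- tab[(tab$resname == "MET" & tab$name == "SD") |
              (tab$resname == "CYS" & tab$name == "SG"), ]
  out <- numeric(0)
  for (i in seq_len(nrow(ions)))
    for (j in seq_len(nrow(sulf))) {
      d <- sqrt(sum((ions[i, c("x", "y", "z")] -
                     sulf[j, c("x", "y", "z")])^2))
      if (d <= cutoff) out <- c(out, d)
    }
  sort(out)
}

# Random rigid-body transform helpers.
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(xyz, R, t) sweep(xyz %*% t(R), 2, t, "+")

# Build a hand-made trajectory from an atoms x 3 x frames array.
manual_trajectory <- function(frames, labels = NULL, dt = 0.1) {
  if (is.null(labels)) labels <- paste0("A", seq_len(dim(frames)[1]))
  structure(list(frames = frames, labels = labels,
                 roles = rep("atom", length(labels)), dt = dt,
                 ground_truth = list(dissociation_frame = NULL)),
            class = "ion_trajectory")
}
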