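#' Distance-energy curves
#'
#' An `energy_curve` is a table of anchor-ion distances (Angstrom, strictly
#' increasing) and interaction energies (kcal/mol), tagged with a provenance
#' label: `"reference"` for a reference scan the fit targets, `"mm_default"`
#' for the molecular-mechanics curve under generic combination rules, or
#' `"mm_nbfix"` when a pair override is in force.
#'
#' @param distances ascending numeric vector, Angstrom.
#' @param energies numeric vector of equal length, kcal/mol.
#' @param source_label one of `"reference"`, `"mm_default"`, `"mm_nbfix"`.
#' @return An object of class `energy_curve`.
#' @export
as_energy_curve <- function(distances, energies,
                            source_label = c("reference", "mm_default",
                                             "mm_nbfix")) {
  source_label <- match.arg(source_label)
  if (length(distances) != length(energies))
    stop("distances and energies must have equal length")
  if (any(diff(distances) <= 0))
    stop("distances must be strictly increasing")
  structure(list(distances = as.numeric(distances),
                 energies = as.numeric(energies),
                 source_label = source_label),
            class = "energy_curve")
}

#' @export
print.energy_curve <- function(x, ...) {
  m <- which.min(x$energies)
  cat(sprintf("<energy_curve> %s: %d points, %.2f-%.2f A, min %.3f kcal/mol near %.2f A\n",
              x$source_label, length(x$distances), min(x$distances),
              max(x$distances), x$energies[m], x$distances[m]))
  invisible(x)
}

#' @export
as.data.frame.energy_curve <- function(x, ...)
  data.frame(distance_A = x$distances, energy_kcal_mol = x$energies)

#' Read / write energy curves as two-column TSV
#'
#' The file carries a `# source: <label>` header line followed by a
#' `distance_A<TAB>energy_kcal_mol` header and the data rows.
#'
#' @param curve an [as_energy_curve()] object.
#' @param path file path.
#' @return `write_curve` returns `path` invisibly; `read_curve` the curve.
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# source: ", curve$source_label), con)
  writeLines("distance_A\tenergy_kcal_mol", con)
  writeLines(sprintf("%.10g\t%.10g", curve$distances, curve$energies), con)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  ln <- readLines(path)
  src <- sub("^# source:\\s*", "", ln[1])
  if (!src %in% c("reference", "mm_default", "mm_nbfix"))
    stop("missing or unknown '# source:' header in ", path)
  d <- utils::read.table(text = ln[-(1:2)], sep = "\t")
  as_energy_curve(d[[1]], d[[2]], src)
}

ion_record <- function(position, type = "SOD", charge = 1, name = "ION",
                       element = "Na") {
  list(name = name, type = type, element = element, charge = charge,
       position = as.numeric(position))
}

#' Nonbonded interaction energy between a rigid molecule and an ion
#'
#' Sums, over every (atom, ion) pair, the Coulomb term
#' `k_e * q_i * q_ion / r` and the 12-6 Lennard-Jones term
#' `eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)`, with the pair parameters
#' from [combine_lj()] (so NBFIX overrides apply) and epsilon entering as a
#' negative well: the minimum of an isolated neutral pair is `-eps_ij` at
#' `r = Rmin_ij`. No cutoff or switching is applied; the scan geometry is a
#' bare dimer.
#'
#' @param mol a [molecule_geometry()].
#' @param ion_position 3-vector, Angstrom.
#' @param params a [parameter_set()] carrying charges for `mol$label`.
#' @param ion_type LJ type of the ion (default `"SOD"`).
#' @param ion_charge ion charge, elementary units (default +1).
#' @return energy in kcal/mol.
#' @export
pair_interaction_energy <- function(mol, ion_position, params,
                                    ion_type = "SOD", ion_charge = 1) {
  a <- mol$atoms
  xyz <- coords(mol)
  r <- sqrt(rowSums(sweep(xyz, 2, as.numeric(ion_position))^2))
  if (any(r < 0.1))
    stop("ion within 0.1 Angstrom of atom ",
         a$name[which.min(r)], "; energy singular")
  q <- vapply(a$name, function(nm) lookup_charge(params, mol$label, nm),
              numeric(1))
  lj <- vapply(a$type, function(ty) combine_lj(ty, ion_type, params),
               numeric(2))
  eps <- lj[1, ]; rmin <- lj[2, ]
  x6 <- (rmin / r)^6
  sum(params$coulomb_constant * q * ion_charge / r + eps * (x6^2 - 2 * x6))
}

#' Evaluate an energy curve over scan configurations
#'
#' Computes [pair_interaction_energy()] at every ion position of an approach
#' series (see [build_approach_series()]). The curve is labelled
#' `"mm_default"` when the parameter set carries no pair overrides and
#' `"mm_nbfix"` otherwise.
#'
#' @param configs data frame from [build_approach_series()] (columns
#'   `distance`, `x`, `y`, `z`).
#' @inheritParams pair_interaction_energy
#' @return An [as_energy_curve()] object.
#' @export
energy_curve <- function(configs, mol, params, ion_type = "SOD",
                         ion_charge = 1) {
  if (nrow(configs) == 0L) stop("no scan configurations supplied")
  e <- vapply(seq_len(nrow(configs)), function(i)
    pair_interaction_energy(mol, c(configs$x[i], configs$y[i], configs$z[i]),
                            params, ion_type, ion_charge),
    numeric(1))
  lab <- if (nrow(params$overrides) > 0L) "mm_nbfix" else "mm_default"
  as_energy_curve(configs$distance, e, lab)
}
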