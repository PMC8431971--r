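#' Force-field parameter sets in the CHARMM dialect
#'
#' A `parameter_set` carries per-type Lennard-Jones parameters, per-atom
#' partial charges keyed by (molecule label, atom name), and pair-specific
#' overrides (NBFIX). Conventions follow the CHARMM parameter-file dialect:
#' the file stores the well depth epsilon as a negative number and per-type
#' Rmin/2; internally the well depth is always a positive magnitude, and pair
#' overrides carry the full pair Rmin.
#'
#' @param lj_types data frame with columns `type`, `well_depth` (kcal/mol,
#'   positive magnitude), `rmin_half` (Angstrom).
#' @param charges data frame with columns `molecule`, `atom`, `charge`
#'   (elementary charge units); may be empty.
#' @param overrides data frame with columns `type_a`, `type_b`, `well_depth`
#'   (positive magnitude), `rmin` (full pair Rmin, Angstrom); may be empty.
#' @param coulomb_constant electrostatic prefactor, kcal*Angstrom/(mol*e^2).
#'   Default is the CHARMM convention value 332.0636.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(lj_types,
                          charges = empty_charges(),
                          overrides = empty_overrides(),
                          coulomb_constant = 332.0636) {
  stopifnot(is.data.frame(lj_types))
  if (nrow(lj_types) == 0L) stop("at least one LJ type is required")
  if (anyDuplicated(lj_types$type))
    stop("duplicate LJ type: ",
         paste(unique(lj_types$type[duplicated(lj_types$type)]), collapse = ", "))
  if (any(lj_types$well_depth < 0)) stop("well_depth must be stored as positive magnitude")
  if (any(lj_types$rmin_half <= 0)) stop("rmin_half must be positive")
  if (nrow(overrides) > 0L && any(overrides$rmin <= 0))
    stop("override rmin must be positive")
  if (coulomb_constant <= 0) stop("coulomb_constant must be positive")
  structure(list(lj_types = lj_types, charges = charges,
                 overrides = overrides, coulomb_constant = coulomb_constant),
            class = "parameter_set")
}

empty_charges <- function()
  data.frame(molecule = character(), atom = character(), charge = numeric())
empty_overrides <- function()
  data.frame(type_a = character(), type_b = character(),
             well_depth = numeric(), rmin = numeric())

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> ", nrow(x$lj_types), " LJ types, ",
      nrow(x$charges), " charges, ", nrow(x$overrides),
      " NBFIX override(s)\n", sep = "")
  if (nrow(x$overrides) > 0L)
    for (i in seq_len(nrow(x$overrides)))
      cat(sprintf("  NBFIX %s-%s: eps = -%.4g kcal/mol, Rmin = %.4g A\n",
                  x$overrides$type_a[i], x$overrides$type_b[i],
                  x$overrides$well_depth[i], x$overrides$rmin[i]))
  invisible(x)
}

strip_comment <- function(x) sub("!.*$", "", x)

#' Parse parameter text in the CHARMM dialect
#'
#' Recognized sections: `NONBONDED` (columns `type ignored -eps rmin_half`,
#' epsilon written negative as in CHARMM files), optional `NBFIX`
#' (`type_a type_b -eps rmin`, full pair Rmin), and an optional `CHARGES`
#' section (`molecule atom charge`) which this dialect adds to carry the
#' partial charges that CHARMM proper keeps in topology files. Comments start
#' with `!`; `END` or a new section keyword closes a section.
#'
#' @param text character vector of lines, or a single string with embedded
#'   newlines.
#' @param coulomb_constant see [parameter_set()].
#' @return A [parameter_set()].
#' @seealso [read_parameter_file()], [write_parameter_set()]
#' @export
load_parameter_set <- function(text, coulomb_constant = 332.0636) {
  if (length(text) == 1L && grepl("\n", text))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  section <- ""
  lj <- list(); ov <- list(); ch <- list()
  keywords <- c("NONBONDED", "NBFIX", "CHARGES", "END")
  for (i in seq_along(text)) {
    ln <- trimws(strip_comment(text[i]))
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (toupper(tok[1]) %in% keywords) {
      section <- toupper(tok[1])
      if (section == "END") section <- ""
      next
    }
    bad <- function(msg) stop("parse error at line ", i, ": ", msg,
                              " [", text[i], "]", call. = FALSE)
    if (section == "NONBONDED") {
      if (length(tok) < 4L) bad("expected 'type ignored epsilon rmin_half'")
      val <- suppressWarnings(as.numeric(tok[2:4]))
      if (any(is.na(val))) bad("non-numeric field")
      if (val[2] > 0) bad("epsilon must be written as a negative number")
      lj[[length(lj) + 1L]] <- data.frame(type = tok[1],
                                          well_depth = abs(val[2]),
                                          rmin_half = val[3])
    } else if (section == "NBFIX") {
      if (length(tok) < 4L) bad("expected 'type_a type_b epsilon rmin'")
      val <- suppressWarnings(as.numeric(tok[3:4]))
      if (any(is.na(val))) bad("non-numeric field")
      if (val[1] > 0) bad("epsilon must be written as a negative number")
      ov[[length(ov) + 1L]] <- data.frame(type_a = tok[1], type_b = tok[2],
                                          well_depth = abs(val[1]),
                                          rmin = val[2])
    } else if (section == "CHARGES") {
      if (length(tok) < 3L) bad("expected 'molecule atom charge'")
      q <- suppressWarnings(as.numeric(tok[3]))
      if (is.na(q)) bad("non-numeric charge")
      ch[[length(ch) + 1L]] <- data.frame(molecule = tok[1], atom = tok[2],
                                          charge = q)
    } else {
      bad("content outside any recognized section")
    }
  }
  if (length(lj) == 0L)
    stop("no NONBONDED entries found; the NONBONDED section is required")
  parameter_set(do.call(rbind, lj),
                if (length(ch)) do.call(rbind, ch) else empty_charges(),
                if (length(ov)) do.call(rbind, ov) else empty_overrides(),
                coulomb_constant)
}

#' @rdname load_parameter_set
#' @param path path to a parameter file.
#' @export
read_parameter_file <- function(path, coulomb_constant = 332.0636)
  load_parameter_set(readLines(path), coulomb_constant)

#' Serialize NBFIX overrides in the CHARMM dialect
#'
#' Writes one `type_a type_b -eps rmin` line per override, epsilon with a
#' negative sign as CHARMM files require. The output round-trips through
#' [load_parameter_set()] bit-identically for the override fields.
#'
#' @param overrides data frame of overrides as in [parameter_set()], or a
#'   `parameter_set` whose overrides are taken.
#' @param header include the `NBFIX` section keyword line.
#' @return character vector of lines.
#' @export
write_nbfix_stanza <- function(overrides, header = TRUE) {
  if (inherits(overrides, "parameter_set")) overrides <- overrides$overrides
  if (nrow(overrides) == 0L) stop("no overrides to write")
  lines <- sprintf("%-6s %-6s %s %s", overrides$type_a, overrides$type_b,
                   paste0("-", format(overrides$well_depth, trim = TRUE,
                                      digits = 15)),
                   format(overrides$rmin, trim = TRUE, digits = 15))
  if (header) c("NBFIX", lines) else lines
}

#' Serialize a full parameter set in the CHARMM dialect
#'
#' @param params a [parameter_set()].
#' @param path optional file path; if given, lines are written there.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_parameter_set <- function(params, path = NULL) {
  lj <- params$lj_types
  lines <- c("NONBONDED",
             sprintf("%-6s 0.0 %s %s", lj$type,
                     paste0("-", format(lj$well_depth, trim = TRUE, digits = 15)),
                     format(lj$rmin_half, trim = TRUE, digits = 15)))
  if (nrow(params$charges) > 0L) {
    ch <- params$charges
    lines <- c(lines, "", "CHARGES",
               sprintf("%-18s %-6s %s", ch$molecule, ch$atom,
                       format(ch$charge, trim = TRUE, digits = 15)))
  }
  if (nrow(params$overrides) > 0L)
    lines <- c(lines, "", write_nbfix_stanza(params$overrides))
  lines <- c(lines, "END")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Combine Lennard-Jones parameters for an atom-type pair
#'
#' Applies the pair override (NBFIX) verbatim when one exists for the pair
#' (in either order); otherwise uses the Lorentz-Berthelot rules of the
#' dialect: geometric-mean well depth, arithmetic sum of the per-type Rmin/2.
#'
#' @param type_a,type_b atom-type labels.
#' @param params a [parameter_set()].
#' @return named numeric vector `c(well_depth =, rmin =)` (kcal/mol, Angstrom).
#' @export
combine_lj <- function(type_a, type_b, params) {
  ov <- params$overrides
  if (nrow(ov) > 0L) {
    hit <- which((ov$type_a == type_a & ov$type_b == type_b) |
                 (ov$type_a == type_b & ov$type_b == type_a))
    if (length(hit) > 0L) {
      i <- hit[1]
      return(c(well_depth = ov$well_depth[i], rmin = ov$rmin[i]))
    }
  }
  lj <- params$lj_types
  ia <- match(type_a, lj$type); ib <- match(type_b, lj$type)
  if (is.na(ia)) stop("unknown atom type: ", type_a)
  if (is.na(ib)) stop("unknown atom type: ", type_b)
  c(well_depth = sqrt(lj$well_depth[ia] * lj$well_depth[ib]),
    rmin = lj$rmin_half[ia] + lj$rmin_half[ib])
}

lookup_charge <- function(params, molecule, atom) {
  ch <- params$charges
  i <- which(ch$molecule == molecule & ch$atom == atom)
  if (length(i) == 0L)
    stop("no charge recorded for (", molecule, ", ", atom, ")")
  ch$charge[i[1]]
}

#' Packaged default parameters for the thioether/thiol analogs
#'
#' A small CHARMM-dialect parameter set covering the atom types of the
#' packaged analog geometries (aliphatic carbons, nonpolar hydrogens, a thiol
#' hydrogen, thioether/thiol sulfur) and the sodium ion, with neutral-molecule
#' partial charges patterned on aliphatic-sulfide charge assignments. The same
#' content ships as `inst/extdata/base_charmm.prm`.
#'
#' @param with_met_override if `TRUE`, include the packaged S-Na+ NBFIX
#'   correction (well depth 13.4 kcal/mol, Rmin 2.8 Angstrom).
#' @return A [parameter_set()].
#' @export
default_parameter_set <- function(with_met_override = FALSE) {
  lj <- data.frame(
    type = c("CT3", "CT2", "HA", "HS", "S", "SOD"),
    well_depth = c(0.078, 0.056, 0.024, 0.10, 0.45, 0.0469),
    rmin_half = c(2.040, 2.010, 1.340, 0.450, 2.000, 1.41075)
  )
  ch <- rbind(
    data.frame(molecule = "methylthioethane",
               atom = c("SD", "C3", "C2", "C1",
                        "H31", "H32", "H33", "H21", "H22",
                        "H11", "H12", "H13"),
               charge = c(-0.09, -0.22, -0.14, -0.27, rep(0.09, 8))),
    data.frame(molecule = "methanethiol",
               atom = c("SG", "C1", "HG", "H11", "H12", "H13"),
               charge = c(-0.23, -0.20, 0.16, rep(0.09, 3)))
  )
  ov <- if (with_met_override) met_na_override() else empty_overrides()
  parameter_set(lj, ch, ov)
}

#' The packaged S-Na+ NBFIX correction
#'
#' The pair-specific Lennard-Jones override for the thioether sulfur - sodium
#' interaction distributed with this package: well depth 13.4 kcal/mol
#' (written as -13.4 in the CHARMM dialect) and pair Rmin 2.8 Angstrom.
#'
#' @return one-row override data frame as in [parameter_set()].
#' @export
met_na_override <- function() {
  data.frame(type_a = "S", type_b = "SOD", well_depth = 13.4, rmin = 2.8)
}

#' Apply or replace pair overrides on a parameter set
#'
#' @param params a [parameter_set()].
#' @param overrides override data frame (see [parameter_set()]).
#' @return A new `parameter_set` with `overrides` installed.
#' @export
with_override <- function(params, overrides) {
  parameter_set(params$lj_types, params$charges, overrides,
                params$coulomb_constant)
}
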