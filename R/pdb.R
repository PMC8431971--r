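#' @importFrom bio3d read.pdb read.cif
NULL

## Read a structure file (PDB or mmCIF, optionally gzipped) into a uniform
## atom table. Uses bio3d for parsing; only the first model is read.
read_structure_atoms <- function(path) {
  real <- path
  if (grepl("\\.gz$", path)) {
    tmp <- tempfile(fileext = paste0(".", tools::file_ext(sub("\\.gz$", "", path))))
    con <- gzfile(path, "rt"); on.exit(close(con))
    writeLines(readLines(con), tmp)
    real <- tmp
  }
  ext <- tolower(tools::file_ext(real))
  pdb <- tryCatch(
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(real, verbose = FALSE)
    else bio3d::read.pdb(real, verbose = FALSE, multi = FALSE),
    error = function(e) stop("cannot parse structure file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- pdb$atom
  data.frame(type = a$type, name = a$elety, alt = a$alt, resname = a$resid,
             chain = a$chain, resno = a$resno, x = a$x, y = a$y, z = a$z,
             occupancy = if (!is.null(a$o)) a$o else 1,
             element = if (!is.null(a$elesy)) a$elesy else "",
             stringsAsFactors = FALSE)
}

## Resolution from REMARK 2 (PDB) or the standard mmCIF items; NA if absent.
structure_resolution <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  ln <- readLines(con)
  hit <- grep("^REMARK\\s+2\\s+RESOLUTION\\.", ln, value = TRUE)
  if (length(hit) > 0L) {
    v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.\\s*([0-9.]+).*", "\\1",
                                         hit[1])))
    return(v)
  }
  cif <- grep("_(refine\\.ls_d_res_high|reflns\\.d_resolution_high)\\s",
              ln, value = TRUE)
  if (length(cif) > 0L) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(cif[1]), "\\s+")[[1]][2]))
    return(v)
  }
  NA_real_
}

## Altloc policy: keep the highest-occupancy conformer of each
## (chain, resno, name) group; ties resolved in favour of altloc "A"/"".
resolve_altloc <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "" | alt == "A")) return(atoms[alt %in% c("", "A"), , drop = FALSE])
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name)
  ord <- order(key, -atoms$occupancy, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$resname,
                          atoms$name)), , drop = FALSE]
}

is_na_ion <- function(atoms)
  atoms$resname == "NA" &
    (toupper(trimws(atoms$element)) == "NA" | trimws(atoms$name) == "NA")

is_thiolate_sulfur <- function(atoms)
  (atoms$resname == "MET" & atoms$name == "SD") |
  (atoms$resname == "CYS" & atoms$name == "SG")

#' Scan one structure for sodium-sulfur contacts
#'
#' Finds every pair of a sodium ion (HETATM with residue name `NA`) and a
#' methionine `SD` or cysteine `SG` sulfur whose distance does not exceed
#' `distance_cutoff` (inclusive). Structures whose recorded resolution
#' exceeds `resolution_max` yield no hits; a missing resolution raises a
#' warning and the structure is skipped (reported by [scan_corpus()]).
#' Only the first model is scanned and the highest-occupancy alternate
#' conformer is used.
#'
#' @param path structure file (`.pdb`, `.ent`, `.cif`, optionally `.gz`).
#' @param distance_cutoff contact distance threshold, Angstrom (default 3.5,
#'   inclusive).
#' @param resolution_max maximum accepted resolution, Angstrom (default 3.0);
#'   `Inf` disables the filter.
#' @param structure_id id to report; default the file base name.
#' @return data frame of contact hits with columns `structure_id`,
#'   `resolution`, `ion_chain`, `ion_resnum`, `residue_kind`,
#'   `residue_chain`, `residue_resnum`, `sulfur_atom`, `distance_A`,
#'   `model_number`. Zero rows when nothing qualifies.
#' @export
scan_structure <- function(path, distance_cutoff = 3.5, resolution_max = 3.0,
                           structure_id = NULL) {
  if (is.null(structure_id))
    structure_id <- sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                        basename(path), ignore.case = TRUE)
  empty <- data.frame(structure_id = character(), resolution = numeric(),
                      ion_chain = character(), ion_resnum = integer(),
                      residue_kind = character(), residue_chain = character(),
                      residue_resnum = integer(), sulfur_atom = character(),
                      distance_A = numeric(), model_number = integer())
  res <- structure_resolution(path)
  if (is.na(res)) {
    warning("no resolution recorded in ", path, "; structure skipped")
    return(structure(empty, skipped = TRUE))
  }
  if (res > resolution_max) return(empty)
  atoms <- resolve_altloc(read_structure_atoms(path))
  ions <- atoms[is_na_ion(atoms), , drop = FALSE]
  sulf <- atoms[is_thiolate_sulfur(atoms), , drop = FALSE]
  if (nrow(ions) == 0L || nrow(sulf) == 0L) return(empty)
  hits <- empty
  for (i in seq_len(nrow(ions))) {
    d <- sqrt((sulf$x - ions$x[i])^2 + (sulf$y - ions$y[i])^2 +
              (sulf$z - ions$z[i])^2)
    sel <- which(d <= distance_cutoff)
    if (length(sel) == 0L) next
    hits <- rbind(hits, data.frame(
      structure_id = structure_id, resolution = res,
      ion_chain = ions$chain[i], ion_resnum = ions$resno[i],
      residue_kind = sulf$resname[sel], residue_chain = sulf$chain[sel],
      residue_resnum = sulf$resno[sel], sulfur_atom = sulf$name[sel],
      distance_A = d[sel], model_number = 1L))
  }
  hits
}

#' Scan a corpus of structure files for sodium-sulfur contacts
#'
#' Applies [scan_structure()] to every path (or to every structure file in a
#' directory), concatenating hits sorted by structure id then distance.
#' Individual file failures and structures without a recorded resolution are
#' logged, counted and skipped; the scan continues.
#'
#' @param paths character vector of files, or a single directory.
#' @param distance_cutoff,resolution_max as in [scan_structure()].
#' @return list with `hits` (combined contact table) and `summary`
#'   (list: `scanned`, `skipped`, `structures_with_hits`, `n_hits`,
#'   `warnings`).
#' @export
scan_corpus <- function(paths, distance_cutoff = 3.5, resolution_max = 3.0) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)(\\.gz)?$",
                        full.names = TRUE, ignore.case = TRUE)
  hits <- list(); scanned <- 0L; skipped <- 0L; warns <- character(0)
  for (p in paths) {
    h <- tryCatch(
      withCallingHandlers(
        scan_structure(p, distance_cutoff, resolution_max),
        warning = function(w) {
          warns <<- c(warns, conditionMessage(w))
          invokeRestart("muffleWarning")
        }),
      error = function(e) {
        warns <<- c(warns, conditionMessage(e))
        structure(data.frame(), skipped = TRUE)
      })
    if (isTRUE(attr(h, "skipped"))) { skipped <- skipped + 1L; next }
    scanned <- scanned + 1L
    if (nrow(h) > 0L) hits[[length(hits) + 1L]] <- h
  }
  tab <- if (length(hits)) do.call(rbind, hits) else
    scan_structure_empty_table()
  if (nrow(tab) > 0L)
    tab <- tab[order(tab$structure_id, tab$distance_A), , drop = FALSE]
  list(hits = tab,
       summary = list(scanned = scanned, skipped = skipped,
                      structures_with_hits = length(unique(tab$structure_id)),
                      n_hits = nrow(tab), warnings = warns))
}

scan_structure_empty_table <- function()
  data.frame(structure_id = character(), resolution = numeric(),
             ion_chain = character(), ion_resnum = integer(),
             residue_kind = character(), residue_chain = character(),
             residue_resnum = integer(), sulfur_atom = character(),
             distance_A = numeric(), model_number = integer())

#' Per-chain ion-atom site distance and its mean
#'
#' For each chain, reports the minimum distance between any atom matched by
#' `ion_selector` and any atom matched by `atom_selector` within that chain,
#' plus the mean over chains. Selectors are lists of atom-table filters
#' (`resname`, `name`, `resno`, `chain`, `element`), combined with AND;
#' a selector that matches nothing is an error listing the candidates.
#'
#' @param path structure file.
#' @param ion_selector,atom_selector selector lists, e.g.
#'   `list(resname = "NA")` and `list(resname = "MET", resno = 314,
#'   name = "SD")`.
#' @param group_by_chain when `FALSE`, a single global minimum is returned.
#' @param digits rounding applied to the reported mean (default 1, i.e.
#'   0.1 Angstrom).
#' @return list with `per_chain` (named numeric), `mean` (rounded) and
#'   `mean_unrounded`.
#' @export
measure_site_distance <- function(path, ion_selector = list(resname = "NA"),
                                  atom_selector, group_by_chain = TRUE,
                                  digits = 1) {
  atoms <- resolve_altloc(read_structure_atoms(path))
  pick <- function(sel, what) {
    keep <- rep(TRUE, nrow(atoms))
    for (f in names(sel)) {
      if (!f %in% names(atoms)) stop("unknown selector field: ", f)
      keep <- keep & atoms[[f]] %in% sel[[f]]
    }
    out <- atoms[keep, , drop = FALSE]
    if (nrow(out) == 0L)
      stop(what, " selector matched nothing; available residues: ",
           paste(utils::head(unique(paste(atoms$resname, atoms$resno)), 20),
                 collapse = ", "))
    out
  }
  ions <- pick(ion_selector, "ion")
  targ <- pick(atom_selector, "atom")
  chains <- if (group_by_chain) sort(unique(targ$chain)) else "all"
  per <- vapply(chains, function(ch) {
    tt <- if (group_by_chain) targ[targ$chain == ch, , drop = FALSE] else targ
    ii <- if (group_by_chain && any(ions$chain == ch))
      ions[ions$chain == ch, , drop = FALSE] else ions
    min(sqrt(outer(tt$x, ii$x, "-")^2 + outer(tt$y, ii$y, "-")^2 +
             outer(tt$z, ii$z, "-")^2))
  }, numeric(1))
  names(per) <- chains
  list(per_chain = per, mean = round(mean(per), digits),
       mean_unrounded = mean(per))
}

#' Write a contact table as TSV
#'
#' @param hits contact table from [scan_structure()] or [scan_corpus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
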