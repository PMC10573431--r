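#' Read a PDB structure into an atom tibble
#'
#' Parses ATOM and HETATM records of a (single-model) PDB file into a tibble
#' with one row per atom. HETATM records are treated identically to ATOM
#' records, because organophosphate moieties and the fluoride ion appear as
#' heteroatoms in real entries. If the file contains several MODEL blocks only
#' the first is returned; use [read_trajectory()] for multi-model files.
#'
#' Partial charges are never taken from the PDB file (the format has no
#' reliable charge column); they enter through adduct tables
#' ([read_adduct_table()]) or explicit assignment to the `charge` column.
#'
#' @param path Path to a PDB file.
#' @return A tibble with columns `serial`, `name`, `element`, `resname`,
#'   `resseq`, `chain`, `x`, `y`, `z` (Angstrom) and `charge` (NA unless
#'   assigned later), plus a `"title"` attribute.
#' @seealso [write_pdb()], [select_atom()], [read_trajectory()]
#' @export
#' @examples
#' site <- make_active_site(n_waters_near = 2, n_waters_far = 1, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(site, f)
#' read_pdb(f)
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  check_pdb_coordinates(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atoms_from_bio3d(pdb, path)
}

# Fixed-column sanity scan so that a malformed coordinate field is reported
# with its line number (bio3d would silently coerce or fail opaquely).
check_pdb_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    xyz <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
             substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(xyz))
    if (any(is.na(vals)) || any(!is.finite(vals))) {
      abort(paste0("malformed coordinate field on line ", i, " of ", path,
                   ": '", trimws(lines[i]), "'"))
    }
  }
  if (!any(is_atom)) {
    abort(paste0("no ATOM/HETATM records in ", path))
  }
  invisible(TRUE)
}

atoms_from_bio3d <- function(pdb, path) {
  at <- pdb$atom
  n <- nrow(at)
  if (is.null(at) || n == 0) abort(paste0("empty structure in ", path))
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | elem == ""
  # fall back on the first letter of the atom name when the element column
  # is absent (common in hand-made files)
  elem[blank] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[blank])), 1, 1)
  out <- tibble(
    serial  = as.integer(at$eleno),
    name    = trimws(at$elety),
    element = toupper(elem),
    resname = trimws(at$resid),
    resseq  = as.integer(at$resno),
    chain   = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    charge  = NA_real_
  )
  if (anyDuplicated(out$serial)) {
    out$serial <- seq_len(n)
  }
  attr(out, "title") <- if (!is.null(pdb$header)) paste(pdb$header, collapse = " ") else ""
  out
}

#' Write an atom tibble as a PDB file
#'
#' @param structure Atom tibble as returned by [read_pdb()] or
#'   [make_active_site()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  validate_structure(structure)
  het <- structure$resname %in% c("HOH", "WAT", "SOL") |
    structure$element %in% c("F", "CL", "BR", "I", "NA", "K")
  bio3d::write.pdb(
    file = path,
    xyz  = as.vector(rbind(structure$x, structure$y, structure$z)),
    type = ifelse(het, "HETATM", "ATOM"),
    resno = structure$resseq,
    resid = structure$resname,
    eleno = structure$serial,
    elety = structure$name,
    chain = structure$chain,
    elesy = structure$element
  )
  invisible(path)
}

validate_structure <- function(structure) {
  needed <- c("serial", "name", "element", "resname", "resseq", "chain",
              "x", "y", "z")
  missing <- setdiff(needed, names(structure))
  if (length(missing) > 0) {
    abort(paste0("structure lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(structure) == 0) abort("structure has no atoms")
  if (!all(is.finite(structure$x) & is.finite(structure$y) & is.finite(structure$z))) {
    abort("structure has non-finite coordinates")
  }
  if (anyDuplicated(structure$serial)) abort("duplicate atom serials")
  invisible(structure)
}

#' Select a single atom by residue number and atom name
#'
#' Addressing convention used throughout: an atom is identified by the
#' `(resseq, name)` pair, e.g. `(198, "OG")` for the catalytic serine's
#' gamma-oxygen or `(438, "NE2")` for the protonated histidine nitrogen.
#'
#' @param structure Atom tibble.
#' @param resseq Residue sequence number.
#' @param name Atom name (e.g. `"P"`, `"OG"`, `"NE2"`, `"F"`).
#' @return One-row tibble. Errors if no atom or more than one atom matches.
#' @export
select_atom <- function(structure, resseq, name) {
  validate_structure(structure)
  hit <- structure[structure$resseq == resseq & structure$name == name, ]
  if (nrow(hit) == 0) {
    abort(paste0("no atom (", resseq, ", ", name, ") in structure"))
  }
  if (nrow(hit) > 1) {
    abort(paste0("ambiguous selection: ", nrow(hit), " atoms match (",
                 resseq, ", ", name, ")"))
  }
  hit
}

#' Coordinates of an atom row as a numeric 3-vector
#'
#' @param atom One-row atom tibble.
#' @return Numeric vector `c(x, y, z)` in Angstrom.
#' @export
atom_xyz <- function(atom) {
  if (nrow(atom) != 1) abort("atom_xyz() expects exactly one atom row")
  c(atom$x, atom$y, atom$z)
}

#' Read a docking pose table
#'
#' Reads a CSV with columns `site`, `distance` and `delta_G`: the modification
#' site label, the distance (Angstrom) between the functionally significant
#' atoms of the attacking and attacked partners, and the estimated binding
#' free energy (kcal/mol). The case-insensitive sentinel `"not found"` in the
#' distance column marks sites where no productive conformation was located;
#' those rows get `NA` distances (and `NA` free energies if blank).
#'
#' @param path CSV file with header.
#' @return Tibble with columns `site` (character), `distance` (numeric,
#'   Angstrom, `NA` when absent) and `delta_G` (kcal/mol).
#' @seealso [filter_productive_poses()]
#' @export
#' @examples
#' read_pose_table(fluorelease_example("hsa_cbdp_poses"))
read_pose_table <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"))
  needed <- c("site", "distance", "delta_G")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(paste0("pose table ", path, " lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dist_chr <- trimws(df$distance)
  absent <- tolower(dist_chr) == "not found" | dist_chr == ""
  dist <- suppressWarnings(as.numeric(dist_chr))
  if (any(is.na(dist) & !absent)) {
    bad <- which(is.na(dist) & !absent)[1]
    abort(paste0("unparseable distance '", dist_chr[bad], "' in row ", bad,
                 " of ", path))
  }
  dist[absent] <- NA_real_
  if (any(!is.na(dist) & dist <= 0)) abort("pose distances must be positive")
  tibble(
    site = trimws(df$site),
    distance = dist,
    delta_G = suppressWarnings(as.numeric(df$delta_G))
  )
}
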