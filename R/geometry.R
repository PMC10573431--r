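#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
#' @examples
#' dist3(c(0, 0, 0), c(0, 3, 4)) # 5
dist3 <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  sqrt(sum((a - b)^2))
}

#' Place a fluoride probe in line with the P=O bond
#'
#' Computes the coordinates of a fluoride ion placed at a fixed distance from
#' the adduct's phosphorus atom so that fluorine, phosphorus and the phosphoryl
#' oxygen lie on one straight line, with the fluoride anti to the phosphoryl
#' oxygen (beyond P on the O-to-P ray). This is the manual-docking starting
#' geometry for the in-line nucleophilic attack of F- on the phosphorus: the
#' anti orientation points the probe into the catalytic gorge rather than into
#' the P=O bond.
#'
#' @param p_coord Phosphorus coordinates, numeric 3-vector (Angstrom).
#' @param phosphoryl_o_coord Phosphoryl oxygen coordinates, 3-vector.
#' @param distance Target P-F separation in Angstrom (default 2.0).
#' @return Numeric 3-vector: the fluoride coordinates. By construction
#'   `dist3(result, p_coord) == distance` and the cross product of `F - P`
#'   and `O - P` vanishes.
#' @export
#' @examples
#' place_fluoride(c(0, 0, 0), c(0, 0, 1.48)) # c(0, 0, -2)
place_fluoride <- function(p_coord, phosphoryl_o_coord, distance = 2.0) {
  stopifnot(length(p_coord) == 3, length(phosphoryl_o_coord) == 3,
            is.finite(distance), distance > 0)
  v <- phosphoryl_o_coord - p_coord
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) abort("phosphorus and phosphoryl oxygen coincide")
  p_coord - distance * v / nv
}

#' Is a nucleophilic attack geometrically feasible?
#'
#' A conformation is productive when the distance between the functionally
#' significant atoms (attacking nucleophile and attacked electrophile) does
#' not exceed the cutoff, so that the in-line attack can occur.
#'
#' @param dist Distance(s) in Angstrom; `NA` (pose not found) yields `FALSE`.
#' @param cutoff Feasibility cutoff in Angstrom (default 4.0).
#' @return Logical vector, `TRUE` where `dist <= cutoff`.
#' @export
#' @examples
#' is_attack_feasible(c(3.37, 4.40, 4.0))
is_attack_feasible <- function(dist, cutoff = 4.0) {
  stopifnot(is.finite(cutoff), cutoff > 0)
  if (any(dist < 0, na.rm = TRUE)) abort("distances must be non-negative")
  !is.na(dist) & dist <= cutoff
}

#' Geometric hydrogen-bond test
#'
#' Classifies a donor/hydrogen/acceptor triple as hydrogen bonded when the
#' donor-acceptor distance does not exceed `d_cut` and the donor-H-acceptor
#' angle is at least `angle_cut`. The caller is responsible for passing a
#' hydrogen that is covalently bound to the donor. Defaults (3.5 Angstrom,
#' 120 degrees) are common literature criteria.
#'
#' @param donor,hydrogen,acceptor One-row atom tibbles (see [select_atom()])
#'   or numeric 3-vectors.
#' @param d_cut Donor-acceptor distance cutoff, Angstrom.
#' @param angle_cut Minimum donor-H-acceptor angle, degrees.
#' @return `TRUE` or `FALSE`.
#' @export
detect_hbond <- function(donor, hydrogen, acceptor, d_cut = 3.5, angle_cut = 120) {
  d <- as_coords(donor); h <- as_coords(hydrogen); a <- as_coords(acceptor)
  if (dist3(d, h) < 1e-6 || dist3(a, h) < 1e-6) {
    abort("degenerate geometry: hydrogen coincides with donor or acceptor")
  }
  da <- dist3(d, a)
  v1 <- d - h
  v2 <- a - h
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  da <= d_cut && ang >= angle_cut
}

as_coords <- function(x) {
  if (is.data.frame(x)) atom_xyz(x) else {
    stopifnot(is.numeric(x), length(x) == 3)
    as.numeric(x)
  }
}

#' Add a fluoride probe atom to a structure
#'
#' Convenience wrapper: selects the phosphorus and phosphoryl oxygen by
#' residue/name, computes the probe position with [place_fluoride()] and
#' appends a fluoride HETATM row.
#'
#' @param structure Atom tibble.
#' @param resseq Residue carrying the phosphorus (e.g. the modified serine).
#' @param p_name,o_name Atom names of the phosphorus and phosphoryl oxygen.
#' @param distance P-F placement distance, Angstrom.
#' @return The structure with one extra row (resname `"F"`, atom name `"F"`).
#' @export
add_fluoride <- function(structure, resseq, p_name = "P", o_name = "O1P",
                         distance = 2.0) {
  p <- select_atom(structure, resseq, p_name)
  o <- select_atom(structure, resseq, o_name)
  fpos <- place_fluoride(atom_xyz(p), atom_xyz(o), distance)
  frow <- tibble(
    serial = max(structure$serial) + 1L,
    name = "F", element = "F", resname = "F",
    resseq = max(structure$resseq) + 1L,
    chain = structure$chain[1],
    x = fpos[1], y = fpos[2], z = fpos[3], charge = NA_real_
  )
  out <- dplyr::bind_rows(structure, frow)
  attr(out, "title") <- attr(structure, "title")
  out
}
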