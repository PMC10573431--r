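#' Construct a trajectory object
#'
#' A trajectory couples a reference atom table with per-frame coordinates and
#' frame times. All frames share the reference's atom order.
#'
#' @param atoms Reference atom tibble (see [read_pdb()]).
#' @param coords Numeric array `[n_frames, n_atoms, 3]`, Angstrom.
#' @param times Frame times in picoseconds, strictly increasing, one per frame.
#' @return An object of class `md_trajectory`.
#' @export
new_trajectory <- function(atoms, coords, times) {
  validate_structure(atoms)
  stopifnot(is.array(coords), length(dim(coords)) == 3)
  if (dim(coords)[2] != nrow(atoms) || dim(coords)[3] != 3) {
    abort("coords must be an [n_frames, n_atoms, 3] array matching the atom table")
  }
  if (length(times) != dim(coords)[1]) abort("one time per frame required")
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  structure(list(atoms = atoms, coords = coords, times = as.numeric(times)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("<md_trajectory> ", dim(x$coords)[1], " frames, ", nrow(x$atoms),
      " atoms, t = ", x$times[1], "..", x$times[length(x$times)], " ps\n",
      sep = "")
  invisible(x)
}

#' @export
dim.md_trajectory <- function(x) dim(x$coords)[1:2]

#' Read a multi-model PDB as a trajectory
#'
#' MODEL/ENDMDL blocks become frames. PDB files carry no time stamps, so frame
#' times are supplied either explicitly or as a fixed spacing `dt` (frame i at
#' `(i - 1) * dt` ps), matching fixed-step MD output.
#'
#' @param path Multi-model PDB file.
#' @param dt Frame spacing in ps (ignored when `times` is given).
#' @param times Optional explicit frame times (ps).
#' @return An `md_trajectory`.
#' @export
read_trajectory <- function(path, dt = 1, times = NULL) {
  check_pdb_coordinates(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  atoms <- atoms_from_bio3d(pdb, path)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- nrow(atoms)
  coords <- array(NA_real_, c(n_frames, n_atoms, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * n_atoms, by = 3), drop = FALSE]
  coords[, , 2] <- xyz[, seq(2, 3 * n_atoms, by = 3), drop = FALSE]
  coords[, , 3] <- xyz[, seq(3, 3 * n_atoms, by = 3), drop = FALSE]
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt
  new_trajectory(atoms, coords, times)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj An `md_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  n_frames <- dim(traj$coords)[1]
  n_atoms <- dim(traj$coords)[2]
  xyz <- matrix(NA_real_, n_frames, 3 * n_atoms)
  xyz[, seq(1, 3 * n_atoms, by = 3)] <- traj$coords[, , 1]
  xyz[, seq(2, 3 * n_atoms, by = 3)] <- traj$coords[, , 2]
  xyz[, seq(3, 3 * n_atoms, by = 3)] <- traj$coords[, , 3]
  at <- traj$atoms
  het <- at$resname %in% c("HOH", "WAT", "SOL") | at$element %in% "F"
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(het, "HETATM", "ATOM"),
    resno = at$resseq, resid = at$resname, eleno = at$serial,
    elety = at$name, chain = at$chain, elesy = at$element
  )
  invisible(path)
}

#' Extract one frame of a trajectory as a structure
#'
#' @param traj An `md_trajectory`.
#' @param frame Frame index (1-based).
#' @return Atom tibble with that frame's coordinates.
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (frame < 1 || frame > dim(traj$coords)[1]) abort("frame index out of range")
  out <- traj$atoms
  out$x <- traj$coords[frame, , 1]
  out$y <- traj$coords[frame, , 2]
  out$z <- traj$coords[frame, , 3]
  out
}

#' Interatomic distance time series
#'
#' The central observable of the trajectory analysis: the distance between two
#' atoms (typically the adduct phosphorus and the fluoride ion) at every frame.
#'
#' @param traj An `md_trajectory`.
#' @param atom_a,atom_b Atom indices into the trajectory's atom table.
#' @param label Series label (default built from the two atom names).
#' @return A tibble of class `distance_series` with columns `time_ps` and
#'   `dist_A`.
#' @export
distance_series <- function(traj, atom_a, atom_b, label = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  n_atoms <- dim(traj$coords)[2]
  if (atom_a < 1 || atom_a > n_atoms || atom_b < 1 || atom_b > n_atoms) {
    abort("atom index out of range")
  }
  d <- sqrt((traj$coords[, atom_a, 1] - traj$coords[, atom_b, 1])^2 +
            (traj$coords[, atom_a, 2] - traj$coords[, atom_b, 2])^2 +
            (traj$coords[, atom_a, 3] - traj$coords[, atom_b, 3])^2)
  out <- tibble(time_ps = traj$times, dist_A = d)
  class(out) <- c("distance_series", class(out))
  attr(out, "label") <- label %||%
    paste0("dist", traj$atoms$name[atom_a], "-", traj$atoms$name[atom_b])
  out
}

#' Locate an atom index in a trajectory
#'
#' @param traj An `md_trajectory`.
#' @param resseq,name Residue number and atom name (see [select_atom()]).
#' @return Integer row index into the trajectory's atom table.
#' @export
trajectory_atom <- function(traj, resseq, name) {
  hit <- which(traj$atoms$resseq == resseq & traj$atoms$name == name)
  if (length(hit) == 0) abort(paste0("no atom (", resseq, ", ", name, ")"))
  if (length(hit) > 1) abort("ambiguous atom selection in trajectory")
  hit
}

#' Mean of a distance series over a time interval
#'
#' Arithmetic mean of the series values with `t0 <= t <= t1`; this is the
#' quantity reported as the average P-F distance over a stable trajectory
#' interval. All frames are weighted equally (fixed-step MD output).
#'
#' @param series A `distance_series` (or any tibble with `time_ps`/`dist_A`).
#' @param t0,t1 Interval bounds in ps, `t0 < t1`.
#' @return Mean distance in Angstrom.
#' @export
interval_mean <- function(series, t0, t1) {
  if (!all(c("time_ps", "dist_A") %in% names(series))) {
    abort("series must have columns time_ps and dist_A")
  }
  if (!(t0 < t1)) abort("interval requires t0 < t1")
  sel <- series$time_ps >= t0 & series$time_ps <= t1
  if (!any(sel)) abort("no frames in the requested interval")
  mean(series$dist_A[sel])
}

#' Productive residence time of a distance series
#'
#' Time at which the probe first leaves the productive position: the time of
#' the last frame of the initial contiguous run of values at or below the
#' cutoff. Returns 0 when the first frame already exceeds the cutoff. Re-entry
#' after the first escape is not credited (use [residence_runs()] to see all
#' below-cutoff episodes).
#'
#' @param series A `distance_series`.
#' @param cutoff Productive-position cutoff, Angstrom (default 4.0).
#' @return Residence time in ps.
#' @export
residence_time <- function(series, cutoff = 4.0) {
  if (nrow(series) == 0) abort("empty series")
  above <- series$dist_A > cutoff
  if (above[1]) return(0)
  first_out <- match(TRUE, above)
  if (is.na(first_out)) return(series$time_ps[nrow(series)])
  series$time_ps[first_out - 1]
}

#' All below-cutoff runs of a distance series
#'
#' @param series A `distance_series`.
#' @param cutoff Cutoff in Angstrom.
#' @return Tibble with one row per contiguous run of frames at or below the
#'   cutoff: `t_start`, `t_end` (ps) and `n_frames`.
#' @export
residence_runs <- function(series, cutoff = 4.0) {
  if (nrow(series) == 0) abort("empty series")
  below <- series$dist_A <= cutoff
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(
    t_start = series$time_ps[starts[keep]],
    t_end = series$time_ps[ends[keep]],
    n_frames = r$lengths[keep]
  )
}

#' Count water molecules hydrating an ion
#'
#' Number of distinct water molecules whose oxygen atom lies within `cutoff`
#' of the ion in one structure frame. Waters are recognized by residue name
#' (`HOH`, `WAT`, `SOL` by default, covering crystallographic and MD naming);
#' each water residue is counted at most once.
#'
#' @param structure_frame Atom tibble (a static structure or a
#'   [trajectory_frame()]).
#' @param ion One-row atom tibble or numeric 3-vector: the ion position.
#' @param cutoff Ion to water-oxygen cutoff, Angstrom (default 3.5; the
#'   first-shell boundary for fluoride).
#' @param water_resnames Residue names treated as water.
#' @return Integer count (0 when the frame has no waters).
#' @export
hydration_count <- function(structure_frame, ion, cutoff = 3.5,
                            water_resnames = c("HOH", "WAT", "SOL")) {
  validate_structure(structure_frame)
  ipos <- as_coords(ion)
  w <- structure_frame[structure_frame$resname %in% water_resnames &
                         structure_frame$element == "O", ]
  if (nrow(w) == 0) return(0L)
  d <- sqrt((w$x - ipos[1])^2 + (w$y - ipos[2])^2 + (w$z - ipos[3])^2)
  length(unique(w$resseq[d <= cutoff]))
}

#' Summary of a trajectory's probe behaviour
#'
#' One-stop analysis used by the command-line `analyze` subcommand: distance
#' series between two atoms, interval mean, residence time, all below-cutoff
#' runs, and the ion hydration count in the frame closest to the end of the
#' interval.
#'
#' @param traj An `md_trajectory`.
#' @param atom_a,atom_b Atom indices (phosphorus and probe).
#' @param t0,t1 Averaging interval (ps).
#' @param cutoff Productive-position cutoff (Angstrom).
#' @param hydration_cutoff Ion-water cutoff (Angstrom).
#' @return List with `series`, `mean_dist`, `residence_ps`, `runs`,
#'   `hydration`.
#' @export
analyze_trajectory <- function(traj, atom_a, atom_b, t0 = 0, t1 = 1000,
                               cutoff = 4.0, hydration_cutoff = 3.5) {
  ser <- distance_series(traj, atom_a, atom_b)
  key_frame <- which.min(abs(traj$times - t1))
  frame <- trajectory_frame(traj, key_frame)
  list(
    series = ser,
    mean_dist = interval_mean(ser, t0, t1),
    residence_ps = residence_time(ser, cutoff),
    runs = residence_runs(ser, cutoff),
    hydration = hydration_count(frame, frame[atom_b, ],
                                cutoff = hydration_cutoff)
  )
}
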