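# Seeded generators. All of them restore the caller's RNG state, so a seed is
# mandatory and no global random state leaks between calls.

with_seed <- function(seed, fn) {
  if (is.null(seed) || !is.finite(seed)) abort("a finite seed is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

# unit vector uniform on the sphere
runif_sphere <- function(n = 1) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a toy phosphylated active-site fragment
#'
#' Builds a small, fully synthetic structure emulating the scene around a
#' covalent organophosphate adduct probed by a fluoride ion: a tetrahedral
#' phosphorus bonded to the attacked serine oxygen `OG` at 1.69 Angstrom (a
#' typical P-O(gamma) bond length in the scored adducts) and to a phosphoryl
#' oxygen `O1P` at 1.48 Angstrom, two substituent stubs, a protonated
#' histidine (`NE2`/`HE2`) able to stabilize the probe, a fluoride ion placed
#' anti to the phosphoryl oxygen, and water molecules planted inside and
#' outside the ion's first hydration shell.
#'
#' @param n_waters_near Waters whose oxygen is inside 3.5 Angstrom of the ion.
#' @param n_waters_far Waters outside 5 Angstrom of the ion.
#' @param plant_hbond Place the histidine so that its N-H donates an ideal
#'   hydrogen bond to the fluoride (donor-acceptor 2.8 Angstrom, near-linear).
#' @param seed RNG seed (mandatory; the generator is a pure function of its
#'   arguments).
#' @param ion_distance Planted P-F distance, Angstrom (default 2.0, the
#'   manual-placement distance).
#' @return Atom tibble (see [read_pdb()]). Residues: `OPS 198` (modified
#'   serine fragment), `HIS 438`, `F 900` (the ion), `HOH 500+` (waters).
#' @export
#' @examples
#' site <- make_active_site(3, 2, seed = 42)
#' hydration_count(site, select_atom(site, 900, "F"))
make_active_site <- function(n_waters_near, n_waters_far, plant_hbond = FALSE,
                             seed, ion_distance = 2.0) {
  stopifnot(n_waters_near >= 0, n_waters_far >= 0, ion_distance > 0)
  with_seed(seed, function() {
    s3 <- 1 / sqrt(3)
    d <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * s3
    p <- c(0, 0, 0)
    og <- d[1, ] * 1.69
    o1p <- d[2, ] * 1.48
    o2 <- d[3, ] * 1.62   # ester oxygen of the O-alkyl substituent
    c2 <- d[4, ] * 1.80   # first carbon of R2
    fion <- p - d[2, ] * ion_distance  # anti to the phosphoryl oxygen

    rows <- list(
      list("P",   "P", "OPS", 198L, p),
      list("OG",  "O", "OPS", 198L, og),
      list("O1P", "O", "OPS", 198L, o1p),
      list("O2",  "O", "OPS", 198L, o2),
      list("C2",  "C", "OPS", 198L, c2)
    )
    # protonated histidine: N-H pointing at the ion when an H-bond is planted,
    # otherwise parked away from it
    if (plant_hbond) {
      u <- runif_sphere()
      ne2 <- fion + 2.8 * u
      he2 <- ne2 - 1.0 * u          # N-H along N->F: angle 180 deg
    } else {
      ne2 <- fion + c(6, 0, 0)
      he2 <- ne2 + c(0.0, 1.0, 0.0)
    }
    rows <- c(rows, list(
      list("NE2", "N", "HIS", 438L, ne2),
      list("HE2", "H", "HIS", 438L, he2),
      list("F",   "F", "F",   900L, fion)
    ))
    wat <- 500L
    add_water <- function(rows, pos, idx) {
      c(rows, list(list("O", "O", "HOH", idx, pos)))
    }
    if (n_waters_near > 0) {
      for (i in seq_len(n_waters_near)) {
        pos <- fion + runif(1, 2.4, 3.2) * runif_sphere()
        rows <- add_water(rows, pos, wat); wat <- wat + 1L
      }
    }
    if (n_waters_far > 0) {
      for (i in seq_len(n_waters_far)) {
        pos <- fion + runif(1, 6.0, 8.0) * runif_sphere()
        rows <- add_water(rows, pos, wat); wat <- wat + 1L
      }
    }
    out <- tibble(
      serial = seq_along(rows),
      name = vapply(rows, `[[`, "", 1),
      element = vapply(rows, `[[`, "", 2),
      resname = vapply(rows, `[[`, "", 3),
      resseq = vapply(rows, function(r) as.integer(r[[4]]), 1L),
      chain = "A",
      x = vapply(rows, function(r) r[[5]][1], 1.0),
      y = vapply(rows, function(r) r[[5]][2], 1.0),
      z = vapply(rows, function(r) r[[5]][3], 1.0),
      charge = NA_real_
    )
    attr(out, "title") <- "synthetic active-site fragment"
    out
  })
}

#' Parameters of the synthetic tethered-ion process
#'
#' Defines a probe ion that fluctuates around a target distance from the
#' phosphorus (a discrete mean-reverting AR(1) radial process with isotropic
#' angular jitter), then escapes at a programmed time and drifts outward.
#' This emulates the phenomenology of a fluoride ion that remains in the
#' productive position for a known residence time and then leaves the active
#' site; it is a statistical stand-in, not a physical model.
#'
#' Defaults describe the reference condition used throughout the tests: a
#' 2 ns trace at 1 ps resolution, tether at 3.0 Angstrom (the middle of the
#' observed mean P-F distance range) with 0.25 Angstrom spread, escape at
#' 1300 ps and a fast 1.5 Angstrom/ps outward drift.
#'
#' @param tether_mean Target P-ion distance, Angstrom.
#' @param tether_sd Stationary spread of the tethered distance, Angstrom
#'   (0 gives a constant pre-escape distance).
#' @param escape_time Programmed escape time, ps; must lie within the
#'   simulated span.
#' @param post_escape_drift Outward drift rate after escape, Angstrom/ps.
#' @param frame_dt Frame spacing, ps.
#' @param n_frames Number of frames.
#' @param seed RNG seed (mandatory).
#' @param ar1_phi Frame-to-frame autocorrelation of the tethered process.
#' @return A `tether_params` list.
#' @export
tether_params <- function(tether_mean = 3.0, tether_sd = 0.25,
                          escape_time = 1300, post_escape_drift = 1.5,
                          frame_dt = 1, n_frames = 2000, seed,
                          ar1_phi = 0.6) {
  stopifnot(tether_mean > 0, tether_sd >= 0, post_escape_drift >= 0,
            frame_dt > 0, n_frames >= 2, ar1_phi >= 0, ar1_phi < 1)
  span <- (n_frames - 1) * frame_dt
  if (escape_time < 0 || escape_time > span) {
    abort("escape_time must lie within the simulated time span")
  }
  structure(list(tether_mean = tether_mean, tether_sd = tether_sd,
                 escape_time = escape_time,
                 post_escape_drift = post_escape_drift,
                 frame_dt = frame_dt, n_frames = n_frames, seed = seed,
                 ar1_phi = ar1_phi),
            class = "tether_params")
}

#' Generate a synthetic tethered/escaping ion trajectory
#'
#' All atoms of the reference structure stay fixed except the ion (`F`), whose
#' distance from the phosphorus follows the mean-reverting process of
#' [tether_params()] until the programmed escape time and then grows linearly.
#' The direction from phosphorus to ion performs a small isotropic random walk
#' on the sphere, so frames look like jittery coordinates rather than motion
#' along a ray. Waters inside the ion's first shell (3.5 Angstrom) in the
#' reference travel rigidly with the ion — the hydrated fluoride keeps its
#' shell as it moves — so per-frame hydration counts equal the planted
#' near-water number. Bit-identical for identical parameters and seed.
#'
#' @param params A [tether_params()] object.
#' @param reference Atom tibble containing a `P` atom and an ion atom named
#'   `F` (e.g. from [make_active_site()]).
#' @return An [new_trajectory()] object with `params$n_frames` frames.
#' @export
#' @examples
#' site <- make_active_site(2, 1, seed = 7)
#' traj <- make_trajectory(tether_params(n_frames = 200, escape_time = 150,
#'                                       seed = 7), site)
#' residence_time(distance_series(traj, trajectory_atom(traj, 198, "P"),
#'                                trajectory_atom(traj, 900, "F")))
make_trajectory <- function(params, reference) {
  stopifnot(inherits(params, "tether_params"))
  validate_structure(reference)
  i_p <- which(reference$name == "P")
  i_f <- which(reference$name == "F" & reference$element == "F")
  if (length(i_p) != 1 || length(i_f) != 1) {
    abort("reference must contain exactly one P atom and one F ion")
  }
  with_seed(params$seed, function() {
    n <- params$n_frames
    times <- (seq_len(n) - 1) * params$frame_dt
    phi <- params$ar1_phi
    sd_inn <- params$tether_sd * sqrt(1 - phi^2)
    r <- numeric(n)
    r[1] <- params$tether_mean
    tethered <- times <= params$escape_time
    for (t in 2:n) {
      if (tethered[t]) {
        r[t] <- params$tether_mean + phi * (r[t - 1] - params$tether_mean) +
          rnorm(1, 0, sd_inn)
      } else {
        r[t] <- r[t - 1] + params$post_escape_drift * params$frame_dt
      }
    }
    r <- pmax(r, 0.5)
    # direction random-walks on the sphere
    p0 <- c(reference$x[i_p], reference$y[i_p], reference$z[i_p])
    f0 <- c(reference$x[i_f], reference$y[i_f], reference$z[i_f])
    u <- f0 - p0
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-9) c(0, 0, 1) else u / nu
    n_atoms <- nrow(reference)
    coords <- array(NA_real_, c(n, n_atoms, 3))
    base <- as.matrix(reference[, c("x", "y", "z")])
    # first-shell waters ride along with the ion
    is_w <- reference$resname %in% c("HOH", "WAT", "SOL")
    w_d <- sqrt(colSums((t(base) - f0)^2))
    shell <- which(is_w & w_d <= 3.5)
    shell_off <- if (length(shell) > 0) {
      base[shell, , drop = FALSE] - matrix(f0, length(shell), 3, byrow = TRUE)
    }
    for (t in seq_len(n)) {
      if (t > 1) {
        u <- u + 0.05 * as.numeric(runif_sphere())
        u <- u / sqrt(sum(u^2))
      }
      fr <- base
      fpos <- p0 + r[t] * u
      fr[i_f, ] <- fpos
      if (length(shell) > 0) {
        fr[shell, ] <- shell_off + matrix(fpos, length(shell), 3, byrow = TRUE)
      }
      coords[t, , ] <- fr
    }
    new_trajectory(reference, coords, times)
  })
}

#' Generate synthetic adduct charge records
#'
#' Draws `n` charge/distance records with the statistical structure of the
#' scored adduct series: `q_P` uniform on (2.2, 2.4) e, `q_O` on
#' (-0.65, -0.54) e, `q_F` on (-0.76, -0.70) e, `dist_P_O` on (1.68, 1.70)
#' Angstrom and `dist_P_F` on (2.7, 4.0) Angstrom. Within these ranges the
#' P-O attraction always dominates the P-F attraction, so the barrier score
#' of every record is positive.
#'
#' @param n Number of records (`> 0`).
#' @param seed RNG seed (mandatory).
#' @return Tibble with columns `adduct_id`, `q_P`, `q_O`, `q_F`, `dist_P_O`,
#'   `dist_P_F`; reproducible per seed.
#' @export
#' @examples
#' make_adduct_records(5, seed = 1) |> delta_e_el()
make_adduct_records <- function(n, seed) {
  if (!is.numeric(n) || n <= 0) abort("n must be a positive integer")
  with_seed(seed, function() {
    tibble(
      adduct_id = sprintf("Syn%02d", seq_len(n)),
      q_P = runif(n, 2.2, 2.4),
      q_O = runif(n, -0.65, -0.54),
      q_F = runif(n, -0.76, -0.70),
      dist_P_O = runif(n, 1.68, 1.70),
      dist_P_F = runif(n, 2.7, 4.0)
    )
  })
}
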