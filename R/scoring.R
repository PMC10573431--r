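#' Screened Coulomb interaction energy
#'
#' Electrostatic interaction energy of two point charges at distance `r` in a
#' medium of effective relative dielectric `epsilon`:
#' `E = k q1 q2 / (epsilon r)` with `k = 332.0637` kcal A / (mol e^2). The
#' default `epsilon = 4` is the calibrated effective screening of the buried
#' active-site environment; it is the value under which the packaged reference
#' energies are reproduced from their charges and distances.
#'
#' @param q1,q2 Partial charges in elementary charge units (vectorized).
#' @param r Separation in Angstrom, `> 0`.
#' @param epsilon Effective relative dielectric, `> 0` (default 4).
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' coulomb_energy(2.240, -0.748, 2.753) # P...F- attraction, about -50.5
coulomb_energy <- function(q1, q2, r, epsilon = 4.0) {
  if (any(!is.finite(r)) || any(r <= 0)) abort("r must be positive and finite")
  if (any(!is.finite(epsilon)) || any(epsilon <= 0)) abort("epsilon must be positive")
  .k_coulomb * q1 * q2 / (epsilon * r)
}

#' Electrostatic barrier score of an adduct
#'
#' Computes, for each adduct row, the screened-Coulomb energies of the P-O
#' (phosphorus to attacked serine/tyrosine oxygen) and P-F (phosphorus to
#' fluoride) pairs, and their difference
#' `delta_e_el = e_el_P_F - e_el_P_O` (kcal/mol). Because the P-O pair sits at
#' covalent-bond distance while the fluoride is farther away, the P-O
#' attraction is the stronger of the two and the score is positive; the lower
#' the score, the easier the adduct is reactivated by fluoride.
#'
#' The sign convention is fixed so that the score is the energetic price of
#' trading the existing P-O contact for the incoming P-F contact.
#'
#' @param data Tibble with columns `q_P`, `q_O`, `q_F` (elementary charges)
#'   and `dist_P_O`, `dist_P_F` (Angstrom), e.g. from [read_adduct_table()]
#'   or [make_adduct_records()].
#' @param epsilon Effective relative dielectric (default 4).
#' @param validate Check the physical sign/range invariants (`q_P > 0`,
#'   `q_O < 0`, `q_F < 0`, `dist_P_O` within covalent range) and fail on
#'   violation. Set `FALSE` to score arbitrary charge sets.
#' @return The input tibble with columns `e_el_P_O`, `e_el_P_F` and
#'   `delta_e_el` appended (kcal/mol).
#' @seealso [score_reactivation()] for the fitted-object interface,
#'   [rank_adducts()] for ordering.
#' @export
#' @examples
#' read_adduct_table(fluorelease_example("bche_am1_charges")) |>
#'   delta_e_el()
delta_e_el <- function(data, epsilon = 4.0, validate = TRUE) {
  needed <- c("q_P", "q_O", "q_F", "dist_P_O", "dist_P_F")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!stats::complete.cases(data[needed]))) {
    abort("charge/distance fields must be complete")
  }
  if (validate) {
    if (any(data$q_P <= 0)) abort("q_P must be positive (override with validate = FALSE)")
    if (any(data$q_O >= 0)) abort("q_O must be negative (override with validate = FALSE)")
    if (any(data$q_F >= 0)) abort("q_F must be negative (override with validate = FALSE)")
    if (any(data$dist_P_O <= 1.0 | data$dist_P_O >= 2.5)) {
      abort("dist_P_O outside the covalent range (1, 2.5) A (override with validate = FALSE)")
    }
    if (any(data$dist_P_F <= 0)) abort("dist_P_F must be positive")
  }
  dplyr::mutate(
    data,
    e_el_P_O = coulomb_energy(.data$q_P, .data$q_O, .data$dist_P_O, epsilon),
    e_el_P_F = coulomb_energy(.data$q_P, .data$q_F, .data$dist_P_F, epsilon),
    delta_e_el = .data$e_el_P_F - .data$e_el_P_O
  )
}

#' Score a set of adducts for reactivation difficulty
#'
#' Fitted-object interface over [delta_e_el()]: scores every adduct, ranks
#' them (ascending barrier = easiest first) and keeps the scoring parameters.
#' Use [tidy()] for the per-adduct table, [glance()] for a one-row summary and
#' [autoplot()] for a barrier-score chart.
#'
#' @inheritParams delta_e_el
#' @return An object of class `reactivation_score`.
#' @export
#' @examples
#' fit <- read_adduct_table(fluorelease_example("bche_am1_charges")) |>
#'   score_reactivation()
#' tidy(fit)
#' glance(fit)
score_reactivation <- function(data, epsilon = 4.0, validate = TRUE) {
  if (nrow(data) == 0) abort("no adduct records to score")
  scored <- delta_e_el(data, epsilon = epsilon, validate = validate)
  ranked <- rank_adducts(scored, score = "delta_e_el", criterion = "am1_delta_e")
  structure(list(scores = scored, ranking = ranked, epsilon = epsilon),
            class = "reactivation_score")
}

#' @export
print.reactivation_score <- function(x, ...) {
  cat("<reactivation_score> ", nrow(x$scores), " adducts, epsilon = ",
      x$epsilon, "\n", sep = "")
  cat("easiest:", x$ranking$adduct_id[1],
      " hardest:", x$ranking$adduct_id[nrow(x$ranking)], "\n")
  invisible(x)
}

#' @rdname score_reactivation
#' @param x A `reactivation_score`.
#' @param ... Unused.
#' @export
tidy.reactivation_score <- function(x, ...) {
  dplyr::left_join(x$ranking[, c("adduct_id", "rank")], x$scores,
                   by = "adduct_id") |>
    dplyr::arrange(.data$rank)
}

#' @rdname score_reactivation
#' @export
glance.reactivation_score <- function(x, ...) {
  tibble(
    n_adducts = nrow(x$scores),
    epsilon = x$epsilon,
    min_delta_e_el = min(x$scores$delta_e_el),
    max_delta_e_el = max(x$scores$delta_e_el),
    easiest = x$ranking$adduct_id[1],
    hardest = x$ranking$adduct_id[nrow(x$ranking)]
  )
}

#' Rank adducts by a reactivation-difficulty score
#'
#' Stable ascending sort (easiest to reactivate first) with ties broken by
#' adduct id. Two criteria are used in practice: the mean P-F distance over a
#' stable MD interval (`"mm_distance"`, molecular-mechanics view) and the
#' electrostatic barrier score (`"am1_delta_e"`).
#'
#' @param data Tibble with an `adduct_id` column and the score column.
#' @param score Column to rank by (name or tidy-eval column), e.g.
#'   `delta_e_el` or `mean_dist_P_F`.
#' @param criterion Label stored in the output: `"am1_delta_e"` or
#'   `"mm_distance"`.
#' @return Tibble with `rank`, `adduct_id`, `score`, `criterion`; `score`
#'   values are non-decreasing in rank order (rank 1 = easiest reactivation).
#' @export
#' @examples
#' read.csv(fluorelease_example("bche_md_distances")) |>
#'   rank_adducts(score = "mean_dist_P_F", criterion = "mm_distance")
rank_adducts <- function(data, score, criterion = c("am1_delta_e", "mm_distance")) {
  criterion <- match.arg(criterion)
  if (!"adduct_id" %in% names(data)) abort("data must have an adduct_id column")
  score_quo <- enquo(score)
  vals <- eval_tidy(score_quo, data)
  if (is.character(vals) && length(vals) == 1 && vals %in% names(data)) {
    vals <- data[[vals]]
  }
  if (length(vals) != nrow(data)) abort("one score per record required")
  if (any(is.na(vals))) abort("scores must be complete")
  ord <- order(vals, data$adduct_id, method = "radix")
  tibble(
    rank = seq_along(ord),
    adduct_id = data$adduct_id[ord],
    score = vals[ord],
    criterion = criterion
  )
}

#' Dissociation constant from binding free energy
#'
#' `K_d = exp(dG / (R T))` with `R = 1.98720425e-3` kcal/(mol K) and a 1 M
#' standard state, so `dG = 0` gives `K_d = 1` M. A docking estimate of about
#' -7 kcal/mol at room temperature corresponds to a K_d of about 7 micromolar.
#'
#' @param delta_g Binding free energy, kcal/mol (negative = favourable).
#' @param temperature Kelvin (default 298.15).
#' @return Dissociation constant in mol/L.
#' @export
#' @examples
#' kd_from_dg(-7) # about 7e-6 M
kd_from_dg <- function(delta_g, temperature = 298.15) {
  if (any(temperature <= 0)) abort("temperature must be positive")
  exp(delta_g / (.r_gas * temperature))
}

#' @rdname kd_from_dg
#' @param kd Dissociation constant, mol/L (`> 0`).
#' @export
dg_from_kd <- function(kd, temperature = 298.15) {
  if (any(temperature <= 0)) abort("temperature must be positive")
  if (any(kd <= 0)) abort("kd must be positive")
  .r_gas * temperature * log(kd)
}

#' Keep the productive docking poses
#'
#' Retains poses whose functional-atom distance is present and does not exceed
#' the cutoff; sites where no productive conformation was found (absent
#' distance) are dropped.
#'
#' @param poses Tibble from [read_pose_table()].
#' @param cutoff Feasibility cutoff, Angstrom (default 4.0).
#' @return The filtered tibble.
#' @export
#' @examples
#' read_pose_table(fluorelease_example("hsa_cbdp_poses")) |>
#'   filter_productive_poses()
filter_productive_poses <- function(poses, cutoff = 4.0) {
  if (!"distance" %in% names(poses)) abort("poses must have a distance column")
  dplyr::filter(poses, is_attack_feasible(.data$distance, cutoff))
}
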