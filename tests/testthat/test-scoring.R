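test_that("screened Coulomb energy has the right closed-form values", {
  # unit charges at k / (eps * 100) spacing give exactly -100 kcal/mol
  expect_equal(coulomb_energy(1, -1, 3.320637, epsilon = 1), -100,
               tolerance = 1e-9)
  expect_equal(coulomb_energy(0, -0.7, 3.1), 0)
  expect_equal(coulomb_energy(2.240, -0.748, 2.753), -50.540, tolerance = 0.05)
  expect_error(coulomb_energy(1, 1, 0), "positive")
  expect_error(coulomb_energy(1, 1, 2, epsilon = -4), "positive")
})

test_that("coulomb energy scales homogeneously in 1/r and 1/epsilon", {
  set.seed(4)
  q1 <- runif(20, 0.5, 3); q2 <- runif(20, -1, -0.1)
  r <- runif(20, 1, 5); s <- runif(20, 1.1, 3)
  expect_equal(coulomb_energy(q1, q2, r * s), coulomb_energy(q1, q2, r) / s)
  expect_equal(coulomb_energy(q1, q2, r, epsilon = 4 * s),
               coulomb_energy(q1, q2, r, epsilon = 4) / s)
})

test_that("every reference adduct row is reproduced within 0.05 kcal/mol", {
  sc <- delta_e_el(table5())
  expect_equal(nrow(sc), 11)
  expect_lt(max(abs(sc$e_el_P_O - sc$e_el_P_O_ref)), 0.05)
  expect_lt(max(abs(sc$e_el_P_F - sc$e_el_P_F_ref)), 0.05)
  expect_lt(max(abs(sc$delta_e_el - sc$delta_e_el_ref)), 0.05)
  expect_equal(sc$delta_e_el, sc$e_el_P_F - sc$e_el_P_O)  # exact identity
  ad9 <- sc[sc$adduct_id == "Ad9", ]
  expect_equal(ad9$delta_e_el, 37.575, tolerance = 0.05)
})

test_that("the barrier score is antisymmetric under swapping the two partners", {
  rec <- table5()[3, ]
  swapped <- dplyr::mutate(rec, q_O = rec$q_F, q_F = rec$q_O,
                           dist_P_O = rec$dist_P_F, dist_P_F = rec$dist_P_O)
  a <- delta_e_el(rec, validate = FALSE)$delta_e_el
  b <- delta_e_el(swapped, validate = FALSE)$delta_e_el
  expect_equal(a, -b, tolerance = 1e-12)
})

test_that("degenerate and invalid charge records are rejected", {
  rec <- table5()[1, ]
  same <- dplyr::mutate(rec, q_F = .data$q_O, dist_P_F = .data$dist_P_O)
  expect_equal(delta_e_el(same)$delta_e_el, 0)
  bad <- dplyr::mutate(rec, q_P = -1)
  expect_error(delta_e_el(bad), "q_P")
  expect_silent(delta_e_el(bad, validate = FALSE))
  expect_error(delta_e_el(dplyr::mutate(rec, q_F = NA)), "complete")
  expect_error(delta_e_el(rec[, -which(names(rec) == "q_O")]), "missing column")
})

test_that("free-energy / dissociation-constant conversion round trips", {
  expect_equal(kd_from_dg(0), 1)
  expect_equal(signif(kd_from_dg(-7) * 1e6, 1), 7)  # about 7 micromolar
  rt <- 1.98720425e-3 * 298.15
  expect_equal(kd_from_dg(-rt * log(1e6)), 1e-6, tolerance = 1e-12)
  set.seed(2)
  dg <- runif(20, -12, 2)
  expect_equal(dg_from_kd(kd_from_dg(dg)), dg, tolerance = 1e-10)
  kd <- 10^runif(5, -9, 0)
  expect_equal(kd_from_dg(dg_from_kd(kd)), kd, tolerance = 1e-10)
  expect_error(kd_from_dg(-7, temperature = -1), "positive")
  expect_error(dg_from_kd(0), "positive")
})

test_that("ranking is a stable ascending sort with id tie-breaks", {
  sc <- delta_e_el(table5())
  rk <- rank_adducts(sc, score = delta_e_el)
  expect_equal(rk$adduct_id,
               c("Ad7", "Ad11", "Ad1", "Ad2", "Ad4", "Ad6", "Ad3", "Ad5",
                 "Ad8", "Ad10", "Ad9"))
  expect_true(all(diff(rk$score) >= 0))

  md <- read.csv(fluorelease_example("bche_md_distances"))
  rk_md <- rank_adducts(md, score = mean_dist_P_F, criterion = "mm_distance")
  expect_equal(rk_md$adduct_id,
               c("Ad1", "Ad11", "Ad2", "Ad7", "Ad4", "Ad5", "Ad6", "Ad10",
                 "Ad3", "Ad8", "Ad9"))
  # tie at 3.52 A broken lexicographically: Ad3 before Ad8
  tie <- rk_md[rk_md$score == 3.52, ]
  expect_equal(tie$adduct_id, c("Ad3", "Ad8"))

  single <- rank_adducts(sc[5, ], score = delta_e_el)
  expect_equal(nrow(single), 1)
  expect_equal(single$rank, 1)
})

test_that("ranking is invariant under permutation of the input rows", {
  sc <- delta_e_el(table5())
  set.seed(31)
  for (i in 1:10) {
    perm <- sc[sample(nrow(sc)), ]
    expect_equal(rank_adducts(perm, score = delta_e_el)$adduct_id,
                 rank_adducts(sc, score = delta_e_el)$adduct_id)
  }
  expect_error(rank_adducts(dplyr::mutate(sc, delta_e_el = NA), delta_e_el),
               "complete")
})

test_that("productive-pose filtering keeps present distances at or below cutoff", {
  poses <- read_pose_table(fluorelease_example("hsa_cbdp_poses"))
  kept <- filter_productive_poses(poses)
  expect_equal(nrow(kept), 11)
  expect_false(any(c("Tyr138", "Lys432") %in% kept$site))
  expect_true("Tyr140" %in% kept$site)   # 4.0 A boundary retained

  far <- tibble::tibble(site = c("a", "b"), distance = c(4.5, 9),
                        delta_G = c(-1, -2))
  expect_equal(nrow(filter_productive_poses(far)), 0)
})

test_that("score_reactivation exposes tidy, glance and the scored fit", {
  fit <- score_reactivation(table5())
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$adduct_id[1], "Ad7")
  expect_equal(td$rank, 1:11)
  gl <- glance(fit)
  expect_equal(gl$n_adducts, 11)
  expect_equal(gl$easiest, "Ad7")
  expect_equal(gl$hardest, "Ad9")
  expect_equal(gl$epsilon, 4)
  expect_error(score_reactivation(table5()[0, ]), "no adduct")
})
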