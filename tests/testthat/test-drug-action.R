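test_that("each mechanism adds exactly its reaction set", {
  m_riva <- attach_drug(coag_base,
                        drug_state("rivaroxaban", 100, "ug_l"))
  added <- setdiff(vapply(m_riva$reactions, `[[`, character(1), "id"),
                   vapply(coag_base$reactions, `[[`, character(1), "id"))
  expect_setequal(added, c("RBay1", "RBay1s", "RBay2", "RBay3", "RBay4",
                           "RBay5"))
  expect_length(added, 6)

  m_hep <- attach_drug(coag_base, drug_state("enoxaparin", 1, "mg_l"))
  added <- setdiff(vapply(m_hep$reactions, `[[`, character(1), "id"),
                   vapply(coag_base$reactions, `[[`, character(1), "id"))
  expect_setequal(added, paste0("RHep", 1:11))
  expect_length(added, 11)

  expect_error(attach_drug(m_riva, drug_state("rivaroxaban", 1, "ug_l")),
               "collision")
})

test_that("a zero-concentration drug is a null perturbation", {
  pt0 <- run_pt(coag_base)$clotting_time
  for (d in c("rivaroxaban", "melagatran", "enoxaparin")) {
    ptz <- run_pt(coag_base, drug = drug_state(d, 0))$clotting_time
    expect_equal(ptz, pt0, tolerance = 1e-4)
  }
})

test_that("total drug is conserved in the closed system", {
  d <- drug_state("rivaroxaban", 150, "ug_l")
  m <- attach_drug(coag_base, d)
  tr <- run_pt(m)$trajectory
  w <- setNames(rep(1, 6), c("Bay59_7939", "Bay59_7939_Bound",
                             "Bay59_7939_Xa", "Bay59_7939_Xa_lipid",
                             "Bay59_7939_Xa_Va_lipid",
                             "Bay59_7939_Xa_ATIII"))
  expect_lt(conserved_moiety_residual(tr, w),
            1e-6 * d$concentration)
})

test_that("enoxaparin turns AT over catalytically", {
  d <- drug_state("enoxaparin", 0.5, "mg_l")
  m <- attach_drug(coag_base, d)
  tr <- run_pt(m)$trajectory
  # the heparin moiety (free + protein-bound + AT complex) is conserved
  w <- c(Hep = 1, Hep_Bound = 1, ATIIIa = 1)
  expect_lt(conserved_moiety_residual(tr, w), 1e-6 * d$concentration)
  # while inhibited factor Xa accumulates
  xa_at <- tr$concentrations[, "Xa_ATIII"]
  expect_gt(xa_at[length(xa_at)], 10 * d$concentration * 1e-3)
})

test_that("warfarin scales exactly the vitamin K-dependent pool", {
  ini <- initial_state(coag_base)
  out <- apply_warfarin(ini, warfarin_state(0.5))
  scaled <- c("II", "VII", "VIIa", "IX", "X", "PC", "PS")
  expect_equal(out[scaled], ini[scaled] / 2)
  untouched <- setdiff(names(ini), scaled)
  expect_equal(out[untouched], ini[untouched])
  expect_equal(apply_warfarin(ini, warfarin_state(1)), ini)
  expect_error(warfarin_state(0), "fraction")
  expect_error(warfarin_state(1.5), "fraction")
})

test_that("PT lengthens monotonically as factor levels fall", {
  f_grid <- c(0.2, 0.4, 0.7, 1.0)
  pts <- vapply(f_grid, function(f)
    run_pt(coag_base, warfarin = warfarin_state(f))$clotting_time,
    numeric(1))
  expect_true(all(diff(pts) <= 0))
})

test_that("warfarin titration round-trips the target INR", {
  pt0 <- run_pt(coag_base)$clotting_time
  f2 <- warfarin_fraction_for_inr(coag_base, 2.0)
  inr2 <- run_pt(coag_base, warfarin = warfarin_state(f2))$clotting_time /
    pt0
  expect_equal(inr2, 2.0, tolerance = 2e-3)
  expect_equal(warfarin_fraction_for_inr(coag_base, 1), 1)
  f15 <- warfarin_fraction_for_inr(coag_base, 1.5)
  f30 <- warfarin_fraction_for_inr(coag_base, 3.0)
  expect_lt(f30, f15)
  expect_error(warfarin_fraction_for_inr(coag_base, 0.8), ">= 1")
})

test_that("unit conversions follow the molar bookkeeping", {
  expect_equal(mass_to_molar("enoxaparin", 1, "mg_l"), 1e-3 / 4500)
  expect_equal(mass_to_molar("enoxaparin", 1, "mg_l"), 2.22e-7,
               tolerance = 1e-2)
  # 100 anti-Xa U/ml = 1 mg/ml enoxaparin
  expect_equal(mass_to_molar("enoxaparin", 100, "anti_xa_u_ml"),
               1 / 4500)
  expect_equal(mass_to_molar("enoxaparin", 0, "ug_l"), 0)
  expect_equal(mass_to_molar("melagatran", 0.21, "uM"), 2.1e-7)
  expect_error(mass_to_molar("rivaroxaban", 1, "anti_xa_u_ml"),
               "anti-Xa")
})
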