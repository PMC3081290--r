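test_that("a zero-coupling open system reproduces the closed model", {
  ini <- initial_state(coag_base)
  ini["TF"] <- 1e-11
  mc <- set_initials(coag_base, ini)
  mo <- open_system(mc, flow_config(0))
  t1 <- simulate_model(mc, 300, n_out = 151)
  t2 <- simulate_model(mo, 300, n_out = 151)
  expect_equal(t2$concentrations, t1$concentrations, tolerance = 1e-10)
})

test_that("a reaction-free open system relaxes exponentially to blood", {
  m <- network_model(
    data.frame(name = c("A", "B"), initial_concentration = c(0, 5),
               mobile = c(TRUE, FALSE), lipid_bound = FALSE),
    list(),
    setNames(numeric(0), character(0)))
  alpha <- 2e6; D <- 5e-7          # alpha * D = 1 /s
  mo <- open_system(m, flow_config(alpha, D = D,
                                   c_blood = c(A = 1, B = 0)))
  tr <- simulate_model(mo, 3, n_out = 31)
  i1 <- which.min(abs(tr$times - 1))
  expect_equal(unname(tr$concentrations[i1, "A"]), 1 - exp(-1),
               tolerance = 1e-6)
  # the immobile species feels no transport at any coupling strength
  expect_equal(unname(tr$concentrations[, "B"]), rep(5, 31))
})

test_that("immobile species receive no transport term in the full model", {
  ini <- initial_state(coag_base)
  ini["TF"] <- 1e-11
  ini["Ia"] <- 5e-7
  m <- set_initials(coag_base, ini)
  mo <- open_system(m, flow_config(1e5))
  f_open <- assemble_rhs(mo)
  f_closed <- assemble_rhs(m)
  st <- initial_state(mo)
  st["Xa"] <- 1e-9   # deviate from the reservoir so transport is visible
  st["TF"] <- 2e-11
  imm <- mo$species$name[!mo$species$mobile]
  expect_true(all(c("TF", "Ia") %in% imm))
  d1 <- f_open(st); d2 <- f_closed(st)
  expect_equal(d1[imm], d2[imm])
  # mobile species gain exactly alpha * D * (c_blood - c)
  expect_equal(d1[["Xa"]] - d2[["Xa"]], 1e5 * 5e-7 * (0 - 1e-9),
               tolerance = 1e-10)
})

test_that("triggered scenarios clot at rest and zero trigger does not", {
  r <- run_scenario(coag_base, trigger_scenario("extrinsic_strong"))
  expect_true(r$clot)
  expect_lt(r$clotting_time, 3600)
  zero <- structure(list(name = "none", TF = 0, XIIa = 0),
                    class = "coag_scenario")
  expect_false(run_scenario(coag_base, zero)$clot)
})

test_that("washout never converts a no-clot into a clot", {
  clots <- vapply(c(0, 1e4, 1e5, 1e6), function(a)
    run_scenario(coag_base, trigger_scenario("extrinsic_strong"),
                 alpha = a)$clot, logical(1))
  expect_true(all(diff(as.integer(clots)) <= 0))
})

test_that("alpha_crit honours its bracket and tolerance contract", {
  sc <- trigger_scenario("extrinsic_strong")
  ac <- alpha_crit(coag_base, sc, rel_tol = 1e-2)
  expect_lt(ac$bracket[1], ac$alpha_crit)
  expect_equal(ac$alpha_crit, ac$bracket[2])
  expect_lte((ac$bracket[2] - ac$bracket[1]) / ac$bracket[1], 1e-2)
  # halving the tolerance moves the answer by less than the coarser one
  ac2 <- alpha_crit(coag_base, sc, rel_tol = 5e-3)
  expect_lt(abs(ac2$alpha_crit - ac$alpha_crit) / ac$alpha_crit, 1e-2)
  # independence from the starting bracket
  ac3 <- alpha_crit(coag_base, sc, bracket = c(10, 1e8), rel_tol = 1e-2)
  expect_equal(ac3$alpha_crit, ac$alpha_crit, tolerance = 1e-2)
})

test_that("stronger triggers need more washout to suppress", {
  a_strong <- alpha_crit(coag_base, trigger_scenario("extrinsic_strong"),
                         rel_tol = 1e-2)$alpha_crit
  a_weak <- alpha_crit(coag_base, trigger_scenario("extrinsic_weak"),
                       rel_tol = 1e-2)$alpha_crit
  expect_gt(a_strong, a_weak)
})

test_that("stronger anticoagulation lowers the washout threshold", {
  sc <- trigger_scenario("intrinsic_strong")
  hi <- alpha_crit(coag_base, sc,
                   drug = drug_state("rivaroxaban", 13.66, "ug_l"),
                   rel_tol = 1e-2)$alpha_crit
  lo <- alpha_crit(coag_base, sc,
                   drug = drug_state("rivaroxaban", 195.15, "ug_l"),
                   rel_tol = 1e-2)$alpha_crit
  expect_lte(lo, hi)
})
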