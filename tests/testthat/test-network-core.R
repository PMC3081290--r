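test_that("rate laws evaluate signed mass-action monomials", {
  # prothrombin activation law k16 * [Xa] * [II]
  r9 <- rate_law(list(list(sign = 1, constants = "k16",
                           species = c("Xa", "II"))))
  expect_equal(eval_rate(r9, c(Xa = 0, II = 1.4e-6), c(k16 = 1e8)), 0)
  expect_equal(eval_rate(r9, c(Xa = 1e-9, II = 1.4e-6), c(k16 = 1e8)),
               1.4e-7)
  # reversible inhibitor binding at its equilibrium point is silent
  rbay <- rate_law(list(
    list(sign = 1, constants = "kBay1", species = c("Bay", "Xa")),
    list(sign = -1, constants = c("kBay1", "kBay_Ki_Xa"),
         species = "Bay_Xa")))
  p <- c(kBay1 = 1.7e7, kBay_Ki_Xa = 4e-10)
  st <- c(Bay = 2e-9, Xa = 2e-10, Bay_Xa = 2e-9 * 2e-10 / 4e-10)
  expect_equal(eval_rate(rbay, st, p), 0)
  expect_error(eval_rate(r9, c(Xa = 1e-9, II = 1e-6), c(k15 = 1)),
               "k16")
  expect_error(eval_rate(r9, c(Xa = 1e-9), c(k16 = 1e8)), "II")
})

test_that("assembled derivative matches the mass-action definition", {
  m <- tiny_decay_model(k = 2, A0 = 3)
  f <- assemble_rhs(m)
  dy <- f(c(A = 3, B = 0))
  expect_equal(unname(dy["A"]), -6)
  expect_equal(unname(dy["B"]), 6)
})

test_that("assembled RHS equals the brute-force per-reaction oracle", {
  f <- assemble_rhs(coag_base)
  set.seed(42)
  for (i in 1:100) {
    st <- random_state(coag_base)
    expect_equal(f(st), brute_force_rhs(coag_base, st),
                 tolerance = 1e-12)
  }
})

test_that("single-reaction networks match closed-form solutions", {
  tr <- simulate_model(tiny_decay_model(), horizon = 5, n_out = 101)
  expect_equal(tr$concentrations[1, ], c(A = 1, B = 0))
  i1 <- which.min(abs(tr$times - 1))
  expect_equal(unname(tr$concentrations[i1, "A"]), exp(-1),
               tolerance = 1e-6)
  expect_equal(unname(tr$concentrations[i1, "B"]), 1 - exp(-1),
               tolerance = 1e-6)
  # symmetric reversible isomerisation equilibrates at A = B = A0/2
  tr2 <- simulate_model(tiny_reversible_model(), horizon = 30, n_out = 61)
  expect_equal(unname(tr2$concentrations[61, "A"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(tr2$concentrations[61, "B"]), 0.5, tolerance = 1e-6)
})

test_that("trajectories stay non-negative and start at the initials", {
  tr <- run_pt(coag_base)$trajectory
  expect_true(all(tr$concentrations >= 0))
  expect_equal(tr$concentrations[1, ],
               initial_state(tr$model)[colnames(tr$concentrations)])
  expect_true(all(diff(tr$times) > 0))
})

test_that("fibrin accumulation is monotone in a PT run", {
  tr <- run_pt(coag_base)$trajectory
  expect_true(all(diff(tr$concentrations[, "Ia"]) >= 0))
})

test_that("threshold crossing interpolates and handles no-crossing", {
  # synthetic linear trajectory c(t) = t nM/s
  traj <- structure(list(
    times = seq(0, 200, by = 10),
    concentrations = matrix(seq(0, 200, by = 10) * 1e-9,
                            dimnames = list(NULL, "S")),
    model = NULL, rtol = 1e-8, atol = 1e-14),
    class = "coag_trajectory")
  expect_equal(first_crossing_time(traj, "S", 100e-9), 100)
  flat <- traj
  flat$concentrations[] <- 1e-9
  expect_true(is.na(first_crossing_time(flat, "S", 100e-9)))
  expect_error(first_crossing_time(traj, "missing", 1), "missing")
})

test_that("crossing refinement agrees with a much finer re-integration", {
  cfg <- pt_config()
  coarse <- run_pt(coag_base, config = cfg, n_out = 61L)
  fine <- run_pt(coag_base, config = cfg, n_out = 6001L)
  expect_lt(abs(coarse$clotting_time - fine$clotting_time) /
              fine$clotting_time, 0.005)
})

test_that("conserved moieties are conserved, and rejected when invalid", {
  tr1 <- simulate_model(tiny_decay_model(), horizon = 5, n_out = 51)
  expect_lt(conserved_moiety_residual(tr1, c(A = 1, B = 1)), 1e-9)
  expect_error(conserved_moiety_residual(tr1, c(A = 1)), "null-vector")

  tr <- run_pt(coag_base)$trajectory
  w <- prothrombin_weights()
  total0 <- sum(initial_state(tr$model)[names(w)] * w)
  expect_lt(conserved_moiety_residual(tr, w), 1e-6 * total0)

  # an open system is rejected: transport breaks closure
  mo <- open_system(coag_base, flow_config(alpha = 1e4))
  tro <- simulate_model(mo, horizon = 10, n_out = 11)
  expect_error(conserved_moiety_residual(tro, w), "open")
})

test_that("model validation is total and names the offender", {
  sp <- data.frame(name = c("A", "B"), initial_concentration = c(1, 0),
                   mobile = TRUE, lipid_bound = FALSE)
  expect_error(network_model(sp,
    list(irreversible("r1", c(A = 1), c(C = 1), "k")), c(k = 1)), "C")
  expect_error(network_model(sp,
    list(irreversible("r1", c(A = 1), c(B = 1), "kmiss")), c(k = 1)),
    "kmiss")
  expect_error(network_model(sp[c(1, 1), ],
    list(irreversible("r1", c(A = 1), c(A = 1), "k")), c(k = 1)),
    "duplicate")
  # stoichiometric matrix column = products minus reactants
  m <- tiny_reversible_model()
  expect_equal(unname(m$stoichiometric_matrix[, "iso"]), c(-1, 1))
})

test_that("trajectory CSV writer emits tidy long format", {
  tr <- simulate_model(tiny_decay_model(), horizon = 1, n_out = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  df <- read.csv(path)
  expect_named(df, c("time_s", "species", "concentration_mol_l"))
  expect_equal(nrow(df), 22)
})
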