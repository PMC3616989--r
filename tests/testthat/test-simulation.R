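test_that("canonical initial states are built correctly", {
  y <- fa_initial_state("rac", include_rna = FALSE)
  expect_equal(y[["ACI"]], 1); expect_equal(y[["RAC"]], 1)
  expect_equal(sum(y), 2)

  y2 <- fa_initial_state("rho", include_rna = TRUE)
  expect_equal(y2[["ACIm"]], 1); expect_equal(y2[["RHO"]], 1)
  expect_equal(unname(y2[c("MA", "MC", "MI")]), rep(0.5, 3))
  expect_equal(sum(y2), 3.5)

  y3 <- fa_initial_state("custom",
                         overrides = list(ACI = 0.9, ACIm = 0.1, RAC = 1))
  expect_equal(unname(y3[c("ACI", "ACIm", "RAC", "RHO")]), c(0.9, 0.1, 1, 0))
  expect_error(fa_initial_state("custom", overrides = c(XYZ = 1)), "XYZ")
})

test_that("degenerate and short integrations behave as contracts say", {
  ps <- fa_params("PS1")
  cfg <- fa_config(include_rna = FALSE)
  y0 <- fa_initial_state("rac", include_rna = FALSE)
  tr0 <- fa_integrate(y0, ps, cfg, t_end = 0)
  expect_equal(length(tr0$times), 1)
  expect_equal(unname(tr0$states[1, ]), unname(y0))

  tr <- fa_integrate(y0, ps, cfg, t_end = 1, n_eval = 120)
  expect_true(all(diff(tr$times) > 0))
  # focal complexes settle near their plateau within the first time unit
  final_aci <- unname(tr$states[nrow(tr$states), "ACI"])
  expect_equal(final_aci, 0.352, tolerance = 0.05)
})

test_that("no-flux trajectories conserve the three material totals", {
  set.seed(11)
  cfg <- fa_config(include_rna = FALSE)
  totals <- function(states) cbind(
    a = rowSums(states[, c("A", "AC", "ACI", "ACIm")]),
    c = rowSums(states[, c("C", "AC", "CI", "ACI", "ACIm")]),
    i = rowSums(states[, c("I", "CI", "ACI", "ACIm")]))
  for (case in list(list(fa_params("PS1"), "rac"),
                    list(fa_params("PS1"), "rho"),
                    list(fa_params("PS3"), "rho"),
                    list(random_parameter_set(), "rho"))) {
    ic <- fa_initial_state(case[[2]], include_rna = FALSE)
    tr <- fa_integrate(ic, case[[1]], cfg, t_end = 1000, n_eval = 80)
    tt <- totals(tr$states)
    drift <- apply(abs(sweep(tt, 2, tt[1, ])), 2, max)
    expect_lt(max(drift), 1e-6)
  }
})

test_that("the assembly model is bistable between Rac and Rho states", {
  ps <- fa_params("PS1")
  cfg <- fa_config(include_rna = FALSE)
  rac <- fa_steady_state(ps, cfg, "rac")
  rho <- fa_steady_state(ps, cfg, "rho")
  expect_true(rac$converged && rho$converged)
  expect_lt(rac$state[["ACIm"]], 0.01)
  expect_gt(rho$state[["ACIm"]], 0.5)
})

test_that("steady states are idempotent under further integration", {
  ps <- fa_params("PS1")
  cfg <- fa_config(include_rna = FALSE)
  ss <- fa_steady_state(ps, cfg, "rho")
  tr <- fa_integrate(ss$state, ps, cfg, t_end = 1e5, n_eval = 10)
  expect_lt(max(abs(tr$states[nrow(tr$states), ] - ss$state) /
                  pmax(abs(ss$state), 1e-3)), 1e-6)
})

test_that("catch bonds stabilise the Rho state at least as much as slip", {
  for (l in c("PS1", "PS2", "PS3")) {
    ps <- fa_params(l)
    slip <- fa_steady_state(ps, fa_config(include_rna = FALSE,
                                          slip_fraction = 1), "rho")
    catch <- fa_steady_state(ps, fa_config(include_rna = FALSE,
                                           slip_fraction = 0), "rho")
    expect_gte(catch$state[["ACIm"]], slip$state[["ACIm"]])
  }
})

test_that("perturbed initial conditions fall into the Rho state", {
  ps <- fa_params("PS1")
  ic <- fa_initial_state("custom",
                         overrides = c(ACI = 0.9, ACIm = 0.1, RAC = 1))
  slip <- fa_steady_state(ps, fa_config(include_rna = FALSE,
                                        slip_fraction = 1), ic)
  catch <- fa_steady_state(ps, fa_config(include_rna = FALSE,
                                         slip_fraction = 0), ic)
  expect_gt(slip$state[["ACIm"]], 0.5)
  expect_gt(catch$state[["ACIm"]], slip$state[["ACIm"]])
})

test_that("time to steady state captures the separated timescales", {
  ps <- fa_params("PS1")
  cfg <- fa_config(include_rna = FALSE)
  tr_rac <- fa_integrate(fa_initial_state("rac", include_rna = FALSE),
                         ps, cfg, t_end = 1000, n_eval = 500)
  expect_lt(time_to_steady(tr_rac, 0.05), 1)
  tr_rho <- fa_integrate(fa_initial_state("rho", include_rna = FALSE),
                         ps, cfg, t_end = 5000, n_eval = 500)
  t_rho <- time_to_steady(tr_rho, 0.05)
  expect_gt(t_rho, 3); expect_lt(t_rho, 100)
  # constant trajectory converges at its first time point
  ss <- fa_steady_state(ps, cfg, "rho")
  tr_const <- fa_integrate(ss$state, ps, cfg, t_end = 10, n_eval = 20)
  expect_equal(time_to_steady(tr_const, 0.05), 0)
})
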