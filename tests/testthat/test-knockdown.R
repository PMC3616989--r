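test_that("closed-form mRNA plateau matches the simulated knockdown", {
  rp <- fa_params("PS3")$rnai
  plateau <- mrna_knockdown_plateau(rp)
  # hand value: 100 * 17.3 / (17.3 + 60/(1 + 10^-4.5))
  expect_equal(plateau, 100 * 17.3 / (17.3 + 60 / (1 + 10^-4.5)),
               tolerance = 1e-12)
  kd <- run_knockdown(fa_params("PS3"),
                      fa_config(knockdown_target = "MC"), "rac")
  expect_equal(100 * kd$post$state[["MC"]] / kd$pre$state[["MC"]], plateau,
               tolerance = 1e-4)
})

test_that("connector knockdown protocol reports consistent reductions", {
  ps <- fa_params("PS3")
  kd <- run_knockdown(ps, fa_config(knockdown_target = "MC"), "rho")
  expect_true(kd$pre$converged && kd$post$converged)
  # untargeted mRNAs are untouched
  expect_equal(kd$reductions[["MA"]], 0, tolerance = 1e-6)
  expect_equal(kd$reductions[["MI"]], 0, tolerance = 1e-6)
  # the connector chain is depleted
  expect_gt(kd$reductions[["MC"]], 50)
  expect_gt(kd$reductions[["C"]], 50)
  expect_gt(kd$reductions[["ACIm"]], 50)
  # trajectory starts at the untreated steady state
  expect_equal(unname(kd$trajectory$states[1, ]), unname(kd$pre$state),
               tolerance = 1e-8)
})

test_that("mature-adhesion loss follows the stability hierarchy", {
  ps <- fa_params("PS3")
  loss <- function(s, ic) {
    run_knockdown(ps, fa_config(slip_fraction = s, knockdown_target = "MC"),
                  ic)$reductions[["ACIm"]]
  }
  rac_slip <- loss(1, "rac")
  rho_slip <- loss(1, "rho")
  rho_catch <- loss(0, "rho")
  expect_gte(rac_slip, rho_slip)
  expect_gte(rho_slip, rho_catch)
})

test_that("the knockdown transient is essentially complete by t = 3000", {
  ps <- fa_params("PS3")
  kd <- run_knockdown(ps, fa_config(knockdown_target = "MC"), "rho")
  tr <- kd$trajectory
  aci_m <- tr$states[, "ACIm"]
  total_change <- aci_m[1] - kd$post$state[["ACIm"]]
  at3000 <- aci_m[which.min(abs(tr$times - 3000))]
  expect_gt((aci_m[1] - at3000) / total_change, 0.95)
})

test_that("Rho depletion trades mature adhesions for focal complexes", {
  kd <- run_rho_knockdown(fa_params("PS2"), fa_config())
  expect_gt(kd$reductions[["ACIm"]], 0)
  expect_lt(kd$reductions[["ACI"]], 0)
  # depletion schedule endpoints
  rp <- fa_params("PS2")$rnai
  sched <- function(t) 1 - 0.8 * (1 - exp(-rp$r_sirna * t))
  expect_equal(sched(0), 1)
  expect_equal(sched(1e9), 0.2, tolerance = 1e-9)
})

test_that("regulator-Z knockdown raises connector and both adhesion pools", {
  kd <- run_z_knockdown(fa_params("PS3"), fa_config())
  expect_lt(kd$reductions[["C"]], 0)
  expect_lt(kd$reductions[["ACI"]], 0)
  expect_lt(kd$reductions[["ACIm"]], 0)
  # untreated, the Z extension is exactly neutral: Z sits at k_Z/d_Z and
  # the effective connector degradation equals d_C
  ps <- fa_params("PS3")
  with_z <- fa_steady_state(ps, fa_config(z_extension = fa_z_params()),
                            "rho", sirna_active = FALSE)
  without <- fa_steady_state(ps, fa_config(), "rho", sirna_active = FALSE)
  expect_equal(with_z$state[["Z"]], 1, tolerance = 1e-6)
  expect_equal(unname(with_z$state[fa_species()]), unname(without$state),
               tolerance = 1e-6)
})

test_that("slip-fraction sweep endpoints match the pure bond models", {
  ps <- fa_params("PS3")
  sw <- slip_fraction_sweep(ps, "rho", s_grid = c(0, 0.5, 1))
  pure_catch <- run_knockdown(ps, fa_config(slip_fraction = 0,
                                            knockdown_target = "MC"), "rho")
  pure_slip <- run_knockdown(ps, fa_config(slip_fraction = 1,
                                           knockdown_target = "MC"), "rho")
  expect_equal(sw$ACIm_pre[1], pure_catch$pre$state[["ACIm"]],
               tolerance = 1e-8)
  expect_equal(sw$ACIm_post[3], pure_slip$post$state[["ACIm"]],
               tolerance = 1e-8)
  expect_true(all(sw$converged))
})

test_that("pathway variant without direct A+C binding keeps the Rho state", {
  ps <- fa_params("PS1")
  cfg <- fa_config(include_rna = FALSE, slip_fraction = 0,
                   alpha_AC_disabled = TRUE)
  ss <- fa_steady_state(ps, cfg, "rho")
  expect_true(ss$converged)
  expect_gt(ss$state[["ACIm"]], ss$state[["ACI"]])
  expect_gt(ss$state[["ACI"]], 0)
})

test_that("knockdown runner rejects inconsistent configurations", {
  expect_error(run_knockdown(fa_params("PS1"), fa_config(), "rac"),
               "target")
  expect_error(run_knockdown(fa_params("PS1"),
                             fa_config(include_rna = FALSE,
                                       knockdown_target = "MC"), "rac"),
               "include_rna")
  expect_warning(run_knockdown(fa_params("PS3"),
                               fa_config(knockdown_target = "MI"), "rac"),
                 "drastic")
})
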