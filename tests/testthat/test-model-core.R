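test_that("per-bond force follows the load-sharing expression", {
  kp <- fa_kinetic_params(alpha_A = 1, delta_A = 1, alpha_I = 1, delta_I = 1,
                          alpha_AC = 1, delta_AC = 1, alpha_CI = 1,
                          delta_CI = 1, tau_ACI = 1, epsilon = 0.001,
                          chi = 0.001, sigma = 1)
  st <- fa_initial_state("custom")
  expect_equal(fa_force(st, kp), 0.001)

  st2 <- fa_initial_state("custom", overrides = c(RHO = 1, ACIm = 1))
  expect_equal(fa_force(st2, kp), 1.001 / 4)  # (0.001 + 1) / (1 + 1*(0 + 3*1))

  kp0 <- fa_kinetic_params(alpha_A = 1, delta_A = 1, alpha_I = 1, delta_I = 1,
                           alpha_AC = 1, delta_AC = 1, alpha_CI = 1,
                           delta_CI = 1, tau_ACI = 1, epsilon = 0.001,
                           chi = 0.001, sigma = 0)
  st3 <- fa_initial_state("custom", overrides = c(RHO = 0.5))
  expect_equal(fa_force(st3, kp0), 0.501)
})

test_that("bond factor interpolates slip and catch Bell laws", {
  expect_equal(bond_factor(1, 1), exp(1))
  expect_equal(bond_factor(1, 0), exp(-1))
  for (f in c(0, 0.3, 2, 10)) expect_equal(bond_factor(f, 0.5), 1)
  # mixture symmetry: s and 1-s factors are reciprocal at any force
  for (i in 1:20) {
    f <- runif(1, 0, 5); s <- runif(1)
    expect_equal(bond_factor(f, s) * bond_factor(f, 1 - s), 1,
                 tolerance = 1e-12)
  }
})

test_that("force-modified rates match the substitution rules", {
  kp <- fa_params("PS1")$kinetic
  # maturation vanishes without force
  kp_nochi <- kp; kp_nochi$chi <- 0
  st0 <- fa_initial_state("custom")
  er0 <- effective_rates(st0, kp_nochi, 1)
  expect_equal(er0$tau_eff, 0)
  # PS1 with full Rho, no adhesions: F = 1.001
  st1 <- fa_initial_state("custom", overrides = c(RHO = 1))
  er1 <- effective_rates(st1, kp, 1)
  expect_equal(er1$force, 1.001)
  expect_equal(er1$tau_eff, 10 * 1.001^2)
  # derived mature-adhesion disassembly rate at zero force, slip
  erk <- effective_rates(st0, kp_nochi, 1)
  expect_equal(erk$kappa_ACIm_eff, 0.001 * (1 + 100) / 2)  # 0.0505
})

test_that("RNAi degradation is a saturating Hill response", {
  rp <- fa_params("PS1")$rnai
  expect_equal(rnai_degradation(1, 0, rp), 0)
  expect_equal(rnai_degradation(2, rp$gamma_half, rp), rp$d_max * 2 / 2)
  expect_equal(rnai_degradation(1, 1, rp), 60 / (1 + 10^-4.5),
               tolerance = 1e-12)
  # monotone in siRNA and bounded by d_max * mX
  sir <- sort(runif(50, 0, 5))
  rates <- vapply(sir, function(s) rnai_degradation(1.7, s, rp), numeric(1))
  expect_true(all(diff(rates) >= -1e-12))
  expect_true(all(rates <= rp$d_max * 1.7))
})

test_that("siRNA onset curve is hyperbolic with the right plateau", {
  rp <- fa_params("PS1")$rnai
  expect_equal(sirna_level(0, rp), 0)
  expect_equal(sirna_level(1e7, rp), 1, tolerance = 1e-6)
  expect_equal(sirna_level(1e4, rp), 1 - exp(-1))
  expect_error(sirna_level(-1, rp), "t >= 0")
})

test_that("rhs matches an independent literal transcription of the equations", {
  set.seed(42)
  for (i in 1:100) {
    ps <- random_parameter_set()
    y <- random_state()
    s <- sample(c(0, 1, runif(1)), 1)
    rna <- i %% 2 == 0
    target <- sample(c("none", "MC", "MA", "MI"), 1)
    t <- runif(1, 0, 1e5)
    cfg <- fa_config(include_rna = rna, slip_fraction = s,
                     knockdown_target = target)
    got <- fa_rhs(t, y, ps, cfg)
    want <- rhs_literal(t, y, ps, slip_fraction = s, include_rna = rna,
                        target = if (rna) target else "none")
    denom <- pmax(abs(want), 1e-8)
    expect_lt(max(abs(got - want) / denom), 1e-12)
  }
})

test_that("rhs structural limits: zero state and steady state", {
  ps <- fa_params("PS1")
  y0 <- fa_initial_state("custom")
  d <- fa_rhs(0, y0, ps, fa_config())
  expect_equal(unname(d[c("MA", "MC", "MI")]), rep(17.3, 3))
  expect_true(all(d[setdiff(names(d), c("MA", "MC", "MI"))] == 0))
  # at a converged steady state every derivative is numerically zero
  ss <- fa_steady_state(ps, fa_config(), "rho", sirna_active = FALSE)
  dss <- fa_rhs(0, ss$state, ps, fa_config(), sirna_active = FALSE)
  expect_lt(max(abs(dss)), 1e-6)
})

test_that("no-flux mode conserves the three material totals in the rhs", {
  set.seed(7)
  cfg <- fa_config(include_rna = FALSE)
  for (i in 1:20) {
    ps <- random_parameter_set()
    y <- random_state()
    d <- fa_rhs(0, y, ps, cfg)
    expect_equal(sum(d[c("A", "AC", "ACI", "ACIm")]), 0, tolerance = 1e-10)
    expect_equal(sum(d[c("C", "AC", "CI", "ACI", "ACIm")]), 0,
                 tolerance = 1e-10)
    expect_equal(sum(d[c("I", "CI", "ACI", "ACIm")]), 0, tolerance = 1e-10)
  }
})

test_that("configuration validation catches inconsistent scenarios", {
  expect_error(fa_config(slip_fraction = 1.5), "slip_fraction")
  expect_error(fa_config(knockdown_target = "Z"), "z_extension")
  expect_silent(fa_config(knockdown_target = "Z", z_extension = fa_z_params()))
})
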