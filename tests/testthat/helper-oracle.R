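# Independent literal transcription of the model equations, written
# directly term by term (no reaction decomposition, no stoichiometry
# matrix).  Used as the oracle that the packaged right-hand side must
# reproduce to machine precision.
rhs_literal <- function(t, y, ps, slip_fraction = 1, include_rna = TRUE,
                        target = "none", sirna_active = TRUE) {
  kp <- ps$kinetic; rp <- ps$rnai; sg <- ps$signaling
  MA <- y[["MA"]]; MC <- y[["MC"]]; MI <- y[["MI"]]
  A <- y[["A"]]; C <- y[["C"]]; I <- y[["I"]]
  AC <- y[["AC"]]; CI <- y[["CI"]]
  ACI <- y[["ACI"]]; ACIm <- y[["ACIm"]]
  RAC <- y[["RAC"]]; RHO <- y[["RHO"]]

  Fr <- (kp$chi + kp$rho_RHO * RHO) / (1 + kp$sigma * (ACI + kp$m * ACIm))
  ex <- exp((2 * slip_fraction - 1) * Fr)
  dA_ <- kp$delta_A * ex
  dI_ <- kp$delta_I * ex
  tau_ <- kp$tau_ACI * Fr^kp$n
  kap_ <- kp$epsilon * (kp$delta_A + kp$delta_I) / 2 * ex
  ab <- 1 + kp$rho_RAC * RAC

  sir <- if (sirna_active && target %in% c("MA", "MC", "MI"))
    rp$sirna_max * (1 - exp(-rp$r_sirna * max(t, 0))) else 0
  hill <- if (sir > 0)
    rp$d_max * sir^rp$h / (rp$gamma_half^rp$h + sir^rp$h) else 0
  del <- function(sp, conc) if (target == sp) hill * conc else 0

  if (include_rna) {
    dMA <- rp$k_MA - rp$d_MA * MA - del("MA", MA)
    dMC <- rp$k_MC - rp$d_MC * MC - del("MC", MC)
    dMI <- rp$k_MI - rp$d_MI * MI - del("MI", MI)
    fluxA <- rp$k_TA * MA - rp$d_A * A
    fluxC <- rp$k_TC * MC - rp$d_C * C
    fluxI <- rp$k_TI * MI - rp$d_I * I
  } else {
    dMA <- dMC <- dMI <- 0
    fluxA <- fluxC <- fluxI <- 0
  }
  dA <- -kp$alpha_AC * A * C + kp$delta_AC * AC -
    kp$alpha_A * ab * A * CI + dA_ * ACI + fluxA
  dC <- -kp$alpha_AC * A * C + kp$delta_AC * AC -
    kp$alpha_CI * C * I + kp$delta_CI * CI + fluxC
  dI <- -kp$alpha_CI * C * I + kp$delta_CI * CI -
    kp$alpha_I * ab * AC * I + dI_ * ACI + fluxI
  dAC <- kp$alpha_AC * A * C - kp$delta_AC * AC -
    kp$alpha_I * ab * AC * I + dI_ * ACI
  dCI <- kp$alpha_CI * C * I - kp$delta_CI * CI -
    kp$alpha_A * ab * A * CI + dA_ * ACI
  dACI <- kp$alpha_A * ab * A * CI - dA_ * ACI +
    kp$alpha_I * ab * AC * I - dI_ * ACI - tau_ * ACI + kap_ * ACIm
  dACIm <- tau_ * ACI - kap_ * ACIm
  dRAC <- sg$kappa_RAC * ACI * (sg$rac_total - RAC) -
    sg$beta_RAC * RAC * (sg$v * RHO)^sg$gamma_RAC /
      (sg$K_RAC + (sg$v * RHO)^sg$gamma_RAC)
  dRHO <- sg$kappa_RHO * ACIm * (sg$rho_total - RHO) -
    sg$beta_RHO * RHO * RAC^sg$gamma_RHO / (sg$K_RHO + RAC^sg$gamma_RHO)

  c(MA = dMA, MC = dMC, MI = dMI, A = dA, C = dC, I = dI, AC = dAC,
    CI = dCI, ACI = dACI, ACIm = dACIm, RAC = dRAC, RHO = dRHO)
}

# random strictly positive parameter set (log-uniform rates) for
# property-style checks
random_parameter_set <- function(label = "rand") {
  lu <- function(lo, hi) 10^stats::runif(1, log10(lo), log10(hi))
  kin <- fa_kinetic_params(
    alpha_A = lu(1, 1e4), delta_A = lu(0.1, 100),
    alpha_I = lu(1, 1e4), delta_I = lu(0.1, 100),
    alpha_AC = lu(0.01, 100), delta_AC = lu(0.1, 100),
    alpha_CI = lu(0.01, 1e4), delta_CI = lu(0.1, 100),
    tau_ACI = lu(1, 100), epsilon = lu(1e-4, 1e-2),
    chi = lu(1e-4, 1e-2), sigma = lu(0.1, 10),
    m = 3, n = 2, rho_RAC = lu(0.1, 10), rho_RHO = lu(0.1, 10))
  rna <- fa_rnai_params(
    k_MA = lu(1, 100), k_MC = lu(1, 100), k_MI = lu(1, 100),
    d_MA = lu(1, 100), d_MC = lu(1, 100), d_MI = lu(1, 100),
    k_TA = lu(0.01, 10), k_TC = lu(0.01, 10), k_TI = lu(0.01, 10),
    d_A = lu(1, 100), d_C = lu(1, 100), d_I = lu(1, 100),
    d_max = lu(10, 100), gamma_half = lu(0.01, 1), h = lu(1, 6),
    sirna_max = 1, r_sirna = 1e-4)
  sig <- fa_signaling_params(
    kappa_RAC = lu(0.1, 10), kappa_RHO = lu(0.1, 10),
    beta_RAC = lu(0.1, 10), beta_RHO = lu(0.1, 10),
    K_RAC = lu(0.1, 10), K_RHO = lu(0.1, 10),
    gamma_RAC = 4, gamma_RHO = 4, v = lu(0.5, 2))
  fa_parameter_set(label, kin, rna, sig)
}

random_state <- function() {
  y <- stats::runif(12, 0, 1.5)
  names(y) <- fa_species()
  y
}
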