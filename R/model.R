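#' Scenario configuration for the kinetic model
#'
#' Collects the structural switches of the model: whether the RNA part
#' (transcription, translation, degradation) is included, the bond model
#' as a slip fraction, the knockdown target, and optional pathway
#' variants.
#'
#' The slip fraction \code{s} interpolates between the two extreme
#' force-response scenarios: \code{s = 1} is the pure slip-bond model
#' (dissociation accelerates exponentially with force), \code{s = 0} the
#' pure catch-bond model (dissociation is suppressed by force), and
#' intermediate values mix the two Bell exponents as exp((2s-1) F).
#'
#' @param include_rna logical; include mRNA dynamics and protein
#'   turnover (the "external fluxes").  With \code{FALSE} the model is
#'   the closed assembly system in which the three material totals are
#'   conserved.
#' @param slip_fraction fraction of slip bonds in [0, 1]; 1 = slip,
#'   0 = catch.
#' @param knockdown_target one of "none", "MC", "MA", "MI", "RHO", "Z".
#'   mRNA targets add the Hill-kinetic RNAi degradation term to that
#'   mRNA only; "RHO" shrinks the total Rho pool in a time-dependent
#'   manner; "Z" requires \code{z_extension}.
#' @param alpha_AC_disabled logical; switch off the direct A + C -> AC
#'   assembly path (the variant in which CI must form first).
#' @param z_extension optional \code{\link{fa_z_params}}: adds a 13th
#'   species Z controlling connector degradation.
#' @param rho_kd_fraction residual fraction of the Rho pool after a
#'   full Rho knockdown (default 0.2, i.e. reduction from 1 to 0.2).
#' @return object of class \code{fa_config}.
#' @export
fa_config <- function(include_rna = TRUE, slip_fraction = 1,
                      knockdown_target = c("none", "MC", "MA", "MI", "RHO", "Z"),
                      alpha_AC_disabled = FALSE, z_extension = NULL,
                      rho_kd_fraction = 0.2) {
  knockdown_target <- match.arg(knockdown_target)
  if (!is.numeric(slip_fraction) || slip_fraction < 0 || slip_fraction > 1)
    stop("slip_fraction must lie in [0, 1]", call. = FALSE)
  if (knockdown_target == "Z" && is.null(z_extension))
    stop("knockdown_target = 'Z' requires a z_extension", call. = FALSE)
  if (!is.null(z_extension) && !inherits(z_extension, "fa_z_params"))
    stop("z_extension must be created with fa_z_params()", call. = FALSE)
  structure(list(include_rna = isTRUE(include_rna),
                 slip_fraction = as.numeric(slip_fraction),
                 knockdown_target = knockdown_target,
                 alpha_AC_disabled = isTRUE(alpha_AC_disabled),
                 z_extension = z_extension,
                 rho_kd_fraction = as.numeric(rho_kd_fraction)),
            class = "fa_config")
}

#' Auxiliary degradation-regulator parameters
#'
#' Parameters of the optional 13th species Z, a regulator (e.g. a
#' protease such as calpain) that controls the degradation of the
#' connector component.  Z follows simple production/degradation
#' kinetics, dZ/dt = k_Z - d_Z Z (minus an RNAi term when Z is the
#' knockdown target), and the effective connector degradation rate is
#' d_C * Z / Z_ss with Z_ss = k_Z/d_Z, so the untreated system is left
#' unchanged by construction.
#'
#' @param k_Z production rate (default 10).
#' @param d_Z degradation rate constant (default 10; protein-like
#'   turnover with steady state 1).
#' @return object of class \code{fa_z_params}.
#' @export
fa_z_params <- function(k_Z = 10, d_Z = 10) {
  if (k_Z <= 0 || d_Z <= 0) stop("k_Z and d_Z must be positive", call. = FALSE)
  structure(list(k_Z = as.numeric(k_Z), d_Z = as.numeric(d_Z)),
            class = "fa_z_params")
}

#' Per-bond contractile force
#'
#' The force acting on the adhesion bonds: active Rho drives myosin
#' contractility on top of a basal level chi, and the total force is
#' shared over the existing adhesion structures (load sharing), with
#' mature adhesions weighted m-fold because they bear higher stress:
#' F = (chi + rho_RHO * RHO) / (1 + sigma * (ACI + m * ACIm)).
#'
#' @param state named state vector (needs RHO, ACI, ACIm).
#' @param kp \code{fa_kinetic_params}.
#' @return dimensionless force (scalar).
#' @export
fa_force <- function(state, kp) {
  (kp$chi + kp$rho_RHO * state[["RHO"]]) /
    (1 + kp$sigma * (state[["ACI"]] + kp$m * state[["ACIm"]]))
}

#' Bell-law bond factor for a slip/catch mixture
#'
#' Multiplier applied to the force-sensitive dissociation rates.  A pure
#' slip bond dissociates as exp(+F), a pure catch bond as exp(-F); a
#' mixture with slip fraction s gives exp(s F - (1-s) F) = exp((2s-1) F).
#' At s = 1/2 the two exponents cancel for any force.
#'
#' @param force per-bond force (>= 0).
#' @param slip_fraction fraction of slip bonds in [0, 1].
#' @return dimensionless multiplier.
#' @export
bond_factor <- function(force, slip_fraction) {
  exp((2 * slip_fraction - 1) * force)
}

#' Force-modified rate constants
#'
#' Evaluates the four force-dependent rate substitutions at a given
#' state: the dissociation rates of actin and integrin from the full
#' complex pick up the Bell bond factor, maturation scales as F^n, and
#' the mature-adhesion disassembly rate is derived as
#' epsilon * (delta_A + delta_I)/2 times the bond factor (it is never an
#' independent parameter).
#'
#' @param state named state vector.
#' @param kp \code{fa_kinetic_params}.
#' @param slip_fraction fraction of slip bonds.
#' @return named list with \code{force}, \code{delta_A_eff},
#'   \code{delta_I_eff}, \code{tau_eff}, \code{kappa_ACIm_eff}.
#' @export
effective_rates <- function(state, kp, slip_fraction) {
  f <- fa_force(state, kp)
  b <- bond_factor(f, slip_fraction)
  list(force = f,
       delta_A_eff = kp$delta_A * b,
       delta_I_eff = kp$delta_I * b,
       tau_eff = kp$tau_ACI * f^kp$n,
       kappa_ACIm_eff = kp$epsilon * (kp$delta_A + kp$delta_I) / 2 * b)
}

#' Hill-kinetic RNAi degradation rate
#'
#' Additional degradation flux of a targeted mRNA due to siRNA,
#' d_max * sirna^h / (gamma_half^h + sirna^h) * mX.  The saturation at
#' high siRNA reflects saturation of the silencing machinery.
#'
#' @param mX mRNA concentration (>= 0).
#' @param sirna siRNA concentration (>= 0).
#' @param rp \code{fa_rnai_params}.
#' @return degradation rate (concentration per time).
#' @export
rnai_degradation <- function(mX, sirna, rp) {
  if (sirna <= 0) return(0 * mX)
  rp$d_max * sirna^rp$h / (rp$gamma_half^rp$h + sirna^rp$h) * mX
}

#' siRNA concentration time course
#'
#' Hyperbolic onset of the intracellular siRNA concentration after the
#' start of treatment: sirna_max * (1 - exp(-r_sirna t)).  The onset
#' rate lumps uptake and transport and is chosen so the plateau is
#' reached after roughly two days.
#'
#' @param t time since knockdown start (>= 0).
#' @param rp \code{fa_rnai_params}.
#' @return siRNA concentration.
#' @export
sirna_level <- function(t, rp) {
  if (any(t < 0)) stop("sirna_level is defined for t >= 0", call. = FALSE)
  rp$sirna_max * (1 - exp(-rp$r_sirna * t))
}

# ---------------------------------------------------------------------------
# reaction catalog and right-hand side
# ---------------------------------------------------------------------------

.fa_reactions <- c("prod_MA", "prod_MC", "prod_MI",
                   "deg_MA", "deg_MC", "deg_MI",
                   "transl_A", "transl_C", "transl_I",
                   "deg_A", "deg_C", "deg_I",
                   "bind_AC", "bind_CI", "bind_A_CI", "bind_AC_I",
                   "maturation", "fa_disassembly",
                   "rac_activation", "rac_inhibition",
                   "rho_activation", "rho_inhibition")

#' Reaction catalog
#'
#' Names of the net reactions the model is decomposed into, in the order
#' used by \code{\link{reaction_rates}} and by the per-reaction scaling
#' multipliers of the sensitivity analysis.  Reversible assembly steps
#' are single net reactions (forward minus backward rate); each mRNA
#' degradation bundles the basal and RNAi terms.  With the Z extension
#' two further reactions (\code{prod_Z}, \code{deg_Z}) are appended.
#'
#' @param cfg \code{fa_config}.
#' @return character vector of reaction names.
#' @export
reaction_catalog <- function(cfg = fa_config()) {
  if (!is.null(cfg$z_extension)) c(.fa_reactions, "prod_Z", "deg_Z")
  else .fa_reactions
}

# stoichiometry: species x reactions, built once per configuration
.fa_stoich <- function(cfg) {
  sp <- fa_species(with_z = !is.null(cfg$z_extension))
  rx <- reaction_catalog(cfg)
  N <- matrix(0, length(sp), length(rx), dimnames = list(sp, rx))
  N["MA", "prod_MA"] <- 1;  N["MC", "prod_MC"] <- 1;  N["MI", "prod_MI"] <- 1
  N["MA", "deg_MA"] <- -1;  N["MC", "deg_MC"] <- -1;  N["MI", "deg_MI"] <- -1
  N["A", "transl_A"] <- 1;  N["C", "transl_C"] <- 1;  N["I", "transl_I"] <- 1
  N["A", "deg_A"] <- -1;    N["C", "deg_C"] <- -1;    N["I", "deg_I"] <- -1
  N[c("A", "C", "AC"), "bind_AC"] <- c(-1, -1, 1)
  N[c("C", "I", "CI"), "bind_CI"] <- c(-1, -1, 1)
  N[c("A", "CI", "ACI"), "bind_A_CI"] <- c(-1, -1, 1)
  N[c("AC", "I", "ACI"), "bind_AC_I"] <- c(-1, -1, 1)
  N[c("ACI", "ACIm"), "maturation"] <- c(-1, 1)
  N[c("ACIm", "ACI"), "fa_disassembly"] <- c(-1, 1)
  N["RAC", "rac_activation"] <- 1;  N["RAC", "rac_inhibition"] <- -1
  N["RHO", "rho_activation"] <- 1;  N["RHO", "rho_inhibition"] <- -1
  if (!is.null(cfg$z_extension)) {
    N["Z", "prod_Z"] <- 1; N["Z", "deg_Z"] <- -1
  }
  N
}

#' Net reaction rates at a state
#'
#' Evaluates the net rate of every reaction in
#' \code{\link{reaction_catalog}} at time \code{t} and state
#' \code{state}.  Time matters only through the siRNA onset curve and,
#' for a Rho knockdown, the shrinking Rho pool.
#'
#' @param t time (time units, approximately minutes).
#' @param state named state vector in canonical order.
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}.
#' @param sirna_active logical; whether the siRNA treatment (and, for a
#'   Rho target, pool depletion) is switched on.
#' @return named numeric vector of net rates.
#' @export
reaction_rates <- function(t, state, ps, cfg, sirna_active = TRUE) {
  kp <- ps$kinetic; rp <- ps$rnai; sg <- ps$signaling
  MA <- state[["MA"]]; MC <- state[["MC"]]; MI <- state[["MI"]]
  A <- state[["A"]]; C <- state[["C"]]; I <- state[["I"]]
  AC <- state[["AC"]]; CI <- state[["CI"]]
  ACI <- state[["ACI"]]; ACIm <- state[["ACIm"]]
  RAC <- state[["RAC"]]; RHO <- state[["RHO"]]

  er <- effective_rates(state, kp, cfg$slip_fraction)
  rac_boost <- 1 + kp$rho_RAC * RAC

  sir <- if (sirna_active && cfg$knockdown_target %in% c("MA", "MC", "MI", "Z"))
    sirna_level(max(t, 0), rp) else 0

  rho_total <- sg$rho_total
  if (sirna_active && cfg$knockdown_target == "RHO")
    rho_total <- sg$rho_total *
      (1 - (1 - cfg$rho_kd_fraction) * (1 - exp(-rp$r_sirna * max(t, 0))))

  v <- numeric(length(reaction_catalog(cfg)))
  names(v) <- reaction_catalog(cfg)
  if (cfg$include_rna) {
    v["prod_MA"] <- rp$k_MA; v["prod_MC"] <- rp$k_MC; v["prod_MI"] <- rp$k_MI
    v["deg_MA"] <- rp$d_MA * MA +
      if (cfg$knockdown_target == "MA") rnai_degradation(MA, sir, rp) else 0
    v["deg_MC"] <- rp$d_MC * MC +
      if (cfg$knockdown_target == "MC") rnai_degradation(MC, sir, rp) else 0
    v["deg_MI"] <- rp$d_MI * MI +
      if (cfg$knockdown_target == "MI") rnai_degradation(MI, sir, rp) else 0
    v["transl_A"] <- rp$k_TA * MA
    v["transl_C"] <- rp$k_TC * MC
    v["transl_I"] <- rp$k_TI * MI
    d_C_eff <- rp$d_C
    if (!is.null(cfg$z_extension)) {
      zp <- cfg$z_extension
      d_C_eff <- rp$d_C * state[["Z"]] / (zp$k_Z / zp$d_Z)
    }
    v["deg_A"] <- rp$d_A * A
    v["deg_C"] <- d_C_eff * C
    v["deg_I"] <- rp$d_I * I
  }
  alpha_AC <- if (cfg$alpha_AC_disabled) 0 else kp$alpha_AC
  v["bind_AC"] <- alpha_AC * A * C - kp$delta_AC * AC
  v["bind_CI"] <- kp$alpha_CI * C * I - kp$delta_CI * CI
  v["bind_A_CI"] <- kp$alpha_A * rac_boost * A * CI - er$delta_A_eff * ACI
  v["bind_AC_I"] <- kp$alpha_I * rac_boost * AC * I - er$delta_I_eff * ACI
  v["maturation"] <- er$tau_eff * ACI
  v["fa_disassembly"] <- er$kappa_ACIm_eff * ACIm
  hill_rac <- (sg$v * RHO)^sg$gamma_RAC /
    (sg$K_RAC + (sg$v * RHO)^sg$gamma_RAC)
  hill_rho <- RAC^sg$gamma_RHO / (sg$K_RHO + RAC^sg$gamma_RHO)
  v["rac_activation"] <- sg$kappa_RAC * ACI * (sg$rac_total - RAC)
  v["rac_inhibition"] <- sg$beta_RAC * RAC * hill_rac
  v["rho_activation"] <- sg$kappa_RHO * ACIm * (rho_total - RHO)
  v["rho_inhibition"] <- sg$beta_RHO * RHO * hill_rho
  if (!is.null(cfg$z_extension)) {
    zp <- cfg$z_extension
    v["prod_Z"] <- zp$k_Z
    v["deg_Z"] <- zp$d_Z * state[["Z"]] +
      if (cfg$knockdown_target == "Z") rnai_degradation(state[["Z"]], sir, rp) else 0
  }
  v
}

#' Right-hand side of the kinetic model
#'
#' Time derivatives of all species, assembled as the stoichiometry
#' matrix applied to the net reaction rates (optionally scaled by
#' per-reaction multipliers, the handles used by the metabolic control
#' analysis).
#'
#' @param t time.
#' @param state named state vector (12 species, 13 with Z).
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}.
#' @param multipliers optional named vector of per-reaction scale
#'   factors (default all 1).
#' @param sirna_active logical; see \code{\link{reaction_rates}}.
#' @return named vector of derivatives.
#' @export
fa_rhs <- function(t, state, ps, cfg, multipliers = NULL,
                   sirna_active = TRUE) {
  N <- .fa_stoich(cfg)
  v <- reaction_rates(t, state, ps, cfg, sirna_active)
  if (!is.null(multipliers)) v[names(multipliers)] <- v[names(multipliers)] * multipliers
  drop(N %*% v)
}

# fast closure used by the integrator: pre-resolves every scalar and the
# stoichiometry so the per-step cost stays small
.fa_make_deriv <- function(ps, cfg, multipliers = NULL, sirna_active = TRUE) {
  kp <- ps$kinetic; rp <- ps$rnai; sg <- ps$signaling
  s <- cfg$slip_fraction
  alpha_A <- kp$alpha_A; delta_A <- kp$delta_A
  alpha_I <- kp$alpha_I; delta_I <- kp$delta_I
  alpha_AC <- if (cfg$alpha_AC_disabled) 0 else kp$alpha_AC
  delta_AC <- kp$delta_AC; alpha_CI <- kp$alpha_CI; delta_CI <- kp$delta_CI
  tau_ACI <- kp$tau_ACI; kap0 <- kp$epsilon * (delta_A + delta_I) / 2
  chi <- kp$chi; sigma <- kp$sigma; mw <- kp$m; nexp <- kp$n
  rho_RAC <- kp$rho_RAC; rho_RHO <- kp$rho_RHO
  include_rna <- cfg$include_rna
  target <- cfg$knockdown_target
  has_z <- !is.null(cfg$z_extension)
  if (has_z) { kZ <- cfg$z_extension$k_Z; dZ <- cfg$z_extension$d_Z
               Zss <- kZ / dZ }
  mrna_target <- sirna_active && target %in% c("MA", "MC", "MI", "Z")
  rho_kd <- sirna_active && target == "RHO"
  rho_floor <- cfg$rho_kd_fraction
  d_hill <- rp$d_max; Gh <- rp$gamma_half^rp$h; hh <- rp$h
  smax <- rp$sirna_max; rs <- rp$r_sirna
  kRAC <- sg$kappa_RAC; kRHO <- sg$kappa_RHO
  bRAC <- sg$beta_RAC; bRHO <- sg$beta_RHO
  KRAC <- sg$K_RAC; KRHO <- sg$K_RHO
  gRAC <- sg$gamma_RAC; gRHO <- sg$gamma_RHO; vfb <- sg$v
  rac_tot <- sg$rac_total; rho_tot0 <- sg$rho_total
  mult <- rep(1, length(reaction_catalog(cfg)))
  names(mult) <- reaction_catalog(cfg)
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), names(mult))
    if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    mult[names(multipliers)] <- multipliers
  }
  N <- .fa_stoich(cfg)

  function(t, y, parms) {
    sir <- if (mrna_target) smax * (1 - exp(-rs * max(t, 0))) else 0
    del <- if (sir > 0) d_hill * sir^hh / (Gh + sir^hh) else 0
    rho_tot <- if (rho_kd)
      rho_tot0 * (1 - (1 - rho_floor) * (1 - exp(-rs * max(t, 0))))
    else rho_tot0
    ACI <- y[9]; ACIm <- y[10]; RAC <- y[11]; RHO <- y[12]
    Fr <- (chi + rho_RHO * RHO) / (1 + sigma * (ACI + mw * ACIm))
    b <- exp((2 * s - 1) * Fr)
    rb <- 1 + rho_RAC * RAC
    v <- numeric(length(mult))
    if (include_rna) {
      v[1] <- rp$k_MA; v[2] <- rp$k_MC; v[3] <- rp$k_MI
      v[4] <- rp$d_MA * y[1] + if (target == "MA") del * y[1] else 0
      v[5] <- rp$d_MC * y[2] + if (target == "MC") del * y[2] else 0
      v[6] <- rp$d_MI * y[3] + if (target == "MI") del * y[3] else 0
      v[7] <- rp$k_TA * y[1]; v[8] <- rp$k_TC * y[2]; v[9] <- rp$k_TI * y[3]
      dCe <- if (has_z) rp$d_C * y[13] / Zss else rp$d_C
      v[10] <- rp$d_A * y[4]; v[11] <- dCe * y[5]; v[12] <- rp$d_I * y[6]
    }
    v[13] <- alpha_AC * y[4] * y[5] - delta_AC * y[7]
    v[14] <- alpha_CI * y[5] * y[6] - delta_CI * y[8]
    v[15] <- alpha_A * rb * y[4] * y[8] - delta_A * b * ACI
    v[16] <- alpha_I * rb * y[7] * y[6] - delta_I * b * ACI
    v[17] <- tau_ACI * Fr^nexp * ACI
    v[18] <- kap0 * b * ACIm
    vr <- (vfb * RHO)^gRAC
    v[19] <- kRAC * ACI * (rac_tot - RAC)
    v[20] <- bRAC * RAC * vr / (KRAC + vr)
    ra <- RAC^gRHO
    v[21] <- kRHO * ACIm * (rho_tot - RHO)
    v[22] <- bRHO * RHO * ra / (KRHO + ra)
    if (has_z) {
      v[23] <- kZ
      v[24] <- dZ * y[13] + if (target == "Z") del * y[13] else 0
    }
    list(drop(N %*% (mult * v)))
  }
}
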