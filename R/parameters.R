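# canonical species order used by every state vector and output table;
# the mature complex (often written with a trailing '#') is spelled ACIm
.fa_species <- c("MA", "MC", "MI", "A", "C", "I",
                 "AC", "CI", "ACI", "ACIm", "RAC", "RHO")

.kinetic_fields <- c("alpha_A", "delta_A", "alpha_I", "delta_I",
                     "alpha_AC", "delta_AC", "alpha_CI", "delta_CI",
                     "tau_ACI", "epsilon", "chi", "sigma", "m", "n",
                     "rho_RAC", "rho_RHO")

.rnai_fields <- c("k_MA", "k_MC", "k_MI", "d_MA", "d_MC", "d_MI",
                  "k_TA", "k_TC", "k_TI", "d_A", "d_C", "d_I",
                  "d_max", "gamma_half", "h", "sirna_max", "r_sirna")

.signaling_fields <- c("kappa_RAC", "kappa_RHO", "beta_RAC", "beta_RHO",
                       "K_RAC", "K_RHO", "gamma_RAC", "gamma_RHO", "v",
                       "rac_total", "rho_total")

#' Canonical species names
#'
#' Returns the canonical ordering of the model species: the three mRNAs
#' (MA, MC, MI), the monomeric proteins actin (A), connector (C) and
#' integrin (I), the intermediate complexes AC and CI, the focal complex
#' ACI, the mature focal adhesion ACIm, and the active GTPase pools RAC
#' and RHO.  With the optional degradation-regulator extension a 13th
#' species Z is appended.
#'
#' @param with_z logical; append the auxiliary regulator species Z.
#' @return character vector of species names.
#' @export
fa_species <- function(with_z = FALSE) {
  if (with_z) c(.fa_species, "Z") else .fa_species
}

#' Assembly, force and signalling-gain parameters
#'
#' Constructs the kinetic block of a parameter set: mass-action rate
#' constants for the hierarchical assembly reactions, the maturation
#' rate constant, and the dimensionless force-model constants.  Time is
#' measured in the model's rescaled unit (approximately minutes);
#' concentrations are dimensionless and of order one.
#'
#' @param alpha_A,delta_A association/dissociation rate constants for
#'   actin binding to CI (forming the full complex ACI).
#' @param alpha_I,delta_I association/dissociation rate constants for
#'   integrin binding to AC.
#' @param alpha_AC,delta_AC rate constants for A + C <-> AC.
#' @param alpha_CI,delta_CI rate constants for C + I <-> CI.
#' @param tau_ACI maturation rate constant for ACI -> ACIm; the realised
#'   rate is tau_ACI * F^n with F the per-bond force.
#' @param epsilon focal-adhesion stability factor: the ACIm -> ACI
#'   disassembly rate is epsilon * (delta_A + delta_I)/2 times the bond
#'   factor, so small epsilon makes mature adhesions long-lived.
#' @param chi basal contractility present without active Rho.
#' @param sigma load-sharing weight: larger adhesions spread the total
#'   force over more bonds, reducing the per-bond force.
#' @param m force weight of mature adhesions relative to focal
#'   complexes in the load-sharing denominator (default 3).
#' @param n exponent of the force dependence of maturation (default 2).
#' @param rho_RAC gain of active Rac on the two complex-assembly steps.
#' @param rho_RHO gain of active Rho on contractile force.
#' @return object of class \code{fa_kinetic_params} (named list).
#' @export
fa_kinetic_params <- function(alpha_A, delta_A, alpha_I, delta_I,
                              alpha_AC, delta_AC, alpha_CI, delta_CI,
                              tau_ACI, epsilon, chi = 0.001, sigma = 1,
                              m = 3, n = 2, rho_RAC = 1, rho_RHO = 1) {
  kp <- mget(.kinetic_fields)
  kp <- lapply(kp, as.numeric)
  rate_like <- c("alpha_A", "delta_A", "alpha_I", "delta_I", "alpha_AC",
                 "delta_AC", "alpha_CI", "delta_CI", "tau_ACI", "epsilon")
  for (f in rate_like)
    if (!is.finite(kp[[f]]) || kp[[f]] <= 0)
      stop("kinetic parameter '", f, "' must be a positive number", call. = FALSE)
  if (kp$m < 1 || kp$n < 1) stop("m and n must be >= 1", call. = FALSE)
  if (kp$chi < 0 || kp$sigma < 0) stop("chi and sigma must be >= 0", call. = FALSE)
  structure(kp, class = "fa_kinetic_params")
}

#' mRNA turnover, translation and RNA-interference parameters
#'
#' Constructs the RNA block of a parameter set: basal mRNA production and
#' degradation, translation, protein degradation, and the phenomenological
#' Hill-kinetic description of siRNA-mediated knockdown.
#'
#' @param k_MA,k_MC,k_MI mRNA production rate constants.
#' @param d_MA,d_MC,d_MI basal mRNA degradation rate constants.
#' @param k_TA,k_TC,k_TI translation rate constants.
#' @param d_A,d_C,d_I monomeric protein degradation rate constants.
#' @param d_max maximal additional mRNA degradation rate at saturating
#'   siRNA; chosen so the knocked-down mRNA plateaus near 20 percent of
#'   its untreated level.
#' @param gamma_half siRNA concentration at half-maximal degradation.
#' @param h Hill coefficient of the siRNA dose response.
#' @param sirna_max plateau siRNA concentration reached after onset.
#' @param r_sirna onset rate of the siRNA concentration; its inverse sets
#'   the roughly two-day knockdown timescale.
#' @return object of class \code{fa_rnai_params}.
#' @export
fa_rnai_params <- function(k_MA, k_MC, k_MI, d_MA, d_MC, d_MI,
                           k_TA, k_TC, k_TI, d_A, d_C, d_I,
                           d_max = 60, gamma_half = 0.1, h = 4.5,
                           sirna_max = 1, r_sirna = 1e-4) {
  rp <- lapply(mget(.rnai_fields), as.numeric)
  for (f in .rnai_fields)
    if (!is.finite(rp[[f]]) || rp[[f]] <= 0)
      stop("RNAi parameter '", f, "' must be a positive number", call. = FALSE)
  structure(rp, class = "fa_rnai_params")
}

#' Rac/Rho signalling parameters
#'
#' Constructs the GTPase block: activation of Rac by focal complexes and
#' of Rho by focal adhesions, and their mutual inhibition through Hill
#' functions (double-negative feedback).  Total pools (active+inactive)
#' are conserved; \code{rac_total}/\code{rho_total} generalise the fixed
#' unit pools so that Rho depletion scenarios can shrink the Rho pool.
#'
#' @param kappa_RAC,kappa_RHO activation gains (per unit ACI resp. ACIm).
#' @param beta_RAC,beta_RHO maximal mutual-inhibition rates.
#' @param K_RAC,K_RHO Hill half-saturation constants of the inhibition.
#' @param gamma_RAC,gamma_RHO Hill coefficients (default 4: sharp switch).
#' @param v feedback gain applied to Rho inside the Rac-inhibition Hill
#'   term only.
#' @param rac_total,rho_total conserved total GTPase pools (default 1).
#' @return object of class \code{fa_signaling_params}.
#' @export
fa_signaling_params <- function(kappa_RAC = 1, kappa_RHO = 1,
                                beta_RAC = 1, beta_RHO = 1,
                                K_RAC = 1, K_RHO = 1,
                                gamma_RAC = 4, gamma_RHO = 4, v = 1,
                                rac_total = 1, rho_total = 1) {
  sp <- lapply(mget(.signaling_fields), as.numeric)
  for (f in .signaling_fields)
    if (!is.finite(sp[[f]]) || sp[[f]] <= 0)
      stop("signalling parameter '", f, "' must be a positive number", call. = FALSE)
  if (sp$gamma_RAC < 1 || sp$gamma_RHO < 1)
    stop("Hill coefficients must be >= 1", call. = FALSE)
  structure(sp, class = "fa_signaling_params")
}

#' Complete model parameter set
#'
#' Bundles the kinetic, RNAi and signalling blocks under a label.  The
#' three reference sets shipped with the package are available through
#' \code{\link{fa_params}}.
#'
#' @param label short identifier (e.g. "PS1").
#' @param kinetic \code{fa_kinetic_params}.
#' @param rnai \code{fa_rnai_params}.
#' @param signaling \code{fa_signaling_params}.
#' @return object of class \code{fa_parameter_set}.
#' @export
fa_parameter_set <- function(label, kinetic, rnai, signaling) {
  stopifnot(inherits(kinetic, "fa_kinetic_params"),
            inherits(rnai, "fa_rnai_params"),
            inherits(signaling, "fa_signaling_params"))
  structure(list(label = as.character(label), kinetic = kinetic,
                 rnai = rnai, signaling = signaling),
            class = "fa_parameter_set")
}

# the three reference parameter sets; values identical to the published
# table, translation rates to all printed digits
.fa_builtin <- local({
  kin <- function(aA, dA, aI, dI, aAC, dAC, aCI, dCI)
    fa_kinetic_params(alpha_A = aA, delta_A = dA, alpha_I = aI, delta_I = dI,
                      alpha_AC = aAC, delta_AC = dAC, alpha_CI = aCI,
                      delta_CI = dCI, tau_ACI = 10, epsilon = 0.001,
                      chi = 0.001, sigma = 1)
  rna <- function(kTA, kTC, kTI)
    fa_rnai_params(k_MA = 17.3, k_MC = 17.3, k_MI = 17.3,
                   d_MA = 17.3, d_MC = 17.3, d_MI = 17.3,
                   k_TA = kTA, k_TC = kTC, k_TI = kTI,
                   d_A = 10, d_C = 10, d_I = 10)
  sig <- fa_signaling_params()
  list(
    PS1 = fa_parameter_set("PS1", kin(10000, 1, 100, 100, 0.1, 10, 10, 100),
                           rna(2.07681, 2.07437, 2.59193), sig),
    PS2 = fa_parameter_set("PS2", kin(1000, 100, 1000, 100, 0.01, 10, 10000, 10),
                           rna(0.735221, 0.0206286, 0.652918), sig),
    PS3 = fa_parameter_set("PS3", kin(10, 1, 100, 100, 100, 10, 0.01, 100),
                           rna(1.03706, 1.03476, 2.08517), sig)
  )
})

#' Reference parameter sets
#'
#' Returns one of the three reference parameter sets PS1, PS2 or PS3.
#' They share identical RNAi and signalling blocks and differ in the
#' assembly rate constants and translation rates; all were calibrated so
#' that the fraction of connector bound to actin is about 0.3 and the
#' focal-adhesion maturation timescale is tens of minutes.
#'
#' @param label one of "PS1", "PS2", "PS3".
#' @return \code{fa_parameter_set}.
#' @examples
#' ps <- fa_params("PS1")
#' ps$kinetic$alpha_A   # 10000
#' @export
fa_params <- function(label = c("PS1", "PS2", "PS3")) {
  label <- match.arg(label)
  .fa_builtin[[label]]
}

#' @export
print.fa_parameter_set <- function(x, ...) {
  cat("<fa_parameter_set>", x$label, "\n")
  cat("  kinetic:  ", paste0(names(x$kinetic), "=",
                             vapply(x$kinetic, format, ""), collapse = ", "), "\n")
  cat("  rnai:     ", paste0(names(x$rnai), "=",
                             vapply(x$rnai, format, ""), collapse = ", "), "\n")
  cat("  signaling:", paste0(names(x$signaling), "=",
                             vapply(x$signaling, format, ""), collapse = ", "), "\n")
  invisible(x)
}

#' Read a parameter set from a JSON or YAML file
#'
#' Files are flat-by-block documents with top-level keys \code{label},
#' \code{kinetic}, \code{rnai} and \code{signaling}; parameter names
#' follow the conventional symbols transliterated (alpha_A, delta_AC,
#' tau_ACI, epsilon, chi, sigma, rho_RHO, ...) so files can be audited
#' against the published table.  Labels "PS1", "PS2", "PS3" are also
#' accepted directly and resolve to the built-in sets.
#'
#' @param path file path, or one of the built-in labels.
#' @return \code{fa_parameter_set}.
#' @export
read_parameter_set <- function(path) {
  if (path %in% names(.fa_builtin)) return(.fa_builtin[[path]])
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML parameter files",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  for (blk in c("label", "kinetic", "rnai", "signaling"))
    if (is.null(raw[[blk]]))
      stop("parameter file is missing block '", blk, "'", call. = FALSE)
  check_fields <- function(block, fields, name) {
    missing <- setdiff(fields, names(block))
    extra <- setdiff(names(block), fields)
    if (length(missing))
      stop("missing ", name, " parameter(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (length(extra))
      stop("unknown ", name, " parameter(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    block[fields]
  }
  kin <- check_fields(raw$kinetic, .kinetic_fields, "kinetic")
  rna <- check_fields(raw$rnai, .rnai_fields, "RNAi")
  sig <- check_fields(raw$signaling, .signaling_fields, "signalling")
  fa_parameter_set(raw$label,
                   do.call(fa_kinetic_params, kin),
                   do.call(fa_rnai_params, rna),
                   do.call(fa_signaling_params, sig))
}

#' Write a parameter set to JSON
#'
#' Inverse of \code{\link{read_parameter_set}}; the round trip is exact
#' (numbers are written at full precision).
#'
#' @param ps \code{fa_parameter_set}.
#' @param path output path (".json").
#' @return \code{path}, invisibly.
#' @export
write_parameter_set <- function(ps, path) {
  stopifnot(inherits(ps, "fa_parameter_set"))
  doc <- list(label = ps$label,
              kinetic = unclass(ps$kinetic),
              rnai = unclass(ps$rnai),
              signaling = unclass(ps$signaling))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# flatten/rebuild helpers used by the geometric interpolation
.fa_flatten <- function(ps) {
  c(unlist(ps$kinetic), unlist(ps$rnai), unlist(ps$signaling))
}

.fa_rebuild <- function(values, label) {
  nk <- length(.kinetic_fields); nr <- length(.rnai_fields)
  kin <- as.list(values[seq_len(nk)])
  rna <- as.list(values[nk + seq_len(nr)])
  sig <- as.list(values[nk + nr + seq_along(.signaling_fields)])
  names(kin) <- .kinetic_fields; names(rna) <- .rnai_fields
  names(sig) <- .signaling_fields
  fa_parameter_set(label,
                   do.call(fa_kinetic_params, kin),
                   do.call(fa_rnai_params, rna),
                   do.call(fa_signaling_params, sig))
}
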