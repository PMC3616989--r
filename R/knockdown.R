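#' Run an RNAi knockdown scenario
#'
#' Implements the standard knockdown protocol: (1) equilibrate the
#' untreated full model from the chosen canonical initial condition,
#' (2) restart at t = 0 with the siRNA treatment switched on for the
#' configured target, (3) integrate through the multi-day knockdown
#' phase, and (4) compare pre- and post-knockdown steady states.
#'
#' Percent reductions are 100 (pre - post) / pre per species; negative
#' values denote increases (e.g. focal complexes under Rho knockdown).
#' Actin (MA) and integrin (MI) targets are supported but biologically
#' drastic (cells lacking integrin cannot adhere; actin loss is lethal),
#' so they trigger a warning.
#'
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config} with \code{knockdown_target} set; for
#'   mRNA and Z targets \code{include_rna} must be TRUE.
#' @param ic_kind "rac" or "rho".
#' @param t_kd horizon of the recorded knockdown trajectory (default
#'   6000 time units, well past the circa two-day plateau).
#' @param n_eval output points of the knockdown trajectory.
#' @return object of class \code{fa_knockdown}: list with \code{pre}
#'   and \code{post} (\code{fa_steady_state}), \code{trajectory}
#'   (\code{fa_trajectory} of the knockdown phase), and
#'   \code{reductions} (named percent reductions; NA where the
#'   untreated level is numerically zero).
#' @export
run_knockdown <- function(ps, cfg, ic_kind = c("rac", "rho"),
                          t_kd = 6000, n_eval = 300) {
  ic_kind <- match.arg(ic_kind)
  if (cfg$knockdown_target == "none")
    stop("cfg$knockdown_target must name a target", call. = FALSE)
  if (!cfg$include_rna && cfg$knockdown_target != "RHO")
    stop("mRNA and Z knockdowns require include_rna = TRUE", call. = FALSE)
  if (cfg$knockdown_target %in% c("MA", "MI"))
    warning("knockdown of ", cfg$knockdown_target,
            " is biologically drastic (loss of actin/integrin function)",
            call. = FALSE)
  ic <- fa_initial_state(ic_kind, include_rna = cfg$include_rna,
                         with_z = !is.null(cfg$z_extension))
  pre <- fa_steady_state(ps, cfg, ic, sirna_active = FALSE)
  if (!pre$converged)
    stop("untreated equilibration did not converge (residual ",
         format(pre$verification_residual), ")", call. = FALSE)
  traj <- fa_integrate(pre$state, ps, cfg, t_end = t_kd, n_eval = n_eval,
                       sirna_active = TRUE)
  post <- fa_steady_state(ps, cfg, pre$state, sirna_active = TRUE)
  reductions <- ifelse(abs(pre$state) > 1e-12,
                       100 * (pre$state - post$state) / pre$state, NA_real_)
  names(reductions) <- names(pre$state)
  structure(list(pre = pre, post = post, trajectory = traj,
                 reductions = reductions, target = cfg$knockdown_target,
                 ic_kind = ic_kind, ps_label = ps$label,
                 slip_fraction = cfg$slip_fraction),
            class = "fa_knockdown")
}

#' @export
print.fa_knockdown <- function(x, ...) {
  cat("<fa_knockdown> target:", x$target, " ps:", x$ps_label,
      " ic:", x$ic_kind, " s:", x$slip_fraction, "\n")
  show <- intersect(c("MA", "MC", "MI", "C", "ACI", "ACIm", "Z"),
                    names(x$reductions))
  tab <- data.frame(pre = round(x$pre$state[show], 5),
                    post = round(x$post$state[show], 5),
                    reduction_pct = round(x$reductions[show], 2))
  print(tab)
  invisible(x)
}

#' Rho knockdown
#'
#' Depletes the total Rho pool in a time-dependent manner mirroring the
#' siRNA onset curve: rho_total(t) = rho_total (1 - (1 - f)(1 -
#' exp(-r_sirna t))) with residual fraction f (default 0.2, i.e. the
#' pool shrinks from 1 to 0.2).  The run starts from the pre-equilibrated
#' wild-type steady state of the chosen configuration.  The expected
#' signature is a loss of mature adhesions together with a gain of focal
#' complexes, because Rac is released from Rho inhibition.
#'
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}; its \code{knockdown_target} is forced to
#'   "RHO".  Works with or without the RNA part.
#' @param ic_kind "rac" or "rho" (default "rho": the depletion acts on
#'   the adhesion-dominated state).
#' @param t_kd,n_eval as in \code{\link{run_knockdown}}.
#' @return \code{fa_knockdown}.
#' @export
run_rho_knockdown <- function(ps, cfg = fa_config(), ic_kind = "rho",
                              t_kd = 6000, n_eval = 300) {
  cfg$knockdown_target <- "RHO"
  run_knockdown(ps, cfg, ic_kind, t_kd = t_kd, n_eval = n_eval)
}

#' Knockdown of the auxiliary degradation regulator Z
#'
#' Adds the 13th species Z that controls connector degradation
#' (effective rate d_C Z / Z_ss) and knocks Z down via the RNAi term.
#' Less Z means slower connector degradation, so C rises and with it
#' both focal complexes and mature adhesions: all three reductions are
#' negative.
#'
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}; a default Z extension is attached if
#'   none is present and the target is forced to "Z".
#' @param ic_kind "rac" or "rho".
#' @param t_kd,n_eval as in \code{\link{run_knockdown}}.
#' @return \code{fa_knockdown}.
#' @export
run_z_knockdown <- function(ps, cfg = fa_config(), ic_kind = "rho",
                            t_kd = 6000, n_eval = 300) {
  if (is.null(cfg$z_extension)) cfg$z_extension <- fa_z_params()
  cfg$knockdown_target <- "Z"
  run_knockdown(ps, cfg, ic_kind, t_kd = t_kd, n_eval = n_eval)
}

#' Steady states across a slip-fraction sweep
#'
#' Computes pre- and post-knockdown (connector mRNA) steady states of
#' the full model on a grid of slip fractions.  The mature-adhesion
#' level falls almost linearly as the bond mixture shifts from pure
#' catch (s = 0) to pure slip (s = 1).
#'
#' @param ps \code{fa_parameter_set}.
#' @param ic_kind "rac" or "rho".
#' @param s_grid slip fractions in [0, 1].
#' @param target knocked-down mRNA (default "MC").
#' @return data.frame with columns \code{s}, \code{ACI_pre},
#'   \code{ACIm_pre}, \code{ACI_post}, \code{ACIm_post}, \code{converged};
#'   failed grid points carry NA and do not abort the sweep.
#' @export
slip_fraction_sweep <- function(ps, ic_kind = c("rho", "rac"),
                                s_grid = seq(0, 1, length.out = 11),
                                target = "MC") {
  ic_kind <- match.arg(ic_kind)
  stopifnot(all(s_grid >= 0 & s_grid <= 1))
  rows <- lapply(s_grid, function(s) {
    cfg <- fa_config(include_rna = TRUE, slip_fraction = s,
                     knockdown_target = target)
    out <- tryCatch({
      kd <- run_knockdown(ps, cfg, ic_kind)
      data.frame(s = s,
                 ACI_pre = kd$pre$state[["ACI"]],
                 ACIm_pre = kd$pre$state[["ACIm"]],
                 ACI_post = kd$post$state[["ACI"]],
                 ACIm_post = kd$post$state[["ACIm"]],
                 converged = kd$pre$converged && kd$post$converged)
    }, error = function(e)
      data.frame(s = s, ACI_pre = NA_real_, ACIm_pre = NA_real_,
                 ACI_post = NA_real_, ACIm_post = NA_real_,
                 converged = FALSE))
    out
  })
  do.call(rbind, rows)
}

#' Closed-form mRNA knockdown plateau
#'
#' For a single targeted mRNA with production k, basal degradation d_M
#' and the saturating RNAi term, the treated steady state at plateau
#' siRNA is k / (d_M + d_max sirna^h / (gamma_half^h + sirna^h)).
#' Relative to the untreated steady state k / d_M this gives the
#' residual mRNA fraction, about 20 percent with the reference RNAi
#' parameters.
#'
#' @param rp \code{fa_rnai_params}.
#' @param species which mRNA ("MC", "MA" or "MI").
#' @return residual plateau level as a percentage of the untreated
#'   steady state.
#' @export
mrna_knockdown_plateau <- function(rp, species = "MC") {
  k <- rp[[paste0("k_", species)]]
  dm <- rp[[paste0("d_", species)]]
  del <- rp$d_max * rp$sirna_max^rp$h /
    (rp$gamma_half^rp$h + rp$sirna_max^rp$h)
  100 * (k / (dm + del)) / (k / dm)
}
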