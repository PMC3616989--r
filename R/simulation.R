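#' Canonical initial states
#'
#' The two canonical initial conditions select the two branches of the
#' bistable system: the Rac initial condition (\code{kind = "rac"})
#' starts with unit focal complexes and fully active Rac, the Rho
#' initial condition (\code{kind = "rho"}) with unit mature adhesions
#' and fully active Rho.  When the RNA part is included the three mRNAs
#' start at 0.5.  \code{kind = "custom"} starts from all zeros and
#' applies \code{overrides} (also applied, last, for the other kinds).
#'
#' @param kind one of "rac", "rho", "custom".
#' @param include_rna logical; set mRNAs to 0.5.
#' @param overrides named numeric vector or list of species values.
#' @param with_z logical; include the auxiliary species Z (initialised
#'   at its steady state 1 unless overridden).
#' @return named state vector in canonical order.
#' @examples
#' fa_initial_state("rac", include_rna = FALSE)
#' fa_initial_state("custom", overrides = c(ACI = 0.9, ACIm = 0.1, RAC = 1))
#' @export
fa_initial_state <- function(kind = c("rac", "rho", "custom"),
                             include_rna = TRUE, overrides = NULL,
                             with_z = FALSE) {
  kind <- match.arg(kind)
  sp <- fa_species(with_z)
  y <- stats::setNames(numeric(length(sp)), sp)
  if (kind == "rac") { y["ACI"] <- 1; y["RAC"] <- 1 }
  if (kind == "rho") { y["ACIm"] <- 1; y["RHO"] <- 1 }
  if (include_rna && kind != "custom") y[c("MA", "MC", "MI")] <- 0.5
  if (with_z) y["Z"] <- 1
  if (!is.null(overrides)) {
    overrides <- unlist(overrides)
    bad <- setdiff(names(overrides), sp)
    if (length(bad))
      stop("unknown species in overrides: ", paste(bad, collapse = ", "),
           call. = FALSE)
    y[names(overrides)] <- overrides
  }
  y
}

#' Integrate the model over time
#'
#' Solves the stiff ODE system with \code{deSolve::lsoda} (the rate
#' constants span more than five orders of magnitude, so a
#' stiffness-switching method is required).  Default tolerances resolve
#' species down to about 1e-3 reliably.
#'
#' @param state0 named initial state (see \code{\link{fa_initial_state}}).
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}.
#' @param t_end end time (> 0; \code{t_end = 0} returns the single-point
#'   trajectory at the initial state).
#' @param n_eval number of output points (log-spaced after the first
#'   decade boundary when \code{log_spacing}, otherwise linear).
#' @param log_spacing logical; use logarithmically spaced output times,
#'   which resolves the sub-minute, sub-hour and multi-day phases of the
#'   dynamics in one trajectory.
#' @param multipliers optional per-reaction scale factors.
#' @param sirna_active logical; enable the siRNA terms.
#' @param rtol,atol integrator tolerances.
#' @return object of class \code{fa_trajectory}: list with \code{times},
#'   a \code{states} matrix (rows = times, columns = species), and
#'   provenance (\code{ps_label}, \code{cfg}).
#' @export
fa_integrate <- function(state0, ps, cfg = fa_config(), t_end, n_eval = 200,
                         log_spacing = TRUE, multipliers = NULL,
                         sirna_active = TRUE, rtol = 1e-8, atol = 1e-10) {
  stopifnot(t_end >= 0)
  if (t_end == 0) {
    traj <- list(times = 0, states = matrix(state0, nrow = 1,
                                            dimnames = list(NULL, names(state0))),
                 ps_label = ps$label, cfg = cfg)
    class(traj) <- "fa_trajectory"
    return(traj)
  }
  times <- if (log_spacing && t_end > 1) {
    unique(c(0, 10^seq(log10(min(1e-3, t_end / 10)), log10(t_end),
                       length.out = n_eval - 1)))
  } else {
    seq(0, t_end, length.out = max(n_eval, 2))
  }
  deriv <- .fa_make_deriv(ps, cfg, multipliers, sirna_active)
  out <- deSolve::lsoda(y = state0, times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  states <- out[, -1, drop = FALSE]
  colnames(states) <- names(state0)
  if (nrow(out) < length(times) || any(!is.finite(states))) {
    bad <- which(rowSums(!is.finite(states)) > 0)
    t_bad <- if (length(bad)) out[bad[1], 1] else max(out[, 1])
    stop("integration failed: non-finite state at t = ", t_bad, call. = FALSE)
  }
  if (min(states) < -1e-8)
    stop("integration failed: species below -1e-8 (min = ",
         format(min(states)), ")", call. = FALSE)
  traj <- list(times = out[, 1], states = states,
               ps_label = ps$label, cfg = cfg)
  class(traj) <- "fa_trajectory"
  traj
}

#' @export
print.fa_trajectory <- function(x, ...) {
  cat("<fa_trajectory> ", length(x$times), " points, t in [",
      min(x$times), ", ", max(x$times), "], species: ",
      paste(colnames(x$states), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Export a trajectory as a data frame / CSV
#'
#' @param x \code{fa_trajectory}.
#' @param ... unused.
#' @return data.frame with a \code{time} column and one column per
#'   species in canonical order.
#' @export
as.data.frame.fa_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Steady state with long-horizon verification
#'
#' Integrates to \code{t_final} (default 999999 time units) and verifies
#' convergence against the state at \code{t_check} (default 500000): the
#' residual is the maximum over species of |x(t_final) - x(t_check)|
#' relative to max(|x(t_final)|, 1e-3), so the criterion has an absolute
#' floor of 1e-9 for near-zero species at the default tolerance 1e-6.
#'
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}.
#' @param ic initial state vector, or a kind accepted by
#'   \code{\link{fa_initial_state}} ("rac"/"rho").
#' @param t_final,t_check integration horizon and checkpoint.
#' @param tol convergence tolerance on the residual.
#' @param multipliers optional per-reaction scale factors.
#' @param sirna_active logical; enable the siRNA terms.
#' @return object of class \code{fa_steady_state}: list with
#'   \code{state}, \code{t_final}, \code{verification_residual},
#'   \code{converged}.
#' @export
fa_steady_state <- function(ps, cfg = fa_config(), ic = "rho",
                            t_final = 999999, t_check = t_final * 0.5,
                            tol = 1e-6, multipliers = NULL,
                            sirna_active = TRUE) {
  if (is.character(ic))
    ic <- fa_initial_state(ic, include_rna = cfg$include_rna,
                           with_z = !is.null(cfg$z_extension))
  deriv <- .fa_make_deriv(ps, cfg, multipliers, sirna_active)
  out <- deSolve::lsoda(y = ic, times = c(0, t_check, t_final), func = deriv,
                        parms = NULL, rtol = 1e-8, atol = 1e-10,
                        maxsteps = 100000)
  if (nrow(out) < 3 || any(!is.finite(out)))
    stop("steady-state integration failed for ", ps$label, call. = FALSE)
  xf <- out[3, -1]; xc <- out[2, -1]
  residual <- max(abs(xf - xc) / pmax(abs(xf), 1e-3))
  res <- list(state = stats::setNames(as.numeric(xf), names(ic)),
              t_final = t_final,
              verification_residual = residual,
              converged = residual < tol)
  class(res) <- "fa_steady_state"
  res
}

#' @export
print.fa_steady_state <- function(x, ...) {
  cat("<fa_steady_state> converged:", x$converged,
      " residual:", format(x$verification_residual, digits = 3), "\n")
  print(round(x$state, 6))
  invisible(x)
}

#' Time to reach steady state
#'
#' Earliest time after which every species stays within \code{rel_tol}
#' (relative, with a small absolute floor) of its final value, for a
#' trajectory that has converged.  Used to quantify the sub-minute
#' focal-complex, sub-hour maturation and multi-day knockdown
#' timescales.
#'
#' @param traj \code{fa_trajectory}.
#' @param rel_tol relative tolerance (default 0.05).
#' @param abs_floor concentration resolution floor: species whose final
#'   value lies below it are measured on the floor scale rather than
#'   relatively, so biologically invisible trace species (e.g. active
#'   Rho of order 1e-4 in a Rac-dominated state) do not dominate the
#'   convergence time.
#' @return time (same units as the trajectory).
#' @export
time_to_steady <- function(traj, rel_tol = 0.05, abs_floor = 1e-2) {
  states <- traj$states
  final <- states[nrow(states), ]
  scale <- pmax(abs(final), abs_floor)
  dev <- sweep(abs(sweep(states, 2, final)), 2, scale, "/")
  maxdev <- apply(dev, 1, max)
  ok <- rev(cumprod(rev(maxdev <= rel_tol))) > 0  # TRUE from first index whose tail is all within tol
  if (!ok[length(ok)])
    stop("trajectory has not converged at its final point", call. = FALSE)
  traj$times[which(ok)[1]]
}
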