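#' Geometric interpolation between two parameter sets
#'
#' Every numeric parameter is interpolated with a power law,
#' g(q) = g1^(1-q) g2^q, the natural interpolation for rate constants
#' that span several orders of magnitude.  q = 0 returns the first set
#' exactly, q = 1 the second.
#'
#' @param psA,psB anchor \code{fa_parameter_set}s (all parameters must
#'   be strictly positive, which the constructors guarantee).
#' @param q interpolation coordinate in [0, 1].
#' @param label label of the interpolated set.
#' @return \code{fa_parameter_set}.
#' @export
interpolate_params <- function(psA, psB, q,
                               label = sprintf("%s:%s@%.4f", psA$label,
                                               psB$label, q)) {
  stopifnot(q >= 0, q <= 1)
  a <- .fa_flatten(psA); b <- .fa_flatten(psB)
  stopifnot(identical(names(a), names(b)))
  if (any(a <= 0) || any(b <= 0))
    stop("geometric interpolation requires strictly positive anchors",
         call. = FALSE)
  .fa_rebuild(a^(1 - q) * b^q, label)
}

#' Interpolated parameter path through the three reference sets
#'
#' Builds an ensemble of parameter sets along a closed path through
#' parameter space: the path coordinate p runs from 0 to 3 with the
#' reference sets at the integers (p = 0: PS1, p = 1: PS2, p = 2: PS3);
#' the final segment returns from PS3 towards PS1 so p = 3 closes the
#' loop.  Within each segment parameters follow the geometric
#' interpolation of \code{\link{interpolate_params}}, which produces the
#' characteristic kinks at integer p where the direction in parameter
#' space changes.
#'
#' @param n_sets number of sets, equally spaced in p (>= 4).
#' @return object of class \code{fa_parameter_path}: list with \code{p}
#'   (coordinates) and \code{sets} (list of \code{fa_parameter_set}).
#' @export
parameter_path <- function(n_sets = 300) {
  stopifnot(n_sets >= 4)
  anchors <- list(fa_params("PS1"), fa_params("PS2"),
                  fa_params("PS3"), fa_params("PS1"))
  p <- seq(0, 3, length.out = n_sets)
  sets <- lapply(p, function(pi) {
    seg <- min(floor(pi), 2)
    q <- pi - seg
    if (q == 0) {
      ps <- anchors[[seg + 1]]
      ps$label <- sprintf("p=%.4f (%s)", pi, ps$label)
      ps
    } else {
      interpolate_params(anchors[[seg + 1]], anchors[[seg + 2]], q,
                         label = sprintf("p=%.4f", pi))
    }
  })
  structure(list(p = p, sets = sets), class = "fa_parameter_path")
}

#' @export
print.fa_parameter_path <- function(x, ...) {
  cat("<fa_parameter_path>", length(x$sets),
      "sets, p in [0, 3] through PS1 -> PS2 -> PS3 -> PS1\n")
  invisible(x)
}

#' Concentration control coefficient
#'
#' Scaled sensitivity of a steady-state concentration to the rate of a
#' single reaction, C^i_k = (nu_k / S_i) dS_i / dnu_k.  Each reaction
#' carries a dedicated multiplier p_k (default 1) scaling its net rate
#' only, so C^i_k = d ln S_i / d ln p_k; this is required because several
#' rate constants enter more than one reaction (delta_A, for instance,
#' appears in both the complex disassembly and the derived
#' mature-adhesion disassembly rate).  The derivative is taken by
#' central finite differences at p_k (1 +/- step), re-solving the steady
#' state from the same initial condition.
#'
#' Computations where the perturbed steady states are inconsistent with
#' a smooth response (forward and backward one-sided differences
#' disagreeing by more than tenfold at a non-negligible separation,
#' the signature of a jump to the other bistable branch) return NA with
#' a warning, as do species whose steady-state value is below 1e-9.
#'
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}.
#' @param ic_kind "rac" or "rho".
#' @param species species name (e.g. "ACIm").
#' @param reaction reaction name from \code{\link{reaction_catalog}}.
#' @param step relative finite-difference step (default 1e-3).
#' @param base optional pre-computed unperturbed \code{fa_steady_state}
#'   (saves one solve when computing several coefficients).
#' @return list with \code{coefficient}, \code{species},
#'   \code{reaction}, \code{valid}, and the unperturbed steady state
#'   \code{base}.
#' @export
ccc <- function(ps, cfg = fa_config(), ic_kind = c("rho", "rac"),
                species = "ACIm", reaction = "deg_MC", step = 1e-3,
                base = NULL) {
  ic_kind <- match.arg(ic_kind)
  reaction <- match.arg(reaction, reaction_catalog(cfg))
  species <- match.arg(species, fa_species(!is.null(cfg$z_extension)))
  ic <- fa_initial_state(ic_kind, include_rna = cfg$include_rna,
                         with_z = !is.null(cfg$z_extension))
  if (is.null(base))
    base <- fa_steady_state(ps, cfg, ic, sirna_active = FALSE)
  if (!base$converged)
    stop("unperturbed steady state did not converge", call. = FALSE)
  v0 <- reaction_rates(t = base$t_final, base$state, ps, cfg,
                       sirna_active = FALSE)[[reaction]]
  if (abs(v0) < 1e-12)
    stop("reaction '", reaction, "' has zero net rate at this steady state",
         call. = FALSE)
  S0 <- base$state[[species]]
  if (abs(S0) < 1e-9) {
    warning("steady-state ", species, " below 1e-9; coefficient undefined")
    return(list(coefficient = NA_real_, species = species,
                reaction = reaction, valid = FALSE, base = base))
  }
  solve_at <- function(mult) {
    m <- stats::setNames(mult, reaction)
    fa_steady_state(ps, cfg, ic, multipliers = m,
                    sirna_active = FALSE)$state[[species]]
  }
  Sp <- solve_at(1 + step)
  Sm <- solve_at(1 - step)
  central <- (Sp - Sm) / (2 * step) / S0
  fwd <- (Sp - S0) / step / S0
  bwd <- (S0 - Sm) / step / S0
  # branch-jump guard: one-sided estimates must agree with each other
  valid <- TRUE
  spread <- abs(fwd - bwd)
  if (spread > 10 * max(abs(central), 1e-6) && abs(Sp - Sm) > 1e-4 * abs(S0)) {
    warning("inconsistent one-sided differences for reaction '", reaction,
            "'; possible branch jump")
    valid <- FALSE
  }
  list(coefficient = if (valid) central else NA_real_,
       species = species, reaction = reaction, valid = valid, base = base)
}

#' All concentration control coefficients of one species
#'
#' Computes C^i_k for one species over every reaction of the catalog and
#' the summation-theorem residual sum_k C^i_k, which vanishes for an
#' exact steady state (scaling all rates together only rescales time).
#' The residual is the standard internal consistency check on the
#' steady-state solution.
#'
#' @param ps,cfg,ic_kind,species,step as in \code{\link{ccc}}.
#' @return object of class \code{fa_ccc}: list with
#'   \code{coefficients} (named vector over reactions),
#'   \code{summation_residual}, \code{species}, \code{ps_label},
#'   \code{ic_kind}, \code{slip_fraction}.
#' @export
ccc_all <- function(ps, cfg = fa_config(), ic_kind = c("rho", "rac"),
                    species = "ACIm", step = 1e-3) {
  ic_kind <- match.arg(ic_kind)
  ic <- fa_initial_state(ic_kind, include_rna = cfg$include_rna,
                         with_z = !is.null(cfg$z_extension))
  base <- fa_steady_state(ps, cfg, ic, sirna_active = FALSE)
  rx <- reaction_catalog(cfg)
  if (!cfg$include_rna)
    rx <- setdiff(rx, c("prod_MA", "prod_MC", "prod_MI", "deg_MA", "deg_MC",
                        "deg_MI", "transl_A", "transl_C", "transl_I",
                        "deg_A", "deg_C", "deg_I"))
  co <- vapply(rx, function(r)
    ccc(ps, cfg, ic_kind, species, r, step, base = base)$coefficient,
    numeric(1))
  structure(list(coefficients = co,
                 summation_residual = sum(co),
                 species = species, ps_label = ps$label,
                 ic_kind = ic_kind, slip_fraction = cfg$slip_fraction),
            class = "fa_ccc")
}

#' @export
print.fa_ccc <- function(x, ...) {
  cat("<fa_ccc>", x$species, "|", x$ps_label, "| ic:", x$ic_kind,
      "| s:", x$slip_fraction, "\n")
  print(round(x$coefficients, 5))
  cat("summation residual:", format(x$summation_residual, digits = 3), "\n")
  invisible(x)
}

#' Control coefficients along a parameter path
#'
#' Reproduces the sensitivity-analysis ensemble: concentration control
#' coefficients of the mature-adhesion level with respect to the three
#' mRNA degradation reactions, for every parameter set along an
#' interpolated path, at the untreated steady state of the full model.
#'
#' @param path \code{fa_parameter_path} (or the output of
#'   \code{parameter_path(n)}).
#' @param cfg \code{fa_config} (full model; the mRNA degradation
#'   reactions do not exist without the RNA part).
#' @param ic_kind "rac" or "rho".
#' @param species target species (default "ACIm").
#' @param reactions reactions to perturb (default the three mRNA
#'   degradations).
#' @param step finite-difference step.
#' @return data.frame with columns \code{p}, \code{label},
#'   \code{ic_kind}, \code{slip_fraction}, \code{reaction},
#'   \code{coefficient}; per-set failures yield NA rows.
#' @export
ccc_over_path <- function(path, cfg = fa_config(), ic_kind = c("rho", "rac"),
                          species = "ACIm",
                          reactions = c("deg_MA", "deg_MC", "deg_MI"),
                          step = 1e-3) {
  ic_kind <- match.arg(ic_kind)
  if (!cfg$include_rna)
    stop("mRNA degradation reactions require the full model", call. = FALSE)
  rows <- mapply(function(pi, ps) {
    co <- tryCatch({
      ic <- fa_initial_state(ic_kind, include_rna = TRUE)
      base <- fa_steady_state(ps, cfg, ic, sirna_active = FALSE)
      vapply(reactions, function(r)
        ccc(ps, cfg, ic_kind, species, r, step, base = base)$coefficient,
        numeric(1))
    }, error = function(e) stats::setNames(rep(NA_real_, length(reactions)),
                                           reactions))
    data.frame(p = pi, label = ps$label, ic_kind = ic_kind,
               slip_fraction = cfg$slip_fraction,
               reaction = reactions, coefficient = unname(co))
  }, path$p, path$sets, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
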