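# resolve a parameter name to its block within a parameter set
.fa_find_param <- function(ps, name) {
  for (blk in c("kinetic", "rnai", "signaling"))
    if (name %in% names(ps[[blk]])) return(blk)
  stop("unknown parameter: ", name, call. = FALSE)
}

.fa_set_param <- function(ps, name, value) {
  blk <- .fa_find_param(ps, name)
  ps[[blk]][[name]] <- value
  ps
}

# steady-state ACIm from both canonical ICs at one parameter value;
# shortened horizon (1e5) — the no-flux model equilibrates within ~1e3
# units, verified against the full-length protocol on spot checks
.fa_branches <- function(ps, cfg, param_name, value, t_final = 1e5) {
  ps2 <- .fa_set_param(ps, param_name, value)
  get_one <- function(kind) {
    tryCatch(
      fa_steady_state(ps2, cfg, kind, t_final = t_final)$state[["ACIm"]],
      error = function(e) NA_real_)
  }
  c(rac = get_one("rac"), rho = get_one("rho"))
}

#' One-parameter bifurcation sweep
#'
#' Computes steady-state mature-adhesion levels (ACIm) from both
#' canonical initial conditions over a grid of values of a single
#' parameter.  Branches are classified by the selecting initial
#' condition (no continuation is used: both the sweep and the original
#' diagrams are generated by integrating from the two ICs).  Where the
#' two branches separate the system is bistable.
#'
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config} (typically the no-RNA assembly model).
#' @param param_name parameter to vary (e.g. "rho_RHO").
#' @param grid vector of parameter values.
#' @return object of class \code{fa_bifurcation}: list with
#'   \code{param_name}, \code{grid}, \code{branch_rac},
#'   \code{branch_rho}; failed grid points are NA and do not abort the
#'   sweep.
#' @export
bifurcation_sweep <- function(ps, cfg = fa_config(include_rna = FALSE),
                              param_name = "rho_RHO",
                              grid = 10^seq(-2, 1, length.out = 60)) {
  .fa_find_param(ps, param_name)
  br <- vapply(grid, function(v) .fa_branches(ps, cfg, param_name, v),
               numeric(2))
  structure(list(param_name = param_name, grid = grid,
                 branch_rac = br["rac", ], branch_rho = br["rho", ]),
            class = "fa_bifurcation")
}

#' @export
print.fa_bifurcation <- function(x, ...) {
  cat("<fa_bifurcation> parameter:", x$param_name, " over [",
      format(min(x$grid)), ",", format(max(x$grid)), "],",
      length(x$grid), "points\n")
  sep <- abs(x$branch_rho - x$branch_rac)
  cat("  max branch separation (ACIm):", format(max(sep, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @export
as.data.frame.fa_bifurcation <- function(x, ...) {
  data.frame(param = x$grid, ACIm_rac = x$branch_rac, ACIm_rho = x$branch_rho)
}

#' Bistable interval of a parameter
#'
#' Locates the interval of a parameter over which the two canonical
#' initial conditions settle on distinct mature-adhesion levels
#' (|ACIm(rho branch) - ACIm(rac branch)| > threshold).  A log-spaced
#' coarse sweep brackets the onset and offset; each edge is then refined
#' by bisection to a relative precision of 1e-2.
#'
#' @param ps \code{fa_parameter_set}.
#' @param cfg \code{fa_config}.
#' @param param_name parameter to vary.
#' @param lo,hi search range (lo < hi, positive for log spacing).
#' @param threshold absolute ACIm separation defining bistability
#'   (default 0.05).
#' @param n_grid coarse grid size (default 60).
#' @return list with \code{lower}, \code{upper} (NA if no bistability
#'   was found in range), \code{threshold}, and the coarse
#'   \code{sweep} (\code{fa_bifurcation}).
#' @export
bistable_interval <- function(ps, cfg = fa_config(include_rna = FALSE),
                              param_name = "rho_RHO", lo = 0.01, hi = 10,
                              threshold = 0.05, n_grid = 60) {
  stopifnot(lo < hi, lo > 0, threshold > 0)
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  sw <- bifurcation_sweep(ps, cfg, param_name, grid)
  sep <- abs(sw$branch_rho - sw$branch_rac)
  inside <- !is.na(sep) & sep > threshold
  if (!any(inside))
    return(list(lower = NA_real_, upper = NA_real_, threshold = threshold,
                sweep = sw))
  sep_at <- function(v) {
    b <- .fa_branches(ps, cfg, param_name, v)
    abs(b[["rho"]] - b[["rac"]])
  }
  bisect <- function(a, b, inside_at_b) {
    # invariant: separation crosses the threshold between a and b
    while ((b - a) / b > 1e-2) {
      mid <- sqrt(a * b)
      if ((sep_at(mid) > threshold) == inside_at_b) b <- mid else a <- mid
    }
    sqrt(a * b)
  }
  i_first <- which(inside)[1]
  i_last <- which(inside)[length(which(inside))]
  lower <- if (i_first == 1) grid[1] else
    bisect(grid[i_first - 1], grid[i_first], inside_at_b = TRUE)
  upper <- if (i_last == length(grid)) grid[length(grid)] else
    bisect(grid[i_last], grid[i_last + 1], inside_at_b = FALSE)
  list(lower = lower, upper = upper, threshold = threshold, sweep = sw)
}
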