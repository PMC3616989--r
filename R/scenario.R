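# parse a bond specification: "slip", "catch" or "mix:<s>"
.fa_parse_bond <- function(bond) {
  if (bond == "slip") return(1)
  if (bond == "catch") return(0)
  if (grepl("^mix:", bond)) {
    s <- suppressWarnings(as.numeric(sub("^mix:", "", bond)))
    if (is.na(s) || s < 0 || s > 1)
      stop("invalid bond spec '", bond, "': mixture fraction must be in [0, 1]",
           call. = FALSE)
    return(s)
  }
  stop("invalid bond spec '", bond, "' (use slip, catch or mix:<s>)",
       call. = FALSE)
}

#' Run a named analysis scenario
#'
#' Dispatches to the main analyses (time-course simulation, knockdown,
#' bifurcation sweep, metabolic control analysis) from a flat
#' configuration, writes CSV results and a JSON run manifest recording
#' parameters, configuration and convergence diagnostics.  This is the
#' programmatic backend of the command-line interface shipped in
#' \code{inst/cli/fadyn.R}.
#'
#' @param scenario one of "simulate", "knockdown", "bifurcate", "mca",
#'   "validate-params".
#' @param param_set parameter-set label ("PS1".."PS3") or file path.
#' @param bond "slip", "catch" or "mix:<s>".
#' @param ic "rac" or "rho".
#' @param out output CSV path (a matching "<out>.manifest.json" is
#'   written next to it); NULL suppresses writing.
#' @param include_rna logical; full model vs assembly-only model.
#' @param target knockdown target (knockdown scenario).
#' @param t_end simulation horizon (simulate scenario).
#' @param param,lo,hi,n_points bifurcation sweep controls.
#' @param n_sets ensemble size (mca scenario).
#' @return the scenario result object, invisibly; the CSV rendering is
#'   written to \code{out}.
#' @export
run_scenario <- function(scenario = c("simulate", "knockdown", "bifurcate",
                                      "mca", "validate-params"),
                         param_set = "PS1", bond = "slip", ic = "rho",
                         out = NULL, include_rna = TRUE, target = "MC",
                         t_end = 100, param = "rho_RHO", lo = 0.01, hi = 10,
                         n_points = 60, n_sets = 30) {
  scenario <- match.arg(scenario)
  ps <- read_parameter_set(param_set)
  s <- .fa_parse_bond(bond)
  result <- switch(scenario,
    "validate-params" = ps,
    "simulate" = {
      cfg <- fa_config(include_rna = include_rna, slip_fraction = s)
      ic0 <- fa_initial_state(ic, include_rna = include_rna)
      fa_integrate(ic0, ps, cfg, t_end = t_end)
    },
    "knockdown" = {
      if (target == "RHO") {
        run_rho_knockdown(ps, fa_config(include_rna = include_rna,
                                        slip_fraction = s), ic_kind = ic)
      } else if (target == "Z") {
        run_z_knockdown(ps, fa_config(include_rna = include_rna,
                                      slip_fraction = s,
                                      z_extension = fa_z_params()),
                        ic_kind = ic)
      } else {
        cfg <- fa_config(include_rna = include_rna, slip_fraction = s,
                         knockdown_target = target)
        run_knockdown(ps, cfg, ic_kind = ic)
      }
    },
    "bifurcate" = {
      cfg <- fa_config(include_rna = include_rna, slip_fraction = s)
      bistable_interval(ps, cfg, param, lo = lo, hi = hi,
                        n_grid = n_points)
    },
    "mca" = {
      cfg <- fa_config(include_rna = TRUE, slip_fraction = s)
      ccc_over_path(parameter_path(n_sets), cfg, ic_kind = ic)
    })
  if (!is.null(out)) {
    tab <- switch(scenario,
      "validate-params" = data.frame(parameter = names(.fa_flatten(ps)),
                                     value = unname(.fa_flatten(ps))),
      "simulate" = as.data.frame(result),
      "knockdown" = data.frame(species = names(result$pre$state),
                               pre = unname(result$pre$state),
                               post = unname(result$post$state),
                               reduction_pct = unname(result$reductions)),
      "bifurcate" = as.data.frame(result$sweep),
      "mca" = result)
    utils::write.csv(tab, out, row.names = FALSE)
    manifest <- list(
      scenario = scenario, param_set_label = ps$label,
      parameters = list(kinetic = unclass(ps$kinetic),
                        rnai = unclass(ps$rnai),
                        signaling = unclass(ps$signaling)),
      bond = bond, slip_fraction = s, ic = ic, include_rna = include_rna,
      target = target, t_end = t_end,
      bifurcation = if (scenario == "bifurcate")
        list(param = param, lo = lo, hi = hi, n_points = n_points,
             lower = result$lower, upper = result$upper,
             threshold = result$threshold),
      diagnostics = if (scenario == "knockdown")
        list(pre_residual = result$pre$verification_residual,
             post_residual = result$post$verification_residual),
      package_version = as.character(utils::packageVersion("fadyn")),
      r_version = R.version.string)
    jsonlite::write_json(manifest[!vapply(manifest, is.null, logical(1))],
                         paste0(out, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
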