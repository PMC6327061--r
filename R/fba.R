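#' Default numeric cutoffs of the costless-secretion pipeline
#'
#' \itemize{
#'   \item \code{secretion_cutoff}: 0.01 mmol/gDW/h; exchange fluxes at or
#'     above it count as secretion, at or below its negative as uptake.
#'     This guards against reporting numerically spurious secretions.
#'   \item \code{growth_threshold}: 1e-6 1/h; binary growth status.
#'   \item \code{growth_slack}: 1e-9 relative slack on the
#'     \code{v_g,s >= v_g,0} constraint, absorbing LP tolerance.
#' }
#' @return named list of cutoffs.
#' @export
fba_defaults <- function() {
  list(secretion_cutoff = 0.01,
       growth_threshold = 1e-6,
       growth_slack = 1e-9)
}

flux_solution <- function(status, growth_rate, fluxes) {
  structure(list(status = status,
                 growth_rate = growth_rate,
                 fluxes = fluxes,
                 total_abs_flux = if (is.null(fluxes)) NA_real_
                                  else sum(abs(fluxes))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s; growth %.6g /h; sum|v| %.6g\n",
              x$status, x$growth_rate, x$total_abs_flux))
  invisible(x)
}

#' Maximize growth on a medium (plain FBA)
#'
#' Applies the medium to the model's exchange bounds and maximizes biomass
#' flux subject to the steady-state constraint S v = 0 and flux bounds.
#' An infeasible program (e.g. an unsatisfiable maintenance flux) reports
#' growth 0 by contract.
#'
#' @param model harmonized \code{metabolic_model}.
#' @param medium a \code{medium}.
#' @param oxygen_override per-organism oxygen state, see
#'   \code{\link{apply_medium}}.
#' @param defaults cutoff list, see \code{\link{fba_defaults}}.
#' @return a \code{flux_solution}; \code{growth_rate} is \code{v_g,0}.
#' @export
#' @examples
#' ferm <- make_organism(toy_spec_ferm())$model
#' med <- build_medium(c("nh4_e", "co2_e"), "glc_e", oxygen = "absent")
#' solve_growth(ferm, med)$growth_rate # 5
solve_growth <- function(model, medium, oxygen_override = NULL,
                         defaults = fba_defaults()) {
  bounded <- apply_medium(model, medium, oxygen_override)
  obj <- as.numeric(reaction_ids(bounded) == bounded$biomass_id)
  res <- model_lp(bounded, obj, maximize = TRUE)
  if (res$status != "optimal")
    return(flux_solution(res$status, 0, NULL))
  flux_solution("optimal", res$objective, res$x)
}

extract_secretions <- function(fluxes, model, cutoff) {
  ex <- exchanges(model)
  f <- fluxes[ex$reaction_id]
  sec <- f[f >= cutoff]
  stats::setNames(as.numeric(sec),
                  ex$metabolite_id[match(names(sec), ex$reaction_id)])
}

extract_uptakes <- function(fluxes, model, cutoff) {
  ex <- exchanges(model)
  f <- fluxes[ex$reaction_id]
  up <- f[f <= -cutoff]
  stats::setNames(as.numeric(up),
                  ex$metabolite_id[match(names(up), ex$reaction_id)])
}

#' Costlessly secreted metabolites at optimal growth
#'
#' The two-stage computation at the core of the pipeline.  Stage 1
#' maximizes biomass flux, giving \code{v_g,0}.  Stage 2 minimizes the sum
#' of absolute fluxes (linearized by splitting every flux into
#' non-negative forward/backward parts) subject to steady state, bounds,
#' and \code{v_g,s >= v_g,0} (with a 1e-9 relative slack).  The secretion
#' profile is the set of exchange fluxes at or above the 0.01 mmol/gDW/h
#' cutoff in the stage-2 solution; by construction every reported
#' secretion is costless in the sense that forcing it at the reported rate
#' cannot reduce the optimal growth rate.
#'
#' @inheritParams solve_growth
#' @return list with \code{solution} (stage-2 \code{flux_solution}, growth
#'   = \code{v_g,s}), \code{secretions} (metabolite id -> flux),
#'   \code{uptakes} (metabolite id -> flux, negative), and \code{grew}
#'   (logical, \code{v_g,0 >=} growth threshold).  When the organism does
#'   not grow the secretion set is empty by contract.
#' @export
costless_secretions <- function(model, medium, oxygen_override = NULL,
                                defaults = fba_defaults()) {
  stage1 <- solve_growth(model, medium, oxygen_override, defaults)
  if (stage1$status != "optimal" ||
      stage1$growth_rate < defaults$growth_threshold)
    return(list(solution = stage1, secretions = numeric(0),
                uptakes = numeric(0), grew = FALSE))
  bounded <- apply_medium(model, medium, oxygen_override)
  vg0 <- stage1$growth_rate
  res <- model_min_total_flux(bounded, bounded$biomass_id, vg0)
  if (res$status != "optimal") {
    # numerically impossible given stage 1 succeeded; retry with slack
    for (slack in c(defaults$growth_slack, 1e-6)) {
      res <- model_min_total_flux(bounded, bounded$biomass_id,
                                  vg0 * (1 - slack))
      if (res$status == "optimal") break
    }
  }
  if (res$status != "optimal")
    stop("flux minimization failed with status ", res$status)
  sol <- flux_solution("optimal", res$x[[bounded$biomass_id]], res$x)
  list(solution = sol,
       secretions = extract_secretions(res$x, bounded,
                                       defaults$secretion_cutoff),
       uptakes = extract_uptakes(res$x, bounded,
                                 defaults$secretion_cutoff),
       grew = TRUE)
}

#' Growth cost of a forced secretion
#'
#' Fixes the exchange flux of one metabolite at \code{v_s} (secretion
#' positive), re-maximizes growth and compares the constrained optimum
#' \code{v_g,s} with the unconstrained \code{v_g,0}: \code{costless} iff
#' \code{v_g,s >= v_g,0} within 1e-9 relative tolerance, \code{beneficial}
#' iff strictly greater, \code{costly} otherwise, or \code{infeasible} if
#' the forced secretion admits no flux state at all.
#'
#' @inheritParams solve_growth
#' @param metabolite canonical external metabolite id with an exchange
#'   reaction in the model.
#' @param v_s forced secretion flux (mmol/gDW/h).
#' @return list with \code{category}, \code{delta_growth}
#'   (\code{v_g,s - v_g,0}), \code{v_g0}, \code{v_gs}.
#' @export
secretion_cost <- function(model, medium, metabolite, v_s,
                           oxygen_override = NULL,
                           defaults = fba_defaults()) {
  bounded <- apply_medium(model, medium, oxygen_override)
  ex <- exchanges(bounded)
  hit <- ex$reaction_id[ex$metabolite_id == metabolite]
  if (length(hit) != 1L)
    stop("no exchange reaction for metabolite ", metabolite)
  base <- solve_growth(model, medium, oxygen_override, defaults)
  if (base$status != "optimal")
    return(list(category = "infeasible", delta_growth = NA_real_,
                v_g0 = 0, v_gs = NA_real_))
  vg0 <- base$growth_rate
  obj <- as.numeric(reaction_ids(bounded) == bounded$biomass_id)
  forced <- model_lp(bounded, obj, maximize = TRUE,
                     extra_lb = stats::setNames(list(v_s), hit),
                     extra_ub = stats::setNames(list(v_s), hit))
  if (forced$status != "optimal")
    return(list(category = "infeasible", delta_growth = NA_real_,
                v_g0 = vg0, v_gs = NA_real_))
  vgs <- forced$objective
  tol <- defaults$growth_slack
  category <- if (vgs > vg0 * (1 + tol) + tol) "beneficial"
              else if (vgs >= vg0 * (1 - tol) - tol) "costless"
              else "costly"
  list(category = category, delta_growth = vgs - vg0,
       v_g0 = vg0, v_gs = vgs)
}

#' Secretions under alternative objective functions
#'
#' Besides growth maximization, supports minimization of biomass
#' production and maximization/minimization of flux through the ATP
#' maintenance reaction, each with biomass flux bounded below at
#' 0.01 1/h.  The same stage-2 total-flux minimization and secretion
#' extraction are applied with the objective flux pinned at its optimum.
#'
#' @inheritParams solve_growth
#' @param objective one of \code{"max_growth"}, \code{"min_biomass"},
#'   \code{"max_atp"}, \code{"min_atp"}.
#' @param biomass_floor lower bound on biomass flux for the non-growth
#'   objectives (1/h).
#' @return same shape as \code{\link{costless_secretions}}.
#' @export
solve_alternative_objective <- function(model, medium,
                                        objective = c("max_growth",
                                                      "min_biomass",
                                                      "max_atp", "min_atp"),
                                        oxygen_override = NULL,
                                        biomass_floor = 0.01,
                                        defaults = fba_defaults()) {
  objective <- match.arg(objective)
  if (objective == "max_growth")
    return(costless_secretions(model, medium, oxygen_override, defaults))
  if (objective %in% c("max_atp", "min_atp") && is.na(model$atpm_id))
    stop("model has no ATP maintenance reaction")
  bounded <- apply_medium(model, medium, oxygen_override)
  target <- if (objective == "min_biomass") bounded$biomass_id
            else bounded$atpm_id
  maximize <- objective == "max_atp"
  obj <- as.numeric(reaction_ids(bounded) == target)
  floor_lb <- stats::setNames(list(biomass_floor), bounded$biomass_id)
  stage1 <- model_lp(bounded, obj, maximize = maximize,
                     extra_lb = floor_lb)
  if (stage1$status != "optimal")
    return(list(solution = flux_solution(stage1$status, 0, NULL),
                secretions = numeric(0), uptakes = numeric(0),
                grew = FALSE))
  opt <- stage1$objective
  slack <- defaults$growth_slack
  eps <- abs(opt) * slack + slack
  res <- model_min_total_flux(
    bounded, target,
    pinned_lb = if (maximize) opt - eps else -Inf,
    pinned_ub = if (maximize) NULL else opt + eps,
    extra_lb = floor_lb)
  if (res$status != "optimal")
    stop("flux minimization failed with status ", res$status)
  sol <- flux_solution("optimal", res$x[[bounded$biomass_id]], res$x)
  list(solution = sol,
       secretions = extract_secretions(res$x, bounded,
                                       defaults$secretion_cutoff),
       uptakes = extract_uptakes(res$x, bounded,
                                 defaults$secretion_cutoff),
       grew = sol$growth_rate >= defaults$growth_threshold)
}

#' Export a flux solution as TSV
#' @param solution a \code{flux_solution}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fluxes_tsv <- function(solution, path) {
  utils::write.table(
    data.frame(reaction_id = names(solution$fluxes),
               flux = as.numeric(solution$fluxes)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
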