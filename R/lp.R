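#' @useDynLib crossfeedr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Solve a bounded linear program
#'
#' Thin deterministic interface over the package's dense two-phase simplex:
#' optimize \code{obj'v} subject to \code{A v = rhs} and
#' \code{lb <= v <= ub}.  All bounds must be finite (stoichiometric models
#' conventionally cap fluxes at +/-1000 mmol/gDW/h).
#'
#' @param obj numeric objective coefficients, length \code{ncol(A)}.
#' @param A dense constraint matrix (equalities).
#' @param rhs right-hand side vector.
#' @param lb,ub finite lower/upper variable bounds.
#' @param maximize maximize instead of minimize?
#' @return list with \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"iterlimit"}),
#'   \code{x} (solution in the original variable space) and
#'   \code{objective}.
#' @keywords internal
lp_solve <- function(obj, A, rhs, lb, ub, maximize = FALSE) {
  A <- as.matrix(A)
  n <- ncol(A)
  m <- nrow(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(rhs) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("lp_solve requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    stop("lower bound exceeds upper bound")
  # Shift to x = v - lb >= 0; upper bounds become explicit slack rows.
  width <- ub - lb
  b1 <- rhs - A %*% lb
  Afull <- rbind(cbind(A, matrix(0, m, n)),
                 cbind(diag(n), diag(n)))
  bfull <- c(as.numeric(b1), width)
  cfull <- c(if (maximize) -obj else obj, rep(0, n))
  res <- .simplex_core(Afull, bfull, cfull)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "infeasible",
                   "2" = "unbounded", "3" = "iterlimit")
  if (status != "optimal")
    return(list(status = status, x = NULL, objective = NA_real_))
  v <- res$x[seq_len(n)] + lb
  list(status = "optimal", x = as.numeric(v),
       objective = sum(obj * v))
}

# Solve max/min of a single reaction flux (or arbitrary linear objective)
# over a metabolic model's flux cone.  Returns fluxes named by reaction id.
model_lp <- function(model, objective_coefs, maximize = TRUE,
                     extra_lb = NULL, extra_ub = NULL) {
  S <- model_stoichiometry(model)
  lb <- vapply(model$reactions, function(r) r$lb, numeric(1))
  ub <- vapply(model$reactions, function(r) r$ub, numeric(1))
  names(lb) <- names(ub) <- reaction_ids(model)
  if (!is.null(extra_lb)) lb[names(extra_lb)] <- pmax(lb[names(extra_lb)],
                                                      unlist(extra_lb))
  if (!is.null(extra_ub)) ub[names(extra_ub)] <- pmin(ub[names(extra_ub)],
                                                      unlist(extra_ub))
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  res <- lp_solve(objective_coefs, S, rep(0, nrow(S)), lb, ub,
                  maximize = maximize)
  if (res$status == "optimal") names(res$x) <- reaction_ids(model)
  res
}

# Minimize sum(|v|) subject to S v = 0, bounds, and a floor on one flux
# (the biomass or alternative-objective reaction).  Fluxes are split into
# non-negative forward/backward parts so the L1 objective is linear.
model_min_total_flux <- function(model, pinned_id, pinned_lb,
                                 pinned_ub = NULL,
                                 extra_lb = NULL, extra_ub = NULL) {
  S <- model_stoichiometry(model)
  rids <- reaction_ids(model)
  n <- length(rids)
  lb <- vapply(model$reactions, function(r) r$lb, numeric(1))
  ub <- vapply(model$reactions, function(r) r$ub, numeric(1))
  names(lb) <- names(ub) <- rids
  if (!is.null(extra_lb)) lb[names(extra_lb)] <- pmax(lb[names(extra_lb)],
                                                      unlist(extra_lb))
  if (!is.null(extra_ub)) ub[names(extra_ub)] <- pmin(ub[names(extra_ub)],
                                                      unlist(extra_ub))
  lb[pinned_id] <- max(lb[pinned_id], pinned_lb)
  if (!is.null(pinned_ub)) ub[pinned_id] <- min(ub[pinned_id], pinned_ub)
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  # v = p - q with p, q >= 0.
  p_ub <- pmax(ub, 0)
  q_ub <- pmax(-lb, 0)
  p_lb <- pmax(lb, 0)
  q_lb <- pmax(-ub, 0)
  A <- cbind(S, -S)
  res <- lp_solve(rep(1, 2 * n), A, rep(0, nrow(S)),
                  c(p_lb, q_lb), c(p_ub, q_ub), maximize = FALSE)
  if (res$status != "optimal")
    return(list(status = res$status, x = NULL, objective = NA_real_))
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  names(v) <- rids
  list(status = "optimal", x = v, objective = res$objective)
}
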