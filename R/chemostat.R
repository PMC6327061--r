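#' Chemostat model parameters
#'
#' Parameters of the two-species Monod chemostat used to probe motif
#' stability.  Defaults (all overridable) are order-of-magnitude choices
#' from the chemostat literature; the nutrient inflow term I is an
#' additive constant (g/L/h as implemented) applied to every primary
#' resource in the motif topology.
#'
#' @param mu_max length-2 maximum specific growth rates (1/h).
#' @param D dilution rate (1/h).
#' @param I nutrient inflow constant per primary resource (g/L/h).
#' @param k half-saturation constant for primary resources (g/L).
#' @param k_mt half-saturation constant for cross-fed metabolites (g/L).
#' @param K yield ratio for primary resources (g nutrient / g cells).
#' @param K_mt yield ratio for cross-fed metabolites.
#' @param k_sec cross-fed metabolite secretion rate constant (1/h).
#' @param s0 initial organism abundances (g/L); resources start at 0.
#' @param t_end simulation horizon (h).
#' @param threshold abundance above which an organism counts as
#'   surviving at \code{t_end} (g/L).
#' @return object of class \code{chemostat_params}.
#' @export
chemostat_params <- function(mu_max = c(0.5, 0.5), D = 0.1, I = 0.1,
                             k = 0.05, k_mt = 0.05, K = 0.5, K_mt = 0.5,
                             k_sec = 0.1, s0 = c(0.1, 0.1),
                             t_end = 500, threshold = 0.05) {
  stopifnot(length(mu_max) == 2, all(mu_max >= 0), D > 0, I >= 0,
            k > 0, k_mt > 0, K > 0, K_mt > 0, k_sec >= 0,
            length(s0) == 2, all(s0 >= 0), t_end > 0, threshold >= 0)
  structure(list(mu_max = mu_max, D = D, I = I, k = k, k_mt = k_mt,
                 K = K, K_mt = K_mt, k_sec = k_sec, s0 = s0,
                 t_end = t_end, threshold = threshold),
            class = "chemostat_params")
}

# Representative topology per motif code.  P: bitmask of primary
# resources consumed (1 = alpha, 2 = beta); X: organism consumes the
# partner's cross-fed metabolite.  Where a two-resource motif admits
# several topologies one representative is fixed: the second organism is
# the generalist consuming both carbon sources (as a product of Monod
# terms), and cross-feeding always flows from organism 1 (plus the
# reverse edge for mutualism).
motif_topologies <- list(
  N1a = list(P1 = 1L, P2 = 0L, X1 = FALSE, X2 = FALSE),
  N1b = list(P1 = 1L, P2 = 1L, X1 = FALSE, X2 = FALSE),
  N2a = list(P1 = 1L, P2 = 2L, X1 = FALSE, X2 = FALSE),
  N2b = list(P1 = 1L, P2 = 3L, X1 = FALSE, X2 = FALSE),
  C1a = list(P1 = 1L, P2 = 0L, X1 = FALSE, X2 = TRUE),
  C1b = list(P1 = 1L, P2 = 1L, X1 = FALSE, X2 = TRUE),
  C2a = list(P1 = 1L, P2 = 2L, X1 = FALSE, X2 = TRUE),
  C2b = list(P1 = 1L, P2 = 3L, X1 = FALSE, X2 = TRUE),
  M1a = list(P1 = 1L, P2 = 0L, X1 = TRUE, X2 = TRUE),
  M1b = list(P1 = 1L, P2 = 1L, X1 = TRUE, X2 = TRUE),
  M2a = list(P1 = 1L, P2 = 2L, X1 = TRUE, X2 = TRUE),
  M2b = list(P1 = 1L, P2 = 3L, X1 = TRUE, X2 = TRUE))

#' Build the chemostat ODE system for an interaction motif
#'
#' Wires the two-organism Monod chemostat according to the motif's
#' representative topology: "b" codes share carbon source alpha, "2"
#' codes add a second carbon source beta (entering the generalist's
#' growth as a product of Monod terms), C codes add one cross-feeding
#' edge (organism 1 feeds organism 2), M codes add both edges.  An
#' organism whose only resource is a cross-fed metabolite grows on its
#' Monod term alone.
#'
#' @param motif_code one of the 12 codes \code{[NCM][12][ab]}.
#' @param params a \code{chemostat_params}.
#' @return object of class \code{chemostat_system} with the topology, a
#'   plain-R right-hand-side closure \code{rhs(t, y)} (reference
#'   implementation used for cross-checks), and the initial state.
#' @export
build_motif_system <- function(motif_code, params = chemostat_params()) {
  topo <- motif_topologies[[motif_code]]
  if (is.null(topo)) stop("unknown motif code: ", motif_code)
  stopifnot(inherits(params, "chemostat_params"))
  p <- params
  monod <- function(m, k) if (m > 0) m / (k + m) else 0
  rhs <- function(t, y) {
    s1 <- y[1]; s2 <- y[2]; mA <- y[3]; mB <- y[4]
    t1 <- y[5]; t2 <- y[6]
    g1p <- if (topo$P1 > 0L)
      p$mu_max[1] *
        (if (bitwAnd(topo$P1, 1L)) monod(mA, p$k) else 1) *
        (if (bitwAnd(topo$P1, 2L)) monod(mB, p$k) else 1) else 0
    g2p <- if (topo$P2 > 0L)
      p$mu_max[2] *
        (if (bitwAnd(topo$P2, 1L)) monod(mA, p$k) else 1) *
        (if (bitwAnd(topo$P2, 2L)) monod(mB, p$k) else 1) else 0
    g1x <- if (topo$X1) p$mu_max[1] * monod(t2, p$k_mt) else 0
    g2x <- if (topo$X2) p$mu_max[2] * monod(t1, p$k_mt) else 0
    useA <- bitwAnd(topo$P1, 1L) || bitwAnd(topo$P2, 1L)
    useB <- bitwAnd(topo$P1, 2L) || bitwAnd(topo$P2, 2L)
    c(s1 * (g1p + g1x - p$D),
      s2 * (g2p + g2x - p$D),
      (if (useA) p$I else 0) - p$D * mA -
        (if (bitwAnd(topo$P1, 1L)) s1 / p$K * g1p else 0) -
        (if (bitwAnd(topo$P2, 1L)) s2 / p$K * g2p else 0),
      (if (useB) p$I else 0) - p$D * mB -
        (if (bitwAnd(topo$P1, 2L)) s1 / p$K * g1p else 0) -
        (if (bitwAnd(topo$P2, 2L)) s2 / p$K * g2p else 0),
      if (topo$X2) p$k_sec * s1 - s2 / p$K_mt * g2x - p$D * t1 else 0,
      if (topo$X1) p$k_sec * s2 - s1 / p$K_mt * g1x - p$D * t2 else 0)
  }
  structure(list(motif_code = motif_code, topology = topo,
                 params = params, rhs = rhs,
                 y0 = c(params$s0[1], params$s0[2], 0, 0, 0, 0)),
            class = "chemostat_system")
}

cpars <- function(system) {
  p <- system$params; topo <- system$topology
  list(mu1 = p$mu_max[1], mu2 = p$mu_max[2], D = p$D,
       I_A = p$I, I_B = p$I, k = p$k, k_mt = p$k_mt,
       K = p$K, K_mt = p$K_mt, k_sec = p$k_sec,
       P1 = topo$P1, P2 = topo$P2, X1 = topo$X1, X2 = topo$X2)
}

#' Integrate a chemostat system
#'
#' Adaptive embedded Runge-Kutta 4(5) integration (relative tolerance
#' 1e-6) with non-negativity enforced by clipping at zero; the number of
#' clip events is attached to the result.
#'
#' @param system a \code{chemostat_system}.
#' @param times output time points (h); defaults to 501 points spanning
#'   \code{[0, t_end]}.
#' @return data.frame with columns \code{time, s1, s2, mA, mB, mt1, mt2}
#'   and attribute \code{n_clipped}.
#' @export
simulate_chemostat <- function(system, times = NULL) {
  stopifnot(inherits(system, "chemostat_system"))
  if (is.null(times))
    times <- seq(0, system$params$t_end, length.out = 501)
  stopifnot(all(is.finite(system$y0)))
  res <- .chemostat_run(cpars(system), system$y0, times)
  out <- data.frame(time = times, res$states)
  attr(out, "n_clipped") <- res$n_clipped
  out
}

#' Stability map of a motif over a grid of maximum growth rates
#'
#' For each cell of a \code{grid_n} x \code{grid_n} grid over
#' \code{mu_max} in [0, 1] per organism, integrates the motif's chemostat
#' system to \code{t_end} and marks the cell stable when both organism
#' abundances finish at or above the survival threshold (0.05 g/L by
#' default).
#'
#' @param motif_code motif to map.
#' @param params a \code{chemostat_params}; \code{mu_max} is overridden
#'   by the grid.
#' @param grid_n grid resolution per axis (>= 2), default 51.
#' @param mu_range range of mu_max swept on both axes.
#' @return object of class \code{motif_stability_map} with the grid axes
#'   and the boolean \code{stable} matrix (rows: organism 1).
#' @export
stability_map <- function(motif_code, params = chemostat_params(),
                          grid_n = 51, mu_range = c(0, 1)) {
  stopifnot(grid_n >= 2)
  mu <- seq(mu_range[1], mu_range[2], length.out = grid_n)
  system <- build_motif_system(motif_code, params)
  stable <- .chemostat_grid(cpars(system), system$y0, mu, mu,
                            params$t_end, params$threshold)
  dimnames(stable) <- list(sprintf("%.4f", mu), sprintf("%.4f", mu))
  structure(list(motif_code = motif_code, mu = mu, stable = stable,
                 params = params),
            class = "motif_stability_map")
}

#' @export
print.motif_stability_map <- function(x, ...) {
  cat(sprintf("<motif_stability_map> %s: %d x %d grid, stable fraction %.3f\n",
              x$motif_code, length(x$mu), length(x$mu),
              mean(x$stable)))
  invisible(x)
}

#' Write a stability map as TSV plus JSON metadata
#' @param map a \code{motif_stability_map}.
#' @param path base path; writes \code{<path>.tsv} and
#'   \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
write_stability_map <- function(map, path) {
  utils::write.table(map$stable * 1L, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  jsonlite::write_json(
    list(motif = map$motif_code, mu = map$mu,
         params = unclass(map$params)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Single-species chemostat break-even growth rate
#'
#' A lone Monod consumer of one resource with inflow I and dilution D
#' washes out unless its growth at the consumer-free resource level
#' \code{m* = I/D} exceeds D; the break-even maximum growth rate is
#' \deqn{\mu^* = D\,(k + I/D)/(I/D).}
#'
#' @param params a \code{chemostat_params}.
#' @return the break-even mu_max (1/h).
#' @export
break_even_mu <- function(params = chemostat_params()) {
  mstar <- params$I / params$D
  params$D * (params$k + mstar) / mstar
}

#' Single-species persistence across a mu_max grid
#'
#' Runs the one-organism submodel (organism 2 absent) and reports which
#' grid values of mu_max leave the species above the survival threshold
#' at \code{t_end}.  Used to cross-check the closed-form washout
#' criterion of \code{\link{break_even_mu}}.
#'
#' @param params a \code{chemostat_params}.
#' @param grid_n grid resolution over \code{mu_range}.
#' @param mu_range swept range of mu_max.
#' @return data.frame with \code{mu} and logical \code{persists}.
#' @export
single_species_persistence <- function(params = chemostat_params(),
                                       grid_n = 51, mu_range = c(0, 1)) {
  mu <- seq(mu_range[1], mu_range[2], length.out = grid_n)
  persists <- vapply(mu, function(m) {
    p <- params
    p$mu_max <- c(m, 0)
    system <- build_motif_system("N1a", p)
    system$y0[2] <- 0 # no second organism
    res <- .chemostat_run(cpars(system), system$y0,
                          c(0, params$t_end))
    res$states[2, "s1"] >= params$threshold
  }, logical(1))
  data.frame(mu = mu, persists = persists)
}
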