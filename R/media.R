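#' Construct a growth medium
#'
#' A medium is the set of external metabolites available for uptake: a base
#' of non-limiting nutrients (N/S/P sources, ions, vitamins), one or more
#' growth-limiting carbon sources, an oxygen flag, and a (initially empty)
#' set of cross-fed metabolites added during medium expansion.  Oxygen is
#' recorded here but applied per organism at bound time, which lets one
#' co-simulation mix oxic and anoxic partners.
#'
#' @param base character vector of canonical base-metabolite ids (M_min).
#' @param carbon_sources character vector of carbon-source ids (alpha,
#'   beta, ...); must be disjoint from \code{base}.
#' @param oxygen \code{"present"} or \code{"absent"}.
#' @param oxygen_id canonical id of the oxygen exchange metabolite.
#' @param bound_policy list with uptake-bound magnitudes (mmol/gDW/h):
#'   \code{carbon_uptake_max} (default 10), \code{nonlimiting_uptake_max}
#'   (default 1000), \code{crossfed_uptake_max} (default 10).
#' @return object of class \code{medium}.
#' @export
#' @examples
#' build_medium(c("nh4_e", "co2_e"), "glc_e", oxygen = "absent")
build_medium <- function(base, carbon_sources,
                         oxygen = c("present", "absent"),
                         oxygen_id = "o2_e",
                         bound_policy = list()) {
  oxygen <- match.arg(oxygen)
  base <- unique(as.character(base))
  carbon_sources <- as.character(carbon_sources)
  if (length(carbon_sources) < 1L) stop("need at least one carbon source")
  if (anyDuplicated(carbon_sources))
    stop("duplicate carbon source: ",
         paste(unique(carbon_sources[duplicated(carbon_sources)]),
               collapse = ", "))
  overlap <- intersect(carbon_sources, base)
  if (length(overlap))
    stop("carbon source also listed in base medium: ",
         paste(overlap, collapse = ", "))
  policy <- utils::modifyList(
    list(carbon_uptake_max = 10,
         nonlimiting_uptake_max = 1000,
         crossfed_uptake_max = 10),
    bound_policy)
  structure(list(base = base,
                 carbon_sources = carbon_sources,
                 oxygen = oxygen,
                 oxygen_id = oxygen_id,
                 crossfed = character(0),
                 bound_policy = policy),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("<medium> %d base + carbons {%s} + %d crossfed; oxygen %s\n",
              length(x$base), paste(x$carbon_sources, collapse = ", "),
              length(x$crossfed), x$oxygen))
  invisible(x)
}

medium_metabolites <- function(medium)
  unique(c(medium$base, medium$carbon_sources, medium$crossfed))

#' Apply a medium to a model as exchange bounds
#'
#' Sets the uptake bound (magnitude of allowed negative exchange flux) of
#' every exchange reaction: non-limiting for base metabolites (and oxygen
#' when present), the carbon cap (default 10 mmol/gDW/h) for carbon
#' sources, the cross-fed cap for expansion metabolites, and zero for
#' everything else, blocking uptake of metabolites not in the medium.  The
#' secretion direction of every exchange is left open at the non-limiting
#' bound.
#'
#' @param model harmonized \code{metabolic_model}.
#' @param medium a \code{medium}.
#' @param oxygen_override per-organism oxygen state (\code{"present"} /
#'   \code{"absent"}) overriding \code{medium$oxygen}; \code{NULL} to use
#'   the medium's flag.
#' @param quiet suppress the warning listing medium metabolites for which
#'   the model has no exchange reaction (those are simply not taken up).
#' @return the bounded model.
#' @export
apply_medium <- function(model, medium, oxygen_override = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(medium, "medium"))
  oxy <- if (is.null(oxygen_override)) medium$oxygen else
    match.arg(oxygen_override, c("present", "absent"))
  pol <- medium$bound_policy
  uptake <- stats::setNames(
    rep(pol$nonlimiting_uptake_max, length(medium$base)), medium$base)
  uptake[medium$carbon_sources] <- pol$carbon_uptake_max
  uptake[setdiff(medium$crossfed, names(uptake))] <- pol$crossfed_uptake_max
  uptake[medium$oxygen_id] <-
    if (oxy == "present") pol$nonlimiting_uptake_max else 0
  seen <- character(0)
  model$reactions <- lapply(model$reactions, function(r) {
    if (!isTRUE(r$exchange)) return(r)
    met <- r$exchanged_metabolite
    cap <- if (met %in% names(uptake)) uptake[[met]] else 0
    r$lb <- -cap
    r$ub <- pol$nonlimiting_uptake_max
    seen <<- c(seen, met)
    r
  })
  missing <- setdiff(setdiff(names(uptake), medium$oxygen_id), seen)
  if (length(missing) && !quiet)
    warning("model ", model$model_id,
            " has no exchange for medium metabolites: ",
            paste(missing, collapse = ", "))
  model
}

#' Expand a medium with newly secreted metabolites
#'
#' Implements one medium-update step of the iterative co-culture
#' experiment: cross-fed metabolites accumulate monotonically, and the
#' returned \code{changed} flag distinguishes a growing medium from the
#' fixed point at which no new metabolites appear.
#'
#' @param medium a \code{medium}.
#' @param secreted_ids canonical ids secreted in the current iteration.
#' @return list with the updated \code{medium} and logical \code{changed}.
#' @export
expand_medium <- function(medium, secreted_ids) {
  stopifnot(inherits(medium, "medium"))
  new <- setdiff(unique(as.character(secreted_ids)),
                 medium_metabolites(medium))
  medium$crossfed <- c(medium$crossfed, new)
  list(medium = medium, changed = length(new) > 0L)
}

#' Read a medium from a TSV definition
#'
#' Columns: \code{metabolite_id}, \code{role} (\code{base} /
#' \code{carbon} / \code{crossfed}), \code{uptake_max} (optional override
#' of the role's policy bound, applied policy-wide per role).
#'
#' @param path TSV file.
#' @param oxygen,oxygen_id see \code{\link{build_medium}}.
#' @return a \code{medium}.
#' @export
read_medium_tsv <- function(path, oxygen = "present", oxygen_id = "o2_e") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("metabolite_id", "role") %in% names(tab)))
  med <- build_medium(tab$metabolite_id[tab$role == "base"],
                      tab$metabolite_id[tab$role == "carbon"],
                      oxygen = oxygen, oxygen_id = oxygen_id)
  med$crossfed <- setdiff(tab$metabolite_id[tab$role == "crossfed"],
                          medium_metabolites(med))
  med
}

#' Write a medium as TSV
#' @param medium a \code{medium}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_medium_tsv <- function(medium, path) {
  pol <- medium$bound_policy
  tab <- rbind(
    data.frame(metabolite_id = medium$base, role = "base",
               uptake_max = pol$nonlimiting_uptake_max),
    data.frame(metabolite_id = medium$carbon_sources, role = "carbon",
               uptake_max = pol$carbon_uptake_max),
    if (length(medium$crossfed))
      data.frame(metabolite_id = medium$crossfed, role = "crossfed",
                 uptake_max = pol$crossfed_uptake_max))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
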