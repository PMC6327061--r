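#' Construct a constraint-based metabolic model
#'
#' The central data structure of the package: an ordered metabolite list, an
#' ordered reaction list with flux bounds, one designated biomass reaction
#' and (optionally) an ATP maintenance reaction.  Compartments are reduced
#' to internal/external; an exchange reaction is a boundary reaction that
#' touches exactly one external metabolite with stoichiometric coefficient
#' -1, so that positive exchange flux means secretion and negative flux
#' means uptake.
#'
#' @param model_id short identifier.
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{external} (logical).
#' @param reactions list of reactions; each a list with \code{id},
#'   \code{stoich} (named numeric: metabolite id -> coefficient),
#'   \code{lb}, \code{ub} (mmol/gDW/h) and optionally \code{exchange}
#'   (logical; auto-detected when missing).
#' @param biomass_id id of the biomass reaction.
#' @param atpm_id id of the ATP maintenance (NGAM) reaction, or \code{NA}.
#' @return an object of class \code{metabolic_model}.
#' @export
#' @examples
#' m <- make_organism(toy_spec_ferm())$model
#' print(m)
metabolic_model <- function(model_id, metabolites, reactions, biomass_id,
                            atpm_id = NA_character_) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "external") %in% names(metabolites)))
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  reactions <- lapply(reactions, function(r) {
    r$stoich <- unlist(r$stoich)
    storage.mode(r$stoich) <- "double"
    r$lb <- as.numeric(r$lb)
    r$ub <- as.numeric(r$ub)
    r
  })
  m <- structure(list(model_id = model_id,
                      metabolites = metabolites,
                      reactions = reactions,
                      biomass_id = biomass_id,
                      atpm_id = atpm_id),
                 class = "metabolic_model")
  m <- detect_exchanges(m)
  validate_model(m)
  m
}

reaction_ids <- function(model)
  vapply(model$reactions, function(r) r$id, character(1))

metabolite_ids <- function(model) model$metabolites$id

#' External metabolite ids of a model
#' @param model a \code{metabolic_model}.
#' @return character vector of external metabolite ids.
#' @export
external_metabolites <- function(model)
  model$metabolites$id[model$metabolites$external]

# Fill in exchange flags/exchanged_metabolite by the single-external-
# metabolite rule; pre-set flags are kept but checked by validate_model().
detect_exchanges <- function(model) {
  ext <- external_metabolites(model)
  model$reactions <- lapply(model$reactions, function(r) {
    touched <- names(r$stoich)
    ext_touched <- intersect(touched, ext)
    auto <- length(touched) == length(ext_touched) &&
      length(ext_touched) == 1L &&
      isTRUE(all.equal(unname(r$stoich[ext_touched]), -1))
    if (is.null(r$exchange)) r$exchange <- auto
    r$exchanged_metabolite <-
      if (isTRUE(r$exchange)) ext_touched[1L] else NA_character_
    r
  })
  model
}

#' Validate a metabolic model's structural invariants
#'
#' Checks that stoichiometries reference declared metabolites, that
#' \code{lb <= ub} everywhere, that the biomass reaction exists, and that
#' every exchange reaction touches exactly one external metabolite with
#' coefficient -1.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly; errors on violation.
#' @export
validate_model <- function(model) {
  rids <- reaction_ids(model)
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  if (anyDuplicated(model$metabolites$id))
    stop("duplicate metabolite ids")
  mids <- metabolite_ids(model)
  for (r in model$reactions) {
    bad <- setdiff(names(r$stoich), mids)
    if (length(bad))
      stop("reaction ", r$id, " references undeclared metabolites: ",
           paste(bad, collapse = ", "))
    if (r$lb > r$ub)
      stop("reaction ", r$id, ": lower bound exceeds upper bound")
    if (isTRUE(r$exchange)) {
      ext <- intersect(names(r$stoich), external_metabolites(model))
      if (length(r$stoich) != 1L || length(ext) != 1L ||
          !isTRUE(all.equal(unname(r$stoich[ext]), -1)))
        stop("exchange reaction ", r$id,
             " must touch exactly one external metabolite with coefficient -1")
    }
  }
  if (is.na(model$biomass_id) || !(model$biomass_id %in% rids))
    stop("no biomass reaction")
  if (!is.na(model$atpm_id) && !(model$atpm_id %in% rids))
    stop("ATP maintenance reaction ", model$atpm_id, " not found")
  invisible(model)
}

#' Stoichiometric matrix of a model
#' @param model a \code{metabolic_model}.
#' @return dense numeric matrix (metabolites x reactions), dimnames set.
#' @export
model_stoichiometry <- function(model) {
  mids <- metabolite_ids(model)
  rids <- reaction_ids(model)
  S <- matrix(0, length(mids), length(rids),
              dimnames = list(mids, rids))
  for (k in seq_along(model$reactions)) {
    st <- model$reactions[[k]]$stoich
    S[names(st), k] <- st
  }
  S
}

#' Exchange reactions of a model
#' @param model a \code{metabolic_model}.
#' @return data.frame with columns \code{reaction_id},
#'   \code{metabolite_id}, \code{lb}, \code{ub}.
#' @export
exchanges <- function(model) {
  ex <- Filter(function(r) isTRUE(r$exchange), model$reactions)
  data.frame(reaction_id = vapply(ex, `[[`, character(1), "id"),
             metabolite_id = vapply(ex, `[[`, character(1),
                                    "exchanged_metabolite"),
             lb = vapply(ex, `[[`, numeric(1), "lb"),
             ub = vapply(ex, `[[`, numeric(1), "ub"),
             stringsAsFactors = FALSE)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d metabolites (%d external), %d reactions (%d exchanges)\n",
              x$model_id, nrow(x$metabolites),
              sum(x$metabolites$external), length(x$reactions),
              nrow(exchanges(x))))
  cat("  biomass:", x$biomass_id,
      if (!is.na(x$atpm_id)) paste0("  NGAM: ", x$atpm_id) else "", "\n")
  invisible(x)
}

#' Read a metabolic model from disk
#'
#' Two formats are supported: the package's plain-text \code{toy_json}
#' dialect (the reference format, see \code{\link{write_model}}) and SBML
#' Level 3 with flux bounds encoded as parameters referenced through
#' \code{fbc} reaction attributes.
#'
#' @param path file path.
#' @param format \code{"toy_json"} or \code{"sbml"}; \code{"auto"} picks by
#'   file extension.
#' @return a validated \code{metabolic_model}; exchange reactions are
#'   auto-detected by the single-external-metabolite rule when not
#'   annotated.
#' @export
read_model <- function(path, format = c("auto", "toy_json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "toy_json"
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         toy_json = read_model_toy_json(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#'
#' Round-trip contract: \code{read_model(write_model(m, p), fmt)}
#' reproduces stoichiometry, bounds, ids and flags exactly.
#'
#' @param model a validated \code{metabolic_model}.
#' @param path output file path.
#' @param format \code{"toy_json"} or \code{"sbml"}.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, format = c("toy_json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (length(model$reactions) == 0L) stop("model has no reactions")
  switch(format,
         toy_json = write_model_toy_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

# ---- toy_json (versioned plain-text dialect) -------------------------------

read_model_toy_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$id) || is.null(j$metabolites) || is.null(j$reactions))
    stop("not a toy_json model: ", path)
  mets <- data.frame(
    id = vapply(j$metabolites, function(m) m$id, character(1)),
    name = vapply(j$metabolites, function(m)
      if (is.null(m$name)) m$id else m$name, character(1)),
    external = vapply(j$metabolites, function(m)
      isTRUE(m$external), logical(1)),
    stringsAsFactors = FALSE)
  rxns <- lapply(j$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoich),
         lb = r$lb, ub = r$ub,
         exchange = if (is.null(r$exchange)) NULL else isTRUE(r$exchange))
  })
  if (is.null(j$biomass)) stop("no biomass reaction")
  atpm <- j$atpm
  if (!is.character(atpm) || length(atpm) != 1L) atpm <- NA_character_
  metabolic_model(j$id, mets, rxns, j$biomass, atpm_id = atpm)
}

write_model_toy_json <- function(model, path) {
  j <- list(
    format = "toy_json",
    version = 1L,
    id = model$model_id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           external = model$metabolites$external[i])),
    reactions = lapply(model$reactions, function(r)
      list(id = r$id, stoich = as.list(r$stoich),
           lb = r$lb, ub = r$ub, exchange = isTRUE(r$exchange))),
    biomass = model$biomass_id)
  if (!is.na(model$atpm_id)) j$atpm <- model$atpm_id
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

# ---- SBML Level 3 (flux bounds via parameters) -----------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<sbml xmlns=\"%s\" xmlns:fbc=\"%s\" level=\"3\" ",
                   "version=\"1\" fbc:required=\"false\">"),
            SBML_NS, FBC_NS),
    sprintf("  <model id=\"%s\" fbc:strict=\"true\">", esc(model$model_id)))
  if (!is.na(model$atpm_id))
    lines <- c(lines,
      "    <annotation>",
      sprintf("      <crossfeedr xmlns=\"https://crossfeedr.invalid/sbml\" atpMaintenance=\"%s\"/>",
              esc(model$atpm_id)),
      "    </annotation>")
  lines <- c(lines,
    "    <listOfCompartments>",
    "      <compartment id=\"internal\" constant=\"true\"/>",
    "      <compartment id=\"external\" constant=\"true\"/>",
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites)))
    lines <- c(lines, sprintf(
      paste0("      <species id=\"%s\" name=\"%s\" compartment=\"%s\" ",
             "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"false\" ",
             "constant=\"false\"/>"),
      esc(model$metabolites$id[i]), esc(model$metabolites$name[i]),
      if (model$metabolites$external[i]) "external" else "internal"))
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in model$reactions)
    lines <- c(lines,
      sprintf("      <parameter id=\"bnd_lb_%s\" value=\"%s\" constant=\"true\"/>",
              esc(r$id), num(r$lb)),
      sprintf("      <parameter id=\"bnd_ub_%s\" value=\"%s\" constant=\"true\"/>",
              esc(r$id), num(r$ub)))
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      paste0("      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\" ",
             "fbc:lowerFluxBound=\"bnd_lb_%s\" fbc:upperFluxBound=\"bnd_ub_%s\">"),
      esc(r$id), if (r$lb < 0) "true" else "false", esc(r$id), esc(r$id)))
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    if (length(reac)) {
      lines <- c(lines, "        <listOfReactants>")
      for (s in names(reac))
        lines <- c(lines, sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
          esc(s), num(-reac[[s]])))
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "        <listOfProducts>")
      for (s in names(prod))
        lines <- c(lines, sprintf(
          "          <speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
          esc(s), num(prod[[s]])))
      lines <- c(lines, "        </listOfProducts>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines,
    "    </listOfReactions>",
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    "      <fbc:objective fbc:id=\"obj\" fbc:type=\"maximize\">",
    "        <fbc:listOfFluxObjectives>",
    sprintf("          <fbc:fluxObjective fbc:reaction=\"%s\" fbc:coefficient=\"1\"/>",
            esc(model$biomass_id)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
  writeLines(lines, path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(model_node)) stop("not an SBML file: ", path)
  model_id <- xml2::xml_attr(model_node, "id")

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    external = xml2::xml_attr(species, "compartment") %in%
      c("external", "e"),
    stringsAsFactors = FALSE)

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                             xml2::xml_attr(pars, "id"))

  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rnodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val))
      par_val[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val))
      par_val[[ub_ref]] else 1000
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference"))
      st[xml2::xml_attr(sr, "species")] <-
        -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference"))
      st[xml2::xml_attr(sr, "species")] <-
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    list(id = id, stoich = st, lb = lb, ub = ub)
  })

  obj <- xml2::xml_find_first(doc,
                              ".//*[local-name()='fluxObjective']")
  if (is.na(obj)) stop("no biomass reaction")
  biomass_id <- xml2::xml_attr(obj, "reaction")
  ann <- xml2::xml_find_first(doc,
                              ".//annotation/*[local-name()='crossfeedr']")
  atpm <- if (!is.na(ann)) xml2::xml_attr(ann, "atpMaintenance")
          else NA_character_
  metabolic_model(model_id, mets, rxns, biomass_id, atpm_id = atpm)
}

# ---- namespace harmonization -----------------------------------------------

#' Harmonize external metabolite namespaces across models
#'
#' Applies a mapping from model-local external metabolite ids to canonical
#' ids shared across models, so that two models' exchange reactions for the
#' same compound report the same id and medium membership can be tested by
#' id equality.
#'
#' @param models list of \code{metabolic_model}s.
#' @param namespace_map named character vector: local id -> canonical id.
#' @param strict error on external metabolites missing from the map?  With
#'   \code{strict = FALSE} unmapped ids pass through with a warning.
#' @return list of models with renamed external metabolites.
#' @export
harmonize <- function(models, namespace_map = character(0), strict = TRUE) {
  stopifnot(is.character(namespace_map))
  if (anyDuplicated(names(namespace_map)))
    stop("namespace map is not a function: duplicate local ids")
  lapply(models, function(m) {
    ext <- external_metabolites(m)
    unmapped <- setdiff(ext, names(namespace_map))
    if (length(unmapped) && strict)
      stop("model ", m$model_id, ": unmapped external metabolites: ",
           paste(unmapped, collapse = ", "))
    if (length(unmapped) && !strict)
      warning("model ", m$model_id, ": passing through unmapped ids: ",
              paste(unmapped, collapse = ", "))
    trans <- stats::setNames(ext, ext)
    hit <- intersect(ext, names(namespace_map))
    trans[hit] <- namespace_map[hit]
    if (anyDuplicated(trans))
      stop("model ", m$model_id, ": duplicate canonical exchange ids: ",
           paste(unique(trans[duplicated(trans)]), collapse = ", "))
    # internal ids must not collide with new canonical ids
    clash <- intersect(trans, setdiff(metabolite_ids(m), ext))
    if (length(clash))
      stop("model ", m$model_id, ": canonical ids collide with internal ids: ",
           paste(clash, collapse = ", "))
    ren <- function(x) ifelse(x %in% names(trans), trans[x], x)
    m$metabolites$id <- unname(ren(m$metabolites$id))
    m$reactions <- lapply(m$reactions, function(r) {
      names(r$stoich) <- unname(ren(names(r$stoich)))
      if (!is.na(r$exchanged_metabolite))
        r$exchanged_metabolite <- unname(ren(r$exchanged_metabolite))
      r
    })
    validate_model(m)
    m
  })
}
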