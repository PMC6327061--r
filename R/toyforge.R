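#' Specification of a toy organism
#'
#' Describes a small, flux-consistent (not elementally balanced) metabolic
#' network emulating facultative-anaerobe behaviour: carbon substrates
#' enter through capped transporters, ATP is produced by a fermentation
#' branch (low yield, secretes acetate), a respiration branch (high yield,
#' requires oxygen, secretes CO2) and/or acetate oxidation, and biomass
#' consumes carbon skeleton, ATP and ammonium.  With these default yields
#' the optimal growth rates are hand-derivable: a pure fermenter on one
#' carbon source capped at 10 mmol/gDW/h grows at 5/h while secreting
#' 10 mmol/gDW/h acetate; a respirer grows at 25/3 per carbon source while
#' secreting 10 mmol/gDW/h CO2.
#'
#' @param id model id.
#' @param substrates external carbon metabolite ids (e.g. "glc_e").
#' @param fermentation,respiration,use_ac pathway flags (acetate
#'   fermentation; oxygen-requiring respiration; acetate oxidation).
#' @param ac_biomass build biomass from acetate instead of a substrate
#'   skeleton (acetate specialists).
#' @param acox_co2 does acetate oxidation release CO2?
#' @param n_source \code{"nh4"} (ammonium from the medium) or \code{"pep"}
#'   (a peptide that is deaminated into carbon skeleton plus excess
#'   ammonium, which is then secreted).
#' @param pep_cap transporter capacity for the peptide (mmol/gDW/h).
#' @param yields pathway stoichiometry overrides; see defaults in source.
#' @param biomass biomass recipe (carbon skeleton, ATP, ammonium
#'   coefficients).
#' @param ngam minimum flux through the ATP maintenance reaction.
#' @param inert_externals external metabolites given an exchange reaction
#'   but no synthesis or consumption path (useful to probe infeasible
#'   forced secretions).
#' @return object of class \code{toy_spec}.
#' @export
toy_spec <- function(id, substrates = character(0),
                     fermentation = FALSE, respiration = FALSE,
                     use_ac = FALSE, ac_biomass = FALSE,
                     acox_co2 = TRUE,
                     n_source = c("nh4", "pep"), pep_cap = 10,
                     yields = list(), biomass = list(),
                     ngam = 0, inert_externals = character(0)) {
  n_source <- match.arg(n_source)
  if (!fermentation && !respiration && !use_ac && !ac_biomass)
    stop("organism ", id, " has no ATP-generating route")
  if (ac_biomass && !use_ac)
    stop("ac_biomass requires use_ac (no acetate uptake route)")
  y <- utils::modifyList(
    list(ferm_atp = 2, ferm_ac = 2,
         resp_atp = 10, resp_o2 = 6, resp_co2 = 6,
         acox_atp = 1, acox_co2 = 1, deam_nh4 = 2),
    yields)
  bm <- utils::modifyList(list(c = 1, atp = 2, nh4 = 0.5), biomass)
  structure(list(id = id, substrates = substrates,
                 fermentation = fermentation, respiration = respiration,
                 use_ac = use_ac, ac_biomass = ac_biomass,
                 acox_co2 = acox_co2, n_source = n_source,
                 pep_cap = pep_cap, yields = y, biomass = bm,
                 ngam = ngam, inert_externals = inert_externals),
            class = "toy_spec")
}

#' Canonical fermenter spec (the worked example organism)
#'
#' A facultative anaerobe on glucose: fermentation (2 ATP + 2 acetate per
#' glucose), respiration (10 ATP + 6 CO2 per glucose, 6 O2), biomass
#' 1 glucose + 2 ATP + 0.5 ammonium.  Anoxic optimal growth on glucose
#' capped at 10 is exactly 5/h with 10 mmol/gDW/h acetate secreted; oxic
#' growth is 25/3 with 10 mmol/gDW/h CO2 and no acetate.
#' @param id model id.
#' @param n_source see \code{\link{toy_spec}}.
#' @return a \code{toy_spec}.
#' @export
toy_spec_ferm <- function(id = "FERM", n_source = "nh4")
  toy_spec(id, substrates = "glc_e", fermentation = TRUE,
           respiration = TRUE, n_source = n_source,
           inert_externals = "etoh_e")

#' Acetate-specialist spec
#'
#' Cannot import glucose; grows on acetate (1 ATP + 1 CO2 per acetate
#' oxidized, biomass built from acetate).  On acetate capped at 10 the
#' optimal growth rate is 10/3 with 20/3 CO2 secreted.
#' @param id model id.
#' @return a \code{toy_spec}.
#' @export
toy_spec_acsp <- function(id = "ACSP")
  toy_spec(id, substrates = character(0), use_ac = TRUE,
           ac_biomass = TRUE)

int_id <- function(ext) sub("_e$", "_c", ext)

#' Build a metabolic model from a toy spec
#'
#' Deterministic: the spec fully determines the model, so the seed only
#' participates in bookkeeping.  Errors when the assembled network exceeds
#' 15 reactions or the spec is inconsistent.
#'
#' @param spec a \code{toy_spec}.
#' @param seed unused entropy slot kept for interface symmetry.
#' @return list with \code{model} (a \code{metabolic_model}) and
#'   \code{ground_truth} (expected solo growth per oxygen state on the
#'   spec's own substrates, expected anoxic secretion set; derivations in
#'   comments).
#' @export
make_organism <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "toy_spec"))
  y <- spec$yields; bm <- spec$biomass
  subs <- spec$substrates
  has_ac <- spec$fermentation || spec$use_ac
  has_co2 <- spec$respiration ||
    (spec$use_ac && spec$acox_co2)
  has_pep <- spec$n_source == "pep"

  ext <- c(subs,
           if (has_ac) "ac_e",
           if (has_co2) "co2_e",
           if (spec$respiration) "o2_e",
           "nh4_e",
           if (has_pep) "pep_e",
           spec$inert_externals)
  ext <- unique(ext)
  ints <- c(vapply(subs, int_id, character(1)),
            if (has_ac || spec$ac_biomass) "ac_c",
            if (has_co2) "co2_c",
            if (spec$respiration) "o2_c",
            "nh4_c",
            if (has_pep) "pep_c",
            "atp")
  multi <- length(subs) > 1L
  if (multi) ints <- c(ints, "prec_c")
  # carbon skeleton consumed by catabolism and biomass
  skel <- if (spec$ac_biomass) "ac_c"
          else if (multi) "prec_c"
          else if (length(subs)) int_id(subs[1L])
          else if (has_pep) stop("peptide-only organisms need a substrate ",
                                 "to deaminate into")
          else "ac_c"
  ints <- unique(ints)

  rxn <- list()
  add <- function(id, stoich, lb = 0, ub = 1000)
    rxn[[length(rxn) + 1L]] <<- list(id = id, stoich = stoich,
                                     lb = lb, ub = ub)
  for (m in ext) add(paste0("EX_", m), stats::setNames(-1, m),
                     lb = -1000, ub = 1000)
  for (s in subs) add(paste0("T_", int_id(s)),
                      stats::setNames(c(-1, 1), c(s, int_id(s))))
  if (has_ac)
    add("T_ac", stats::setNames(c(-1, 1), c("ac_c", "ac_e")),
        lb = -1000, ub = 1000)
  if (has_co2)
    add("T_co2", stats::setNames(c(-1, 1), c("co2_c", "co2_e")),
        lb = -1000, ub = 1000)
  if (spec$respiration)
    add("T_o2", stats::setNames(c(-1, 1), c("o2_e", "o2_c")))
  add("T_nh4", stats::setNames(c(-1, 1), c("nh4_e", "nh4_c")),
      lb = if (has_pep) -1000 else 0, ub = 1000)
  if (has_pep) {
    add("T_pep", stats::setNames(c(-1, 1), c("pep_e", "pep_c")),
        ub = spec$pep_cap)
    deam_to <- if (spec$ac_biomass) "ac_c"
               else if (length(subs)) int_id(subs[1L]) else skel
    add("DEAM", stats::setNames(c(-1, 1, y$deam_nh4),
                                c("pep_c", deam_to, "nh4_c")))
  }
  if (multi)
    for (s in subs)
      add(paste0("PREC_", int_id(s)),
          stats::setNames(c(-1, 1), c(int_id(s), "prec_c")))
  if (spec$fermentation)
    add("FERM", stats::setNames(c(-1, y$ferm_ac, y$ferm_atp),
                                c(skel, "ac_c", "atp")))
  if (spec$respiration)
    add("RESP", stats::setNames(c(-1, -y$resp_o2, y$resp_co2, y$resp_atp),
                                c(skel, "o2_c", "co2_c", "atp")))
  if (spec$use_ac) {
    st <- c(-1, y$acox_atp)
    nm <- c("ac_c", "atp")
    if (spec$acox_co2) { st <- c(st, y$acox_co2); nm <- c(nm, "co2_c") }
    add("ACOX", stats::setNames(st, nm))
  }
  add("BIOMASS", stats::setNames(c(-bm$c, -bm$atp, -bm$nh4),
                                 c(skel, "atp", "nh4_c")))
  add("ATPM", stats::setNames(-1, "atp"), lb = spec$ngam)

  if (length(rxn) > 15L)
    stop("toy organism ", spec$id, " would need ", length(rxn),
         " reactions (> 15); simplify the spec")
  mets <- data.frame(id = c(ext, ints),
                     name = c(ext, ints),
                     external = c(rep(TRUE, length(ext)),
                                  rep(FALSE, length(ints))),
                     stringsAsFactors = FALSE)
  model <- metabolic_model(spec$id, mets, rxn, "BIOMASS", atpm_id = "ATPM")

  # Closed-form solo growth on the spec's substrates (each capped at 10)
  # plus deaminated peptide carbon; see derivations:
  #   fermenter:            v + f = U, 2f = 2v          -> v = U/2
  #   fermenter + acox:     v + f = U, 4f >= 2v         -> v = 2U/3
  #   respirer (oxic):      v(1 + 2/10) <= U            -> v = 5U/6
  #   acetate specialist:   v + x = U_ac, x = 2v        -> v = U_ac/3
  U <- 10 * length(subs) + if (has_pep) spec$pep_cap else 0
  solo <- function(oxic) {
    if (spec$ac_biomass) return(0) # no acetate in a fresh medium
    if (U == 0) return(0)
    cand <- c(
      if (spec$fermentation && !spec$use_ac) U / 2,
      if (spec$fermentation && spec$use_ac)
        U * (y$ferm_atp + y$ferm_ac * y$acox_atp) /
          (bm$atp + y$ferm_atp + y$ferm_ac * y$acox_atp),
      if (spec$respiration && oxic)
        U * y$resp_atp / (y$resp_atp + bm$atp))
    if (length(cand)) max(cand) else 0
  }
  gt <- list(
    solo_growth = c(oxic = solo(TRUE), anoxic = solo(FALSE)),
    anoxic_secretions =
      if (spec$fermentation && !spec$use_ac && U > 0) "ac_e"
      else character(0))
  list(model = model, ground_truth = gt)
}

# Media helpers shared by the motif-pair and suite generators.
toy_base_medium <- function(with_nh4 = TRUE, with_pep = FALSE)
  c(if (with_nh4) "nh4_e", if (with_pep) "pep_e", "co2_e", "h2o_e", "h_e")

#' Engineered organism pair realizing a target interaction motif
#'
#' Emits two toy models plus a starting medium whose full pipeline run
#' (iterative co-simulation, then interaction classification) recovers
#' exactly the requested motif code.  Eleven of the twelve grammar codes
#' are constructible; "N1a" (a single consumed carbon source, no
#' competition, no exchange) is not, because the partner organism would
#' have nothing to grow on.
#'
#' @param motif_code one of N1b, N2a, N2b, C1a, C1b, C2a, C2b, M1a, M1b,
#'   M2a, M2b.
#' @return list with \code{model_i}, \code{model_j}, \code{medium},
#'   \code{oxygen} (per organism) and \code{ground_truth} (motif code and
#'   per-organism obligate-syntrophy flags).
#' @export
make_motif_pair <- function(motif_code) {
  ferm <- function(id, subs = "glc_e", n = "nh4")
    toy_spec(id, substrates = subs, fermentation = TRUE, n_source = n)
  fermac <- function(id, subs, n = "nh4", co2 = TRUE)
    toy_spec(id, substrates = subs, fermentation = TRUE, use_ac = TRUE,
             acox_co2 = co2, n_source = n)
  resp <- function(id, subs = "glc_e")
    toy_spec(id, substrates = subs, respiration = TRUE)

  oxic <- c("present", "present"); anoxic <- c("absent", "absent")
  cfg <- switch(
    motif_code,
    "N1b" = list(resp("RSP1"), resp("RSP2"), carbons = "glc_e",
                 oxy = oxic, base = toy_base_medium(),
                 obligate = c(FALSE, FALSE)),
    "N2a" = list(resp("RSP1"), resp("RSP2", "fru_e"),
                 carbons = c("glc_e", "fru_e"), oxy = oxic,
                 base = toy_base_medium(), obligate = c(FALSE, FALSE)),
    "N2b" = list(resp("RSP1"), resp("RSP2", c("glc_e", "fru_e")),
                 carbons = c("glc_e", "fru_e"), oxy = oxic,
                 base = toy_base_medium(), obligate = c(FALSE, FALSE)),
    "C1a" = list(toy_spec_ferm("FERM"), toy_spec_acsp("ACSP"),
                 carbons = "glc_e", oxy = anoxic,
                 base = toy_base_medium(), obligate = c(FALSE, TRUE)),
    "C1b" = list(ferm("FRM1"), fermac("FAC2", "glc_e"),
                 carbons = "glc_e", oxy = anoxic,
                 base = toy_base_medium(), obligate = c(FALSE, FALSE)),
    "C2a" = list(ferm("FRM1"), fermac("FAC2", "fru_e"),
                 carbons = c("glc_e", "fru_e"), oxy = anoxic,
                 base = toy_base_medium(), obligate = c(FALSE, FALSE)),
    "C2b" = list(ferm("FRM1"), fermac("FAC2", c("glc_e", "fru_e"),
                                      co2 = FALSE),
                 carbons = c("glc_e", "fru_e"), oxy = anoxic,
                 base = toy_base_medium(), obligate = c(FALSE, FALSE)),
    "M1a" = list(ferm("FRM1"),
                 toy_spec("DAC2", use_ac = TRUE, ac_biomass = TRUE,
                          n_source = "pep"),
                 carbons = "glc_e", oxy = anoxic,
                 base = toy_base_medium(with_nh4 = FALSE,
                                        with_pep = TRUE),
                 obligate = c(TRUE, FALSE)),
    "M1b" = list(ferm("FRM1"), fermac("FAC2", "glc_e", n = "pep"),
                 carbons = "glc_e", oxy = anoxic,
                 base = toy_base_medium(with_nh4 = FALSE,
                                        with_pep = TRUE),
                 obligate = c(TRUE, FALSE)),
    "M2a" = list(ferm("FRM1"), fermac("FAC2", "fru_e", n = "pep"),
                 carbons = c("glc_e", "fru_e"), oxy = anoxic,
                 base = toy_base_medium(with_nh4 = FALSE,
                                        with_pep = TRUE),
                 obligate = c(TRUE, FALSE)),
    "M2b" = list(ferm("FRM1", c("glc_e", "fru_e")),
                 fermac("FAC2", "glc_e", n = "pep", co2 = FALSE),
                 carbons = c("glc_e", "fru_e"), oxy = anoxic,
                 base = toy_base_medium(with_nh4 = FALSE,
                                        with_pep = TRUE),
                 obligate = c(TRUE, FALSE)),
    "N1a" = stop("motif N1a is not constructible: with one consumed ",
                 "carbon source, no competition and no exchange the ",
                 "second organism cannot grow"),
    stop("unknown motif code: ", motif_code))
  medium <- build_medium(cfg$base, cfg$carbons, oxygen = cfg$oxy[1])
  list(model_i = make_organism(cfg[[1]])$model,
       model_j = make_organism(cfg[[2]])$model,
       medium = medium, oxygen = cfg$oxy,
       ground_truth = list(motif = motif_code,
                           obligate = cfg$obligate))
}

#' Randomized (seeded) toy community suite
#'
#' Generates \code{n_organisms} toy models over \code{n_carbons} generic
#' carbon sources, mixing fermentation/respiration/acetate-oxidation
#' flags, with every carbon source guaranteed at least one consumer.
#' Deterministic for a fixed seed.
#'
#' @param n_organisms number of organisms (>= 2).
#' @param n_carbons number of carbon sources (>= 2).
#' @param seed RNG seed.
#' @return list with \code{models}, \code{carbon_sources},
#'   \code{base_metabolites} and the organism \code{specs}.
#' @export
make_suite <- function(n_organisms, n_carbons, seed = 1L) {
  stopifnot(n_organisms >= 2L, n_carbons >= 2L)
  carbons <- sprintf("cs%02d_e", seq_len(n_carbons))
  specs <- withr_seed(seed, {
    lapply(seq_len(n_organisms), function(k) {
      subs <- sample(carbons, sample(1:2, 1))
      # guarantee every carbon has a consumer
      forced <- if (k <= n_carbons)
        carbons[seq(k, n_carbons, by = n_organisms)] else character(0)
      subs <- unique(c(forced, subs))
      if (length(subs) > 2L) subs <- subs[1:2]
      # keep the assembled network within the 15-reaction budget:
      # generalists (two substrates) get a single ATP pathway
      if (length(subs) > 1L) {
        fermentation <- runif(1) < 0.6
        respiration <- !fermentation
        use_ac <- fermentation && runif(1) < 0.5
        acox_co2 <- FALSE
      } else {
        fermentation <- runif(1) < 0.6
        respiration <- !fermentation || runif(1) < 0.5
        use_ac <- runif(1) < 0.5
        acox_co2 <- TRUE
      }
      toy_spec(sprintf("ORG%02d", k), substrates = subs,
               fermentation = fermentation, respiration = respiration,
               use_ac = use_ac, acox_co2 = acox_co2)
    })
  })
  # a consumer may have been truncated away; re-add coverage greedily
  covered <- unique(unlist(lapply(specs, `[[`, "substrates")))
  missing <- setdiff(carbons, covered)
  for (m in missing) {
    k <- which.min(vapply(specs, function(s) length(s$substrates),
                          integer(1)))
    s <- specs[[k]]
    specs[[k]] <- toy_spec(s$id,
                           substrates = unique(c(m, s$substrates))[1:2],
                           fermentation = TRUE, respiration = FALSE,
                           use_ac = s$use_ac, acox_co2 = s$acox_co2)
  }
  models <- lapply(specs, function(s) make_organism(s)$model)
  list(models = models, carbon_sources = carbons,
       base_metabolites = toy_base_medium(), specs = specs)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Write a toy suite to a directory
#'
#' Emits toy_json models, a media TSV, a carbon-source list (one id per
#' line) and a ground-truth JSON; byte-identical for a fixed seed.
#'
#' @param suite result of \code{\link{make_suite}}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_suite <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in suite$models)
    write_model(m, file.path(dir, paste0(m$model_id, ".json")),
                "toy_json")
  med <- build_medium(suite$base_metabolites, suite$carbon_sources,
                      oxygen = "present")
  write_medium_tsv(med, file.path(dir, "medium.tsv"))
  writeLines(suite$carbon_sources, file.path(dir, "carbons.txt"))
  gt <- lapply(suite$specs, function(s)
    make_organism(s)$ground_truth)
  names(gt) <- vapply(suite$specs, `[[`, character(1), "id")
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
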