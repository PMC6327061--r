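# Shared fixtures: all built in code, nothing on disk.

std_base <- function() c("nh4_e", "co2_e", "h2o_e", "h_e")

glc_medium <- function(oxygen = "absent")
  build_medium(std_base(), "glc_e", oxygen = oxygen)

ferm_model <- function() make_organism(toy_spec_ferm())$model
acsp_model <- function() make_organism(toy_spec_acsp())$model

# Minimal hand-built model: one carbon A_e, uptake, biomass; no ATP
# maintenance reaction.  Growth on A capped at 10 is 10.
tiny_model <- function(id = "TINY") {
  metabolic_model(
    id,
    metabolites = data.frame(id = c("A_e", "A_c"),
                             external = c(TRUE, FALSE)),
    reactions = list(
      list(id = "EX_A", stoich = c(A_e = -1), lb = -1000, ub = 1000),
      list(id = "T_A", stoich = c(A_e = -1, A_c = 1), lb = 0, ub = 1000),
      list(id = "BIOMASS", stoich = c(A_c = -1), lb = 0, ub = 1000)),
    biomass_id = "BIOMASS")
}

model_equal <- function(a, b) {
  identical(model_stoichiometry(a), model_stoichiometry(b)) &&
    isTRUE(all.equal(
      lapply(a$reactions, function(r) c(r$lb, r$ub)),
      lapply(b$reactions, function(r) c(r$lb, r$ub)))) &&
    identical(a$biomass_id, b$biomass_id) &&
    identical(a$atpm_id, b$atpm_id) &&
    identical(exchanges(a), exchanges(b)) &&
    identical(a$metabolites$external, b$metabolites$external)
}

# Fabricate a pair_experiment record directly (for classifier unit tests
# that need exact control over secretion/uptake sets).
fake_record <- function(ids = c("ORGA", "ORGB"),
                        carbons = "glc_e",
                        sec_i = c(ac_e = 5), sec_j = numeric(0),
                        up_i = c(glc_e = -10), up_j = c(ac_e = -5),
                        growth = c(TRUE, TRUE),
                        solo = c(TRUE, FALSE)) {
  med <- build_medium(std_base(), carbons, oxygen = "absent")
  entry <- list(growth = growth, growth_rate = c(1, 1),
                secretions = list(sec_i, sec_j),
                uptakes = list(up_i, up_j), medium = med)
  structure(list(organisms = ids, carbon_sources = carbons,
                 oxygen = c("absent", "absent"),
                 iterations = list(entry), c_s = 1L,
                 solo_growth = solo, final_medium = med,
                 nonterminated = FALSE),
            class = "pair_experiment")
}

# Dense-LP instance (no flux splitting) for the independent oracle.
lp_instance <- function(model, medium, oxygen = NULL) {
  b <- apply_medium(model, medium, oxygen)
  list(S = model_stoichiometry(b),
       lb = vapply(b$reactions, function(r) r$lb, numeric(1)),
       ub = vapply(b$reactions, function(r) r$ub, numeric(1)),
       obj = as.numeric(vapply(b$reactions, `[[`, character(1), "id")
                        == b$biomass_id))
}

# Independent LP oracle: SciPy's HiGHS solver via one batched python
# call, solving max obj'v s.t. S v = 0, lb <= v <= ub directly on the
# dense matrix.  Entirely separate code path from the package's simplex.
oracle_lp_batch <- function(instances) {
  payload <- lapply(instances, function(q)
    list(obj = q$obj, S = as.vector(t(q$S)),
         m = nrow(q$S), n = ncol(q$S), lb = q$lb, ub = q$ub))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from scipy.optimize import linprog",
    "insts = json.load(open(sys.argv[1]))",
    "out = []",
    "for q in insts:",
    "    S = np.array(q['S']).reshape(q['m'][0], q['n'][0])",
    "    r = linprog(-np.array(q['obj']), A_eq=S,",
    "                b_eq=np.zeros(q['m'][0]),",
    "                bounds=list(zip(q['lb'], q['ub'])), method='highs')",
    "    out.append(-r.fun if r.status == 0 else None)",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, fin, fout),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  vapply(jsonlite::read_json(fout), function(x)
    if (is.null(x)) NA_real_ else as.numeric(x), numeric(1))
}

all_motif_codes <- c("N1b", "N2a", "N2b", "C1a", "C1b", "C2a", "C2b",
                     "M1a", "M1b", "M2a", "M2b")
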