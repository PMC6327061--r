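test_that("toy organisms honour their ground truth", {
  for (spec in list(toy_spec_ferm(),
                    toy_spec("FAC", "glc_e", fermentation = TRUE,
                             use_ac = TRUE),
                    toy_spec("RSP", "fru_e", respiration = TRUE),
                    toy_spec("GEN", c("glc_e", "fru_e"),
                             fermentation = TRUE))) {
    org <- make_organism(spec)
    expect_lte(length(org$model$reactions), 15L)
    validate_model(org$model)
    med <- build_medium(std_base(), spec$substrates, oxygen = "present")
    for (cond in c("oxic", "anoxic")) {
      o2 <- if (cond == "oxic") "present" else "absent"
      g <- solve_growth(org$model, med, o2)$growth_rate
      expect_equal(g, org$ground_truth$solo_growth[[cond]],
                   tolerance = 1e-6, label = paste(spec$id, cond))
    }
    sec <- costless_secretions(org$model, med, "absent")$secretions
    expect_setequal(as.character(setdiff(names(sec), "co2_e")),
                    org$ground_truth$anoxic_secretions)
  }
})

test_that("toy specs are validated", {
  expect_error(toy_spec("NIL"), "no ATP-generating route")
  expect_error(toy_spec("BAD", ac_biomass = TRUE),
               "requires use_ac")
  expect_error(make_organism(toy_spec("BIG", c("a_e", "b_e", "c_e"),
                                      fermentation = TRUE,
                                      respiration = TRUE,
                                      use_ac = TRUE)),
               "> 15")
})

test_that("the acetate specialist cannot grow on glucose", {
  acsp <- make_organism(toy_spec_acsp())
  expect_equal(solve_growth(acsp$model, glc_medium())$growth_rate, 0)
  # but grows at 10/3 once acetate is cross-fed
  med <- expand_medium(glc_medium(), "ac_e")$medium
  expect_equal(solve_growth(acsp$model, med)$growth_rate, 10 / 3,
               tolerance = 1e-9)
})

test_that("organism generation is deterministic and spec-driven", {
  a <- make_organism(toy_spec_ferm(), seed = 1)
  b <- make_organism(toy_spec_ferm(), seed = 999)
  expect_true(model_equal(a$model, b$model))
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("generated suites are valid, feasible and seeded", {
  s1 <- make_suite(4, 6, seed = 7)
  expect_length(s1$models, 4)
  for (m in s1$models) {
    validate_model(m)
    expect_lte(length(m$reactions), 15L)
  }
  # every carbon source has at least one consumer
  consumed <- unique(unlist(lapply(s1$specs, `[[`, "substrates")))
  expect_setequal(intersect(s1$carbon_sources, consumed),
                  s1$carbon_sources)
  # plan over the suite matches the combinatorial count
  plan <- plan_sweep(s1$models, s1$carbon_sources)
  expect_equal(n_configs(plan), 6 * 15 * 2)
  # same seed -> byte-identical files
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  write_suite(s1, d1)
  write_suite(make_suite(4, 6, seed = 7), d2)
  write_suite(make_suite(4, 6, seed = 8), d3)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_false(all(vapply(list.files(d3), function(f)
    identical(readLines(file.path(d1, f)),
              readLines(file.path(d3, f))), logical(1))))
  # every generated model is feasible (NGAM satisfiable) on the suite
  # medium with every carbon available
  med <- build_medium(s1$base_metabolites, s1$carbon_sources,
                      oxygen = "present")
  for (m in s1$models)
    expect_identical(solve_growth(m, med, "present")$status, "optimal")
})

test_that("suite models load back from disk identically", {
  s <- make_suite(3, 3, seed = 4)
  d <- tempfile()
  write_suite(s, d)
  for (m in s$models) {
    back <- read_model(file.path(d, paste0(m$model_id, ".json")))
    expect_true(model_equal(m, back))
  }
})
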