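# The FERM organism's optima are hand-derivable:
#   anoxic:  glucose split v+f <= 10, ATP 2f = 2v        -> v_g,0 = 5
#   oxic:    respiration 10 ATP/glc -> 1.2 v <= 10       -> v_g,0 = 25/3
#   forced acetate 1.0 oxic: 0.5 glc diverted            -> v_g,s = 8
test_that("worked FERM growth and secretion values are reproduced", {
  m <- ferm_model()
  med <- glc_medium()
  an <- solve_growth(m, med, "absent")
  expect_equal(an$growth_rate, 5, tolerance = 1e-9)
  ox <- solve_growth(m, med, "present")
  expect_equal(ox$growth_rate, 25 / 3, tolerance = 1e-9)

  cs_an <- costless_secretions(m, med, "absent")
  expect_equal(cs_an$secretions, c(ac_e = 10), tolerance = 1e-9)
  expect_false("co2_e" %in% names(cs_an$secretions))
  cs_ox <- costless_secretions(m, med, "present")
  expect_equal(cs_ox$secretions, c(co2_e = 10), tolerance = 1e-9)
  expect_false("ac_e" %in% names(cs_ox$secretions))
})

test_that("no carbon source means no growth, infeasible NGAM means status", {
  m <- ferm_model()
  med <- build_medium(std_base(), "fru_e", oxygen = "absent") # unusable
  expect_equal(solve_growth(m, med)$growth_rate, 0)
  expect_identical(costless_secretions(m, med)$secretions, numeric(0))
  # NGAM that cannot be satisfied -> infeasible, growth 0 by contract
  spec <- toy_spec_ferm()
  spec$ngam <- 1
  hungry <- make_organism(spec)$model
  sol <- solve_growth(hungry, med, "absent")
  expect_identical(sol$status, "infeasible")
  expect_equal(sol$growth_rate, 0)
})

test_that("forced secretion costs match the hand LP", {
  m <- ferm_model()
  med <- glc_medium()
  r <- secretion_cost(m, med, "ac_e", 1.0, "present")
  expect_identical(r$category, "costly")
  expect_equal(r$delta_growth, -1 / 3, tolerance = 1e-9)
  expect_equal(r$v_gs, 8, tolerance = 1e-9)
  r2 <- secretion_cost(m, med, "ac_e", 10, "absent")
  expect_identical(r2$category, "costless")
  expect_equal(r2$delta_growth, 0, tolerance = 1e-9)
  # no synthesis path -> infeasible, reported distinctly
  r3 <- secretion_cost(m, med, "etoh_e", 1, "absent")
  expect_identical(r3$category, "infeasible")
  expect_error(secretion_cost(m, med, "ghost_e", 1), "no exchange")
})

test_that("every returned optimum is at steady state and within bounds", {
  m <- ferm_model()
  med <- glc_medium()
  S <- model_stoichiometry(m)
  for (o2 in c("present", "absent")) {
    cs <- costless_secretions(m, med, o2)
    v <- cs$solution$fluxes[colnames(S)]
    expect_lt(max(abs(S %*% v)), 1e-6)
    b <- apply_medium(m, med, o2)
    lb <- vapply(b$reactions, function(r) r$lb, numeric(1))
    ub <- vapply(b$reactions, function(r) r$ub, numeric(1))
    expect_true(all(v >= lb - 1e-7 & v <= ub + 1e-7))
  }
})

test_that("flux minimization never increases total |v| at fixed growth", {
  suite <- make_suite(4, 4, seed = 9)
  med <- build_medium(suite$base_metabolites,
                      suite$carbon_sources[1:2], oxygen = "present")
  for (m in suite$models) {
    s1 <- solve_growth(m, med, "present")
    if (s1$growth_rate < 1e-6) next
    cs <- costless_secretions(m, med, "present")
    expect_lte(cs$solution$total_abs_flux, s1$total_abs_flux + 1e-7)
    expect_gte(cs$solution$growth_rate,
               s1$growth_rate * (1 - 1e-9) - 1e-12)
  }
})

test_that("costlessness re-verification holds for reported secretions", {
  # the defining inequality: forcing any reported secretion at its
  # reported flux cannot reduce optimal growth
  suite <- make_suite(4, 4, seed = 5)
  set.seed(5)
  for (m in suite$models) for (o2 in c("present", "absent")) {
    cs <- sample(suite$carbon_sources, 2)
    med <- build_medium(suite$base_metabolites, cs, oxygen = o2)
    res <- costless_secretions(m, med, o2)
    if (!res$grew) next
    for (met in names(res$secretions)) {
      probe <- secretion_cost(m, med, met, res$secretions[[met]], o2)
      expect_true(probe$category %in% c("costless", "beneficial"),
                  label = paste(m$model_id, o2, met))
    }
  }
})

test_that("alternative objectives respect the biomass floor", {
  m <- ferm_model()
  med <- glc_medium()
  mb <- solve_alternative_objective(m, med, "min_biomass", "absent")
  expect_equal(mb$solution$growth_rate, 0.01, tolerance = 1e-8)
  # any ATP demand forces fermentation: acetate still secreted
  expect_equal(mb$secretions, c(ac_e = 0.02), tolerance = 1e-7)

  # max_atp anoxic: all glucose not used for biomass is fermented;
  # ATPM = 2*(10 - 0.01) - 2*0.01 = 19.96
  ma <- solve_alternative_objective(m, med, "max_atp", "absent")
  expect_equal(ma$solution$fluxes[["ATPM"]], 19.96, tolerance = 1e-6)

  # max_growth is by definition the two-stage costless computation
  mg <- solve_alternative_objective(m, med, "max_growth", "absent")
  base <- costless_secretions(m, med, "absent")
  expect_equal(mg$secretions, base$secretions)
  expect_equal(mg$solution$growth_rate, base$solution$growth_rate)

  expect_error(
    solve_alternative_objective(tiny_model(),
                                build_medium(std_base(), "A_e"),
                                "max_atp"),
    "no ATP maintenance")
})

test_that("solver is deterministic run to run", {
  m <- ferm_model()
  med <- glc_medium()
  a <- costless_secretions(m, med, "present")
  b <- costless_secretions(m, med, "present")
  expect_identical(a$solution$fluxes, b$solution$fluxes)
  expect_identical(a$secretions, b$secretions)
})

test_that("flux solutions export as TSV", {
  cs <- costless_secretions(ferm_model(), glc_medium(), "absent")
  path <- tempfile(fileext = ".tsv")
  write_fluxes_tsv(cs$solution, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 15)
  expect_equal(tab$flux[tab$reaction_id == "BIOMASS"], 5,
               tolerance = 1e-9)
})
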