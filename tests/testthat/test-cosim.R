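test_that("the worked FERM+ACSP experiment unfolds as derived", {
  pr <- make_motif_pair("C1a")
  rec <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
                             "absent", "absent")
  expect_equal(rec$c_s, 2L)
  expect_identical(rec$solo_growth, c(TRUE, FALSE))
  it1 <- rec$iterations[[1]]
  expect_identical(it1$growth, c(TRUE, FALSE))
  expect_equal(it1$secretions[[1]], c(ac_e = 10), tolerance = 1e-9)
  it2 <- rec$iterations[[2]]
  expect_identical(it2$growth, c(TRUE, TRUE))
  # ACSP grows on cross-fed acetate at 10/3, burning 2/3 of it to CO2
  expect_equal(it2$growth_rate[2], 10 / 3, tolerance = 1e-9)
  expect_equal(it2$secretions[[2]][["co2_e"]], 20 / 3, tolerance = 1e-9)
  expect_equal(it2$uptakes[[2]][["ac_e"]], -10, tolerance = 1e-9)
  # the final medium would not change under one more iteration
  ex <- expand_medium(rec$final_medium,
                      unlist(lapply(it2$secretions, names)))
  expect_false(ex$changed)
})

test_that("two non-growers stop at c_s = 1 with no expansion", {
  m1 <- make_organism(toy_spec("R1", "glc_e", respiration = TRUE))$model
  m2 <- make_organism(toy_spec("R2", "glc_e", respiration = TRUE))$model
  med <- glc_medium("absent") # respirers cannot grow anoxically
  rec <- run_pair_experiment(m1, m2, med, "absent", "absent")
  expect_equal(rec$c_s, 1L)
  expect_identical(rec$iterations[[1]]$growth, c(FALSE, FALSE))
  expect_length(rec$final_medium$crossfed, 0)
})

test_that("hybrid oxic-anoxic experiments apply oxygen per organism", {
  m1 <- ferm_model()
  m2 <- make_organism(toy_spec("FERM2", "glc_e", fermentation = TRUE,
                               respiration = TRUE))$model
  med <- glc_medium("present")
  rec <- run_pair_experiment(m1, m2, med, "present", "absent")
  it1 <- rec$iterations[[1]]
  # oxic partner respires (CO2, growth 25/3); anoxic partner ferments
  expect_equal(it1$growth_rate[1], 25 / 3, tolerance = 1e-9)
  expect_equal(it1$growth_rate[2], 5, tolerance = 1e-9)
  expect_true("ac_e" %in% names(it1$secretions[[2]]))
  expect_false("ac_e" %in% names(it1$secretions[[1]]))
})

test_that("medium expansion is monotone and terminates within the bound", {
  suite <- make_suite(4, 5, seed = 21)
  set.seed(21)
  n_ext_universe <- function(a, b)
    length(union(external_metabolites(a), external_metabolites(b)))
  for (rep in 1:6) {
    ij <- sample(length(suite$models), 2)
    cs <- sample(suite$carbon_sources, 2)
    o2 <- sample(c("present", "absent"), 1)
    med <- build_medium(suite$base_metabolites, cs, oxygen = o2)
    a <- suite$models[[ij[1]]]; b <- suite$models[[ij[2]]]
    rec <- run_pair_experiment(a, b, med, o2, o2)
    expect_false(rec$nonterminated)
    expect_lte(rec$c_s, n_ext_universe(a, b))
    meds <- lapply(rec$iterations, function(it)
      c(it$medium$base, it$medium$carbon_sources, it$medium$crossfed))
    for (k in seq_along(meds)[-1]) {
      expect_true(all(meds[[k - 1]] %in% meds[[k]])) # M monotone
      # growth statuses never regress
      expect_true(all(rec$iterations[[k]]$growth >=
                        rec$iterations[[k - 1]]$growth))
    }
  }
})

test_that("swapping organism order relabels but preserves the experiment", {
  pr <- make_motif_pair("M1b")
  r1 <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
                            "absent", "absent")
  r2 <- run_pair_experiment(pr$model_j, pr$model_i, pr$medium,
                            "absent", "absent")
  expect_equal(r1$c_s, r2$c_s)
  for (k in seq_len(r1$c_s)) {
    expect_identical(r1$iterations[[k]]$growth,
                     rev(r2$iterations[[k]]$growth))
    expect_equal(r1$iterations[[k]]$secretions,
                 r2$iterations[[k]]$secretions[2:1])
    expect_equal(r1$iterations[[k]]$uptakes,
                 r2$iterations[[k]]$uptakes[2:1])
  }
  l1 <- classify_interaction(r1)
  l2 <- classify_interaction(r2)
  expect_identical(l1$motif_code, l2$motif_code)
  expect_identical(l1$direction, "both")
  expect_identical(l2$direction, "both")
})

test_that("an exceeded iteration cap flags the record", {
  pr <- make_motif_pair("C1a")
  rec <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
                             "absent", "absent", max_iter = 1)
  expect_true(rec$nonterminated)
  expect_error(classify_interaction(rec), "nonterminated")
})

test_that("plan_sweep enumerates the combinatorial design", {
  plan <- plan_sweep(sprintf("m%d", 1:3), sprintf("c%d", 1:3))
  expect_equal(n_configs(plan), 3 * 3 * 2) # C(3,2) x C(3,2) x 2
  plan1 <- plan_sweep(sprintf("m%d", 1:2), sprintf("c%d", 1:2),
                      oxygen_conditions = "present")
  expect_equal(n_configs(plan1), 1L)
  cfg <- sweep_config(plan1, 1)
  expect_identical(cfg$organisms, c("m1", "m2"))
  expect_identical(cfg$oxygen, "present")
  # lazy indexing covers every cell exactly once
  plan2 <- plan_sweep(sprintf("m%d", 1:4), sprintf("c%d", 1:3))
  seen <- vapply(seq_len(n_configs(plan2)), function(k) {
    cfg <- sweep_config(plan2, k)
    paste(c(cfg$organisms, cfg$carbons, cfg$oxygen), collapse = "|")
  }, character(1))
  expect_equal(anyDuplicated(seen), 0L)
  expect_length(seen, 6 * 3 * 2)
  expect_error(plan_sweep("m1", "c1"), "at least")
  expect_error(plan_sweep(c("m1", "m1"), c("c1", "c2")), "duplicate")
})

test_that("run_sweep produces one labelled row per config and resumes", {
  suite <- make_suite(3, 3, seed = 2)
  plan <- plan_sweep(suite$models, suite$carbon_sources,
                     oxygen_conditions = "present",
                     base_metabolites = suite$base_metabolites)
  expect_equal(n_configs(plan), 3 * 3 * 1)
  full <- run_sweep(plan)
  expect_equal(nrow(full), 9L)
  expect_true(all(full$interaction %in%
                    c("classified", "no-pair-growth")))
  # motifs present exactly on rows where both organisms grew
  expect_identical(full$motif != "",
                   full$grow_i == 1L & full$grow_j == 1L)

  path <- tempfile(fileext = ".tsv")
  full2 <- run_sweep(plan, output_path = path)
  expect_equal(full2, full)
  # truncate the checkpoint and resume: identical final table
  lines <- readLines(path)
  writeLines(lines[1:4], path)
  resumed <- run_sweep(plan, output_path = path, resume = TRUE)
  expect_equal(resumed[, names(full)], full, tolerance = 1e-6)
  # corrupted header is detected
  writeLines(c("bogus\theader", lines[-1]), path)
  expect_error(run_sweep(plan, output_path = path, resume = TRUE),
               "corrupt checkpoint")
})

test_that("an empty plan yields an empty table with the header", {
  suite <- make_suite(2, 2, seed = 1)
  plan <- plan_sweep(suite$models, suite$carbon_sources,
                     oxygen_conditions = character(0))
  expect_equal(n_configs(plan), 0L)
  out <- run_sweep(plan)
  expect_equal(nrow(out), 0L)
  expect_true(all(c("org_i", "motif", "c_s") %in% names(out)))
})
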