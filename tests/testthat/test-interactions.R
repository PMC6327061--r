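test_that("interaction classes follow the edge/competition definitions", {
  # commensal, no competition on the single consumed carbon
  lab <- classify_interaction(fake_record())
  expect_identical(lab$iclass, "C")
  expect_identical(lab$motif_code, "C1a")
  expect_identical(lab$direction, "i->j")
  expect_equal(lab$exchange_edges$metabolite, "ac_e")

  # both consume glc, no exchange -> competitive exclusion motif N1b
  lab2 <- classify_interaction(fake_record(
    sec_i = numeric(0), sec_j = numeric(0),
    up_i = c(glc_e = -10), up_j = c(glc_e = -10)))
  expect_identical(lab2$motif_code, "N1b")

  # reciprocal edges with shared carbon -> M1b
  lab3 <- classify_interaction(fake_record(
    sec_i = c(ac_e = 5), sec_j = c(nh4_e = 3),
    up_i = c(glc_e = -10, nh4_e = -1),
    up_j = c(glc_e = -10, ac_e = -5)))
  expect_identical(lab3$motif_code, "M1b")
  expect_identical(lab3$direction, "both")
  expect_equal(nrow(lab3$exchange_edges), 2)
})

test_that("water and protons are excluded from exchange evidence", {
  rec <- fake_record(sec_i = c(h2o_e = 8, h_e = 3),
                     up_j = c(glc_e = -10, h2o_e = -2, h_e = -1),
                     up_i = c(glc_e = -10))
  lab <- classify_interaction(rec)
  expect_identical(lab$iclass, "N")
  expect_identical(lab$motif_code, "N1b")
  # but CO2 (an enabling byproduct) is evidence by default
  rec2 <- fake_record(sec_i = c(co2_e = 4),
                      up_j = c(glc_e = -10, co2_e = -2),
                      up_i = c(glc_e = -10))
  expect_identical(classify_interaction(rec2)$iclass, "C")
  # exclusion list is configurable
  expect_identical(
    classify_interaction(rec2, exclusion = c("h2o_e", "h_e",
                                             "co2_e"))$iclass, "N")
})

test_that("pairs without mutual growth are labelled no-pair-growth", {
  rec <- fake_record(growth = c(TRUE, FALSE))
  lab <- classify_interaction(rec)
  expect_identical(lab$status, "no-pair-growth")
  expect_true(is.na(lab$motif_code))
})

test_that("uptake evidence is strictly by cutoff", {
  # receiver flux above -0.01 does not count as an edge
  rec <- fake_record(sec_i = c(ac_e = 5), up_j = c(glc_e = -10,
                                                   ac_e = -0.005))
  # uptakes below cutoff never enter the record in the real pipeline;
  # classify works on what the record carries
  rec$iterations[[1]]$uptakes[[2]] <- c(glc_e = -10)
  expect_identical(classify_interaction(rec)$iclass, "N")
})

test_that("obligate syntrophy needs failed solo growth plus pair growth", {
  pr <- make_motif_pair("C1a")
  rec <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
                             "absent", "absent")
  ob <- obligate_syntrophy(rec)
  expect_identical(unname(ob), c(FALSE, TRUE))
  expect_identical(names(ob), c("FERM", "ACSP"))
  both_solo <- fake_record(solo = c(TRUE, TRUE))
  expect_identical(unname(obligate_syntrophy(both_solo)),
                   c(FALSE, FALSE))
})

test_that("motif ground truth is recovered for every constructible code", {
  for (code in all_motif_codes) {
    pr <- make_motif_pair(code)
    rec <- run_pair_experiment(pr$model_i, pr$model_j, pr$medium,
                               pr$oxygen[1], pr$oxygen[2])
    lab <- classify_interaction(rec)
    expect_identical(lab$motif_code, code, label = code)
    expect_match(lab$motif_code, "^[NCM][12][ab]$")
    expect_identical(unname(obligate_syntrophy(rec)),
                     pr$ground_truth$obligate, label = code)
  }
  expect_error(make_motif_pair("N1a"), "not constructible")
  expect_error(make_motif_pair("Z9x"), "unknown motif")
})

test_that("cooperativity index matches its printed formula", {
  # boundary: pair growth everywhere, no single-source growth
  expect_equal(cooperativity_index(91, 0, 0, 14), 1)
  # independence null: normalized pair frequency = product of singles
  expect_equal(cooperativity_index(91, 91, 91, 14), 0)
  expect_equal(cooperativity_index(45, 30, 60, 14),
               45 / 91 - (30 / 91) * (60 / 91), tolerance = 1e-12)
  expect_equal(cooperativity_index(45, 30, 60, 14), 0.2771404,
               tolerance = 1e-6)
  # independent arithmetic oracle on randomized counts
  set.seed(7)
  for (rep in 1:50) {
    N <- sample(2:20, 3, replace = TRUE)
    nm <- choose(N, 2)
    g <- vapply(nm, function(x) sample(0:x, 1), numeric(1))
    direct <- g[1] / nm[1] - g[2] / nm[2] * (g[3] / nm[3])
    expect_equal(cooperativity_index(g[1], g[2], g[3],
                                     N[1], N[2], N[3]),
                 direct, tolerance = 1e-12)
    expect_true(abs(direct) <= 1)
  }
  expect_error(cooperativity_index(5, 1, 1, 1), "at least two")
  expect_error(cooperativity_index(99, 1, 1, 14), "must lie in")
})

test_that("sweep summaries conserve counts and report correlations", {
  suite <- make_suite(4, 4, seed = 13)
  plan <- plan_sweep(suite$models, suite$carbon_sources,
                     base_metabolites = suite$base_metabolites)
  res <- run_sweep(plan)
  s <- summarize_sweep(res)
  expect_equal(sum(s$cs_distribution$Freq), nrow(res))
  n_pair_growth <- sum(res$grow_i == 1 & res$grow_j == 1)
  expect_equal(sum(s$motif_frequency$Freq), n_pair_growth)
  expect_true(all(grepl("^[NCM][0-2][ab]$", s$motif_frequency$motif)))
  sp <- s$cosecretion_spearman
  expect_true(!is.null(sp))
  expect_equal(rownames(sp), colnames(sp))
  # constant indicator columns are undefined
  const <- apply(sp, 1, function(r) all(is.na(r)))
  expect_true(all(is.na(diag(sp)[const])))
  off <- sp[upper.tri(sp)]
  expect_true(all(is.na(off) | (off >= -1 & off <= 1)))
  expect_error(summarize_sweep(res[0, ]), "empty")
})

test_that("identical secretion columns give Spearman rho of 1", {
  res <- data.frame(
    c_s = c(1L, 1L, 1L),
    secreted_i = c("x_e:1;y_e:1", "", "x_e:2;y_e:5"),
    secreted_j = c("", "z_e:1", ""),
    interaction = rep("classified", 3),
    motif = rep("N1b", 3),
    grow_i = 1L, grow_j = 1L,
    stringsAsFactors = FALSE)
  s <- summarize_sweep(res)
  expect_equal(s$cosecretion_spearman["x_e", "y_e"], 1)
  expect_true(is.na(s$cosecretion_spearman["x_e", "x_e"]) ||
                s$cosecretion_spearman["x_e", "x_e"] == 1)
})
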