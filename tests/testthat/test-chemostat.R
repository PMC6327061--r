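test_that("parameters and topologies are validated", {
  expect_s3_class(chemostat_params(), "chemostat_params")
  expect_error(chemostat_params(D = 0), "D > 0")
  expect_error(chemostat_params(mu_max = c(-1, 0.5)))
  expect_error(build_motif_system("Q9z"), "unknown motif")
  sys <- build_motif_system("N2a")
  expect_identical(sys$topology$P2, 2L)
  sysC <- build_motif_system("C1a")
  expect_identical(sysC$topology, list(P1 = 1L, P2 = 0L, X1 = FALSE,
                                       X2 = TRUE))
  sysM <- build_motif_system("M1b")
  expect_true(sysM$topology$X1 && sysM$topology$X2)
})

test_that("compiled dynamics agree with the plain-R right-hand side", {
  # short-horizon comparison against a fine fixed-step RK4 built on the
  # exported R closure
  for (code in c("N1b", "C1a", "M2b")) {
    sys <- build_motif_system(code, chemostat_params(mu_max = c(0.6,
                                                                0.4)))
    rk4 <- function(y, t_end, h = 0.001) {
      t <- 0
      while (t < t_end - 1e-12) {
        k1 <- sys$rhs(t, y)
        k2 <- sys$rhs(t + h / 2, y + h / 2 * k1)
        k3 <- sys$rhs(t + h / 2, y + h / 2 * k2)
        k4 <- sys$rhs(t + h, y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
        t <- t + h
      }
      y
    }
    ref <- rk4(sys$y0, 5)
    got <- simulate_chemostat(sys, times = c(0, 5))
    expect_equal(as.numeric(got[2, -1]), ref, tolerance = 1e-5,
                 label = code)
  }
})

test_that("washout limit: zero growth rates decay as exp(-D t)", {
  p <- chemostat_params(mu_max = c(0, 0))
  sys <- build_motif_system("N1b", p)
  tr <- simulate_chemostat(sys, times = c(0, 10, 20))
  expect_equal(tr$s1[2], 0.1 * exp(-p$D * 10), tolerance = 1e-6)
  expect_equal(tr$s2[3], 0.1 * exp(-p$D * 20), tolerance = 1e-6)
  map <- stability_map("N1b", p, grid_n = 2)
  expect_false(any(map$stable[1, ])) # mu_max = 0 corners wash out
})

test_that("single-species washout matches the closed-form break-even", {
  p <- chemostat_params()
  mu_star <- break_even_mu(p)
  expect_equal(mu_star, p$D * (p$k + p$I / p$D) / (p$I / p$D))
  sp <- single_species_persistence(p, grid_n = 51)
  step <- diff(sp$mu[1:2])
  boundary <- sp$mu[min(which(sp$persists))]
  expect_lte(abs(boundary - mu_star), step + 1e-9)
  # persistence is monotone in mu_max
  expect_true(all(diff(sp$persists) >= 0))
})

test_that("trajectories stay non-negative with clipping accounted", {
  sys <- build_motif_system("M2b", chemostat_params(mu_max = c(1, 1)))
  tr <- simulate_chemostat(sys)
  expect_true(all(as.matrix(tr[, -1]) >= 0))
  expect_gte(attr(tr, "n_clipped"), 0)
  expect_error(simulate_chemostat(
    structure(list(y0 = c(NA, 1, 0, 0, 0, 0)),
              class = "chemostat_system")))
})

test_that("stability maps are symmetric for symmetric motifs", {
  p <- chemostat_params()
  for (code in c("N1b", "N2a", "M1b")) {
    map <- stability_map(code, p, grid_n = 21)
    expect_identical(map$stable, t(map$stable), label = code)
  }
})

test_that("C1a stable region grows with the secretion rate", {
  lo <- stability_map("C1a", chemostat_params(k_sec = 0.05),
                      grid_n = 21)
  hi <- stability_map("C1a", chemostat_params(k_sec = 0.1),
                      grid_n = 21)
  expect_true(all(hi$stable[lo$stable])) # nested regions
  expect_gte(sum(hi$stable), sum(lo$stable))
})

test_that("stability map IO writes grid plus metadata", {
  map <- stability_map("C1a", grid_n = 5)
  base <- tempfile()
  write_stability_map(map, base)
  tab <- read.delim(paste0(base, ".tsv"), row.names = 1)
  expect_equal(dim(tab), c(5, 5))
  meta <- jsonlite::read_json(paste0(base, ".json"))
  expect_identical(meta$motif, "C1a")
})
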