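tiny_config <- function(seed = 7) {
  sim_config(bvoc_params(), L = 20, steps = 60,
             density_emitter = 0.02, density_nonemitter = 0.02, seed = seed)
}

test_that("a degenerate one-cell diagram equals the underlying run", {
  cfg <- tiny_config()
  pd <- phase_diagram_lattice(0.5, 0.9, cfg, n_replicates = 1)
  expect_equal(nrow(pd), 1L)
  cfg1 <- cfg
  cfg1$seed <- replicate_seeds(cfg$seed, 1)[1]
  sim <- run_simulation(cfg1)
  want <- if (sim$emitters_extinct) 0 else sim$final_frequency
  expect_equal(pd$mean_frequency, want)
  expect_identical(attr(pd, "config"), cfg)
})

test_that("phase diagram cells are complete, bounded summaries", {
  cfg <- tiny_config()
  pd <- phase_diagram_lattice(c(0.2, 0.8), c(0.3, 0.7), cfg, n_replicates = 2)
  expect_equal(nrow(pd), 4L)
  expect_true(all(pd$mean_frequency >= 0 & pd$mean_frequency <= 1))
  expect_true(all(pd$n_replicates == 2L))
  expect_true(all(pd$n_emitter_extinct <= 2L))
})

test_that("range comparison pairs the two signaling radii by seed", {
  cfg <- tiny_config()
  rc <- range_comparison(0.3, 0.7, cfg, r_d = 1, n_replicates = 2)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$difference,
               rc$mean_frequency_rbvoc1 - rc$mean_frequency_rbvoc2)
  expect_length(rc$freq_rbvoc1[[1]], 2L)
  # the r_bvoc = 1 arm is the plain simulation with the same derived seed
  cfg1 <- cfg
  cfg1$params <- update_params(cfg$params, alpha1 = 0.3, alpha2 = 0.7,
                               r_bvoc = 1L, r_d = 1L)
  cfg1$seed <- replicate_seeds(cfg$seed, 2)[1]
  sim <- run_simulation(cfg1)
  want <- if (sim$emitters_extinct) 0 else sim$final_frequency
  expect_equal(rc$freq_rbvoc1[[1]][1], want)
})

test_that("dispersal comparison covers the four range combinations", {
  cfg <- tiny_config()
  dc <- dispersal_comparison(cfg, n_replicates = 2)
  expect_equal(nrow(dc), 4L)
  expect_setequal(sprintf("%d%d", dc$r_bvoc, dc$r_d), c("11", "12", "21", "22"))
  expect_true(all(is.na(dc$join_count) | (dc$join_count >= 0 & dc$join_count <= 1)))
  snaps <- attr(dc, "snapshots")
  expect_length(snaps, 4L)
  expect_true(all(vapply(snaps, is.matrix, logical(1))))
})

test_that("join count is 1 on a monoculture and 0 on a strategy checkerboard", {
  expect_equal(join_count(matrix(EMITTER, 5, 5)), 1)
  # rook-adjacent checkerboard neighbors always differ
  expect_equal(join_count(checkerboard_lattice(8)), 0)
  expect_true(is.na(join_count(matrix(VACANT, 4, 4))))
})

test_that("join count matches the hypergeometric expectation under random labels", {
  set.seed(51)
  n_e <- 40L; n_n <- 60L
  vals <- replicate(200, {
    lab <- sample(c(rep(EMITTER, n_e), rep(NONEMITTER, n_n)))
    join_count(matrix(lab, 10, 10))
  })
  expect_equal(mean(vals), join_count_expected(n_e, n_n), tolerance = 0.01)
})

test_that("lattice outcomes track the mean-field regime ranking", {
  # emitter-dominant vs cheater-dominant mean-field cells keep their order
  cfg <- sim_config(bvoc_params(), L = 30, steps = 800,
                    density_emitter = 0.005, density_nonemitter = 0.005,
                    seed = 17)
  seeds <- replicate_seeds(cfg$seed, 3)
  run_at <- function(a1, a2) {
    mean(vapply(seeds, function(s) {
      cfg1 <- cfg
      cfg1$params <- update_params(cfg$params, alpha1 = a1, alpha2 = a2)
      cfg1$seed <- s
      sim <- run_simulation(cfg1)
      if (sim$emitters_extinct) 0 else sim$final_frequency
    }, numeric(1)))
  }
  expect_equal(classify_ess(update_params(cfg$params, alpha1 = 0.1,
                                          alpha2 = 0.9))$regime,
               "emitter_dominant")
  expect_equal(classify_ess(update_params(cfg$params, alpha1 = 0.9,
                                          alpha2 = 0.5))$regime,
               "nonemitter_dominant")
  expect_gt(run_at(0.1, 0.9), run_at(0.9, 0.5))
})

test_that("simulation configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "params:",
    "  alpha1: 0.3",
    "  alpha2: 0.7",
    "  r_bvoc: 2",
    "L: 40",
    "steps: 100",
    "density_emitter: 0.001",
    "density_nonemitter: 0.0002",
    "seed: 5"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "bvoc_sim_config")
  expect_equal(cfg$params$alpha1, 0.3)
  expect_equal(cfg$params$r_bvoc, 2L)
  expect_equal(cfg$L, 40L)
  expect_equal(cfg$density_nonemitter, 2e-4)
})

test_that("clustered emitters gain from the public good even without cost or intra benefit", {
  # at alpha1 = 1, c = 0 but alpha2 < 1, per-site fitness is identical for
  # the two strategies, yet emitters cluster (limited dispersal) and raise
  # each other's fitness; the assortment makes them spread
  pr <- bvoc_params(alpha1 = 1, alpha2 = 0.5, c = 0)
  seeds <- replicate_seeds(811, 8)
  freqs <- vapply(seeds, function(s) {
    sim <- run_simulation(sim_config(pr, L = 30, steps = 1000,
                                     density_emitter = 0.02,
                                     density_nonemitter = 0.02, seed = s))
    if (sim$population_extinct) NA_real_ else sim$final_frequency
  }, numeric(1))
  freqs <- freqs[!is.na(freqs)]
  expect_lt(t.test(freqs, mu = 0.5, alternative = "greater")$p.value, 0.05)
})
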