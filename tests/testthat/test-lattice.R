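test_that("Moore neighborhoods wrap on the torus and have the right size", {
  nb <- moore_neighborhood(1, 1, 1, 100)
  expect_equal(nrow(nb), 9L)
  expect_true(any(nb$i == 100 & nb$j == 100))
  expect_equal(nrow(moore_neighborhood(6, 6, 2, 100)), 25L)
  expect_equal(nrow(moore_neighborhood(6, 6, 1, 100, include_focal = FALSE)), 8L)
  expect_error(moore_neighborhood(1, 1, 50, 100), "wraps")
})

test_that("the neighborhood is symmetric under reflection through the focal site", {
  nb <- moore_neighborhood(5, 9, 2, 20)
  # reflect each offset through (5, 9), wrap, and recover the same set
  refl <- data.frame(
    i = ((5 - (nb$i - 5) - 1) %% 20) + 1,
    j = ((9 - (nb$j - 9) - 1) %% 20) + 1
  )
  key <- function(d) sort(paste(d$i, d$j))
  expect_identical(key(nb), key(refl))
})

test_that("emitter counts exclude the focal site by default", {
  empty <- matrix(VACANT, 9, 9)
  expect_equal(count_emitters_in_range(empty, 5, 5, 1), 0L)
  ring <- matrix(VACANT, 9, 9)
  ring[4:6, 4:6] <- EMITTER
  expect_equal(count_emitters_in_range(ring, 5, 5, 1), 8L)
  expect_equal(count_emitters_in_range(ring, 5, 5, 1, include_focal = TRUE), 9L)
  # on a checkerboard the 4 diagonal neighbors share the focal site's type
  cb <- checkerboard_lattice(8)
  i <- which(cb == EMITTER, arr.ind = TRUE)[1, ]
  expect_equal(count_emitters_in_range(cb, i[1], i[2], 1), 4L)
})

test_that("the fitness field matches the per-site formulas", {
  pr <- bvoc_params(alpha1 = 0.5, alpha2 = 0.5, p = 0.4, c = 0.1)
  s <- matrix(VACANT, 7, 7)
  s[4, 4] <- EMITTER
  f <- compute_fitness_field(s, pr)
  expect_equal(f[4, 4], (1 - 0.4 * 0.5) * 0.9)        # isolated emitter
  expect_equal(sum(f), f[4, 4])                       # vacant sites are 0
  s[2, 2] <- NONEMITTER
  expect_equal(compute_fitness_field(s, pr)[2, 2], 1 - 0.4)  # isolated cheater

  # non-emitter flanked by 3 emitters: alpha2hat = 0.5^3
  s2 <- matrix(VACANT, 7, 7)
  s2[4, 4] <- NONEMITTER
  s2[3, 3] <- s2[3, 4] <- s2[3, 5] <- EMITTER
  expect_equal(compute_fitness_field(s2, pr)[4, 4], 1 - 0.4 * 0.125)

  # dual route: field agrees with looping the exported scalar operations
  set.seed(41)
  s3 <- init_lattice(12, 0.3, 0.3)
  f3 <- compute_fitness_field(s3, pr)
  for (k in sample(144, 20)) {
    i <- (k - 1) %% 12 + 1; j <- (k - 1) %/% 12 + 1
    m <- count_emitters_in_range(s3, i, j, pr$r_bvoc)
    want <- if (s3[i, j] == EMITTER) {
      fitness_emitter(pr$alpha1, gross_inter_effect_local(m, pr$alpha2),
                      pr$p, pr$c, pr$fhat)
    } else if (s3[i, j] == NONEMITTER) {
      fitness_nonemitter(gross_inter_effect_local(m, pr$alpha2), pr$p, pr$fhat)
    } else 0
    expect_equal(f3[i, j], want)
  }
})

test_that("colonization probabilities are fitness shares that sum to one", {
  s <- matrix(VACANT, 5, 5)
  fit <- matrix(0, 5, 5)
  expect_identical(colonization_probabilities(s, fit, 3, 3, 1),
                   c(prob_emitter = 0, prob_nonemitter = 0))
  s[2, 2] <- EMITTER; fit[2, 2] <- 0.72
  expect_identical(colonization_probabilities(s, fit, 3, 3, 1),
                   c(prob_emitter = 1, prob_nonemitter = 0))
  s[3, 4] <- NONEMITTER; fit[3, 4] <- 0.9
  pcol <- colonization_probabilities(s, fit, 3, 3, 1)
  expect_equal(unname(pcol), c(0.72, 0.9) / 1.62)
  expect_equal(sum(pcol), 1)
})

test_that("colonization probabilities sum to 0 or 1 at every vacant site", {
  set.seed(42)
  pr <- bvoc_params()
  s <- init_lattice(15, 0.2, 0.2)
  fit <- compute_fitness_field(s, pr)
  vac <- which(s == VACANT, arr.ind = TRUE)
  sums <- apply(vac, 1, function(ij)
    sum(colonization_probabilities(s, fit, ij[1], ij[2], pr$r_d)))
  expect_true(all(abs(sums) < 1e-12 | abs(sums - 1) < 1e-12))
})

test_that("a lattice generation conserves sites and honors absorbing states", {
  pr <- bvoc_params()
  # all-vacant lattice is absorbing
  empty <- matrix(VACANT, 10, 10)
  expect_identical(lattice_step(empty, pr), empty)
  # with no mortality a fully occupied lattice is frozen
  frozen <- update_params(pr, d = 0)
  cb <- checkerboard_lattice(8)
  expect_identical(lattice_step(cb, frozen), cb)
  # counts always sum to L^2
  set.seed(43)
  s <- init_lattice(20, 0.05, 0.05)
  for (t in 1:20) {
    s <- lattice_step(s, pr)
    expect_equal(sum(s == VACANT) + sum(s == EMITTER) + sum(s == NONEMITTER),
                 400L)
  }
})

test_that("a lone plant colonizes its whole dispersal neighborhood when d = 0", {
  pr <- bvoc_params(d = 0, r_d = 1)
  s <- matrix(VACANT, 7, 7)
  s[4, 4] <- EMITTER
  set.seed(44)
  s1 <- lattice_step(s, pr)
  expect_true(all(s1[3:5, 3:5] == EMITTER))
  expect_equal(sum(s1 == EMITTER), 9L)
})

test_that("random seeding hits the requested densities and validates input", {
  set.seed(45)
  expect_true(all(init_lattice(30, 0, 0) == VACANT))
  expect_true(all(init_lattice(30, 1, 0) == EMITTER))
  expect_error(init_lattice(30, 0.8, 0.5), "densities")
  s <- init_lattice(100, 0.001, 0.001)
  expect_lt(sum(s == EMITTER), 30)   # ~Binomial(1e4, 0.001)
  expect_gt(sum(s == EMITTER), 0)
})

test_that("emitter frequency is the share of occupied sites", {
  expect_equal(emitter_frequency(matrix(EMITTER, 3, 3)), 1)
  expect_equal(emitter_frequency(matrix(NONEMITTER, 3, 3)), 0)
  s <- matrix(c(rep(EMITTER, 30), rep(NONEMITTER, 70)), 10, 10)
  expect_equal(emitter_frequency(s), 0.3)
  expect_error(emitter_frequency(matrix(VACANT, 3, 3)), "all-vacant")
})

test_that("simulations are reproducible from their seed", {
  cfg <- sim_config(bvoc_params(), L = 25, steps = 120,
                    density_emitter = 0.02, density_nonemitter = 0.02,
                    seed = 99)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$final_state, b$final_state)
  # a zero-length run is just the initial census
  cfg0 <- sim_config(bvoc_params(), L = 10, steps = 0, seed = 1)
  expect_equal(nrow(run_simulation(cfg0)$counts), 1L)
})

test_that("an empty initial lattice is flagged as extinct immediately", {
  cfg <- sim_config(bvoc_params(), L = 10, steps = 50,
                    density_emitter = 0, density_nonemitter = 0, seed = 3)
  sim <- run_simulation(cfg)
  expect_true(sim$population_extinct)
  expect_true(sim$emitters_extinct)
  expect_true(is.na(sim$final_frequency))
  expect_lt(sim$steps_run, 50L)
})

test_that("snapshots round-trip through the plain-text format", {
  set.seed(46)
  s <- init_lattice(12, 0.3, 0.3)
  path <- withr::local_tempfile(fileext = ".txt")
  write_snapshot(s, path)
  expect_identical(read_snapshot(path), s)
})

test_that("replicate seeds are a stable deterministic mapping", {
  expect_identical(replicate_seeds(42, 5), replicate_seeds(42, 5))
  expect_identical(replicate_seeds(42, 5)[1:3], replicate_seeds(42, 3))
  expect_false(any(replicate_seeds(1, 4) == replicate_seeds(2, 4)))
})
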