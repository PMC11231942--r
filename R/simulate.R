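#' Simulation configuration
#'
#' Bundles the model parameters with the run settings of a lattice
#' simulation. The full-scale study profile is `L = 100`, `steps = 30000`,
#' seeding densities `(0.001, 0.001)` (the alternatives `(0.001, 0.0002)`
#' and `(0.0002, 0.001)` probe initial-condition dependence); the scaled
#' desk profile used by the experiment drivers is `L = 50`, `steps = 5000`.
#'
#' @param params A [bvoc_params()] object.
#' @param L Lattice side length.
#' @param steps Number of synchronous generations.
#' @param density_emitter,density_nonemitter Initial seeding probabilities.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param record_every Record counts every this many steps (the final step
#'   is always recorded).
#' @return An object of class `bvoc_sim_config`.
#' @examples
#' sim_config(bvoc_params(), L = 50, steps = 1000, seed = 1)
#' @export
sim_config <- function(params = bvoc_params(), L = 100L, steps = 30000L,
                       density_emitter = 0.001, density_nonemitter = 0.001,
                       seed = NULL, record_every = 1L) {
  stopifnot(inherits(params, "bvoc_params"))
  L <- check_count(L, "L", min = 2L)
  steps <- check_count(steps, "steps", min = 0L)
  record_every <- check_count(record_every, "record_every", min = 1L)
  if (!is.null(seed)) seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(params = params, L = L, steps = steps,
         density_emitter = density_emitter,
         density_nonemitter = density_nonemitter,
         seed = seed, record_every = record_every),
    class = "bvoc_sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys are the [sim_config()] arguments; model parameters sit
#' under a `params:` mapping with the [bvoc_params()] argument names.
#'
#' @param path Path to a YAML file.
#' @return A `bvoc_sim_config` object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(bvoc_params, y$params %||% list())
  y$params <- NULL
  do.call(sim_config, c(list(params = params), y))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive independent per-replicate seeds from a master seed
#'
#' Deterministic and stable mapping: the master seed initializes R's RNG
#' once, and the replicate seeds are drawn as a single `sample.int()` over
#' `1..2^31 - 2`. Replicate `k` always receives the `k`-th element.
#'
#' @param seed Master seed (integer).
#' @param n Number of replicate seeds.
#' @return An integer vector of length `n`.
#' @examples
#' replicate_seeds(42, 3)
#' @export
replicate_seeds <- function(seed, n) {
  seed <- check_count(seed, "seed", min = 0L)
  n <- check_count(n, "n", min = 1L)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Run one lattice simulation
#'
#' Seeds the lattice, iterates [lattice_step()] for the configured number of
#' generations, and records the three site-state counts. Counts are taken
#' after colonization and before the next mortality event, so at census the
#' lattice is (near-)fully occupied once the population has established.
#' The run terminates early, flagged as extinct, if every site becomes
#' vacant (an absorbing state).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `bvoc_sim` with components `counts` (tibble:
#'   `step`, `n_emitter`, `n_nonemitter`, `n_vacant`), `final_state` (the
#'   last state matrix), `final_frequency` (emitter share among occupied
#'   sites at the last recorded step, `NA` if all vacant),
#'   `emitters_extinct`, `population_extinct`, `steps_run`, and `config`.
#' @examples
#' sim <- run_simulation(sim_config(bvoc_params(), L = 30, steps = 200, seed = 1))
#' glance(sim)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "bvoc_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$params
  state <- init_lattice(config$L, config$density_emitter,
                        config$density_nonemitter)

  count3 <- function(s) {
    tabulate(as.vector(s) + 1L, nbins = 3L)  # vacant, emitter, nonemitter
  }
  n_rec <- config$steps %/% config$record_every + 2L
  rec <- matrix(NA_integer_, n_rec, 4L)
  k <- 1L
  rec[k, ] <- c(0L, count3(state)[c(2L, 3L, 1L)])

  steps_run <- 0L
  for (t in seq_len(config$steps)) {
    state <- lattice_step(state, p)
    steps_run <- t
    if (t %% config$record_every == 0L || t == config$steps) {
      k <- k + 1L
      rec[k, ] <- c(t, count3(state)[c(2L, 3L, 1L)])
    }
    if (all(state == VACANT)) {
      if (t %% config$record_every != 0L && t != config$steps) {
        k <- k + 1L
        rec[k, ] <- c(t, count3(state)[c(2L, 3L, 1L)])
      }
      break
    }
  }
  rec <- rec[seq_len(k), , drop = FALSE]
  counts <- tibble(
    step = rec[, 1], n_emitter = rec[, 2],
    n_nonemitter = rec[, 3], n_vacant = rec[, 4]
  )
  occ <- sum(state != VACANT)
  structure(
    list(
      counts = counts,
      final_state = state,
      final_frequency = if (occ > 0) sum(state == EMITTER) / occ else NA_real_,
      emitters_extinct = sum(state == EMITTER) == 0L,
      population_extinct = occ == 0L,
      steps_run = steps_run,
      config = config
    ),
    class = "bvoc_sim"
  )
}

#' @export
print.bvoc_sim <- function(x, ...) {
  cat(sprintf("<bvoc_sim> %d x %d lattice, %d steps run (seed %s)\n",
              x$config$L, x$config$L, x$steps_run,
              x$config$seed %||% "unset"))
  cat(sprintf("  final emitter frequency: %s; emitters extinct: %s\n",
              format(x$final_frequency, digits = 4), x$emitters_extinct))
  invisible(x)
}

#' @describeIn run_simulation Per-step site-state counts as a tibble.
#' @param x A `bvoc_sim` object.
#' @param ... Unused.
#' @export
tidy.bvoc_sim <- function(x, ...) x$counts

#' @describeIn run_simulation One-row run summary.
#' @export
glance.bvoc_sim <- function(x, ...) {
  tibble(
    final_frequency = x$final_frequency,
    emitters_extinct = x$emitters_extinct,
    population_extinct = x$population_extinct,
    steps_run = x$steps_run,
    L = x$config$L,
    seed = x$config$seed %||% NA_integer_
  )
}
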