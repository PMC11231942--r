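# Experiment drivers: alpha1-alpha2 phase diagrams, signaling- and
# dispersal-range comparisons, and the join-count clustering statistic.

run_cell <- function(alpha1, alpha2, config, seeds, r_bvoc = NULL, r_d = NULL,
                     keep_state = FALSE) {
  upd <- list(alpha1 = alpha1, alpha2 = alpha2)
  if (!is.null(r_bvoc)) upd$r_bvoc <- r_bvoc
  if (!is.null(r_d)) upd$r_d <- r_d
  params <- do.call(update_params, c(list(config$params), upd))
  purrr::map(seeds, function(s) {
    cfg <- config
    cfg$params <- params
    cfg$seed <- s
    sim <- run_simulation(cfg)
    list(
      # emitter extinction (including total extinction) counts as frequency 0
      frequency = if (sim$emitters_extinct) 0 else sim$final_frequency,
      emitters_extinct = sim$emitters_extinct,
      population_extinct = sim$population_extinct,
      state = if (keep_state) sim$final_state else NULL
    )
  })
}

cell_summary <- function(reps) {
  freq <- purrr::map_dbl(reps, "frequency")
  tibble(
    mean_frequency = mean(freq),
    sd_frequency = sd(freq),
    n_replicates = length(reps),
    n_emitter_extinct = sum(purrr::map_lgl(reps, "emitters_extinct")),
    n_population_extinct = sum(purrr::map_lgl(reps, "population_extinct"))
  )
}

#' Lattice phase diagram over the alpha1-alpha2 plane
#'
#' For every `(alpha1, alpha2)` cell, runs `n_replicates` independent
#' simulations and summarizes the final emitter frequency (mean and sd
#' across replicates). Replicates in which emitters went extinct contribute
#' frequency 0. Replicate seeds are derived from `config$seed` via
#' [replicate_seeds()] and reused across cells, so the whole diagram is
#' reproducible from one master seed.
#'
#' @param alpha1_grid,alpha2_grid Grids strictly inside (0, 1).
#' @param config A [sim_config()]; its `seed` is the master seed.
#' @param n_replicates Independent runs per cell.
#' @return A tibble with one row per cell: `alpha1`, `alpha2`,
#'   `mean_frequency`, `sd_frequency`, `n_replicates`, `n_emitter_extinct`,
#'   `n_population_extinct`; the configuration is attached as attribute
#'   `"config"`.
#' @examples
#' \donttest{
#' cfg <- sim_config(bvoc_params(), L = 30, steps = 500, seed = 7)
#' phase_diagram_lattice(c(0.2, 0.8), c(0.5), cfg, n_replicates = 2)
#' }
#' @export
phase_diagram_lattice <- function(alpha1_grid, alpha2_grid, config,
                                  n_replicates = 10L) {
  stopifnot(inherits(config, "bvoc_sim_config"), !is.null(config$seed))
  seeds <- replicate_seeds(config$seed, n_replicates)
  out <- tidyr::expand_grid(alpha1 = alpha1_grid, alpha2 = alpha2_grid) |>
    dplyr::mutate(purrr::map2_dfr(.data$alpha1, .data$alpha2, function(a1, a2) {
      cell_summary(run_cell(a1, a2, config, seeds))
    }))
  attr(out, "config") <- config
  out
}

#' Effect of the BVOC signaling range on emitter frequency
#'
#' Runs each `(alpha1, alpha2)` cell twice — with signaling radius
#' `r_bvoc = 1` and `r_bvoc = 2` — at a fixed dispersal radius, pairing the
#' two arms by replicate seed, and reports the cellwise difference in mean
#' final emitter frequency. Positive differences mean the short signaling
#' range favors emitters (cheaters are excluded from the public good more
#' effectively when the signal does not travel far).
#'
#' @inheritParams phase_diagram_lattice
#' @param r_d Dispersal radius held fixed (1 or 2).
#' @return A tibble per cell: `alpha1`, `alpha2`, `mean_frequency_rbvoc1`,
#'   `mean_frequency_rbvoc2`, `difference`, plus per-replicate frequencies
#'   in list-columns `freq_rbvoc1`, `freq_rbvoc2`.
#' @export
range_comparison <- function(alpha1_grid, alpha2_grid, config,
                             r_d = 1L, n_replicates = 10L) {
  stopifnot(inherits(config, "bvoc_sim_config"), !is.null(config$seed))
  seeds <- replicate_seeds(config$seed, n_replicates)
  out <- tidyr::expand_grid(alpha1 = alpha1_grid, alpha2 = alpha2_grid) |>
    dplyr::mutate(purrr::map2_dfr(.data$alpha1, .data$alpha2, function(a1, a2) {
      f1 <- purrr::map_dbl(
        run_cell(a1, a2, config, seeds, r_bvoc = 1L, r_d = r_d), "frequency")
      f2 <- purrr::map_dbl(
        run_cell(a1, a2, config, seeds, r_bvoc = 2L, r_d = r_d), "frequency")
      tibble(
        mean_frequency_rbvoc1 = mean(f1),
        mean_frequency_rbvoc2 = mean(f2),
        difference = mean(f1) - mean(f2),
        freq_rbvoc1 = list(f1),
        freq_rbvoc2 = list(f2)
      )
    }))
  attr(out, "config") <- config
  out
}

#' Compare all four signaling x dispersal range combinations
#'
#' Runs the four combinations `(r_bvoc, r_d)` in `{1, 2}^2` at one
#' `(alpha1, alpha2)` point, reports mean and sd of the final emitter
#' frequency, and quantifies spatial clumping of the surviving emitters
#' with the [join_count()] statistic of the final lattice of the first
#' replicate (kept as attribute `"snapshots"`).
#'
#' @param config A [sim_config()] whose `params` carry the focal
#'   `alpha1`, `alpha2`; `seed` is the master seed.
#' @param n_replicates Independent runs per combination.
#' @return A tibble with one row per combination: `r_bvoc`, `r_d`,
#'   `mean_frequency`, `sd_frequency`, `n_replicates`, `n_emitter_extinct`,
#'   `join_count` (of the first replicate's final lattice), with the four
#'   final states in attribute `"snapshots"` and per-replicate frequencies
#'   in list-column `frequencies`.
#' @export
dispersal_comparison <- function(config, n_replicates = 10L) {
  stopifnot(inherits(config, "bvoc_sim_config"), !is.null(config$seed))
  seeds <- replicate_seeds(config$seed, n_replicates)
  combos <- tidyr::expand_grid(r_bvoc = c(1L, 2L), r_d = c(1L, 2L))
  snapshots <- list()
  out <- combos |>
    dplyr::mutate(purrr::map2_dfr(.data$r_bvoc, .data$r_d, function(rb, rd) {
      reps <- run_cell(config$params$alpha1, config$params$alpha2, config,
                       seeds, r_bvoc = rb, r_d = rd, keep_state = TRUE)
      snapshots[[sprintf("rbvoc%d_rd%d", rb, rd)]] <<- reps[[1]]$state
      dplyr::bind_cols(
        cell_summary(reps),
        tibble(join_count = join_count(reps[[1]]$state),
               frequencies = list(purrr::map_dbl(reps, "frequency")))
      )
    }))
  attr(out, "snapshots") <- snapshots
  attr(out, "config") <- config
  out
}

#' Join-count clustering statistic
#'
#' The fraction of same-type pairs among all pairs of occupied,
#' nearest-neighbor (rook-adjacent, torus) sites. Values near 1 indicate
#' strong clumping of like strategies; under random labeling of the
#' occupied sites the expectation is given by [join_count_expected()].
#' `NA` when fewer than one occupied adjacent pair exists.
#'
#' @param state Lattice state matrix.
#' @return Fraction in \[0, 1\], or `NA`.
#' @examples
#' join_count(matrix(EMITTER, 4, 4))   # 1
#' @export
join_count <- function(state) {
  L <- nrow(state)
  shift <- function(m, di, dj) {
    m[((seq_len(L) - 1 + di) %% L) + 1,
      ((seq_len(ncol(m)) - 1 + dj) %% ncol(m)) + 1, drop = FALSE]
  }
  occ <- state != VACANT
  same <- total <- 0
  for (d in list(c(1, 0), c(0, 1))) {  # each unordered torus pair once
    nb <- shift(state, d[1], d[2])
    both <- occ & (nb != VACANT)
    total <- total + sum(both)
    same <- same + sum(both & state == nb)
  }
  if (total == 0) NA_real_ else same / total
}

#' Expected join-count under random labeling
#'
#' Expectation of [join_count()] when `n_e` emitters and `n_n` non-emitters
#' are placed uniformly at random on the occupied sites (hypergeometric
#' pair sampling): `(n_e(n_e-1) + n_n(n_n-1)) / (m(m-1))` with
#' `m = n_e + n_n`.
#'
#' @param n_e,n_n Counts of emitters and non-emitters.
#' @return Expected same-type pair fraction.
#' @export
join_count_expected <- function(n_e, n_n) {
  m <- n_e + n_n
  if (m < 2) return(NA_real_)
  (n_e * (n_e - 1) + n_n * (n_n - 1)) / (m * (m - 1))
}
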