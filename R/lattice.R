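# Site-state encoding for the lattice: integer matrix with
#   0 = vacant, 1 = emitter, 2 = non-emitter.

#' Site-state codes
#'
#' Integer codes used in lattice state matrices.
#' @format `EMITTER = 1L`, `NONEMITTER = 2L`, `VACANT = 0L`.
#' @name site_states
NULL

#' @rdname site_states
#' @export
EMITTER <- 1L
#' @rdname site_states
#' @export
NONEMITTER <- 2L
#' @rdname site_states
#' @export
VACANT <- 0L

# periodic box sum of a numeric matrix over the Moore neighborhood of
# radius r (separable: rows then columns); includes the focal cell
box_sum <- function(m, r) {
  L <- nrow(m)
  idx <- seq_len(L)
  acc <- matrix(0, L, L)
  for (k in -r:r) acc <- acc + m[((idx - 1 + k) %% L) + 1, , drop = FALSE]
  out <- matrix(0, L, L)
  for (k in -r:r) out <- out + acc[, ((idx - 1 + k) %% L) + 1, drop = FALSE]
  out
}

#' Moore neighborhood on the periodic lattice
#'
#' All sites within Chebyshev distance `r` of `(i, j)` on the `L x L` torus,
#' the focal site included unless `include_focal = FALSE`. Coordinates are
#' 1-based and wrap modulo `L`.
#'
#' @param i,j Focal site coordinates in `1..L`.
#' @param r Neighborhood radius (>= 1).
#' @param L Lattice side length; `2r + 1` must not exceed `L`, otherwise the
#'   wrapped neighborhood would double-count sites.
#' @param include_focal Keep `(i, j)` itself in the set?
#' @return A tibble of coordinates `i`, `j` with `(2r+1)^2` rows (one fewer
#'   when the focal site is excluded).
#' @examples
#' moore_neighborhood(1, 1, 1, 100)
#' @export
moore_neighborhood <- function(i, j, r, L, include_focal = TRUE) {
  r <- check_count(r, "r", min = 1L)
  L <- check_count(L, "L", min = 1L)
  if (2L * r + 1L > L)
    abort(sprintf("radius r = %d wraps around the torus of size L = %d.", r, L))
  if (i < 1 || i > L || j < 1 || j > L) abort("(i, j) must lie in 1..L.")
  off <- tidyr::expand_grid(di = -r:r, dj = -r:r)
  if (!include_focal) off <- dplyr::filter(off, .data$di != 0 | .data$dj != 0)
  tibble(
    i = ((i - 1 + off$di) %% L) + 1L,
    j = ((j - 1 + off$dj) %% L) + 1L
  )
}

#' Count emitting neighbors within signaling range
#'
#' The number `M` of emitter-occupied sites within the Moore `r_bvoc`
#' neighborhood of `(i, j)`. By default the focal site is excluded: the
#' benefit of a plant's own signal is carried by `alpha1`, so counting the
#' plant itself in `M` would credit it twice.
#'
#' @param state Lattice state matrix.
#' @param i,j Focal site coordinates.
#' @param r_bvoc Signaling radius.
#' @param include_focal Count the focal site if it is an emitter?
#' @return Nonnegative integer count.
#' @export
count_emitters_in_range <- function(state, i, j, r_bvoc, include_focal = FALSE) {
  nb <- moore_neighborhood(i, j, r_bvoc, nrow(state),
                           include_focal = include_focal)
  sum(state[cbind(nb$i, nb$j)] == EMITTER)
}

#' Fitness at every lattice site
#'
#' Emitter sites receive \eqn{f_E = (1 - p\,\alpha_1\,\alpha_2^M)(1-c)\hat f},
#' non-emitter sites \eqn{f_N = (1 - p\,\alpha_2^M)\hat f}, where `M` counts
#' emitting neighbors within the `r_bvoc` Moore neighborhood (focal site
#' excluded). Vacant sites have fitness 0.
#'
#' @param state Lattice state matrix.
#' @param params A [bvoc_params()] object (uses `alpha1`, `alpha2`, `p`, `c`,
#'   `fhat`, `r_bvoc`).
#' @return A numeric matrix of expected seed counts, same shape as `state`.
#' @export
compute_fitness_field <- function(state, params) {
  stopifnot(inherits(params, "bvoc_params"))
  is_e <- state == EMITTER
  is_n <- state == NONEMITTER
  m <- box_sum(is_e + 0, params$r_bvoc) - (is_e + 0)  # exclude focal emitter
  a2hat <- params$alpha2^m
  fit <- matrix(0, nrow(state), ncol(state))
  fit[is_e] <- (1 - params$p * params$alpha1 * a2hat[is_e]) *
    (1 - params$c) * params$fhat
  fit[is_n] <- (1 - params$p * a2hat[is_n]) * params$fhat
  fit
}

#' Colonization probabilities for a vacant site
#'
#' Seeds reaching the vacant site `(i, j)` come from every occupied site in
#' its Moore `r_d` dispersal neighborhood, in proportion to fitness. With
#' `F` the total fitness in range, the site is colonized by an emitter with
#' probability (emitter fitness sum)/`F` and by a non-emitter with the
#' complementary share; when `F = 0` (no occupied neighbor) it stays vacant.
#'
#' @param state Lattice state matrix.
#' @param fitness Fitness field, e.g. from [compute_fitness_field()].
#' @param i,j Vacant-site coordinates.
#' @param r_d Dispersal radius.
#' @return Named numeric vector `c(prob_emitter, prob_nonemitter)`; the two
#'   sum to 1 when any seeds arrive and are both 0 otherwise.
#' @export
colonization_probabilities <- function(state, fitness, i, j, r_d) {
  nb <- moore_neighborhood(i, j, r_d, nrow(state))
  s <- state[cbind(nb$i, nb$j)]
  f <- fitness[cbind(nb$i, nb$j)]
  fe <- sum(f[s == EMITTER])
  fn <- sum(f[s == NONEMITTER])
  total <- fe + fn
  if (total <= 0) {
    c(prob_emitter = 0, prob_nonemitter = 0)
  } else {
    c(prob_emitter = fe / total, prob_nonemitter = fn / total)
  }
}

#' Random initial lattice
#'
#' Each site independently becomes an emitter with probability
#' `density_emitter`, a non-emitter with probability `density_nonemitter`,
#' and stays vacant otherwise. Draws come from R's global RNG; call
#' `set.seed()` for reproducibility.
#'
#' @param L Lattice side length.
#' @param density_emitter,density_nonemitter Seeding probabilities; must be
#'   nonnegative and sum to at most 1.
#' @return An `L x L` integer state matrix.
#' @examples
#' set.seed(1)
#' table(init_lattice(50, 0.001, 0.001))
#' @export
init_lattice <- function(L, density_emitter, density_nonemitter) {
  L <- check_count(L, "L", min = 1L)
  if (density_emitter < 0 || density_nonemitter < 0 ||
      density_emitter + density_nonemitter > 1)
    abort("initial densities must be nonnegative and sum to at most 1.")
  u <- runif(L * L)
  s <- ifelse(u < density_emitter, EMITTER,
       ifelse(u < density_emitter + density_nonemitter, NONEMITTER, VACANT))
  matrix(as.integer(s), L, L)
}

#' One synchronous lattice generation
#'
#' Applies the update protocol: (1) fitness is computed at every site on the
#' current state; (2) every occupied site dies independently with
#' probability `d`, and dead plants contribute no seeds (their fitness is
#' zeroed); (3) every vacant site — pre-existing or newly vacated — is
#' colonized in a single categorical draw with the probabilities of
#' [colonization_probabilities()], all draws using the same post-death
#' fitness field (synchronous update).
#'
#' @param state Lattice state matrix.
#' @param params A [bvoc_params()] object.
#' @return The next state matrix.
#' @export
lattice_step <- function(state, params) {
  stopifnot(inherits(params, "bvoc_params"))
  L <- nrow(state)
  is_e <- state == EMITTER
  is_n <- state == NONEMITTER
  occupied <- is_e | is_n

  fit <- compute_fitness_field(state, params)

  survives <- occupied & (matrix(runif(L * L), L, L) >= params$d)
  fit_e <- fit * (is_e & survives)
  fit_n <- fit * (is_n & survives)

  se <- box_sum(fit_e, params$r_d)
  sn <- box_sum(fit_n, params$r_d)
  total <- se + sn

  vacant <- !survives
  new_state <- state
  new_state[vacant] <- VACANT
  u <- matrix(runif(L * L), L, L)
  reachable <- vacant & total > 0
  p_e <- ifelse(total > 0, se / total, 0)
  new_state[reachable & u < p_e] <- EMITTER
  new_state[reachable & u >= p_e] <- NONEMITTER
  new_state
}

#' Frequency of emitters among occupied sites
#'
#' @param state Lattice state matrix with at least one occupied site.
#' @return `#emitters / #occupied`, in \[0, 1\].
#' @export
emitter_frequency <- function(state) {
  occ <- sum(state != VACANT)
  if (occ == 0) abort("emitter frequency is undefined on an all-vacant lattice.")
  sum(state == EMITTER) / occ
}

#' Long-format view of a lattice state
#'
#' @param state Lattice state matrix.
#' @return A tibble with columns `i`, `j`, `state` (factor: vacant /
#'   emitter / nonemitter).
#' @export
lattice_tbl <- function(state) {
  L <- nrow(state)
  tibble(
    i = rep(seq_len(L), times = ncol(state)),
    j = rep(seq_len(ncol(state)), each = L),
    state = factor(c("vacant", "emitter", "nonemitter")[as.vector(state) + 1L],
                   levels = c("emitter", "nonemitter", "vacant"))
  )
}

#' Write / read a lattice snapshot as plain text
#'
#' One row of characters per lattice row: `E` = emitter, `N` = non-emitter,
#' `0` = vacant.
#'
#' @param state Lattice state matrix.
#' @param path File path.
#' @return `write_snapshot()` returns `path` invisibly; `read_snapshot()`
#'   returns the integer state matrix.
#' @export
write_snapshot <- function(state, path) {
  chars <- matrix(c("0", "E", "N")[state + 1L], nrow(state), ncol(state))
  writeLines(apply(chars, 1, paste0, collapse = ""), path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  rows <- readLines(path)
  codes <- c(`0` = VACANT, E = EMITTER, N = NONEMITTER)
  m <- t(vapply(strsplit(rows, ""), function(r) unname(codes[r]),
                integer(nchar(rows[1]))))
  matrix(as.integer(m), length(rows))
}
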