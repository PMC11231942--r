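#' Gross inter-communication effect in the random distribution model
#'
#' When plants are randomly distributed, the number of emitters among the
#' `n` neighbors within signaling range is Binomial(`n`, `x_e`), and the
#' expectation of `alpha2^k` over that distribution has the closed form
#' \deqn{\bar\alpha_2 = (1 + (\alpha_2 - 1) x_E)^n.}
#'
#' @param x_e Global emitter frequency in \[0, 1\] (vectorized).
#' @param alpha2 Per-emitter damage multiplier in (0, 1].
#' @param n Expected number of neighbors within signaling range (>= 0).
#' @return The mean damage multiplier, in (0, 1].
#' @seealso [binomial_gross_inter_oracle()] for the explicit binomial sum.
#' @examples
#' gross_inter_effect_meanfield(0.3, 0.6, 8)
#' @export
gross_inter_effect_meanfield <- function(x_e, alpha2, n) {
  if (!is.numeric(x_e) || any(!is.finite(x_e)) || any(x_e < 0) || any(x_e > 1))
    abort("`x_e` must lie in [0, 1].")
  check_range(alpha2, "alpha2", 0, 1, upper_open = FALSE)
  n <- check_count(n, "n", min = 0L)
  (1 + (alpha2 - 1) * x_e)^n
}

#' Binomial-sum oracle for the mean gross inter-communication effect
#'
#' Computes the expectation of `alpha2^k` over `k ~ Binomial(n, x_e)` by
#' explicit summation over `k = 0, ..., n`. This is an independent check of
#' the closed form in [gross_inter_effect_meanfield()]; the two agree to
#' machine precision.
#'
#' @inheritParams gross_inter_effect_meanfield
#' @return The exact binomial expectation (scalar).
#' @examples
#' binomial_gross_inter_oracle(0.5, 0.5, 2)   # 0.5625
#' @export
binomial_gross_inter_oracle <- function(x_e, alpha2, n) {
  stopifnot(length(x_e) == 1L, x_e >= 0, x_e <= 1)
  check_range(alpha2, "alpha2", 0, 1, upper_open = FALSE)
  n <- check_count(n, "n", min = 0L)
  if (n > 64L) abort("`n` must be <= 64 for exact summation.")
  k <- 0:n
  sum(alpha2^k * dbinom(k, n, x_e))
}

# unvalidated fitness pair at frequency x (analytic extension outside [0,1]
# is used for finite differences at the boundary equilibria)
mf_fitness <- function(x_e, params) {
  a2bar <- (1 + (params$alpha2 - 1) * x_e)^params$n
  list(
    f_e = (1 - params$p * params$alpha1 * a2bar) * (1 - params$c) * params$fhat,
    f_n = (1 - params$p * a2bar) * params$fhat
  )
}

g_raw <- function(x_e, params) {
  f <- mf_fitness(x_e, params)
  x_e * (1 - x_e) * (f$f_e - f$f_n)
}

#' Population mean fitness
#'
#' \eqn{\phi = x_E f_E + (1 - x_E) f_N}, with both fitnesses evaluated at the
#' mean gross inter-communication effect \eqn{\bar\alpha_2(x_E)}.
#'
#' @param x_e Emitter frequency in \[0, 1\] (vectorized).
#' @param params A [bvoc_params()] object.
#' @return Mean expected seed count.
#' @examples
#' mean_fitness(0.5, bvoc_params())
#' @export
mean_fitness <- function(x_e, params) {
  stopifnot(inherits(params, "bvoc_params"))
  if (any(x_e < 0) || any(x_e > 1)) abort("`x_e` must lie in [0, 1].")
  f <- mf_fitness(x_e, params)
  x_e * f$f_e + (1 - x_e) * f$f_n
}

#' Replicator dynamics right-hand side
#'
#' The rate of change of the emitter frequency,
#' \eqn{g(x_E) = x_E (f_E - \phi) = x_E (1 - x_E)(f_E - f_N)}. It vanishes
#' at the monomorphic states \eqn{x_E = 0} and \eqn{x_E = 1} for all
#' parameter values.
#'
#' @inheritParams mean_fitness
#' @return The growth rate of `x_e` (vectorized).
#' @examples
#' replicator_rhs(c(0, 0.5, 1), bvoc_params())
#' @export
replicator_rhs <- function(x_e, params) {
  stopifnot(inherits(params, "bvoc_params"))
  if (any(x_e < 0) || any(x_e > 1)) abort("`x_e` must lie in [0, 1].")
  g_raw(x_e, params)
}

#' Interior (coexistence) equilibrium of the replicator dynamics
#'
#' Solves \eqn{f_E(x_E) = f_N(x_E)} in closed form. Equal fitness requires
#' the mean damage multiplier to hit the target
#' \eqn{\bar\alpha_2^* = c / (p (1 + (c - 1)\alpha_1))}, giving
#' \deqn{x_E^* = \frac{(\bar\alpha_2^*)^{1/n} - 1}{\alpha_2 - 1}.}
#' The equilibrium exists (lies strictly inside (0, 1)) exactly when the
#' coexistence condition holds; otherwise `NA` is returned.
#'
#' @inheritParams mean_fitness
#' @return The coexistence frequency in (0, 1), or `NA_real_` when absent.
#' @examples
#' interior_equilibrium(bvoc_params(alpha1 = 0.5, alpha2 = 0.9, n = 8))
#' @export
interior_equilibrium <- function(params) {
  stopifnot(inherits(params, "bvoc_params"))
  denom <- params$p * (1 + (params$c - 1) * params$alpha1)
  if (denom <= 0) return(NA_real_)
  target <- params$c / denom
  if (target <= 0) return(NA_real_)  # c = 0: fitnesses never cross inside
  x_star <- (target^(1 / params$n) - 1) / (params$alpha2 - 1)
  if (is.finite(x_star) && x_star > 0 && x_star < 1) x_star else NA_real_
}

#' Coexistence condition on the intra-communication effect
#'
#' Emitters and non-emitters coexist at a stable interior frequency exactly
#' when `alpha1` lies strictly between the two closed-form bounds
#' \deqn{\frac{\alpha_2^n p - c}{\alpha_2^n p (1 - c)} < \alpha_1 <
#'       \frac{p - c}{p (1 - c)}.}
#' The upper bound is the emission viability threshold; the lower bound is
#' where the fully-emitting population becomes invadable by cheaters.
#'
#' @inheritParams mean_fitness
#' @return `TRUE` iff both inequalities hold strictly.
#' @examples
#' coexistence_condition(bvoc_params(alpha1 = 0.5, alpha2 = 0.9, n = 8))
#' @export
coexistence_condition <- function(params) {
  stopifnot(inherits(params, "bvoc_params"))
  b <- regime_bounds(params)
  params$alpha1 > b$lower && params$alpha1 < b$upper
}

regime_bounds <- function(params) {
  a2n <- params$alpha2^params$n
  list(
    lower = (a2n * params$p - params$c) / (a2n * params$p * (1 - params$c)),
    upper = emission_viability_threshold(params$p, params$c)
  )
}

#' Viability threshold for the emission strategy
#'
#' Emission can evolve at all only if an isolated emitter outproduces an
#' isolated non-emitter, i.e. if its own-signal protection outweighs the
#' emission cost. That happens when
#' \deqn{\alpha_1 < \frac{p - c}{p (1 - c)}.}
#' This function returns the threshold; it is positive only when `c < p`.
#'
#' @param p Herbivory rate in (0, 1).
#' @param c Emission cost in \[0, 1).
#' @return The threshold value of `alpha1` (possibly nonpositive).
#' @examples
#' emission_viability_threshold(0.4, 0.1)   # 5/6
#' @export
emission_viability_threshold <- function(p, c) {
  check_range(p, "p", 0, 1)
  check_range(c, "c", 0, 1, lower_open = FALSE)
  (p - c) / (p * (1 - c))
}
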