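#' Model parameters for the BVOC emission game
#'
#' Bundles every symbolic parameter shared by the lattice and mean-field
#' models. Defaults follow the focal parameterization used throughout the
#' package's analyses: herbivory rate `p = 0.4`, emission cost `c = 0.1`,
#' per-step mortality `d = 0.05`, and `n = 8` expected neighbors within
#' signaling range (the Moore-1 neighborhood size).
#'
#' Both communication effects are damage *multipliers*, so smaller values mean
#' stronger protection: a plant's own signaling scales its herbivory damage by
#' `alpha1`, and each emitting neighbor scales it by a further factor of
#' `alpha2` (compounding to `alpha2^M` over `M` emitting neighbors).
#'
#' @param alpha1 Intra-communication effect, in (0, 1]. The value 1 (no
#'   own-signal benefit) is admitted so that the neutral limit
#'   `alpha1 = 1, c = 0`, in which emitters and non-emitters are exchangeable,
#'   can be simulated.
#' @param alpha2 Inter-communication effect per emitting neighbor, in (0, 1].
#'   The value 1 switches inter-communication off entirely; together with
#'   `alpha1 = 1, c = 0` it gives the fully neutral limit in which the two
#'   strategies are exchangeable. Note that `alpha1 = 1, c = 0` alone does
#'   *not* make the spatial process label-symmetric: emitters with
#'   `alpha2 < 1` still raise the fitness of their (mostly emitter)
#'   neighbors, and that assortment advantage is real selection.
#' @param p Herbivory damage rate absent any communication, in (0, 1).
#' @param c Fractional cost of BVOC emission, in \[0, 1).
#' @param fhat Seeds produced absent herbivory and emission cost (> 0). A
#'   common factor of all fitnesses; it cancels from colonization
#'   probabilities and from the sign of the replicator dynamics.
#' @param d Per-step mortality probability, in \[0, 1).
#' @param n Expected number of neighbors within signaling range
#'   (mean-field model only); positive integer.
#' @param r_bvoc Moore radius of BVOC signaling (lattice model only).
#' @param r_d Moore radius of seed dispersal (lattice model only).
#'
#' @return An object of class `bvoc_params` (a named list).
#' @examples
#' bvoc_params(alpha1 = 0.5, alpha2 = 0.9)
#' @export
bvoc_params <- function(alpha1 = 0.5, alpha2 = 0.9, p = 0.4, c = 0.1,
                        fhat = 1, d = 0.05, n = 8L, r_bvoc = 1L, r_d = 1L) {
  check_range(alpha1, "alpha1", lower = 0, upper = 1,
              lower_open = TRUE, upper_open = FALSE)
  check_range(alpha2, "alpha2", lower = 0, upper = 1, upper_open = FALSE)
  check_range(p, "p", lower = 0, upper = 1)
  check_range(c, "c", lower = 0, upper = 1, lower_open = FALSE)
  check_range(d, "d", lower = 0, upper = 1, lower_open = FALSE)
  if (!is.numeric(fhat) || length(fhat) != 1L || !is.finite(fhat) || fhat <= 0)
    abort("`fhat` must be a single positive number.")
  n <- check_count(n, "n", min = 1L)
  r_bvoc <- check_count(r_bvoc, "r_bvoc", min = 1L)
  r_d <- check_count(r_d, "r_d", min = 1L)
  structure(
    list(alpha1 = alpha1, alpha2 = alpha2, p = p, c = c, fhat = fhat,
         d = d, n = n, r_bvoc = r_bvoc, r_d = r_d),
    class = "bvoc_params"
  )
}

#' @export
print.bvoc_params <- function(x, ...) {
  cat("<bvoc_params>\n")
  cat(sprintf("  alpha1 = %g (intra-communication), alpha2 = %g (inter-communication)\n",
              x$alpha1, x$alpha2))
  cat(sprintf("  p = %g (herbivory), c = %g (emission cost), fhat = %g, d = %g (mortality)\n",
              x$p, x$c, x$fhat, x$d))
  cat(sprintf("  n = %d (mean-field neighbors), r_bvoc = %d, r_d = %d (lattice radii)\n",
              x$n, x$r_bvoc, x$r_d))
  invisible(x)
}

#' Update a subset of model parameters
#'
#' @param params A [bvoc_params()] object.
#' @param ... Named parameters to replace (revalidated).
#' @return A new `bvoc_params` object.
#' @examples
#' update_params(bvoc_params(), alpha1 = 0.2, r_bvoc = 2)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "bvoc_params"))
  new <- utils::modifyList(unclass(params), list(...))
  do.call(bvoc_params, new)
}

# range check with an error message naming the offending symbol
check_range <- function(x, name, lower, upper,
                        lower_open = TRUE, upper_open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number.", name))
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside %s%g, %g%s.", name, x,
                  if (lower_open) "(" else "[", lower, upper,
                  if (upper_open) ")" else "]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min)
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  as.integer(x)
}
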