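#' Gross inter-communication effect from a count of emitting neighbors
#'
#' A plant surrounded by `m_emitters` BVOC-emitting neighbors has its
#' herbivory damage scaled by `alpha2` once per emitter, i.e. by
#' `alpha2 ^ m_emitters`. With no emitting neighbors the effect is the empty
#' product, 1 (no damage reduction).
#'
#' @param m_emitters Number of emitting neighbors (nonnegative integer;
#'   vectorized).
#' @param alpha2 Per-emitter damage multiplier in (0, 1].
#' @return `alpha2 ^ m_emitters`, in (0, 1].
#' @examples
#' gross_inter_effect_local(0:3, 0.5)
#' @export
gross_inter_effect_local <- function(m_emitters, alpha2) {
  if (!is.numeric(m_emitters) || any(!is.finite(m_emitters)) ||
      any(m_emitters < 0) || any(m_emitters != floor(m_emitters)))
    abort("`m_emitters` must be nonnegative integer(s).")
  check_range(alpha2, "alpha2", lower = 0, upper = 1, upper_open = FALSE)
  alpha2^m_emitters
}

#' Fitness of a BVOC emitter
#'
#' Expected seed output of an emitting plant: herbivory damage `p` is
#' attenuated by the plant's own signaling (`alpha1`) and by its emitting
#' neighbors (`gross_inter`), and the whole output is discounted by the
#' emission cost `c`:
#' \deqn{f_E = (1 - p\,\alpha_1\,\hat\alpha_2)\,(1 - c)\,\hat f.}
#'
#' @param alpha1 Intra-communication effect in (0, 1].
#' @param gross_inter Gross inter-communication effect in (0, 1] (from
#'   [gross_inter_effect_local()] or [gross_inter_effect_meanfield()]).
#' @param p Herbivory rate in (0, 1).
#' @param c Emission cost in \[0, 1).
#' @param fhat Seed count absent herbivory and cost.
#' @return Expected seed count (vectorized over `gross_inter`).
#' @examples
#' fitness_emitter(0.5, 1, p = 0.4, c = 0.1)    # 0.72
#' @export
fitness_emitter <- function(alpha1, gross_inter, p, c, fhat = 1) {
  check_range(alpha1, "alpha1", 0, 1, upper_open = FALSE)
  check_gross_inter(gross_inter)
  check_range(p, "p", 0, 1)
  check_range(c, "c", 0, 1, lower_open = FALSE)
  (1 - p * alpha1 * gross_inter) * (1 - c) * fhat
}

#' Fitness of a BVOC non-emitter
#'
#' Expected seed output of a non-emitting plant (a potential cheater): it
#' pays no emission cost and gets no own-signal protection, but still
#' benefits from emitting neighbors through `gross_inter`:
#' \deqn{f_N = (1 - p\,\hat\alpha_2)\,\hat f.}
#' A vacant site has fitness 0 by convention.
#'
#' @inheritParams fitness_emitter
#' @return Expected seed count (vectorized over `gross_inter`).
#' @examples
#' fitness_nonemitter(0.25, p = 0.4)            # 0.9
#' @export
fitness_nonemitter <- function(gross_inter, p, fhat = 1) {
  check_gross_inter(gross_inter)
  check_range(p, "p", 0, 1)
  (1 - p * gross_inter) * fhat
}

check_gross_inter <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x > 1))
    abort("`gross_inter` must lie in (0, 1].")
  invisible(x)
}
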