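# Random valid parameter draws used by property-style tests.
# All draws use the caller's RNG state; tests set their own seeds.

random_params <- function(n_max = 20L, alpha1_range = c(0.02, 0.98)) {
  bvoc_params(
    alpha1 = runif(1, alpha1_range[1], alpha1_range[2]),
    alpha2 = runif(1, 0.02, 0.98),
    p = runif(1, 0.05, 0.95),
    c = runif(1, 0.02, 0.9),
    n = sample.int(n_max, 1)
  )
}

# mean-field fitness pair at frequency x, built from the exported core
# fitness functions (independent of the internal mf_fitness helper)
mf_pair <- function(x, params) {
  a2bar <- gross_inter_effect_meanfield(x, params$alpha2, params$n)
  list(
    f_e = fitness_emitter(params$alpha1, a2bar, params$p, params$c, params$fhat),
    f_n = fitness_nonemitter(a2bar, params$p, params$fhat)
  )
}

# an 8x8 checkerboard of emitters and non-emitters (no vacancies)
checkerboard_lattice <- function(L = 8L) {
  idx <- outer(seq_len(L), seq_len(L), `+`)
  matrix(ifelse(idx %% 2 == 0, EMITTER, NONEMITTER), L, L)
}
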