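# Shared fixtures and independent oracles, all built in code.

# Classical infinite-sites mutation-selection-balance prediction for the
# baseline inbreeding depression of a fully outcrossing population:
# heterozygous load is Poisson with mean U/(h s); a selfed offspring keeps a
# parental heterozygous mutation het with prob 1/2, makes it homozygous with
# prob 1/4 and loses it with prob 1/4, so per-mutation fitness factors are
# 1 - hs/2 - s/4 (selfed) vs 1 - hs (outcrossed, transmission prob 1/2 from
# each parent); Poisson thinning and the shared new-mutation factor give
# delta0 = 1 - exp(-U (1 - 2h) / (4h)).
msb_delta0 <- function(U, h) 1 - exp(-U * (1 - 2 * h) / (4 * h))

# Minimal parameter set for unit tests.
toy_params <- function(...) {
  args <- list(...)
  defaults <- list(N = 100, U = 0, s = 0.2, h = 0.1, L = 10, n_z = 10,
                   U_z = 0, k = 3, z_c = 0, lambda = 0, generations = 10,
                   window = 5, seed = 1)
  defaults[names(args)] <- args
  do.call(sim_params, defaults)
}

# An individual with chosen deleterious positions and uniform trait alleles.
toy_individual <- function(params, pos1 = numeric(0), pos2 = numeric(0),
                           trait = 1L) {
  new_individual(haplotype(rep(trait, params$n_z), pos1),
                 haplotype(rep(trait, params$n_z), pos2), params)
}

# Wrap a list of individuals as a population.
as_population <- function(inds, generation = 0L) {
  structure(list(individuals = inds, generation = generation),
            class = "population")
}

# Deterministic family table with exactly linear fitness functions of alpha.
linear_family_table <- function(n = 101, a = 0.7, b = -0.2, c = 0.9,
                                d = 0.1, alpha = seq(0.1, 0.9, length.out = n)) {
  data.frame(alpha = alpha, w_self = a + b * alpha, w_out = c + d * alpha)
}
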