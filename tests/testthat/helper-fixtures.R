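# small shared fixtures, built in code

quiet_simulate <- function(...) suppressWarnings(simulate_library(...))

small_refs <- function(seed = 101, n_te = 3, n_infra = 3, n_hp = 2) {
  make_references(n_te = n_te, n_infra = n_infra, n_hp = n_hp, seed = seed)
}

small_library <- function(genotype = genotype_wildtype(), seed = 202,
                          n_pirna = 2000, n_sirna = 1000,
                          n_infrastructural = 500, refs = small_refs(), ...) {
  spec <- library_spec(genotype, n_pirna = n_pirna, n_sirna = n_sirna,
                       n_infrastructural = n_infrastructural, seed = seed,
                       ...)
  quiet_simulate(refs, spec)
}
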