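# Shared fixtures, built once per test session.

# the flux-profiling fixture: a larger toy with per-gene expression burden
# (so every knockout's parsimonious flux vector is distinct), simulated
# under base medium plus vitamin supplements, with recorded fluxes
ml_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      toy <- build_toy_gem(
        toy_gem_config(n_carbons = 10, n_pathway_genes = 5,
                       n_yield_motifs = 3, include_maintenance = TRUE),
        verify = FALSE)
      fit <- simulate_fitness(toy$truth, fitness_gen_config(seed = 2))
      scen <- scenario_spec(medium = toy$medium,
                            supplements = toy$corrections$supplements)
      sim <- simulate_predictions(toy$model, fit, scen,
                                  filter_unconditional = FALSE,
                                  record_fluxes = TRUE)
      fm <- assemble_flux_matrix(sim)
      cl <- filter_and_cluster(fm)
      cache <<- list(toy = toy, fitness = fit, sim = sim,
                     fm = fm, clusters = cl,
                     planted = "EX_nut1_e")
    }
    cache
  }
})

# scenario builders for the default toy
toy_scenarios <- function(toy) {
  list(
    uncorrected = scenario_spec(medium = toy$medium),
    supplements = scenario_spec(medium = toy$medium,
                                supplements = toy$corrections$supplements),
    isoenzyme = scenario_spec(medium = toy$medium,
                              isoenzyme_reassign = toy$corrections$isoenzyme_reassign),
    irreversible = scenario_spec(medium = toy$medium,
                                 irreversible = toy$corrections$irreversible),
    combined = scenario_spec(medium = toy$medium,
                             supplements = toy$corrections$supplements,
                             isoenzyme_reassign = toy$corrections$isoenzyme_reassign,
                             irreversible = toy$corrections$irreversible))
}
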