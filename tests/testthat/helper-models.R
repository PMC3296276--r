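# tiny fixture networks built in code

birth_death_model <- function(k = 10, g = 1, horizon = 5, init = 0) {
  model_definition(
    "birth_death",
    species = list(ad_species("A", initial_count = init)),
    reactions = list(
      ad_reaction("birth", products = c(A = 1), rate_parameter = "k"),
      ad_reaction("death", reactants = c(A = 1), rate_parameter = "g")),
    parameters = list(ad_parameter("k", k), ad_parameter("g", g)),
    horizon = horizon)
}

# open two-species chain 0 -> A -> B -> 0; linear, so the CME solution
# is product-Poisson with analytically known means
chain_model <- function(k = 20, c = 2, g = 1, horizon = 3) {
  model_definition(
    "chain",
    species = list(ad_species("A"), ad_species("B")),
    reactions = list(
      ad_reaction("in", products = c(A = 1), rate_parameter = "k"),
      ad_reaction("conv", reactants = c(A = 1), products = c(B = 1),
                  rate_parameter = "c"),
      ad_reaction("out", reactants = c(B = 1), rate_parameter = "g")),
    parameters = list(ad_parameter("k", k), ad_parameter("c", c),
                      ad_parameter("g", g)),
    horizon = horizon)
}

frozen_model <- function(init = c(A = 7)) {
  model_definition(
    "frozen",
    species = list(ad_species("A", initial_count = init[["A"]])),
    reactions = list(),
    parameters = list(),
    horizon = 2)
}

# shared heavyweight ensembles, computed once per test session
.ens_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.ens_cache[[key]])) .ens_cache[[key]] <- force(expr)
  .ens_cache[[key]]
}
cached_sweep <- function() {
  cached("sweep", run_clearance_sweep(n_runs = 100, base_seed = 1))
}
cached_day0 <- function() cached_sweep()$day_0
cached_none <- function() cached_sweep()$none
cached_elevated <- function() {
  cached("elev", {
    m <- elevated_network("abeta_production")
    ens <- run_ensemble(m, 100, 8)
    ens$trajectories
  })
}
end_mean_of <- function(summary, obs) {
  unname(summary$mean_series[obs, ncol(summary$mean_series)])
}
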